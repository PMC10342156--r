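#' Configuration for the synthetic follicle/granulosa dataset
#'
#' Defaults encode the data regime the pipeline targets: two lineages
#' (follicle, granulosa) by two stages (primordial, primary), a handful to a
#' few dozen cells per group, sparse non-negative expression on the
#' log2(FPKM+1) scale, a small set of stage-shifted lncRNAs per lineage,
#' co-expressed target-gene modules driven by latent factors that also
#' separate the stages, pathway graphs containing planted activated modules,
#' and a disease gene list enriched in those modules.
#'
#' @param n_cells_per_group Cells per (lineage, stage) group.
#' @param n_pc_genes,n_lnc_genes,n_mirnas Feature counts.
#' @param n_planted_de_lnc Stage-shifted lncRNAs (split between lineages).
#' @param de_shift Added to planted lncRNAs in the primary stage of their
#'   lineage (log2 units).
#' @param n_clusters_per_lnc,cluster_size Planted co-expression clusters per
#'   planted lncRNA and genes per cluster (>= 3).
#' @param cluster_rho Target within-cluster (within-stage) Pearson
#'   correlation in (0, 1).
#' @param cluster_factor_sd Standard deviation of the shared latent
#'   factor's contribution to each cluster gene (log2 units). Together
#'   with `cluster_rho` this fixes the cluster-gene noise
#'   `s = cluster_factor_sd * sqrt((1-rho)/rho)`, so the within-stage
#'   correlation is `a^2/(a^2+s^2) = cluster_rho` exactly. The default is
#'   small relative to `activity_shift`: planted clusters model the
#'   tightly co-regulated, strongly stage-discriminative modules the
#'   pipeline is designed to retain.
#' @param shared_mirnas_per_pair miRNAs guaranteed shared for each planted
#'   (lncRNA, mRNA) pair.
#' @param n_pathways,module_size Pathway graphs and genes per dense module
#'   (>= 3, and >= `cluster_size`).
#' @param activity_shift Mean stage difference (log2 units) given to every
#'   planted module gene.
#' @param dropout_rate Gene-by-cell Bernoulli zeroing probability for
#'   background genes (planted signal genes are exempt, so planted effects
#'   keep their nominal sizes and survive the expressed-feature filter by
#'   construction).
#' @param noise_sd Per-value Gaussian noise standard deviation (log2 units).
#' @param mirna_set_mean Poisson mean of per-transcript miRNA set sizes.
#' @param n_poi_genes Size of the simulated disease (POI) gene list; at
#'   least half is drawn from planted module genes.
#' @param seed Integer seed; the same seed reproduces the full bundle.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_cells_per_group = 15,
                              n_pc_genes = 500,
                              n_lnc_genes = 60,
                              n_mirnas = 200,
                              n_planted_de_lnc = 6,
                              de_shift = 1.5,
                              n_clusters_per_lnc = 2,
                              cluster_size = 5,
                              cluster_rho = 0.85,
                              cluster_factor_sd = 0.35,
                              shared_mirnas_per_pair = 8,
                              n_pathways = 8,
                              module_size = 8,
                              activity_shift = 1.0,
                              dropout_rate = 0.3,
                              noise_sd = 0.6,
                              mirna_set_mean = 15,
                              n_poi_genes = 20,
                              seed = 1L) {
  cfg <- list(n_cells_per_group = n_cells_per_group, n_pc_genes = n_pc_genes,
              n_lnc_genes = n_lnc_genes, n_mirnas = n_mirnas,
              n_planted_de_lnc = n_planted_de_lnc, de_shift = de_shift,
              n_clusters_per_lnc = n_clusters_per_lnc,
              cluster_size = cluster_size, cluster_rho = cluster_rho,
              cluster_factor_sd = cluster_factor_sd,
              shared_mirnas_per_pair = shared_mirnas_per_pair,
              n_pathways = n_pathways, module_size = module_size,
              activity_shift = activity_shift, dropout_rate = dropout_rate,
              noise_sd = noise_sd, mirna_set_mean = mirna_set_mean,
              n_poi_genes = n_poi_genes, seed = as.integer(seed))
  counts <- c("n_cells_per_group", "n_pc_genes", "n_lnc_genes", "n_mirnas",
              "n_pathways", "mirna_set_mean")
  for (f in counts)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 1)
      stop("'", f, "' must be a positive count")
  for (f in c("n_planted_de_lnc", "n_clusters_per_lnc",
              "shared_mirnas_per_pair", "n_poi_genes"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0)
      stop("'", f, "' must be a non-negative count")
  if (cfg$dropout_rate < 0 || cfg$dropout_rate > 1)
    stop("'dropout_rate' must be a probability in [0, 1]")
  if (cfg$cluster_rho <= 0 || cfg$cluster_rho >= 1)
    stop("'cluster_rho' must lie strictly in (0, 1)")
  if (cfg$cluster_size < 3)
    stop("'cluster_size' must be at least 3")
  if (cfg$module_size < 3)
    stop("'module_size' must be at least 3 (minimum subpathway size)")
  if (cfg$module_size < cfg$cluster_size)
    stop("'module_size' must be at least 'cluster_size'")
  if (cfg$noise_sd < 0) stop("'noise_sd' must be non-negative")
  if (cfg$cluster_factor_sd < 0) stop("'cluster_factor_sd' must be non-negative")
  if (cfg$shared_mirnas_per_pair > cfg$n_mirnas)
    stop("'shared_mirnas_per_pair' exceeds the miRNA universe")
  needed <- cfg$n_planted_de_lnc * cfg$n_clusters_per_lnc * cfg$module_size
  if (needed > cfg$n_pc_genes)
    stop("planted cluster/module demands (", needed,
         " genes) exceed n_pc_genes (", cfg$n_pc_genes, ")")
  if (cfg$n_planted_de_lnc > cfg$n_lnc_genes)
    stop("'n_planted_de_lnc' exceeds 'n_lnc_genes'")
  structure(cfg, class = "simulation_config")
}

#' Generate the synthetic expression matrix with planted structure
#'
#' Draws per-gene baseline means from a right-skewed Gamma, adds Gaussian
#' noise per value, truncates at zero and applies Bernoulli dropout to
#' background genes. Planted lncRNAs get `de_shift` added in the primary
#' stage of their lineage. Each planted cluster's genes share a per-cell
#' latent factor with loading `a = cluster_factor_sd` and independent
#' noise `s = a * sqrt((1-rho)/rho)`, so the expected within-stage
#' within-cluster correlation is `a^2/(a^2 + s^2) = cluster_rho`; every
#' planted module gene (cluster members and their module companions) is
#' additionally shifted by `activity_shift` in the primary stage, making
#' the module both co-expressed and stage-discriminative.
#'
#' @param cfg A [simulation_config()].
#' @return List with `expression` (an `ExpressionMatrix`) and `truth` (the
#'   partial ground-truth record: planted lncRNAs per lineage, planted
#'   (lncRNA, mRNA) pairs, planted clusters and planted modules).
#' @export
generate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  pc  <- sprintf("PCG%04d", seq_len(cfg$n_pc_genes))
  lnc <- sprintf("LNC%03d", seq_len(cfg$n_lnc_genes))
  genes <- c(pc, lnc)
  groups <- expand.grid(stage = STAGE_LEVELS[1:2], lineage = LINEAGE_LEVELS,
                        stringsAsFactors = FALSE)[, c("lineage", "stage")]
  cells <- character(0); lineage <- character(0); stage <- character(0)
  for (i in seq_len(nrow(groups))) {
    ids <- sprintf("%s_%s_%02d", substr(groups$lineage[i], 1, 3),
                   groups$stage[i], seq_len(cfg$n_cells_per_group))
    cells <- c(cells, ids)
    lineage <- c(lineage, rep(groups$lineage[i], length(ids)))
    stage <- c(stage, rep(groups$stage[i], length(ids)))
  }
  n_g <- length(genes); n_c <- length(cells)

  ## Planting plan: stage-shifted lncRNAs split between lineages; disjoint
  ## clusters (and module companions) carved out of the protein-coding pool.
  planted_lnc <- if (cfg$n_planted_de_lnc > 0)
    sample(lnc, cfg$n_planted_de_lnc) else character(0)
  lnc_lineage <- rep(LINEAGE_LEVELS, length.out = length(planted_lnc))
  pool <- sample(pc)  # shuffled protein-coding pool to carve modules from
  take <- function(k) { out <- pool[seq_len(k)]; pool <<- pool[-seq_len(k)]; out }
  clusters <- list(); modules <- list()
  for (j in seq_along(planted_lnc)) {
    L <- planted_lnc[j]
    clusters[[L]] <- list()
    for (ci in seq_len(cfg$n_clusters_per_lnc)) {
      cl_genes <- take(cfg$cluster_size)
      comp <- take(cfg$module_size - cfg$cluster_size)
      clusters[[L]][[ci]] <- cl_genes
      modules[[length(modules) + 1L]] <- list(
        lncRNA = L, lineage = lnc_lineage[j], cluster_index = ci,
        cluster_genes = cl_genes, companion_genes = comp,
        genes = c(cl_genes, comp))
    }
  }

  mu <- stats::setNames(stats::rgamma(n_g, shape = 2, rate = 0.7), genes)
  vals <- matrix(mu, n_g, n_c, dimnames = list(genes, cells)) +
    cfg$noise_sd * matrix(stats::rnorm(n_g * n_c), n_g, n_c)

  primary <- stage == "primary"
  for (j in seq_along(planted_lnc))
    vals[planted_lnc[j], primary & lineage == lnc_lineage[j]] <-
      vals[planted_lnc[j], primary & lineage == lnc_lineage[j]] + cfg$de_shift

  a <- cfg$cluster_factor_sd
  s <- a * sqrt((1 - cfg$cluster_rho) / cfg$cluster_rho)
  for (mod in modules) {
    in_lin <- lineage == mod$lineage
    shift <- cfg$activity_shift * (primary & in_lin)
    f <- stats::rnorm(sum(in_lin))  # shared latent factor, one value per cell
    for (g in mod$cluster_genes)
      vals[g, in_lin] <- mu[g] + a * f + s * stats::rnorm(sum(in_lin))
    vals[mod$cluster_genes, ] <-
      vals[mod$cluster_genes, , drop = FALSE] +
      matrix(shift, length(mod$cluster_genes), n_c, byrow = TRUE)
    for (g in mod$companion_genes)
      vals[g, ] <- vals[g, ] + shift
  }

  vals <- pmax(vals, 0)

  planted_rows <- unique(c(planted_lnc, unlist(lapply(modules, `[[`, "genes"))))
  if (cfg$dropout_rate > 0) {
    keep <- matrix(stats::rbinom(n_g * n_c, 1, 1 - cfg$dropout_rate), n_g, n_c)
    keep[rownames(vals) %in% planted_rows, ] <- 1
    vals <- vals * keep
  }

  mat <- expression_matrix(
    vals,
    gene_biotype = stats::setNames(
      c(rep("protein_coding", length(pc)), rep("lncRNA", length(lnc))), genes),
    cell_lineage = stats::setNames(lineage, cells),
    cell_stage = stats::setNames(stage, cells))

  pairs <- do.call(rbind, c(list(
    data.frame(lncRNA = character(), mRNA = character())),
    lapply(modules, function(m)
      data.frame(lncRNA = m$lncRNA, mRNA = m$cluster_genes,
                 stringsAsFactors = FALSE))))
  truth <- list(
    planted_de_lnc = split(planted_lnc, factor(lnc_lineage, LINEAGE_LEVELS)),
    planted_pairs = pairs,
    planted_clusters = clusters,
    planted_modules = modules,
    gene_ids = list(protein_coding = pc, lncRNA = lnc))
  list(expression = mat, truth = truth)
}

#' Generate the synthetic miRNA interaction table
#'
#' Every transcript receives a random miRNA set with Poisson-distributed
#' size (mean `mirna_set_mean`). For each planted (lncRNA, mRNA) pair the
#' mRNA's set is seeded with `shared_mirnas_per_pair` members of that
#' lncRNA's set before random fill, so planted pairs share miRNAs well
#' beyond chance; all other sets are uniform draws from the universe.
#'
#' @param cfg A [simulation_config()].
#' @param truth Partial ground truth from [generate_expression()].
#' @return An `InteractionTable` with `universe_m = n_mirnas`.
#' @export
generate_interactions <- function(cfg, truth) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed + 1L)
  mirnas <- sprintf("miR-%03d", seq_len(cfg$n_mirnas))
  draw_size <- function(n) pmin(cfg$n_mirnas,
                                pmax(1L, stats::rpois(n, cfg$mirna_set_mean)))
  lncs <- truth$gene_ids$lncRNA
  planted_lnc <- unique(truth$planted_pairs$lncRNA)
  lnc_sets <- stats::setNames(vector("list", length(lncs)), lncs)
  for (L in lncs) {
    size <- if (L %in% planted_lnc)
      min(cfg$n_mirnas,
          cfg$shared_mirnas_per_pair +
            stats::rpois(1, max(0, cfg$mirna_set_mean -
                                     cfg$shared_mirnas_per_pair)))
    else draw_size(1)
    lnc_sets[[L]] <- sample(mirnas, size)
  }
  bad <- planted_lnc[vapply(lnc_sets[planted_lnc], length, 1L) <
                       cfg$shared_mirnas_per_pair]
  if (length(bad))
    stop("shared_mirnas_per_pair exceeds the miRNA set size of lncRNA(s): ",
         paste(bad, collapse = ", "))

  mrnas <- truth$gene_ids$protein_coding
  pair_lnc <- stats::setNames(truth$planted_pairs$lncRNA,
                              truth$planted_pairs$mRNA)
  mrna_sets <- stats::setNames(vector("list", length(mrnas)), mrnas)
  for (g in mrnas) {
    size <- draw_size(1)
    if (g %in% names(pair_lnc)) {
      host <- lnc_sets[[pair_lnc[[g]]]]
      shared <- sample(host, cfg$shared_mirnas_per_pair)
      rest <- setdiff(mirnas, shared)
      extra <- max(0, size - length(shared))
      mrna_sets[[g]] <- c(shared, sample(rest, min(extra, length(rest))))
    } else {
      mrna_sets[[g]] <- sample(mirnas, size)
    }
  }
  interaction_table(
    data.frame(mirna = unlist(mrna_sets, use.names = FALSE),
               target = rep(mrnas, lengths(mrna_sets))),
    data.frame(mirna = unlist(lnc_sets, use.names = FALSE),
               target = rep(lncs, lengths(lnc_sets))),
    universe_m = cfg$n_mirnas)
}

## Erdos-Renyi dense block over `nodes` (edge prob 0.9), resampled until the
## block has diameter <= 2, so module recovery by distance-k cliques is
## guaranteed by construction.
dense_module_edges <- function(nodes) {
  s <- length(nodes)
  pairs <- t(utils::combn(nodes, 2))
  repeat {
    keep <- stats::runif(nrow(pairs)) < 0.9
    edges <- pairs[keep, , drop = FALSE]
    d <- matrix(Inf, s, s, dimnames = list(nodes, nodes))
    diag(d) <- 0
    d[edges] <- 1; d[edges[, c(2, 1), drop = FALSE]] <- 1
    for (v in nodes)  # two-hop closure is enough to test diameter <= 2
      d[d[, v] == 1, d[v, ] == 1] <- pmin(d[d[, v] == 1, d[v, ] == 1], 2)
    if (all(d <= 2)) return(edges)
  }
}

#' Generate pathway graphs containing the planted activated modules
#'
#' Each pathway is a chain of dense modules (Erdos-Renyi blocks with edge
#' probability 0.9, resampled to diameter <= 2) joined by single-edge
#' bridges. Planted modules (one per planted target cluster, containing the
#' cluster genes plus their stage-shifted companions) are distributed
#' round-robin over the pathways and padded with background modules of
#' unshifted genes. Completes the ground truth with the pathway assignment,
#' the planted (lncRNA, pathway) links, and a POI gene list drawn at least
#' half from planted module genes.
#'
#' @param cfg A [simulation_config()].
#' @param truth Partial ground truth from [generate_expression()].
#' @return List with `pathways` (list of `PathwayGraph`) and the completed
#'   `truth` (adds `planted_active_subpathways`, `planted_links`,
#'   `poi_genes`).
#' @export
generate_pathways <- function(cfg, truth) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed + 2L)
  pids <- sprintf("path%02d", seq_len(cfg$n_pathways))
  planted <- truth$planted_modules
  planted_genes <- unlist(lapply(planted, `[[`, "genes"))
  background_pool <- sample(setdiff(truth$gene_ids$protein_coding,
                                    planted_genes))

  ## round-robin planted modules, pad every pathway to >= 2 modules
  assignment <- stats::setNames(vector("list", length(pids)), pids)
  for (i in seq_along(planted)) {
    p <- pids[((i - 1) %% length(pids)) + 1]
    planted[[i]]$pathway_id <- p
    assignment[[p]] <- c(assignment[[p]], list(planted[[i]]))
  }
  for (p in pids) {
    while (length(assignment[[p]]) < 2 &&
           length(background_pool) >= cfg$module_size) {
      g <- background_pool[seq_len(cfg$module_size)]
      background_pool <- background_pool[-seq_len(cfg$module_size)]
      assignment[[p]] <- c(assignment[[p]],
                           list(list(lncRNA = NA, genes = g)))
    }
    if (!length(assignment[[p]]))
      stop("not enough protein-coding genes to populate pathway ", p)
  }

  graphs <- lapply(pids, function(p) {
    mods <- assignment[[p]]
    edges <- do.call(rbind, lapply(mods, function(m) dense_module_edges(m$genes)))
    if (length(mods) > 1)  # single-edge bridges chaining consecutive modules
      for (i in seq_len(length(mods) - 1))
        edges <- rbind(edges, c(sample(mods[[i]]$genes, 1),
                                sample(mods[[i + 1]]$genes, 1)))
    pathway_graph(p, edges,
                  nodes = unique(unlist(lapply(mods, `[[`, "genes"))))
  })

  planted_module_genes <- unique(planted_genes)
  n_from_planted <- min(length(planted_module_genes),
                        ceiling(cfg$n_poi_genes / 2))
  poi <- sample(planted_module_genes, n_from_planted)
  rest <- setdiff(truth$gene_ids$protein_coding, poi)
  poi <- sort(c(poi, sample(rest, min(length(rest),
                                      cfg$n_poi_genes - n_from_planted))))

  truth$planted_modules <- planted
  truth$planted_active_subpathways <- lapply(planted, function(m)
    list(pathway_id = m$pathway_id, lncRNA = m$lncRNA,
         lineage = m$lineage, genes = m$genes))
  links <- unique(do.call(rbind, c(
    list(data.frame(lncRNA = character(), pathway_id = character())),
    lapply(planted, function(m)
      data.frame(lncRNA = m$lncRNA, pathway_id = m$pathway_id,
                 stringsAsFactors = FALSE)))))
  rownames(links) <- NULL
  truth$planted_links <- links
  truth$poi_genes <- poi
  list(pathways = graphs, truth = truth)
}

#' Generate the full synthetic input bundle
#'
#' Runs [generate_expression()], [generate_interactions()] and
#' [generate_pathways()] under the configuration's seed and returns the
#' complete bundle with ground truth.
#'
#' @param cfg A [simulation_config()].
#' @return List with `expression`, `interactions`, `pathways`, `truth` and
#'   `config`.
#' @export
simulate_dataset <- function(cfg) {
  ge <- generate_expression(cfg)
  tbl <- generate_interactions(cfg, ge$truth)
  pw <- generate_pathways(cfg, ge$truth)
  list(expression = ge$expression, interactions = tbl,
       pathways = pw$pathways, truth = pw$truth, config = cfg)
}
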