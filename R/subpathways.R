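#' Extract distance-k clique subpathways from a pathway graph
#'
#' A subpathway is a maximal node set in which every pair of genes lies
#' within shortest-path distance `k` of each other inside the pathway
#' graph. Found by building the k-th graph power (edge iff distance <= k)
#' and enumerating its maximal cliques; sets smaller than `min_size` are
#' discarded. Ids are `<pathway_id>_<i>` with subpathways ordered by
#' descending size, then lexicographically.
#'
#' @param graph A `PathwayGraph`.
#' @param k Maximum within-subpathway shortest-path distance.
#' @param min_size Minimum subpathway size (>= 3 by the method's
#'   convention).
#' @return List of `Subpathway` objects: each a list with `subpathway_id`,
#'   `pathway_id`, `genes` (sorted).
#' @export
extract_k_clique_subpathways <- function(graph, k = 4, min_size = 3) {
  stopifnot(inherits(graph, "PathwayGraph"))
  if (k < 1) stop("'k' must be at least 1")
  if (!length(graph$nodes) || !nrow(graph$edges)) return(list())
  g <- igraph::graph_from_edgelist(graph$edges, directed = FALSE)
  isolated <- setdiff(graph$nodes, igraph::V(g)$name)
  if (length(isolated))
    g <- igraph::add_vertices(g, length(isolated), name = isolated)
  d <- igraph::distances(g)
  adj <- d <= k & d > 0
  gp <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cl <- igraph::max_cliques(gp, min = min_size)
  sets <- unique(lapply(cl, function(v) sort(igraph::V(gp)$name[v])))
  if (!length(sets)) return(list())
  keys <- vapply(sets, paste, "", collapse = "\r")
  sets <- sets[order(-lengths(sets), keys)]
  lapply(seq_along(sets), function(i)
    structure(list(subpathway_id = paste0(graph$pathway_id, "_", i),
                   pathway_id = graph$pathway_id, genes = sets[[i]]),
              class = "Subpathway"))
}

#' @export
print.Subpathway <- function(x, ...) {
  cat("Subpathway ", x$subpathway_id, ": ", length(x$genes), " genes\n",
      sep = "")
  invisible(x)
}

#' Per-gene Welch t statistics between two cell groups
#'
#' Welch (unequal-variance) two-sample t per gene, oriented
#' `group_b - group_a` (pass primordial cells as `group_a` and primary as
#' `group_b` to get the activation orientation). Genes with zero variance
#' in both groups get t = 0 when the means agree; when the means differ
#' the statistic is undefined and reported as a signed infinity sentinel
#' with a warning (such genes are excluded from activity averaging).
#'
#' @param mat An `ExpressionMatrix`.
#' @param group_a,group_b Cell id vectors, each with >= 2 cells.
#' @param genes Gene ids; default all.
#' @return Named numeric vector of t statistics.
#' @export
gene_t_scores <- function(mat, group_a, group_b,
                          genes = rownames(mat$values)) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("both groups need at least 2 cells")
  va <- mat$values[genes, group_a, drop = FALSE]
  vb <- mat$values[genes, group_b, drop = FALSE]
  ma <- rowMeans(va); mb <- rowMeans(vb)
  sa <- apply(va, 1, stats::var); sb <- apply(vb, 1, stats::var)
  se <- sqrt(sa / length(group_a) + sb / length(group_b))
  t <- (mb - ma) / se
  degen <- se == 0
  t[degen & mb == ma] <- 0
  if (any(degen & mb != ma)) {
    warning(sum(degen & mb != ma),
            " zero-variance gene(s) with unequal means reported as ",
            "infinite t and excluded from activity averaging")
    t[degen & mb != ma] <- sign(mb - ma)[degen & mb != ma] * Inf
  }
  stats::setNames(t, genes)
}

#' Subpathway activity: mean per-gene t statistic
#'
#' @param t_scores Per-gene t statistics (non-finite entries are dropped
#'   with the count of genes actually averaged recorded).
#' @return Numeric activity score with attribute `n` (genes averaged).
#' @export
subpathway_activity <- function(t_scores) {
  t <- t_scores[is.finite(t_scores)]
  if (!length(t)) stop("no finite t-scores to average")
  structure(mean(t), n = length(t))
}

#' Permutation p-value for a subpathway's activity
#'
#' Competitive null: draw `B` random gene sets of the subpathway's size,
#' without replacement, from all measured genes (genome-wide pool), and
#' compare absolute activities. Add-one smoothing keeps the p-value in
#' `[1/(B+1), 1]`.
#'
#' @param mat An `ExpressionMatrix`.
#' @param subpathway_genes Gene set to score.
#' @param group_a,group_b Cell groups for the stage contrast.
#' @param B Number of permutations.
#' @param seed Integer seed.
#' @param t_all Optional precomputed [gene_t_scores()] over all measured
#'   genes (avoids recomputation when scoring many subpathways).
#' @return Two-sided permutation p-value in (0, 1].
#' @export
permutation_pvalue <- function(mat, subpathway_genes, group_a, group_b,
                               B = 1000, seed = 1L, t_all = NULL) {
  if (B < 1) stop("'B' must be at least 1")
  if (is.null(t_all))
    t_all <- suppressWarnings(gene_t_scores(mat, group_a, group_b))
  t_all <- t_all[is.finite(t_all)]
  genes <- intersect(subpathway_genes, names(t_all))
  n <- length(genes)
  if (n == 0) stop("no measured genes in the subpathway")
  if (n > length(t_all))
    stop("subpathway size exceeds the measured-gene pool")
  obs <- mean(t_all[genes])
  set.seed(seed)
  perm <- vapply(seq_len(B), function(b)
    mean(t_all[sample.int(length(t_all), n)]), numeric(1))
  (1 + sum(abs(perm) >= abs(obs))) / (B + 1)
}

#' Score activity and permutation significance for many subpathways
#'
#' Computes the Welch t statistics once and scores every subpathway's
#' activity (mean t of its measured genes) with a seeded permutation
#' p-value ([permutation_pvalue()]; the i-th subpathway uses `seed + i`).
#'
#' @param mat An `ExpressionMatrix`.
#' @param subpathways List of `Subpathway` (or named list of gene sets).
#' @param group_a,group_b Cell groups for the stage contrast (primordial,
#'   primary).
#' @param B Permutations per subpathway.
#' @param seed Integer base seed.
#' @return A `SubpathwayActivityTable` data frame: `subpathway_id`,
#'   `pathway_id`, `n`, `activity`, `perm_p`; attribute `t_scores` holds
#'   the per-gene t vector used.
#' @export
subpathway_activity_table <- function(mat, subpathways, group_a, group_b,
                                      B = 1000, seed = 1L) {
  t_all <- suppressWarnings(gene_t_scores(mat, group_a, group_b))
  t_fin <- t_all[is.finite(t_all)]
  rows <- lapply(seq_along(subpathways), function(i) {
    sp <- subpathways[[i]]
    if (!is.list(sp))
      sp <- list(subpathway_id = names(subpathways)[i],
                 pathway_id = NA_character_, genes = sp)
    genes <- intersect(sp$genes, names(t_fin))
    if (!length(genes)) return(NULL)
    act <- subpathway_activity(t_fin[genes])
    p <- permutation_pvalue(mat, genes, group_a, group_b, B = B,
                            seed = seed + i, t_all = t_fin)
    data.frame(subpathway_id = sp$subpathway_id, pathway_id = sp$pathway_id,
               n = attr(act, "n"), activity = as.numeric(act), perm_p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(list(data.frame(
    subpathway_id = character(), pathway_id = character(), n = integer(),
    activity = numeric(), perm_p = numeric())), rows))
  rownames(out) <- NULL
  structure(out, t_scores = t_all,
            class = c("SubpathwayActivityTable", "data.frame"))
}

#' Cell-type specificity of subpathway expression
#'
#' `specificity[i, j] = E_ij / E_i` where `E_ij` is the mean expression of
#' subpathway i's genes over the cells of type j and `E_i` the mean over
#' all cells. Because `E_i` is the cell-count-weighted mixture of the
#' `E_ij`, the weighted specificities of a defined row sum to 1. Rows with
#' `E_i = 0` are undefined (NA) and flagged.
#'
#' @param mat An `ExpressionMatrix`.
#' @param subpathways List of `Subpathway` (or named list of gene sets).
#' @param cell_types Factor (or character) over the matrix's cells
#'   partitioning them into types; every type must be non-empty.
#' @return A `SpecificityMatrix`: list with `specificity` (subpathway x
#'   type), `E` (mean expression per type), `E_overall`, `n_cells` (per
#'   type) and `undefined` (subpathway ids with `E_i = 0`).
#' @export
pathway_specificity <- function(mat, subpathways, cell_types) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  cell_types <- as.factor(cell_types)
  if (length(cell_types) != ncol(mat$values))
    stop("'cell_types' must label every cell")
  if (any(table(cell_types) == 0)) stop("every cell type must be non-empty")
  ids <- vapply(seq_along(subpathways), function(i) {
    sp <- subpathways[[i]]
    if (is.list(sp)) sp$subpathway_id else names(subpathways)[i]
  }, "")
  types <- levels(cell_types)
  E <- matrix(NA_real_, length(subpathways), length(types),
              dimnames = list(ids, types))
  E_overall <- stats::setNames(numeric(length(subpathways)), ids)
  for (i in seq_along(subpathways)) {
    sp <- subpathways[[i]]
    genes <- intersect(if (is.list(sp)) sp$genes else sp,
                       rownames(mat$values))
    if (!length(genes)) { E_overall[i] <- NA; next }
    per_cell <- colMeans(mat$values[genes, , drop = FALSE])
    E[i, ] <- vapply(types, function(ty) mean(per_cell[cell_types == ty]),
                     numeric(1))
    E_overall[i] <- mean(per_cell)
  }
  spec <- E / E_overall
  undefined <- ids[!is.na(E_overall) & E_overall == 0 | is.na(E_overall)]
  spec[ids %in% undefined, ] <- NA
  structure(list(specificity = spec, E = E, E_overall = E_overall,
                 n_cells = as.integer(table(cell_types)),
                 undefined = undefined),
            class = "SpecificityMatrix")
}

#' @export
print.SpecificityMatrix <- function(x, ...) {
  cat("SpecificityMatrix:", nrow(x$specificity), "subpathways x",
      ncol(x$specificity), "cell types")
  if (length(x$undefined)) cat(" (", length(x$undefined), "undefined )")
  cat("\n")
  invisible(x)
}

#' Single-sample gene-set enrichment scores per cell
#'
#' For each cell, genes are ranked by expression (descending, ties broken
#' by gene symbol for determinism) and the enrichment score of a set is the
#' sum over the ranked list of the difference between the weighted in-set
#' empirical CDF (weights `rank^weight`, highest expression getting the
#' largest rank) and the unweighted out-set empirical CDF.
#'
#' @param mat An `ExpressionMatrix`.
#' @param gene_sets Named list of gene sets (or a `GeneSetCollection`).
#' @param weight Rank-weight exponent (0.25 by the method's convention).
#' @return Matrix of scores, sets x cells; a set with no measured genes
#'   yields NA for every cell; a set covering all genes yields 0 with a
#'   warning (the out-set CDF is degenerate).
#' @export
ssgsea_scores <- function(mat, gene_sets, weight = 0.25) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  genes <- rownames(mat$values)
  G <- length(genes)
  out <- matrix(NA_real_, length(gene_sets), ncol(mat$values),
                dimnames = list(names(gene_sets), colnames(mat$values)))
  measured <- lapply(gene_sets, intersect, x = genes)
  for (s in seq_along(gene_sets)) {
    if (!length(measured[[s]]))
      next
    if (length(measured[[s]]) == G) {
      warning("set ", names(gene_sets)[s],
              " covers every measured gene; score defined as 0")
      out[s, ] <- 0
    }
  }
  for (cell in seq_len(ncol(mat$values))) {
    v <- mat$values[, cell]
    ord <- order(-v, genes)         # descending value, symbol tie-break
    rnk <- (G:1)^weight             # position 1 (top) gets the largest rank
    in_top <- genes[ord]
    for (s in seq_along(gene_sets)) {
      sz <- length(measured[[s]])
      if (sz == 0 || sz == G) next
      ind <- in_top %in% measured[[s]]
      p_in <- cumsum(rnk * ind) / sum(rnk * ind)
      p_out <- cumsum(!ind) / (G - sz)
      out[s, cell] <- sum(p_in - p_out)
    }
  }
  out
}
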