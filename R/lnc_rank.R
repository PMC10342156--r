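#' Significance of the overlap between a target cluster and a subpathway
#'
#' Upper-tail hypergeometric probability of drawing at least the observed
#' number of shared genes: population = universe, successes = subpathway
#' genes, draws = cluster genes. Shares the tail kernel of
#' [shared_mirna_pvalue()].
#'
#' @param cluster_genes,subpathway_genes Gene sets, both contained in
#'   `universe`.
#' @param universe Background gene set.
#' @return Overlap p-value `q` in (0, 1]; 1 when the overlap is empty.
#' @export
overlap_pvalue <- function(cluster_genes, subpathway_genes, universe) {
  cluster_genes <- unique(cluster_genes)
  subpathway_genes <- unique(subpathway_genes)
  universe <- unique(universe)
  bad <- c(setdiff(cluster_genes, universe),
           setdiff(subpathway_genes, universe))
  if (length(bad))
    stop("gene(s) outside the universe: ", paste(bad, collapse = ", "))
  hyper_upper_tail(length(universe), length(subpathway_genes),
                   length(cluster_genes),
                   length(intersect(cluster_genes, subpathway_genes)))
}

#' Entropy of an overlap p-value
#'
#' `-log10(q)`: 0 for q = 1, larger for stronger overlaps.
#'
#' @param q p-value in (0, 1].
#' @return Non-negative entropy.
#' @export
entropy_score <- function(q) {
  if (any(q <= 0) || any(q > 1)) stop("'q' must lie in (0, 1]")
  -log10(q)
}

#' lncRNA rank (LR) score over its subpathway links
#'
#' `LR = sum_i(Entropy_i * P_i) / n` over the lncRNA's linked dynamic
#' subpathways, where `Entropy_i = -log10 q_i` of the cluster/subpathway
#' overlap and `P_i` is the subpathway's activity score. A lncRNA whose
#' several clusters hit one subpathway contributes that subpathway once,
#' keeping the smallest q (n indexes subpathways, not clusters).
#'
#' @param links Data frame of one lncRNA's links with columns
#'   `subpathway_id`, `q`, `P` (and optionally `lncRNA`).
#' @return List with `lncRNA` (if present), `n_links` and `LR`.
#' @export
lr_score <- function(links) {
  links <- as.data.frame(links)
  if (!nrow(links)) stop("at least one link required")
  links <- links[order(links$subpathway_id, links$q), , drop = FALSE]
  links <- links[!duplicated(links$subpathway_id), , drop = FALSE]
  lr <- mean(entropy_score(links$q) * links$P)
  list(lncRNA = if ("lncRNA" %in% names(links)) links$lncRNA[1] else NA,
       n_links = nrow(links), LR = lr)
}

#' Link target clusters to dynamic subpathways and rank the lncRNAs
#'
#' Dynamic subpathways are those with permutation p below `alpha_dyn`.
#' Every (cluster, dynamic subpathway) pair with overlap q below
#' `alpha_link` becomes a link (both gene sets are intersected with the
#' universe before testing); per lncRNA the links are deduplicated to one
#' per subpathway (smallest q) and averaged into the LR score. Links are
#' annotated with their POI-gene overlap and the whole network is returned
#' as typed nodes and edges.
#'
#' @param clusters List of `TargetCluster` ([build_target_clusters()]).
#' @param activities A `SubpathwayActivityTable`.
#' @param subpathways The scored subpathways (list of `Subpathway`).
#' @param universe Background gene set for overlap tests (typically the
#'   measured protein-coding genes intersected with the pathway nodes).
#' @param alpha_link Threshold on overlap q.
#' @param alpha_dyn Threshold on permutation p.
#' @param poi Disease (POI) gene list for annotation.
#' @return List of class `LncSubpathwayNetwork` with `links` (data frame:
#'   lncRNA, cluster_index, subpathway_id, overlap_genes, q, entropy, P,
#'   poi_overlap), `ranks` (data frame: lncRNA, n_links, LR, descending
#'   LR, ties lexicographic) and `network` (nodes/edges lists ready for
#'   JSON export).
#' @export
assemble_network <- function(clusters, activities, subpathways, universe,
                             alpha_link = 0.05, alpha_dyn = 0.05,
                             poi = character()) {
  sp_genes <- stats::setNames(
    lapply(subpathways, function(s) intersect(s$genes, universe)),
    vapply(subpathways, `[[`, "", "subpathway_id"))
  dyn <- activities$subpathway_id[activities$perm_p < alpha_dyn]
  act <- stats::setNames(activities$activity, activities$subpathway_id)
  rows <- list()
  for (cl in clusters) {
    cl_genes <- intersect(cl$genes, universe)
    if (!length(cl_genes)) next
    for (sid in dyn) {
      sg <- sp_genes[[sid]]
      if (is.null(sg) || !length(sg)) next
      ov <- intersect(cl_genes, sg)
      q <- overlap_pvalue(cl_genes, sg, universe)
      if (q >= alpha_link) next
      rows[[length(rows) + 1L]] <- data.frame(
        lncRNA = cl$lncRNA, cluster_index = cl$cluster_index,
        subpathway_id = sid,
        overlap_genes = paste(sort(ov), collapse = ";"),
        q = q, entropy = entropy_score(q), P = unname(act[sid]),
        poi_overlap = paste(sort(intersect(ov, poi)), collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  links <- do.call(rbind, c(list(data.frame(
    lncRNA = character(), cluster_index = integer(),
    subpathway_id = character(), overlap_genes = character(), q = numeric(),
    entropy = numeric(), P = numeric(), poi_overlap = character())), rows))
  links <- links[order(links$lncRNA, links$subpathway_id, links$q), ,
                 drop = FALSE]
  rownames(links) <- NULL

  ranks <- do.call(rbind, lapply(split(links, links$lncRNA), function(df) {
    sc <- lr_score(df)
    data.frame(lncRNA = sc$lncRNA, n_links = sc$n_links, LR = sc$LR,
               stringsAsFactors = FALSE)
  }))
  if (is.null(ranks))
    ranks <- data.frame(lncRNA = character(), n_links = integer(),
                        LR = numeric())
  ranks <- ranks[order(-ranks$LR, ranks$lncRNA), , drop = FALSE]
  rownames(ranks) <- NULL

  skipped <- setdiff(unique(vapply(clusters, `[[`, "", "lncRNA")),
                     ranks$lncRNA)
  if (length(skipped))
    message("lncRNA(s) with zero links omitted from ranks: ",
            paste(skipped, collapse = ", "))

  node <- function(id, type) list(id = id, type = type)
  nodes <- c(
    lapply(unique(links$lncRNA), node, type = "lncRNA"),
    lapply(unique(unlist(strsplit(links$overlap_genes, ";", fixed = TRUE))),
           node, type = "gene"),
    lapply(unique(links$subpathway_id), node, type = "subpathway"))
  edges <- list()
  for (i in seq_len(nrow(links))) {
    ov <- strsplit(links$overlap_genes[i], ";", fixed = TRUE)[[1]]
    for (g in ov) {
      edges[[length(edges) + 1L]] <- list(
        from = links$lncRNA[i], to = g, type = "targets")
      edges[[length(edges) + 1L]] <- list(
        from = g, to = links$subpathway_id[i], type = "member_of")
      if (g %in% poi)
        edges[[length(edges) + 1L]] <- list(
          from = g, to = links$subpathway_id[i], type = "overlaps_poi")
    }
  }
  dedup_edges <- !duplicated(vapply(edges, function(e)
    paste(e$from, e$to, e$type, sep = "\r"), ""))
  structure(list(links = links, ranks = ranks,
                 network = list(nodes = nodes, edges = edges[dedup_edges])),
            class = "LncSubpathwayNetwork")
}

#' @export
print.LncSubpathwayNetwork <- function(x, ...) {
  cat("LncSubpathwayNetwork:", nrow(x$links), "links,",
      nrow(x$ranks), "ranked lncRNAs\n")
  if (nrow(x$ranks))
    print(utils::head(x$ranks, 10))
  invisible(x)
}

#' Direction-of-change summary of subpathway genes after lncRNA knockdown
#'
#' For each shared subpathway gene, `delta = mean(knockdown) -
#' mean(control)`; `fraction_down` is the fraction with strictly negative
#' delta, with an exact one-sided sign test against 0.5 (are more genes
#' down than chance?).
#'
#' @param control,knockdown Expression matrices (numeric matrices with gene
#'   row names, or `ExpressionMatrix` objects) sharing a gene space.
#' @param subpathway_genes Genes of the subpathway to summarize.
#' @return List with `fraction_down`, `delta` (named per gene) and
#'   `sign_test_p`.
#' @export
knockdown_direction_summary <- function(control, knockdown,
                                        subpathway_genes) {
  as_mat <- function(x) if (inherits(x, "ExpressionMatrix")) x$values else x
  control <- as_mat(control); knockdown <- as_mat(knockdown)
  genes <- Reduce(intersect, list(rownames(control), rownames(knockdown),
                                  unique(subpathway_genes)))
  if (!length(genes)) stop("no shared subpathway genes between matrices")
  delta <- rowMeans(knockdown[genes, , drop = FALSE]) -
    rowMeans(control[genes, , drop = FALSE])
  down <- sum(delta < 0)
  p <- stats::binom.test(down, length(genes), p = 0.5,
                         alternative = "greater")$p.value
  list(fraction_down = down / length(genes), delta = delta,
       sign_test_p = p)
}
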