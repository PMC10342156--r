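#' log2(x + 1) normalization
#'
#' Elementwise `log2(x + 1)` of a non-negative FPKM (or count-like) matrix;
#' monotone, with 0 mapped to 0.
#'
#' @param raw Non-negative numeric matrix or vector.
#' @return Matrix/vector of the same shape on the log2(FPKM+1) scale.
#' @export
log2_normalize <- function(raw) {
  if (!is.numeric(raw)) stop("'raw' must be numeric")
  if (any(!is.finite(raw))) stop("'raw' must be finite")
  if (any(raw < 0)) stop("'raw' must be non-negative")
  log2(raw + 1)
}

#' Per-cell QC statistics
#'
#' For each cell, the number of detected features (values > 0) and the
#' sample standard deviation of its values, both over the requested biotype
#' subset.
#'
#' @param mat An `ExpressionMatrix`.
#' @param biotype Optional `"protein_coding"` or `"lncRNA"`; default uses
#'   all genes.
#' @return Data frame with columns `cell_id`, `nFeature`, `sd`.
#' @export
qc_cell_stats <- function(mat, biotype = NULL) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  genes <- if (is.null(biotype)) rownames(mat$values)
           else genes_of_biotype(mat, biotype)
  if (!length(genes)) stop("empty biotype subset")
  v <- mat$values[genes, , drop = FALSE]
  data.frame(cell_id = colnames(v),
             nFeature = colSums(v > 0),
             sd = apply(v, 2, stats::sd),
             row.names = NULL)
}

#' Expressed-feature filter within one lineage
#'
#' A gene is retained iff (1) some stage group of the lineage has mean
#' expression >= `min_mean`, and (2) some stage group has a fraction of
#' expressing cells (value > 0) >= `min_frac`. The two conditions are
#' evaluated independently and may be met in different groups.
#'
#' @param mat An `ExpressionMatrix`.
#' @param lineage `"follicle"` or `"granulosa"`.
#' @param min_mean Group-mean threshold (log2(FPKM+1) units).
#' @param min_frac Expressed-fraction threshold in \[0, 1\].
#' @return An `ExpressedFeatureReport`: list with `retained` (character),
#'   `lineage`, and `diagnostics` (per-gene data frame with `biotype`,
#'   `max_group_mean`, `max_group_frac`, `retained`).
#' @export
select_expressed_features <- function(mat, lineage, min_mean = 1,
                                      min_frac = 0.7) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  check_levels(lineage, LINEAGE_LEVELS, "lineage")
  if (min_frac < 0 || min_frac > 1) stop("'min_frac' must lie in [0, 1]")
  cells <- cells_for(mat, lineage = lineage)
  if (!length(cells)) stop("lineage ", lineage, " has no cells")
  stages <- droplevels(mat$cell_stage[cells])
  v <- mat$values[, cells, drop = FALSE]
  per_group <- function(f) {
    out <- vapply(levels(stages), function(s)
      f(v[, stages == s, drop = FALSE]), numeric(nrow(v)))
    matrix(out, nrow = nrow(v))  # keep matrix shape for single-gene input
  }
  group_means <- per_group(rowMeans)
  group_fracs <- per_group(function(x) rowMeans(x > 0))
  max_mean <- apply(group_means, 1, max)
  max_frac <- apply(group_fracs, 1, max)
  retained <- max_mean >= min_mean & max_frac >= min_frac
  diag <- data.frame(gene = rownames(v),
                     biotype = as.character(mat$gene_biotype),
                     max_group_mean = max_mean,
                     max_group_frac = max_frac,
                     retained = retained, row.names = NULL)
  structure(list(retained = rownames(v)[retained], lineage = lineage,
                 min_mean = min_mean, min_frac = min_frac,
                 diagnostics = diag),
            class = "ExpressedFeatureReport")
}

#' @export
print.ExpressedFeatureReport <- function(x, ...) {
  tab <- table(x$diagnostics$biotype[x$diagnostics$retained])
  cat("ExpressedFeatureReport (", x$lineage, "): ",
      length(x$retained), "/", nrow(x$diagnostics), " genes retained (",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Two-sided rank-sum test per feature with Bonferroni correction over the
#' tested features: exact enumeration when both groups have <= 10 cells and
#' the feature is tie-free, normal approximation with the midrank tie
#' correction otherwise. Log2 fold change is `mean(group_b) - mean(group_a)`
#' on the log2(FPKM+1) scale, so pass the reference group (e.g. primordial)
#' as `group_a`.
#'
#' Optional prefilters mirroring common marker-test defaults are exposed
#' but off: `min_lfc` drops features with |log2 fold change| below the
#' threshold and `min_frac_detect` drops features detected (value > 0) in
#' less than that fraction of cells in both groups; Bonferroni then
#' corrects over the features actually tested.
#'
#' @param mat An `ExpressionMatrix`.
#' @param group_a,group_b Disjoint, non-empty cell id vectors.
#' @param features Gene ids to test; default all genes.
#' @param a_label,b_label Labels used in the `direction` column.
#' @param min_lfc Minimum absolute log2 fold change prefilter (0 = off;
#'   0.25 reproduces the common marker-test default).
#' @param min_frac_detect Minimum detection fraction in at least one group
#'   (0 = off; 0.1 reproduces the common default).
#' @return A `DifferentialTable` data frame: `gene`, `mean_a`, `mean_b`,
#'   `lfc`, `stat` (rank-sum W), `p`, `p_bonf`, `direction`.
#' @export
wilcoxon_de <- function(mat, group_a, group_b,
                        features = rownames(mat$values),
                        a_label = "primordial", b_label = "primary",
                        min_lfc = 0, min_frac_detect = 0) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  if (!length(group_a) || !length(group_b))
    stop("both groups must be non-empty")
  if (length(intersect(group_a, group_b)))
    stop("cell groups overlap: ",
         paste(intersect(group_a, group_b), collapse = ", "))
  if (min_lfc > 0 || min_frac_detect > 0) {
    fa <- rowMeans(mat$values[features, group_a, drop = FALSE] > 0)
    fb <- rowMeans(mat$values[features, group_b, drop = FALSE] > 0)
    d <- abs(rowMeans(mat$values[features, group_b, drop = FALSE]) -
               rowMeans(mat$values[features, group_a, drop = FALSE]))
    features <- features[pmax(fa, fb) >= min_frac_detect & d >= min_lfc]
    if (!length(features)) stop("no features pass the prefilters")
  }
  va <- mat$values[features, group_a, drop = FALSE]
  vb <- mat$values[features, group_b, drop = FALSE]
  res <- t(vapply(seq_along(features), function(i) {
    x <- va[i, ]; y <- vb[i, ]
    ties <- anyDuplicated(c(x, y)) > 0
    use_exact <- !ties && length(x) <= 10 && length(y) <= 10
    if (length(unique(c(x, y))) == 1L) return(c(length(x) * length(y) / 2, 1))
    w <- suppressWarnings(stats::wilcox.test(
      y, x, exact = use_exact, correct = FALSE))
    c(unname(w$statistic), w$p.value)
  }, numeric(2)))
  lfc <- rowMeans(vb) - rowMeans(va)
  p <- pmin(1, pmax(res[, 2], .Machine$double.xmin))
  out <- data.frame(
    gene = features,
    mean_a = rowMeans(va), mean_b = rowMeans(vb), lfc = lfc,
    stat = res[, 1], p = p,
    p_bonf = pmin(1, p * length(features)),
    direction = ifelse(lfc > 0, paste0("up_in_", b_label),
                       ifelse(lfc < 0, paste0("up_in_", a_label), "flat")),
    row.names = NULL)
  structure(out, a_label = a_label, b_label = b_label,
            class = c("DifferentialTable", "data.frame"))
}
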