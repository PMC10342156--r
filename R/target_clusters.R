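#' Pairwise Pearson correlation of genes across cells
#'
#' Correlation of target-gene expression over the primordial and primary
#' cells of one lineage (or any cell set with >= 3 cells). Genes with zero
#' variance over the cells are excluded from the returned matrix and listed
#' in the `excluded` attribute.
#'
#' @param mat An `ExpressionMatrix`.
#' @param genes Gene ids to correlate.
#' @param cells Cell ids (>= 3).
#' @return Symmetric correlation matrix over the non-constant genes, with
#'   attribute `excluded` naming the zero-variance genes.
#' @export
pairwise_pcc <- function(mat, genes, cells) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  if (length(cells) < 3) stop("need at least 3 cells for correlation")
  v <- t(mat$values[genes, cells, drop = FALSE])
  sds <- apply(v, 2, stats::sd)
  excluded <- colnames(v)[sds == 0]
  v <- v[, sds > 0, drop = FALSE]
  r <- stats::cor(v)
  structure(r, excluded = excluded)
}

#' Cut a correlation matrix into tight co-expression clusters
#'
#' Hierarchical clustering on distance `1 - r` with complete linkage, cut at
#' height `1 - threshold`; complete linkage makes the cut criterion hold for
#' every within-cluster pair (minimum within-cluster correlation >=
#' `threshold`). Clusters smaller than `min_size` are discarded.
#'
#' @param pcc Symmetric correlation matrix (as from [pairwise_pcc()]).
#' @param threshold Minimum within-cluster pairwise correlation.
#' @param min_size Minimum cluster size.
#' @return List of character vectors (gene sets), possibly empty.
#' @export
cut_clusters <- function(pcc, threshold = 0.7, min_size = 3) {
  if (is.null(dim(pcc)) || nrow(pcc) < min_size) return(list())
  hc <- stats::hclust(stats::as.dist(1 - pcc), method = "complete")
  grp <- stats::cutree(hc, h = 1 - threshold)
  out <- split(names(grp), grp)
  out <- out[lengths(out) >= min_size]
  names(out) <- NULL
  lapply(out, sort)
}

## Rank/Mann-Whitney AUC with ties contributing 1/2 (trapezoidal ROC).
auc_rank <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("both classes required for AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated SVM discrimination score of a gene cluster
#'
#' How well a cluster's genes separate two follicle stages: per repetition,
#' cells are stratified into `folds` folds (reduced to the minority class
#' size when smaller, minimum 2); a radial-kernel SVM with default
#' regularization is trained on the training folds (features standardized
#' with training-fold parameters only) and held-out cells are scored by
#' decision value; the repetition's AUC pools all out-of-fold decision
#' values, with ties contributing 1/2. The final score is the mean AUC over
#' `reps` repetitions.
#'
#' @param mat An `ExpressionMatrix`.
#' @param cluster Gene ids used as features.
#' @param cells Cell ids to classify.
#' @param labels Factor of two classes over `cells` (second level is the
#'   positive class); defaults to the cells' stage.
#' @param folds,reps Cross-validation folds and repetitions.
#' @param seed Integer seed; the full AUC vector is reproducible.
#' @return List with `mean_auc` and `auc_per_repetition` (length `reps`).
#' @export
cluster_auc <- function(mat, cluster, cells, labels = NULL, folds = 5,
                        reps = 100, seed = 1L) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  if (is.null(labels))
    labels <- factor(as.character(mat$cell_stage[cells]),
                     levels = intersect(STAGE_LEVELS,
                                        as.character(mat$cell_stage[cells])))
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2)
    stop("exactly two classes required, found: ",
         paste(levels(labels), collapse = ", "))
  if (min(table(labels)) < 2) stop("each class needs at least 2 cells")
  x <- t(mat$values[cluster, cells, drop = FALSE])
  positive <- levels(labels)[2]
  k <- max(2L, min(folds, min(table(labels))))
  set.seed(seed)
  aucs <- vapply(seq_len(reps), function(rep) {
    fold <- integer(length(labels))
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    scores <- numeric(length(labels))
    for (f in seq_len(k)) {
      tr <- fold != f; te <- !tr
      ctr <- colMeans(x[tr, , drop = FALSE])
      scl <- apply(x[tr, , drop = FALSE], 2, stats::sd)
      scl[scl == 0] <- 1
      xtr <- sweep(sweep(x[tr, , drop = FALSE], 2, ctr), 2, scl, "/")
      xte <- sweep(sweep(x[te, , drop = FALSE], 2, ctr), 2, scl, "/")
      fit <- e1071::svm(xtr, labels[tr], kernel = "radial", scale = FALSE)
      pr <- stats::predict(fit, xte, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      ## decision value sign refers to the first class named in the column
      first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
      scores[te] <- if (identical(first, positive)) dv[, 1] else -dv[, 1]
    }
    auc_rank(scores, labels == positive)
  }, numeric(1))
  list(mean_auc = mean(aucs), auc_per_repetition = aucs)
}

#' Build stage-discriminative target clusters for every lncRNA
#'
#' For each lncRNA in the ceRNA pair table: correlate its target genes over
#' the primordial + primary cells of one lineage, cut tight co-expression
#' clusters ([cut_clusters()]), score each cluster by cross-validated SVM
#' AUC ([cluster_auc()]), and retain clusters with mean AUC strictly above
#' `auc_min`. Cluster indices are assigned per lncRNA in descending mean
#' AUC.
#'
#' @param mat An `ExpressionMatrix`.
#' @param pairs A `CeRNAPairTable` (columns `lncRNA`, `mRNA`).
#' @param lineage Lineage whose primordial + primary cells are used.
#' @param pcc_threshold,min_size Clustering parameters ([cut_clusters()]).
#' @param auc_min Retention threshold on mean AUC (strict).
#' @param folds,reps,seed Cross-validation parameters ([cluster_auc()]).
#' @return List of `TargetCluster` objects: each a list with `lncRNA`,
#'   `cluster_index`, `genes`, `mean_auc`, `auc_per_repetition`.
#' @export
build_target_clusters <- function(mat, pairs, lineage, pcc_threshold = 0.7,
                                  min_size = 3, auc_min = 0.8, folds = 5,
                                  reps = 100, seed = 1L) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  cells <- cells_for(mat, lineage = lineage,
                     stage = c("primordial", "primary"))
  out <- list()
  counter <- 0L
  for (lnc in sort(unique(pairs$lncRNA))) {
    targets <- intersect(unique(pairs$mRNA[pairs$lncRNA == lnc]),
                         rownames(mat$values))
    kept <- list()
    if (length(targets) >= min_size) {
      pcc <- pairwise_pcc(mat, targets, cells)
      for (genes in cut_clusters(pcc, pcc_threshold, min_size)) {
        counter <- counter + 1L
        auc <- cluster_auc(mat, genes, cells, folds = folds, reps = reps,
                           seed = seed + counter)
        if (auc$mean_auc > auc_min)
          kept[[length(kept) + 1L]] <- list(
            lncRNA = lnc, genes = genes, mean_auc = auc$mean_auc,
            auc_per_repetition = auc$auc_per_repetition)
      }
    }
    if (!length(kept)) {
      message("lncRNA ", lnc, ": no cluster retained")
      next
    }
    kept <- kept[order(-vapply(kept, `[[`, 1, "mean_auc"))]
    for (i in seq_along(kept)) {
      kept[[i]]$cluster_index <- i
      out[[length(out) + 1L]] <-
        structure(kept[[i]][c("lncRNA", "cluster_index", "genes",
                              "mean_auc", "auc_per_repetition")],
                  class = "TargetCluster")
    }
  }
  out
}

#' @export
print.TargetCluster <- function(x, ...) {
  cat("TargetCluster ", x$lncRNA, "#", x$cluster_index, ": ",
      length(x$genes), " genes, mean AUC ", round(x$mean_auc, 3), "\n",
      sep = "")
  invisible(x)
}
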