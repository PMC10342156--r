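#' @keywords internal
"_PACKAGE"

## Controlled vocabularies shared across the pipeline.
STAGE_LEVELS   <- c("primordial", "primary", "secondary", "antral", "preovulatory")
LINEAGE_LEVELS <- c("follicle", "granulosa")
BIOTYPE_LEVELS <- c("protein_coding", "lncRNA")

#' Construct an annotated genes x cells expression matrix
#'
#' Container for normalized single-cell expression (log2(FPKM+1) scale) with
#' the per-gene and per-cell annotations every pipeline stage relies on:
#' gene biotype (protein-coding vs lncRNA), cell lineage (follicle vs
#' granulosa) and ordered developmental stage.
#'
#' @param values Numeric matrix, genes in rows and cells in columns, with
#'   unique row and column names. Values must be finite and non-negative.
#' @param gene_biotype Character vector, one of `"protein_coding"` or
#'   `"lncRNA"` per gene, in row order (or named by gene).
#' @param cell_lineage Character vector, `"follicle"` or `"granulosa"` per
#'   cell, in column order (or named by cell).
#' @param cell_stage Character vector of stages per cell; levels are ordered
#'   `primordial < primary < secondary < antral < preovulatory`.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `gene_biotype` (factor), `cell_lineage` (factor) and
#'   `cell_stage` (ordered factor), the last three named by gene/cell id.
#' @export
expression_matrix <- function(values, gene_biotype, cell_lineage, cell_stage) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  gid <- rownames(values)
  cid <- colnames(values)
  if (is.null(gid) || is.null(cid))
    stop("'values' must have gene row names and cell column names")
  if (anyDuplicated(gid))
    stop("duplicate gene identifier(s): ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "))
  if (anyDuplicated(cid))
    stop("duplicate cell identifier(s): ",
         paste(unique(cid[duplicated(cid)]), collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression values must be finite")
  if (any(values < 0))
    stop("expression values must be non-negative")

  gene_biotype <- align_annotation(gene_biotype, gid, "gene_biotype", "gene")
  cell_lineage <- align_annotation(cell_lineage, cid, "cell_lineage", "cell")
  cell_stage   <- align_annotation(cell_stage, cid, "cell_stage", "cell")

  check_levels(gene_biotype, BIOTYPE_LEVELS, "gene_biotype")
  check_levels(cell_lineage, LINEAGE_LEVELS, "cell_lineage")
  check_levels(cell_stage, STAGE_LEVELS, "cell_stage")

  structure(
    list(values = values,
         gene_biotype = factor(stats::setNames(as.character(gene_biotype), gid),
                               levels = BIOTYPE_LEVELS),
         cell_lineage = factor(stats::setNames(as.character(cell_lineage), cid),
                               levels = LINEAGE_LEVELS),
         cell_stage = factor(stats::setNames(as.character(cell_stage), cid),
                             levels = STAGE_LEVELS, ordered = TRUE)),
    class = "ExpressionMatrix")
}

align_annotation <- function(x, ids, what, unit) {
  if (!is.null(names(x))) {
    missing <- setdiff(ids, names(x))
    if (length(missing))
      stop("missing ", what, " for ", unit, "(s): ",
           paste(missing, collapse = ", "))
    x <- x[ids]
  } else if (length(x) != length(ids)) {
    stop("'", what, "' must have one entry per ", unit)
  }
  if (anyNA(x)) {
    bad <- ids[is.na(x)]
    stop("missing ", what, " for ", unit, "(s): ", paste(bad, collapse = ", "))
  }
  x
}

check_levels <- function(x, levels, what) {
  bad <- setdiff(unique(as.character(x)), levels)
  if (length(bad))
    stop("invalid ", what, " value(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(levels, collapse = ", "), ")")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$values), "genes x", ncol(x$values), "cells\n")
  cat("  biotypes: ",
      paste(sprintf("%s=%d", levels(x$gene_biotype),
                    tabulate(x$gene_biotype, length(levels(x$gene_biotype)))),
            collapse = ", "), "\n", sep = "")
  grp <- table(droplevels(x$cell_lineage), droplevels(x$cell_stage))
  cat("  cells per (lineage, stage):\n")
  print(grp)
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Select cell identifiers by lineage and/or stage
#'
#' @param mat An `ExpressionMatrix`.
#' @param lineage Optional lineage to keep.
#' @param stage Optional stage (or stages) to keep.
#' @return Character vector of cell ids, in matrix column order.
#' @export
cells_for <- function(mat, lineage = NULL, stage = NULL) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  keep <- rep(TRUE, ncol(mat$values))
  if (!is.null(lineage)) keep <- keep & (as.character(mat$cell_lineage) %in% lineage)
  if (!is.null(stage))   keep <- keep & (as.character(mat$cell_stage) %in% stage)
  colnames(mat$values)[keep]
}

#' Gene identifiers of one biotype
#'
#' @param mat An `ExpressionMatrix`.
#' @param biotype `"protein_coding"` or `"lncRNA"`.
#' @return Character vector of gene ids, in matrix row order.
#' @export
genes_of_biotype <- function(mat, biotype) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  check_levels(biotype, BIOTYPE_LEVELS, "biotype")
  rownames(mat$values)[as.character(mat$gene_biotype) == biotype]
}

#' Subset an ExpressionMatrix by genes and/or cells
#'
#' @param mat An `ExpressionMatrix`.
#' @param genes Optional gene ids to keep (order preserved as given).
#' @param cells Optional cell ids to keep.
#' @return A new `ExpressionMatrix`.
#' @export
subset_expression <- function(mat, genes = NULL, cells = NULL) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  if (is.null(genes)) genes <- rownames(mat$values)
  if (is.null(cells)) cells <- colnames(mat$values)
  missing_g <- setdiff(genes, rownames(mat$values))
  if (length(missing_g))
    stop("unknown gene id(s): ", paste(missing_g, collapse = ", "))
  missing_c <- setdiff(cells, colnames(mat$values))
  if (length(missing_c))
    stop("unknown cell id(s): ", paste(missing_c, collapse = ", "))
  expression_matrix(mat$values[genes, cells, drop = FALSE],
                    stats::setNames(as.character(mat$gene_biotype[genes]), genes),
                    stats::setNames(as.character(mat$cell_lineage[cells]), cells),
                    stats::setNames(as.character(mat$cell_stage[cells]), cells))
}
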