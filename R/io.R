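#' Read a dense expression table with cell and gene metadata
#'
#' Expression is tab-separated: first column gene symbol, header row of cell
#' ids. Cell metadata maps `cell_id` to `lineage` and `stage`; gene metadata
#' maps `gene_id` to `biotype`. Metadata must cover every id in the matrix;
#' anything missing is a hard error naming the offending id.
#'
#' @param path Expression TSV.
#' @param cell_metadata_path TSV with columns `cell_id`, `lineage`, `stage`.
#' @param gene_metadata_path TSV with columns `gene_id`, `biotype`.
#' @return An [expression_matrix()] with file row/column order preserved.
#' @export
read_expression_table <- function(path, cell_metadata_path, gene_metadata_path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty expression file: ", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  cell_ids <- header[-1]
  if (anyDuplicated(cell_ids))
    stop("duplicate cell identifier(s) in ", path, ": ",
         paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  gene_ids <- vapply(body, `[[`, "", 1L)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifier(s) in ", path, ": ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  values <- matrix(NA_real_, length(gene_ids), length(cell_ids),
                   dimnames = list(gene_ids, cell_ids))
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != length(cell_ids) + 1L)
      stop("line ", i + 1L, " of ", path, ": expected ",
           length(cell_ids) + 1L, " fields, found ", length(row))
    v <- suppressWarnings(as.numeric(row[-1]))
    if (anyNA(v))
      stop("line ", i + 1L, " of ", path, ": non-numeric value for gene ",
           row[[1]])
    values[i, ] <- v
  }

  cmeta <- utils::read.delim(cell_metadata_path, stringsAsFactors = FALSE)
  gmeta <- utils::read.delim(gene_metadata_path, stringsAsFactors = FALSE)
  req <- function(df, cols, p) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop(p, ": missing column(s) ", paste(miss, collapse = ", "))
  }
  req(cmeta, c("cell_id", "lineage", "stage"), cell_metadata_path)
  req(gmeta, c("gene_id", "biotype"), gene_metadata_path)

  expression_matrix(
    values,
    gene_biotype = stats::setNames(gmeta$biotype, gmeta$gene_id),
    cell_lineage = stats::setNames(cmeta$lineage, cmeta$cell_id),
    cell_stage   = stats::setNames(cmeta$stage, cmeta$cell_id))
}

#' Write an ExpressionMatrix and its metadata as TSV
#'
#' @param mat An `ExpressionMatrix`.
#' @param path,cell_metadata_path,gene_metadata_path Output TSV paths.
#' @return Invisibly, `mat`.
#' @export
write_expression_table <- function(mat, path, cell_metadata_path,
                                   gene_metadata_path) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  df <- data.frame(gene_id = rownames(mat$values), mat$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(cell_id = colnames(mat$values),
               lineage = as.character(mat$cell_lineage),
               stage = as.character(mat$cell_stage)),
    cell_metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = rownames(mat$values),
               biotype = as.character(mat$gene_biotype)),
    gene_metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mat)
}

#' Read gene sets from a GMT file
#'
#' One set per line: set id, description, then one gene per field. Duplicate
#' genes within a set are deduplicated with a warning; a line with fewer than
#' three fields is a hard error.
#'
#' @param path GMT file.
#' @return A `GeneSetCollection`: named list of character vectors with a
#'   `description` attribute (named character vector).
#' @export
read_gene_sets_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop("line ", i, " of ", path,
           ": GMT line needs at least 3 tab-separated fields")
    id <- fields[[1]]
    if (id %in% names(sets)) stop("duplicate set id: ", id)
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("set ", id, ": duplicate gene(s) deduplicated: ",
              paste(unique(genes[duplicated(genes)]), collapse = ", "))
      genes <- unique(genes)
    }
    sets[[id]] <- genes
    desc[[id]] <- fields[[2]]
  }
  structure(sets, description = desc, class = "GeneSetCollection")
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors (or a `GeneSetCollection`).
#' @param path Output path.
#' @param description Optional named character vector of descriptions;
#'   defaults to the collection's `description` attribute or `"na"`.
#' @return Invisibly, `path`.
#' @export
write_gene_sets_gmt <- function(sets, path, description = NULL) {
  if (is.null(description)) description <- attr(sets, "description")
  lines <- vapply(names(sets), function(id) {
    d <- if (!is.null(description) && !is.na(description[id]) &&
             id %in% names(description)) description[[id]] else "na"
    paste(c(id, d, sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Construct a pathway graph
#'
#' A simple undirected graph over gene symbols: no self-loops, no duplicate
#' edges, every edge endpoint listed in `nodes`.
#'
#' @param pathway_id Identifier.
#' @param edges Two-column character matrix of unordered gene pairs.
#' @param nodes Optional node set; defaults to the union of edge endpoints
#'   (isolated nodes may be added explicitly).
#' @return An object of class `PathwayGraph`.
#' @export
pathway_graph <- function(pathway_id, edges, nodes = NULL) {
  if (is.null(dim(edges))) edges <- matrix(edges, ncol = 2, byrow = TRUE)
  storage.mode(edges) <- "character"
  loops <- edges[, 1] == edges[, 2]
  if (any(loops)) {
    warning("pathway ", pathway_id, ": dropped ", sum(loops), " self-loop(s)")
    edges <- edges[!loops, , drop = FALSE]
  }
  key <- apply(edges, 1, function(e) paste(sort(e), collapse = "\r"))
  edges <- edges[!duplicated(key), , drop = FALSE]
  endpoint <- unique(as.vector(edges))
  if (is.null(nodes)) nodes <- endpoint
  else {
    bad <- setdiff(endpoint, nodes)
    if (length(bad)) stop("pathway ", pathway_id,
                          ": edge endpoint(s) not in nodes: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(pathway_id = pathway_id, nodes = sort(unique(nodes)),
                 edges = edges),
            class = "PathwayGraph")
}

#' @export
print.PathwayGraph <- function(x, ...) {
  cat("PathwayGraph", x$pathway_id, "-", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Read pathway graphs from a tab-separated edge list
#'
#' Lines are `pathway_id<TAB>geneA<TAB>geneB`. Duplicate edges are collapsed;
#' self-loops are dropped with a warning; a malformed line is a hard error.
#'
#' @param path Edge-list TSV (no header).
#' @return List of `PathwayGraph`, one per distinct pathway id (file order).
#' @export
read_pathway_edges <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3L))
    stop("line ", which(nf != 3L)[1], " of ", path,
         ": expected 3 tab-separated fields")
  pid <- vapply(parts, `[[`, "", 1L)
  a <- vapply(parts, `[[`, "", 2L)
  b <- vapply(parts, `[[`, "", 3L)
  lapply(unique(pid), function(p) {
    sel <- pid == p
    pathway_graph(p, cbind(a[sel], b[sel]))
  })
}

#' Write pathway graphs as a tab-separated edge list
#'
#' @param graphs List of `PathwayGraph`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pathway_edges <- function(graphs, path) {
  lines <- unlist(lapply(graphs, function(g) {
    if (!nrow(g$edges)) return(character())
    paste(g$pathway_id, g$edges[, 1], g$edges[, 2], sep = "\t")
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a miRNA interaction table
#'
#' Bipartite miRNA-transcript interaction sets split by target class, plus
#' the size of the miRNA universe used as the hypergeometric population in
#' ceRNA tests.
#'
#' @param mirna_mrna Data frame with columns `mirna`, `target` (mRNA pairs).
#' @param mirna_lnc Data frame with columns `mirna`, `target` (lncRNA pairs).
#' @param universe_m Positive integer, at least the number of distinct miRNAs
#'   appearing in either pair set.
#' @return An object of class `InteractionTable`.
#' @export
interaction_table <- function(mirna_mrna, mirna_lnc, universe_m) {
  dedup <- function(df) {
    df <- df[, c("mirna", "target")]
    df[!duplicated(paste(df$mirna, df$target, sep = "\r")), , drop = FALSE]
  }
  mirna_mrna <- dedup(as.data.frame(mirna_mrna))
  mirna_lnc <- dedup(as.data.frame(mirna_lnc))
  n_mirna <- length(unique(c(mirna_mrna$mirna, mirna_lnc$mirna)))
  universe_m <- as.integer(universe_m)
  if (!is.finite(universe_m) || universe_m < 1)
    stop("universe_m must be a positive integer")
  if (universe_m < n_mirna)
    stop("universe_m (", universe_m, ") is smaller than the number of ",
         "distinct miRNAs in the table (", n_mirna, ")")
  structure(list(mirna_mrna = mirna_mrna, mirna_lnc = mirna_lnc,
                 universe_m = universe_m),
            class = "InteractionTable")
}

#' @export
print.InteractionTable <- function(x, ...) {
  cat("InteractionTable:", nrow(x$mirna_mrna), "miRNA-mRNA pairs,",
      nrow(x$mirna_lnc), "miRNA-lncRNA pairs, universe m =",
      x$universe_m, "\n")
  invisible(x)
}

#' Read a miRNA interaction table from TSV
#'
#' Lines are `miRNA<TAB>target<TAB>class` with class `mRNA` or `lncRNA`.
#'
#' @param path Interaction TSV (no header).
#' @param universe_m Positive integer, or `"auto"` to use the number of
#'   distinct miRNA ids in the file.
#' @return An `InteractionTable`.
#' @export
read_interaction_table <- function(path, universe_m = "auto") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    if (identical(universe_m, "auto"))
      stop("empty interaction file with universe_m = \"auto\": ",
           "no miRNA universe can be inferred")
    empty <- data.frame(mirna = character(), target = character())
    return(interaction_table(empty, empty, universe_m))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3L))
    stop("line ", which(nf != 3L)[1], " of ", path,
         ": expected 3 tab-separated fields")
  mirna <- vapply(parts, `[[`, "", 1L)
  target <- vapply(parts, `[[`, "", 2L)
  cls <- vapply(parts, `[[`, "", 3L)
  bad <- setdiff(unique(cls), c("mRNA", "lncRNA"))
  if (length(bad))
    stop("unknown target class token(s): ", paste(bad, collapse = ", "))
  if (identical(universe_m, "auto")) universe_m <- length(unique(mirna))
  interaction_table(
    data.frame(mirna = mirna[cls == "mRNA"], target = target[cls == "mRNA"]),
    data.frame(mirna = mirna[cls == "lncRNA"], target = target[cls == "lncRNA"]),
    universe_m)
}

#' Write a miRNA interaction table as TSV
#'
#' @param tbl An `InteractionTable`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_interaction_table <- function(tbl, path) {
  stopifnot(inherits(tbl, "InteractionTable"))
  lines <- c(
    if (nrow(tbl$mirna_mrna))
      paste(tbl$mirna_mrna$mirna, tbl$mirna_mrna$target, "mRNA", sep = "\t"),
    if (nrow(tbl$mirna_lnc))
      paste(tbl$mirna_lnc$mirna, tbl$mirna_lnc$target, "lncRNA", sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
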