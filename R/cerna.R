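#' Significance of miRNAs shared between a lncRNA and an mRNA
#'
#' Hypergeometric upper-tail test of the competing-endogenous-RNA (ceRNA)
#' hypothesis: out of a universe of `m` miRNAs, the mRNA interacts with `t`
#' of them, the lncRNA with `n`, and `r` are shared. The p-value is
#' P(X >= r) under random overlap.
#'
#' @param m Total miRNA universe size.
#' @param t miRNAs interacting with the mRNA.
#' @param n miRNAs interacting with the lncRNA.
#' @param r Number of shared miRNAs.
#' @return Upper-tail probability in (0, 1]; 1 when `r = 0`.
#' @examples
#' shared_mirna_pvalue(20, 5, 5, 5)  # 1/choose(20,5)
#' @export
shared_mirna_pvalue <- function(m, t, n, r) hyper_upper_tail(m, t, n, r)

#' Call ceRNA lncRNA-mRNA pairs by the shared-miRNA test
#'
#' For every (lncRNA, mRNA) pair with at least one shared miRNA, computes
#' [shared_mirna_pvalue()] with `m` the table's miRNA universe, `t` the
#' mRNA's miRNA degree and `n` the lncRNA's miRNA degree, and keeps pairs
#' with p below `alpha` (raw p by default, matching the method's p < 0.05
#' convention; Benjamini-Hochberg across tested pairs available via
#' `adjust = "BH"`).
#'
#' @param tbl An `InteractionTable`.
#' @param lncs lncRNA symbols to test (typically the expressed lncRNAs).
#' @param mrnas mRNA symbols to test (typically the expressed protein-coding
#'   genes).
#' @param alpha Significance level on the (possibly adjusted) p-value.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A data frame of class `CeRNAPairTable` with columns `lncRNA`,
#'   `mRNA`, `m`, `t`, `n`, `r`, `shared_mirnas` (semicolon-joined ids) and
#'   `p`, ordered by lncRNA then mRNA; attribute `alpha` records the cutoff
#'   and attribute `n_tested` the number of pairs tested (r >= 1).
#' @export
call_cerna_pairs <- function(tbl, lncs, mrnas, alpha = 0.05,
                             adjust = c("none", "BH")) {
  stopifnot(inherits(tbl, "InteractionTable"))
  adjust <- match.arg(adjust)
  if (tbl$universe_m < 1) stop("empty miRNA universe")
  lnc_sets <- lapply(split(tbl$mirna_lnc$mirna, tbl$mirna_lnc$target), unique)
  mrna_sets <- lapply(split(tbl$mirna_mrna$mirna, tbl$mirna_mrna$target),
                      unique)
  lnc_sets <- lnc_sets[intersect(sort(unique(lncs)), names(lnc_sets))]
  mrna_sets <- mrna_sets[intersect(sort(unique(mrnas)), names(mrna_sets))]
  empty <- data.frame(lncRNA = character(), mRNA = character(),
                      m = integer(), t = integer(), n = integer(),
                      r = integer(), shared_mirnas = character(),
                      p = numeric())
  if (!length(lnc_sets) || !length(mrna_sets)) {
    return(structure(empty, alpha = alpha, adjust = adjust, n_tested = 0L,
                     p_tested = numeric(),
                     class = c("CeRNAPairTable", "data.frame")))
  }
  ## shared-miRNA counts for all pairs at once via 0/1 incidence crossprod
  mirnas <- unique(c(unlist(lnc_sets), unlist(mrna_sets)))
  inc <- function(sets) {
    M <- matrix(0L, length(mirnas), length(sets),
                dimnames = list(mirnas, names(sets)))
    M[cbind(match(unlist(sets), mirnas),
            rep(seq_along(sets), lengths(sets)))] <- 1L
    M
  }
  r_mat <- crossprod(inc(lnc_sets), inc(mrna_sets))  # lnc x mrna overlap
  hit <- which(r_mat >= 1, arr.ind = TRUE)
  out <- data.frame(
    lncRNA = rownames(r_mat)[hit[, 1]], mRNA = colnames(r_mat)[hit[, 2]],
    m = tbl$universe_m,
    t = unname(lengths(mrna_sets)[hit[, 2]]),
    n = unname(lengths(lnc_sets)[hit[, 1]]),
    r = r_mat[hit], shared_mirnas = NA_character_,
    p = NA_real_, stringsAsFactors = FALSE)
  key <- paste(out$t, out$n, out$r)
  uk <- !duplicated(key)
  p_by_key <- stats::setNames(
    mapply(function(t, n, r) hyper_upper_tail(tbl$universe_m, t, n, r),
           out$t[uk], out$n[uk], out$r[uk]),
    key[uk])
  out$p <- unname(p_by_key[key])
  n_tested <- nrow(out)
  p_all <- out$p
  crit <- if (adjust == "BH") stats::p.adjust(out$p, "BH") else out$p
  out <- out[crit < alpha, , drop = FALSE]
  out <- out[order(out$lncRNA, out$mRNA), , drop = FALSE]
  rownames(out) <- NULL
  out$shared_mirnas <- vapply(seq_len(nrow(out)), function(i)
    paste(sort(intersect(lnc_sets[[out$lncRNA[i]]],
                         mrna_sets[[out$mRNA[i]]])), collapse = ";"), "")
  if (!nrow(out)) out <- empty
  structure(out, alpha = alpha, adjust = adjust, n_tested = n_tested,
            p_tested = p_all,
            class = c("CeRNAPairTable", "data.frame"))
}
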