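# Rank-rank hypergeometric overlap (RRHO) between two differential-expression
# signatures, plus the flat Fisher overlap of two gene sets.
#
# Genes are ranked by the signed significance score sign(logFC) * (-log10 p),
# so strongly induced genes sit at the top of the list and strongly repressed
# genes at the bottom. The RRHO map slides a threshold down both lists and
# tests the overlap of the two top fragments with a one-sided hypergeometric
# tail; the grid of tests is BH-adjusted and reported as -log10(FDR).

#' Rank genes by signed significance
#'
#' @param de_table data.frame with columns `gene`, `logFC`, `p` (p in (0,1];
#'   floor zero p-values upstream, e.g. at 1e-300).
#' @return data.frame (`gene`, `score`) ordered by descending score, ties
#'   broken by gene id.
#' @export
rank_genes <- function(de_table) {
  req <- c("gene", "logFC", "p")
  if (!all(req %in% names(de_table))) {
    stop("de_table needs columns gene, logFC, p")
  }
  if (anyDuplicated(de_table$gene)) stop("duplicate gene ids in de_table")
  if (any(is.na(de_table$p) | de_table$p <= 0 | de_table$p > 1)) {
    stop("p must lie in (0, 1]; floor zero p-values before ranking")
  }
  score <- sign(de_table$logFC) * (-log10(de_table$p))
  ord <- order(-score, de_table$gene)
  data.frame(gene = de_table$gene[ord], score = score[ord],
             stringsAsFactors = FALSE)
}

#' Upper tail of the hypergeometric distribution
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: `k` successes among `n`
#' draws without replacement from a population of `N` with `K` successes.
#' Exact (no normal approximation). Vectorized.
#'
#' @param N Population size.
#' @param K Successes in the population.
#' @param n Number of draws.
#' @param k Observed successes.
#' @return `P(X >= k)`.
#' @export
hypergeom_tail <- function(N, K, n, k) {
  bad <- k < 0 | K > N | n > N | k > pmin(K, n) | N < 0
  if (any(bad)) stop("need 0 <= k <= min(K, n) <= N")
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Rank-rank hypergeometric overlap map
#'
#' For each pair of rank thresholds `(i * step, j * step)` computes the
#' overlap of the two list heads and its one-sided hypergeometric tail
#' p-value; the full grid is BH-adjusted and returned as -log10(FDR). Rows
#' index thresholds in `list_a`, columns in `list_b`; the top-left corner
#' therefore measures concordance of the two list heads (up-up under the
#' signed-significance ranking).
#'
#' @param list_a,list_b Ranked lists from [rank_genes()] over the same gene
#'   universe.
#' @param step Genes per threshold increment; default `max(1, floor(N/100))`
#'   caps the map at 100 x 100.
#' @return List of class `rrho_map`: `neglog_fdr` matrix, `thresholds_a`,
#'   `thresholds_b`, `step`, `orientation`.
#' @export
rrho_map <- function(list_a, list_b, step = NULL) {
  missing_b <- setdiff(list_a$gene, list_b$gene)
  missing_a <- setdiff(list_b$gene, list_a$gene)
  if (length(missing_b) || length(missing_a)) {
    stop(sprintf("gene universes differ (e.g. %s)",
                 paste(utils::head(c(missing_b, missing_a), 3L), collapse = ", ")))
  }
  N <- nrow(list_a)
  if (is.null(step)) step <- max(1L, floor(N / 100))
  step <- as.integer(step)
  if (step < 1L) stop("step must be >= 1")
  M <- ceiling(N / step)
  rank_a <- seq_len(N)
  rank_b <- match(list_a$gene, list_b$gene)
  bin_a <- ceiling(rank_a / step)
  bin_b <- ceiling(rank_b / step)
  cnt <- unclass(table(factor(bin_a, levels = seq_len(M)),
                       factor(bin_b, levels = seq_len(M))))
  dimnames(cnt) <- NULL
  k <- apply(apply(cnt, 2L, cumsum), 1L, cumsum)  # k[j,i] after second apply
  k <- t(k)                                       # k[i,j] = |top_i(A) & top_j(B)|
  thr <- pmin(seq_len(M) * step, N)
  Kmat <- matrix(thr, M, M)             # draws-from-A threshold per row
  nmat <- matrix(thr, M, M, byrow = TRUE)
  p <- hypergeom_tail(N, Kmat, nmat, pmin(k, pmin(Kmat, nmat)))
  fdr <- matrix(stats::p.adjust(as.vector(p), method = "BH"), M, M)
  structure(list(neglog_fdr = -log10(fdr), thresholds_a = thr,
                 thresholds_b = thr, step = step,
                 orientation = "top-left corner = concordant heads (up-up)"),
            class = "rrho_map")
}

#' @export
print.rrho_map <- function(x, ...) {
  cat(sprintf("RRHO map: %d x %d thresholds (step %d); max -log10(FDR) = %.2f\n",
              nrow(x$neglog_fdr), ncol(x$neglog_fdr), x$step,
              max(x$neglog_fdr)))
  invisible(x)
}

#' Fisher exact overlap of two gene sets
#'
#' One-sided (enrichment) exact test on the 2x2 membership table over a
#' finite universe.
#'
#' @param set_a,set_b Character vectors, subsets of `universe`.
#' @param universe Character vector of all genes considered.
#' @return List with `overlap`, sample `odds_ratio`, and one-sided `p`.
#' @export
fisher_overlap <- function(set_a, set_b, universe) {
  if (!length(universe)) stop("universe must not be empty")
  universe <- unique(universe)
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop("sets must be subsets of the universe")
  }
  a <- length(intersect(set_a, set_b))
  b <- length(setdiff(set_a, set_b))
  cc <- length(setdiff(set_b, set_a))
  d <- length(universe) - a - b - cc
  tab <- matrix(c(a, b, cc, d), nrow = 2L)
  ft <- stats::fisher.test(tab, alternative = "greater")
  or <- if (b * cc == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * cc)
  list(overlap = a, odds_ratio = or, p = ft$p.value)
}
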