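# shared builders for toy fixtures; everything is generated in code

# single-chromosome track from a numeric vector
toy_track <- function(x, chrom = "chr1", condition = "toy") {
  signal_track(stats::setNames(list(as.numeric(x)), chrom), condition = condition)
}

# gene table on one chromosome
toy_genes <- function(tss, chrom = "chr1", ids = NULL) {
  n <- length(tss)
  if (is.null(ids)) ids <- sprintf("g%02d", seq_len(n))
  data.frame(gene_id = ids, chrom = chrom, tss = as.integer(tss),
             strand = "+", body_start = as.integer(tss),
             body_end = as.integer(tss + 1000L), stringsAsFactors = FALSE)
}

# a small, fast simulation configuration for property tests; any field can
# be overridden through ...
small_config <- function(seed, ...) {
  defaults <- list(n_chroms = 1L, chrom_length = 2e5L, n_genes = 60L,
                   n_tfs = 3L, sites_per_tf = 40L, n_targets = 8L,
                   n_replicates = 2L, n_haplotypes = 120L, n_variants = 300L,
                   ld_block_size = 10L, n_causal = 2L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, c(list(seed = seed), args))
}

# brute-force one-vs-many interval overlap (1-based closed coordinates)
brute_overlap <- function(q_start, q_end, q_chrom, s_start, s_end, s_chrom) {
  which(s_chrom == q_chrom & s_start <= q_end & s_end >= q_start)
}

# exhaustive hypergeometric upper tail by enumerating all draws of size n
# from a population 1..N with successes 1..K
enum_hyper_tail <- function(N, K, n, k) {
  if (n == 0L) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}
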