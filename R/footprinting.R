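# Bias-corrected footprint scoring at motif sites, per-site dynamic
# binding-site (DBS) calling at a two-fold change, and per-TF global
# differential binding with a size-matched permutation null.
#
# The footprint score of a site is the depletion of (corrected) cut signal
# in the motif relative to its immediate flanks: mean(flanks) - mean(center),
# clipped at zero. The bias model is a simple order-k k-mer rate division
# (default k = 2), which the synthetic generator plants exactly.

#' Footprinting parameters
#'
#' @param flank_width Flank window on each side of the motif, bp.
#' @param epsilon Pseudocount stabilizing the fold change between conditions.
#' @param kmer_k Order of the k-mer cut-bias model.
#' @param fold_threshold DBS log2 fold-change threshold ("two-fold" = 1).
#' @param tf_delta_threshold Per-TF effect-size threshold on the scaled
#'   score axis.
#' @param fdr_threshold Per-TF significance threshold (BH FDR).
#' @return List of class `FootprintParams`.
#' @export
footprint_params <- function(flank_width = 30L, epsilon = 0.01, kmer_k = 2L,
                             fold_threshold = 1.0, tf_delta_threshold = 0.1,
                             fdr_threshold = 0.05) {
  if (flank_width <= 0) stop("flank_width must be > 0")
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (fold_threshold <= 0) stop("fold_threshold must be > 0")
  structure(list(flank_width = as.integer(flank_width), epsilon = epsilon,
                 kmer_k = as.integer(kmer_k), fold_threshold = fold_threshold,
                 tf_delta_threshold = tf_delta_threshold,
                 fdr_threshold = fdr_threshold),
            class = "FootprintParams")
}

#' Correct intrinsic cut-site sequence bias
#'
#' Divides the raw signal at every base by the relative cut rate of the k-mer
#' starting there, then rescales so the library size matches the input.
#' K-mers absent from the rate table get rate 1; their count is reported in a
#' single warning.
#'
#' @param track A [signal_track()].
#' @param genome Named list of per-base character vectors (one per
#'   chromosome), as produced by [simulate_annotation()].
#' @param kmer_rates Named numeric vector of expected relative cut rates per
#'   k-mer.
#' @param params A [footprint_params()]; `kmer_k` sets the model order.
#' @return A bias-corrected [signal_track()] with the original library size.
#' @export
correct_bias <- function(track, genome, kmer_rates, params = footprint_params()) {
  stopifnot(inherits(track, "SignalTrack"))
  k <- params$kmer_k
  sizes <- track_chrom_sizes(track)
  if (!all(names(sizes) %in% names(genome))) {
    stop("genome does not cover all track chromosomes")
  }
  unseen <- 0L
  corrected <- lapply(names(sizes), function(ch) {
    x <- track$signal[[ch]]
    g <- genome[[ch]]
    if (length(g) != length(x)) stop(sprintf("genome length mismatch on %s", ch))
    n <- length(x)
    if (n < k) return(x)
    nk <- n - k + 1L
    key <- g[seq_len(nk)]
    if (k > 1L) {
      for (j in seq_len(k - 1L)) key <- paste0(key, g[(1L + j):(nk + j)])
    }
    r <- unname(kmer_rates[key])
    miss <- is.na(r)
    unseen <<- unseen + sum(miss)
    r[miss] <- 1
    rate <- c(r, rep(1, k - 1L))  # trailing bases have no full k-mer
    x / rate
  })
  names(corrected) <- names(sizes)
  if (unseen > 0L) {
    warning(sprintf("%d position(s) carried a k-mer absent from the rate table; rate 1 used",
                    unseen))
  }
  out <- signal_track(corrected, condition = track$condition)
  if (out$library_size > 0 && track$library_size > 0) {
    f <- track$library_size / out$library_size
    out <- signal_track(lapply(out$signal, function(x) x * f),
                        condition = track$condition)
  }
  out
}

#' Footprint score of motif sites
#'
#' Score = max(0, mean signal in the two `flank_width` windows abutting the
#' site minus mean signal within the site). Vectorized over sites.
#'
#' @param track A [signal_track()] (bias-corrected, depth-normalized).
#' @param sites A GRanges of motif sites.
#' @param params A [footprint_params()].
#' @return Numeric vector of scores, one per site.
#' @export
footprint_score <- function(track, sites, params = footprint_params()) {
  stopifnot(inherits(track, "SignalTrack"))
  f <- params$flank_width
  sizes <- track_chrom_sizes(track)
  chrom <- as.character(GenomicRanges::seqnames(sites))
  if (!all(chrom %in% names(sizes))) stop("site chromosome absent from track")
  s <- GenomicRanges::start(sites)
  e <- GenomicRanges::end(sites)
  if (any(s - f < 1L) || any(e + f > sizes[chrom])) {
    stop("site plus flanks extends beyond the chromosome")
  }
  score <- numeric(length(sites))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    cs <- c(0, cumsum(track$signal[[ch]]))
    si <- s[idx]; ei <- e[idx]
    center <- (cs[ei + 1L] - cs[si]) / (ei - si + 1L)
    flanks <- ((cs[si] - cs[si - f]) + (cs[ei + f + 1L] - cs[ei + 1L])) / (2 * f)
    score[idx] <- pmax(0, flanks - center)
  }
  score
}

#' Call dynamic binding sites between two conditions
#'
#' Per site, the change is `log2((score_treated + eps) / (score_control +
#' eps))`; sites with `|change| >= fold_threshold` are dynamic, labelled
#' `activated` (change > 0) or `repressed`.
#'
#' @param per_tf_sites Named list: TF -> GRanges of motif sites.
#' @param treated,control Depth-normalized, bias-corrected [signal_track()]s.
#' @param params A [footprint_params()].
#' @return A GRanges of dynamic sites with metadata `tf`, `site_id` (when
#'   present on the input), `score_treated`, `score_control`, `delta`
#'   (log2 change) and `direction`.
#' @export
call_dbs <- function(per_tf_sites, treated, control, params = footprint_params()) {
  eps <- params$epsilon
  out <- lapply(names(per_tf_sites), function(tf) {
    sites <- per_tf_sites[[tf]]
    if (!length(sites)) return(NULL)
    st <- footprint_score(treated, sites, params)
    sc <- footprint_score(control, sites, params)
    delta <- log2((st + eps) / (sc + eps))
    keep <- abs(delta) >= params$fold_threshold
    if (!any(keep)) return(NULL)
    g <- sites[keep]
    S4Vectors::mcols(g) <- NULL
    g$tf <- tf
    if (!is.null(sites$site_id)) g$site_id <- sites$site_id[keep]
    g$score_treated <- st[keep]
    g$score_control <- sc[keep]
    g$delta <- delta[keep]
    g$direction <- ifelse(delta[keep] > 0, "activated", "repressed")
    g
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    g <- GenomicRanges::GRanges()
    g$tf <- character(0); g$score_treated <- numeric(0)
    g$score_control <- numeric(0); g$delta <- numeric(0)
    g$direction <- character(0)
    return(g)
  }
  unlist(GenomicRanges::GRangesList(out), use.names = FALSE)
}

#' Per-TF global differential binding
#'
#' Footprint scores of all sites of all TFs are min-max scaled to `[0, 1]`
#' (jointly over both conditions); each TF's effect is the mean per-site
#' scaled-score change (treated minus control). Significance comes from
#' `n_perm` means of size-matched random site draws from the pooled site
#' universe (two-sided, add-one), with BH correction across TFs. A TF is
#' flagged significant when `fdr < fdr_threshold` and `|delta_score| >
#' tf_delta_threshold`.
#'
#' @param per_tf_sites Named list: TF -> GRanges of motif sites (>= 2 TFs
#'   with sites required; TFs with zero sites are dropped with a warning).
#' @param treated,control Depth-normalized, bias-corrected [signal_track()]s.
#' @param params A [footprint_params()].
#' @param n_perm Number of permutation draws.
#' @param seed Permutation seed.
#' @return data.frame with `tf`, `delta_score`, `p`, `fdr`, `n_sites`,
#'   `significant`.
#' @export
tf_differential <- function(per_tf_sites, treated, control,
                            params = footprint_params(), n_perm = 1000L,
                            seed = 1L) {
  empty <- vapply(per_tf_sites, function(g) length(g) == 0L, logical(1))
  if (any(empty)) {
    warning(sprintf("excluding TF(s) with no sites: %s",
                    paste(names(per_tf_sites)[empty], collapse = ", ")))
    per_tf_sites <- per_tf_sites[!empty]
  }
  if (length(per_tf_sites) < 2L) {
    stop("tf_differential needs at least two TFs with sites")
  }
  tf_of <- rep(names(per_tf_sites), vapply(per_tf_sites, length, integer(1)))
  all_sites <- unlist(GenomicRanges::GRangesList(lapply(per_tf_sites, function(g) {
    S4Vectors::mcols(g) <- NULL
    g
  })), use.names = FALSE)
  st <- footprint_score(treated, all_sites, params)
  sc <- footprint_score(control, all_sites, params)
  rng <- range(c(st, sc))
  span <- diff(rng)
  if (span > 0) {
    st <- (st - rng[1L]) / span
    sc <- (sc - rng[1L]) / span
  } else {
    st <- st * 0
    sc <- sc * 0
  }
  d <- st - sc
  center <- mean(d)
  tfs <- names(per_tf_sites)
  obs <- vapply(tfs, function(tf) mean(d[tf_of == tf]), numeric(1))
  set.seed(seed)
  p <- vapply(tfs, function(tf) {
    n_t <- sum(tf_of == tf)
    null_means <- vapply(seq_len(n_perm), function(i) {
      mean(d[sample.int(length(d), n_t)])
    }, numeric(1))
    (1 + sum(abs(null_means - center) >= abs(obs[[tf]] - center))) / (n_perm + 1)
  }, numeric(1))
  out <- data.frame(tf = tfs, delta_score = unname(obs), p = unname(p),
                    fdr = stats::p.adjust(p, method = "BH"),
                    n_sites = vapply(tfs, function(tf) sum(tf_of == tf), integer(1)),
                    stringsAsFactors = FALSE)
  out$significant <- out$fdr < params$fdr_threshold &
    abs(out$delta_score) > params$tf_delta_threshold
  rownames(out) <- NULL
  out[order(out$p, out$tf), , drop = FALSE]
}
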