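# regulatory-potential scoring, in-silico deletion and the targeted ISD null

test_that("RP weights decay as designed: 1 at the TSS, 1/2 at delta", {
  # bin centers at 5, 15, 25, ... for bin_size 10
  p <- rp_params(decay_half_distance = 10, window = 50, bin_size = 10)
  x <- numeric(100)
  x[3] <- 1  # mass inside bin 1 (center 5)
  tr <- toy_track(x)
  g <- toy_genes(5)
  expect_equal(unname(compute_rp(tr, g, p)), 1.0)
  y <- numeric(100); y[12] <- 1  # bin 2, center 15 = delta away from tss 5
  expect_equal(unname(compute_rp(toy_track(y), g, p)), 0.5)
  expect_equal(unname(compute_rp(toy_track(x + y), g, p)), 1.5)
  # bins beyond the window contribute nothing
  z <- numeric(100); z[95] <- 100
  expect_equal(unname(compute_rp(toy_track(z), g, p)), 0)
})

test_that("RP is linear in the signal and errors on off-chromosome TSS", {
  set.seed(8)
  tr <- toy_track(rpois(5000, 1))
  g <- toy_genes(c(1000, 2500, 4000))
  p <- rp_params(decay_half_distance = 200, window = 1000, bin_size = 100)
  rp1 <- compute_rp(tr, g, p)
  tr3 <- toy_track(tr$signal$chr1 * 3)
  expect_equal(compute_rp(tr3, g, p), 3 * rp1)
  expect_error(compute_rp(tr, toy_genes(6000), p), "off its chromosome")
  expect_error(rp_params(bin_size = 333), "divide")
})

test_that("RP matches an independent per-base summation at bin_size 1", {
  set.seed(14)
  n <- 20L
  x <- runif(n) * 5
  g <- toy_genes(c(4, 11, 17))
  p <- rp_params(decay_half_distance = 3, window = 9, bin_size = 1)
  got <- compute_rp(toy_track(x), g, p)
  # oracle: loop over bases, weight 2^(-|center - tss| / delta), centers at
  # i - 0.5 for 1 bp bins
  want <- vapply(g$tss, function(tss) {
    s <- 0
    for (i in seq_len(n)) {
      d <- abs((i - 0.5) - tss)
      if (d <= 9) s <- s + x[i] * 2^(-d / 3)
    }
    s
  }, numeric(1))
  expect_equal(unname(got), want, tolerance = 1e-9)
})

test_that("in-silico deletion zeroes exactly the masked bases", {
  set.seed(2)
  x <- rpois(300, 2)
  tr <- toy_track(x)
  expect_equal(insilico_delete(tr, GenomicRanges::GRanges())$signal$chr1, as.numeric(x))
  all_sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 300))
  expect_equal(insilico_delete(tr, all_sites)$library_size, 0)
  site <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 150))
  del <- insilico_delete(tr, site)
  expect_equal(del$signal$chr1[101:150], rep(0, 50))
  expect_equal(del$signal$chr1[-(101:150)], as.numeric(x[-(101:150)]))
})

test_that("masking a site holding 30% of a gene's weighted signal drops RP by 30%", {
  p <- rp_params(decay_half_distance = 1000, window = 4000, bin_size = 100)
  x <- numeric(10000)
  x[1950] <- 7   # same bin as the TSS (bin 20, center 1950)
  x[2250] <- 3 * 2^(300 / 1000)  # bin 23: decay-weighted contribution = 3
  tr <- toy_track(x)
  g <- toy_genes(1950)
  rp0 <- compute_rp(tr, g, p)
  rp1 <- compute_rp(insilico_delete(tr, GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(2201, 2300))), g, p)
  expect_equal(unname(delta_rp(rp0, rp1)), 0.3, tolerance = 1e-12)
})

test_that("delta_rp arithmetic, guards and edge cases", {
  before <- c(a = 10, b = 5, c = 0)
  expect_equal(unname(delta_rp(before, c(a = 8.9, b = 5, c = 0))["a"]), 0.11)
  expect_equal(unname(delta_rp(before, before)), c(0, 0, 0))
  expect_equal(unname(delta_rp(before, c(a = 0, b = 0, c = 0))), c(1, 1, 0))
  expect_error(delta_rp(before, c(a = 11, b = 5, c = 0)), "never add")
  expect_error(delta_rp(before, c(a = 1, b = 1)), "different gene universes")
})

test_that("deleting a superset of sites never shrinks any gene's delta-RP", {
  set.seed(77)
  tr <- toy_track(rpois(50000, 1) + 2)
  g <- toy_genes(seq(5000, 45000, length.out = 12))
  p <- rp_params()
  starts <- sample(2000:47000, 30)
  sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(starts, width = 15))
  for (k in c(5, 15)) {
    d_small <- isd_delta_rp(tr, sites[1:k], g, delete_pad = 100, params = p)
    d_big <- isd_delta_rp(tr, sites[1:(k + 10)], g, delete_pad = 100, params = p)
    expect_true(all(d_big >= d_small - 1e-12))
  }
})

test_that("background matching reproduces the DE expression profile", {
  set.seed(5)
  genes <- sprintf("g%03d", 1:200)
  expr <- stats::setNames(2^rnorm(200, 5, 1.5), genes)
  de <- sample(genes, 30)
  sets <- match_background_genes(de, genes, expr, n_sets = 200, set_size = 30,
                                 seed = 42)
  expect_length(sets, 200L)
  expect_true(all(lengths(sets) == 30L))
  expect_false(any(vapply(sets, function(s) any(s %in% de), logical(1))))
  # no duplicates within a set
  expect_true(all(vapply(sets, function(s) !anyDuplicated(s), logical(1))))
  # matched sets track the DE mean expression within 5%
  m <- mean(vapply(sets, function(s) mean(expr[s]), numeric(1)))
  expect_lt(abs(m - mean(expr[de])) / mean(expr[de]), 0.05)
  # determinism
  sets2 <- match_background_genes(de, genes, expr, n_sets = 200, set_size = 30,
                                  seed = 42)
  expect_identical(sets, sets2)
  expect_error(match_background_genes(de, genes, expr, 10, set_size = 10),
               "set_size")
})

test_that("a fully concentrated DE stratum exhausts-or-errors cleanly", {
  genes <- sprintf("g%02d", 1:40)
  expr <- stats::setNames(seq_along(genes), genes)
  de <- genes[17:20]  # all of stratum 5 under 10 bins of 4
  expect_error(
    match_background_genes(de, genes, expr, n_sets = 5, set_size = 4),
    "stratum 5")
  # with 4 bins the stratum holds 10 genes: all background comes from it
  sets <- match_background_genes(de, genes, expr, n_sets = 20, set_size = 4,
                                 n_bins = 4, seed = 1)
  expect_true(all(unlist(sets) %in% genes[11:20]))
})

test_that("targeted ISD handles the empty and threshold edge cases", {
  set.seed(10)
  tr <- toy_track(rpois(20000, 1) + 1)
  g <- toy_genes(seq(2000, 18000, length.out = 8))
  expr <- stats::setNames(rep(c(1, 2), 4), g$gene_id)
  res <- targeted_isd(tr, GenomicRanges::GRanges(), g, g$gene_id[1:2], expr,
                      n_null = 50, n_bins = 2, seed = 1)
  expect_equal(res$observed, 0L)
  expect_equal(res$p, 1)
  expect_true(all(res$null_counts == 0))
})

test_that("a gene at exactly the disruption threshold is not counted", {
  # construct delta-RP of exactly 0.10 for the single DE gene: the TSS bin
  # holds 10 units and the masked base holds exactly 1 of them
  p <- rp_params(decay_half_distance = 1000, window = 4000, bin_size = 100)
  x <- numeric(10000)
  x[1950] <- 9    # TSS bin (1901-2000)
  x[1910] <- 1    # same bin, so both carry weight 1
  tr <- toy_track(x)
  g <- toy_genes(c(1950, 5950))
  expr <- stats::setNames(c(1, 1), g$gene_id)
  site <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1910, 1910))
  drp <- isd_delta_rp(tr, site, g, delete_pad = 0, params = p)
  expect_equal(unname(drp[1]), 0.1, tolerance = 1e-12)
  res <- targeted_isd(tr, site, g, g$gene_id[1], expr, n_null = 20,
                      delete_pad = 0, disrupt_threshold = 0.10, n_bins = 1,
                      seed = 1, params = p)
  expect_equal(res$observed, 0L)
})

test_that("regulator ranking rejects bad inputs and bottoms out silent TFs", {
  g <- sprintf("g%d", 1:30)
  d0 <- stats::setNames(rep(0, 30), g)
  d1 <- stats::setNames(c(rep(0.5, 5), runif(25, 0, 0.2)), g)
  rr <- rank_regulators(list(quiet = d0, loud = d1), g[1:5], g,
                        n_background = 10, seed = 2)
  expect_equal(rr$tf[1], "loud")
  expect_equal(rr$p[rr$tf == "quiet"], 1)
  expect_true(all(rr$fdr >= rr$p))
  expect_error(rank_regulators(list(a = d1), character(0), g, 10), "empty")
  expect_error(rank_regulators(list(a = d1), g[1:5], g, n_background = 28),
               "exceeds")
})
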