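# LD computation, pruning/pooling, filters, DBS overlap and annotation

panel_from_counts <- function(n11, n10, n01, n00) {
  x <- c(rep(1, n11), rep(1, n10), rep(0, n01), rep(0, n00))
  y <- c(rep(1, n11), rep(0, n10), rep(1, n01), rep(0, n00))
  m <- cbind(a = x, b = y)
  m
}

test_that("r2 reproduces hand-computed haplotype correlations", {
  expect_equal(compute_r2(panel_from_counts(50, 0, 0, 50), "a", "b"), 1)
  expect_equal(compute_r2(panel_from_counts(25, 25, 25, 25), "a", "b"), 0)
  # counts 40/10/10/40: pA = pB = 0.5, pAB = 0.4 -> r2 = 0.36
  expect_equal(compute_r2(panel_from_counts(40, 10, 10, 40), "a", "b"), 0.36,
               tolerance = 1e-12)
  expect_error(compute_r2(panel_from_counts(50, 50, 0, 0), "a", "b"),
               "monomorphic")
})

test_that("r2 is symmetric and bounded on random panels", {
  set.seed(17)
  panel <- matrix(rbinom(200 * 12, 1, runif(12, 0.2, 0.8)[rep(1:12, each = 200)]),
                  nrow = 200)
  colnames(panel) <- sprintf("v%02d", 1:12)
  for (k in 1:20) {
    ij <- sample(12, 2)
    r <- compute_r2(panel, ij[1], ij[2])
    expect_equal(r, compute_r2(panel, ij[2], ij[1]))
    expect_gte(r, 0); expect_lte(r, 1)
  }
})

test_that("greedy pruning keeps the smaller-p proxy and audits pairwise r2", {
  v <- data.frame(rsid = c("a", "b"), chrom = "chr1", p = c(1e-10, 1e-9))
  panel <- panel_from_counts(50, 0, 0, 50)
  out <- ld_prune(v, panel)
  expect_equal(out$rsid, "a")
  # single variant: kept
  expect_equal(ld_prune(v[1, ], panel[, "a", drop = FALSE])$rsid, "a")
  # synthetic panel audit: retained set pairwise r2 <= 0.1
  cfg <- small_config(seed = 33)
  ann <- simulate_annotation(cfg)
  gw <- simulate_haplotypes_gwas(cfg, ann$altered)
  kept <- ld_prune(gw$variants, gw$panel, r2_max = 0.1)
  expect_gt(nrow(kept), 1L)
  n_check <- min(12L, nrow(kept))
  for (i in seq_len(n_check - 1L)) {
    for (j in seq.int(i + 1L, n_check)) {
      if (kept$chrom[i] == kept$chrom[j]) {
        expect_lte(compute_r2(gw$panel, kept$rsid[i], kept$rsid[j]), 0.1)
      }
    }
  }
  # input order does not matter
  shuffled <- gw$variants[sample(nrow(gw$variants)), ]
  expect_equal(ld_prune(shuffled, gw$panel, 0.1)$rsid, kept$rsid)
})

test_that("pooling is strict at the threshold and resolves contested proxies", {
  v <- data.frame(rsid = c("a", "b"), chrom = "chr1", p = c(1e-10, 0.5))
  perfect <- panel_from_counts(50, 0, 0, 50)
  pools <- ld_pool(v[1, ], v, perfect, r2_min = 0.8)
  expect_equal(pools$a, c("a", "b"))
  # no proxies above threshold: the pool is the index alone
  indep <- panel_from_counts(25, 25, 25, 25)
  expect_equal(ld_pool(v[1, ], v, indep, r2_min = 0.8)$a, "a")
  # r2 exactly equal to the threshold is NOT pooled (strict inequality)
  mid <- panel_from_counts(40, 10, 10, 40)
  r2_exact <- compute_r2(mid, "a", "b")
  expect_equal(ld_pool(v[1, ], v, mid, r2_min = r2_exact)$a, "a")
  # contested proxy goes to the lower-p index
  tri <- cbind(panel_from_counts(50, 0, 0, 50), c = panel_from_counts(50, 0, 0, 50)[, 1])
  vv <- data.frame(rsid = c("a", "c", "b"), chrom = "chr1", p = c(1e-10, 1e-4, 0.5))
  pl <- ld_pool(vv[1:2, ], vv, tri, r2_min = 0.8)
  expect_true("b" %in% pl$a)
  expect_false("b" %in% pl$c)
})

test_that("significance and MAF filters are strict", {
  v <- data.frame(rsid = c("a", "b", "c", "d"),
                  p = c(5e-8, 4.9e-8, 1e-9, 1e-9),
                  maf = c(0.2, 0.2, 0.009, 0.01))
  out <- filter_variants(v)
  expect_equal(out$rsid, "b")
})

test_that("variants land in extended DBSs with half-open boundary behaviour", {
  dbs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2001, 2015))
  dbs$site_id <- "s1"
  v <- data.frame(rsid = c("in_site", "in_pad", "past_end"),
                  chrom = "chr1",
                  pos = c(2010L, 2515L, 2516L),  # extended end = 2015 + 500
                  ref = "A", alt = "C", p = c(1e-9, 1e-9, 1e-9))
  pools <- list(in_site = c("in_site", "in_pad", "past_end"))
  tab <- overlap_dbs_variants(pools, v, dbs, pad = 500)
  expect_equal(sort(tab$rsid), c("in_pad", "in_site"))
  expect_true(all(tab$locus_id == 1L))
  expect_true(all(tab$index_rsid == "in_site"))
  # the printed interval is BED-style 0-based half-open
  expect_equal(unique(tab$dbs), "chr1-1500-2515")
})

test_that("annotation reports gene bodies and intergenic positions", {
  genes <- data.frame(gene_id = c("CALCRL", "TFPI"), chrom = "chr2",
                      body_start = c(1000L, 9000L), body_end = c(2000L, 9500L))
  expect_equal(annotate_variant("chr2", 1500, genes), "CALCRL intron")
  expect_equal(annotate_variant("chr2", 5000, genes), "Intergenic region")
  expect_equal(annotate_variant("chr3", 1500, genes), "Intergenic region")
  # body ends are closed in 1-based coordinates; one past is intergenic
  expect_equal(annotate_variant("chr2", 2000, genes), "CALCRL intron")
  expect_equal(annotate_variant("chr2", 2001, genes), "Intergenic region")
})

test_that("allelic imbalance is an exact two-sided binomial test", {
  expect_equal(allelic_imbalance(10, 10), 1)
  expect_equal(allelic_imbalance(20, 0), 2 * 0.5^20, tolerance = 1e-12)
  expect_error(allelic_imbalance(0, 0), "at least 1")
  expect_error(allelic_imbalance(-1, 5), "non-negative")
})

test_that("allelic imbalance p-values are calibrated under balanced counts", {
  set.seed(77)
  k <- rbinom(500, 50, 0.5)
  ps <- vapply(k, function(x) allelic_imbalance(x, 50 - x), numeric(1))
  # no excess of small p-values (one-sided KS against uniform)
  ks <- suppressWarnings(stats::ks.test(ps, "punif", alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
  # the empirical rejection rate matches the exact achievable level
  exact <- sum(stats::dbinom(0:50, 50, 0.5)[
    vapply(0:50, function(x) stats::binom.test(x, 50)$p.value, numeric(1)) <= 0.05])
  expect_lt(abs(mean(ps <= 0.05) - exact), 3 * sqrt(exact * (1 - exact) / 500))
})

test_that("the printed prioritized-variant table parses and groups into loci", {
  f <- system.file("extdata", "prioritized_variants.tsv", package = "regshift")
  tab <- read_prioritized_table(f)
  expect_equal(nrow(tab), 8L)
  expect_equal(length(unique(tab$locus_id)), 5L)
  expect_equal(tab$pos[tab$rsid == "rs56170783"], 56550459L)
  expect_s4_class(attr(tab, "dbs_ranges"), "GRanges")
})
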