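# Seeded generator for a complete toy dataset with the statistical structure
# the downstream stages assume: Poisson cut counts with peak enrichment and
# footprint depletion at motif sites, a planted regulator whose altered sites
# sit near designated target genes, replicate-level expression with a planted
# log-fold-change, a concordance-tunable second signature, and LD-block
# haplotypes with causal variants planted inside altered binding sites.
#
# One master seed drives everything; each stage re-seeds at a fixed offset so
# adding a stage never perturbs the draws of earlier stages.

# fixed, recorded dinucleotide cut-bias lookup (relative rates)
.dinuc_bias <- c(
  AA = 0.62, AC = 1.41, AG = 0.85, AT = 1.12,
  CA = 1.55, CC = 0.72, CG = 0.50, CT = 1.05,
  GA = 1.18, GC = 0.95, GG = 0.66, GT = 1.33,
  TA = 0.78, TC = 1.25, TG = 1.48, TT = 0.58
)

#' Simulation configuration
#'
#' Defaults describe the desk-scale study conditions: 2 chromosomes of 1 Mb,
#' 200 genes, 5 TFs with 200 motif sites each, 2,000 variants over 500
#' haplotypes. `regulator_effect` is the log2 fold-change planted on target
#' genes of the designated regulator (TF1); `footprint_depth` is the
#' fractional depletion of cut signal within a bound motif.
#'
#' @param seed Integer master seed (absolute value below 2^31 - 16).
#' @param n_chroms,chrom_length Genome shape.
#' @param n_genes Number of gene models.
#' @param n_tfs,sites_per_tf,site_width Motif-site universe shape.
#' @param frac_altered_sites Fraction of the planted regulator's sites whose
#'   binding changes with treatment (each placed near a target gene).
#' @param footprint_depth Fractional center depletion at bound motifs, in
#'   `[0,1]`.
#' @param peak_height,background_rate Mean cuts/bp inside peaks (+/-
#'   `peak_pad` bp around each site) and elsewhere.
#' @param peak_pad Half-width of the accessible peak around each site, bp.
#' @param regulator_effect log2 fold-change added to target genes in the
#'   treated condition.
#' @param n_replicates Replicates per condition (>= 2).
#' @param rep_sd Replicate noise sd on the log2 expression scale.
#' @param plaque_concordance Correlation `rho` between the treated signature
#'   and the second ("plaque-like") signature used for rank-rank overlap.
#' @param n_targets Number of target genes of the planted regulator.
#' @param n_haplotypes,n_variants,ld_block_size Haplotype panel shape; LD
#'   blocks are runs of `ld_block_size` consecutive variants.
#' @param n_causal Number of planted causal GWAS loci.
#' @param causal_in_dbs Place each causal variant inside an altered binding
#'   site of the planted regulator.
#' @param regulator_mode `"activation"` (altered sites bound in treated only)
#'   or `"repression"` (bound in control only).
#' @return A validated list of class `SimulationConfig`.
#' @export
sim_config <- function(seed,
                       n_chroms = 2L, chrom_length = 1e6L,
                       n_genes = 200L,
                       n_tfs = 5L, sites_per_tf = 200L, site_width = 15L,
                       frac_altered_sites = 0.5,
                       footprint_depth = 0.5,
                       peak_height = 2.0, background_rate = 0.05,
                       peak_pad = 200L,
                       regulator_effect = 2,
                       n_replicates = 3L, rep_sd = 0.4,
                       plaque_concordance = 0.7,
                       n_targets = 25L,
                       n_haplotypes = 500L, n_variants = 2000L,
                       ld_block_size = 20L,
                       n_causal = 4L, causal_in_dbs = TRUE,
                       regulator_mode = c("activation", "repression")) {
  cfg <- list(
    seed = as.integer(seed),
    n_chroms = as.integer(n_chroms), chrom_length = as.integer(chrom_length),
    n_genes = as.integer(n_genes),
    n_tfs = as.integer(n_tfs), sites_per_tf = as.integer(sites_per_tf),
    site_width = as.integer(site_width),
    frac_altered_sites = frac_altered_sites,
    footprint_depth = footprint_depth,
    peak_height = peak_height, background_rate = background_rate,
    peak_pad = as.integer(peak_pad),
    regulator_effect = regulator_effect,
    n_replicates = as.integer(n_replicates), rep_sd = rep_sd,
    plaque_concordance = plaque_concordance,
    n_targets = as.integer(n_targets),
    n_haplotypes = as.integer(n_haplotypes), n_variants = as.integer(n_variants),
    ld_block_size = as.integer(ld_block_size),
    n_causal = as.integer(n_causal), causal_in_dbs = isTRUE(causal_in_dbs),
    regulator_mode = match.arg(regulator_mode)
  )
  counts <- c("n_chroms", "chrom_length", "n_genes", "n_tfs", "sites_per_tf",
              "site_width", "n_replicates", "n_haplotypes", "n_variants",
              "ld_block_size", "n_targets")
  if (any(vapply(cfg[counts], function(x) is.na(x) || x <= 0L, logical(1)))) {
    stop("all size parameters must be positive integers")
  }
  if (is.na(cfg$seed) || abs(seed) >= 2^31 - 16) stop("seed must be an integer below 2^31 - 16")
  if (cfg$frac_altered_sites < 0 || cfg$frac_altered_sites > 1) {
    stop("frac_altered_sites must be in [0, 1]")
  }
  if (cfg$footprint_depth < 0 || cfg$footprint_depth > 1) {
    stop("footprint_depth must be in [0, 1]")
  }
  if (cfg$peak_height < 0 || cfg$background_rate < 0) stop("rates must be >= 0")
  if (cfg$n_replicates < 2L) stop("n_replicates must be at least 2")
  if (cfg$plaque_concordance < -1 || cfg$plaque_concordance > 1) {
    stop("plaque_concordance must be in [-1, 1]")
  }
  if (cfg$n_targets >= cfg$n_genes) stop("n_targets must be smaller than n_genes")
  if (cfg$n_causal < 0L) stop("n_causal must be >= 0")
  class(cfg) <- "SimulationConfig"
  cfg
}

# Resolve within-chromosome overlaps among candidate sites by redrawing the
# clashing ones; `redraw(i)` regenerates a start for site i under its own rule.
.resolve_overlaps <- function(abs_start, width, redraw, max_iter = 200L) {
  for (iter in seq_len(max_iter)) {
    ir <- IRanges::IRanges(start = abs_start, width = width)
    ov <- IRanges::findOverlaps(ir, drop.self = TRUE)
    clash <- unique(S4Vectors::queryHits(ov))
    if (!length(clash)) return(abs_start)
    for (i in clash) abs_start[i] <- redraw(i)
  }
  stop("genome too small to place sites without overlap")
}

#' Simulate gene models and TF binding-site sets
#'
#' Places gene TSSs uniformly (with a margin so regulatory-potential windows
#' stay interior), draws a random genome sequence for the dinucleotide bias
#' model, and places `site_width`-bp motif sites per TF, non-overlapping
#' within a TF. TF1 is the planted regulator: a `frac_altered_sites` fraction
#' of its sites is marked altered, each placed within 10 kb of a designated
#' target gene's TSS.
#'
#' @param cfg A [sim_config()].
#' @return List with `chrom_sizes`, `genome` (list of per-base vectors),
#'   `bias` (named dinucleotide rate lookup), `genes` (data.frame with
#'   gene_id, chrom, tss, strand, body extents, baseline expression),
#'   `sites` (named list of GRanges with `site_id` and `altered` columns),
#'   `regulator`, `altered` (GRanges), `targets` (gene ids).
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed + 1L)
  L <- cfg$chrom_length
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  chrom_sizes <- stats::setNames(rep(L, cfg$n_chroms), chroms)
  genome <- lapply(chrom_sizes, function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE))

  margin <- min(120000L, max(1000L, L %/% 5L))
  if (L <= 2L * margin + 10L) margin <- L %/% 4L
  gene_chrom <- sample(chroms, cfg$n_genes, replace = TRUE)
  tss <- margin + sample.int(L - 2L * margin, cfg$n_genes, replace = TRUE)
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  body_len <- round(stats::runif(cfg$n_genes, 5000, 50000))
  body_start <- ifelse(strand == "+", tss, pmax(1, tss - body_len))
  body_end <- ifelse(strand == "+", pmin(L, tss + body_len), tss)
  genes <- data.frame(
    gene_id = sprintf("G%03d", seq_len(cfg$n_genes)),
    chrom = gene_chrom, tss = as.integer(tss), strand = strand,
    body_start = as.integer(body_start), body_end = as.integer(body_end),
    expression = 2^stats::rnorm(cfg$n_genes, mean = 5, sd = 1.5),
    stringsAsFactors = FALSE
  )
  targets <- sort(sample(genes$gene_id, cfg$n_targets))

  w <- cfg$site_width
  lo <- cfg$peak_pad + 1001L          # keep peaks and footprint flanks interior
  hi <- L - cfg$peak_pad - w - 1000L
  if (hi <= lo) stop("genome too small to place sites without overlap")
  tfs <- paste0("TF", seq_len(cfg$n_tfs))
  regulator <- tfs[1L]
  n_alt <- round(cfg$frac_altered_sites * cfg$sites_per_tf)
  chrom_off <- stats::setNames((seq_along(chroms) - 1L) * L, chroms)

  draw_near <- function(t0) {
    d <- sample(c(-1L, 1L), 1L) * (500L + sample.int(9500L, 1L))
    as.integer(min(max(t0 + d, lo), hi))
  }
  draw_unif <- function() lo + sample.int(hi - lo, 1L)

  sites <- vector("list", cfg$n_tfs)
  names(sites) <- tfs
  for (tf in tfs) {
    if (tf == regulator && n_alt > 0L) {
      alt_genes <- rep(targets, length.out = n_alt)
      gi <- match(alt_genes, genes$gene_id)
      alt_chrom <- genes$chrom[gi]
      anchor_tss <- genes$tss[gi]
    } else {
      alt_chrom <- character(0)
      anchor_tss <- integer(0)
    }
    n_unif <- cfg$sites_per_tf - length(alt_chrom)
    site_chrom <- c(alt_chrom, sample(chroms, n_unif, replace = TRUE))
    anchor <- c(anchor_tss, rep(NA_integer_, n_unif))
    start1 <- vapply(seq_along(site_chrom), function(i) {
      if (is.na(anchor[i])) draw_unif() else draw_near(anchor[i])
    }, integer(1))
    abs_start <- .resolve_overlaps(
      start1 + chrom_off[site_chrom], w,
      redraw = function(i) {
        s <- if (is.na(anchor[i])) draw_unif() else draw_near(anchor[i])
        s + chrom_off[[site_chrom[i]]]
      }
    )
    start1 <- as.integer(abs_start - chrom_off[site_chrom])
    gr <- GenomicRanges::GRanges(site_chrom, IRanges::IRanges(start = start1, width = w))
    gr$site_id <- sprintf("%s_s%03d", tf, seq_along(gr))
    gr$altered <- c(rep(TRUE, length(alt_chrom)), rep(FALSE, n_unif))
    sites[[tf]] <- gr
  }

  altered <- sites[[regulator]][sites[[regulator]]$altered]
  list(chrom_sizes = chrom_sizes, genome = genome, bias = .dinuc_bias,
       genes = genes, sites = sites, regulator = regulator,
       altered = altered, targets = targets)
}

# per-base dinucleotide bias multiplier for one chromosome's base vector
.bias_vector <- function(bases, bias) {
  n <- length(bases)
  if (n < 2L) return(rep(1, n))
  key <- paste0(bases[-n], bases[-1L])
  b <- unname(bias[key])
  b[is.na(b)] <- 1
  c(b, 1)
}

#' Simulate per-base cut-count tracks
#'
#' Per-base counts are Poisson with mean `background_rate`, elevated to
#' `peak_height` within `peak_pad` bp of every site. Within a bound site's
#' motif span the rate is multiplied by `1 - footprint_depth`; altered sites
#' of the planted regulator are bound in the treated condition only
#' (activation mode) or the control condition only (repression mode). Every
#' base is further modulated by the recorded dinucleotide bias lookup.
#'
#' @param cfg A [sim_config()].
#' @param annotation Output of [simulate_annotation()].
#' @return Named list of [signal_track()]s, one per `(condition, replicate)`,
#'   with names like `"treated_1"`, plus attribute `"rates"` holding the
#'   per-condition expected-rate vectors (before Poisson noise).
#' @export
simulate_cut_tracks <- function(cfg, annotation) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed + 2L)
  chroms <- names(annotation$chrom_sizes)
  all_sites <- unlist(GenomicRanges::GRangesList(annotation$sites), use.names = FALSE)
  bias_by_chrom <- lapply(chroms, function(ch)
    .bias_vector(annotation$genome[[ch]], annotation$bias))
  names(bias_by_chrom) <- chroms

  bound_in <- function(cond) {
    # altered regulator sites are condition-specific; all others always bound
    alt <- all_sites$altered
    if (cfg$regulator_mode == "activation") !alt | (cond == "treated")
    else !alt | (cond == "control")
  }

  rates <- list()
  for (cond in c("treated", "control")) {
    keep <- bound_in(cond)
    site_chrom <- as.character(GenomicRanges::seqnames(all_sites))
    rate <- lapply(chroms, function(ch) {
      L <- annotation$chrom_sizes[[ch]]
      r <- rep(cfg$background_rate, L)
      on_ch_idx <- which(site_chrom == ch)
      on_ch <- all_sites[on_ch_idx]
      if (length(on_ch)) {
        ps <- pmax(1L, GenomicRanges::start(on_ch) - cfg$peak_pad)
        pe <- pmin(L, GenomicRanges::end(on_ch) + cfg$peak_pad)
        pos <- sequence(nvec = pe - ps + 1L, from = ps)
        r[pos] <- cfg$peak_height
      }
      bnd <- all_sites[on_ch_idx[keep[on_ch_idx]]]
      if (length(bnd)) {
        pos <- sequence(nvec = GenomicRanges::width(bnd), from = GenomicRanges::start(bnd))
        r[pos] <- r[pos] * (1 - cfg$footprint_depth)
      }
      r * bias_by_chrom[[ch]]
    })
    names(rate) <- chroms
    rates[[cond]] <- rate
  }

  tracks <- list()
  for (cond in c("treated", "control")) {
    for (rep_i in seq_len(cfg$n_replicates)) {
      sig <- lapply(rates[[cond]], function(r) as.numeric(stats::rpois(length(r), r)))
      tracks[[paste0(cond, "_", rep_i)]] <-
        signal_track(sig, condition = paste0(cond, "_", rep_i))
    }
  }
  attr(tracks, "rates") <- rates
  tracks
}

#' Simulate replicate expression and differential-expression tables
#'
#' Baseline expression is log-normal (taken from the annotation); target
#' genes of the planted regulator receive `regulator_effect` log2 fold-change
#' in the treated condition. Per-gene p-values come from a pooled two-sample
#' t-test over `n_replicates` replicates per condition. A second
#' ("plaque-like") signature is generated with signed-score correlation
#' `plaque_concordance` to the treated signature.
#'
#' @param cfg A [sim_config()].
#' @param annotation Output of [simulate_annotation()].
#' @return List with `expression` (gene x replicate table, linear scale),
#'   `de` (gene, logFC, p, fdr), `de_plaque` (same columns), and
#'   `de_genes` (gene ids with BH FDR < 0.05 in `de`).
#' @export
simulate_expression_de <- function(cfg, annotation) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  if (cfg$n_replicates < 2L) stop("n_replicates must be at least 2")
  set.seed(cfg$seed + 3L)
  genes <- annotation$genes
  n <- nrow(genes)
  nr <- cfg$n_replicates
  base <- log2(genes$expression)
  effect <- ifelse(genes$gene_id %in% annotation$targets, cfg$regulator_effect, 0)
  if (cfg$regulator_mode == "repression") effect <- -effect

  trt <- matrix(stats::rnorm(n * nr, mean = base + effect, sd = cfg$rep_sd), nrow = n)
  ctl <- matrix(stats::rnorm(n * nr, mean = base, sd = cfg$rep_sd), nrow = n)
  m_t <- rowMeans(trt); m_c <- rowMeans(ctl)
  v_t <- apply(trt, 1L, stats::var); v_c <- apply(ctl, 1L, stats::var)
  sp <- sqrt((v_t + v_c) / 2) * sqrt(2 / nr)
  tstat <- (m_t - m_c) / sp
  p <- 2 * stats::pt(-abs(tstat), df = 2 * nr - 2)
  p <- pmin(pmax(p, 1e-300), 1)
  de <- data.frame(gene = genes$gene_id, logFC = m_t - m_c, p = p,
                   fdr = stats::p.adjust(p, method = "BH"),
                   stringsAsFactors = FALSE)

  # second signature built in signed z space so its p-values stay uniform
  # under the null: z2 = rho * z1 + sqrt(1 - rho^2) * eta with z1 the signed
  # probit of the treated p-value (a N(0,1) draw for unaffected genes)
  z1 <- sign(de$logFC) * stats::qnorm(de$p / 2, lower.tail = FALSE)
  rho <- cfg$plaque_concordance
  z2 <- rho * z1 + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n)
  p2 <- pmin(pmax(2 * stats::pnorm(-abs(z2)), 1e-300), 1)
  de_plaque <- data.frame(gene = genes$gene_id, logFC = z2, p = p2,
                          fdr = stats::p.adjust(p2, method = "BH"),
                          stringsAsFactors = FALSE)

  expr <- cbind(trt, ctl)
  colnames(expr) <- c(paste0("treated_", seq_len(nr)), paste0("control_", seq_len(nr)))
  expression <- data.frame(gene = genes$gene_id, 2^expr, stringsAsFactors = FALSE)

  list(expression = expression, de = de, de_plaque = de_plaque,
       de_genes = de$gene[de$fdr < 0.05])
}

#' Simulate an LD-block haplotype panel and GWAS summary statistics
#'
#' Variants are placed uniformly per chromosome; haplotypes are built in LD
#' blocks of `ld_block_size` consecutive variants by a copy-with-mutation
#' scheme (each block copies a shared binary pattern with a 2% per-allele
#' flip rate), so within-block pairwise r^2 is high and cross-block r^2 is
#' approximately 0. Each planted causal locus gets one variant repositioned
#' inside an altered binding site (when `causal_in_dbs`), a genome-wide
#' significant p-value, and graded p-values on its within-block proxies. MAF
#' of every variant exceeds 1% by construction.
#'
#' @param cfg A [sim_config()].
#' @param dbs GRanges of dynamic-binding-site intervals used to host causal
#'   variants (typically `annotation$altered`).
#' @return List with `panel` (0/1 matrix, haplotypes x variants, columns named
#'   by rsid), `variants` (rsid, chrom, pos, ref, alt, p, beta, maf, block),
#'   and `truth` (data.frame of planted causal variants).
#' @export
simulate_haplotypes_gwas <- function(cfg, dbs) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  if (cfg$causal_in_dbs && cfg$n_causal > 0L && (is.null(dbs) || length(dbs) == 0L)) {
    stop("no dynamic binding sites available to host causal variants")
  }
  set.seed(cfg$seed + 4L)
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  L <- cfg$chrom_length
  n_per <- diff(round(seq(0, cfg$n_variants, length.out = cfg$n_chroms + 1L)))
  chrom_v <- rep(chroms, n_per)
  pos <- unlist(lapply(n_per, function(k) sort(sample.int(L, k))), use.names = FALSE)

  # LD blocks: runs of consecutive variants within a chromosome
  block <- integer(cfg$n_variants)
  nb <- 0L
  for (ci in seq_along(chroms)) {
    idx <- which(chrom_v == chroms[ci])
    b <- (seq_along(idx) - 1L) %/% cfg$ld_block_size + 1L
    block[idx] <- nb + b
    nb <- nb + max(b)
  }

  panel <- matrix(0L, nrow = cfg$n_haplotypes, ncol = cfg$n_variants)
  for (b in seq_len(nb)) {
    idx <- which(block == b)
    theta <- stats::runif(1, 0.2, 0.8)
    z <- stats::rbinom(cfg$n_haplotypes, 1L, theta)
    for (j in idx) {
      repeat {
        flip <- stats::rbinom(cfg$n_haplotypes, 1L, 0.02)
        col <- abs(z - flip)
        f <- mean(col)
        if (f > 0.01 && f < 0.99) break
      }
      panel[, j] <- col
    }
  }

  p <- stats::runif(cfg$n_variants, min = 1e-6, max = 1)
  beta <- stats::rnorm(cfg$n_variants, 0, 0.02)
  is_causal <- logical(cfg$n_variants)

  causal_site <- integer(0)
  if (cfg$n_causal > 0L) {
    host <- if (cfg$causal_in_dbs) dbs else NULL
    # pick blocks to carry causal loci, spread across chromosomes that have a
    # host site (or any chromosome when causal variants are unconstrained)
    chosen_blocks <- integer(0)
    chosen_sites <- integer(0)
    if (!is.null(host)) {
      host_chrom <- as.character(GenomicRanges::seqnames(host))
      ok <- which(host_chrom %in% chroms)
      if (!length(ok)) stop("no dynamic binding sites available to host causal variants")
      pick <- sample(ok, min(cfg$n_causal, length(ok)))
      for (s in pick) {
        cand <- setdiff(unique(block[chrom_v == host_chrom[s]]), chosen_blocks)
        if (!length(cand)) next
        chosen_blocks <- c(chosen_blocks, if (length(cand) == 1L) cand else sample(cand, 1L))
        chosen_sites <- c(chosen_sites, s)
      }
    } else {
      chosen_blocks <- sample.int(nb, min(cfg$n_causal, nb))
      chosen_sites <- rep(NA_integer_, length(chosen_blocks))
    }
    for (k in seq_along(chosen_blocks)) {
      idx <- which(block == chosen_blocks[k])
      causal_j <- idx[ceiling(length(idx) / 2)]
      if (!is.na(chosen_sites[k])) {
        s <- host[chosen_sites[k]]
        pos[causal_j] <- as.integer(GenomicRanges::start(s) +
                                      GenomicRanges::width(s) %/% 2L)
      }
      is_causal[causal_j] <- TRUE
      p[causal_j] <- 10^(-stats::runif(1, 9, 12))
      proxies <- setdiff(idx, causal_j)
      p[proxies] <- pmin(1, p[causal_j] * 10^stats::runif(length(proxies), 1, 3))
      beta[causal_j] <- sample(c(-1, 1), 1L) * 0.04
    }
    causal_site <- chosen_sites
  }

  maf <- pmin(colMeans(panel), 1 - colMeans(panel))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, cfg$n_variants, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  rsid <- sprintf("rs%06d", seq_len(cfg$n_variants))
  colnames(panel) <- rsid
  variants <- data.frame(
    rsid = rsid, chrom = chrom_v, pos = as.integer(pos), ref = ref, alt = alt,
    p = p, beta = beta, maf = maf, block = block, stringsAsFactors = FALSE
  )
  ci <- which(is_causal)
  truth <- variants[ci, c("rsid", "chrom", "pos", "block")]
  if (length(ci) && length(causal_site) && !all(is.na(causal_site))) {
    s <- dbs[causal_site]
    truth$site_id <- s$site_id
    truth$site_start <- GenomicRanges::start(s)
    truth$site_end <- GenomicRanges::end(s)
  }
  rownames(truth) <- NULL
  list(panel = panel, variants = variants, truth = truth)
}

#' Simulate the full dataset
#'
#' Runs all generator stages under one master seed and optionally writes every
#' table and track to `outdir` in the formats the package readers consume
#' (BED, bedGraph, tab-separated tables, chrom.sizes), together with
#' planted-truth sidecar files for recovery tests.
#'
#' @param cfg A [sim_config()].
#' @param outdir Optional output directory; created if missing.
#' @return List with `config`, `annotation`, `tracks`, `expression`
#'   (tables from [simulate_expression_de()]) and `gwas` (from
#'   [simulate_haplotypes_gwas()]).
#' @export
simulate_dataset <- function(cfg, outdir = NULL) {
  annotation <- simulate_annotation(cfg)
  tracks <- simulate_cut_tracks(cfg, annotation)
  expression <- simulate_expression_de(cfg, annotation)
  gwas <- if (cfg$n_causal > 0L || cfg$n_variants > 0L) {
    simulate_haplotypes_gwas(cfg, annotation$altered)
  } else NULL

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(f) file.path(outdir, f)
    write_chrom_sizes(annotation$chrom_sizes, fp("chrom.sizes"))
    data.table::fwrite(annotation$genes, fp("genes.tsv"), sep = "\t")
    data.table::fwrite(expression$expression, fp("expression.tsv"), sep = "\t")
    data.table::fwrite(expression$de, fp("de_treated.tsv"), sep = "\t")
    data.table::fwrite(expression$de_plaque, fp("de_plaque.tsv"), sep = "\t")
    for (tf in names(annotation$sites)) {
      gr <- annotation$sites[[tf]]
      gr$name <- gr$site_id
      gr$score <- as.integer(gr$altered)
      write_bed(gr, fp(sprintf("sites_%s.bed", tf)))
    }
    for (nm in names(tracks)) {
      write_bedgraph(tracks[[nm]], fp(sprintf("cuts_%s.bedgraph", nm)))
    }
    alt <- annotation$altered
    alt$name <- alt$site_id
    write_bed(alt, fp("truth_altered_sites.bed"))
    data.table::fwrite(data.table::data.table(gene = annotation$targets),
                       fp("truth_targets.tsv"), sep = "\t")
    data.table::fwrite(
      data.table::data.table(kmer = names(annotation$bias), rate = annotation$bias),
      fp("truth_bias.tsv"), sep = "\t")
    if (!is.null(gwas)) {
      data.table::fwrite(gwas$variants, fp("gwas.tsv"), sep = "\t")
      data.table::fwrite(data.table::as.data.table(gwas$panel), fp("haplotypes.tsv"),
                         sep = "\t")
      data.table::fwrite(gwas$truth, fp("truth_causal_variants.tsv"), sep = "\t")
    }
  }
  list(config = cfg, annotation = annotation, tracks = tracks,
       expression = expression, gwas = gwas)
}
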