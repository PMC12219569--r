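# GWAS variant processing: genome-wide significance and MAF filters, greedy
# LD pruning to index variants, pooling of high-LD proxies per locus, overlap
# with extended dynamic binding sites, gene-body annotation and the
# allelic-imbalance binomial test.
#
# LD is computed from a user-supplied (or synthetic) haplotype panel: a 0/1
# matrix of haplotypes x variants with columns named by rsid. Variant
# positions are 1-based, as printed in GWAS tables.

#' Squared allelic correlation (r^2) between two panel columns
#'
#' `r^2 = (p_AB - p_A p_B)^2 / (p_A(1-p_A) p_B(1-p_B))` from haplotype
#' frequencies.
#'
#' @param panel 0/1 matrix, haplotypes x variants, columns named by rsid.
#' @param i,j Column indices or rsids.
#' @return r^2 in `[0, 1]`.
#' @export
compute_r2 <- function(panel, i, j) {
  x <- panel[, i]
  y <- panel[, j]
  pa <- mean(x); pb <- mean(y)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) {
    stop("monomorphic panel column: r^2 undefined")
  }
  pab <- mean(x * y)
  (pab - pa * pb)^2 / (pa * (1 - pa) * pb * (1 - pb))
}

# r^2 of one column against many (vectorized over columns `js`)
.r2_vec <- function(panel, i, js) {
  x <- panel[, i]
  pa <- mean(x)
  if (pa %in% c(0, 1)) stop("monomorphic panel column: r^2 undefined")
  sub <- panel[, js, drop = FALSE]
  pb <- colMeans(sub)
  pab <- colMeans(sub * x)
  out <- (pab - pa * pb)^2 / (pa * (1 - pa) * pb * (1 - pb))
  out[pb %in% c(0, 1)] <- NA_real_
  out
}

#' Greedy LD pruning to approximately independent index variants
#'
#' Walks the variants by ascending p (ties broken by rsid) and keeps a
#' variant iff its r^2 with every already-kept variant on the same
#' chromosome is at most `r2_max`; the retained set is pairwise
#' `r^2 <= r2_max`.
#'
#' @param variants data.frame with at least `rsid`, `chrom`, `p`.
#' @param panel Haplotype panel with columns named by rsid.
#' @param r2_max Pruning threshold (variants with r^2 above it are
#'   redundant).
#' @return The retained subset of `variants`, ordered by ascending p.
#' @export
ld_prune <- function(variants, panel, r2_max = 0.1) {
  if (!nrow(variants)) return(variants)
  if (!all(variants$rsid %in% colnames(panel))) {
    stop("panel lacks columns for some variants")
  }
  ord <- order(variants$p, variants$rsid)
  kept <- integer(0)
  for (i in ord) {
    same <- kept[variants$chrom[kept] == variants$chrom[i]]
    if (length(same)) {
      r2 <- .r2_vec(panel, variants$rsid[i], variants$rsid[same])
      if (any(r2 > r2_max, na.rm = TRUE)) next
    }
    kept <- c(kept, i)
  }
  out <- variants[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pool high-LD proxies around each index variant
#'
#' Each pool holds the index variant plus every same-chromosome variant with
#' `r^2` strictly greater than `r2_min` to it. Pools are disjoint: a variant
#' in high LD with several index variants is assigned to the index with the
#' smaller p-value.
#'
#' @param index_variants data.frame of index variants (from [ld_prune()]).
#' @param all_variants data.frame of candidate proxies (typically the full
#'   variant table).
#' @param panel Haplotype panel with columns named by rsid.
#' @param r2_min Pooling threshold (strict inequality).
#' @return Named list: index rsid -> character vector of pooled rsids
#'   (including the index itself).
#' @export
ld_pool <- function(index_variants, all_variants, panel, r2_min = 0.8) {
  pools <- stats::setNames(vector("list", nrow(index_variants)),
                           index_variants$rsid)
  if (!nrow(index_variants)) return(pools)
  assigned <- character(0)
  ord <- order(index_variants$p, index_variants$rsid)
  for (i in ord) {
    idx <- index_variants$rsid[i]
    cand <- all_variants[all_variants$chrom == index_variants$chrom[i] &
                           all_variants$rsid != idx &
                           !(all_variants$rsid %in% assigned), , drop = FALSE]
    proxies <- character(0)
    if (nrow(cand)) {
      r2 <- .r2_vec(panel, idx, cand$rsid)
      proxies <- cand$rsid[!is.na(r2) & r2 > r2_min]
    }
    pools[[idx]] <- c(idx, proxies)
    assigned <- c(assigned, idx, proxies)
  }
  pools
}

#' Filter GWAS variants on significance and frequency
#'
#' Keeps variants with `p < p_max` and `maf > maf_min` (both strict).
#'
#' @param variants data.frame with `p` and `maf` columns.
#' @param p_max Genome-wide significance threshold.
#' @param maf_min Common-variant minor-allele-frequency threshold.
#' @return The retained subset.
#' @export
filter_variants <- function(variants, p_max = 5e-8, maf_min = 0.01) {
  out <- variants[variants$p < p_max & variants$maf > maf_min, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect pooled variants with extended dynamic binding sites
#'
#' Extends each DBS interval by `pad` bp on both sides and retains every
#' pooled variant whose (1-based) position falls inside an extended DBS.
#' Rows are annotated with the extended interval (printed BED-style,
#' 0-based half-open), the hosting DBS index as `locus_id`, and the index
#' variant whose pool the variant belongs to.
#'
#' @param pools Named list from [ld_pool()].
#' @param variants data.frame with `rsid`, `chrom`, `pos`, `ref`, `alt`, `p`.
#' @param dbs GRanges of (un-extended) dynamic binding sites.
#' @param pad Extension in bp applied here (the footprinting convention is
#'   500 bp at each end).
#' @param genes Optional gene models (with `body_start`/`body_end`) for the
#'   annotation column.
#' @param chrom_sizes Optional named lengths for clipping the extension.
#' @return data.frame: `rsid`, `chrom`, `pos`, `ref`, `alt`, `p`, `dbs`,
#'   `locus_id`, `index_rsid`, `annotation`.
#' @export
overlap_dbs_variants <- function(pools, variants, dbs, pad = 500L,
                                 genes = NULL, chrom_sizes = NULL) {
  pooled <- unlist(pools, use.names = FALSE)
  idx_of <- rep(names(pools), lengths(pools))
  v <- variants[match(pooled, variants$rsid), , drop = FALSE]
  if (anyNA(v$rsid)) stop("pooled rsid absent from variant table")
  empty <- data.frame(rsid = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0), alt = character(0),
                      p = numeric(0), dbs = character(0), locus_id = integer(0),
                      index_rsid = character(0), annotation = character(0),
                      stringsAsFactors = FALSE)
  if (!nrow(v) || length(dbs) == 0L) return(empty)
  ext <- extend_intervals(dbs, pad, chrom_sizes)
  points <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, v$pos))
  hits <- GenomicRanges::findOverlaps(points, ext, ignore.strand = TRUE)
  if (!length(hits)) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  # a variant inside two overlapping extended DBSs is reported once per DBS
  out <- data.frame(
    rsid = v$rsid[qi], chrom = v$chrom[qi], pos = v$pos[qi],
    ref = v$ref[qi], alt = v$alt[qi], p = v$p[qi],
    dbs = sprintf("%s-%d-%d", as.character(GenomicRanges::seqnames(ext))[si],
                  GenomicRanges::start(ext)[si] - 1L,
                  GenomicRanges::end(ext)[si]),
    locus_id = si,
    index_rsid = idx_of[qi],
    stringsAsFactors = FALSE
  )
  out$annotation <- if (!is.null(genes)) {
    vapply(seq_len(nrow(out)), function(r) {
      annotate_variant(out$chrom[r], out$pos[r], genes)
    }, character(1))
  } else NA_character_
  out <- out[order(out$locus_id, out$p, out$rsid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate a position against gene bodies
#'
#' Returns `"<gene> intron"` when the (1-based) position falls inside a gene
#' body (a containment proxy: exon structure is not modelled), otherwise
#' `"Intergenic region"`.
#'
#' @param chrom Chromosome name.
#' @param pos 1-based position.
#' @param genes data.frame with `gene_id`, `chrom`, `body_start`, `body_end`
#'   (1-based, closed).
#' @return Character label.
#' @export
annotate_variant <- function(chrom, pos, genes) {
  hit <- which(genes$chrom == chrom & pos >= genes$body_start &
                 pos <= genes$body_end)
  if (length(hit)) sprintf("%s intron", genes$gene_id[hit[1L]])
  else "Intergenic region"
}

#' Allelic imbalance test
#'
#' Exact two-sided binomial test of the reference-allele read count against
#' a balanced proportion of 0.5, the standard check for allele-specific
#' chromatin accessibility at a heterozygous site.
#'
#' @param ref_count,alt_count Non-negative allele-specific read counts
#'   (sum >= 1).
#' @return Two-sided p-value.
#' @export
allelic_imbalance <- function(ref_count, alt_count) {
  if (ref_count < 0 || alt_count < 0) stop("counts must be non-negative")
  n <- ref_count + alt_count
  if (n < 1) stop("total count must be at least 1")
  stats::binom.test(ref_count, n, p = 0.5, alternative = "two.sided")$p.value
}

#' Parse a printed DBS interval string
#'
#' Accepts `"chr2-187423908-187424925"` (and the typographic en-dash variant
#' used in print); the printed coordinates are BED-style 0-based half-open.
#'
#' @param x Character vector of interval strings.
#' @return A GRanges (1-based closed).
#' @export
parse_dbs_interval <- function(x) {
  m <- regmatches(x, regexec("^(.+?)-([0-9]+)[-–]([0-9]+)$", x))
  bad <- which(lengths(m) != 4L)
  if (length(bad)) stop(sprintf("cannot parse DBS interval '%s'", x[bad[1L]]))
  chrom <- vapply(m, `[`, character(1), 2L)
  s0 <- as.numeric(vapply(m, `[`, character(1), 3L))
  e0 <- as.numeric(vapply(m, `[`, character(1), 4L))
  if (any(s0 >= e0)) stop("DBS interval start must precede end")
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = s0 + 1, end = e0))
}

#' Read a prioritized-variant report table
#'
#' Reads a tab-separated table with columns `rsid`, `chrom`, `pos`, `ref`,
#' `alt`, `dbs`, `annotation` (header required; positions may carry thousands
#' separators, `alt` may list several alleles comma-separated). Assigns a
#' `locus_id` by grouping rows that share a DBS interval and verifies that
#' every position falls inside its DBS.
#'
#' @param path Path to the table.
#' @return data.frame with parsed columns plus `locus_id`, and the parsed
#'   DBS GRanges as attribute `"dbs_ranges"`.
#' @export
read_prioritized_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  names(dt) <- tolower(names(dt))
  req <- c("rsid", "chrom", "pos", "ref", "alt", "dbs")
  if (!all(req %in% names(dt))) {
    stop(sprintf("prioritized table needs columns: %s", paste(req, collapse = ", ")))
  }
  out <- as.data.frame(dt)
  out$pos <- as.integer(gsub("[ ,]", "", out$pos))
  if (anyNA(out$pos) || any(out$pos < 1L)) stop("positions must be positive integers")
  gr <- parse_dbs_interval(out$dbs)
  inside <- out$chrom == as.character(GenomicRanges::seqnames(gr)) &
    out$pos >= GenomicRanges::start(gr) & out$pos <= GenomicRanges::end(gr)
  if (!all(inside)) {
    stop(sprintf("variant %s lies outside its DBS interval",
                 out$rsid[which(!inside)[1L]]))
  }
  out$locus_id <- match(out$dbs, unique(out$dbs))
  attr(out, "dbs_ranges") <- gr
  out
}
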