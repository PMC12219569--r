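# Readers/writers for the plain-text genomic formats the pipeline touches,
# plus the interval algebra shared by all modules.
#
# Conventions: on disk, BED and bedGraph are 0-based half-open; in memory all
# intervals are GRanges (1-based, closed), the Bioconductor convention.
# Variant tables print 1-based positions and are kept 1-based.

#' Read a two-column chromosome sizes file
#'
#' @param path Path to a tab-separated file with columns chromosome name and
#'   length in bp (no header).
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  stopifnot(file.exists(path))
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (ncol(dt) < 2L) stop("chrom sizes file must have two columns")
  sizes <- as.integer(dt[[2L]])
  if (anyNA(sizes) || any(sizes <= 0L)) stop("chromosome lengths must be positive integers")
  stats::setNames(sizes, dt[[1L]])
}

#' Write chromosome sizes
#'
#' @param sizes Named integer vector of chromosome lengths.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_chrom_sizes <- function(sizes, path) {
  data.table::fwrite(data.table::data.table(names(sizes), as.integer(sizes)),
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a BED file into a GRanges
#'
#' BED intervals are 0-based half-open on disk; the returned GRanges is
#' 1-based closed, so a BED record `chr1 10 15` becomes `chr1:11-15`.
#' Optional columns 4-6 (name, score, strand) are captured when present.
#' Input order is preserved.
#'
#' @param path Path to a BED3/BED6 file (tab-separated, no header).
#' @param chrom_sizes Optional named vector of chromosome lengths; when given,
#'   records beyond a chromosome end are an error and seqlengths are set.
#' @return A GRanges, with metadata columns `name` and `score` if present.
#' @export
read_bed <- function(path, chrom_sizes = NULL) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0L) return(GenomicRanges::GRanges())
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          colClasses = list(character = 1))
  if (ncol(dt) < 3L) {
    stop(sprintf("malformed BED at line 1: fewer than 3 tab-separated fields"))
  }
  start0 <- suppressWarnings(as.numeric(dt[[2L]]))
  end0   <- suppressWarnings(as.numeric(dt[[3L]]))
  bad <- which(is.na(start0) | is.na(end0) | is.na(dt[[1L]]) | dt[[1L]] == "")
  if (length(bad)) {
    stop(sprintf("malformed BED at line %d: non-numeric coordinates or empty chrom", bad[1L]))
  }
  bad <- which(start0 < 0 | start0 >= end0)
  if (length(bad)) {
    stop(sprintf("invalid interval at line %d: need 0 <= start < end", bad[1L]))
  }
  if (!is.null(chrom_sizes)) {
    unknown <- which(!(dt[[1L]] %in% names(chrom_sizes)))
    if (length(unknown)) {
      stop(sprintf("unknown chromosome '%s' at line %d", dt[[1L]][unknown[1L]], unknown[1L]))
    }
    over <- which(end0 > chrom_sizes[dt[[1L]]])
    if (length(over)) {
      stop(sprintf("interval beyond chromosome end at line %d", over[1L]))
    }
  }
  gr <- GenomicRanges::GRanges(
    seqnames = dt[[1L]],
    ranges = IRanges::IRanges(start = as.integer(start0) + 1L, end = as.integer(end0)),
    strand = if (ncol(dt) >= 6L) ifelse(dt[[6L]] %in% c("+", "-"), dt[[6L]], "*") else "*"
  )
  if (ncol(dt) >= 4L) gr$name <- as.character(dt[[4L]])
  if (ncol(dt) >= 5L) gr$score <- suppressWarnings(as.numeric(dt[[5L]]))
  if (!is.null(chrom_sizes)) {
    GenomeInfoDb::seqlengths(gr) <- chrom_sizes[GenomeInfoDb::seqlevels(gr)]
  }
  gr
}

#' Write a GRanges as BED
#'
#' Writes BED6 when `name` or `score` metadata are present, BED3 otherwise.
#' Round-trips byte-stably with [read_bed()] for canonical 6-column input.
#'
#' @param gr A GRanges.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(gr, path) {
  chrom <- as.character(GenomicRanges::seqnames(gr))
  s0 <- GenomicRanges::start(gr) - 1L
  e0 <- GenomicRanges::end(gr)
  if (!is.null(gr$name) || !is.null(gr$score)) {
    nm <- if (is.null(gr$name)) rep(".", length(gr)) else as.character(gr$name)
    sc <- if (is.null(gr$score)) rep(0, length(gr)) else gr$score
    st <- as.character(GenomicRanges::strand(gr))
    st[st == "*"] <- "."
    sc_chr <- vapply(sc, function(v) format(v, trim = TRUE, scientific = FALSE),
                     character(1))
    dt <- data.table::data.table(chrom, s0, e0, nm, sc_chr, st)
  } else {
    dt <- data.table::data.table(chrom, s0, e0)
  }
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a bedGraph file into a per-base signal track
#'
#' Expands interval values to per-base resolution. Bases not covered by any
#' record are 0. Records must be non-overlapping and non-negative.
#'
#' @param path Path to a 4-column bedGraph (chrom, start, end, value).
#' @param chrom_sizes Named vector of chromosome lengths covering every
#'   chromosome in the file (required: it fixes the track dimensions).
#' @param condition Label stored on the returned track.
#' @return A [signal_track()].
#' @export
read_bedgraph <- function(path, chrom_sizes, condition = "signal") {
  stopifnot(file.exists(path), !is.null(names(chrom_sizes)))
  sig <- lapply(chrom_sizes, function(n) numeric(n))
  if (file.size(path) > 0L) {
    dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                            colClasses = list(character = 1))
    if (ncol(dt) < 4L) stop("malformed bedGraph at line 1: fewer than 4 fields")
    chrom <- dt[[1L]]
    start0 <- suppressWarnings(as.numeric(dt[[2L]]))
    end0 <- suppressWarnings(as.numeric(dt[[3L]]))
    val <- suppressWarnings(as.numeric(dt[[4L]]))
    bad <- which(is.na(start0) | is.na(end0) | is.na(val))
    if (length(bad)) stop(sprintf("malformed bedGraph at line %d", bad[1L]))
    bad <- which(start0 < 0 | start0 >= end0)
    if (length(bad)) stop(sprintf("invalid interval at line %d: need 0 <= start < end", bad[1L]))
    bad <- which(val < 0)
    if (length(bad)) stop(sprintf("negative signal value at line %d", bad[1L]))
    unknown <- which(!(chrom %in% names(chrom_sizes)))
    if (length(unknown)) {
      stop(sprintf("unknown chromosome '%s' at line %d", chrom[unknown[1L]], unknown[1L]))
    }
    over <- which(end0 > chrom_sizes[chrom])
    if (length(over)) stop(sprintf("record beyond chromosome end at line %d", over[1L]))
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      o <- i[order(start0[i])]
      if (length(o) > 1L && any(start0[o][-1L] < end0[o][-length(o)])) {
        k <- which(start0[o][-1L] < end0[o][-length(o)])[1L]
        stop(sprintf("overlapping bedGraph records on %s (lines %d and %d)",
                     ch, o[k], o[k + 1L]))
      }
      w <- as.integer(end0[o] - start0[o])
      pos <- sequence(nvec = w, from = as.integer(start0[o]) + 1L)
      sig[[ch]][pos] <- rep(val[o], w)
    }
  }
  signal_track(sig, condition = condition)
}

#' Write a signal track as bedGraph
#'
#' Zero runs are omitted; adjacent equal values are merged into one record.
#'
#' @param track A [signal_track()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path) {
  out <- vector("list", length(track$signal))
  for (k in seq_along(track$signal)) {
    ch <- names(track$signal)[k]
    r <- rle(track$signal[[k]])
    e0 <- cumsum(r$lengths)
    s0 <- e0 - r$lengths
    keep <- r$values != 0
    out[[k]] <- data.table::data.table(chrom = ch, start = s0[keep],
                                       end = e0[keep], value = r$values[keep])
  }
  data.table::fwrite(data.table::rbindlist(out), path, sep = "\t",
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Subset intervals overlapping a query
#'
#' Returns the subjects sharing at least one base with the query. Adjacent
#' but non-overlapping intervals (BED half-open neighbours) do not hit.
#'
#' @param query A GRanges of length 1 (or more; any overlap counts).
#' @param subjects A GRanges.
#' @return The overlapping subset of `subjects`.
#' @export
overlap_intervals <- function(query, subjects) {
  IRanges::subsetByOverlaps(subjects, query, ignore.strand = TRUE)
}

#' Extend intervals symmetrically
#'
#' Grows every interval by `pad` bp on both sides, clipping at position 1 and,
#' when `chrom_sizes` is supplied, at the chromosome end. Metadata columns are
#' preserved.
#'
#' @param sites A GRanges.
#' @param pad Non-negative padding in bp.
#' @param chrom_sizes Optional named vector of chromosome lengths.
#' @return The extended GRanges.
#' @export
extend_intervals <- function(sites, pad, chrom_sizes = NULL) {
  if (!is.numeric(pad) || length(pad) != 1L || is.na(pad) || pad < 0) {
    stop("pad must be a single non-negative number")
  }
  pad <- as.integer(pad)
  s <- pmax(1L, GenomicRanges::start(sites) - pad)
  e <- GenomicRanges::end(sites) + pad
  if (!is.null(chrom_sizes)) {
    lim <- chrom_sizes[as.character(GenomicRanges::seqnames(sites))]
    if (anyNA(lim)) stop("chrom_sizes does not cover all chromosomes in sites")
    e <- pmin(e, as.integer(lim))
  }
  out <- sites
  GenomicRanges::ranges(out) <- IRanges::IRanges(start = s, end = e)
  out
}
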