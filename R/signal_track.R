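# Per-base cut-count signal, one numeric vector per chromosome.

#' Construct a signal track
#'
#' A signal track holds per-base non-negative signal (typically transposase
#' cut counts) for each chromosome, a condition label, and the library size
#' (total signal over all chromosomes).
#'
#' @param signal Named list of non-negative numeric vectors, one per
#'   chromosome; names are chromosome names.
#' @param condition Label for the condition/replicate this track represents.
#' @return An object of class `SignalTrack`.
#' @export
signal_track <- function(signal, condition = "signal") {
  if (!is.list(signal) || is.null(names(signal)) || any(names(signal) == "")) {
    stop("signal must be a named list of numeric vectors")
  }
  signal <- lapply(signal, as.numeric)
  if (any(vapply(signal, function(x) anyNA(x) || any(x < 0), logical(1)))) {
    stop("signal values must be non-negative and non-missing")
  }
  structure(
    list(signal = signal,
         condition = as.character(condition),
         library_size = sum(vapply(signal, sum, numeric(1)))),
    class = "SignalTrack"
  )
}

#' @export
print.SignalTrack <- function(x, ...) {
  cat(sprintf("SignalTrack '%s': %d chromosome(s), library size %.4g\n",
              x$condition, length(x$signal), x$library_size))
  for (ch in names(x$signal)) {
    cat(sprintf("  %s: %d bp, total %.4g\n", ch, length(x$signal[[ch]]),
                sum(x$signal[[ch]])))
  }
  invisible(x)
}

#' Chromosome lengths of a track
#'
#' @param track A [signal_track()].
#' @return Named integer vector of chromosome lengths.
#' @export
track_chrom_sizes <- function(track) {
  stats::setNames(as.integer(lengths(track$signal)), names(track$signal))
}

#' Depth-normalize a track to counts per million
#'
#' Rescales the signal so the library size equals 1e6. Scoring operations
#' that compare conditions assume their input tracks are CPM-normalized.
#'
#' @param track A [signal_track()].
#' @return A CPM-scaled [signal_track()].
#' @export
normalize_cpm <- function(track) {
  if (track$library_size <= 0) stop("cannot CPM-normalize an empty track")
  f <- 1e6 / track$library_size
  signal_track(lapply(track$signal, function(x) x * f), condition = track$condition)
}

#' Merge replicate tracks by summation
#'
#' @param tracks List of [signal_track()] objects on identical chromosomes.
#' @param condition Label for the merged track.
#' @return A [signal_track()] holding the base-wise sum.
#' @export
merge_tracks <- function(tracks, condition = "merged") {
  stopifnot(length(tracks) >= 1L)
  sizes <- lapply(tracks, track_chrom_sizes)
  if (!all(vapply(sizes[-1], identical, logical(1), y = sizes[[1]]))) {
    stop("tracks differ in chromosomes or lengths")
  }
  sig <- tracks[[1]]$signal
  for (t in tracks[-1]) {
    for (ch in names(sig)) sig[[ch]] <- sig[[ch]] + t$signal[[ch]]
  }
  signal_track(sig, condition = condition)
}
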