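.TRACK_NORMS <- c("raw", "RPM", "RRPM", "RPKM", "percent_max", "zscore")

#' Binned signal track over the target genome
#'
#' Per-chromosome vectors of signal over fixed-width non-overlapping bins.
#' The last bin of a chromosome whose length is not a multiple of
#' `bin_size` is kept at its natural (shorter) width and flagged in
#' `partial_bin`. The normalization tag travels with the values so that a
#' track can never silently be treated on the wrong scale.
#'
#' @param values named list of numeric vectors, one per target chromosome
#'   of `layout` (a single unnamed vector is accepted for single-chromosome
#'   layouts); each of length `ceiling(chrom_length / bin_size)`.
#' @param bin_size bin width in bp.
#' @param layout a [genome_layout()]; only target chromosomes carry signal.
#' @param normalization one of `r paste(.TRACK_NORMS, collapse = ", ")`.
#' @param mark,time free-text labels (histone mark, time point).
#' @return An object of class `BinnedTrack`.
#' @export
binned_track <- function(values, bin_size, layout, normalization = "raw",
                         mark = NA_character_, time = NA_character_) {
  stopifnot(inherits(layout, "GenomeLayout"))
  if (!is.numeric(bin_size) || length(bin_size) != 1 || bin_size < 1 ||
      bin_size != floor(bin_size))
    stop("bin_size must be a positive integer")
  if (!normalization %in% .TRACK_NORMS)
    stop("unknown normalization tag: ", normalization)
  lens <- layout$target
  if (is.numeric(values) && length(lens) == 1) values <- setNames(list(values), names(lens))
  if (!is.list(values) || is.null(names(values)))
    stop("values must be a named list of per-chromosome vectors")
  if (!setequal(names(values), names(lens)))
    stop("value chromosomes must match the target chromosomes of the layout")
  values <- values[names(lens)]
  for (ch in names(lens)) {
    expected <- ceiling(lens[[ch]] / bin_size)
    if (length(values[[ch]]) != expected)
      stop(sprintf("chromosome %s: expected %d bins, got %d",
                   ch, expected, length(values[[ch]])))
    if (anyNA(values[[ch]])) stop("track values must not contain NA (", ch, ")")
    if (normalization != "zscore" && any(values[[ch]] < -1e-9))
      stop("track values must be non-negative under normalization ", normalization)
    if (normalization == "percent_max" && any(values[[ch]] > 100 + 1e-9))
      stop("percent_max values must lie in [0, 100]")
    values[[ch]] <- as.numeric(values[[ch]])
  }
  structure(list(values = values,
                 bin_size = as.integer(bin_size),
                 chrom_lengths = lens,
                 normalization = normalization,
                 mark = mark, time = time,
                 partial_bin = (lens %% bin_size) != 0),
            class = "BinnedTrack")
}

#' @export
print.BinnedTrack <- function(x, ...) {
  cat(sprintf("BinnedTrack [%s]: %d bp bins, %d chromosome(s), %d bins total",
              x$normalization, x$bin_size, length(x$values),
              sum(lengths(x$values))))
  if (!is.na(x$mark)) cat(" | mark:", x$mark)
  if (!is.na(x$time)) cat(" | time:", x$time)
  cat("\n")
  invisible(x)
}

#' Bin coordinates of a track
#' @param track a [binned_track()].
#' @return GRanges of all bins in chromosome order (last bin clipped to the
#'   chromosome end).
#' @export
bin_ranges <- function(track) {
  lens <- track$chrom_lengths
  bs <- track$bin_size
  nb <- ceiling(lens / bs)
  chrom <- rep(names(lens), nb)
  start0 <- unlist(lapply(nb, function(n) (seq_len(n) - 1) * bs), use.names = FALSE)
  end <- pmin(start0 + bs, rep(unname(lens), nb))
  GRanges(chrom, IRanges(start0 + 1, end))
}

#' All bin values of a track as one vector
#' @param track a [binned_track()].
#' @param chrom optional chromosome name.
#' @return Numeric vector (chromosome order of the layout).
#' @export
track_values <- function(track, chrom = NULL) {
  if (is.null(chrom)) return(unlist(track$values, use.names = FALSE))
  if (!chrom %in% names(track$values)) stop("no such chromosome: ", chrom)
  track$values[[chrom]]
}

# internal: multiply all values by a scalar and retag
.scale_track <- function(track, factor, normalization) {
  track$values <- lapply(track$values, `*`, factor)
  track$normalization <- normalization
  track
}

#' Target/spike-in read totals recorded on a track by [bin_counts()]
#' @param track a [binned_track()] produced by [bin_counts()].
#' @return A [library_counts()] object.
#' @export
read_totals <- function(track) {
  rt <- attr(track, "read_totals")
  if (is.null(rt)) stop("track carries no read totals (not made by bin_counts)")
  library_counts(rt[["target"]], rt[["spikein"]])
}
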