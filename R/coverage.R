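# Read extension, binning and normalization: the RPM / RRPM machinery that
# turns aligned single-end reads into comparable signal tracks.

#' Extend reads to the library fragment length
#'
#' Single-end reads report only the 5' end of the sequenced fragment. Each
#' read is extended to `target_length` bp from its 5' alignment end in the
#' strand direction (the standard ChIP-seq fragment-extension step), then
#' clipped to the chromosome.
#'
#' @param reads GRanges of aligned reads; unstranded reads are treated as
#'   `+` with a warning.
#' @param target_length fragment length in bp (e.g. 250 or 500).
#' @param layout a [genome_layout()]; reads on chromosomes absent from it
#'   are an error.
#' @return GRanges of extended fragments (strand preserved).
#' @export
extend_reads <- function(reads, target_length, layout) {
  stopifnot(is(reads, "GRanges"), inherits(layout, "GenomeLayout"))
  if (!is.numeric(target_length) || target_length <= 0)
    stop("target_length must be positive")
  chrom <- as.character(seqnames(reads))
  lens <- c(layout$target, layout$spikein)
  unknown <- setdiff(unique(chrom), names(lens))
  if (length(unknown)) stop("read on chromosome absent from layout: ", unknown[1])
  st <- as.character(strand(reads))
  if (any(st == "*")) {
    warning(sum(st == "*"), " unstranded read(s) treated as '+'")
    st[st == "*"] <- "+"
  }
  L <- unname(lens[chrom])
  s0 <- start(reads) - 1
  e <- end(reads)
  new_s0 <- ifelse(st == "+", s0, pmax(0, e - target_length))
  new_e <- ifelse(st == "+", pmin(L, s0 + target_length), e)
  GRanges(chrom, IRanges(new_s0 + 1, new_e), strand = st,
          seqinfo = layout_seqinfo(layout))
}

#' Count extended reads in fixed-width bins
#'
#' A read contributes one count to every bin it overlaps by at least one bp
#' (occupancy-style counting of extended fragments, not midpoint or
#' fractional counting). Reads on spike-in chromosomes are excluded from
#' the track and counted separately; both totals are recorded on the result
#' and retrievable with [read_totals()].
#'
#' @param extended GRanges of (extended) reads over target and/or spike-in
#'   chromosomes.
#' @param bin_size bin width in bp.
#' @param layout a [genome_layout()].
#' @param mark,time labels stored on the track.
#' @return A raw-count [binned_track()] over the target chromosomes.
#' @export
bin_counts <- function(extended, bin_size, layout,
                       mark = NA_character_, time = NA_character_) {
  stopifnot(is(extended, "GRanges"), inherits(layout, "GenomeLayout"))
  chrom <- as.character(seqnames(extended))
  spike <- is_spikein_chrom(layout, chrom)
  target_reads <- granges(extended[!spike])
  lens <- layout$target
  nb <- ceiling(lens / bin_size)
  bins <- GRanges(rep(names(lens), nb),
                  IRanges(unlist(lapply(nb, function(n) (seq_len(n) - 1) * bin_size),
                                 use.names = FALSE) + 1,
                          pmin(unlist(lapply(nb, function(n) seq_len(n) * bin_size),
                                      use.names = FALSE), rep(unname(lens), nb))))
  counts <- countOverlaps(bins, target_reads, ignore.strand = TRUE)
  values <- split(as.numeric(counts), factor(rep(names(lens), nb), levels = names(lens)))
  track <- binned_track(as.list(values), bin_size, layout, normalization = "raw",
                        mark = mark, time = time)
  attr(track, "read_totals") <- c(target = length(target_reads), spikein = sum(spike))
  track
}

#' Reads-per-million normalization
#'
#' Scales every bin by `1e6 / target_unique_reads`: the conventional
#' within-library depth normalization. RPM makes profile *shapes*
#' comparable but deliberately erases between-sample differences in total
#' material — which is exactly what the spike-in normalization [rrpm()]
#' restores.
#'
#' @param track a raw-count [binned_track()].
#' @param counts a [library_counts()].
#' @return The RPM-normalized track.
#' @export
rpm <- function(track, counts) {
  stopifnot(inherits(track, "BinnedTrack"), inherits(counts, "LibraryCounts"))
  if (track$normalization != "raw")
    stop("rpm() expects a raw-count track, got ", track$normalization)
  if (counts$target_unique_reads <= 0)
    stop("RPM requires target_unique_reads > 0")
  .scale_track(track, 1e6 / counts$target_unique_reads, "RPM")
}

#' Reference-adjusted reads-per-million (spike-in normalization)
#'
#' Scales every bin by `1e6 / spikein_unique_reads`. Because the exogenous
#' spike-in chromatin is constant across samples, its read total calibrates
#' the between-sample scale, so RRPM values are quantitatively comparable
#' across libraries of a time course — quantitative differences that RPM
#' normalization erases.
#'
#' @inheritParams rpm
#' @return The RRPM-normalized track.
#' @export
rrpm <- function(track, counts) {
  stopifnot(inherits(track, "BinnedTrack"), inherits(counts, "LibraryCounts"))
  if (track$normalization != "raw")
    stop("rrpm() expects a raw-count track, got ", track$normalization)
  if (counts$spikein_unique_reads <= 0)
    stop("RRPM precondition violated: spikein_unique_reads must be > 0 ",
         "(spike-in normalization needs recovered spike-in reads)")
  .scale_track(track, 1e6 / counts$spikein_unique_reads, "RRPM")
}

#' Reads per kilobase per million over regions
#'
#' `count * 1e9 / (region_length_bp * target_unique_reads)`.
#'
#' @param counts numeric vector of read counts per region.
#' @param regions GRanges (lengths taken from widths) or numeric vector of
#'   region lengths in bp.
#' @param lib a [library_counts()].
#' @return Numeric vector of RPKM values.
#' @export
rpkm <- function(counts, regions, lib) {
  stopifnot(inherits(lib, "LibraryCounts"))
  len <- if (is(regions, "GRanges")) width(regions) else as.numeric(regions)
  if (length(len) != length(counts)) stop("counts and regions differ in length")
  if (any(len <= 0)) stop("zero-length region in RPKM computation")
  if (lib$target_unique_reads <= 0) stop("RPKM requires target_unique_reads > 0")
  counts * 1e9 / (len * lib$target_unique_reads)
}

#' Percent-of-maximum scaling
#'
#' `v * 100 / max(v)`, computed over the value set supplied (typically one
#' displayed locus or one anchor matrix, not genome-wide). A degenerate
#' all-zero input returns zeros with the `zero_max` attribute set.
#'
#' @param x numeric vector or [binned_track()].
#' @param ... unused.
#' @return Same shape as the input, scaled to `[0, 100]`; attribute
#'   `zero_max` flags the degenerate case.
#' @export
percent_of_max <- function(x, ...) UseMethod("percent_of_max")

#' @rdname percent_of_max
#' @export
percent_of_max.default <- function(x, ...) {
  if (!length(x)) stop("percent_of_max needs at least one value")
  m <- max(x)
  out <- if (m <= 0) x * 0 else x * 100 / m
  attr(out, "zero_max") <- m <= 0
  out
}

#' @rdname percent_of_max
#' @export
percent_of_max.BinnedTrack <- function(x, ...) {
  v <- track_values(x)
  m <- max(v)
  out <- if (m <= 0) lapply(x$values, `*`, 0) else lapply(x$values, function(z) z * 100 / m)
  track <- x
  track$values <- out
  track$normalization <- "percent_max"
  attr(track, "zero_max") <- m <= 0
  track
}

#' Z-score normalization
#'
#' `z = (x - mu) / sigma` with `mu` and `sigma` the mean and standard
#' deviation of the supplied values. By default `sigma` is the population
#' (divide-by-n) standard deviation; the sample convention is available.
#'
#' @param x numeric vector, length >= 2.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return A list with elements `z` (the standardized vector, mean 0 and sd
#'   1), `mu` and `sigma`.
#' @export
zscore <- function(x, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (length(x) < 2) stop("zscore needs at least two values")
  mu <- mean(x)
  sigma <- if (sd_type == "population") sqrt(mean((x - mu)^2)) else sd(x)
  if (sigma == 0) stop("constant signal cannot be z-scored (sigma = 0)")
  list(z = (x - mu) / sigma, mu = mu, sigma = sigma)
}
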