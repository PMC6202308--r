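# Anchor-centred average profiles, length-normalized metagene profiles and
# heatmap scaling.

#' Anchor-centred signal matrix and average profile
#'
#' Extracts, for every anchor, the track signal across `flank` bp on either
#' side of the anchor position, one column per bin. Anchors on the minus
#' strand (interior/feature to the left) are flipped so that the oriented
#' side is uniform across rows — required to produce a border-shaped
#' average profile. Anchor positions are snapped down to the bin grid.
#' Anchors whose flanked window would leave the chromosome are dropped (not
#' clipped) to keep the matrix rectangular.
#'
#' @param track a [binned_track()].
#' @param anchors GRanges of width-1 anchors (e.g. [domain_borders()] or
#'   TSS positions); strand `-` rows are mirrored.
#' @param flank half-window in bp; must be a multiple of the track bin
#'   size.
#' @param zscore_profile also return the z-scored mean profile.
#' @return A list of class `AnchorMatrix`: `matrix` (anchors x positions),
#'   `positions` (bp offsets of column starts), `means` (column means),
#'   optionally `means_z`, `anchors` (the retained anchors) and
#'   `n_dropped`.
#' @export
anchor_profile <- function(track, anchors, flank, zscore_profile = FALSE) {
  stopifnot(inherits(track, "BinnedTrack"), is(anchors, "GRanges"))
  bs <- track$bin_size
  if (flank <= 0 || flank %% bs != 0)
    stop("flank must be a positive multiple of the bin size (", bs, ")")
  lens <- track$chrom_lengths
  chrom <- as.character(seqnames(anchors))
  if (any(!chrom %in% names(lens)))
    stop("anchor on chromosome absent from the track")
  p0 <- ((start(anchors) - 1) %/% bs) * bs
  left <- p0 - flank
  right <- p0 + flank
  valid <- left >= 0 & right <= unname(lens[chrom])
  n_dropped <- sum(!valid)
  use <- which(valid)
  if (!length(use)) stop("no anchor fits within the chromosome with this flank")
  ncol_out <- as.integer(2 * flank / bs)
  mat <- matrix(NA_real_, length(use), ncol_out)
  minus <- as.character(strand(anchors)) == "-"
  for (r in seq_along(use)) {
    i <- use[r]
    idx <- (left[i] / bs + 1):(right[i] / bs)
    row <- track$values[[chrom[i]]][idx]
    mat[r, ] <- if (minus[i]) rev(row) else row
  }
  positions <- seq(-flank, flank - bs, by = bs)
  colnames(mat) <- positions
  out <- list(matrix = mat, positions = positions, means = colMeans(mat),
              anchors = anchors[use], n_dropped = n_dropped)
  if (zscore_profile) out$means_z <- zscore(out$means)$z
  class(out) <- "AnchorMatrix"
  out
}

#' @export
print.AnchorMatrix <- function(x, ...) {
  cat(sprintf("AnchorMatrix: %d anchors x %d positions (%d dropped)\n",
              nrow(x$matrix), ncol(x$matrix), x$n_dropped))
  invisible(x)
}

# bp-weighted mean of track values over the 0-based interval [a, b)
.interval_mean <- function(vals, bs, a, b) {
  i1 <- floor(a / bs) + 1
  i2 <- min(ceiling(b / bs), length(vals))
  idx <- i1:i2
  lo <- pmax(a, (idx - 1) * bs)
  hi <- pmin(b, idx * bs)
  w <- hi - lo
  sum(vals[idx] * w) / sum(w)
}

# resample the 0-based interval [a, b) onto n equal-width pseudo-bins
.resample_interval <- function(vals, bs, a, b, n) {
  edges <- a + (b - a) * (0:n) / n
  vapply(seq_len(n), function(j) .interval_mean(vals, bs, edges[j], edges[j + 1]),
         numeric(1))
}

#' Length-normalized (anchored) metagene profile
#'
#' Corrects for feature-length differences: the signal inside each body
#' (e.g. an open reading frame) is resampled by bp-weighted mean pooling
#' onto `body_bins` equal-width pseudo-bins, and fixed-width flanks in real
#' bp are appended on both sides. Minus-strand bodies are reversed so all
#' rows read 5' to 3'. Bodies shorter than `body_bins` bp, or whose flanks
#' leave the chromosome, are dropped with a count.
#'
#' @param track a [binned_track()].
#' @param bodies stranded GRanges of feature bodies.
#' @param body_bins number of pseudo-bins inside the body (default 100).
#' @param flank flank width in bp on each side (default 2000); must be a
#'   multiple of the bin size (0 disables flanks).
#' @return A list of class `BodyProfile`: `matrix` (bodies x positions),
#'   `profile` (column means), `n_dropped`, and the column layout
#'   (`n_flank_cols`, `body_bins`).
#' @export
anchored_body_profile <- function(track, bodies, body_bins = 100, flank = 2000) {
  stopifnot(inherits(track, "BinnedTrack"), is(bodies, "GRanges"))
  bs <- track$bin_size
  if (body_bins < 1) stop("body_bins must be >= 1")
  if (flank < 0 || (flank > 0 && flank %% bs != 0))
    stop("flank must be 0 or a positive multiple of the bin size (", bs, ")")
  lens <- track$chrom_lengths
  chrom <- as.character(seqnames(bodies))
  if (any(!chrom %in% names(lens)))
    stop("body on chromosome absent from the track")
  s0 <- start(bodies) - 1
  e <- end(bodies)
  valid <- (e - s0) >= body_bins & (s0 - flank) >= 0 & (e + flank) <= unname(lens[chrom])
  n_dropped <- sum(!valid)
  use <- which(valid)
  if (!length(use)) stop("no body usable with this body_bins/flank setting")
  nfc <- as.integer(flank / bs)
  mat <- matrix(NA_real_, length(use), 2 * nfc + body_bins)
  minus <- as.character(strand(bodies)) == "-"
  for (r in seq_along(use)) {
    i <- use[r]
    v <- track$values[[chrom[i]]]
    up <- if (nfc) .resample_interval(v, bs, s0[i] - flank, s0[i], nfc) else numeric(0)
    body <- .resample_interval(v, bs, s0[i], e[i], body_bins)
    down <- if (nfc) .resample_interval(v, bs, e[i], e[i] + flank, nfc) else numeric(0)
    row <- c(up, body, down)
    mat[r, ] <- if (minus[i]) rev(row) else row
  }
  structure(list(matrix = mat, profile = colMeans(mat),
                 n_flank_cols = nfc, body_bins = as.integer(body_bins),
                 n_dropped = n_dropped),
            class = "BodyProfile")
}

#' Percent-of-maximum scaling of a profile/heatmap matrix
#'
#' Scales all cells to percent of the matrix maximum — the per-sample
#' scaling used when colouring parental and nascent heatmaps separately.
#' Row order is preserved (sorting is the caller's concern); scaling is
#' idempotent. An all-zero matrix returns zeros with the `zero_max`
#' attribute set.
#'
#' @param m numeric matrix (or the `matrix` element of an `AnchorMatrix`).
#' @param scaling currently only `"percent_max_per_sample"`.
#' @return The scaled matrix.
#' @export
heatmap_matrix <- function(m, scaling = "percent_max_per_sample") {
  scaling <- match.arg(scaling, "percent_max_per_sample")
  if (inherits(m, "AnchorMatrix")) m <- m$matrix
  if (!length(m)) stop("empty matrix")
  mx <- max(m)
  out <- if (mx <= 0) m * 0 else m * 100 / mx
  attr(out, "zero_max") <- mx <= 0
  out
}
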