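# Interval operations specific to replicated-chromatin analysis: windowing
# parental peaks, restricting to replicated DNA, oriented domain borders,
# and parental-to-nascent peak displacement.

#' Tile peaks into fixed-width windows
#'
#' Each peak is tiled from its start into non-overlapping windows of
#' exactly `window_size` bp; a trailing remainder shorter than
#' `window_size` is dropped so that all windows are size-comparable. Peaks
#' shorter than `window_size` therefore contribute no windows.
#'
#' @param peaks GRanges of source peaks.
#' @param window_size window width in bp.
#' @return GRanges of windows in peak order, with a `source_peak` metadata
#'   column giving the index of the originating peak; `window_size` is
#'   recorded in `metadata()`.
#' @export
tile_peaks <- function(peaks, window_size) {
  stopifnot(is(peaks, "GRanges"))
  if (!is.numeric(window_size) || window_size < 1 || window_size != floor(window_size))
    stop("window_size must be a positive integer")
  k <- width(peaks) %/% window_size
  idx <- rep(seq_along(peaks), k)
  off <- (sequence(k) - 1) * window_size
  gr <- GRanges(seqnames(peaks)[idx],
                IRanges(start(peaks)[idx] + off, width = window_size),
                seqinfo = seqinfo(peaks))
  mcols(gr)$source_peak <- idx
  metadata(gr)$window_size <- as.integer(window_size)
  gr
}

#' Keep windows overlapping a region set
#'
#' Retains windows whose total intersection with the union of `regions` is
#' at least `min_overlap` bp (half-open arithmetic on disk translates to
#' >= 1 bp shared under the default). Output order follows input order.
#'
#' @param windows GRanges (e.g. from [tile_peaks()]).
#' @param regions GRanges, e.g. replicated regions.
#' @param min_overlap minimum intersection in bp (default 1).
#' @return The retained windows, metadata preserved.
#' @export
filter_by_overlap <- function(windows, regions, min_overlap = 1) {
  stopifnot(is(windows, "GRanges"), is(regions, "GRanges"))
  if (min_overlap < 1) stop("min_overlap must be >= 1")
  red <- reduce(granges(regions), ignore.strand = TRUE)
  hits <- findOverlaps(windows, red, ignore.strand = TRUE)
  if (!length(hits)) {
    out <- windows[integer(0)]
  } else {
    ov <- width(pintersect(granges(windows)[queryHits(hits)], red[subjectHits(hits)]))
    tot <- rowsum(ov, queryHits(hits))
    keep_idx <- as.integer(rownames(tot))[tot[, 1] >= min_overlap]
    out <- windows[sort(keep_idx)]
  }
  metadata(out) <- metadata(windows)
  out
}

.stop_if_self_overlapping <- function(x, what) {
  h <- findOverlaps(x, ignore.strand = TRUE, drop.self = TRUE, drop.redundant = TRUE)
  if (length(h)) {
    i <- queryHits(h)[1]; j <- subjectHits(h)[1]
    stop(sprintf("%s peaks overlap within the input list: #%d (%s:%d-%d) and #%d (%s:%d-%d)",
                 what, i, as.character(seqnames(x))[i], start(x)[i], end(x)[i],
                 j, as.character(seqnames(x))[j], start(x)[j], end(x)[j]),
         call. = FALSE)
  }
}

#' Pair parental and nascent peaks overlapping exactly once
#'
#' Retains only reciprocally unique pairs: a parental peak overlapping
#' exactly one nascent peak which in turn overlaps exactly one parental
#' peak. For each pair the absolute distances between the two start
#' coordinates and between the two end coordinates are reported; these
#' per-end distances measure how far the nascent peak is displaced from
#' its parental position.
#'
#' @param parental,nascent GRanges; each list must be internally
#'   non-overlapping (an error names the offending pair otherwise).
#' @param on_overlap what to do with peaks that overlap *within* one input
#'   list: `"error"` (default, the strict contract) or `"drop"`, which
#'   removes all members of self-overlapping clusters from that list
#'   before pairing — mirroring that merged/ambiguous peak calls can never
#'   satisfy the reciprocally-unique rule.
#' @return A data.frame of class `PeakPairs` with one row per retained
#'   pair: coordinates of both peaks (1-based, GRanges convention),
#'   `start_distance` and `end_distance` in bp, and the source indices
#'   (into the possibly self-overlap-pruned inputs).
#' @export
pair_unique_peaks <- function(parental, nascent,
                              on_overlap = c("error", "drop")) {
  stopifnot(is(parental, "GRanges"), is(nascent, "GRanges"))
  on_overlap <- match.arg(on_overlap)
  if (on_overlap == "error") {
    .stop_if_self_overlapping(parental, "parental")
    .stop_if_self_overlapping(nascent, "nascent")
  } else {
    drop_self <- function(x) {
      bad <- unique(c(queryHits(findOverlaps(x, ignore.strand = TRUE,
                                             drop.self = TRUE))))
      if (length(bad)) x[-bad] else x
    }
    parental <- drop_self(parental)
    nascent <- drop_self(nascent)
  }
  cPN <- countOverlaps(parental, nascent, ignore.strand = TRUE)
  cNP <- countOverlaps(nascent, parental, ignore.strand = TRUE)
  h <- findOverlaps(parental, nascent, ignore.strand = TRUE)
  keep <- cPN[queryHits(h)] == 1 & cNP[subjectHits(h)] == 1
  h <- h[keep]
  p <- queryHits(h); n <- subjectHits(h)
  out <- data.frame(chrom = as.character(seqnames(parental))[p],
                    parental_start = start(parental)[p],
                    parental_end = end(parental)[p],
                    nascent_start = start(nascent)[n],
                    nascent_end = end(nascent)[n],
                    start_distance = abs(start(parental)[p] - start(nascent)[n]),
                    end_distance = abs(end(parental)[p] - end(nascent)[n]),
                    parental_idx = p, nascent_idx = n,
                    stringsAsFactors = FALSE)
  class(out) <- c("PeakPairs", "data.frame")
  out
}

#' Summarize parental-to-nascent peak displacement
#'
#' The per-pair displacement is the mean of the start-end and end-end
#' distances; both per-end vectors and the pooled convention are also
#' reported so either aggregation is recoverable.
#'
#' @param pairs a `PeakPairs` data.frame from [pair_unique_peaks()].
#' @param aggregation `"per_pair_mean"` (default: average the two end
#'   distances within each pair, then summarize over pairs) or `"pooled"`
#'   (pool all end distances).
#' @return A list with `n`, `mean`, `median` (under the chosen
#'   aggregation), the per-pair distances, and per-end summaries.
#' @export
displacement_summary <- function(pairs, aggregation = c("per_pair_mean", "pooled")) {
  aggregation <- match.arg(aggregation)
  if (!nrow(pairs)) stop("displacement_summary needs at least one pair")
  per_pair <- (pairs$start_distance + pairs$end_distance) / 2
  pooled <- c(pairs$start_distance, pairs$end_distance)
  main <- if (aggregation == "per_pair_mean") per_pair else pooled
  list(n = nrow(pairs),
       aggregation = aggregation,
       mean = mean(main),
       median = median(main),
       per_pair = per_pair,
       per_pair_mean = mean(per_pair),
       pooled_mean = mean(pooled),
       start_mean = mean(pairs$start_distance),
       end_mean = mean(pairs$end_distance),
       start_distances = pairs$start_distance,
       end_distances = pairs$end_distance)
}

#' Oriented anchors at domain borders
#'
#' Emits both edges of each broad domain as width-1 anchors carrying the
#' side of the domain interior (strand `+`: interior to the right of the
#' anchor, i.e. a left border; strand `-`: interior to the left). Because
#' domain borders frequently coincide with borders of the replicated
#' regions themselves — where signal drops for reasons unrelated to the
#' mark — anchors closer than `min_distance` to any replicated-region edge
#' are removed.
#'
#' @param domains GRanges of non-overlapping broad domains.
#' @param replicated GRanges of replicated regions; an empty set is an
#'   error (no border can be assessed without replicated DNA).
#' @param min_distance minimum distance in bp from any replicated-region
#'   edge (default 5000).
#' @return GRanges of width-1 anchors with metadata `domain_idx` and
#'   `side` (`"left"`/`"right"`); strand encodes the interior direction.
#' @export
domain_borders <- function(domains, replicated, min_distance = 5000) {
  stopifnot(is(domains, "GRanges"), is(replicated, "GRanges"))
  .stop_if_self_overlapping(domains, "domain")
  if (!length(replicated))
    stop("replicated region set is empty: borders cannot be anchored")
  # 0-based edge coordinates; a width-1 anchor at edge e covers base e+1
  left0 <- start(domains) - 1
  right0 <- end(domains)
  anchors <- GRanges(rep(as.character(seqnames(domains)), 2),
                     IRanges(c(left0, right0) + 1, width = 1),
                     strand = rep(c("+", "-"), each = length(domains)))
  mcols(anchors)$domain_idx <- rep(seq_along(domains), 2)
  mcols(anchors)$side <- rep(c("left", "right"), each = length(domains))
  rep_edges <- split(c(start(replicated) - 1, end(replicated)),
                     rep(as.character(seqnames(replicated)), 2))
  pos0 <- start(anchors) - 1
  chrom <- as.character(seqnames(anchors))
  dist <- vapply(seq_along(anchors), function(i) {
    e <- rep_edges[[chrom[i]]]
    if (is.null(e)) Inf else min(abs(pos0[i] - e))
  }, numeric(1))
  anchors[dist >= min_distance]
}
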