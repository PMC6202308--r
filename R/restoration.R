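# Core kinetic analysis: per-window time courses of spike-in-normalized
# signal and discrete classification of restoration / loss behaviour.

.category_label <- function(x) sub("^T", "R", x)

#' Time course of per-window signal
#'
#' Windows x timepoints matrix of (typically RRPM) signal for one mark and
#' one replicate, with strictly increasing timepoints.
#'
#' @param values numeric matrix, one row per window, one column per
#'   timepoint; no missing cells, values >= 0.
#' @param windows GRanges, one range per matrix row.
#' @param labels character timepoint labels (e.g. `"T0"`, `"T1"`, ...).
#' @param hours numeric hours since replication, strictly increasing.
#' @param mark,replicate free-text labels.
#' @param lib_counts optional list of [library_counts()], one per timepoint.
#' @return An object of class `TimeCourse`.
#' @export
timecourse <- function(values, windows, labels, hours,
                       mark = NA_character_, replicate = NA_character_,
                       lib_counts = NULL) {
  values <- as.matrix(values)
  stopifnot(is(windows, "GRanges"))
  if (length(labels) != length(hours) || ncol(values) != length(labels))
    stop("labels, hours and value columns must agree")
  if (length(hours) < 2) stop("a time course needs at least two timepoints")
  if (any(diff(hours) <= 0)) stop("timepoints must be strictly increasing in hours")
  if (nrow(values) != length(windows))
    stop("matrix rows must match the window set")
  if (anyNA(values)) stop("time-course matrix must be complete (no NA)")
  if (any(values < 0)) stop("time-course values must be >= 0")
  colnames(values) <- labels
  structure(list(values = values, windows = windows,
                 labels = labels, hours = as.numeric(hours),
                 mark = mark, replicate = replicate,
                 lib_counts = lib_counts),
            class = "TimeCourse")
}

#' @export
print.TimeCourse <- function(x, ...) {
  cat(sprintf("TimeCourse: %d windows x %d timepoints (%s)",
              nrow(x$values), ncol(x$values), paste(x$labels, collapse = ", ")))
  if (!is.na(x$mark)) cat(" | mark:", x$mark)
  if (!is.na(x$replicate)) cat(" | replicate:", x$replicate)
  cat("\n")
  invisible(x)
}

#' Assemble a window-level time course from binned tracks
#'
#' The value of a window at each timepoint is the sum of the constituent
#' bin values of that timepoint's track. Windows must align with the bin
#' grid (start and end on bin boundaries) so the sum is exact; re-binning
#' reads directly at window size would give identical sums by construction.
#'
#' @param tracks list of [binned_track()] (typically RRPM), one per
#'   timepoint, all sharing bin size and layout.
#' @param labels,hours timepoint labels and hours, parallel to `tracks`.
#' @param windows GRanges of uniform-width windows aligned to the bin grid.
#' @param lib_counts optional list of [library_counts()] parallel to tracks.
#' @param mark,replicate labels stored on the result.
#' @return A [timecourse()].
#' @export
assemble_timecourse <- function(tracks, labels, hours, windows,
                                lib_counts = NULL, mark = NA_character_,
                                replicate = NA_character_) {
  if (length(tracks) != length(labels))
    stop("one track per timepoint label is required")
  bs <- unique(vapply(tracks, function(t) t$bin_size, integer(1)))
  if (length(bs) != 1) stop("all tracks must share one bin size")
  lens <- tracks[[1]]$chrom_lengths
  for (t in tracks) if (!identical(t$chrom_lengths, lens))
    stop("all tracks must share one genome layout")
  chrom <- as.character(seqnames(windows))
  if (any(!chrom %in% names(lens)))
    stop("window on chromosome absent from the tracks: ",
         setdiff(chrom, names(lens))[1])
  s0 <- start(windows) - 1
  e <- end(windows)
  if (any(s0 %% bs != 0 | e %% bs != 0))
    stop("windows must align to the ", bs, " bp bin grid")
  if (any(e > unname(lens[chrom])))
    stop("window extends beyond chromosome end")
  i1 <- s0 %/% bs + 1
  i2 <- e %/% bs
  values <- vapply(tracks, function(t) {
    cs <- lapply(t$values, function(v) c(0, cumsum(v)))
    vapply(seq_along(windows),
           function(w) cs[[chrom[w]]][i2[w] + 1] - cs[[chrom[w]]][i1[w]],
           numeric(1))
  }, numeric(length(windows)))
  values <- matrix(values, ncol = length(tracks))
  timecourse(values, windows, labels, hours, mark = mark,
             replicate = replicate, lib_counts = lib_counts)
}

#' Classify per-window restoration kinetics
#'
#' A window's restoration category is the earliest timepoint at which its
#' signal has reached the final-timepoint level within `fold_threshold`:
#' category = earliest `t` with `final_level / level(t) <= fold_threshold`
#' (`<` under `boundary = "open"`). Windows already at their final level at
#' the first timepoint get the first label ("R0"); windows that only reach
#' it at the final timepoint get the final label. A zero level at an
#' earlier timepoint gives an infinite ratio there (not yet restored); a
#' zero *final* level makes the window unclassifiable — such windows are
#' reported with `NA` category and counted, never silently dropped.
#'
#' Under `strict = TRUE` the literal reading of the published filter is
#' applied: windows with no ratio above the threshold (i.e. already
#' restored at the first timepoint) are excluded from classification
#' (category `NA`, counted in `attr(, "n_strict_dropped")`). The default
#' keeps them as the first category, since displayed category charts
#' include an "R0" class.
#'
#' @param tc a [timecourse()].
#' @param fold_threshold restoration fold threshold (default 1.5).
#' @param boundary whether a ratio exactly at the threshold counts as
#'   restored (`"closed"`, default) or not (`"open"`).
#' @param strict apply the literal "ratios greater than threshold only"
#'   filter (default `FALSE`).
#' @return A data.frame of class `RestorationCalls`: window coordinates,
#'   per-timepoint ratios (`ratio_<label>` = final / level at label),
#'   `category` (factor over R-labels, `NA` when unclassifiable or
#'   strict-dropped) and `classifiable`. Attributes `n_unclassifiable` and
#'   `n_strict_dropped` report the exclusion counts.
#' @export
classify_restoration <- function(tc, fold_threshold = 1.5,
                                 boundary = c("closed", "open"),
                                 strict = FALSE) {
  stopifnot(inherits(tc, "TimeCourse"))
  boundary <- match.arg(boundary)
  if (fold_threshold <= 0) stop("fold_threshold must be positive")
  m <- tc$values
  Tn <- ncol(m)
  final <- m[, Tn]
  earlier <- m[, -Tn, drop = FALSE]
  ratios <- final / earlier              # 0 earlier, positive final -> Inf
  classifiable <- final > 0
  restored <- if (boundary == "closed") ratios <= fold_threshold else ratios < fold_threshold
  restored[!classifiable, ] <- FALSE
  # earliest restored timepoint; the final timepoint restores by definition
  full <- cbind(restored, TRUE)
  cat_idx <- max.col(full, ties.method = "first")
  rlabels <- .category_label(tc$labels)
  category <- factor(rlabels[cat_idx], levels = rlabels)
  category[!classifiable] <- NA
  n_strict <- 0L
  if (strict) {
    never_below <- rowSums(ratios > fold_threshold) == 0 & classifiable
    n_strict <- sum(never_below)
    category[never_below] <- NA
  }
  out <- data.frame(chrom = as.character(seqnames(tc$windows)),
                    start = start(tc$windows), end = end(tc$windows),
                    stringsAsFactors = FALSE)
  rat <- as.data.frame(ratios)
  names(rat) <- paste0("ratio_", tc$labels[-Tn])
  out <- cbind(out, rat)
  out$category <- category
  out$classifiable <- classifiable
  class(out) <- c("RestorationCalls", "data.frame")
  attr(out, "n_unclassifiable") <- sum(!classifiable)
  attr(out, "n_strict_dropped") <- n_strict
  attr(out, "labels") <- rlabels
  out
}

#' Keep windows with concordant categories across replicates
#'
#' Retains windows whose category is identical in both replicate call
#' sets (windows unclassified in either replicate cannot be concordant).
#' The retained fraction — concordant / compared — is reported as an
#' attribute, where compared counts windows classified in both replicates.
#'
#' @param calls_rep1,calls_rep2 call data.frames from
#'   [classify_restoration()] or [classify_loss()] over the same window
#'   set (an error otherwise).
#' @return The concordant subset (categories from replicate 1, which equal
#'   replicate 2's) with a `concordant` column; attributes
#'   `retained_fraction` and `n_compared`.
#' @export
replicate_concordance <- function(calls_rep1, calls_rep2) {
  same <- identical(calls_rep1$chrom, calls_rep2$chrom) &&
    identical(calls_rep1$start, calls_rep2$start) &&
    identical(calls_rep1$end, calls_rep2$end)
  if (!same) stop("replicate call sets cover different windows")
  both <- !is.na(calls_rep1$category) & !is.na(calls_rep2$category)
  conc <- both & calls_rep1$category == calls_rep2$category
  out <- calls_rep1[conc, , drop = FALSE]
  out$concordant <- TRUE
  attr(out, "retained_fraction") <- if (sum(both)) sum(conc) / sum(both) else NaN
  attr(out, "n_compared") <- sum(both)
  attr(out, "labels") <- attr(calls_rep1, "labels")
  class(out) <- class(calls_rep1)
  out
}

#' Classify per-window signal loss between two timepoints
#'
#' For a two-timepoint course (nascent T0 and a late timepoint under
#' blocked de-novo modification), the fold change `T0 / T_late` is binned
#' into `low` (fold below `low_cut`), `moderate` (between the cuts) and
#' `high` (above `high_cut`). Under the default closed boundaries the
#' moderate band is `[low_cut, high_cut]`; `boundary = "open"` assigns
#' exact-boundary folds to the adjacent outer category. A zero late level
#' with positive T0 is total loss: category `high`, flagged. Zero at both
#' timepoints is unclassifiable (`NA`, counted).
#'
#' @param tc a [timecourse()] with exactly two timepoints.
#' @param low_cut,high_cut fold-change cuts (defaults 1.5 and 3).
#' @param boundary boundary convention for folds exactly at a cut.
#' @return A data.frame of class `LossCalls` with `fold`, `category`
#'   (factor low/moderate/high) and flags; attribute `n_unclassifiable`.
#' @export
classify_loss <- function(tc, low_cut = 1.5, high_cut = 3,
                          boundary = c("closed", "open")) {
  stopifnot(inherits(tc, "TimeCourse"))
  boundary <- match.arg(boundary)
  if (ncol(tc$values) != 2)
    stop("loss classification needs exactly two timepoints (T0 and the late point)")
  if (low_cut <= 0 || high_cut <= low_cut) stop("need 0 < low_cut < high_cut")
  v0 <- tc$values[, 1]
  v1 <- tc$values[, 2]
  fold <- v0 / v1                        # Inf when v1 = 0, v0 > 0; NaN when both 0
  unclass <- v0 == 0 & v1 == 0
  total_loss <- v1 == 0 & v0 > 0
  category <- if (boundary == "closed") {
    ifelse(fold < low_cut, "low", ifelse(fold <= high_cut, "moderate", "high"))
  } else {
    ifelse(fold <= low_cut, "low", ifelse(fold < high_cut, "moderate", "high"))
  }
  category[unclass] <- NA
  category <- factor(category, levels = c("low", "moderate", "high"))
  out <- data.frame(chrom = as.character(seqnames(tc$windows)),
                    start = start(tc$windows), end = end(tc$windows),
                    fold = fold, category = category,
                    total_loss = total_loss,
                    classifiable = !unclass,
                    stringsAsFactors = FALSE)
  class(out) <- c("LossCalls", "data.frame")
  attr(out, "n_unclassifiable") <- sum(unclass)
  attr(out, "labels") <- levels(category)
  out
}

#' Proportion of windows per category
#'
#' @param calls a `RestorationCalls` or `LossCalls` data.frame (or any
#'   data.frame with a factor `category` column). Unclassified windows
#'   (`NA`) are excluded; proportions are over classified windows and sum
#'   to 1.
#' @return Named numeric vector over all category levels.
#' @export
category_proportions <- function(calls) {
  cat <- calls$category
  if (!length(cat)) stop("no calls supplied")
  n <- sum(!is.na(cat))
  if (n == 0) stop("no classified windows")
  tab <- table(cat[!is.na(cat)])
  as.numeric(tab) / n -> p
  setNames(p, names(tab))
}
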