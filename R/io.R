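# File-format boundary. Everything on disk follows the BED convention
# (0-based half-open); in memory the package uses GRanges (1-based closed).
# All conversions happen in this file and nowhere else.

.is_header_line <- function(x) grepl("^(track|browser|#)", x) | !nzchar(x)

# Split kept lines into a character matrix of up to max_fields columns,
# keeping the original file line numbers for error reporting.
.read_tabular <- function(path, max_fields) {
  raw <- readLines(path)
  keep <- !.is_header_line(raw)
  lineno <- which(keep)
  if (!length(lineno))
    return(list(mat = matrix(character(0), 0, max_fields), lineno = integer(0)))
  fields <- strsplit(raw[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (length(unique(nf)) == 1L && nf[1] <= max_fields) {
    mat <- matrix(unlist(fields, use.names = FALSE), ncol = nf[1], byrow = TRUE)
  } else {
    ncol_out <- min(max(nf), max_fields)
    mat <- matrix(NA_character_, length(fields), ncol_out)
    for (j in seq_len(ncol_out)) {
      has <- nf >= j
      mat[has, j] <- vapply(fields[has], `[[`, character(1), j)
    }
  }
  list(mat = mat, lineno = lineno, nfields = nf)
}

.parse_int_col <- function(x, lineno, path, what) {
  v <- suppressWarnings(as.numeric(x))
  bad <- is.na(v) | v != floor(v)
  if (any(bad))
    stop(sprintf("%s: malformed %s at line %d ('%s')",
                 path, what, lineno[which(bad)[1]], x[which(bad)[1]]), call. = FALSE)
  v
}

.check_coords <- function(start0, end, lineno, path) {
  if (any(start0 < 0))
    stop(sprintf("%s: negative start at line %d", path, lineno[which(start0 < 0)[1]]),
         call. = FALSE)
  bad <- end <= start0
  if (any(bad))
    stop(sprintf("%s: empty or inverted interval at line %d (start %d, end %d)",
                 path, lineno[which(bad)[1]], start0[which(bad)[1]], end[which(bad)[1]]),
         call. = FALSE)
}

# Apply the layout policy to a parsed chromosome column. Returns the logical
# keep vector (all TRUE in error mode, which stops on the first unknown name).
.apply_layout_policy <- function(chrom, lineno, path, layout, unknown) {
  if (is.null(layout)) return(rep(TRUE, length(chrom)))
  known <- chrom %in% layout_chroms(layout)
  if (all(known)) return(known | TRUE)
  if (unknown == "error")
    stop(sprintf("%s: chromosome '%s' at line %d is absent from the layout",
                 path, chrom[!known][1], lineno[!known][1]), call. = FALSE)
  warning(sprintf("%s: skipped %d record(s) on chromosomes absent from the layout (%s)",
                  path, sum(!known), paste(unique(chrom[!known]), collapse = ", ")),
          call. = FALSE)
  known
}

.gr_seqinfo <- function(layout) if (is.null(layout)) NULL else layout_seqinfo(layout)

#' Read a BED3-6 file
#'
#' Strict reader for 3- to 6-column BED. Coordinates on disk are 0-based
#' half-open and are converted to the 1-based closed GRanges convention.
#' Input order is preserved; `track`, `browser` and `#` lines are ignored.
#'
#' @param path BED file path.
#' @param layout optional [genome_layout()]; when given, records are checked
#'   against it and the returned GRanges carries its seqinfo.
#' @param unknown policy for records on chromosomes absent from `layout`:
#'   `"error"` (default) or `"skip"` (drop with one warning).
#' @return A [GenomicRanges::GRanges] with optional `name` and `score`
#'   metadata columns.
#' @export
read_bed <- function(path, layout = NULL, unknown = c("error", "skip")) {
  unknown <- match.arg(unknown)
  tab <- .read_tabular(path, 6L)
  if (!nrow(tab$mat))
    return(GRanges(seqinfo = .gr_seqinfo(layout)))
  if (any(tab$nfields < 3))
    stop(sprintf("%s: fewer than 3 fields at line %d", path,
                 tab$lineno[which(tab$nfields < 3)[1]]), call. = FALSE)
  chrom <- tab$mat[, 1]
  start0 <- .parse_int_col(tab$mat[, 2], tab$lineno, path, "start")
  end <- .parse_int_col(tab$mat[, 3], tab$lineno, path, "end")
  .check_coords(start0, end, tab$lineno, path)
  keep <- .apply_layout_policy(chrom, tab$lineno, path, layout, unknown)

  name <- if (ncol(tab$mat) >= 4) tab$mat[, 4] else NULL
  score <- if (ncol(tab$mat) >= 5) {
    sc <- tab$mat[, 5]
    sc[sc %in% c(".", NA)] <- NA
    v <- suppressWarnings(as.numeric(sc))
    bad <- !is.na(sc) & is.na(v)
    if (any(bad))
      stop(sprintf("%s: malformed score at line %d", path, tab$lineno[which(bad)[1]]),
           call. = FALSE)
    v
  } else NULL
  strand <- if (ncol(tab$mat) >= 6) {
    st <- tab$mat[, 6]
    st[is.na(st)] <- "."
    bad <- !st %in% c("+", "-", ".")
    if (any(bad))
      stop(sprintf("%s: malformed strand '%s' at line %d", path,
                   st[which(bad)[1]], tab$lineno[which(bad)[1]]), call. = FALSE)
    st[st == "."] <- "*"
    st
  } else "*"

  gr <- GRanges(chrom[keep], IRanges(start0[keep] + 1, end[keep]),
                strand = if (length(strand) > 1) strand[keep] else strand,
                seqinfo = .gr_seqinfo(layout))
  if (!is.null(name)) {
    nm <- name[keep]; nm[nm %in% "."] <- NA
    mcols(gr)$name <- nm
  }
  if (!is.null(score)) mcols(gr)$score <- score[keep]
  gr
}

#' Write intervals as BED
#'
#' Emits BED3 when the GRanges carries no name/score/strand information,
#' BED6 otherwise (missing fields filled with the BED placeholder `.` and
#' score 0).
#'
#' @param x a GRanges.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  stopifnot(is(x, "GRanges"))
  st <- as.character(strand(x))
  has_extra <- ("name" %in% names(mcols(x))) || ("score" %in% names(mcols(x))) ||
    any(st != "*")
  dt <- data.table(chrom = as.character(seqnames(x)),
                   start = as.integer(start(x) - 1L),
                   end = as.integer(end(x)))
  if (has_extra) {
    nm <- if ("name" %in% names(mcols(x))) as.character(mcols(x)$name) else rep(NA, length(x))
    nm[is.na(nm)] <- "."
    sc <- if ("score" %in% names(mcols(x))) mcols(x)$score else rep(0, length(x))
    sc[is.na(sc)] <- 0
    st[st == "*"] <- "."
    dt <- cbind(dt, data.table(name = nm, score = sc, strand = st))
  }
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read ENCODE narrowPeak / broadPeak files
#'
#' narrowPeak has exactly 10 columns (the last being the summit offset),
#' broadPeak exactly 9. The declared dialect is enforced: a file with the
#' wrong column count is a parse error. The MACS/ENCODE statistics columns
#' are retained as metadata (`signalValue`, `pValue`, `qValue`, and for
#' narrowPeak `summit`, the 0-based offset of the summit within the peak;
#' the conventional `-1` sentinel becomes `NA`).
#'
#' @inheritParams read_bed
#' @param dialect `"narrowPeak"` or `"broadPeak"`.
#' @return A GRanges with peak metadata columns.
#' @export
read_peaks <- function(path, dialect = c("narrowPeak", "broadPeak"),
                       layout = NULL, unknown = c("error", "skip")) {
  dialect <- match.arg(dialect)
  unknown <- match.arg(unknown)
  want <- if (dialect == "narrowPeak") 10L else 9L
  tab <- .read_tabular(path, want)
  if (!nrow(tab$mat)) return(GRanges(seqinfo = .gr_seqinfo(layout)))
  if (!is.null(tab$nfields) && any(tab$nfields != want))
    stop(sprintf("%s: %s requires %d columns but line %d has %d",
                 path, dialect, want,
                 tab$lineno[which(tab$nfields != want)[1]],
                 tab$nfields[which(tab$nfields != want)[1]]), call. = FALSE)
  if (ncol(tab$mat) != want || anyNA(tab$mat))
    stop(sprintf("%s: %s requires exactly %d columns", path, dialect, want),
         call. = FALSE)
  chrom <- tab$mat[, 1]
  start0 <- .parse_int_col(tab$mat[, 2], tab$lineno, path, "start")
  end <- .parse_int_col(tab$mat[, 3], tab$lineno, path, "end")
  .check_coords(start0, end, tab$lineno, path)
  keep <- .apply_layout_policy(chrom, tab$lineno, path, layout, unknown)

  st <- tab$mat[, 6]; st[!st %in% c("+", "-")] <- "*"
  gr <- GRanges(chrom[keep], IRanges(start0[keep] + 1, end[keep]),
                strand = st[keep], seqinfo = .gr_seqinfo(layout))
  nm <- tab$mat[keep, 4]; nm[nm == "."] <- NA
  mcols(gr)$name <- nm
  mcols(gr)$score <- suppressWarnings(as.numeric(tab$mat[keep, 5]))
  mcols(gr)$signalValue <- suppressWarnings(as.numeric(tab$mat[keep, 7]))
  mcols(gr)$pValue <- suppressWarnings(as.numeric(tab$mat[keep, 8]))
  mcols(gr)$qValue <- suppressWarnings(as.numeric(tab$mat[keep, 9]))
  if (dialect == "narrowPeak") {
    summit <- suppressWarnings(as.numeric(tab$mat[keep, 10]))
    summit[summit < 0] <- NA
    mcols(gr)$summit <- summit
  }
  gr
}

#' Write peaks in an ENCODE peak dialect
#' @param x GRanges, optionally carrying the peak metadata columns produced
#'   by [read_peaks()]; absent statistics are written with the ENCODE
#'   missing-value sentinel `-1`.
#' @inheritParams read_peaks
#' @export
write_peaks <- function(x, path, dialect = c("narrowPeak", "broadPeak")) {
  dialect <- match.arg(dialect)
  n <- length(x)
  grab <- function(col, default) {
    v <- if (col %in% names(mcols(x))) mcols(x)[[col]] else rep(default, n)
    v[is.na(v)] <- default
    v
  }
  st <- as.character(strand(x)); st[st == "*"] <- "."
  dt <- data.table(chrom = as.character(seqnames(x)),
                   start = as.integer(start(x) - 1L),
                   end = as.integer(end(x)),
                   name = grab("name", "."),
                   score = grab("score", 0),
                   strand = st,
                   signalValue = grab("signalValue", 0),
                   pValue = grab("pValue", -1),
                   qValue = grab("qValue", -1))
  if (dialect == "narrowPeak") dt$summit <- grab("summit", -1)
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Filter peaks on the q-value column
#'
#' Keeps peaks whose q-value passes `cutoff`. The comparison direction is
#' exposed because printed filtering rules in the literature are sometimes
#' ambiguous about it; the default keeps significant regions
#' (q-value <= cutoff).
#'
#' @param x GRanges with a `qValue` metadata column.
#' @param cutoff q-value cutoff (default 0.05).
#' @param direction `"le"` keeps `q <= cutoff`, `"ge"` keeps `q >= cutoff`.
#' @param neglog10 set `TRUE` when the stored column is -log10(q) (the
#'   MACS/ENCODE convention); the stored values are then converted back to
#'   plain q-values before comparison.
#' @return The filtered GRanges; records with missing q are dropped with a
#'   warning.
#' @export
filter_by_qvalue <- function(x, cutoff = 0.05, direction = c("le", "ge"),
                             neglog10 = FALSE) {
  direction <- match.arg(direction)
  if (!"qValue" %in% names(mcols(x))) stop("no qValue column to filter on")
  q <- mcols(x)$qValue
  if (neglog10) q <- 10^(-q)
  if (anyNA(q)) {
    warning(sum(is.na(q)), " record(s) with missing q-value dropped")
  }
  keep <- if (direction == "le") !is.na(q) & q <= cutoff else !is.na(q) & q >= cutoff
  x[keep]
}

#' Write / read a binned track as bedGraph
#'
#' One line per bin (zeros included so that the round trip is exact); bins
#' are emitted sorted within each chromosome in layout order. Reading
#' requires the record boundaries to sit on the bin grid of the stated
#' `bin_size`; bins absent from the file are zero.
#'
#' @param track a [binned_track()].
#' @param path bedGraph path.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "BinnedTrack"))
  gr <- bin_ranges(track)
  mcols(gr)$score <- unlist(track$values, use.names = FALSE)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname write_bedgraph
#' @param layout a [genome_layout()] giving the target chromosomes.
#' @param bin_size bin width in bp the file is expected to follow.
#' @param normalization,mark,time metadata restored onto the track.
#' @return `read_bedgraph()` returns a [binned_track()].
#' @export
read_bedgraph <- function(path, layout, bin_size, normalization = "raw",
                          mark = NA_character_, time = NA_character_) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  lens <- layout$target
  values <- lapply(lens, function(L) numeric(ceiling(L / bin_size)))
  if (length(gr)) {
    chrom <- as.character(seqnames(gr))
    unknown <- setdiff(unique(chrom), names(lens))
    if (length(unknown))
      stop(path, ": bedGraph record on non-target chromosome ", unknown[1])
    s0 <- start(gr) - 1L; e <- end(gr)
    for (ch in unique(chrom)) {
      i <- chrom == ch
      L <- lens[[ch]]
      ok <- (s0[i] %% bin_size == 0) & (e[i] %% bin_size == 0 | e[i] == L)
      if (!all(ok))
        stop(path, ": record not aligned to the ", bin_size, " bp bin grid on ", ch)
      i1 <- s0[i] %/% bin_size + 1L
      i2 <- as.integer(ceiling(e[i] / bin_size))
      idx <- sequence(i2 - i1 + 1L, from = i1)
      values[[ch]][idx] <- rep(mcols(gr)$score[i], i2 - i1 + 1L)
    }
  }
  binned_track(values, bin_size, layout, normalization = normalization,
               mark = mark, time = time)
}

#' Sidecar metadata for track files
#'
#' Plain `key=value` text recording bin size, normalization state and
#' mark/time labels next to a bedGraph, so the normalization of a track on
#' disk is never ambiguous.
#'
#' @param track a [binned_track()].
#' @param path metadata file path.
#' @export
write_track_metadata <- function(track, path) {
  writeLines(c(paste0("bin_size=", track$bin_size),
               paste0("normalization=", track$normalization),
               paste0("mark=", track$mark),
               paste0("time=", track$time)), path)
  invisible(path)
}

#' @rdname write_track_metadata
#' @return `read_track_metadata()` returns a named character vector.
#' @export
read_track_metadata <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  setNames(vapply(kv, function(x) paste(x[-1], collapse = "="), character(1)),
           vapply(kv, `[[`, character(1), 1))
}
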