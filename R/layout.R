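.validate_chrom_lengths <- function(x, what) {
  if (length(x) == 0) return(setNames(numeric(0), character(0)))
  if (!is.numeric(x)) stop(what, " chromosome lengths must be numeric", call. = FALSE)
  nm <- names(x)
  if (is.null(nm) || any(!nzchar(nm)) || anyNA(nm))
    stop(what, " chromosome lengths must be named by chromosome", call. = FALSE)
  if (anyDuplicated(nm))
    stop("duplicated ", what, " chromosome name: ", nm[duplicated(nm)][1], call. = FALSE)
  if (any(!is.finite(x)) || any(x <= 0) || any(x != floor(x)))
    stop(what, " chromosome lengths must be positive integers", call. = FALSE)
  storage.mode(x) <- "double"
  x
}

#' Dual-genome layout: target and spike-in chromosomes
#'
#' A `GenomeLayout` records the ordered chromosome names and lengths of the
#' target genome (the organism under study) and of the exogenous spike-in
#' genome added in constant proportion for quantitative normalization.
#' Spike-in reads are identified throughout the package by chromosome-name
#' membership in the spike-in set, mirroring dual-genome alignment: both
#' genomes live in one read file and one name space.
#'
#' @param target named numeric vector of target chromosome lengths (bp).
#' @param spikein named numeric vector of spike-in chromosome lengths (bp);
#'   may be empty for experiments without spike-in.
#' @return An object of class `GenomeLayout`.
#' @examples
#' genome_layout(c(chr1 = 1e6), c(dchr2L = 2e5))
#' @export
genome_layout <- function(target, spikein = NULL) {
  target <- .validate_chrom_lengths(target, "target")
  if (length(target) == 0) stop("layout needs at least one target chromosome")
  spikein <- .validate_chrom_lengths(if (is.null(spikein)) numeric(0) else spikein,
                                     "spike-in")
  shared <- intersect(names(target), names(spikein))
  if (length(shared))
    stop("target and spike-in chromosome names must be disjoint: ", shared[1])
  structure(list(target = target, spikein = spikein), class = "GenomeLayout")
}

#' @export
print.GenomeLayout <- function(x, ...) {
  cat("GenomeLayout:", length(x$target), "target chromosome(s),",
      sum(x$target), "bp;", length(x$spikein), "spike-in chromosome(s),",
      sum(x$spikein), "bp\n")
  invisible(x)
}

#' Chromosome names of a layout
#' @param layout a [genome_layout()].
#' @param origin which genome: `"both"`, `"target"` or `"spikein"`.
#' @return Character vector of chromosome names.
#' @export
layout_chroms <- function(layout, origin = c("both", "target", "spikein")) {
  stopifnot(inherits(layout, "GenomeLayout"))
  origin <- match.arg(origin)
  switch(origin,
         both    = c(names(layout$target), names(layout$spikein)),
         target  = names(layout$target),
         spikein = names(layout$spikein))
}

#' Are chromosomes part of the spike-in genome?
#' @param layout a [genome_layout()].
#' @param chrom character vector of chromosome names.
#' @return Logical vector; `NA` is never returned — unknown names error.
#' @export
is_spikein_chrom <- function(layout, chrom) {
  stopifnot(inherits(layout, "GenomeLayout"))
  unknown <- setdiff(unique(chrom), layout_chroms(layout))
  if (length(unknown))
    stop("chromosome not in layout: ", unknown[1])
  chrom %in% names(layout$spikein)
}

#' Seqinfo for a layout
#' @inheritParams layout_chroms
#' @return A [GenomeInfoDb::Seqinfo] covering the requested chromosomes.
#' @export
layout_seqinfo <- function(layout, origin = c("both", "target", "spikein")) {
  origin <- match.arg(origin)
  lens <- switch(origin,
                 both    = c(layout$target, layout$spikein),
                 target  = layout$target,
                 spikein = layout$spikein)
  Seqinfo(seqnames = names(lens), seqlengths = as.integer(lens))
}

#' Read / write chrom-sizes files
#'
#' Two-column tab-separated text: chromosome name, length in bp.
#'
#' @param path file path.
#' @return `read_chrom_sizes()` returns a named numeric vector suitable for
#'   [genome_layout()].
#' @export
read_chrom_sizes <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t", colClasses = list(character = 1))
  if (ncol(dt) < 2) stop("chrom-sizes file must have two columns: ", path)
  setNames(as.numeric(dt[[2]]), dt[[1]])
}

#' @rdname read_chrom_sizes
#' @param lengths named numeric vector of chromosome lengths.
#' @export
write_chrom_sizes <- function(lengths, path) {
  fwrite(data.table(names(lengths), as.integer(lengths)), path,
         sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Library totals for normalization
#'
#' Holds the unique-read totals of one sequencing library split by genome of
#' origin. The spike-in total is the denominator of the reference-adjusted
#' RPM (RRPM) normalization and must be positive before [rrpm()] is applied.
#'
#' @param target_unique_reads integer, uniquely mapped target-genome reads.
#' @param spikein_unique_reads integer, uniquely mapped spike-in reads.
#' @return An object of class `LibraryCounts`.
#' @export
library_counts <- function(target_unique_reads, spikein_unique_reads = 0) {
  t <- as.numeric(target_unique_reads); s <- as.numeric(spikein_unique_reads)
  if (length(t) != 1 || length(s) != 1 || is.na(t) || is.na(s) || t < 0 || s < 0)
    stop("library counts must be single non-negative numbers")
  structure(list(target_unique_reads = t, spikein_unique_reads = s),
            class = "LibraryCounts")
}

#' @export
print.LibraryCounts <- function(x, ...) {
  cat("LibraryCounts: target =", x$target_unique_reads,
      "; spike-in =", x$spikein_unique_reads, "\n")
  invisible(x)
}
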