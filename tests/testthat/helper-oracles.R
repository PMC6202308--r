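# Independent brute-force oracles and small fixture builders. The oracles
# deliberately use per-base / pairwise loops and never the package's (or
# GenomicRanges') interval machinery, so they stay independent of the code
# paths they check.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

toy_layout <- function(target_len = 10000, spike_len = 2000) {
  genome_layout(c(chr1 = target_len), c(spk1 = spike_len))
}

# random reads over one chromosome (1-based GRanges)
random_reads <- function(n, chrom_len, read_len = 50, chrom = "chr1") {
  s0 <- floor(runif(n, 0, chrom_len - read_len))
  GRanges(chrom, IRanges(s0 + 1, width = read_len),
          strand = sample(c("+", "-"), n, replace = TRUE))
}

# random non-overlapping intervals via sorted cut points
random_disjoint <- function(n, chrom_len, min_w = 50, max_w = 400, chrom = "chr1") {
  w <- floor(runif(n, min_w, max_w))
  free <- chrom_len - sum(w)
  stopifnot(free > 0)
  g <- runif(n + 1); g <- g / sum(g) * free
  s0 <- floor(cumsum(g)[seq_len(n)] + c(0, cumsum(w))[seq_len(n)])
  GRanges(chrom, IRanges(s0 + 1, width = w))
}

# oracle: per-base occupancy counting then per-bin "any overlap" per read
oracle_bin_counts <- function(reads, bin_size, chrom_len) {
  nb <- ceiling(chrom_len / bin_size)
  counts <- numeric(nb)
  for (i in seq_along(reads)) {
    s0 <- start(reads)[i] - 1
    e <- end(reads)[i]
    b1 <- s0 %/% bin_size + 1
    b2 <- min(nb, (e - 1) %/% bin_size + 1)
    for (b in b1:b2) counts[b] <- counts[b] + 1
  }
  counts
}

# oracle: total intersection (bp) of one interval with the union of regions,
# computed per base
oracle_overlap_bp <- function(w_start, w_end, regions) {
  bases <- w_start:(w_end - 1)           # 0-based positions
  covered <- rep(FALSE, length(bases))
  for (i in seq_along(regions)) {
    rs <- start(regions)[i] - 1
    re <- end(regions)[i]
    covered <- covered | (bases >= rs & bases < re)
  }
  sum(covered)
}

# oracle: reciprocally unique overlapping pairs by O(n*m) scanning
oracle_unique_pairs <- function(parental, nascent) {
  np <- length(parental); nn <- length(nascent)
  ov <- matrix(FALSE, np, nn)
  for (i in seq_len(np)) for (j in seq_len(nn)) {
    ov[i, j] <- as.character(seqnames(parental))[i] == as.character(seqnames(nascent))[j] &&
      start(parental)[i] <= end(nascent)[j] && start(nascent)[j] <= end(parental)[i]
  }
  pairs <- list()
  for (i in seq_len(np)) for (j in seq_len(nn)) {
    if (ov[i, j] && sum(ov[i, ]) == 1 && sum(ov[, j]) == 1)
      pairs[[length(pairs) + 1]] <- c(i, j,
        abs(start(parental)[i] - start(nascent)[j]),
        abs(end(parental)[i] - end(nascent)[j]))
  }
  if (!length(pairs)) return(matrix(numeric(0), 0, 4))
  do.call(rbind, pairs)
}

# oracle: row extraction around anchors by direct indexing
oracle_anchor_matrix <- function(values, bin_size, anchors_pos0, minus, flank) {
  ncol_out <- 2 * flank / bin_size
  mat <- matrix(NA_real_, length(anchors_pos0), ncol_out)
  for (r in seq_along(anchors_pos0)) {
    p0 <- (anchors_pos0[r] %/% bin_size) * bin_size
    idx <- ((p0 - flank) / bin_size + 1):((p0 + flank) / bin_size)
    row <- values[idx]
    mat[r, ] <- if (minus[r]) rev(row) else row
  }
  mat
}

# direct TimeCourse builder for classifier tests
make_tc <- function(mat, labels = c("T0", "T1", "T6", "T12"),
                    hours = c(0, 1, 6, 12)) {
  mat <- matrix(mat, ncol = length(labels))
  w <- GRanges("chr1", IRanges((seq_len(nrow(mat)) - 1) * 1000 + 1, width = 500))
  timecourse(mat, w, labels, hours)
}

# oracle reclassification of loss calls, scalar logic
oracle_loss_category <- function(v0, v1, low = 1.5, high = 3) {
  if (v0 == 0 && v1 == 0) return(NA_character_)
  f <- v0 / v1
  if (f < low) "low" else if (f <= high) "moderate" else "high"
}

# small deterministic track over the toy layout
make_track <- function(values, bin_size = 25, layout = NULL) {
  if (is.null(layout))
    layout <- genome_layout(c(chr1 = length(values) * bin_size), c(spk1 = 1000))
  binned_track(list(chr1 = as.numeric(values)), bin_size, layout)
}
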