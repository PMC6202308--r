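# Windowing, replicated-region filtering, peak pairing, domain borders.

test_that("tile_peaks tiles from the start and drops remainders", {
  pk <- GRanges("chr1", IRanges(1, 100))      # [0,100) on disk
  w <- tile_peaks(pk, 25)
  expect_length(w, 4)
  expect_equal(start(w), c(1, 26, 51, 76))
  expect_equal(unique(width(w)), 25)
  # 110 bp peak: remainder dropped
  expect_length(tile_peaks(GRanges("chr1", IRanges(1, 110)), 25), 4)
  # shorter than the window: no windows
  expect_length(tile_peaks(GRanges("chr1", IRanges(1, 20)), 25), 0)
  # total tiled length identity over a random peak set
  set.seed(5)
  peaks <- random_disjoint(40, 50000)
  w <- tile_peaks(peaks, 25)
  expect_equal(sum(width(w)), sum((width(peaks) %/% 25) * 25))
  expect_equal(metadata(w)$window_size, 25L)
})

test_that("filter_by_overlap uses half-open overlap against the region union", {
  w <- GRanges("chr1", IRanges(1, 25))        # [0,25)
  expect_length(filter_by_overlap(w, GRanges("chr1", IRanges(21, 30))), 1)  # 5 bp
  expect_length(filter_by_overlap(w, GRanges("chr1", IRanges(26, 50))), 0)  # touching
  # min_overlap across two adjacent union pieces
  regions <- GRanges("chr1", IRanges(c(1, 11), c(10, 30)))
  expect_length(filter_by_overlap(w, regions, min_overlap = 25), 1)
})

test_that("filter_by_overlap matches a per-base oracle and preserves order", {
  for (seed in 1:4) {
    set.seed(100 + seed)
    windows <- random_disjoint(60, 30000, min_w = 25, max_w = 25)
    windows <- windows[sample(length(windows))]      # scrambled input order
    regions <- random_disjoint(25, 30000, min_w = 100, max_w = 1500)
    min_ov <- sample(c(1, 5, 20), 1)
    got <- filter_by_overlap(windows, regions, min_overlap = min_ov)
    keep <- vapply(seq_along(windows), function(i)
      oracle_overlap_bp(start(windows)[i] - 1, end(windows)[i], regions) >= min_ov,
      logical(1))
    expect_equal(as.data.frame(got)[, 1:3],
                 as.data.frame(windows[keep])[, 1:3])
  }
})

test_that("pair_unique_peaks keeps reciprocally unique pairs and measures ends", {
  p <- GRanges("chr1", IRanges(101, 300))
  n <- GRanges("chr1", IRanges(151, 350))
  pr <- pair_unique_peaks(p, n)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$start_distance, 50)
  expect_equal(pr$end_distance, 50)
  # a parental peak overlapping two nascent peaks is excluded
  p2 <- GRanges("chr1", IRanges(1, 500))
  n2 <- GRanges("chr1", IRanges(c(50, 300), c(120, 420)))
  expect_equal(nrow(pair_unique_peaks(p2, n2)), 0)
  # identical lists: all distances zero
  set.seed(8)
  pk <- random_disjoint(30, 20000)
  pr <- pair_unique_peaks(pk, pk)
  expect_equal(nrow(pr), 30)
  expect_true(all(pr$start_distance == 0 & pr$end_distance == 0))
  # overlapping peaks within one list are an error naming the pair
  bad <- GRanges("chr1", IRanges(c(1, 50), c(100, 150)))
  expect_error(pair_unique_peaks(bad, pk), "overlap within the input list")
  # drop mode prunes self-overlapping clusters instead of erroring
  bad2 <- c(bad, GRanges("chr1", IRanges(1000, 1100)))
  other <- GRanges("chr1", IRanges(c(10, 1010), c(90, 1090)))
  pr2 <- pair_unique_peaks(bad2, other, on_overlap = "drop")
  expect_equal(nrow(pr2), 1)
  expect_equal(pr2$parental_start, 1000)
})

test_that("pair_unique_peaks matches the O(n*m) oracle and is symmetric", {
  for (seed in 1:4) {
    set.seed(200 + seed)
    p <- random_disjoint(25, 20000)
    n <- shift(random_disjoint(25, 19000, min_w = 60, max_w = 350), 500)
    got <- pair_unique_peaks(p, n)
    want <- oracle_unique_pairs(p, n)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$parental_idx, want[, 1])
      expect_equal(got$nascent_idx, want[, 2])
      expect_equal(got$start_distance, want[, 3])
      expect_equal(got$end_distance, want[, 4])
    }
    # symmetry: swapping inputs preserves the distance multiset
    rev <- pair_unique_peaks(n, p)
    expect_equal(sort(c(rev$start_distance, rev$end_distance)),
                 sort(c(got$start_distance, got$end_distance)))
  }
})

test_that("displacement_summary aggregates per pair by default", {
  pairs <- data.frame(chrom = "chr1", parental_start = 1, parental_end = 2,
                      nascent_start = 1, nascent_end = 2,
                      start_distance = c(50, 0), end_distance = c(50, 100),
                      parental_idx = 1:2, nascent_idx = 1:2)
  class(pairs) <- c("PeakPairs", "data.frame")
  s <- displacement_summary(pairs)
  expect_equal(s$per_pair, c(50, 50))
  expect_equal(s$mean, 50)
  expect_equal(s$pooled_mean, 50)
  expect_equal(displacement_summary(pairs, "pooled")$mean, 50)
  expect_error(displacement_summary(pairs[0, ]), "at least one pair")
})

test_that("domain_borders emits oriented anchors and applies the 5 kb rule", {
  dom <- GRanges("chr1", IRanges(10001, 30000))       # [10000,30000) on disk
  repl <- GRanges("chr1", IRanges(1, 100000))         # [0,100000)
  a <- domain_borders(dom, repl)
  expect_length(a, 2)                                  # 10 kb and 70 kb away
  expect_equal(start(a) - 1, c(10000, 30000))
  expect_equal(as.character(strand(a)), c("+", "-"))   # interior right / left
  # an edge 3 kb from a replicated border is dropped
  dom2 <- GRanges("chr1", IRanges(3001, 30000))
  a2 <- domain_borders(dom2, repl)
  expect_length(a2, 1)
  expect_equal(mcols(a2)$side, "right")
  # empty replicated set errors
  expect_error(domain_borders(dom, GRanges()), "empty")
})
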