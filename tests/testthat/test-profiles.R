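# Anchor profiles, metagene resampling, heatmap scaling, Hilbert images.

test_that("anchor_profile extracts flanked rows with orientation", {
  # constant track: every column mean equals the constant
  tr <- make_track(rep(3, 400))
  anchors <- GRanges("chr1", IRanges(c(2001, 5001), width = 1), strand = "+")
  prof <- anchor_profile(tr, anchors, flank = 500)
  expect_equal(unname(prof$means), rep(3, 40))
  expect_equal(ncol(prof$matrix), 2 * 500 / 25)
  # step track: 0 left of position 5000 (0-based), 6 right
  v <- c(rep(0, 200), rep(6, 200))
  trs <- make_track(v)
  plus <- anchor_profile(trs, GRanges("chr1", IRanges(5001, width = 1), strand = "+"),
                         flank = 500)
  expect_equal(unname(plus$matrix[1, ]), c(rep(0, 20), rep(6, 20)))
  minus <- anchor_profile(trs, GRanges("chr1", IRanges(5001, width = 1), strand = "-"),
                          flank = 500)
  expect_equal(unname(minus$matrix[1, ]), c(rep(6, 20), rep(0, 20)))
  # anchors whose flank leaves the chromosome are dropped, not clipped
  both <- anchor_profile(trs, GRanges("chr1", IRanges(c(101, 5001), width = 1)),
                         flank = 500)
  expect_equal(nrow(both$matrix), 1)
  expect_equal(both$n_dropped, 1)
  expect_error(anchor_profile(trs, GRanges("chr1", IRanges(101, width = 1)),
                              flank = 500), "no anchor fits")
  expect_error(anchor_profile(trs, GRanges("chr1", IRanges(5001, width = 1)),
                              flank = 510), "multiple of the bin size")
})

test_that("anchor_profile matches a direct-extraction oracle", {
  for (seed in 1:3) {
    set.seed(300 + seed)
    v <- runif(2000)
    tr <- make_track(v)
    pos0 <- sort(sample(3000:46000, 100))
    minus <- sample(c(TRUE, FALSE), 100, replace = TRUE)
    anchors <- GRanges("chr1", IRanges(pos0 + 1, width = 1),
                       strand = ifelse(minus, "-", "+"))
    prof <- anchor_profile(tr, anchors, flank = 1000)
    want <- oracle_anchor_matrix(v, 25, pos0, minus, 1000)
    expect_equal(unname(prof$matrix), want)
  }
})

test_that("anchored_body_profile resamples bodies length-independently", {
  # constant body: ten pseudo-bins of the constant
  tr <- make_track(rep(2, 400))
  body <- GRanges("chr1", IRanges(1001, 2000), strand = "+")
  prof <- anchored_body_profile(tr, body, body_bins = 10, flank = 0)
  expect_equal(unname(prof$matrix[1, ]), rep(2, 10))
  # two ramps of different lengths resample to identical rows
  ramp_track <- function(nbins_body, start_bin, total_bins = 2000) {
    v <- numeric(total_bins)
    v[start_bin + seq_len(nbins_body)] <- (seq_len(nbins_body) - 0.5) / nbins_body
    make_track(v)
  }
  t1 <- ramp_track(40, 100)    # 1000 bp body
  t2 <- ramp_track(80, 100)    # 2000 bp body
  b1 <- GRanges("chr1", IRanges(100 * 25 + 1, width = 1000), strand = "+")
  b2 <- GRanges("chr1", IRanges(100 * 25 + 1, width = 2000), strand = "+")
  r1 <- anchored_body_profile(t1, b1, body_bins = 10, flank = 0)$matrix[1, ]
  r2 <- anchored_body_profile(t2, b2, body_bins = 10, flank = 0)$matrix[1, ]
  expect_equal(r1, r2, tolerance = 1e-6)
  # minus strand reverses the ramp
  b1m <- b1; strand(b1m) <- "-"
  rm <- anchored_body_profile(t1, b1m, body_bins = 10, flank = 0)$matrix[1, ]
  expect_equal(rm, rev(r1), tolerance = 1e-12)
  # resampling conserves the body mean for aligned piecewise-constant signal
  set.seed(4)
  v <- rep(runif(40), each = 1)
  tv <- make_track(c(numeric(100), v, numeric(260)))
  bb <- GRanges("chr1", IRanges(2501, width = 1000), strand = "+")
  row <- anchored_body_profile(tv, bb, body_bins = 20, flank = 0)$matrix[1, ]
  expect_equal(mean(row), mean(v), tolerance = 1e-6)
  # too-short bodies are dropped with a count
  short <- GRanges("chr1", IRanges(1001, 1005), strand = "+")
  expect_error(anchored_body_profile(tr, short, body_bins = 10), "no body usable")
  res <- anchored_body_profile(tr, c(body, short), body_bins = 10, flank = 0)
  expect_equal(res$n_dropped, 1)
})

test_that("heatmap_matrix scales to percent of max and is idempotent", {
  m <- matrix(c(2, 4, 8, 0), 2)
  s <- heatmap_matrix(m)
  expect_equal(max(s), 100)
  expect_equal(s[1, 1], 25)
  expect_equal(unname(heatmap_matrix(s)), unname(s))
  z <- heatmap_matrix(matrix(0, 2, 2))
  expect_true(attr(z, "zero_max"))
  expect_true(all(z == 0))
})

test_that("order-1 Hilbert traversal follows the documented convention", {
  h <- hilbert_map(c(1, 2, 3, 4), 1)
  # visit order (0,0), (0,1), (1,1), (1,0): first step along +y
  expect_equal(h$mapping$x, c(0, 0, 1, 1))
  expect_equal(h$mapping$y, c(0, 1, 1, 0))
  expect_equal(h$grid[1, 1], 1)
  expect_equal(h$grid[1, 2], 2)
  expect_equal(h$grid[2, 2], 3)
  expect_equal(h$grid[2, 1], 4)
})

test_that("Hilbert mapping is a bijection with adjacent consecutive cells", {
  for (k in 1:6) {
    xy <- hilbert_d2xy(k, 0:(4^k - 1))
    cell_id <- xy[, "x"] * 2^k + xy[, "y"]
    expect_equal(sort(cell_id), 0:(4^k - 1))          # bijectivity
    d <- abs(diff(xy[, "x"])) + abs(diff(xy[, "y"]))
    expect_true(all(d == 1))                          # 4-neighbour adjacency
  }
})

test_that("hilbert_map pools, pads and preserves locality", {
  # constant input -> constant image
  h <- hilbert_map(rep(5, 1000), 3)
  expect_true(all(h$grid == 5))
  # shorter than the grid: padded cells flagged and zero
  h2 <- hilbert_map(1:10, 2)
  expect_equal(sum(h2$padded), 6)
  expect_equal(sum(h2$grid), sum(1:10))
  # mean pooling: 2x the grid length with pairs (v, v) reproduces v
  k <- 3; n <- 4^k
  v <- runif(n)
  h3 <- hilbert_map(rep(v, each = 2), k)
  idx <- cbind(h3$mapping$x + 1, h3$mapping$y + 1)
  expect_equal(h3$grid[idx], v, tolerance = 1e-12)
  expect_error(hilbert_map(1:4, 0), "positive integer")
  # locality: mean grid distance grows from linear distance 1 to 4^(k-1)
  k <- 4
  xy <- hilbert_d2xy(k, 0:(4^k - 1))
  grid_dist <- function(d) {
    i <- seq_len(4^k - d)
    mean(abs(xy[i + d, "x"] - xy[i, "x"]) + abs(xy[i + d, "y"] - xy[i, "y"]))
  }
  expect_lt(grid_dist(1), grid_dist(4^(k - 1)))
})
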