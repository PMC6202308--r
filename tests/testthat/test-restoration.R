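# Time-course assembly and the restoration / loss classifiers.

test_that("assemble_timecourse sums bin values over grid-aligned windows", {
  lay <- genome_layout(c(chr1 = 2000), c(spk = 500))
  tr1 <- binned_track(list(chr1 = rep(1, 80)), 25, lay)
  tr2 <- binned_track(list(chr1 = rep(2, 80)), 25, lay)
  w <- GRanges("chr1", IRanges(1, 500))               # 20 bins of 25 bp
  tc <- assemble_timecourse(list(tr1, tr2), c("T0", "T12"), c(0, 12), w)
  expect_equal(unname(tc$values[1, ]), c(20, 40))
  # off-grid window errors
  w_off <- GRanges("chr1", IRanges(3, 502))
  expect_error(assemble_timecourse(list(tr1, tr2), c("T0", "T12"), c(0, 12), w_off),
               "bin grid")
  # hand-summed 3 windows x 2 timepoints fixture
  v <- seq_len(80)
  tr3 <- binned_track(list(chr1 = v), 25, lay)
  w3 <- GRanges("chr1", IRanges(c(1, 501, 1001), width = 500))
  tc3 <- assemble_timecourse(list(tr1, tr3), c("T0", "T12"), c(0, 12), w3)
  expect_equal(unname(tc3$values[, 2]),
               c(sum(v[1:20]), sum(v[21:40]), sum(v[41:60])))
  expect_error(timecourse(matrix(1, 1, 2), GRanges("chr1", IRanges(1, 10)),
                          c("T0", "T1"), c(1, 1)), "strictly increasing")
})

test_that("classify_restoration applies the earliest-reach rule", {
  tc <- make_tc(rbind(c(1, 2, 4, 4),      # ratios 4,2,1 -> R6
                      c(4, 4, 4, 4),      # ratios 1,1,1 -> R0
                      c(1, 3, 3, 3),      # ratios 3,1,1 -> R1
                      c(1, 1, 1, 4)))     # ratios 4,4,4 -> R12
  calls <- classify_restoration(tc)
  expect_equal(as.character(calls$category), c("R6", "R0", "R1", "R12"))
  expect_equal(calls$ratio_T0, c(4, 1, 3, 4))
})

test_that("classifier boundary handling: threshold fold counts as restored", {
  # final 3, earlier 2 -> ratio exactly 1.5
  tc <- make_tc(rbind(c(2, 3, 3, 3)))
  expect_equal(as.character(classify_restoration(tc)$category), "R0")
  expect_equal(as.character(classify_restoration(tc, boundary = "open")$category),
               "R1")
  # just above / just below threshold
  tc2 <- make_tc(rbind(c(1.99, 3, 3, 3), c(2.01, 3, 3, 3)))
  expect_equal(as.character(classify_restoration(tc2)$category), c("R1", "R0"))
})

test_that("zero levels give infinite ratios; zero final level is unclassifiable", {
  tc <- make_tc(rbind(c(0, 0, 2, 2),      # Inf, Inf, 1 -> R6
                      c(0, 0, 0, 0)))     # final 0 -> NA
  calls <- classify_restoration(tc)
  expect_equal(as.character(calls$category)[1], "R6")
  expect_true(is.na(calls$category[2]))
  expect_false(calls$classifiable[2])
  expect_equal(attr(calls, "n_unclassifiable"), 1L)
})

test_that("strict mode drops already-restored windows, permissive keeps them", {
  tc <- make_tc(rbind(c(4, 4, 4, 4), c(1, 4, 4, 4)))
  perm <- classify_restoration(tc)
  expect_equal(as.character(perm$category), c("R0", "R1"))
  strict <- classify_restoration(tc, strict = TRUE)
  expect_true(is.na(strict$category[1]))
  expect_equal(as.character(strict$category[2]), "R1")
  expect_equal(attr(strict, "n_strict_dropped"), 1L)
})

test_that("classification is monotone and scale invariant", {
  set.seed(31)
  for (i in 1:50) {
    lv <- cumsum(runif(4, 0.5, 2))               # increasing levels
    tc <- make_tc(rbind(lv))
    cat0 <- as.character(classify_restoration(tc)$category)
    # raising an earlier level can only move the category earlier or equal
    j <- sample(1:3, 1)
    lv2 <- lv; lv2[j] <- lv2[j] * runif(1, 1, 3)
    cat1 <- as.character(classify_restoration(make_tc(rbind(lv2)))$category)
    order_of <- function(x) match(x, c("R0", "R1", "R6", "R12"))
    expect_lte(order_of(cat1), order_of(cat0))
    # scaling all levels leaves the category unchanged
    catc <- as.character(classify_restoration(make_tc(rbind(lv * runif(1, 0.1, 10))))$category)
    expect_equal(catc, cat0)
  }
})

test_that("replicate_concordance keeps identical categories and reports retention", {
  tc1 <- make_tc(rbind(c(1, 2, 4, 4), c(1, 3, 3, 3), c(4, 4, 4, 4)))
  tc2 <- make_tc(rbind(c(1, 2, 4, 4), c(1, 1, 3, 3), c(4, 4, 4, 4)))
  c1 <- classify_restoration(tc1); c2 <- classify_restoration(tc2)
  conc <- replicate_concordance(c1, c2)
  expect_equal(nrow(conc), 2)                       # R6 and R0 agree, R1 vs R6 differ
  expect_equal(attr(conc, "retained_fraction"), 2 / 3)
  expect_true(all(conc$concordant))
  # identical inputs retain everything
  expect_equal(attr(replicate_concordance(c1, c1), "retained_fraction"), 1)
  # different window sets error
  c3 <- c1; c3$start <- c3$start + 1
  expect_error(replicate_concordance(c1, c3), "different windows")
})

test_that("classify_loss bins folds with closed boundaries and flags edge cases", {
  lv <- rbind(c(10, 9),     # fold 1.11 -> low
              c(10, 5),     # 2 -> moderate
              c(10, 2),     # 5 -> high
              c(15, 10),    # 1.5 -> moderate (closed)
              c(30, 10),    # 3 -> moderate (closed)
              c(10, 0),     # total loss -> high + flag
              c(0, 0))      # unclassifiable
  tc <- make_tc(lv, labels = c("T0", "T24"), hours = c(0, 24))
  calls <- classify_loss(tc)
  expect_equal(as.character(calls$category)[1:6],
               c("low", "moderate", "high", "moderate", "moderate", "high"))
  expect_true(calls$total_loss[6])
  expect_true(is.na(calls$category[7]))
  expect_equal(attr(calls, "n_unclassifiable"), 1L)
  # open boundaries push exact cuts to the outer categories
  open <- classify_loss(tc, boundary = "open")
  expect_equal(as.character(open$category)[4:5], c("low", "high"))
  expect_error(classify_loss(make_tc(rbind(c(1, 2, 3, 4)))), "exactly two")
})

test_that("classify_loss agrees with a scalar reclassification oracle", {
  set.seed(77)
  v0 <- round(c(runif(200, 0, 30), 0), 3)
  v1 <- round(c(runif(200, 0, 30), 0), 3)
  v1[sample(201, 10)] <- 0
  tc <- make_tc(cbind(v0, v1), labels = c("T0", "T24"), hours = c(0, 24))
  calls <- classify_loss(tc)
  want <- vapply(seq_along(v0), function(i) oracle_loss_category(v0[i], v1[i]),
                 character(1))
  expect_equal(as.character(calls$category), want)
})

test_that("category proportions partition classified windows", {
  tc <- make_tc(rbind(c(1, 3, 3, 3), c(1, 1, 3, 3), c(1, 3, 3, 3), c(1, 1, 3, 3)))
  p <- category_proportions(classify_restoration(tc))
  expect_equal(sum(p), 1)
  expect_equal(unname(p[c("R1", "R6")]), c(0.5, 0.5))
  single <- category_proportions(classify_restoration(make_tc(rbind(c(1, 3, 3, 3)))))
  expect_equal(unname(single["R1"]), 1)
})
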