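# The forward simulator: construction, determinism, conservation, caller.

small_cfg <- function(...) {
  sim_config(seed = 99, target_chroms = c(chrT1 = 200000),
             spikein_chroms = c(chrS1 = 50000),
             n_peaks = 20, n_domains = 2, domain_width = 10000,
             depth = 20000, spikein_reads = 5000, ...)
}

test_that("config validation catches inconsistent settings", {
  expect_error(sim_config(dilution = 0), "dilution")
  expect_error(sim_config(dilution = 1.2), "dilution")
  expect_error(sim_config(recycling_sigma = -1), "sigma")
  expect_error(sim_config(plateau_probs = c(T0 = 0.5, T1 = 0.4, T6 = 0.2, T12 = 0)),
               "sum to 1")
  expect_error(sim_config(timepoint_hours = c(0, 1, 1, 12)), "strictly increasing")
  expect_error(sim_config(loss_mode = TRUE), "exactly two")
  expect_silent(validate_sim_config(small_cfg()))
})

test_that("landscape places the requested non-overlapping features", {
  cfg <- sim_config(seed = 3, target_chroms = c(chrT1 = 1e6),
                    spikein_chroms = c(chrS1 = 1e5),
                    n_peaks = 10, peak_width = 1000, n_domains = 0)
  land <- simulate_landscape(cfg)
  pk <- land$features[mcols(land$features)$type == "peak"]
  expect_length(pk, 10)
  expect_equal(sum(width(pk)), 10000)
  expect_length(findOverlaps(land$features, drop.self = TRUE), 0)
  # replicated fraction 0.5 on 1 Mb -> ~500 kb within one region granularity
  cfg2 <- sim_config(seed = 3, target_chroms = c(chrT1 = 1e6),
                     spikein_chroms = c(chrS1 = 1e5),
                     replicated_fraction = 0.5, replicated_region_size = 50000)
  land2 <- simulate_landscape(cfg2)
  expect_lte(abs(sum(width(land2$replicated)) - 5e5), 50000)
  # infeasible packing errors
  expect_error(simulate_landscape(
    sim_config(target_chroms = c(chrT1 = 1e5), spikein_chroms = c(chrS1 = 1e4),
               n_peaks = 200, peak_width = 1000, n_domains = 0)),
    "infeasible packing")
})

test_that("same seed reproduces the simulation exactly", {
  cfg <- small_cfg()
  s1 <- simulate_timecourse(simulate_landscape(cfg), cfg)
  s2 <- simulate_timecourse(simulate_landscape(cfg), cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(as.data.frame(s1$libraries$rep1$T0$reads),
                   as.data.frame(s2$libraries$rep1$T0$reads))
  expect_identical(s1$library_table, s2$library_table)
})

test_that("library totals are Poisson-consistent with the configured depths", {
  cfg <- small_cfg(noise_cv = 0, replicates = 1)
  sim <- simulate_timecourse(simulate_landscape(cfg), cfg)
  t0 <- sim$library_table[sim$library_table$label == "T0", ]
  expect_lt(abs(t0$target - cfg$depth), 5 * sqrt(cfg$depth))
  expect_lt(abs(t0$spikein - cfg$spikein_reads), 5 * sqrt(cfg$spikein_reads))
  # and against the model's own expectations at every timepoint
  expect_true(all(abs(sim$library_table$target - sim$library_table$expected_target)
                  < 5 * sqrt(sim$library_table$expected_target)))
  expect_true(all(abs(sim$library_table$spikein - sim$library_table$expected_spikein)
                  < 5 * sqrt(sim$library_table$expected_spikein)))
})

test_that("every feature has exactly one truth record with its category", {
  cfg <- small_cfg()
  sim <- simulate_timecourse(simulate_landscape(cfg), cfg)
  expect_equal(nrow(sim$truth), cfg$n_peaks + cfg$n_domains)
  expect_equal(anyDuplicated(sim$truth$feature_id), 0)
  expect_true(all(sim$truth$category %in% c("R0", "R1", "R6", "R12")))
  expect_length(sim$nascent_peaks, nrow(sim$truth))
})

test_that("loss mode freezes levels and assigns fold categories", {
  cfg <- small_cfg(loss_mode = TRUE, timepoint_labels = c("T0", "T24"),
                   timepoint_hours = c(0, 24), replicates = 1,
                   loss_probs = c(low = 0.5, moderate = 0.3, high = 0.2))
  sim <- simulate_timecourse(simulate_landscape(cfg), cfg)
  expect_true(all(sim$truth$category %in% c("low", "moderate", "high")))
  expect_equal(unname(sim$truth$loss_fold[sim$truth$category == "moderate"][1]), 2)
  # low-loss regions have expected T0/T24 RRPM ratio = their fold (~1.1)
  expect_true(all(is.na(sim$truth$plateau_hours)))
})

test_that("sigma = 0 leaves nascent features at their parental position", {
  cfg <- small_cfg(recycling_sigma = 0)
  sim <- simulate_timecourse(simulate_landscape(cfg), cfg)
  expect_true(all(sim$truth$delta_bp == 0))
  expect_equal(start(sim$nascent_peaks), start(sim$landscape$features))
  pk_idx <- sim$truth$type == "peak"
  pr <- pair_unique_peaks(sim$landscape$features[pk_idx],
                          sim$nascent_peaks[pk_idx])
  expect_equal(displacement_summary(pr)$mean, 0)
})

test_that("naive_domain_caller finds threshold runs with single-bin gap merging", {
  tr <- make_track(c(0, 0, 5, 5, 5, 0))
  dom <- naive_domain_caller(tr, threshold = 1, min_width = 50)
  expect_length(dom, 1)
  expect_equal(start(dom) - 1, 50)
  expect_equal(end(dom), 125)
  # all-background and above-max thresholds give nothing
  expect_length(naive_domain_caller(make_track(rep(0, 10)), 1, 50), 0)
  expect_length(naive_domain_caller(tr, threshold = 10, min_width = 50), 0)
  # a one-bin gap is bridged, a two-bin gap is not
  tr2 <- make_track(c(2, 2, 0, 2, 2, 0, 0, 2, 2))
  dom2 <- naive_domain_caller(tr2, 1, 50)
  expect_length(dom2, 2)
  expect_equal(width(dom2), c(125, 50))
})

test_that("written simulations expose every pipeline input as plain text", {
  cfg <- small_cfg(replicates = 1)
  sim <- simulate_timecourse(simulate_landscape(cfg), cfg)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  expect_true(file.exists(file.path(dir, "reads", "rep1_T0.bed")))
  expect_true(file.exists(file.path(dir, "parental_peaks.narrowPeak")))
  expect_true(file.exists(file.path(dir, "replicated.broadPeak")))
  expect_true(file.exists(file.path(dir, "config.yaml")))
  cfg2 <- read_sim_config(file.path(dir, "config.yaml"))
  expect_equal(cfg2$depth, cfg$depth)
  expect_equal(cfg2$plateau_probs, cfg$plateau_probs)
  lay <- genome_layout(read_chrom_sizes(file.path(dir, "chrom_sizes_target.txt")),
                       read_chrom_sizes(file.path(dir, "chrom_sizes_spikein.txt")))
  reads <- read_bed(file.path(dir, "reads", "rep1_T0.bed"), lay)
  expect_equal(length(reads),
               sim$libraries$rep1$T0$counts$target_unique_reads +
                 sim$libraries$rep1$T0$counts$spikein_unique_reads)
})
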