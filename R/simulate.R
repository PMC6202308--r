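# Forward simulator of chromatin replication and its measurement by
# spike-in ChOR-seq. The model, in brief:
#
#   * a parental landscape of narrow promoter-like peaks and broad
#     repressive domains over a uniform background;
#   * replication of a subset of the genome (replicated regions); only
#     replicated DNA is captured, so reads are emitted from replicated
#     intervals only;
#   * at T0 (nascent chromatin) the modified signal comes from recycled
#     parental histones: level = dilution * parental (old and new histones
#     mix ~1:1, new histones carry no tri-methylation), re-deposited with a
#     positional displacement drawn per feature from N(0, sigma);
#   * each feature is assigned a plateau timepoint; at and after it the
#     level steps to the full parental level (de novo modification within
#     the pre-existing regions, no widening);
#   * an inhibitor ("loss") mode instead freezes levels at the nascent
#     value and applies a per-feature T0/T_late fold loss;
#   * the library is sequenced to a constant total depth; reads are
#     allocated between target chromatin and the constant exogenous
#     spike-in chromatin in proportion to their mass, which is the physical
#     premise that makes spike-in (RRPM) normalization quantitative;
#   * per-feature counts are Poisson around their expectation, optionally
#     with extra multiplicative lognormal noise.

#' Simulation configuration
#'
#' All knobs of the chromatin-replication simulator, validated. Defaults
#' describe the emulated study conditions: a 1 Mb two-chromosome target
#' genome plus one spike-in chromosome, promoter-like 1 kb peaks and 30 kb
#' broad domains, 70% of the genome replicated, 1:1 dilution by unmodified
#' new histones, a 100 bp recycling displacement, a T0/T1/T6/T12 time
#' course with equal plateau-category probabilities, two replicates,
#' Poisson counting with 10% extra multiplicative noise, and 400k target /
#' 50k spike-in expected reads per nascent library.
#'
#' @param seed integer seed; all randomness of the simulator derives from
#'   it (landscape uses `seed`, time course `seed + 1`).
#' @param target_chroms,spikein_chroms named bp lengths.
#' @param n_peaks,peak_width,peak_level narrow-peak count, width (bp) and
#'   parental modification density (arbitrary mass units per bp).
#' @param n_domains,domain_width,domain_level same for broad domains.
#' @param background_level unmodified-background density (same units);
#'   non-zero so zero/low-signal edge cases occur at realistic rates.
#' @param replicated_fraction fraction of each chromosome replicated
#'   during the labeling pulse.
#' @param replicated_region_size size of individual replicated regions
#'   (bp).
#' @param dilution fraction of the parental level retained on nascent
#'   chromatin (0.5 = 1:1 old:new histone mixing), in (0, 1].
#' @param recycling_sigma sd (bp) of the per-feature re-deposition
#'   displacement; 0 disables displacement.
#' @param timepoint_labels,timepoint_hours the chase time course.
#' @param plateau_probs named probabilities (over the labels) that a
#'   feature plateaus at each timepoint; default equal.
#' @param loss_mode simulate the inhibitor experiment instead: levels are
#'   frozen at the nascent value and per-feature fold losses applied.
#' @param loss_probs,loss_folds category probabilities and target T0/late
#'   folds for loss mode.
#' @param depth expected target-genome reads in the nascent (T0) library.
#' @param spikein_reads expected spike-in reads in the nascent library.
#' @param replicates number of independent replicates.
#' @param noise_cv extra multiplicative lognormal noise (coefficient of
#'   variation) per feature, timepoint and replicate; 0 disables.
#' @param read_length,fragment_length emitted read length and the
#'   fragment size reads should be extended to downstream.
#' @return An object of class `SimulationConfig`.
#' @export
sim_config <- function(seed = 1L,
                       target_chroms = c(chrT1 = 600000, chrT2 = 400000),
                       spikein_chroms = c(chrS1 = 200000),
                       n_peaks = 300, peak_width = 1000, peak_level = 20,
                       n_domains = 8, domain_width = 30000, domain_level = 3,
                       background_level = 0.05,
                       replicated_fraction = 0.7,
                       replicated_region_size = 50000,
                       dilution = 0.5, recycling_sigma = 100,
                       timepoint_labels = c("T0", "T1", "T6", "T12"),
                       timepoint_hours = c(0, 1, 6, 12),
                       plateau_probs = NULL,
                       loss_mode = FALSE,
                       loss_probs = c(low = 0.95, moderate = 0.035, high = 0.015),
                       loss_folds = c(low = 1.1, moderate = 2, high = 4),
                       depth = 400000, spikein_reads = 50000,
                       replicates = 2, noise_cv = 0.10,
                       read_length = 50, fragment_length = 250) {
  if (is.null(plateau_probs))
    plateau_probs <- setNames(rep(1 / length(timepoint_labels),
                                  length(timepoint_labels)), timepoint_labels)
  cfg <- list(seed = as.integer(seed),
              target_chroms = target_chroms, spikein_chroms = spikein_chroms,
              n_peaks = n_peaks, peak_width = peak_width, peak_level = peak_level,
              n_domains = n_domains, domain_width = domain_width,
              domain_level = domain_level,
              background_level = background_level,
              replicated_fraction = replicated_fraction,
              replicated_region_size = replicated_region_size,
              dilution = dilution, recycling_sigma = recycling_sigma,
              timepoint_labels = timepoint_labels,
              timepoint_hours = as.numeric(timepoint_hours),
              plateau_probs = plateau_probs,
              loss_mode = isTRUE(loss_mode),
              loss_probs = loss_probs, loss_folds = loss_folds,
              depth = depth, spikein_reads = spikein_reads,
              replicates = as.integer(replicates), noise_cv = noise_cv,
              read_length = read_length, fragment_length = fragment_length)
  class(cfg) <- "SimulationConfig"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param cfg a `SimulationConfig`.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  .validate_chrom_lengths(cfg$target_chroms, "target")
  .validate_chrom_lengths(cfg$spikein_chroms, "spike-in")
  if (length(cfg$spikein_chroms) == 0 && cfg$spikein_reads > 0)
    stop("spike-in reads requested but no spike-in chromosomes configured")
  if (cfg$dilution <= 0 || cfg$dilution > 1) stop("dilution must lie in (0, 1]")
  if (cfg$recycling_sigma < 0) stop("recycling_sigma must be >= 0")
  if (cfg$depth <= 0 || cfg$spikein_reads < 0) stop("depths must be positive")
  if (cfg$replicates < 1) stop("need at least one replicate")
  if (cfg$noise_cv < 0) stop("noise_cv must be >= 0")
  if (cfg$replicated_fraction <= 0 || cfg$replicated_fraction > 1)
    stop("replicated_fraction must lie in (0, 1]")
  if (length(cfg$timepoint_labels) != length(cfg$timepoint_hours))
    stop("timepoint labels and hours must be parallel")
  if (any(diff(cfg$timepoint_hours) <= 0))
    stop("timepoint hours must be strictly increasing")
  if (cfg$loss_mode) {
    if (length(cfg$timepoint_labels) != 2)
      stop("loss mode uses exactly two timepoints (nascent and late)")
    if (abs(sum(cfg$loss_probs) - 1) > 1e-8) stop("loss_probs must sum to 1")
    if (!identical(sort(names(cfg$loss_probs)), sort(names(cfg$loss_folds))))
      stop("loss_probs and loss_folds must share category names")
    if (any(cfg$loss_folds < 1)) stop("loss folds must be >= 1")
  } else {
    if (!identical(sort(names(cfg$plateau_probs)), sort(cfg$timepoint_labels)))
      stop("plateau_probs must be named by the timepoint labels")
    if (abs(sum(cfg$plateau_probs) - 1) > 1e-8) stop("plateau_probs must sum to 1")
  }
  if (cfg$n_peaks < 0 || cfg$n_domains < 0 || cfg$n_peaks + cfg$n_domains < 1)
    stop("need at least one feature")
  if (cfg$fragment_length < cfg$read_length)
    stop("fragment_length must be >= read_length")
  cfg
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat(sprintf(paste0("SimulationConfig: %d peaks + %d domains on %d bp, ",
                     "%.0f%% replicated, dilution %.2f, sigma %g bp, %s mode, ",
                     "%d replicate(s), seed %d\n"),
              x$n_peaks, x$n_domains, sum(x$target_chroms),
              100 * x$replicated_fraction, x$dilution, x$recycling_sigma,
              if (x$loss_mode) "loss" else "restoration",
              x$replicates, x$seed))
  invisible(x)
}

#' Read / write a simulation configuration as YAML
#' @param path YAML file path.
#' @export
read_sim_config <- function(path) {
  lst <- yaml::read_yaml(path)
  for (f in c("target_chroms", "spikein_chroms", "plateau_probs",
              "loss_probs", "loss_folds"))
    if (!is.null(lst[[f]])) lst[[f]] <- unlist(lst[[f]])
  do.call(sim_config, lst)
}

#' @rdname read_sim_config
#' @param cfg a [sim_config()].
#' @export
write_sim_config <- function(cfg, path) {
  lst <- unclass(cfg)
  for (f in c("target_chroms", "spikein_chroms", "plateau_probs",
              "loss_probs", "loss_folds"))
    lst[[f]] <- as.list(lst[[f]])
  yaml::write_yaml(lst, path)
  invisible(path)
}

# Place features of the given widths without overlap, uniformly at random:
# widths are dealt to chromosomes proportionally to length (largest
# remainder), then within each chromosome the free space is split into
# random gaps (uniform simplex), giving sorted non-overlapping starts.
.place_features <- function(widths, chrom_lengths) {
  n <- length(widths)
  if (!n) return(GRanges())
  share <- n * chrom_lengths / sum(chrom_lengths)
  count <- floor(share)
  rem <- n - sum(count)
  if (rem > 0) {
    extra <- order(share - count, decreasing = TRUE)[seq_len(rem)]
    count[extra] <- count[extra] + 1
  }
  assign <- sample(rep(names(chrom_lengths), count))
  out <- vector("list", length(chrom_lengths))
  names(out) <- names(chrom_lengths)
  pos <- split(seq_len(n), factor(assign, levels = names(chrom_lengths)))
  for (ch in names(chrom_lengths)) {
    idx <- pos[[ch]]
    if (!length(idx)) { out[[ch]] <- NULL; next }
    w <- widths[idx]
    free <- chrom_lengths[[ch]] - sum(w)
    if (free < 0)
      stop("infeasible packing: requested feature mass exceeds chromosome ", ch)
    g <- runif(length(w) + 1)
    g <- g / sum(g) * free
    starts0 <- cumsum(g)[seq_along(w)] + c(0, cumsum(w))[seq_along(w)]
    out[[ch]] <- GRanges(ch, IRanges(floor(starts0) + 1, width = w),
                         feature = idx)
  }
  gr <- unlist(GRangesList(out[!vapply(out, is.null, logical(1))]),
               use.names = FALSE)
  gr[order(mcols(gr)$feature)]
}

# non-overlapping regions covering ~fraction of each chromosome
.place_replicated <- function(chrom_lengths, fraction, region_size) {
  out <- list()
  for (ch in names(chrom_lengths)) {
    L <- chrom_lengths[[ch]]
    target_bp <- fraction * L
    nreg <- floor(target_bp / region_size)
    w <- rep(region_size, nreg)
    remainder <- target_bp - nreg * region_size
    if (remainder >= 1000) w <- c(w, floor(remainder))
    if (!length(w)) next
    free <- L - sum(w)
    g <- runif(length(w) + 1)
    g <- g / sum(g) * free
    starts0 <- cumsum(g)[seq_along(w)] + c(0, cumsum(w))[seq_along(w)]
    out[[ch]] <- GRanges(ch, IRanges(floor(starts0) + 1, width = w))
  }
  if (!length(out)) stop("no replicated regions could be placed")
  sort(unlist(GRangesList(out), use.names = FALSE))
}

#' Simulate the parental chromatin landscape
#'
#' Places non-overlapping narrow peaks and broad domains uniformly at
#' random over the target genome, places replicated regions covering the
#' configured fraction, and derives the per-base parental modification
#' density (feature level inside features, background outside).
#'
#' @param cfg a [sim_config()].
#' @return An object of class `ChorLandscape`: `layout`, `features`
#'   (GRanges with `type`, `level`, `feature_id`), `replicated` (GRanges
#'   with a simulated MACS-style `qValue`, stored as -log10), `density`
#'   (an [IRanges::RleList] over target chromosomes) and `config`.
#' @export
simulate_landscape <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  layout <- genome_layout(cfg$target_chroms, cfg$spikein_chroms)
  total_mass <- cfg$n_peaks * cfg$peak_width + cfg$n_domains * cfg$domain_width
  if (total_mass > sum(cfg$target_chroms))
    stop("infeasible packing: requested feature mass (", total_mass,
         " bp) exceeds the target genome")
  widths <- c(rep(cfg$peak_width, cfg$n_peaks), rep(cfg$domain_width, cfg$n_domains))
  type <- c(rep("peak", cfg$n_peaks), rep("domain", cfg$n_domains))
  level <- c(rep(cfg$peak_level, cfg$n_peaks), rep(cfg$domain_level, cfg$n_domains))
  ord <- sample(length(widths))          # interleave peaks and domains
  placed <- .place_features(widths[ord], cfg$target_chroms)
  feats <- placed[order(mcols(placed)$feature)]
  # undo the shuffle so feature i keeps its identity (type, level)
  feats <- feats[order(ord[mcols(feats)$feature])]
  mcols(feats)$feature <- NULL
  mcols(feats)$type <- type
  mcols(feats)$level <- level
  mcols(feats)$feature_id <- seq_along(feats)
  feats <- .set_seqinfo(feats, layout_seqinfo(layout, "target"))

  replicated <- .place_replicated(cfg$target_chroms, cfg$replicated_fraction,
                                  cfg$replicated_region_size)
  mcols(replicated)$name <- sprintf("rep_%04d", seq_along(replicated))
  mcols(replicated)$qValue <- round(runif(length(replicated), 5, 50), 3)  # -log10(q)
  replicated <- .set_seqinfo(replicated, layout_seqinfo(layout, "target"))

  density <- coverage(feats, weight = mcols(feats)$level) + cfg$background_level
  structure(list(layout = layout, features = feats, replicated = replicated,
                 density = density, config = cfg),
            class = "ChorLandscape")
}

# expected modified level (mass per bp) of each feature at time t_hr
.level_at <- function(cfg, parental, plateau_hr, loss_fold, t_hr, t_index) {
  if (cfg$loss_mode) {
    nascent <- cfg$dilution * parental
    if (t_index == 1) nascent else nascent / loss_fold
  } else {
    parental * (cfg$dilution + (1 - cfg$dilution) * (t_hr >= plateau_hr))
  }
}

# rebuild a GRanges under a full Seqinfo (possibly adding absent levels)
.set_seqinfo <- function(gr, si) {
  out <- GRanges(as.character(seqnames(gr)), ranges(gr),
                 strand = strand(gr), seqinfo = si)
  mcols(out) <- mcols(gr)
  out
}

# turn 0-based fragment centers into read GRanges (single-end convention:
# the read covers the first/last read_length bp of the fragment)
.reads_from_centers <- function(centers, chrom, chrom_len, read_length,
                                fragment_length) {
  n <- length(centers)
  if (!n) return(GRanges())
  st <- sample(c("+", "-"), n, replace = TRUE)
  s0 <- ifelse(st == "+", round(centers - fragment_length / 2),
               round(centers + fragment_length / 2) - read_length)
  s0 <- pmax(0, pmin(s0, chrom_len - read_length))
  GRanges(chrom, IRanges(s0 + 1, width = read_length), strand = st)
}

#' Simulate a spike-in ChOR-seq time course
#'
#' Emits, for every replicate and timepoint, a single-end read set over
#' target plus spike-in chromosomes, the realized library totals, the
#' ground-truth table, and the displaced nascent feature set. See the
#' model sketch in `?sim_config` and the package vignette.
#'
#' @param landscape a [simulate_landscape()] result.
#' @param cfg configuration; defaults to the landscape's own.
#' @return An object of class `ChorSimulation` with elements `config`,
#'   `landscape`, `truth` (per-feature data.frame), `nascent_peaks`
#'   (features shifted by their recycling displacement), `libraries`
#'   (nested list `[[replicate]][[label]]` of `reads` + `counts` +
#'   `expected`) and `library_table` (realized vs expected totals).
#' @export
simulate_timecourse <- function(landscape, cfg = landscape$config) {
  stopifnot(inherits(landscape, "ChorLandscape"))
  validate_sim_config(cfg)
  set.seed(cfg$seed + 1L)
  feats <- landscape$features
  nf <- length(feats)
  labels <- cfg$timepoint_labels
  hours <- cfg$timepoint_hours
  parental <- mcols(feats)$level

  if (cfg$loss_mode) {
    loss_cat <- sample(names(cfg$loss_probs), nf, replace = TRUE,
                       prob = cfg$loss_probs)
    loss_fold <- unname(cfg$loss_folds[loss_cat])
    plateau_lab <- rep(NA_character_, nf)
    plateau_hr <- rep(NA_real_, nf)
  } else {
    plateau_lab <- sample(labels, nf, replace = TRUE,
                          prob = cfg$plateau_probs[labels])
    plateau_hr <- hours[match(plateau_lab, labels)]
    loss_cat <- rep(NA_character_, nf)
    loss_fold <- rep(NA_real_, nf)
  }
  delta <- if (cfg$recycling_sigma > 0)
    round(rnorm(nf, 0, cfg$recycling_sigma)) else rep(0, nf)

  # replicated part of each feature: the only DNA the assay captures
  hits <- findOverlaps(feats, landscape$replicated, ignore.strand = TRUE)
  pieces <- pintersect(granges(feats)[queryHits(hits)],
                       granges(landscape$replicated)[subjectHits(hits)])
  piece_feat <- queryHits(hits)
  rep_bp <- rep(0, nf)
  if (length(hits)) {
    bp <- rowsum(width(pieces), piece_feat)
    rep_bp[as.integer(rownames(bp))] <- bp[, 1]
  }
  repl_union <- reduce(granges(landscape$replicated))
  repl_total_bp <- sum(width(repl_union))

  # spike-in chromatin mass, calibrated so the nascent library splits
  # depth : spikein_reads between target and spike-in
  lv0 <- vapply(seq_len(nf), function(i)
    .level_at(cfg, parental[i], plateau_hr[i], loss_fold[i], hours[1], 1L),
    numeric(1))
  M0 <- sum(lv0 * rep_bp) + cfg$background_level * repl_total_bp
  S <- if (cfg$spikein_reads > 0) cfg$spikein_reads / cfg$depth * M0 else 0
  N_exp <- cfg$depth + cfg$spikein_reads
  sl <- if (cfg$noise_cv > 0) sqrt(log(1 + cfg$noise_cv^2)) else 0

  spike_lens <- cfg$spikein_chroms
  lens <- cfg$target_chroms
  libraries <- vector("list", cfg$replicates)
  names(libraries) <- paste0("rep", seq_len(cfg$replicates))
  lib_rows <- list()

  for (r in seq_len(cfg$replicates)) {
    libraries[[r]] <- vector("list", length(labels))
    names(libraries[[r]]) <- labels
    for (ti in seq_along(labels)) {
      lv <- vapply(seq_len(nf), function(i)
        .level_at(cfg, parental[i], plateau_hr[i], loss_fold[i], hours[ti], ti),
        numeric(1))
      noise <- if (sl > 0) rlnorm(nf, -sl^2 / 2, sl) else rep(1, nf)
      fmass <- lv * rep_bp * noise
      bgmass <- cfg$background_level * repl_total_bp
      M <- sum(fmass) + bgmass
      e_feat <- N_exp * fmass / (M + S)
      e_bg <- N_exp * bgmass / (M + S)
      e_sp <- N_exp * S / (M + S)

      # recycled (displaced) fraction of the modified signal at this time
      p_rec <- if (cfg$loss_mode) rep(1, nf) else
        cfg$dilution / (cfg$dilution + (1 - cfg$dilution) * (hours[ti] >= plateau_hr))

      piece_mass <- (lv * noise)[piece_feat] * width(pieces)
      n_piece <- rpois(length(pieces), N_exp * piece_mass / (M + S))
      fidx <- rep(piece_feat, n_piece)
      centers <- rep(start(pieces) - 1, n_piece) +
        runif(sum(n_piece)) * rep(width(pieces), n_piece)
      rec <- runif(length(centers)) < p_rec[fidx]
      centers <- centers + rec * delta[fidx]
      chrom_f <- rep(as.character(seqnames(pieces)), n_piece)

      n_bg <- rpois(1, e_bg)
      bg_pick <- sample.int(length(repl_union), n_bg, replace = TRUE,
                            prob = width(repl_union))
      bg_centers <- start(repl_union)[bg_pick] - 1 +
        runif(n_bg) * width(repl_union)[bg_pick]
      bg_chrom <- as.character(seqnames(repl_union))[bg_pick]

      all_centers <- c(centers, bg_centers)
      all_chrom <- c(chrom_f, bg_chrom)
      target_reads <- GRanges()
      if (length(all_centers)) {
        grl <- lapply(names(lens), function(ch) {
          i <- all_chrom == ch
          .reads_from_centers(all_centers[i], ch, lens[[ch]],
                              cfg$read_length, cfg$fragment_length)
        })
        target_reads <- unlist(GRangesList(grl[lengths(grl) > 0]),
                               use.names = FALSE)
      }

      spike_reads <- GRanges()
      n_sp <- 0L
      if (S > 0) {
        n_sp <- rpois(1, e_sp)
        sp_chrom <- sample(names(spike_lens), n_sp, replace = TRUE,
                           prob = spike_lens)
        grl <- lapply(names(spike_lens), function(ch) {
          n_ch <- sum(sp_chrom == ch)
          if (!n_ch) return(GRanges())
          s0 <- floor(runif(n_ch) * (spike_lens[[ch]] - cfg$read_length))
          GRanges(ch, IRanges(s0 + 1, width = cfg$read_length),
                  strand = sample(c("+", "-"), n_ch, replace = TRUE))
        })
        spike_reads <- unlist(GRangesList(grl[lengths(grl) > 0]),
                              use.names = FALSE)
      }

      reads <- suppressWarnings(c(target_reads, spike_reads))
      counts <- library_counts(length(target_reads), length(spike_reads))
      libraries[[r]][[labels[ti]]] <-
        list(reads = reads, counts = counts,
             expected = c(target = sum(e_feat) + e_bg, spikein = e_sp))
      lib_rows[[length(lib_rows) + 1]] <-
        data.frame(replicate = names(libraries)[r], label = labels[ti],
                   target = length(target_reads), spikein = length(spike_reads),
                   expected_target = sum(e_feat) + e_bg, expected_spikein = e_sp)
    }
  }

  truth <- data.frame(feature_id = mcols(feats)$feature_id,
                      type = mcols(feats)$type,
                      chrom = as.character(seqnames(feats)),
                      start = start(feats), end = end(feats),
                      parental_level = parental,
                      replicated_bp = rep_bp,
                      frac_replicated = rep_bp / width(feats),
                      category = if (cfg$loss_mode) loss_cat else
                        .category_label(plateau_lab),
                      plateau_hours = plateau_hr,
                      loss_fold = loss_fold,
                      delta_bp = delta,
                      sigma = cfg$recycling_sigma,
                      stringsAsFactors = FALSE)

  nascent <- suppressWarnings(trim(shift(feats, delta)))
  structure(list(config = cfg, landscape = landscape, truth = truth,
                 nascent_peaks = nascent, libraries = libraries,
                 library_table = do.call(rbind, lib_rows),
                 spike_mass = S),
            class = "ChorSimulation")
}

#' @export
print.ChorSimulation <- function(x, ...) {
  cat(sprintf("ChorSimulation: %d features, %d replicate(s) x %d timepoint(s), seed %d\n",
              nrow(x$truth), x$config$replicates,
              length(x$config$timepoint_labels), x$config$seed))
  invisible(x)
}

#' Naive threshold-and-merge domain caller
#'
#' Fixture-grade caller for synthetic tracks: maximal runs of bins with
#' value >= `threshold`, merged across gaps of at most one bin, kept when
#' at least `min_width` bp wide. Not a peak-calling method — a stand-in
#' for consuming externally called peak files in tests and demos.
#'
#' @param track a [binned_track()].
#' @param threshold minimum bin value (must be > 0).
#' @param min_width minimum domain width in bp.
#' @return GRanges of called domains.
#' @export
naive_domain_caller <- function(track, threshold, min_width) {
  stopifnot(inherits(track, "BinnedTrack"))
  if (threshold <= 0) stop("threshold must be > 0")
  bs <- track$bin_size
  out <- list()
  for (ch in names(track$values)) {
    v <- track$values[[ch]] >= threshold
    if (!any(v)) next
    # merge gaps of exactly one bin between two above-threshold runs
    r <- rle(v)
    gap1 <- which(!r$values & r$lengths == 1)
    gap1 <- gap1[gap1 > 1 & gap1 < length(r$values)]
    if (length(gap1)) {
      ends <- cumsum(r$lengths)
      v[ends[gap1]] <- TRUE
      r <- rle(v)
    }
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- which(r$values)
    if (!length(runs)) next
    s0 <- (starts[runs] - 1) * bs
    e <- pmin(ends[runs] * bs, track$chrom_lengths[[ch]])
    keep <- (e - s0) >= min_width
    if (any(keep))
      out[[ch]] <- GRanges(ch, IRanges(s0[keep] + 1, e[keep]))
  }
  if (!length(out)) return(GRanges())
  sort(unlist(GRangesList(out), use.names = FALSE))
}

#' Write a simulation to disk as plain-text files
#'
#' Emits everything the file-based pipeline stages consume: per-library
#' read BEDs, the parental peak (narrowPeak) and domain (broadPeak) calls,
#' replicated regions (broadPeak with simulated q-values), the truth
#' nascent peak BED, chrom-sizes files, the truth and library tables
#' (TSV), and the configuration echoed as YAML.
#'
#' @param sim a [simulate_timecourse()] result.
#' @param dir output directory (created).
#' @return Invisibly, the directory.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "ChorSimulation"))
  dir.create(file.path(dir, "reads"), recursive = TRUE, showWarnings = FALSE)
  land <- sim$landscape
  cfg <- sim$config
  for (r in names(sim$libraries))
    for (lab in names(sim$libraries[[r]]))
      write_bed(sim$libraries[[r]][[lab]]$reads,
                file.path(dir, "reads", paste0(r, "_", lab, ".bed")))
  fwrite(sim$library_table, file.path(dir, "library_table.tsv"), sep = "\t")

  feats <- land$features
  peaks <- feats[mcols(feats)$type == "peak"]
  doms <- feats[mcols(feats)$type == "domain"]
  pk <- granges(peaks)
  mcols(pk)$name <- sprintf("peak_%04d", seq_along(pk))
  mcols(pk)$signalValue <- mcols(peaks)$level
  mcols(pk)$summit <- floor(width(pk) / 2)
  write_peaks(pk, file.path(dir, "parental_peaks.narrowPeak"), "narrowPeak")
  dm <- granges(doms)
  mcols(dm)$name <- sprintf("domain_%04d", seq_along(dm))
  mcols(dm)$signalValue <- mcols(doms)$level
  write_peaks(dm, file.path(dir, "parental_domains.broadPeak"), "broadPeak")
  write_peaks(land$replicated, file.path(dir, "replicated.broadPeak"), "broadPeak")

  nasc <- sim$nascent_peaks[mcols(sim$nascent_peaks)$type == "peak"]
  np <- granges(nasc)
  mcols(np)$name <- sprintf("nascent_%04d", seq_along(np))
  write_bed(np, file.path(dir, "nascent_peaks.bed"))

  write_chrom_sizes(cfg$target_chroms, file.path(dir, "chrom_sizes_target.txt"))
  write_chrom_sizes(cfg$spikein_chroms, file.path(dir, "chrom_sizes_spikein.txt"))
  fwrite(sim$truth, file.path(dir, "truth.tsv"), sep = "\t")
  write_sim_config(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
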