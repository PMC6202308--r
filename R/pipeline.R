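# File-based orchestration of the analysis stages. Each stage_*() function
# reads its inputs from, and writes its outputs to, a run directory, so the
# `all` pipeline is literally the composition of the individual stages and
# a command-line wrapper can expose them as subcommands.

.lib_ids <- function(cfg) {
  expand.grid(replicate = paste0("rep", seq_len(cfg$replicates)),
              label = cfg$timepoint_labels, stringsAsFactors = FALSE)
}

.layout_from_dir <- function(dir) {
  genome_layout(read_chrom_sizes(file.path(dir, "chrom_sizes_target.txt")),
                read_chrom_sizes(file.path(dir, "chrom_sizes_spikein.txt")))
}

#' Pipeline stages
#'
#' File-based stages of the analysis pipeline over a run directory `dir`:
#'
#' * `stage_simulate()` — forward-simulate a time course and write reads,
#'   features, replicated regions, truth and the config echo.
#' * `stage_bin()` — extend reads to the fragment length, count them in
#'   `bin_size` bp bins, write raw bedGraphs with sidecar metadata and the
#'   measured library totals.
#' * `stage_normalize()` — write RPM and RRPM bedGraphs for every library.
#' * `stage_windows()` — tile parental peaks into `window_size` bp windows
#'   and keep those overlapping the (q-filtered) replicated regions.
#' * `stage_classify()` — per-replicate window time courses from the RRPM
#'   tracks, restoration (or loss) classification, replicate concordance,
#'   category proportions and total-signal final/T0 ratios.
#' * `stage_distance()` — pair parental with nascent peaks and summarize
#'   the per-end displacement distances.
#' * `stage_profile()` — oriented domain-border anchors (>= 5 kb from
#'   replicated-region edges) and the anchor-centred RRPM profile.
#' * `stage_hilbert()` — Hilbert-curve image of the final RRPM track on
#'   the first target chromosome.
#'
#' [run_pipeline()] composes all stages and writes the run manifest.
#'
#' @param cfg a [sim_config()].
#' @param dir run directory.
#' @name pipeline-stages
NULL

#' @rdname pipeline-stages
#' @export
stage_simulate <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_timecourse(simulate_landscape(cfg), cfg)
  write_simulation(sim, dir)
  invisible(sim)
}

#' @rdname pipeline-stages
#' @param bin_size track bin width in bp (default 25).
#' @export
stage_bin <- function(dir, bin_size = 25) {
  cfg <- read_sim_config(file.path(dir, "config.yaml"))
  layout <- .layout_from_dir(dir)
  dir.create(file.path(dir, "tracks"), showWarnings = FALSE)
  ids <- .lib_ids(cfg)
  counts <- list()
  for (i in seq_len(nrow(ids))) {
    lib <- paste0(ids$replicate[i], "_", ids$label[i])
    reads <- read_bed(file.path(dir, "reads", paste0(lib, ".bed")), layout)
    ext <- extend_reads(reads, cfg$fragment_length, layout)
    track <- bin_counts(ext, bin_size, layout,
                        mark = "sim", time = ids$label[i])
    write_bedgraph(track, file.path(dir, "tracks", paste0("raw_", lib, ".bedGraph")))
    write_track_metadata(track, file.path(dir, "tracks", paste0("raw_", lib, ".meta")))
    tot <- read_totals(track)
    counts[[i]] <- data.frame(library = lib, replicate = ids$replicate[i],
                              label = ids$label[i],
                              target = tot$target_unique_reads,
                              spikein = tot$spikein_unique_reads)
  }
  fwrite(do.call(rbind, counts), file.path(dir, "tracks", "library_counts.tsv"),
         sep = "\t")
  invisible(dir)
}

.read_lib_counts <- function(dir) {
  dt <- fread(file.path(dir, "tracks", "library_counts.tsv"))
  setNames(lapply(seq_len(nrow(dt)), function(i)
    library_counts(dt$target[i], dt$spikein[i])), dt$library)
}

#' @rdname pipeline-stages
#' @export
stage_normalize <- function(dir) {
  cfg <- read_sim_config(file.path(dir, "config.yaml"))
  layout <- .layout_from_dir(dir)
  meta <- read_track_metadata(list.files(file.path(dir, "tracks"),
                                         pattern = "^raw_.*\\.meta$",
                                         full.names = TRUE)[1])
  bin_size <- as.integer(meta[["bin_size"]])
  libs <- .read_lib_counts(dir)
  for (lib in names(libs)) {
    raw <- read_bedgraph(file.path(dir, "tracks", paste0("raw_", lib, ".bedGraph")),
                         layout, bin_size)
    for (norm in c("rpm", "rrpm")) {
      tr <- if (norm == "rpm") rpm(raw, libs[[lib]]) else rrpm(raw, libs[[lib]])
      write_bedgraph(tr, file.path(dir, "tracks", paste0(norm, "_", lib, ".bedGraph")))
      write_track_metadata(tr, file.path(dir, "tracks", paste0(norm, "_", lib, ".meta")))
    }
  }
  invisible(dir)
}

#' @rdname pipeline-stages
#' @param window_size analysis window width in bp (default 500).
#' @param q_cutoff,q_direction replicated-region q-value filter (see
#'   [filter_by_qvalue()]; the stored column is -log10).
#' @export
stage_windows <- function(dir, window_size = 500, q_cutoff = 0.05,
                          q_direction = "le") {
  layout <- .layout_from_dir(dir)
  peaks <- read_peaks(file.path(dir, "parental_peaks.narrowPeak"),
                      "narrowPeak", layout)
  repl <- read_peaks(file.path(dir, "replicated.broadPeak"), "broadPeak", layout)
  repl <- filter_by_qvalue(repl, q_cutoff, q_direction, neglog10 = TRUE)
  # snap the tiling origin of each peak down to the track bin grid so the
  # window sums over bins are exact (windows act as genomic fixed-grid bins)
  meta_files <- list.files(file.path(dir, "tracks"), pattern = "^raw_.*\\.meta$",
                           full.names = TRUE)
  if (length(meta_files)) {
    bs <- as.integer(read_track_metadata(meta_files[1])[["bin_size"]])
    start(peaks) <- ((start(peaks) - 1) %/% bs) * bs + 1
  }
  windows <- filter_by_overlap(tile_peaks(peaks, window_size), repl)
  out <- granges(windows)
  mcols(out)$name <- sprintf("p%04d.w%02d", mcols(windows)$source_peak,
                             ave(mcols(windows)$source_peak,
                                 mcols(windows)$source_peak, FUN = seq_along))
  mcols(out)$score <- mcols(windows)$source_peak
  write_bed(out, file.path(dir, "windows.bed"))
  invisible(windows)
}

.assemble_from_files <- function(dir, cfg, layout, rep_id, windows,
                                 norm = "rrpm") {
  meta <- read_track_metadata(list.files(file.path(dir, "tracks"),
                                         pattern = "^raw_.*\\.meta$",
                                         full.names = TRUE)[1])
  bin_size <- as.integer(meta[["bin_size"]])
  tracks <- lapply(cfg$timepoint_labels, function(lab)
    read_bedgraph(file.path(dir, "tracks",
                            paste0(norm, "_", rep_id, "_", lab, ".bedGraph")),
                  layout, bin_size, normalization = toupper(norm)))
  assemble_timecourse(tracks, cfg$timepoint_labels, cfg$timepoint_hours,
                      windows, replicate = rep_id)
}

#' @rdname pipeline-stages
#' @param fold_threshold,strict restoration classifier settings (see
#'   [classify_restoration()]).
#' @export
stage_classify <- function(dir, fold_threshold = 1.5, strict = FALSE) {
  cfg <- read_sim_config(file.path(dir, "config.yaml"))
  layout <- .layout_from_dir(dir)
  windows <- read_bed(file.path(dir, "windows.bed"), layout)
  dir.create(file.path(dir, "classify"), showWarnings = FALSE)
  reps <- paste0("rep", seq_len(cfg$replicates))
  calls <- list()
  ratio_rows <- list()
  for (r in reps) {
    tc <- .assemble_from_files(dir, cfg, layout, r, windows, "rrpm")
    calls[[r]] <- if (cfg$loss_mode) classify_loss(tc) else
      classify_restoration(tc, fold_threshold, strict = strict)
    fwrite(as.data.table(calls[[r]]),
           file.path(dir, "classify", paste0(r, "_calls.tsv")), sep = "\t")
    # total-signal final/first ratios under both normalizations
    tc_rpm <- .assemble_from_files(dir, cfg, layout, r, windows, "rpm")
    Tn <- ncol(tc$values)
    ratio_rows[[r]] <- data.frame(
      replicate = r,
      rrpm_final_over_t0 = sum(tc$values[, Tn]) / sum(tc$values[, 1]),
      rpm_final_over_t0 = sum(tc_rpm$values[, Tn]) / sum(tc_rpm$values[, 1]))
  }
  if (length(calls) >= 2) {
    conc <- replicate_concordance(calls[[1]], calls[[2]])
    fwrite(as.data.table(conc), file.path(dir, "classify", "concordant_calls.tsv"),
           sep = "\t")
    props <- category_proportions(conc)
    summary <- data.frame(
      n_windows = nrow(calls[[1]]),
      n_compared = attr(conc, "n_compared"),
      n_concordant = nrow(conc),
      retained_fraction = attr(conc, "retained_fraction"),
      n_unclassifiable_rep1 = attr(calls[[1]], "n_unclassifiable"))
  } else {
    conc <- calls[[1]]
    props <- category_proportions(conc)
    summary <- data.frame(n_windows = nrow(conc),
                          n_compared = NA, n_concordant = NA,
                          retained_fraction = NA,
                          n_unclassifiable_rep1 = attr(conc, "n_unclassifiable"))
  }
  fwrite(data.table(category = names(props), proportion = as.numeric(props)),
         file.path(dir, "classify", "proportions.tsv"), sep = "\t")
  fwrite(summary, file.path(dir, "classify", "summary.tsv"), sep = "\t")
  fwrite(do.call(rbind, ratio_rows), file.path(dir, "classify", "signal_ratios.tsv"),
         sep = "\t")
  invisible(list(calls = calls, concordant = conc, proportions = props,
                 ratios = do.call(rbind, ratio_rows), summary = summary))
}

#' @rdname pipeline-stages
#' @export
stage_distance <- function(dir) {
  layout <- .layout_from_dir(dir)
  parental <- read_peaks(file.path(dir, "parental_peaks.narrowPeak"),
                         "narrowPeak", layout)
  nascent <- read_bed(file.path(dir, "nascent_peaks.bed"), layout)
  pairs <- pair_unique_peaks(parental, nascent, on_overlap = "drop")
  dir.create(file.path(dir, "displacement"), showWarnings = FALSE)
  fwrite(as.data.table(unclass(pairs)), file.path(dir, "displacement", "pairs.tsv"),
         sep = "\t")
  s <- displacement_summary(pairs)
  fwrite(data.table(statistic = c("n_pairs", "per_pair_mean", "per_pair_median",
                                  "pooled_mean", "start_mean", "end_mean"),
                    value = c(s$n, s$per_pair_mean, s$median, s$pooled_mean,
                              s$start_mean, s$end_mean)),
         file.path(dir, "displacement", "summary.tsv"), sep = "\t")
  invisible(s)
}

#' @rdname pipeline-stages
#' @param flank profile half-window in bp (default 2000).
#' @param border_min_distance minimum anchor distance from replicated-region
#'   edges (default 5000).
#' @export
stage_profile <- function(dir, flank = 2000, border_min_distance = 5000) {
  cfg <- read_sim_config(file.path(dir, "config.yaml"))
  layout <- .layout_from_dir(dir)
  domains <- read_peaks(file.path(dir, "parental_domains.broadPeak"),
                        "broadPeak", layout)
  repl <- read_peaks(file.path(dir, "replicated.broadPeak"), "broadPeak", layout)
  anchors <- domain_borders(domains, repl, border_min_distance)
  dir.create(file.path(dir, "profile"), showWarnings = FALSE)
  write_bed(anchors, file.path(dir, "profile", "border_anchors.bed"))
  meta <- read_track_metadata(list.files(file.path(dir, "tracks"),
                                         pattern = "^raw_.*\\.meta$",
                                         full.names = TRUE)[1])
  track <- read_bedgraph(file.path(dir, "tracks",
                                   paste0("rrpm_rep1_", cfg$timepoint_labels[1],
                                          ".bedGraph")),
                         layout, as.integer(meta[["bin_size"]]),
                         normalization = "RRPM")
  prof <- anchor_profile(track, anchors, flank)
  m <- prof$matrix
  fwrite(data.table(position = prof$positions, mean_signal = prof$means),
         file.path(dir, "profile", "border_profile.tsv"), sep = "\t")
  fwrite(as.data.table(m), file.path(dir, "profile", "border_matrix.tsv"),
         sep = "\t")
  invisible(prof)
}

#' @rdname pipeline-stages
#' @param hilbert_order Hilbert-curve order (default 5).
#' @param write_png also render the image as PNG.
#' @export
stage_hilbert <- function(dir, hilbert_order = 5, write_png = FALSE) {
  cfg <- read_sim_config(file.path(dir, "config.yaml"))
  layout <- .layout_from_dir(dir)
  meta <- read_track_metadata(list.files(file.path(dir, "tracks"),
                                         pattern = "^raw_.*\\.meta$",
                                         full.names = TRUE)[1])
  final_lab <- tail(cfg$timepoint_labels, 1)
  track <- read_bedgraph(file.path(dir, "tracks",
                                   paste0("rrpm_rep1_", final_lab, ".bedGraph")),
                         layout, as.integer(meta[["bin_size"]]),
                         normalization = "RRPM")
  hm <- hilbert_map(track_values(track, names(layout$target)[1]), hilbert_order)
  dir.create(file.path(dir, "hilbert"), showWarnings = FALSE)
  fwrite(as.data.table(hm$grid), file.path(dir, "hilbert", "grid.tsv"), sep = "\t")
  if (write_png) {
    png(file.path(dir, "hilbert", "image.png"), 512, 512)
    plot(hm)
    dev.off()
  }
  invisible(hm)
}

#' Write the run manifest
#'
#' JSON record of what was run: subcommand(s), seed, tool version, config
#' digest, input-file digests and a timestamp. Exactly one manifest per
#' run directory.
#'
#' @param dir run directory.
#' @param subcommand character vector of executed stage names.
#' @param seed the run seed.
#' @export
write_manifest <- function(dir, subcommand, seed) {
  cfg_path <- file.path(dir, "config.yaml")
  inputs <- c(cfg_path,
              list.files(file.path(dir, "reads"), full.names = TRUE))
  inputs <- inputs[file.exists(inputs)]
  digests <- md5sum(inputs)
  manifest <- list(tool = "chortools",
                   version = as.character(packageVersion("chortools")),
                   subcommand = subcommand,
                   seed = seed,
                   config_md5 = unname(md5sum(cfg_path)),
                   input_digests = as.list(setNames(unname(digests),
                                                    basename(names(digests)))),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Run the full analysis pipeline on simulated data
#'
#' Composes all stages: simulate, bin, normalize, windows, classify,
#' distance, profile, hilbert, and writes the run manifest. Re-running
#' with the same configuration and seed reproduces byte-identical numeric
#' outputs (the manifest timestamp is the only thing that differs).
#'
#' @param cfg a [sim_config()].
#' @param dir output directory.
#' @param bin_size,window_size,fold_threshold,strict,q_direction,flank,hilbert_order,write_png
#'   stage parameters, see [pipeline-stages].
#' @param seed optional override of `cfg$seed`.
#' @return Invisibly, a list with the classification results, displacement
#'   summary and signal ratios.
#' @export
run_pipeline <- function(cfg = sim_config(), dir,
                         bin_size = 25, window_size = 500,
                         fold_threshold = 1.5, strict = FALSE,
                         q_direction = "le", flank = 2000,
                         hilbert_order = 5, write_png = FALSE,
                         seed = NULL) {
  if (!is.null(seed)) { cfg$seed <- as.integer(seed); cfg <- validate_sim_config(cfg) }
  stage_simulate(cfg, dir)
  stage_bin(dir, bin_size = bin_size)
  stage_normalize(dir)
  stage_windows(dir, window_size = window_size, q_direction = q_direction)
  cls <- stage_classify(dir, fold_threshold = fold_threshold, strict = strict)
  disp <- if (!cfg$loss_mode) stage_distance(dir) else NULL
  prof <- tryCatch(stage_profile(dir, flank = flank), error = function(e) NULL)
  hil <- stage_hilbert(dir, hilbert_order = hilbert_order, write_png = write_png)
  write_manifest(dir, c("simulate", "bin", "normalize", "windows", "classify",
                        if (!cfg$loss_mode) "distance", "profile", "hilbert"),
                 cfg$seed)
  invisible(list(dir = dir, classification = cls, displacement = disp,
                 profile = prof, hilbert = hil))
}
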