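#' Pipeline configuration
#'
#' All tunables default to the study's stated values where one exists:
#' segmentation penalty gamma = 40, calling thresholds +/- 0.3, dLRs cap
#' 0.35, focal retention q < 0.25, broad retention q < 0.3, significance
#' q < 0.1. Every other default is a package design choice documented in the
#' methods vignette.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param genome_params list passed to [generate_genome()].
#' @param design a [cohort_design()].
#' @param noise_sd,outlier_rate,outlier_sd array rendering noise model.
#' @param max_dlrs array QC cap (strict `>` discards); `allowlist` of sample
#'   ids survives it.
#' @param winsor_k MAD winsorization width.
#' @param gamma,normalize segmentation penalty and noise normalization.
#' @param gain_thr,loss_thr calling thresholds.
#' @param n_perm recurrence permutations.
#' @param focal_q,broad_q recurrence retention cutoffs.
#' @param di_tol DNA-index tolerance for the diploid call.
#' @param q_threshold association significance cutoff.
#' @param plan association plan; NULL for [default_association_plan()].
#' @param allowlist QC manual-override sample ids.
#' @param out_dir optional output directory; when set, all stage tables and
#'   the JSON run report are written there.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 11,
                            genome_params = list(n_chromosomes = 8,
                                                 arm_bands = 4,
                                                 band_len = 3e6,
                                                 probe_spacing = 1e5),
                            design = cohort_design(n_patients = 40),
                            noise_sd = 0.15, outlier_rate = 0.01,
                            outlier_sd = 1,
                            max_dlrs = 0.35, winsor_k = 2.5,
                            gamma = 40, normalize = TRUE,
                            gain_thr = 0.3, loss_thr = -0.3,
                            n_perm = 500, focal_q = 0.25, broad_q = 0.3,
                            di_tol = 0.05, q_threshold = 0.1,
                            plan = NULL, allowlist = character(),
                            out_dir = NULL) {
  cfg <- as.list(environment())
  stopifnot(cfg$seed == round(cfg$seed), cfg$n_perm >= 100)
  structure(cfg, class = "pipeline_config")
}

#' Run the full synthetic-cohort pipeline
#'
#' Executes simulate -> render -> QC -> winsorize -> segment -> call ->
#' classify -> recurrence -> aggregate -> associate, collecting per-stage
#' record counts in a run report. Rerunning with an identical configuration
#' (including seed) reproduces every output byte-for-byte.
#'
#' @param config A [pipeline_config()].
#' @return list of class `run_report` with elements `genome`, `grid`,
#'   `cohort`, `profiles` (kept), `discarded`, `segments`, `called`,
#'   `events`, `recurrent`, `units`, `presence`, `associations`, `counts`,
#'   `params`, `wall_clock`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  gp <- config$genome_params
  gp$seed <- config$seed
  gg <- do.call(generate_genome, gp)
  cohort <- generate_cohort(gg$genome, config$design, seed = config$seed + 1)

  profiles <- lapply(seq_along(cohort$samples), function(i)
    render_array(cohort$samples[[i]], gg$grid, noise_sd = config$noise_sd,
                 outlier_rate = config$outlier_rate,
                 outlier_sd = config$outlier_sd,
                 seed = config$seed + 1000 + i))
  qc <- qc_filter(profiles, max_dlrs = config$max_dlrs,
                  allowlist = config$allowlist)
  kept_ids <- vapply(qc$kept, function(p) p$sample, character(1))

  segments <- if (length(qc$kept)) {
    do.call(rbind, lapply(qc$kept, function(p)
      segment_pcf(winsorize(p, k = config$winsor_k), gamma = config$gamma,
                  normalize = config$normalize)))
  } else NULL

  meta <- cohort$metadata[cohort$metadata$biopsy_id %in% kept_ids, ,
                          drop = FALSE]
  if (!is.null(segments) && nrow(meta) >= 2) {
    called <- call_segments(segments, config$gain_thr, config$loss_thr)
    events <- classify_events(called, gg$genome)
    markers <- amplitude_matrices(segments, gg$grid, gg$genome)
    recurrent <- recurrent_cnas(events, markers, gg$genome,
                                n_perm = config$n_perm,
                                seed = config$seed + 2,
                                gain_thr = config$gain_thr,
                                loss_thr = config$loss_thr,
                                focal_q = config$focal_q,
                                broad_q = config$broad_q)
    retained <- recurrent[recurrent$retained, , drop = FALSE]
    units <- build_units(meta, di_tol = config$di_tol)
    presence <- unit_cna_presence(units, events, retained, meta)
    units <- total_scores(units, events, meta)
    associations <- run_association_suite(units, presence, plan = config$plan,
                                          q_threshold = config$q_threshold)
  } else {
    called <- empty_called()
    events <- empty_events()
    recurrent <- retained <- NULL
    units <- if (nrow(meta)) {
      total_scores(build_units(meta, di_tol = config$di_tol), events, meta)
    } else NULL
    presence <- NULL
    associations <- NULL
  }

  report <- structure(list(
    genome = gg$genome, grid = gg$grid, cohort = cohort,
    profiles = qc$kept, discarded = qc$discarded,
    segments = segments, called = called, events = events,
    recurrent = recurrent, units = units, presence = presence,
    associations = associations,
    counts = list(
      biopsies = nrow(cohort$metadata),
      arrays_kept = length(qc$kept),
      arrays_discarded = length(qc$discarded),
      segments = if (is.null(segments)) 0L else nrow(segments),
      called_regions = nrow(called),
      events = nrow(events),
      recurrent_tested = if (is.null(recurrent)) 0L else nrow(recurrent),
      recurrent_retained = if (is.null(retained)) 0L else nrow(retained),
      units = if (is.null(units)) 0L else nrow(units),
      associations = if (is.null(associations)) 0L else nrow(associations)),
    params = config[setdiff(names(config), c("design", "plan"))],
    wall_clock = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "run_report")
  if (!is.null(config$out_dir)) write_run_outputs(report, config$out_dir)
  report
}

empty_called <- function() {
  data.frame(sample = character(), chrom = character(), start = numeric(),
             end = numeric(), n_probes = integer(), mean = numeric(),
             state = character(), stringsAsFactors = FALSE)
}

#' @export
print.run_report <- function(x, ...) {
  cat("oralcna run report\n")
  for (nm in names(x$counts)) cat(sprintf("  %-20s %d\n", nm, x$counts[[nm]]))
  cat(sprintf("  wall clock: %.1f s\n", x$wall_clock))
  invisible(x)
}

# Deterministic on-disk snapshot of a run; the JSON report deliberately
# excludes wall-clock time so reruns are byte-identical.
write_run_outputs <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_cytobands(report$genome, p("cytobands.tsv"))
  write_probe_grid(report$grid, p("probes.tsv"))
  write_metadata(report$cohort$metadata, p("metadata.tsv"))
  if (!is.null(report$segments)) write_seg(report$segments, p("segments.seg"))
  if (nrow(report$events))
    utils::write.table(report$events, p("events.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(report$recurrent))
    utils::write.table(report$recurrent, p("recurrent_cnas.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(report$units))
    utils::write.table(report$units, p("units.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(report$presence))
    utils::write.table(data.frame(unit_id = rownames(report$presence),
                                  report$presence, check.names = FALSE),
                       p("presence.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(report$associations))
    utils::write.table(report$associations, p("associations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  pars <- report$params[setdiff(names(report$params), "out_dir")]
  rep_json <- list(counts = report$counts,
                   params = pars[!vapply(pars, is.null, logical(1))])
  jsonlite::write_json(rep_json, p("run_report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(report)
}
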