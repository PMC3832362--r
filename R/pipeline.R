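# End-to-end pipeline: simulate -> featurize -> gate -> score -> kinetics
# -> report.

#' Build a full-run configuration
#'
#' One nested configuration holding every tunable of the pipeline with its
#' default; round-trips losslessly through JSON.
#'
#' @param seed master seed for the whole run.
#' @param imaging imaging-cytometry block: events per trial, trials per
#'   group, crescent-enriched vs control class fractions, gate spillover.
#' @param kinetics video block: cells per trial, trials per group, the
#'   kinetic model per group, analysis interval and detection threshold.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       imaging = list(
                         n_events = 300L, n_trials_control = 3L,
                         n_trials_treated = 3L, n_events_reference = 600L,
                         treated_sickle_scale = 0.65, spillover = 0.10),
                       kinetics = list(
                         n_cells = 144L, n_trials = 2L,
                         control = list(susceptible_fraction = 0.54,
                                        delay_min = 4.3,
                                        hazard_per_min = 0.165),
                         treated = list(susceptible_fraction = 0.455,
                                        delay_min = 4.3,
                                        hazard_per_min = 0.131),
                         duration_min = 30, fps = 4,
                         interval_frames = 256L,
                         change_threshold = 0.25)) {
  structure(list(seed = as.integer(seed), imaging = imaging,
                 kinetics = kinetics,
                 version = as.character(utils::packageVersion("sicklemetry"))),
            class = "run_config")
}

# Class fractions of a treated (sickling-reduced) induced trial: crescent
# and spiculated fractions scaled down, the difference returned to discs.
scaled_sickle_fractions <- function(scale) {
  f <- default_class_fractions("induced")
  moved <- (f[["crescent"]] + f[["spiculated"]]) * (1 - scale)
  f[["crescent"]] <- f[["crescent"]] * scale
  f[["spiculated"]] <- f[["spiculated"]] * scale
  f[["disc"]] <- f[["disc"]] + moved
  f
}

# Simulate and featurize one imaging trial; returns the feature table with
# ground truth columns bound on.
imaging_trial_features <- function(n_events, fractions, seed) {
  pop <- sample_population(population_config(
    n_events, class_fractions = fractions, seed = seed))
  fx <- featurize_events(pop$events)
  cbind(fx, pop$truth[, c("class", "marker_positive", "mature_crbc")])
}

#' Run the full analysis pipeline
#'
#' Simulates imaging-cytometry trials for a control and a treated group plus
#' an uninduced reference, featurizes all events, calibrates and applies the
#' gating chain, calibrates the sickle gate at the configured spillover on
#' the uninduced reference, computes per-trial percent-sickled endpoints
#' with a Student's t comparison, then runs the video-kinetics arm (sparse
#' rendering, IoU-change detection, endpoint summaries,
#' Gehan-Breslow-Wilcoxon and rank-sum tests). All artifacts are written
#' under `out_dir` when given; reruns with the same configuration are
#' bit-identical apart from timestamps.
#'
#' @param config a [run_config()].
#' @param out_dir optional artifact directory.
#' @return a `run_report` list: imaging endpoints (per-trial percents,
#'   group means +/- SD, t test, gate counts, spillover check), kinetics
#'   endpoints per group (percent sickled, median time, delay, max rate)
#'   with group tests, the configuration echo, package version and seed.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  im <- config$imaging
  kin <- config$kinetics
  log_stage <- function(...) message("[sicklemetry] ", ...)

  ## ---- imaging arm ----
  log_stage("simulating imaging trials")
  ctrl_frac <- default_class_fractions("induced")
  trt_frac <- scaled_sickle_fractions(im$treated_sickle_scale)
  ref_frac <- default_class_fractions("uninduced")
  trials <- list()
  for (i in seq_len(im$n_trials_control))
    trials[[paste0("control_", i)]] <- imaging_trial_features(
      im$n_events, ctrl_frac, derive_seed(config$seed, i, salt = 100))
  for (i in seq_len(im$n_trials_treated))
    trials[[paste0("treated_", i)]] <- imaging_trial_features(
      im$n_events, trt_frac, derive_seed(config$seed, i, salt = 200))
  reference <- imaging_trial_features(
    im$n_events_reference, ref_frac, derive_seed(config$seed, 0, salt = 300))

  log_stage("calibrating and applying gates")
  gcfg <- calibrate_gates(reference)
  gate_counts <- lapply(trials, function(tr) apply_gates(tr, gcfg)$counts)
  gated <- lapply(trials, function(tr) {
    gr <- apply_gates(tr, gcfg)
    tr[tr$event_id %in% gr$final_ids, ]
  })
  ref_gated <- {
    gr <- apply_gates(reference, gcfg)
    reference[reference$event_id %in% gr$final_ids, ]
  }

  log_stage("calibrating sickle gate and scoring")
  sgate <- calibrate_sickle_gate(sickle_score(ref_gated),
                                 spillover = im$spillover)
  ref_spill <- percent_sickled(sickle_score(ref_gated), sgate)
  pct <- vapply(gated, function(tr)
    percent_sickled(sickle_score(tr), sgate), numeric(1))
  is_ctrl <- grepl("^control_", names(pct))
  imaging_test <- compare_groups_t(pct[is_ctrl], pct[!is_ctrl])

  ## ---- kinetics arm ----
  log_stage("running kinetics trials")
  kin_group <- function(pars, salt) {
    lapply(seq_len(kin$n_trials), function(i) {
      cfg <- kinetics_config(kin$n_cells, pars$susceptible_fraction,
                             delay_min = pars$delay_min,
                             hazard_per_min = pars$hazard_per_min,
                             duration_min = kin$duration_min, fps = kin$fps,
                             seed = derive_seed(config$seed, i, salt = salt))
      run_kinetics_trial(cfg, interval_frames = kin$interval_frames,
                         change_threshold = kin$change_threshold)
    })
  }
  ctrl_kin <- kin_group(kin$control, 400)
  trt_kin <- kin_group(kin$treated, 500)
  pool <- function(gr) do.call(rbind, lapply(gr, `[[`, "timelines"))
  ctrl_pool <- pool(ctrl_kin)
  trt_pool <- pool(trt_kin)
  isec <- attr(ctrl_kin[[1]]$timelines, "interval_sec")
  kin_summary <- function(tl) unclass(kinetics_summary(tl, interval_sec = isec))
  gbw <- gehan_breslow_wilcoxon(ctrl_pool, trt_pool)
  wil <- wilcoxon_times(ctrl_pool$time_min[!ctrl_pool$censored],
                        trt_pool$time_min[!trt_pool$censored])

  report <- structure(list(
    seed = config$seed,
    version = as.character(utils::packageVersion("sicklemetry")),
    config = config,
    imaging = list(
      gate_config = unclass(gcfg),
      gate_counts = gate_counts,
      reference_spillover = ref_spill,
      sickle_gate = unclass(sgate),
      percent_positive = as.list(pct),
      group_test = imaging_test),
    kinetics = list(
      control = kin_summary(ctrl_pool),
      treated = kin_summary(trt_pool),
      per_trial_control = lapply(ctrl_kin, function(x) unclass(x$summary)),
      per_trial_treated = lapply(trt_kin, function(x) unclass(x$summary)),
      gbw_test = gbw,
      wilcoxon_times = wil)),
    class = "run_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
    jsonlite::write_json(strip(unclass(report)),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    write_gating_config(gcfg, file.path(out_dir, "gating_config.json"))
    utils::write.csv(do.call(rbind, lapply(names(gated), function(nm)
      cbind(trial = nm, gated[[nm]]))),
      file.path(out_dir, "gated_features.csv"), row.names = FALSE)
    utils::write.csv(rbind(cbind(group = "control", ctrl_pool),
                           cbind(group = "treated", trt_pool)),
                     file.path(out_dir, "timelines.csv"), row.names = FALSE)
    crv <- rbind(cbind(group = "control", cumulative_curve(ctrl_pool)),
                 cbind(group = "treated", cumulative_curve(trt_pool)))
    utils::write.csv(crv, file.path(out_dir, "cumulative_curves.csv"),
                     row.names = FALSE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("sicklemetry run (seed ", x$seed, ")\n", sep = "")
  pp <- unlist(x$imaging$percent_positive)
  is_ctrl <- grepl("^control_", names(pp))
  cat(sprintf("  imaging: control %.1f%% +/- %.1f, treated %.1f%% +/- %.1f (t p=%.3g)\n",
              100 * mean(pp[is_ctrl]), 100 * stats::sd(pp[is_ctrl]),
              100 * mean(pp[!is_ctrl]), 100 * stats::sd(pp[!is_ctrl]),
              x$imaging$group_test$p.value))
  ck <- x$kinetics$control; tk <- x$kinetics$treated
  cat(sprintf("  kinetics: control %.1f%% sickled, median %.2f min; treated %.1f%%, median %.2f min\n",
              100 * ck$pct_sickled, ck$median_time_min,
              100 * tk$pct_sickled, tk$median_time_min))
  cat(sprintf("  GBW p=%.3g, rank-sum p=%.3g\n",
              x$kinetics$gbw_test$p.value, x$kinetics$wilcoxon_times$p.value))
  invisible(x)
}
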