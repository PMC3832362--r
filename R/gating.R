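# Sequential gating chain isolating single, in-focus, enucleated,
# marker-positive mature red-cell events.

GATE_ORDER <- c("non_nucleated", "non_debris", "mid_focus", "marker_positive")

#' Calibrate the gating chain from a reference population
#'
#' Thresholds, in chain order: DNA content split at the
#' between-class-variance maximum of the integrated DNA intensity (falling
#' back to the 99.5th percentile, with a warning flag, when the distribution
#' is not convincingly bimodal); an area window at the 2.5th-97.5th
#' percentiles of the non-nucleated population; a one-sided focus bound; and
#' a marker split at the between-class-variance maximum of the mean in-mask
#' marker intensity (mean rather than integrated intensity, so positivity is
#' not confounded with object size).
#'
#' The default focus bound is the robust lower fence
#' `Q1 - 1.5 * IQR` of the focus score, which removes a separated
#' out-of-focus cluster while retaining essentially all of the in-focus
#' bulk; `focus_rule = "quantile"` instead places the bound at the 25th
#' percentile (discarding a fixed quarter of events regardless of how many
#' are actually defocused).
#'
#' @param features feature table of a reference population (>= 200 rows)
#'   with DNA, area, focus and marker columns.
#' @param focus_rule `"fence"` (default) or `"quantile"`.
#' @param focus_upper optional upper focus bound (default `Inf`).
#' @param dna_col,marker_col feature columns carrying DNA content and
#'   marker staining level.
#' @return a `gating_config`: thresholds, gate order, and flags.
#' @export
calibrate_gates <- function(features, focus_rule = c("fence", "quantile"),
                            focus_upper = Inf, dna_col = "dna_integrated",
                            marker_col = "cd235_mean") {
  focus_rule <- match.arg(focus_rule)
  need <- c(dna_col, "area_um2", "focus_score", marker_col)
  miss <- setdiff(need, colnames(features))
  if (length(miss)) stop("missing feature column: ", paste(miss, collapse = ", "))
  if (nrow(features) < 200)
    stop("need at least 200 reference events (got ", nrow(features), ")")
  dna <- features[[dna_col]][is.finite(features[[dna_col]])]
  sp <- otsu_split(dna)
  dna_fallback <- sp$strength < 0.5
  dna_threshold <- if (dna_fallback)
    unname(stats::quantile(dna, 0.995, type = 7)) else sp$threshold
  non_nuc <- features[is.finite(features[[dna_col]]) &
                        features[[dna_col]] <= dna_threshold, ]
  area <- non_nuc$area_um2[is.finite(non_nuc$area_um2)]
  area_range <- unname(stats::quantile(area, c(0.025, 0.975), type = 7))
  foc <- features$focus_score[is.finite(features$focus_score)]
  qs <- unname(stats::quantile(foc, c(0.25, 0.75), type = 7))
  focus_lower <- if (focus_rule == "fence")
    qs[1] - 1.5 * (qs[2] - qs[1]) else qs[1]
  mk <- features[[marker_col]][is.finite(features[[marker_col]])]
  mk_sp <- otsu_split(mk)
  marker_fallback <- mk_sp$strength < 0.5
  marker_threshold <- if (marker_fallback)
    unname(stats::quantile(mk, 0.5, type = 7)) else mk_sp$threshold
  structure(list(dna_threshold = dna_threshold,
                 area_range = area_range,
                 focus_range = c(focus_lower, focus_upper),
                 marker_threshold = marker_threshold,
                 gate_order = GATE_ORDER,
                 dna_col = dna_col, marker_col = marker_col,
                 focus_rule = focus_rule,
                 dna_unimodal_fallback = dna_fallback,
                 marker_unimodal_fallback = marker_fallback),
            class = "gating_config")
}

#' @export
print.gating_config <- function(x, ...) {
  cat("gating_config:\n",
      sprintf("  DNA <= %.3g%s\n", x$dna_threshold,
              if (x$dna_unimodal_fallback) " (unimodal fallback)" else ""),
      sprintf("  area in [%.3g, %.3g] um^2\n", x$area_range[1], x$area_range[2]),
      sprintf("  focus in [%.3g, %.3g]\n", x$focus_range[1], x$focus_range[2]),
      sprintf("  marker > %.3g\n", x$marker_threshold), sep = "")
  invisible(x)
}

#' Apply the sequential gating chain
#'
#' Gates are applied strictly in order (non-nucleated, non-debris,
#' mid-focus, marker-positive); a later gate is evaluated only for events
#' that passed all earlier gates (`NA` in the trail otherwise). Flagged /
#' degenerate feature records fail the non-debris gate. Because all gates
#' are conjunctive thresholds, the final event set does not depend on gate
#' order — only the trail does.
#'
#' @param features feature table (one row per event) with `event_id`,
#'   `flag`, the configured DNA and marker columns, `area_um2` and
#'   `focus_score`.
#' @param config a `gating_config`.
#' @return a `gating_result`: list with `trail` (per-event logical columns
#'   per gate plus `final`), `counts` (events surviving each gate, starting
#'   from the input count) and `final_ids`.
#' @export
apply_gates <- function(features, config) {
  stopifnot(inherits(config, "gating_config"))
  need <- c("event_id", config$dna_col, "area_um2", "focus_score",
            config$marker_col)
  miss <- setdiff(need, colnames(features))
  if (length(miss)) stop("missing feature column: ", paste(miss, collapse = ", "))
  flag <- if ("flag" %in% colnames(features)) features$flag else
    rep(FALSE, nrow(features))
  dna <- features[[config$dna_col]]
  mk <- features[[config$marker_col]]
  raw <- list(
    non_nucleated = is.finite(dna) & dna <= config$dna_threshold,
    non_debris = !flag & is.finite(features$area_um2) &
      features$area_um2 >= config$area_range[1] &
      features$area_um2 <= config$area_range[2],
    mid_focus = is.finite(features$focus_score) &
      features$focus_score >= config$focus_range[1] &
      features$focus_score <= config$focus_range[2],
    marker_positive = is.finite(mk) & mk > config$marker_threshold)
  raw <- raw[config$gate_order]
  trail <- data.frame(event_id = features$event_id)
  alive <- rep(TRUE, nrow(features))
  counts <- c(input = nrow(features))
  for (g in config$gate_order) {
    col <- rep(NA, nrow(features))
    col[alive] <- raw[[g]][alive]
    trail[[g]] <- col
    alive <- alive & !is.na(col) & col
    counts[[g]] <- sum(alive)
  }
  trail$final <- alive
  structure(list(trail = trail, counts = counts,
                 final_ids = features$event_id[alive], config = config),
            class = "gating_result")
}

#' @export
print.gating_result <- function(x, ...) {
  cat("gating_result: ", paste(names(x$counts), x$counts, sep = "=",
                               collapse = " -> "), "\n")
  invisible(x)
}
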