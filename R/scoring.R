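# Sickle scoring: Fisher's-discriminant metric ranking, the Sickle Score
# classifier, spillover-calibrated gating and the percent-positive endpoint.

#' Fisher's discriminant of a metric between two samples
#'
#' `Fd = |mean_a - mean_b| / (sd_a + sd_b)` with sample standard deviations
#' (n-1 denominator) — the separation convention of the imaging-cytometry
#' software family; a pooled-SD alternative is available via
#' `denominator = "pooled"`. Two identical constants give 0; distinct
#' constants give `Inf`.
#'
#' @param values_a,values_b numeric samples (each of size >= 2).
#' @param denominator `"sum"` (default, `sd_a + sd_b`) or `"pooled"`.
#' @return non-negative Fd value.
#' @export
fishers_discriminant <- function(values_a, values_b,
                                 denominator = c("sum", "pooled")) {
  denominator <- match.arg(denominator)
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each sample needs at least 2 finite values")
  dmu <- abs(mean(values_a) - mean(values_b))
  den <- if (denominator == "sum") stats::sd(values_a) + stats::sd(values_b)
  else sqrt((stats::var(values_a) * (length(values_a) - 1) +
               stats::var(values_b) * (length(values_b) - 1)) /
              (length(values_a) + length(values_b) - 2))
  if (den == 0) return(if (dmu == 0) 0 else Inf)
  dmu / den
}

#' Default metric list for discriminant ranking
#'
#' The mask-based size, shape, texture and brightness metrics considered
#' when ranking separators of sickled versus non-sickled cells. Two kinds
#' of quantity are deliberately excluded: acquisition quality (focus), which
#' is handled upstream by the gating chain rather than being a candidate
#' classifier, and the derived Sickle Score, which is the combination
#' constructed *from* this ranking and is evaluated against the single
#' metrics separately (see [fishers_discriminant()]).
#' @return character vector of feature column names.
#' @export
ranking_metrics <- function() {
  c("area_um2", "length_um", "thickness_min_um", "thickness_max_um",
    "shape_ratio", "symmetry2", "aspect_ratio", "circularity",
    "h_contrast", "h_entropy", "bf_mean")
}

#' Rank metrics by Fisher's discriminant between two labeled sets
#'
#' @param features_a,features_b feature tables (flagged rows are excluded).
#' @param metrics metric columns to rank (default [ranking_metrics()],
#'   intersected with available columns only if all are present — a missing
#'   metric is an error naming it).
#' @param denominator passed to [fishers_discriminant()].
#' @return `data.frame` (`metric`, `fd`) sorted by descending Fd, ties
#'   broken alphabetically.
#' @export
rank_metrics <- function(features_a, features_b, metrics = ranking_metrics(),
                         denominator = "sum") {
  miss <- setdiff(metrics, intersect(colnames(features_a), colnames(features_b)))
  if (length(miss))
    stop("metric absent from feature tables: ", paste(miss, collapse = ", "))
  if ("flag" %in% colnames(features_a)) features_a <- features_a[!features_a$flag, ]
  if ("flag" %in% colnames(features_b)) features_b <- features_b[!features_b$flag, ]
  fd <- vapply(metrics, function(m)
    fishers_discriminant(features_a[[m]], features_b[[m]],
                         denominator = denominator), numeric(1))
  out <- data.frame(metric = metrics, fd = unname(fd))
  out <- out[order(-out$fd, out$metric), ]
  rownames(out) <- NULL
  out
}

#' Sickle Score of feature records
#'
#' The sickling classifier: two-fold boundary symmetry divided by the Shape
#' Ratio, both from the brightfield mask. High for elongated, low-thickness
#' crescents; near zero for discs. Flagged or non-positive-Shape-Ratio
#' records score `NA`.
#'
#' @param features feature table (or single record) with `symmetry2`,
#'   `shape_ratio` and optionally `flag` columns.
#' @return numeric vector of scores.
#' @export
sickle_score <- function(features) {
  s2 <- features$symmetry2
  sr <- features$shape_ratio
  bad <- !is.finite(s2) | !is.finite(sr) | sr <= 0
  if ("flag" %in% colnames(features)) bad <- bad | features$flag
  out <- rep(NA_real_, length(s2))
  out[!bad] <- s2[!bad] / sr[!bad]
  out
}

#' Calibrate the sickle gate at a target spillover
#'
#' Places the score threshold at the `(1 - spillover)` linear-interpolation
#' quantile of a non-sickling control population, so about `spillover` of
#' control events exceed the gate ("~10% spillover" convention).
#'
#' @param control_scores finite Sickle Scores of the uninduced/non-sickling
#'   control population (>= 100 values).
#' @param spillover target spillover fraction in (0, 0.5).
#' @return a `sickle_gate`: list with `threshold`, `spillover`,
#'   `n_calibration`, and a `degenerate` flag (constant scores).
#' @export
calibrate_sickle_gate <- function(control_scores, spillover = 0.10) {
  stopifnot(spillover > 0, spillover < 0.5)
  s <- control_scores[is.finite(control_scores)]
  if (length(s) < 100)
    stop("need at least 100 finite control scores (got ", length(s), ")")
  thr <- unname(stats::quantile(s, 1 - spillover, type = 7))
  structure(list(threshold = thr, spillover = spillover,
                 n_calibration = length(s),
                 degenerate = diff(range(s)) == 0),
            class = "sickle_gate")
}

#' Fraction of events scoring positive for sickle shape distortion
#'
#' @param scores Sickle Scores of gated mature red-cell events; `NA`
#'   (flagged) scores are excluded from numerator and denominator.
#' @param gate a `sickle_gate`.
#' @return fraction of finite scores strictly above the gate threshold.
#' @export
percent_sickled <- function(scores, gate) {
  stopifnot(inherits(gate, "sickle_gate"))
  s <- scores[is.finite(scores)]
  if (length(s) == 0) stop("no finite scores to gate")
  mean(s > gate$threshold)
}

#' Two-sample comparison of per-trial endpoints
#'
#' Student's two-sided t test (equal-variance form by default; Welch via
#' `var_equal = FALSE`) on per-trial percent-positive values.
#'
#' @param percents_a,percents_b per-trial endpoint values (>= 2 per group).
#' @param var_equal equal-variance (classical Student) form if `TRUE`.
#' @return list: `statistic`, `p.value`, `mean_a`, `sd_a`, `mean_b`, `sd_b`.
#' @export
compare_groups_t <- function(percents_a, percents_b, var_equal = TRUE) {
  if (length(percents_a) < 2 || length(percents_b) < 2)
    stop("need at least 2 trials per group")
  tt <- stats::t.test(percents_a, percents_b, var.equal = var_equal)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       mean_a = mean(percents_a), sd_a = stats::sd(percents_a),
       mean_b = mean(percents_b), sd_b = stats::sd(percents_b))
}

#' Generate hand-picked-style training sets
#'
#' Emulates manual selection of prototypical example cells for metric
#' optimization: each labeled set is drawn from a narrow parameter range
#' (hand-picked examples are canonical, not population-typical), rendered
#' and featurized. Sets: `sickle` (crescents), `non_sickle` (normal cells in
#' the orientation mix the detector actually sees: mostly face-on discs plus
#' a minority of tilted, edge-on presentations — cells pass the detector in
#' any orientation, and a tilted disc is a genuinely non-sickled example),
#' `sideways` (pure edge-on presentations), `star`, `wrinkled`.
#'
#' @param n_per_set events per labeled set (>= 20).
#' @param seed master seed.
#' @param pixel_size_um,crop_px rendering geometry.
#' @param sets which labeled sets to build.
#' @return named list of feature tables.
#' @export
make_training_sets <- function(n_per_set = 200L, seed = 1L,
                               pixel_size_um = 0.4, crop_px = 72L,
                               sets = c("sickle", "non_sickle", "sideways",
                                        "star", "wrinkled")) {
  stopifnot(n_per_set >= 20)
  rtn <- function(mu, sd, lo, hi) min(max(stats::rnorm(1, mu, sd), lo), hi)
  draw <- function(class, k) {
    s <- derive_seed(seed, k, salt = match(class, SHAPE_CLASSES))
    with_seed(s, switch(class,
      crescent = {
        sz <- rtn(8, 0.4, 7, 9)
        shape_params("crescent", size_um = sz,
                     elongation = min(rtn(3, 0.15, 2.6, 3.4), 27 / sz),
                     curvature = rtn(0.5, 0.06, 0.3, 0.7),
                     noise_amp = 0.02)
      },
      disc = shape_params("disc", size_um = rtn(8, 0.5, 6.8, 9.2),
                          ellipticity = stats::runif(1, 1, 1.12),
                          noise_amp = 0.02),
      sideways = shape_params("sideways", size_um = rtn(8, 0.4, 7, 9),
                              elongation = rtn(3.5, 0.2, 3, 4),
                              noise_amp = 0.02),
      star = shape_params("star", size_um = rtn(8, 0.4, 7, 9),
                          harmonic_order = sample(4:6, 1), noise_amp = 0.03),
      wrinkled = shape_params("wrinkled", size_um = rtn(8, 0.4, 7, 9),
                              noise_amp = stats::runif(1, 0.15, 0.22))))
  }
  build <- function(classes) {
    evs <- lapply(seq_len(n_per_set), function(k) {
      cl <- classes[1 + (k - 1) %% length(classes)]
      render_cell(draw(cl, k), seed = derive_seed(seed, k, salt = 50 +
                    match(cl, SHAPE_CLASSES)),
                  pixel_size_um = pixel_size_um, crop_px = crop_px)
    })
    featurize_events(evs)
  }
  # non-sickle: 4 of 5 face-on discs, 1 of 5 edge-on (sideways) presentations
  recipes <- list(sickle = "crescent",
                  non_sickle = c("disc", "disc", "disc", "disc", "sideways"),
                  sideways = "sideways", star = "star",
                  wrinkled = "wrinkled")
  lapply(recipes[match.arg(sets, several.ok = TRUE)], build)
}
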