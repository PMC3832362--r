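# Analytic raster shapes and independent geometric oracles used across the
# morphometry tests.

raster_grid <- function(n) {
  ax <- seq_len(n) - (n + 1) / 2
  list(x = matrix(ax, n, n), y = matrix(ax, n, n, byrow = TRUE))
}

raster_circle <- function(r, n = ceiling(2 * r) + 10) {
  g <- raster_grid(n)
  g$x^2 + g$y^2 < r^2
}

raster_rect <- function(w, h, n = max(w, h) + 10) {
  g <- raster_grid(n)
  abs(g$x) < w / 2 & abs(g$y) < h / 2
}

raster_ellipse <- function(a, b, n = 2 * max(a, b) + 10) {
  g <- raster_grid(n)
  (g$x / a)^2 + (g$y / b)^2 < 1
}

# Brute-force pixel oracle for the ellipse minimum thickness: on the
# rasterized shape, the medial axis along the major axis ends at the last
# pixel whose inscribed disc is contained in no other pixel's disc
# (containment tested against EVERY mask pixel, not a local neighborhood);
# the retained path keeps 80% of the half-span and Tmin is twice the
# distance-transform value at its end.
oracle_ellipse_tmin_px <- function(mask) {
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1)))
  nr <- nrow(mask)
  ctr <- round((nr + 1) / 2)
  idx <- which(mask, arr.ind = TRUE)
  dv <- dm[idx]
  last <- NA
  for (x in seq(ctr, nr - 1)) {
    if (!mask[x, ctr]) break
    dist <- sqrt((idx[, 1] - x)^2 + (idx[, 2] - ctr)^2)
    if (any(dv >= dm[x, ctr] + dist - 1e-9 & dist > 0)) break
    last <- x
  }
  s <- last - ctr
  2 * dm[ctr + round(0.8 * s), ctr]
}

# A fake blank image event (background + noise only) for degenerate-path
# tests.
blank_event <- function(crop_px = 64, seed = 1) {
  set.seed(seed)
  bf <- matrix(0.8, crop_px, crop_px) +
    matrix(rnorm(crop_px^2, 0, 0.02), crop_px, crop_px)
  structure(list(channels = list(BF = bf), pixel_size_um = 0.4,
                 crop_px = crop_px, seed = seed, params = NULL),
            class = "image_event")
}

withr_local_tempdir <- function() {
  d <- tempfile("sicklemetry")
  dir.create(d)
  d
}

# Quantize true sickling times up to the sampled-frame grid (the detector's
# event-time convention) without rendering; censored beyond the last sampled
# frame.
grid_detect_times <- function(truth, config, interval_frames = 256L) {
  grid_min <- interval_frames / config$fps / 60
  last <- floor((config$duration_min * 60 * config$fps - 1) / interval_frames) *
    grid_min
  tt <- truth$true_time_min
  k <- ceiling(tt / grid_min)
  det <- k * grid_min
  ok <- !is.na(tt) & det <= last & det > 0
  data.frame(cell_id = truth$cell_id,
             time_min = ifelse(ok, det, config$duration_min),
             censored = !ok)
}
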