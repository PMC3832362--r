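# Sickling-kinetics simulator: per-cell transition times under a
# delay + exponential-hazard model, and a static-field video renderer.

#' Configuration of a sickling time-lapse simulation
#'
#' The generative model: each cell is independently susceptible with
#' probability `susceptible_fraction`; a susceptible cell sickles at
#' `delay_min + Exponential(hazard_per_min)` minutes after induction and
#' morphs from disc to crescent over `transition_sec` seconds. Cells that
#' have not sickled by `duration_min` are right-censored at recording end.
#'
#' @param n_cells number of cells in the trial.
#' @param susceptible_fraction probability a cell can sickle, in `[0, 1]`.
#' @param delay_min absolute delay before any cell can sickle (minutes).
#' @param hazard_per_min exponential hazard rate after the delay (per
#'   minute), `> 0`.
#' @param duration_min recording length (minutes).
#' @param fps acquisition rate (frames per second).
#' @param transition_sec duration of the disc-to-crescent morph (seconds).
#' @param seed master seed.
#' @return a `kinetics_config` object.
#' @export
kinetics_config <- function(n_cells, susceptible_fraction, delay_min = 4.3,
                            hazard_per_min = 0.165, duration_min = 30,
                            fps = 4, transition_sec = 3, seed = 1L) {
  stopifnot(n_cells >= 1, susceptible_fraction >= 0, susceptible_fraction <= 1,
            hazard_per_min > 0, fps > 0, duration_min > 0,
            delay_min >= 0, transition_sec >= 0)
  if (delay_min >= duration_min)
    stop("delay_min must be smaller than duration_min")
  structure(list(n_cells = as.integer(n_cells),
                 susceptible_fraction = susceptible_fraction,
                 delay_min = delay_min, hazard_per_min = hazard_per_min,
                 duration_min = duration_min, fps = fps,
                 transition_sec = transition_sec, seed = as.integer(seed)),
            class = "kinetics_config")
}

#' Simulate ground-truth sickling times
#'
#' @param config a [kinetics_config()].
#' @return `data.frame` with one row per cell: `cell_id`, `susceptible`,
#'   `true_time_min` (`NA` for non-susceptible cells) and
#'   `sickles_in_window` (true time within the recording).
#' @export
simulate_sickling_times <- function(config) {
  stopifnot(inherits(config, "kinetics_config"))
  with_seed(derive_seed(config$seed, 0, salt = 11), {
    n <- config$n_cells
    susceptible <- stats::runif(n) < config$susceptible_fraction
    tt <- rep(NA_real_, n)
    tt[susceptible] <- config$delay_min +
      stats::rexp(sum(susceptible), rate = config$hazard_per_min)
    data.frame(cell_id = seq_len(n), susceptible = susceptible,
               true_time_min = tt,
               sickles_in_window = susceptible & tt <= config$duration_min)
  })
}

#' Field layout for video rendering
#'
#' Cells sit on a static square grid (the recorded cells settle in the dish
#' and do not move); each grid tile must be large enough to hold the fully
#' sickled crescent of its own cell without reaching a neighbor's tile.
#'
#' @param spacing_px grid pitch in pixels (also the per-cell analysis
#'   window).
#' @param pixel_size_um micrometers per pixel.
#' @return a `video_layout` object.
#' @export
video_layout <- function(spacing_px = 48L, pixel_size_um = 0.5) {
  stopifnot(spacing_px >= 16, pixel_size_um > 0)
  structure(list(spacing_px = as.integer(spacing_px),
                 pixel_size_um = pixel_size_um),
            class = "video_layout")
}

# Per-cell video shape draws: modest sizes/elongations so crescents stay
# inside one grid tile.
video_cell_params <- function(seed) {
  with_seed(seed, {
    rtn <- function(mu, sd, lo, hi) min(max(stats::rnorm(1, mu, sd), lo), hi)
    list(size_um = rtn(7.8, 0.5, 6.5, 8.8),
         elongation = rtn(2.2, 0.15, 1.8, 2.4),
         curvature = stats::runif(1, 0.3, 0.7),
         angle = stats::runif(1, 0, 2 * pi))
  })
}

# Render one cell's brightfield tile for a given morph fraction alpha
# (0 = disc, 1 = crescent). Intermediate alphas blend the two appearances.
render_video_tile <- function(cp, alpha, spacing_px, pixel_size_um) {
  g <- coord_grid(spacing_px, pixel_size_um)
  xr <- cos(cp$angle) * g$x + sin(cp$angle) * g$y
  yr <- -sin(cp$angle) * g$x + cos(cp$angle) * g$y
  paint <- function(mask) {
    img <- matrix(BF_BACKGROUND, spacing_px, spacing_px)
    if (any(mask)) {
      dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1)))
      img[mask] <- BF_INTERIOR
      img[mask & dm <= RIM_WIDTH_UM / pixel_size_um] <- BF_RIM
    }
    img
  }
  disc <- function() {
    rad <- sqrt(xr^2 + yr^2)
    paint(rad < cp$size_um / 2)
  }
  crescent <- function() {
    a1 <- cp$size_um * cp$elongation / 2
    b1 <- cp$size_um * 0.42
    dy <- b1 * (0.35 + 0.9 * cp$curvature)
    a2 <- a1 * 0.95
    b2 <- b1 * (0.55 + 0.75 * cp$curvature)
    E1 <- (xr / a1)^2 + (yr / b1)^2 < 1
    E2 <- (xr / a2)^2 + ((yr - dy) / b2)^2 < 1
    paint(E1 & !E2)
  }
  if (alpha <= 0) disc()
  else if (alpha >= 1) crescent()
  else (1 - alpha) * disc() + alpha * crescent()
}

#' Render a sickling time-lapse field
#'
#' Cells appear as discs until their true sickling time, morph to crescents
#' over the configured transition, and remain sickled; positions are static.
#' Only the requested frame indices are rendered, with pixel content
#' identical to what a full rendering would produce at those indices
#' (per-frame noise and per-cell geometry are seeded independently), so
#' sparse frame evaluation is exact.
#'
#' @param truth ground-truth table from [simulate_sickling_times()].
#' @param config the [kinetics_config()] used to generate `truth`.
#' @param layout a [video_layout()].
#' @param frames 0-based frame indices to render (default: the full
#'   recording, `0 : (duration_min * 60 * fps - 1)`).
#' @return a `video_field`: list with `frames` (named list of field
#'   matrices), `frame_idx`, `centers` (`data.frame` of cell grid positions,
#'   1-based tile row/col), `config`, `layout`.
#' @export
render_video <- function(truth, config, layout = video_layout(),
                         frames = NULL) {
  stopifnot(inherits(config, "kinetics_config"),
            inherits(layout, "video_layout"))
  n <- nrow(truth)
  total_frames <- as.integer(round(config$duration_min * 60 * config$fps))
  if (is.null(frames)) frames <- 0:(total_frames - 1)
  frames <- sort(unique(as.integer(frames)))
  if (any(frames < 0 | frames >= total_frames))
    stop("frame indices must lie in [0, ", total_frames - 1, "]")
  sp <- layout$spacing_px
  ps <- layout$pixel_size_um
  # packing check: largest possible crescent (size 8.8 um x elongation 2.4)
  # must fit one tile
  max_ext_px <- (8.8 * 2.4 + 2) / ps
  if (sp < max_ext_px)
    stop("cells would overlap at this density: increase spacing_px to >= ",
         ceiling(max_ext_px), " or enlarge pixel_size_um")
  ncols <- ceiling(sqrt(n))
  nrows <- ceiling(n / ncols)
  cp <- lapply(seq_len(n), function(k)
    video_cell_params(derive_seed(config$seed, k, salt = 21)))
  tile_row <- ((seq_len(n) - 1) %/% ncols) + 1
  tile_col <- ((seq_len(n) - 1) %% ncols) + 1
  centers <- data.frame(cell_id = truth$cell_id, tile_row = tile_row,
                        tile_col = tile_col,
                        center_row = (tile_row - 0.5) * sp,
                        center_col = (tile_col - 0.5) * sp)
  # cache the two endpoint appearances per cell
  disc_tiles <- lapply(cp, render_video_tile, alpha = 0,
                       spacing_px = sp, pixel_size_um = ps)
  cres_tiles <- vector("list", n)
  trans_min <- config$transition_sec / 60
  out <- vector("list", length(frames))
  names(out) <- as.character(frames)
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    t_min <- f / config$fps / 60
    field <- matrix(BF_BACKGROUND, nrows * sp, ncols * sp)
    for (k in seq_len(n)) {
      t0 <- truth$true_time_min[k]
      alpha <- if (is.na(t0) || t_min < t0) 0
               else if (trans_min <= 0 || t_min >= t0 + trans_min) 1
               else (t_min - t0) / trans_min
      tile <- if (alpha <= 0) disc_tiles[[k]]
      else if (alpha >= 1) {
        if (is.null(cres_tiles[[k]]))
          cres_tiles[[k]] <- render_video_tile(cp[[k]], 1, sp, ps)
        cres_tiles[[k]]
      } else render_video_tile(cp[[k]], alpha, sp, ps)
      rr <- ((tile_row[k] - 1) * sp + 1):(tile_row[k] * sp)
      cc <- ((tile_col[k] - 1) * sp + 1):(tile_col[k] * sp)
      field[rr, cc] <- tile
    }
    noise <- with_seed(derive_seed(config$seed, f, salt = 22),
                       stats::rnorm(length(field), 0, PIXEL_NOISE_SD))
    out[[fi]] <- pmax(field + noise, 0)
  }
  structure(list(frames = out, frame_idx = frames, centers = centers,
                 n_cells = n, total_frames = total_frames,
                 config = config, layout = layout),
            class = "video_field")
}

#' @export
print.video_field <- function(x, ...) {
  cat("video_field:", x$n_cells, "cells,", length(x$frame_idx),
      "rendered frames of", x$total_frames, "\n")
  invisible(x)
}
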