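# Ground-truthed imaging-cytometry event populations.

#' Default morphology class fractions
#'
#' Emulates the composition of a sickling-induced (or uninduced) cultured
#' red-blood-cell preparation: a majority of mature enucleated cells (>75%
#' of events non-nucleated, >95% of cells marker-positive) with nucleated
#' precursors, expelled nuclei, debris and doublet aggregates as
#' contaminants. The induced mix carries crescent and spiculated cells; the
#' uninduced mix does not.
#'
#' @param kind `"induced"` or `"uninduced"`.
#' @return named fractions over the ten shape classes, summing to 1.
#' @export
default_class_fractions <- function(kind = c("induced", "uninduced")) {
  kind <- match.arg(kind)
  if (kind == "induced")
    c(disc = 0.36, sideways = 0.09, crescent = 0.17, star = 0.04,
      wrinkled = 0.04, spiculated = 0.03, nucleated = 0.16,
      free_nucleus = 0.05, debris = 0.04, aggregate = 0.02)
  else
    c(disc = 0.56, sideways = 0.12, crescent = 0, star = 0.01,
      wrinkled = 0.04, spiculated = 0, nucleated = 0.16,
      free_nucleus = 0.05, debris = 0.04, aggregate = 0.02)
}

#' Configuration of a synthetic event population
#'
#' @param n_events number of single-cell events to generate.
#' @param class_fractions named map shape class -> fraction, summing to 1.
#' @param marker_positive_fraction fraction of cell-derived events carrying
#'   the erythroid surface marker.
#' @param defocus_fraction fraction of events rendered out of focus.
#' @param channel_gains per-channel multiplicative intensity scales.
#' @param pixel_size_um micrometers per pixel.
#' @param crop_px crop edge length.
#' @param seed master seed; every event is reproducible in isolation via a
#'   counter-based per-event seed.
#' @return a `population_config` object.
#' @export
population_config <- function(n_events,
                              class_fractions = default_class_fractions("induced"),
                              marker_positive_fraction = 0.97,
                              defocus_fraction = 0.02,
                              channel_gains = c(BF = 1, DNA = 1, CD235 = 1),
                              pixel_size_um = 0.4, crop_px = 72L, seed = 1L) {
  stopifnot(n_events >= 1, marker_positive_fraction >= 0,
            marker_positive_fraction <= 1, defocus_fraction >= 0,
            defocus_fraction <= 1, pixel_size_um > 0, crop_px >= 16)
  if (abs(sum(class_fractions) - 1) > 1e-9)
    stop("class fractions must sum to 1 (got ", format(sum(class_fractions)), ")")
  bad <- setdiff(names(class_fractions), SHAPE_CLASSES)
  if (length(bad)) stop("unknown shape_class: ", paste(bad, collapse = ", "))
  structure(list(n_events = as.integer(n_events),
                 class_fractions = class_fractions,
                 marker_positive_fraction = marker_positive_fraction,
                 defocus_fraction = defocus_fraction,
                 channel_gains = channel_gains,
                 pixel_size_um = pixel_size_um, crop_px = as.integer(crop_px),
                 seed = as.integer(seed)),
            class = "population_config")
}

# Per-class geometric parameter draws used for whole populations. Values
# emulate cultured red cells: ~8 um discs with mild ellipticity and boundary
# roughness, crescents elongated ~3x, small debris, ~9.5 um nucleated
# precursors and ~4 um expelled nuclei.
sample_shape_params <- function(class, seed) {
  with_seed(seed, {
    rtn <- function(mu, sd, lo, hi) min(max(stats::rnorm(1, mu, sd), lo), hi)
    switch(class,
      disc = shape_params("disc", size_um = rtn(8, 0.6, 6, 10),
                          ellipticity = stats::runif(1, 1, 1.12),
                          noise_amp = 0.02),
      sideways = shape_params("sideways", size_um = rtn(8, 0.6, 6, 10),
                              elongation = rtn(3.5, 0.4, 2.6, 4.6),
                              noise_amp = 0.02),
      crescent = {
        sz <- rtn(8, 0.6, 6, 10)
        shape_params("crescent", size_um = sz,
                     elongation = min(rtn(3, 0.35, 2, 4.2), 25 / sz),
                     curvature = stats::runif(1, 0.25, 0.75),
                     noise_amp = 0.02)
      },
      star = shape_params("star", size_um = rtn(8, 0.6, 6, 10),
                          harmonic_order = sample(4:6, 1), noise_amp = 0.03),
      wrinkled = shape_params("wrinkled", size_um = rtn(8, 0.6, 6, 10),
                              noise_amp = stats::runif(1, 0.12, 0.25)),
      spiculated = {
        sz <- rtn(8, 0.6, 6, 10)
        shape_params("spiculated", size_um = sz,
                     elongation = min(rtn(3, 0.35, 2, 4.2), 20.5 / sz),
                     curvature = stats::runif(1, 0.25, 0.75),
                     n_spicules = 2 + stats::rpois(1, 4))
      },
      nucleated = shape_params("nucleated", size_um = rtn(9.5, 0.7, 7.5, 11.5),
                               ellipticity = stats::runif(1, 1, 1.1),
                               noise_amp = 0.02),
      free_nucleus = shape_params("free_nucleus", size_um = rtn(4, 0.4, 3, 5)),
      debris = shape_params("debris", size_um = stats::runif(1, 1.6, 3.2)),
      aggregate = shape_params("aggregate", size_um = rtn(8.5, 0.6, 7, 10)))
  })
}

#' Generate a ground-truthed event population
#'
#' Per-class counts follow largest-remainder apportionment of the class
#' fractions (deterministic); event order is a seeded shuffle; each event is
#' rendered under its own counter-derived seed, so the whole population is a
#' pure function of its configuration.
#'
#' @param config a [population_config()].
#' @return list with `events` (list of `image_event`) and `truth`
#'   (`data.frame`: `event_id`, `class`, `marker_positive`, `defocused`,
#'   `seed`, and a `mature_crbc` flag marking marker-positive enucleated
#'   cell classes).
#' @export
sample_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  counts <- apportion_counts(config$n_events, config$class_fractions)
  classes <- rep(names(counts), counts)
  ord <- with_seed(derive_seed(config$seed, 0, salt = 1),
                   sample.int(length(classes)))
  classes <- classes[ord]
  n <- length(classes)
  cell_classes <- setdiff(SHAPE_CLASSES, c("free_nucleus", "debris"))
  mature_classes <- c("disc", "sideways", "crescent", "star", "wrinkled",
                      "spiculated")
  events <- vector("list", n)
  marker <- logical(n)
  defoc <- logical(n)
  seeds <- integer(n)
  for (k in seq_len(n)) {
    seeds[k] <- derive_seed(config$seed, k)
    aux <- with_seed(derive_seed(config$seed, k, salt = 2), stats::runif(2))
    marker[k] <- classes[k] %in% cell_classes &&
      aux[1] < config$marker_positive_fraction
    defoc[k] <- aux[2] < config$defocus_fraction
    params <- sample_shape_params(classes[k],
                                  derive_seed(config$seed, k, salt = 3))
    if (defoc[k]) params$defocus_sigma_px <- 3
    events[[k]] <- render_cell(params, seed = seeds[k],
                               pixel_size_um = config$pixel_size_um,
                               crop_px = config$crop_px,
                               channel_gains = config$channel_gains,
                               marker_positive = marker[k])
  }
  truth <- data.frame(event_id = seq_len(n), class = classes,
                      marker_positive = marker, defocused = defoc,
                      seed = seeds,
                      mature_crbc = classes %in% mature_classes & marker)
  list(events = events, truth = truth)
}
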