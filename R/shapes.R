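# Synthetic single-cell renderer: parametric shapes drawn onto a pixel grid
# as multi-channel brightfield / DNA / surface-marker crops.

SHAPE_CLASSES <- c("disc", "sideways", "crescent", "star", "wrinkled",
                   "spiculated", "nucleated", "free_nucleus", "debris",
                   "aggregate")

# Brightfield appearance constants (fractions of full scale): bright
# background, dark membrane rim, lighter interior, additive Gaussian pixel
# noise at 2% full scale.
BF_BACKGROUND <- 0.80
BF_INTERIOR <- 0.55
BF_RIM <- 0.30
RIM_WIDTH_UM <- 0.8
PIXEL_NOISE_SD <- 0.02
DNA_BACKGROUND <- 0.03
DNA_NUCLEUS <- 0.90
MARKER_BACKGROUND <- 0.02
MARKER_MEMBRANE <- 0.65

#' Parameters of one synthetic cell shape
#'
#' Bundles the geometric knobs of the renderer. `shape_class` selects the
#' morphology family; the remaining fields are interpreted per class:
#' `elongation` is the axis ratio of crescents (and the aspect of sideways
#' cells), `curvature` bends the crescent, `harmonic_order` sets the number
#' of star points, `noise_amp` modulates the boundary of wrinkled cells,
#' `n_spicules` adds protruding membrane fibers, and `defocus_sigma_px`
#' blurs the rendered crop to emulate an out-of-focus event.
#'
#' @param shape_class one of `"disc"`, `"sideways"`, `"crescent"`, `"star"`,
#'   `"wrinkled"`, `"spiculated"`, `"nucleated"`, `"free_nucleus"`,
#'   `"debris"`, `"aggregate"`.
#' @param size_um cell diameter scale in micrometers.
#' @param elongation unitless axis ratio, `>= 1`.
#' @param curvature unitless crescent bending in `[0, 1]`.
#' @param harmonic_order integer `>= 3`, number of star points.
#' @param noise_amp boundary modulation amplitude in `[0, 0.5]`.
#' @param n_spicules integer `>= 0`.
#' @param defocus_sigma_px Gaussian blur scale in pixels, `>= 0`.
#' @param ellipticity mild in-plane axis ratio applied to discs (real red
#'   cells are not perfect circles), `>= 1`.
#' @return a `shape_params` object (validated list).
#' @export
shape_params <- function(shape_class, size_um = 8, elongation = 1,
                         curvature = 0.5, harmonic_order = 5L,
                         noise_amp = 0, n_spicules = 0L,
                         defocus_sigma_px = 0, ellipticity = 1) {
  if (!is.character(shape_class) || length(shape_class) != 1 ||
      !(shape_class %in% SHAPE_CLASSES))
    stop("unknown shape_class: ", paste(shape_class, collapse = ", "),
         " (expected one of ", paste(SHAPE_CLASSES, collapse = ", "), ")")
  stopifnot(size_um > 0, elongation >= 1, curvature >= 0, curvature <= 1,
            harmonic_order >= 3, noise_amp >= 0, noise_amp <= 0.5,
            n_spicules >= 0, defocus_sigma_px >= 0, ellipticity >= 1)
  structure(list(shape_class = shape_class, size_um = size_um,
                 elongation = elongation, curvature = curvature,
                 harmonic_order = as.integer(harmonic_order),
                 noise_amp = noise_amp, n_spicules = as.integer(n_spicules),
                 defocus_sigma_px = defocus_sigma_px,
                 ellipticity = ellipticity),
            class = "shape_params")
}

# Maximum in-plane extent of the shape (um), used for crop-size validation.
shape_extent_um <- function(params) {
  sz <- params$size_um
  ext <- switch(params$shape_class,
    disc = sz * sqrt(params$ellipticity),
    sideways = sz,
    crescent = sz * params$elongation,
    star = sz * 1.35,
    wrinkled = sz * (1 + params$noise_amp),
    spiculated = sz * params$elongation + 2 * SPICULE_LEN_UM,
    nucleated = sz,
    free_nucleus = sz,
    debris = sz * 1.3,
    aggregate = sz * 1.95)
  ext
}

SPICULE_LEN_UM <- 2.2

# Pixel-center coordinate grids (um), origin at crop center. The pixel grid
# is 0-based row-major with origin top-left; physical coordinates are pixel
# centers scaled by pixel_size_um.
coord_grid <- function(crop_px, pixel_size_um) {
  ax <- (seq_len(crop_px) - (crop_px + 1) / 2) * pixel_size_um
  list(x = matrix(ax, crop_px, crop_px),
       y = matrix(ax, crop_px, crop_px, byrow = TRUE))
}

# Smooth random radial modulation: sum of low-order harmonics with seeded
# phases, scaled so the peak deviation equals `amp`.
radial_noise <- function(theta, amp, orders = 3:8) {
  if (amp <= 0) return(rep(0, length(theta)))
  z <- stats::rnorm(length(orders))
  ph <- stats::runif(length(orders), 0, 2 * pi)
  s <- rowSums(sapply(seq_along(orders),
                      function(i) z[i] * cos(orders[i] * theta + ph[i])))
  s / max(abs(s), 1e-12) * amp
}

# Build the object mask (and nucleus mask where applicable) for one shape.
# Called inside render_cell() under the event seed; any RNG use here is part
# of the deterministic rendering.
build_shape_mask <- function(params, crop_px, pixel_size_um) {
  g <- coord_grid(crop_px, pixel_size_um)
  phi <- stats::runif(1, 0, 2 * pi)       # in-plane orientation
  xr <- cos(phi) * g$x + sin(phi) * g$y
  yr <- -sin(phi) * g$x + cos(phi) * g$y
  theta <- atan2(yr, xr)
  rad <- sqrt(xr^2 + yr^2)
  sz <- params$size_um
  nucleus <- NULL

  radial_mask <- function(rfun, amp = params$noise_amp) {
    rr <- rfun(theta) * (1 + radial_noise(theta, amp))
    rad < rr
  }
  ellipse_r <- function(a, b) function(th) a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)

  mask <- switch(params$shape_class,
    disc = {
      q <- sqrt(params$ellipticity)
      radial_mask(ellipse_r(sz / 2 * q, sz / 2 / q))
    },
    sideways = {
      th <- max(params$elongation, 2.5)
      radial_mask(ellipse_r(sz / 2, sz / 2 / th))
    },
    star = {
      # mild lobed distortion: alternative polymerization outcomes are
      # subtler than full crescents
      amp <- 0.22
      radial_mask(function(th) sz / 2 * 0.9 *
                    (1 + amp * cos(params$harmonic_order * th)),
                  amp = min(params$noise_amp, 0.05))
    },
    wrinkled = radial_mask(function(th) rep(sz / 2, length(th)),
                           amp = max(params$noise_amp, 0.1)),
    free_nucleus = radial_mask(function(th) rep(sz / 2, length(th)),
                               amp = max(params$noise_amp, 0.04)),
    debris = radial_mask(function(th) rep(sz / 2, length(th)), amp = 0.3),
    nucleated = {
      q <- sqrt(params$ellipticity)
      m <- radial_mask(ellipse_r(sz / 2 * q, sz / 2 / q))
      ang <- stats::runif(1, 0, 2 * pi)
      nr <- 0.30 * sz
      off <- 0.12 * sz
      nucleus <- (xr - off * cos(ang))^2 + (yr - off * sin(ang))^2 < nr^2
      nucleus <- nucleus & m
      m
    },
    aggregate = {
      # two touching discs (doublet)
      sep <- 0.46 * sz
      d1 <- sqrt((xr - sep)^2 + yr^2)
      d2 <- sqrt((xr + sep)^2 + yr^2)
      (d1 < sz / 2 * 1.02) | (d2 < sz / 2 * 0.96)
    },
    crescent = ,
    spiculated = {
      a1 <- sz * params$elongation / 2
      b1 <- sz * 0.42
      cv <- params$curvature
      dy <- b1 * (0.35 + 0.9 * cv)
      a2 <- a1 * 0.95
      b2 <- b1 * (0.55 + 0.75 * cv)
      E1 <- (xr / a1)^2 + (yr / b1)^2 < 1
      E2 <- (xr / a2)^2 + ((yr - dy) / b2)^2 < 1
      m <- E1 & !E2
      if (params$shape_class == "spiculated" && params$n_spicules > 0)
        m <- add_spicules(m, params$n_spicules, crop_px, pixel_size_um)
      m
    })
  list(mask = mask, nucleus = nucleus)
}

# Draw radial fiber-like protrusions from the object boundary: 1-2 px wide
# segments extending outward along seeded angles.
add_spicules <- function(mask, n, crop_px, pixel_size_um) {
  ctr <- (crop_px + 1) / 2
  len_px <- SPICULE_LEN_UM / pixel_size_um
  angs <- stats::runif(n, 0, 2 * pi)
  for (a in angs) {
    dx <- cos(a); dy <- sin(a)
    tmax <- (crop_px / 2 - 1)
    ts <- seq(1, tmax, by = 0.5)
    px <- round(ctr + ts * dx); py <- round(ctr + ts * dy)
    keep <- px >= 1 & px <= crop_px & py >= 1 & py <= crop_px
    px <- px[keep]; py <- py[keep]; ts <- ts[keep]
    inmask <- mask[cbind(px, py)]
    if (!any(inmask)) next
    edge <- max(ts[inmask])
    seg <- ts > edge & ts <= edge + len_px
    if (any(seg)) mask[cbind(px[seg], py[seg])] <- TRUE
  }
  mask
}

#' Render one multi-channel single-cell image event
#'
#' Draws the shape described by `params` into a square crop, producing a
#' brightfield channel (bright background, dark membrane rim, lighter
#' interior), a DNA-stain channel (above background only for nucleated cells
#' and free nuclei) and a surface-marker channel whose intensity covers the
#' membrane area when the event is marker-positive. Rendering is a pure
#' function of `(params, seed)`.
#'
#' @param params a [shape_params()] object.
#' @param channels channel names to render; must include `"BF"`. Classes
#'   `nucleated` and `free_nucleus` additionally require `"DNA"`.
#' @param seed integer seed controlling orientation, boundary noise and
#'   pixel noise.
#' @param pixel_size_um physical pixel size, micrometers per pixel.
#' @param crop_px crop edge length in pixels.
#' @param channel_gains named multiplicative intensity scales per channel.
#' @param marker_positive logical; does the cell carry the surface marker.
#' @return an `image_event`: list with `channels` (named list of
#'   `crop_px x crop_px` matrices), `pixel_size_um`, `crop_px`, `seed`
#'   and `params`.
#' @export
render_cell <- function(params, channels = c("BF", "DNA", "CD235"), seed = 1L,
                        pixel_size_um = 0.4, crop_px = 72L,
                        channel_gains = c(BF = 1, DNA = 1, CD235 = 1),
                        marker_positive = TRUE) {
  stopifnot(inherits(params, "shape_params"))
  if (!("BF" %in% channels)) stop("channel spec must include brightfield 'BF'")
  if (params$shape_class %in% c("nucleated", "free_nucleus") &&
      !("DNA" %in% channels))
    stop("class '", params$shape_class, "' requires a DNA channel")
  need_um <- shape_extent_um(params) + 4 * pixel_size_um
  if (crop_px * pixel_size_um < need_um)
    stop("crop too small for shape: need at least ",
         ceiling(need_um / pixel_size_um), " px at ", pixel_size_um,
         " um/px (got ", crop_px, ")")

  with_seed(seed, {
    sh <- build_shape_mask(params, crop_px, pixel_size_um)
    mask <- sh$mask
    faint <- params$shape_class == "free_nucleus"
    interior <- if (faint) 0.68 else BF_INTERIOR
    rim_val <- if (faint) 0.50 else BF_RIM
    bf <- matrix(BF_BACKGROUND, crop_px, crop_px)
    if (any(mask)) {
      dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1)))
      bf[mask] <- interior
      rim <- mask & dm <= RIM_WIDTH_UM / pixel_size_um
      bf[rim] <- rim_val
    }
    out <- list()
    for (ch in channels) {
      img <- switch(ch,
        BF = bf,
        DNA = {
          d <- matrix(DNA_BACKGROUND, crop_px, crop_px)
          if (params$shape_class == "free_nucleus") d[mask] <- DNA_NUCLEUS
          if (!is.null(sh$nucleus)) d[sh$nucleus] <- DNA_NUCLEUS
          d
        },
        {
          m <- matrix(MARKER_BACKGROUND, crop_px, crop_px)
          if (marker_positive &&
              !(params$shape_class %in% c("free_nucleus", "debris")))
            m[mask] <- m[mask] + MARKER_MEMBRANE
          m
        })
      gain <- if (ch %in% names(channel_gains)) channel_gains[[ch]] else 1
      img <- img * gain
      if (params$defocus_sigma_px > 0)
        img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img),
                                        sigma = params$defocus_sigma_px))
      img <- img + matrix(stats::rnorm(crop_px^2, 0, PIXEL_NOISE_SD),
                          crop_px, crop_px)
      out[[ch]] <- pmax(img, 0)
    }
    structure(list(channels = out, pixel_size_um = pixel_size_um,
                   crop_px = as.integer(crop_px), seed = as.integer(seed),
                   params = params),
              class = "image_event")
  })
}

#' @export
print.image_event <- function(x, ...) {
  cat("image_event:", x$params$shape_class, "|",
      paste(names(x$channels), collapse = "/"), "|",
      x$crop_px, "px @", x$pixel_size_um, "um/px\n")
  invisible(x)
}
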