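# Per-event morphometry: object mask, axis/thickness metrics, boundary
# Fourier symmetry, co-occurrence texture, focus and intensity features.

MIN_MASK_AREA_PX <- 16

#' Segment the object mask of an image event
#'
#' Thresholds the inverted brightfield channel at an automatic
#' between-class-variance split, fills holes, applies one binary closing and
#' keeps the largest connected component. Crops without measurable object
#' contrast, or whose largest component is smaller than 16 px, are flagged
#' degenerate rather than erroring.
#'
#' @param event an `image_event`.
#' @param channel channel to segment (default brightfield).
#' @return an `object_mask`: list with `mask` (logical matrix), `channel`,
#'   `area_px`, `boundary` (ordered perimeter pixel coordinates, 0-based)
#'   and `degenerate` flag.
#' @export
segment_event <- function(event, channel = "BF") {
  stopifnot(inherits(event, "image_event"))
  if (!(channel %in% names(event$channels)))
    stop("channel not present: ", channel)
  img <- event$channels[[channel]]
  degenerate <- function() {
    structure(list(mask = matrix(FALSE, nrow(img), ncol(img)),
                   channel = channel, area_px = 0L, boundary = NULL,
                   degenerate = TRUE), class = "object_mask")
  }
  qs <- stats::quantile(img, c(0.01, 0.5, 0.99), names = FALSE)
  # contrast guard: a blank crop is noise about a flat background
  if ((qs[3] - qs[1]) < 0.2 * max(qs[2], 1e-9)) return(degenerate())
  inv <- max(img) - img
  th <- otsu_split(as.vector(inv))$threshold
  m <- EBImage::Image((inv > th) * 1)
  m <- EBImage::closing(m, EBImage::makeBrush(3, "box"))
  m <- EBImage::fillHull(m)
  lab <- EBImage::bwlabel(m)
  tab <- tabulate(as.integer(lab))
  if (length(tab) == 0 || max(tab) < MIN_MASK_AREA_PX) return(degenerate())
  keep <- which.max(tab)
  mask <- EBImage::imageData(lab) == keep
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))[[1]]
  structure(list(mask = mask, channel = channel, area_px = as.integer(sum(mask)),
                 boundary = oc, degenerate = FALSE),
            class = "object_mask")
}

## ---- skeleton machinery -------------------------------------------------

# Zhang-Suen parallel thinning. Falls back to the distance-transform argmax
# when parallel deletion annihilates a small symmetric blob.
thin_mask <- function(mask, distmap_m = NULL) {
  m <- mask * 1L
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  shf <- function(p, dr, dc) p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p2 <- shf(pad, -1, 0); p3 <- shf(pad, -1, 1); p4 <- shf(pad, 0, 1)
      p5 <- shf(pad, 1, 1);  p6 <- shf(pad, 1, 0);  p7 <- shf(pad, 1, -1)
      p8 <- shf(pad, 0, -1); p9 <- shf(pad, -1, -1)
      p1 <- pad[2:(nr + 1), 2:(nc + 1)]
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
           (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      cond <- if (sub == 1)
        p1 == 1 & B >= 2 & B <= 6 & A == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      else
        p1 == 1 & B >= 2 & B <= 6 & A == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      if (any(cond)) {
        changed <- TRUE
        p1[cond] <- 0L
        pad[2:(nr + 1), 2:(nc + 1)] <- p1
      }
    }
    if (!changed) break
  }
  sk <- pad[2:(nr + 1), 2:(nc + 1)] > 0
  if (!any(sk) && any(mask)) {
    if (is.null(distmap_m))
      distmap_m <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1)))
    sk[which.max(distmap_m)] <- TRUE
  }
  sk
}

neighbor_count <- function(sk) {
  nr <- nrow(sk); nc <- ncol(sk)
  pad <- matrix(0L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- sk * 1L
  n <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) if (dr || dc)
    n <- n + pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  n
}

# Remove skeleton side branches shorter than `lmin` px: trace from each
# endpoint toward the first junction; if reached within lmin steps the whole
# branch is a spur and is deleted.
prune_branches <- function(sk, lmin) {
  nr <- nrow(sk); nc <- ncol(sk)
  repeat {
    nb <- neighbor_count(sk)
    ep <- which(sk & nb == 1, arr.ind = TRUE)
    removed_any <- FALSE
    for (i in seq_len(nrow(ep))) {
      cur <- as.integer(ep[i, ])
      if (!sk[cur[1], cur[2]]) next
      path <- matrix(NA_integer_, lmin, 2)
      npath <- 0L
      prev <- c(-1L, -1L)
      hit_junction <- FALSE
      repeat {
        if (npath >= lmin) break
        npath <- npath + 1L
        path[npath, ] <- cur
        nbrs <- NULL
        for (dr in -1:1) for (dc in -1:1) if (dr || dc) {
          r <- cur[1] + dr; c <- cur[2] + dc
          if (r >= 1 && r <= nr && c >= 1 && c <= nc && sk[r, c] &&
              !(r == prev[1] && c == prev[2]))
            nbrs <- rbind(nbrs, c(r, c))
        }
        if (is.null(nbrs)) break               # isolated path consumed
        if (nrow(nbrs) > 1) { hit_junction <- TRUE; break }
        nxt <- as.integer(nbrs[1, ])
        if (nb[nxt[1], nxt[2]] >= 3) { hit_junction <- TRUE; break }
        prev <- cur; cur <- nxt
      }
      if (hit_junction && npath < lmin) {
        sk[path[seq_len(npath), , drop = FALSE]] <- FALSE
        removed_any <- TRUE
      }
    }
    if (!removed_any) break
  }
  sk
}

# Parallel thinning retracts skeleton ends short of the true medial axis.
# Extend each endpoint along the distance-transform ridge: continue while
# the candidate pixel is a maximal-disc center (its inscribed disc is not
# contained in a neighbor's) and the step stays within 45 degrees of the
# running direction, preferring the largest distance value. The direction
# constraint keeps corner spurs (e.g. rectangle diagonals) from being
# introduced.
extend_skeleton <- function(sk, dm, max_steps) {
  nr <- nrow(sk); nc <- ncol(sk)
  offs <- cbind(rep(-1:1, 3), rep(-1:1, each = 3))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), ]
  olen <- sqrt(rowSums(offs^2))
  maximal_disc <- function(p) {
    for (i in 1:8) {
      r <- p[1] + offs[i, 1]; c <- p[2] + offs[i, 2]
      if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
          dm[r, c] >= dm[p[1], p[2]] + olen[i] - 1e-6)
        return(FALSE)
    }
    TRUE
  }
  nb <- neighbor_count(sk)
  eps <- which(sk & nb == 1, arr.ind = TRUE)
  for (i in seq_len(nrow(eps))) {
    # incoming direction smoothed over up to 4 path steps
    cur <- as.integer(eps[i, ])
    prev <- cur
    walk <- cur
    for (s in 1:4) {
      found <- FALSE
      for (j in 1:8) {
        r <- walk[1] + offs[j, 1]; c <- walk[2] + offs[j, 2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc && sk[r, c] &&
            !(r == prev[1] && c == prev[2])) {
          prev <- walk; walk <- c(r, c); found <- TRUE; break
        }
      }
      if (!found) break
    }
    dir <- cur - walk
    if (all(dir == 0)) next
    dir <- dir / sqrt(sum(dir^2))
    end <- cur
    for (s in seq_len(max_steps)) {
      best <- NULL; best_dm <- -Inf
      for (j in 1:8) {
        r <- end[1] + offs[j, 1]; c <- end[2] + offs[j, 2]
        if (r < 1 || r > nr || c < 1 || c > nc || sk[r, c] || dm[r, c] <= 0)
          next
        if (sum(offs[j, ] * dir) / olen[j] <= 0.7072) next
        if (!maximal_disc(c(r, c))) next
        if (dm[r, c] > best_dm) { best_dm <- dm[r, c]; best <- c(r, c) }
      }
      if (is.null(best)) break
      sk[best[1], best[2]] <- TRUE
      step <- best - end
      dir <- dir * 0.75 + (step / sqrt(sum(step^2))) * 0.25
      dir <- dir / sqrt(sum(dir^2))
      end <- best
    }
  }
  sk
}

# Erode skeleton endpoints k times (trims k px from each free end), never
# emptying the skeleton.
erode_endpoints <- function(sk, k) {
  for (i in seq_len(k)) {
    ep <- sk & neighbor_count(sk) <= 1
    if (sum(sk) - sum(ep) < 1) break
    sk[ep] <- FALSE
  }
  sk
}

## ---- shape features -----------------------------------------------------

#' Axis, thickness and outline metrics of an object mask
#'
#' Length is the extent of the mask projected on its major principal axis
#' (second-moment eigenvector). Thickness is measured on the medial axis:
#' `Tmax` is twice the largest distance-transform value on the skeleton and
#' `Tmin` twice the smallest value on the retained skeleton, after pruning
#' side branches shorter than 10% of the length and excluding the terminal
#' 10% of the remaining path at each end (unpruned skeleton tips would drive
#' the minimum to zero on every shape). The Shape Ratio is `Tmin / Length`.
#'
#' @param mask an `object_mask` (or plain logical matrix).
#' @param pixel_size_um micrometers per pixel.
#' @return list of metrics in micrometers (and unitless ratios):
#'   `area_um2`, `length_um`, `thickness_min_um`, `thickness_max_um`,
#'   `shape_ratio`, `aspect_ratio`, `circularity`, plus `degenerate`.
#' @export
shape_features <- function(mask, pixel_size_um = 1) {
  boundary <- NULL
  if (inherits(mask, "object_mask")) {
    if (mask$degenerate)
      return(list(degenerate = TRUE))
    boundary <- mask$boundary
    mask <- mask$mask
  }
  if (sum(mask) < MIN_MASK_AREA_PX) return(list(degenerate = TRUE))
  idx <- which(mask, arr.ind = TRUE)
  ctr <- colMeans(idx)
  cc <- sweep(idx, 2, ctr)
  eg <- eigen(stats::cov(cc), symmetric = TRUE)
  proj <- cc %*% eg$vectors
  L_px <- diff(range(proj[, 1])) + 1
  W_px <- diff(range(proj[, 2])) + 1
  # moment-based axis ratio (RMS extents along the principal axes)
  aspect <- sqrt(max(eg$values[1], 1e-12) / max(eg$values[2], 1e-12))

  # work on the bounding box (1 px background pad) for the skeleton pass
  rr <- range(idx[, 1]); rc <- range(idx[, 2])
  r0 <- max(1, rr[1] - 1); r1 <- min(nrow(mask), rr[2] + 1)
  c0 <- max(1, rc[1] - 1); c1 <- min(ncol(mask), rc[2] + 1)
  mask <- mask[r0:r1, c0:c1, drop = FALSE]
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1)))
  sk <- thin_mask(mask, dm)
  sk <- prune_branches(sk, lmin = max(2L, as.integer(round(0.10 * L_px))))
  if (!any(sk)) return(list(degenerate = TRUE))
  sk <- extend_skeleton(sk, dm, max_steps = as.integer(ceiling(0.5 * L_px)))
  n_path <- sum(sk)
  sk_core <- erode_endpoints(sk, as.integer(round(0.10 * n_path)))
  if (!any(sk_core)) sk_core <- sk
  Tmax_px <- 2 * max(dm[sk])
  Tmin_px <- 2 * min(dm[sk_core])

  if (is.null(boundary))
    boundary <- EBImage::ocontour(EBImage::Image(mask * 1))[[1]]
  per_px <- contour_perimeter(boundary)
  area_px <- sum(mask)
  circ <- min(1, 4 * pi * area_px / per_px^2)

  list(degenerate = FALSE,
       area_um2 = area_px * pixel_size_um^2,
       length_um = L_px * pixel_size_um,
       thickness_min_um = Tmin_px * pixel_size_um,
       thickness_max_um = Tmax_px * pixel_size_um,
       shape_ratio = max(min(Tmin_px / L_px, 1.05), 1e-6),
       aspect_ratio = max(aspect, 1),
       circularity = circ)
}

# Chain-code perimeter with sqrt(2) diagonal steps and the standard
# digitization correction factor.
contour_perimeter <- function(oc) {
  if (is.null(oc) || nrow(oc) < 3) return(max(4, 4 * max(1, nrow(oc))))
  d <- rbind(diff(oc), oc[1, ] - oc[nrow(oc), ])
  steps <- sqrt(rowSums(d^2))
  0.948 * sum(steps)
}

#' Two-fold boundary symmetry of an object mask
#'
#' Samples the boundary radius function about the centroid at 256 uniform
#' angles (taking the maximum radius per angle when the boundary is
#' multi-valued, interpolating empty bins circularly) and returns the
#' magnitude ratio of the second to the zeroth discrete Fourier coefficient,
#' `S2 = |c2| / |c0|`. Near zero for circles, large for elongated objects.
#'
#' @param mask an `object_mask` (or logical matrix).
#' @param n_angles number of boundary angle samples.
#' @return unitless `S2` in `[0, 1]`, or `NA` for degenerate masks.
#' @export
symmetry2 <- function(mask, n_angles = 256L) {
  r <- boundary_radius(mask, n_angles)
  if (is.null(r)) return(NA_real_)
  co <- stats::fft(r) / length(r)
  min(Mod(co[3]) / Mod(co[1]), 1)
}

# Boundary radius function r(theta) at n uniform angles about the centroid.
boundary_radius <- function(mask, n_angles = 256L) {
  boundary <- NULL
  if (inherits(mask, "object_mask")) {
    if (mask$degenerate) return(NULL)
    boundary <- mask$boundary
    mask <- mask$mask
  }
  if (sum(mask) < MIN_MASK_AREA_PX) return(NULL)
  if (is.null(boundary))
    boundary <- EBImage::ocontour(EBImage::Image(mask * 1))[[1]]
  idx <- which(mask, arr.ind = TRUE)
  ctr <- colMeans(idx)
  # ocontour returns 0-based (x, y) = (row-1, col-1) pairs
  bx <- boundary[, 1] + 1 - ctr[1]
  by <- boundary[, 2] + 1 - ctr[2]
  th <- atan2(by, bx) %% (2 * pi)
  rr <- sqrt(bx^2 + by^2)
  bin <- floor(th / (2 * pi) * n_angles) + 1
  bin[bin > n_angles] <- n_angles
  r <- rep(NA_real_, n_angles)
  agg <- tapply(rr, bin, max)
  r[as.integer(names(agg))] <- agg
  if (anyNA(r)) {
    # circular linear interpolation across empty bins
    i <- seq_len(n_angles)
    ok <- !is.na(r)
    if (sum(ok) < 3) return(NULL)
    r <- stats::approx(x = c(i[ok] - n_angles, i[ok], i[ok] + n_angles),
                       y = rep(r[ok], 3), xout = i)$y
  }
  r
}

#' Co-occurrence texture of the masked interior
#'
#' Quantizes the in-mask intensities to 16 gray levels (min-max within the
#' mask), accumulates the gray-level co-occurrence matrix at 1 px offset over
#' the four axial directions (up, down, left, right), symmetrizes and
#' normalizes it, and returns `h_contrast = sum P(i,j) (i-j)^2` and
#' `h_entropy = -sum P log2 P` (bits). A constant interior yields `(0, 0)`.
#'
#' @param event an `image_event`.
#' @param mask an `object_mask` (or logical matrix).
#' @param channel channel whose texture is measured.
#' @param n_levels number of gray levels.
#' @return list with `h_contrast` and `h_entropy`.
#' @export
texture_features <- function(event, mask, channel = "BF", n_levels = 16L) {
  if (inherits(mask, "object_mask")) {
    if (mask$degenerate) return(list(h_contrast = NA_real_, h_entropy = NA_real_))
    mask <- mask$mask
  }
  img <- if (inherits(event, "image_event")) event$channels[[channel]] else event
  if (is.null(img)) stop("channel not present: ", channel)
  v <- img[mask]
  rng <- range(v)
  if (diff(rng) <= 0) return(list(h_contrast = 0, h_entropy = 0))
  q <- matrix(NA_integer_, nrow(img), ncol(img))
  q[mask] <- pmin(n_levels, floor((img[mask] - rng[1]) / diff(rng) * n_levels) + 1L)
  nr <- nrow(q); nc <- ncol(q)
  pairs_i <- c(as.vector(q[-nr, ]), as.vector(q[, -nc]))
  pairs_j <- c(as.vector(q[-1, ]),  as.vector(q[, -1]))
  ok <- !is.na(pairs_i) & !is.na(pairs_j)
  if (!any(ok)) return(list(h_contrast = 0, h_entropy = 0))
  i <- pairs_i[ok]; j <- pairs_j[ok]
  # symmetrize (count both directions)
  tab <- tabulate(c((i - 1L) * n_levels + j, (j - 1L) * n_levels + i),
                  nbins = n_levels^2)
  P <- tab / sum(tab)
  lv <- 1:n_levels
  dif2 <- as.vector(outer(lv, lv, function(a, b) (a - b)^2))  # row = j, col = i
  contrast <- sum(P * dif2)
  nz <- P[P > 0]
  list(h_contrast = as.numeric(contrast),
       h_entropy = as.numeric(-sum(nz * log2(nz))))
}

#' Image sharpness score of a crop
#'
#' Root-mean-square gradient magnitude over the whole crop, normalized by
#' the mean intensity; invariant to multiplicative intensity scaling, and
#' decreasing with defocus blur.
#'
#' @param event an `image_event` (or plain matrix).
#' @param channel channel to assess.
#' @return unitless non-negative score; `NA` for a zero-intensity crop.
#' @export
focus_score <- function(event, channel = "BF") {
  img <- if (inherits(event, "image_event")) event$channels[[channel]] else event
  if (is.null(img)) stop("channel not present: ", channel)
  mu <- mean(img)
  if (mu <= 0) return(NA_real_)
  gx <- img[-1, ] - img[-nrow(img), ]
  gy <- img[, -1] - img[, -ncol(img)]
  sqrt((sum(gx^2) + sum(gy^2)) / (length(gx) + length(gy))) / mu
}

#' Full morphometric feature record of one event
#'
#' Composes segmentation, shape, symmetry, texture, focus and per-channel
#' intensity metrics into one flat record, including the Sickle Score
#' (`symmetry2 / shape_ratio` from the brightfield mask). Degenerate masks
#' yield a flagged record with feature fields `NA`, never silent zeros.
#'
#' @param event an `image_event` with a brightfield channel.
#' @param event_id identifier copied into the record.
#' @return one-row `data.frame` with a `flag` column (`TRUE` = degenerate).
#' @export
featurize <- function(event, event_id = NA_integer_) {
  stopifnot(inherits(event, "image_event"))
  if (!("BF" %in% names(event$channels)))
    stop("featurize requires a brightfield ('BF') channel")
  msk <- segment_event(event, "BF")
  base <- data.frame(event_id = event_id, flag = TRUE,
                     area_um2 = NA_real_, length_um = NA_real_,
                     thickness_min_um = NA_real_, thickness_max_um = NA_real_,
                     shape_ratio = NA_real_, symmetry2 = NA_real_,
                     aspect_ratio = NA_real_, circularity = NA_real_,
                     h_contrast = NA_real_, h_entropy = NA_real_,
                     focus_score = NA_real_, sickle_score = NA_real_)
  for (ch in names(event$channels)) {
    cl <- tolower(ch)
    base[[paste0(cl, "_mean")]] <- NA_real_
    base[[paste0(cl, "_integrated")]] <- NA_real_
  }
  base$focus_score <- focus_score(event, "BF")
  sf <- shape_features(msk, event$pixel_size_um)
  if (isTRUE(sf$degenerate)) return(base)
  s2 <- symmetry2(msk)
  tx <- texture_features(event, msk, "BF")
  base$flag <- FALSE
  base$area_um2 <- sf$area_um2
  base$length_um <- sf$length_um
  base$thickness_min_um <- sf$thickness_min_um
  base$thickness_max_um <- sf$thickness_max_um
  base$shape_ratio <- sf$shape_ratio
  base$symmetry2 <- s2
  base$aspect_ratio <- sf$aspect_ratio
  base$circularity <- sf$circularity
  base$h_contrast <- tx$h_contrast
  base$h_entropy <- tx$h_entropy
  for (ch in names(event$channels)) {
    cl <- tolower(ch)
    v <- event$channels[[ch]][msk$mask]
    base[[paste0(cl, "_mean")]] <- mean(v)
    base[[paste0(cl, "_integrated")]] <- sum(v)
  }
  base$sickle_score <- sickle_score(base)
  base
}

#' Featurize a list of events
#'
#' @param events list of `image_event` objects (e.g. from
#'   [sample_population()]).
#' @param event_ids optional identifiers (defaults to list position).
#' @return `data.frame` with one row per event, in input order.
#' @export
featurize_events <- function(events, event_ids = NULL) {
  if (is.null(event_ids)) event_ids <- seq_along(events)
  rows <- lapply(seq_along(events), function(i)
    featurize(events[[i]], event_ids[i]))
  cols <- unique(unlist(lapply(rows, colnames)))
  rows <- lapply(rows, function(r) {
    r[setdiff(cols, colnames(r))] <- NA_real_
    r[cols]
  })
  do.call(rbind, rows)
}
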