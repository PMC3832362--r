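# Masks, axis/thickness metrics, boundary symmetry, texture, focus.

test_that("segmentation recovers rendered objects and flags blanks", {
  ev <- render_cell(shape_params("disc", size_um = 8), seed = 3,
                    pixel_size_um = 0.2, crop_px = 64)
  msk <- segment_event(ev)
  expect_false(msk$degenerate)
  expect_lt(abs(msk$area_px - pi * 20^2) / (pi * 20^2), 0.10)

  expect_true(segment_event(blank_event())$degenerate)

  agg <- render_cell(shape_params("aggregate", size_um = 8), seed = 2)
  am <- segment_event(agg)
  expect_false(am$degenerate)
  # both touching discs end up in a single component
  expect_gt(am$area_px, 1.6 * pi * (4 / 0.4)^2)
})

test_that("axis and thickness metrics match analytic shapes", {
  circ <- shape_features(raster_circle(20), pixel_size_um = 1)
  expect_lt(abs(circ$length_um - 40), 1)
  expect_gte(circ$shape_ratio, 0.9)

  rect <- shape_features(raster_rect(100, 20), pixel_size_um = 1)
  expect_lt(abs(rect$length_um - 100), 3)
  expect_lt(abs(rect$thickness_min_um - 20), 3)
  expect_lt(abs(rect$shape_ratio - 0.2), 0.04)
})

test_that("crescents always score thinner than matched discs", {
  n_bad <- 0
  for (s in 1:100) {
    fd <- featurize(render_cell(shape_params("disc", size_um = 8), seed = s))
    fc <- featurize(render_cell(shape_params("crescent", size_um = 8,
                                             elongation = 3), seed = s))
    if (!(fc$shape_ratio < fd$shape_ratio)) n_bad <- n_bad + 1
  }
  expect_identical(n_bad, 0)
})

test_that("two-fold symmetry behaves as a Fourier harmonic measure", {
  expect_lte(symmetry2(raster_circle(20)), 0.02)

  # explicit O(n^2) DFT of the same sampled boundary radius
  m <- raster_ellipse(40, 20)
  r <- sicklemetry:::boundary_radius(m, 256)
  k <- 0:255
  c0 <- sum(r) / 256
  c2 <- sum(r * exp(-2i * pi * 2 * k / 256)) / 256
  expect_lt(abs(symmetry2(m) - Mod(c2) / Mod(c0)), 1e-3)

  s_c <- symmetry2(raster_circle(20))
  s_e2 <- symmetry2(raster_ellipse(30, 15))
  s_e3 <- symmetry2(raster_ellipse(36, 12))
  expect_true(s_e3 > s_e2 && s_e2 > s_c)
})

test_that("co-occurrence texture matches hand-built matrices", {
  const <- matrix(0.5, 20, 20)
  mask <- matrix(TRUE, 20, 20)
  tx <- texture_features(const, mask)
  expect_identical(c(tx$h_contrast, tx$h_entropy), c(0, 0))

  # strict 1-px checkerboard: every axial co-occurrence joins the extreme
  # levels 1 and 16
  g <- raster_grid(20)
  chk <- 0.2 + 0.6 * ((g$x + g$y) %% 2 == 0)
  tx2 <- texture_features(chk, mask)
  expect_equal(tx2$h_contrast, 225)
  expect_equal(tx2$h_entropy, 1.0)

  worse <- 0
  for (s in 1:100) {
    set.seed(s)
    noisy <- const + matrix(rnorm(400, 0, 0.05), 20, 20)
    txn <- texture_features(noisy, mask)
    if (!(txn$h_contrast > 0 && txn$h_entropy > 0)) worse <- worse + 1
  }
  expect_identical(worse, 0)
})

test_that("focus score tracks sharpness and ignores intensity scale", {
  sharp <- render_cell(shape_params("disc", size_um = 8), seed = 4)
  blurred <- render_cell(shape_params("disc", size_um = 8,
                                      defocus_sigma_px = 3), seed = 4)
  expect_gt(focus_score(sharp), focus_score(blurred))
  expect_equal(focus_score(sharp$channels$BF),
               focus_score(2 * sharp$channels$BF))
  expect_lt(focus_score(blank_event()), focus_score(sharp))
})

test_that("features scale with pixel size and are rotation robust", {
  m <- raster_ellipse(35, 18)
  f1 <- shape_features(m, pixel_size_um = 1)
  f2 <- shape_features(m, pixel_size_um = 2)
  expect_equal(f2$length_um, 2 * f1$length_um)
  expect_equal(f2$thickness_min_um, 2 * f1$thickness_min_um)
  expect_equal(f2$area_um2, 4 * f1$area_um2)
  expect_equal(f2$shape_ratio, f1$shape_ratio)
  expect_equal(symmetry2(m), symmetry2(m))

  rot <- t(m)[ncol(m):1, ]    # 90 degree rotation
  fr <- shape_features(rot, pixel_size_um = 1)
  expect_lt(abs(fr$length_um - f1$length_um) / f1$length_um, 0.02)
  expect_lt(abs(fr$thickness_min_um - f1$thickness_min_um) /
              f1$thickness_min_um, 0.02)
  expect_lt(abs(symmetry2(rot) - symmetry2(m)), 0.02)
})

test_that("featurize composes the record and conserves the batch", {
  fx <- featurize(render_cell(shape_params("disc", size_um = 8), seed = 9), 1)
  expect_false(fx$flag)
  expect_gte(fx$shape_ratio, 0.9)
  expect_true(all(is.finite(c(fx$h_contrast, fx$h_entropy, fx$symmetry2))))
  expect_true(all(c("bf_mean", "bf_integrated", "dna_integrated",
                    "cd235_mean") %in% colnames(fx)))

  evs <- list(render_cell(shape_params("disc"), seed = 1), blank_event(),
              render_cell(shape_params("crescent", elongation = 3), seed = 2))
  fb <- featurize_events(evs)
  expect_identical(nrow(fb), 3L)
  expect_identical(fb$flag, c(FALSE, TRUE, FALSE))
  # flagged records carry NA features, never silent zeros
  expect_true(is.na(fb$shape_ratio[2]) && is.na(fb$sickle_score[2]))
})

test_that("nucleated events stand far above discs in DNA signal", {
  dna_disc <- vapply(1:40, function(s)
    featurize(render_cell(shape_params("disc"), seed = s))$dna_integrated,
    numeric(1))
  dna_nuc <- vapply(1:10, function(s)
    featurize(render_cell(shape_params("nucleated", size_um = 9.5),
                          seed = s))$dna_integrated, numeric(1))
  expect_gt(min(dna_nuc), quantile(dna_disc, 0.99))
})
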