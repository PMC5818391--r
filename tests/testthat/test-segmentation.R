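test_that("find_max locates the regional maximum", {
  g <- grid_spec(c(6, 6, 6), c(2, 2, 2))
  vals <- array(3, c(6, 6, 6))
  img <- image_volume(vals, g)
  reg <- list(ix = 2:4, iy = 2:4, iz = 2:4)
  expect_equal(find_max(img, reg)$AC_max, 3)  # constant field

  vals[3, 4, 2] <- 9
  img <- image_volume(vals, g)
  mx <- find_max(img, reg)
  expect_equal(mx$AC_max, 9)
  expect_equal(mx$location, c(3L, 4L, 2L))

  single <- list(ix = 5L, iy = 5L, iz = 5L)
  expect_equal(find_max(img, single)$AC_max, 3)
  expect_error(find_max(img, list(ix = integer(0), iy = 1L, iz = 1L)),
               class = "nemaquant_invalid_argument")

  # noiseless blurred sphere: maximum at the sphere-center voxel
  geom <- fx_geom()
  img37 <- fx_pet_noiseless("NB")
  s <- geom$spheres[["sphere_37mm"]]
  mx <- find_max(img37, search_region(geom, img37$grid, "sphere_37mm"))
  ctr <- vapply(1:3, function(ax)
    which.min(abs(s$center[ax] - (img37$grid$origin[ax] +
      (seq_len(img37$grid$dims[ax]) - 1) * img37$grid$spacing[ax]))),
    integer(1))
  expect_true(all(abs(mx$location - ctr) <= 1))
})

test_that("estimate_background averages three clean background ROIs", {
  geom <- fx_geom()
  img5 <- simulate_phantom(geom, fx_pet()$grid, activity_config(10, 2),
                           fx_acq_pet_noiseless(), fractions = fx_fm_pet())
  bg <- estimate_background(img5, geom)
  expect_equal(length(bg$roi_means), 3L)
  expect_equal(bg$BG, 2, tolerance = 1e-9)
  expect_equal(unname(bg$roi_means), rep(2, 3), tolerance = 1e-9)

  expect_equal(estimate_background(fx_pet_noiseless("NB"), geom)$BG, 0,
               tolerance = 1e-12)

  # noisy: the 20-seed average lands within 3 standard errors of truth
  bgs <- vapply(1:20, function(seed)
    estimate_background(add_noise(img5, noise_model("gaussian", 0.02, seed)),
                        geom)$BG, numeric(1))
  expect_lt(abs(mean(bgs) - 2), 3 * stats::sd(bgs) / sqrt(20))

  # ROIs that would touch a compartment are rejected
  expect_error(estimate_background(img5, geom, roi_radius_mm = 40),
               class = "nemaquant_geometry_error")
})

test_that("threshold formulas implement the background-adapted rule", {
  expect_equal(adapted_threshold(0.5, 100, 20), 60)
  expect_equal(adapted_threshold(0.3, 50, 0), plain_threshold(0.3, 50))
  expect_equal(adapted_threshold(1, 100, 20), 100)
  expect_equal(plain_threshold(0.4, 50), 20)
  expect_equal(plain_threshold(0.9, 10), 9)
  expect_error(adapted_threshold(0.5, 10, 20),
               class = "nemaquant_infeasible")
  expect_error(plain_threshold(0.5, 0), class = "nemaquant_infeasible")
  expect_error(plain_threshold(0, 10), class = "nemaquant_invalid_argument")
  expect_error(plain_threshold(1.2, 10), class = "nemaquant_invalid_argument")
  expect_error(adapted_threshold(0.5, 10, -1),
               class = "nemaquant_invalid_argument")
})

test_that("grow_voi matches an independent connected-component oracle", {
  # two-level toy: inner cube 10, outside 1, level 5 -> exactly the cube
  g <- grid_spec(c(10, 10, 10), c(1, 1, 1))
  vals <- array(1, c(10, 10, 10))
  vals[4:6, 4:6, 4:6] <- 10
  img <- image_volume(vals, g)
  reg <- list(ix = 1:10, iy = 1:10, iz = 1:10)
  m <- grow_voi(img, 5, c(5L, 5L, 5L), reg)
  expected <- array(FALSE, c(10, 10, 10)); expected[4:6, 4:6, 4:6] <- TRUE
  expect_equal(m, expected)

  # level below the global minimum -> entire region qualifies
  m_all <- grow_voi(img, 0.5, c(5L, 5L, 5L), reg)
  expect_true(all(m_all))

  expect_error(grow_voi(img, 11, c(5L, 5L, 5L), reg),
               class = "nemaquant_infeasible")

  # 100 seeded random 16^3 images against minimum-label propagation
  g16 <- grid_spec(c(16, 16, 16), c(1, 1, 1))
  reg16 <- list(ix = 1:16, iy = 1:16, iz = 1:16)
  set.seed(20260911)
  for (trial in 1:100) {
    vals <- array(stats::runif(16^3), c(16, 16, 16))
    level <- stats::quantile(vals, 0.7)
    qual <- vals >= level
    seeds <- which(qual)
    seed_idx <- arrayInd(seeds[sample.int(length(seeds), 1)], c(16, 16, 16))
    img16 <- image_volume(vals, g16)
    m <- grow_voi(img16, level, as.integer(seed_idx), reg16)
    expect_identical(m, oracle_component_26(qual, as.integer(seed_idx)))
  }
})

test_that("segment dispatches methods and keeps infeasibility first-class", {
  geom <- fx_geom()
  nb <- fx_pet_noiseless("NB")

  # ct method delegates to the reference mask
  m_ct <- segment(nb, geom, "sphere_28mm", "ct")
  ref <- ct_reference_mask(geom, nb$grid, "sphere_28mm")
  expect_identical(m_ct$mask, ref$mask)

  # adapted with BG = 0 equals the plain threshold
  m_t <- segment(nb, geom, "sphere_28mm", "threshold", T = 0.4)
  m_a <- segment(nb, geom, "sphere_28mm", "adapted", T = 0.4)
  expect_identical(m_a$mask, m_t$mask)

  expect_error(segment(nb, geom, "sphere_28mm", "threshold"),
               class = "nemaquant_invalid_argument")  # T missing
})

test_that("threshold masks are nested in T and adapted is nested in plain", {
  geom <- fx_geom()
  img <- simulate_phantom(geom, fx_pet()$grid, fx_activity(5),
                          fx_pet()$acq, seed = 7, fractions = fx_fm_pet())
  for (sid in c("sphere_37mm", "sphere_22mm")) {
    prev <- NULL
    for (T in c(0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9)) {
      res <- segment(img, geom, sid, "threshold", T = T)
      if (!is_feasible(res)) next
      if (!is.null(prev)) expect_true(all(res$mask <= prev))
      prev <- res$mask
    }
    # adapted level >= plain level at equal T when BG > 0
    p <- segment(img, geom, sid, "threshold", T = 0.5)
    a <- segment(img, geom, sid, "adapted", T = 0.5)
    expect_true(is_feasible(p) && is_feasible(a))
    expect_gte(a$absolute_level, p$absolute_level)
    expect_true(all(a$mask <= p$mask))
  }
})

test_that("the 50% isocontour volume converges for large diameter/FWHM", {
  # diameter >= 6 FWHM: use a 3-mm PSF so the three largest spheres qualify
  geom <- fx_geom()
  acq <- acquisition_config("pet-like", psf_fwhm = c(3, 3, 3),
                            noise = noise_model("none"))
  img <- simulate_phantom(geom, fx_pet()$grid, fx_activity("NB"), acq,
                          fractions = fx_fm_pet())
  for (sid in c("sphere_22mm", "sphere_28mm", "sphere_37mm")) {
    res <- segment(img, geom, sid, "threshold", T = 0.5)
    q <- quantify(img, res)
    tv <- geom$spheres[[sid]]$true_volume_cm3
    expect_lt(abs(q$volume_cm3 - tv) / tv, 0.05)
  }
})

test_that("low-contrast SPECT spheres are reported infeasible, not fatal", {
  geom <- fx_geom()
  sp <- fx_spect()
  act <- fx_activity(1.25)
  for (seed in 1:3) {
    img <- simulate_phantom(geom, sp$grid, act, sp$acq, seed = seed,
                            fractions = fx_fm_spect())
    conc <- counts_to_concentration(img, sp$acq$sensitivity_factor,
                                    sp$acq$duration_s)
    for (T in seq(0.1, 0.9, by = 0.1)) {
      res <- segment(conc, geom, "sphere_10mm", "threshold", T = T)
      expect_false(is_feasible(res))
      expect_s3_class(res, "infeasible_segmentation")
    }
  }
})
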