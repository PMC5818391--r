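test_that("sensitivity factor calibration round-trips the simulator", {
  ug <- uniform_phantom_geometry()
  sp <- fx_spect()
  ufm <- fx("fm_uniform_spect", voxelize(ug, sp$grid))
  acq0 <- sp$acq; acq0$noise <- noise_model("none")
  # background filled at 5 kBq/mL, spect-like with factor 10 cps/MBq voxel
  uimg <- fx("uimg_spect",
             simulate_phantom(ug, sp$grid, activity_config(0, 5), acq0,
                              fractions = ufm))
  cal <- sensitivity_factor(uimg, 5 / 1000, acq0$duration_s)
  expect_equal(cal$sensitivity_factor, 10, tolerance = 1e-3)

  # doubling the assumed concentration at fixed counts halves the factor
  cal2 <- sensitivity_factor(uimg, 10 / 1000, acq0$duration_s)
  expect_equal(cal2$sensitivity_factor, cal$sensitivity_factor / 2)

  # noisy uniform images (sigma 5%, seeds 1..20): factor within 2%
  facs <- vapply(1:20, function(seed) {
    n <- add_noise(uimg, noise_model("gaussian", 0.05, seed))
    sensitivity_factor(n, 5 / 1000, acq0$duration_s)$sensitivity_factor
  }, numeric(1))
  expect_true(all(abs(facs - 10) / 10 < 0.02))

  expect_error(sensitivity_factor(uimg, 0, acq0$duration_s),
               class = "nemaquant_invalid_argument")
  pet_img <- fx_pet_noiseless("NB")
  expect_error(sensitivity_factor(pet_img, 5e-3, 180),
               class = "nemaquant_invalid_argument")  # needs counts
})

test_that("counts_to_concentration inverts the simulator calibration", {
  ug <- uniform_phantom_geometry()
  sp <- fx_spect()
  acq0 <- sp$acq; acq0$noise <- noise_model("none")
  uimg <- fx("uimg_spect",
             simulate_phantom(ug, sp$grid, activity_config(0, 5), acq0,
                              fractions = voxelize(ug, sp$grid)))
  conc <- counts_to_concentration(uimg, acq0$sensitivity_factor,
                                  acq0$duration_s)
  expect_equal(conc$value_unit, "kBq/mL")
  interior <- uimg$values == max(uimg$values)
  expect_lt(max(abs(conc$values[interior] - 5)), 1e-6)

  # zero image maps to zero; doubling the factor halves concentrations
  z <- image_volume(array(0, sp$grid$dims), sp$grid, value_unit = "counts")
  expect_true(all(counts_to_concentration(z, 10, 100)$values == 0))
  half <- counts_to_concentration(uimg, 2 * acq0$sensitivity_factor,
                                  acq0$duration_s)
  expect_equal(half$values, conc$values / 2)
  expect_error(counts_to_concentration(conc, 10, 100),
               class = "nemaquant_invalid_argument")  # already kBq/mL
})

test_that("quantify reports max, mean, and voxel-count volume", {
  g <- grid_spec(c(4, 1, 1), c(9.3, 9.3, 9.3))
  img <- image_volume(array(c(4, 8, 1, 1), c(4, 1, 1)), g)
  mask <- array(c(TRUE, TRUE, FALSE, FALSE), c(4, 1, 1))
  q <- quantify(img, mask)
  expect_equal(q$AC_max, 8)
  expect_equal(q$AC_mean, 6)
  expect_equal(q$volume_cm3, 2 * voxel_volume_cm3(g))
  # 33 SPECT voxels -> 26.5 cm^3 (0.80 cm^3/voxel)
  expect_equal(round(33 * voxel_volume_cm3(fx_spect()$grid), 1), 26.5)

  const <- image_volume(array(3, c(4, 1, 1)), g)
  qc <- quantify(const, mask)
  expect_equal(qc$AC_max, qc$AC_mean)
  expect_error(quantify(img, array(FALSE, c(4, 1, 1))),
               class = "nemaquant_infeasible")
})

test_that("recovery_coefficient is measured over true", {
  expect_equal(recovery_coefficient(93, 100), 0.93)
  expect_equal(recovery_coefficient(5, 5), 1)
  expect_equal(recovery_coefficient(0, 7), 0)
  expect_error(recovery_coefficient(1, 0),
               class = "nemaquant_invalid_argument")
})

test_that("sweep_thresholds enumerates sphere x T with flags intact", {
  geom <- fx_geom()
  nb <- fx_pet_noiseless("NB")
  sw <- fx("sweep_nb", sweep_thresholds(nb, geom, fx_activity("NB"),
                                        "threshold"))
  expect_equal(nrow(sw), 6 * 9)
  expect_true(all(sw$T %in% seq(0.1, 0.9, by = 0.1)))

  # volume non-increasing in T per sphere (feasible rows)
  for (sid in unique(sw$sphere_id)) {
    rows <- sw[sw$sphere_id == sid & sw$feasible, ]
    rows <- rows[order(rows$T), ]
    if (nrow(rows) > 1) expect_true(all(diff(rows$volume_cm3) <= 1e-9))
  }

  # at SBR 5:1 the low plain thresholds sit below background and flood:
  # such rows are flagged infeasible but kept
  s5 <- fx_pet_noiseless(5)
  sw5 <- sweep_thresholds(s5, geom, fx_activity(5), "threshold",
                          T_grid = c(0.1, 0.5), sphere_ids = "sphere_37mm")
  expect_equal(nrow(sw5), 2)
  expect_false(sw5$feasible[sw5$T == 0.1])
  expect_true(sw5$feasible[sw5$T == 0.5])
  expect_true(all(is.na(sw5$volume_cm3[!sw5$feasible])))

  expect_error(sweep_thresholds(nb, geom, fx_activity("NB"), "threshold",
                                T_grid = c(0.5, 1.0)),
               class = "nemaquant_invalid_argument")
})

test_that("select_best_threshold follows the median rule with low-T ties", {
  # synthetic table: T = 0.4 has RC_mean = 1 for 4 of 5 spheres
  mk <- function(sphere, T, rc, vol, tv) data.frame(
    sphere_id = sphere, diameter_mm = NA_real_, method = "threshold",
    T = T, sbr = 5, seed = 1L, feasible = TRUE, AC_max = NA_real_,
    AC_mean = NA_real_, volume_cm3 = vol, true_volume_cm3 = tv,
    RC_max = NA_real_, RC_mean = rc, stringsAsFactors = FALSE)
  tab <- rbind(
    do.call(rbind, lapply(1:5, function(i)
      mk(paste0("s", i), 0.4, if (i < 5) 1.0 else 1.5, 10, 10))),
    do.call(rbind, lapply(1:5, function(i)
      mk(paste0("s", i), 0.6, 1.2, 10, 10))))
  class(tab) <- c("sweep_table", "data.frame")
  best <- select_best_threshold(tab, "concentration")
  expect_equal(best$T_star, 0.4)

  # exact tie -> lower T
  tie <- rbind(mk("s1", 0.3, 1.1, 10, 10), mk("s1", 0.5, 1.1, 10, 10))
  class(tie) <- c("sweep_table", "data.frame")
  expect_equal(select_best_threshold(tie, "concentration")$T_star, 0.3)
  expect_equal(select_best_threshold(tie, "volume")$T_star, 0.3)

  none <- mk("s1", 0.4, 1, 10, 10); none$feasible <- FALSE
  class(none) <- c("sweep_table", "data.frame")
  expect_error(select_best_threshold(none), class = "nemaquant_infeasible")
})

test_that("fine volume sweep puts the 37-mm best threshold near 40%", {
  geom <- fx_geom()
  nb <- fx_pet_noiseless("NB")
  swf <- sweep_thresholds(nb, geom, fx_activity("NB"), "threshold",
                          T_grid = seq(0.25, 0.55, by = 0.01),
                          sphere_ids = "sphere_37mm")
  best <- select_best_threshold(swf, "volume")
  expect_gte(best$T_star, 0.35)
  expect_lte(best$T_star, 0.45)
})

test_that("recovery_curve orders spheres and reproduces known directions", {
  geom <- fx_geom()
  nb <- fx_pet_noiseless("NB")
  s5 <- fx_pet_noiseless(5)
  rc_nb <- recovery_curve(nb, geom, fx_activity("NB"), "ct", "mean")
  rc_s5 <- recovery_curve(s5, geom, fx_activity(5), "ct", "mean")
  expect_equal(nrow(rc_nb), 6)
  expect_true(all(diff(rc_nb$diameter_mm) > 0))
  # pure spill-out: CT-based RC_mean < 1 for every sphere, increasing with
  # diameter; background spill-in raises RC at SBR 5:1
  expect_true(all(rc_nb$RC < 1))
  expect_true(all(diff(rc_nb$RC) > 0))
  expect_true(all(rc_s5$RC >= rc_nb$RC))
})
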