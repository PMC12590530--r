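test_that("calibration arithmetic and idempotence", {
  z <- seq(0, 1000, length.out = 100)
  cv <- force_curve(z, rep(1, 100),
                    cantilever_model(spring_constant = 0.03,
                                     deflection_sensitivity = 50))
  cal <- calibrate(cv)
  expect_equal(cal$deflection_nm, rep(50, 100))   # 1 V x 50 nm/V
  expect_equal(cal$force_nn, rep(1.5, 100))       # 0.03 N/m x 50 nm
  expect_identical(calibrate(cal), cal)           # idempotent

  zero <- calibrate(force_curve(z, rep(0, 100)))
  expect_true(all(zero$force_nn == 0))
})

test_that("calibration refuses missing or invalid constants", {
  z <- seq(0, 1000, length.out = 100)
  cv <- force_curve(z, rep(1, 100))
  expect_error(calibrate(cv, sensitivity = -1), "refused")
  expect_error(calibrate(cv, spring_constant = 0), "refused")
})

test_that("calibrate is the exact inverse of decalibrate", {
  cv <- simulate_force_curve(2, seed = 4)
  raw <- decalibrate(cv)
  expect_false(raw$calibrated)
  back <- calibrate(raw)
  expect_equal(back$deflection_nm, cv$deflection_nm)
  expect_equal(back$force_nn, cv$force_nn)
})

test_that("contact point: exact on noiseless, within jitter bound on noisy", {
  cv <- simulate_force_curve(1.5, noise = noise_none(), seed = 1)
  ct <- detect_contact_point(cv)
  i_true <- which(cv$z_nm == cv$truth$contact_z0_nm)
  expect_lte(abs(ct$index - i_true), 1)

  # noisy: z0 within 3x jitter sd of truth in >= 95% of seeds (scaled to 60
  # seeds here; jitter sd 20 nm)
  nm <- noise_model()
  hits <- vapply(1:60, function(s) {
    cvn <- simulate_force_curve(1.5, noise = nm, seed = s)
    ctn <- detect_contact_point(cvn)
    isTRUE(ctn$contact) &&
      abs(ctn$z0_nm - cvn$truth$contact_z0_nm) <= 3 * nm$contact_point_jitter_sd
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("pure-baseline curves are flagged non-contact", {
  z <- seq(0, 4000, length.out = 300)
  set.seed(8)
  noisy <- force_curve(z, 0.001 * z + rnorm(300, 0, 0.5), calibrated = TRUE)
  expect_false(detect_contact_point(noisy)$contact)
  clean <- force_curve(z, 0.001 * z, calibrated = TRUE)
  expect_false(detect_contact_point(clean)$contact)
  expect_equal(fit_sneddon(noisy)$flag, "non_contact")
})

test_that("Sneddon fit matches the brute-force (z0, E) grid oracle", {
  for (E0 in c(0.8, 5)) {
    cv <- simulate_force_curve(E0, noise = noise_none())
    fit <- fit_sneddon(cv)
    oracle <- brute_force_sneddon(cv, z0_range = c(1000, 3000),
                                  E_range = c(E0 / 4, E0 * 4))
    expect_lt(abs(fit$E_kpa - oracle$E_kpa) / oracle$E_kpa, 1e-3)
    expect_lt(abs(fit$E_kpa - E0) / E0, 1e-9)
  }
})

test_that("fitted E scales linearly with the curve's force scale", {
  cv <- simulate_force_curve(1, noise = noise_none())
  f1 <- fit_sneddon(cv)
  # doubling E at fixed geometry: simulate at 2 kPa, same everything else
  cv2 <- simulate_force_curve(2, noise = noise_none())
  f2 <- fit_sneddon(cv2)
  expect_equal(f2$E_kpa / f1$E_kpa, 2, tolerance = 1e-9)
})

test_that("fitted-E bias decreases monotonically over a noise ladder", {
  bias_at <- function(noise_sd) {
    fits <- vapply(1:40, function(s) {
      fit_sneddon(simulate_force_curve(
        1, noise = noise_model(deflection_noise_sd = noise_sd,
                               baseline_tilt = 0,
                               contact_point_jitter_sd = 0),
        seed = s))$E_kpa
    }, numeric(1))
    abs(mean(fits) - 1)
  }
  ladder <- c(bias_at(2), bias_at(0.5), bias_at(0.05))
  expect_true(all(diff(ladder) < 0) || ladder[3] < 1e-3)
  expect_lt(ladder[3], ladder[1])
})

test_that("analyze_map applies QC and flags unusable maps", {
  fm <- simulate_force_map(stage_mechanics("control"), grid_points = 6,
                           n_samples = 300, seed = 5)
  em <- analyze_map(fm)
  expect_s3_class(em, "elasticity_map")
  expect_gte(sum(em$qc == "ok"), round(36 * 240 / 256))
  expect_true(em$usable)

  # noiseless map: zero rejections, per-pixel E equals the truth grid
  fm0 <- simulate_force_map(stage_mechanics("control"), grid_points = 4,
                            noise = noise_none(), n_samples = 300, seed = 6)
  em0 <- analyze_map(fm0)
  expect_equal(sum(em0$qc != "ok"), 0)
  expect_equal(em0$E_kpa, fm0$true_E_kpa, tolerance = 1e-8,
               ignore_attr = TRUE)

  # map of pure-baseline curves: nothing passes, map flagged
  z <- seq(0, 4000, length.out = 300)
  set.seed(2)
  flat <- lapply(1:16, function(i) {
    force_curve(z, 0.001 * z + rnorm(300, 0, 0.5), calibrated = TRUE,
                grid_position = c((i - 1) %/% 4 + 1, (i - 1) %% 4 + 1))
  })
  emf <- analyze_map(flat)
  expect_equal(sum(emf$qc == "ok"), 0)
  expect_false(emf$usable)
})

test_that("curve container round-trips values exactly", {
  des <- study_design(
    data.frame(stage_label = "control", n_specimens = 1L,
               timepoint_days = 3L, sex = "m"),
    maps_per_specimen = 2, grid_points = 3, seed = 12
  )
  coh <- simulate_cohort(des, n_samples = 120)
  sp <- coh$specimens[[1]]
  dir <- withr::local_tempdir()
  path <- write_curve_container(sp, dir)
  back <- read_curve_container(path)
  expect_equal(back$specimen_id, sp$specimen_id)
  expect_length(back$maps, 2)
  for (mi in 1:2) {
    for (ci in seq_along(sp$maps[[mi]]$curves)) {
      a <- sp$maps[[mi]]$curves[[ci]]; b <- back$maps[[mi]]$curves[[ci]]
      expect_identical(b$z_nm, a$z_nm)
      expect_identical(b$deflection_nm, a$deflection_nm)
      expect_equal(b$truth$true_E_kpa, a$truth$true_E_kpa)
    }
    # moduli survive the round trip through the container identically
    expect_identical(analyze_map(back$maps[[mi]])$E_kpa,
                     analyze_map(sp$maps[[mi]])$E_kpa)
  }
})
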