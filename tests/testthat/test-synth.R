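test_that("force-curve forward model inverts exactly without noise", {
  cv <- simulate_force_curve(1, noise = noise_none(), seed = 1)
  fit <- fit_sneddon(cv)
  expect_true(fit$converged)
  expect_lt(abs(fit$E_kpa - 1), 1e-9)
  expect_equal(fit$contact_point_z0, cv$truth$contact_z0_nm)
})

test_that("termination indentation matches the closed-form Sneddon depth", {
  # delta = sqrt(F * pi * (1 - nu^2) / (2 tan(theta) E)) at the 1.8 nN cap
  delta_closed <- sqrt(1.8e-9 * pi * (1 - 0.5^2) / (2 * tan(20 * pi / 180) * 1000))
  expect_equal(delta_closed * 1e9, 2413.759, tolerance = 1e-4)
  expect_equal(sneddon_depth_at_force(1.8, 1), delta_closed * 1e9,
               tolerance = 1e-12)
  # numerical root-find on the forward curve agrees
  cv <- simulate_force_curve(1, noise = noise_none())
  k <- cv$cantilever$spring_constant
  x <- cv$deflection_nm
  delta <- (cv$z_nm - cv$truth$contact_z0_nm) - x
  at_cap <- which.min(abs(k * x - 1.8))
  expect_equal(delta[at_cap], delta_closed * 1e9, tolerance = 1e-3)
})

test_that("hydrogel reference standards are recovered within 5%", {
  # scaled down here (20 seeds); the acceptance suite runs the full 100
  for (E0 in c(0.5, 1.0)) {
    fits <- vapply(1:20, function(s) {
      fit_sneddon(simulate_force_curve(E0, seed = s))$E_kpa
    }, numeric(1))
    expect_lt(abs(mean(fits) - E0) / E0, 0.05)
  }
})

test_that("rejects non-positive modulus or force", {
  expect_error(simulate_force_curve(0), "positive")
  expect_error(simulate_force_curve(-1), "positive")
  expect_error(simulate_force_curve(1, max_force_nn = 0), "max_force")
})

test_that("default force map geometry matches the acquisition protocol", {
  fm <- simulate_force_map(stage_mechanics("control"), seed = 1)
  expect_length(fm$curves, 256)
  expect_equal(fm$pixel_size_um, 1.25)
  expect_equal(dim(fm$true_E_kpa), c(16L, 16L))
})

test_that("degenerate mixture (hep_weight = 0) draws all moduli from the LEP", {
  tis <- tissue_mechanics_model(hep_weight = 0)
  fm <- simulate_force_map(tis, curves = FALSE, seed = 2)
  # LEP at mode 2 kPa, log-sd 0.25: all values far below the 30 kPa HEP
  expect_true(all(fm$E_kpa < 2 * 10^(5 * 0.25)))
  hm <- attr(fm$E_kpa, "hep_mask")
  expect_true(is.null(hm) || sum(hm) == 0)
})

test_that("empirical HEP proportion tracks hep_weight over pooled draws", {
  for (w in c(0.1, 0.3, 0.5)) {
    tis <- tissue_mechanics_model(hep_weight = w)
    set.seed(42)
    vals <- unlist(lapply(1:15, function(i) {
      simulate_force_map(tis, curves = FALSE)$E_kpa
    }))
    expect_gte(length(vals), 3840)
    # HEP component sits at 30 kPa (log-sd 0.3); 10 kPa splits the modes
    prop <- mean(vals > 10)
    se <- sqrt(w * (1 - w) / length(vals))
    expect_lt(abs(prop - w), 3 * se + 0.01)
  }
})

test_that("cohort simulation is deterministic and stage-ordered", {
  gr <- data.frame(stage_label = c("control", "chronic_d21"),
                   n_specimens = c(2L, 2L), timepoint_days = c(21L, 21L),
                   sex = "mixed")
  des <- study_design(gr, maps_per_specimen = 2, grid_points = 8, seed = 7)
  c1 <- simulate_cohort(des, curves = FALSE)
  c2 <- simulate_cohort(des, curves = FALSE)
  expect_identical(c1, c2)

  # closed-form mixture means order control < chronic_d21, and realized
  # cohort means follow
  m_ctrl <- mixture_mean_kpa(stage_mechanics("control"))
  m_d21 <- mixture_mean_kpa(stage_mechanics("chronic_d21"))
  expect_lt(m_ctrl, m_d21)
  mean_of <- function(coh, grp) {
    mean(unlist(lapply(coh$specimens[coh$manifest$group == grp],
                       function(sp) lapply(sp$maps, `[[`, "E_kpa"))))
  }
  expect_lt(mean_of(c1, "control"), mean_of(c1, "chronic_d21"))
})

test_that("a 15-map specimen carries up to 3840 curves", {
  des <- study_design(
    data.frame(stage_label = "control", n_specimens = 1L,
               timepoint_days = 14L, sex = "f"),
    maps_per_specimen = 15, seed = 3
  )
  coh <- simulate_cohort(des, curves = FALSE)
  n_px <- sum(vapply(coh$specimens[[1]]$maps,
                     function(m) length(m$E_kpa), numeric(1)))
  expect_equal(n_px, 3840)
})

test_that("polarized image generator hits its ground-truth fractions", {
  img <- simulate_polarized_image(0.12, 0.03, seed = 11)
  n_tissue <- sum(img$class_map >= 1)
  expect_equal(sum(img$class_map == 2) / n_tissue, 0.12, tolerance = 0.01)
  expect_equal(sum(img$class_map == 3) / n_tissue, 0.03, tolerance = 0.01)
  expect_error(simulate_polarized_image(0.7, 0.5), "fractions")
  expect_error(simulate_polarized_image(-0.1, 0), "fractions")
})

test_that("SHG stack: single frame, noiseless stack, and averaging identity", {
  st1 <- simulate_shg_stack(1, noise_sd = 5, seed = 1)
  expect_equal(dim(st1$frames)[3], 1)
  expect_equal(average_shg(st1)$averaged, st1$frames[, , 1])

  st0 <- simulate_shg_stack(5, noise_sd = 0, seed = 1)
  for (i in 1:5) expect_equal(st0$frames[, , i], st0$signal)
})

test_that("identical seeds reproduce identical images and stacks", {
  expect_identical(simulate_polarized_image(0.1, 0.02, seed = 5),
                   simulate_polarized_image(0.1, 0.02, seed = 5))
  expect_identical(simulate_shg_stack(3, noise_sd = 2, seed = 9),
                   simulate_shg_stack(3, noise_sd = 2, seed = 9))
})

test_that("model constructors enforce their invariants", {
  expect_error(cantilever_model(spring_constant = 0), "spring_constant")
  expect_error(cantilever_model(half_open_angle_theta = 95), "half_open_angle")
  expect_error(tissue_mechanics_model(hep_weight = 1.2), "hep_weight")
  expect_error(tissue_mechanics_model(lep_mode_kpa = 5, hep_mode_kpa = 3,
                                      hep_weight = 0.2), "exceed")
  expect_error(noise_model(deflection_noise_sd = -1), ">= 0")
  expect_error(study_design(data.frame(stage_label = "control",
                                       n_specimens = 0L,
                                       timepoint_days = 3L, sex = "m")),
               "n_specimens")
})
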