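test_that("simulated curves follow the pyramidal Hertz closed form", {
  # tan(25 deg)/sqrt(2) / (1 - 0.25) * delta^2, delta = 1 um, E = 1 kPa
  k_hand <- tan(25 * pi / 180) / sqrt(2) * 1 / (1 - 0.5^2)
  expect_equal(hertz_force(1, 1, 0.5, 25), k_hand)
  expect_equal(hertz_force(-2, 1), 0)

  cv <- simulate_force_curve(curve_sim_config(contact_z_um = 2, z_range_um = 6))
  pre <- cv$z_um > 2
  expect_true(all(cv$signal[pre] == 0))                  # pure baseline region
  i <- which.min(abs((2 - cv$z_um) - 1))                  # delta closest to 1 um
  expect_equal(cv$signal[i], k_hand * (2 - cv$z_um[i])^2)
  expect_true(all(diff(cv$z_um) < 0))                     # approach is monotone
})

test_that("the approach stops at the force setpoint", {
  cv <- simulate_force_curve(curve_sim_config(true_modulus_kPa = 50,
                                              contact_z_um = 2))
  expect_lte(max(cv$signal[-length(cv$signal)]), 5)
  expect_gte(max(cv$signal), 5)
})

test_that("sensitivity calibration inverts the contact slope of a rigid ramp", {
  # slope of 1 V/um corresponds to 1000 nm/V
  cfg <- curve_sim_config(rigid = TRUE, mode = "raw", contact_z_um = 2,
                          z_range_um = 4, spring_constant_N_per_m = 0.06,
                          sensitivity_nm_per_V = 1000)
  sens <- calibrate_sensitivity(simulate_force_curve(cfg))
  expect_equal(as.numeric(sens), 1000, tolerance = 1e-9)
  expect_equal(attr(sens, "slope_V_per_um"), -1, tolerance = 1e-9)

  noisy <- curve_sim_config(rigid = TRUE, mode = "raw", contact_z_um = 2,
                            z_range_um = 4, sensitivity_nm_per_V = 50,
                            noise_sd_nN = 0.05, seed = 8)
  sens2 <- calibrate_sensitivity(simulate_force_curve(noisy))
  expect_lt(abs(as.numeric(sens2) - 50) / 50, 0.02)

  set.seed(9)  # a ramp that never reaches the dish: pure noise signal
  flat <- structure(list(z_um = seq(4, 0, length.out = 200),
                         signal = rnorm(200, 0, 0.002), mode = "raw",
                         segment = "approach",
                         spring_constant_N_per_m = 0.06),
                    class = "force_curve")
  expect_error(calibrate_sensitivity(flat), "calibration error")
  flat$signal <- rep(0, 200)
  expect_error(calibrate_sensitivity(flat), "calibration error")
})

test_that("baseline offset and slope are removed from the non-contact region", {
  cv <- simulate_force_curve(curve_sim_config(
    baseline_offset_nN = 0.5, baseline_slope_nN_per_um = 0.1,
    contact_z_um = 2))
  fsc <- preprocess_curve(cv)
  nc <- fsc$separation_um > attr(fsc, "contact_z_estimate_um") + 0.2
  expect_lt(abs(mean(fsc$force_nN[nc])), 1e-9)

  clean <- simulate_force_curve(curve_sim_config(contact_z_um = 2))
  fsc2 <- preprocess_curve(clean)
  pre <- fsc2$separation_um > 2
  expect_true(all(abs(fsc2$force_nN[pre]) < 1e-9))
  # force mode carries no deflection, so separation is the piezo height
  expect_equal(sort(fsc2$separation_um), sort(clean$z_um))
})

test_that("curves that never leave the baseline cannot be preprocessed", {
  flat <- simulate_force_curve(curve_sim_config(contact_z_um = 2))
  flat$z_um <- flat$z_um[flat$z_um > 2.2]
  flat$signal <- rep(0, length(flat$z_um))
  # all-baseline curve: contact never detected, fit rejected downstream
  fsc <- preprocess_curve(flat)
  fit <- fit_hertz_pyramid(fsc)
  expect_false(fit$converged)
})

test_that("noiseless Hertz fits recover the modulus across three decades", {
  for (E in c(0.1, 1, 10, 100)) {
    fit <- fit_simulated_curve(curve_sim_config(true_modulus_kPa = E,
                                                contact_z_um = 2))
    expect_true(fit$converged)
    expect_lt(abs(fit$E_eff_kPa - E) / E, 1e-6)
    expect_lt(abs(fit$contact_z_um - 2), 1e-4)
  }
})

test_that("profiled fit matches an independent 2-D grid search", {
  cases <- expand.grid(E = c(0.27, 1, 3.6, 8, 30),
                       contact = c(1.4, 2.3))
  for (i in seq_len(nrow(cases))) {
    cfg <- curve_sim_config(true_modulus_kPa = cases$E[i],
                            contact_z_um = cases$contact[i],
                            baseline_offset_nN = 0.2,
                            baseline_slope_nN_per_um = 0.05)
    fsc <- preprocess_curve(simulate_force_curve(cfg))
    fit <- fit_hertz_pyramid(fsc)
    grid <- oracle_grid_hertz(fsc)
    # same optimum within the oracle's grid resolution
    expect_lt(abs(fit$contact_z_um - grid$contact),
              2 * diff(range(fsc$separation_um)) / 240)
    expect_lt(abs(fit$E_eff_kPa - grid$E) / grid$E, 0.02)
    expect_lte(fit$rss, grid$rss + 1e-9)  # profiled fit is never worse
  }
})

test_that("fitted modulus scales linearly with force", {
  fsc <- preprocess_curve(simulate_force_curve(
    curve_sim_config(true_modulus_kPa = 2, contact_z_um = 2,
                     noise_sd_nN = 0.05, seed = 13)))
  fit1 <- fit_hertz_pyramid(fsc)
  fsc3 <- fsc
  fsc3$force_nN <- 3 * fsc3$force_nN
  fit3 <- fit_hertz_pyramid(fsc3)
  expect_equal(fit3$E_eff_kPa, 3 * fit1$E_eff_kPa, tolerance = 1e-8)
})

test_that("tilt correction and angle convention rescale the modulus as documented", {
  fsc <- preprocess_curve(simulate_force_curve(
    curve_sim_config(true_modulus_kPa = 1, contact_z_um = 2)))
  base <- fit_hertz_pyramid(fsc)$E_eff_kPa
  tilted <- fit_hertz_pyramid(fsc, fit_params(tilt_correction = TRUE))$E_eff_kPa
  expect_equal(tilted, base * cos(10 * pi / 180)^2, tolerance = 1e-8)
  edge <- fit_hertz_pyramid(fsc, fit_params(angle_convention = "edge"))$E_eff_kPa
  expect_equal(edge, base * (tan(25 * pi / 180) / sqrt(2)) /
                 (tan(25 * pi / 180) / 2), tolerance = 1e-8)
})

test_that("raw-mode curves round-trip through calibration and fitting", {
  rigid <- simulate_force_curve(curve_sim_config(
    rigid = TRUE, mode = "raw", contact_z_um = 2, z_range_um = 4))
  sens <- as.numeric(calibrate_sensitivity(rigid))
  soft <- simulate_force_curve(curve_sim_config(
    true_modulus_kPa = 0.27, mode = "raw", contact_z_um = 2))
  fit <- fit_hertz_pyramid(preprocess_curve(soft, sensitivity_nm_per_V = sens))
  expect_lt(abs(fit$E_eff_kPa - 0.27) / 0.27, 1e-3)
})

test_that("region aggregation computes means, sems and the stiffness fold", {
  tab <- data.frame(E_eff_kPa = c(3.6, 3.6, 3.6, 0.27, 0.27, 0.27),
                    converged = TRUE,
                    region = rep(c("CV", "outside"), each = 3))
  rs <- aggregate_region(tab, fold = c("CV", "outside"))
  expect_equal(rs$fold, 3.6 / 0.27)         # 13.33, the ~13-fold difference
  expect_equal(round(rs$fold), 13)

  hand <- aggregate_region(data.frame(E_eff_kPa = c(1, 2, 3), converged = TRUE,
                                      region = "r"), fold = "r")
  expect_equal(hand$stats$mean_E_kPa, 2)
  expect_equal(hand$stats$sem_E_kPa, sd(c(1, 2, 3)) / sqrt(3))
  expect_equal(hand$fold, 1)                # region against itself

  single <- aggregate_region(data.frame(E_eff_kPa = 5, converged = TRUE,
                                        region = "r"), fold = "r")
  expect_true(is.na(single$stats$sem_E_kPa))

  tab$converged[4:6] <- FALSE
  expect_error(aggregate_region(tab), "no converged fits")
})

test_that("aggregation ignores fit order and excludes rejected fits", {
  tab <- data.frame(E_eff_kPa = c(1, 2, 3, 100), converged = c(TRUE, TRUE, TRUE, FALSE),
                    region = "r")
  shuffled <- tab[c(3, 1, 4, 2), ]
  a <- aggregate_region(tab, fold = "r")
  b <- aggregate_region(shuffled, fold = "r")
  expect_equal(a$stats$mean_E_kPa, 2)       # the rejected 100 never contributes
  expect_equal(a$stats$mean_E_kPa, b$stats$mean_E_kPa)
  expect_equal(a$stats$rejected, 1)
})

test_that("ensembles of noisy curves recover the true stiffness fold", {
  set.seed(31)
  fits <- function(E, region, n = 25) hertz_fit_table(
    lapply(seq_len(n), function(i) fit_simulated_curve(
      curve_sim_config(true_modulus_kPa = E, noise_sd_nN = 0.25,
                       contact_z_um = 2))), region)
  rs <- aggregate_region(rbind(fits(3.6, "CV"), fits(0.27, "outside")),
                         fold = c("CV", "outside"))
  st <- rs$stats
  rel_se <- sqrt((st$sem_E_kPa[1] / st$mean_E_kPa[1])^2 +
                 (st$sem_E_kPa[2] / st$mean_E_kPa[2])^2)
  expect_lt(abs(rs$fold - 3.6 / 0.27), 3 * rs$fold * rel_se + 1e-9)
})
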