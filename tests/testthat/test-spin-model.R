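test_that("R2,eff from amplitudes matches its closed form and propagates errors", {
  expect_identical(r2eff_from_intensities(1, 1, 0.04), 0)
  expect_equal(r2eff_from_intensities(exp(-1), 1, 0.04), 25)
  expect_equal(r2eff_from_intensities(0.5, 1, 0.02), log(2) / 0.02)
  v <- r2eff_from_intensities(0.5, 1, 0.02, i_err = 0.01, i0_err = 0.02)
  expect_equal(attr(v, "err"), sqrt((0.01 / 0.5)^2 + 0.02^2) / 0.02)
  expect_error(r2eff_from_intensities(-1, 1, 0.04),
               class = "kexdyn_invalid_intensity")
})

test_that("schedules validate their timing", {
  expect_error(cpmg_schedule(0.04, c(25, 33)), class = "kexdyn_schedule_error")
  expect_silent(cpmg_schedule(0.04, c(25, 50, 1000)))
  expect_error(cest_schedule(-0.1, 25, 1:10), class = "kexdyn_schedule_error")
  expect_error(cest_schedule(0.15, 0, 1:10), class = "kexdyn_schedule_error")
})

test_that("CPMG dispersion is flat without shift difference or excited state", {
  sch <- cpmg_schedule(0.04, nu_default)
  p <- two_site_params(400, 0.1)
  r_flat <- simulate_cpmg(residue_spin_params(1, dw_ppm = c("15N" = 0), r2 = 15),
                          p, f850n, sch)
  expect_equal(r_flat, rep(15, length(nu_default)), tolerance = 1e-9)
  r_single <- simulate_cpmg(residue_spin_params(1, dw_ppm = c("15N" = 3), r2 = 15),
                            two_site_params(400, 0), f850n, sch)
  expect_equal(r_single, rep(15, length(nu_default)), tolerance = 1e-9)
})

test_that("matrix propagation agrees with the Carver-Richards closed form", {
  sch <- cpmg_schedule(0.04, nu_default)
  for (k_ex in c(50, 200, 400, 1000, 3000))
    for (p1 in c(0.01, 0.05, 0.1, 0.2))
      for (dw in c(0.5, 2, 6)) {
        res <- residue_spin_params(1, dw_ppm = c("15N" = dw), r2 = 15)
        num <- simulate_cpmg(res, two_site_params(k_ex, p1), f850n, sch,
                             detection = "dominant")
        cr <- carver_richards(k_ex, p1, dw * f850n$ppm2rad, 15, nu_default)
        expect_lt(max(abs(num - cr) / cr), 0.02)
      }
})

test_that("dispersion decays to the population-averaged R2 at fast pulsing", {
  p <- two_site_params(400, 0.1)
  res <- residue_spin_params(1, dw_ppm = c("15N" = 3), r2 = 15)
  hi <- simulate_cpmg(res, p, f850n, cpmg_schedule(0.04, 100 * 400))
  expect_lt(abs(hi - 15) / 15, 0.01)
  # and the dispersion amplitude is non-negative across the curve
  curve <- simulate_cpmg(res, p, f850n, cpmg_schedule(0.04, nu_default))
  expect_gte(curve[1] - curve[length(curve)], 0)
  expect_true(all(curve >= 15 - 1e-6))
})

test_that("fast-exchange limit reproduces the Luz-Meiboom expression", {
  dw_ppm <- 0.5
  dw_rad <- dw_ppm * f850n$ppm2rad          # ~270 rad/s
  k_ex <- 60 * dw_rad                       # deep fast exchange
  p <- two_site_params(k_ex, 0.1)
  res <- residue_spin_params(1, dw_ppm = c("15N" = dw_ppm), r2 = 15)
  num <- simulate_cpmg(res, p, f850n, cpmg_schedule(0.04, nu_default))
  lm <- luz_meiboom(k_ex, 0.1, dw_rad, 15, nu_default)
  rex_num <- num - 15
  rex_lm <- lm - 15
  expect_lt(max(abs(rex_num - rex_lm) / rex_lm), 0.05)
})

test_that("CEST profiles show dips at the ground and excited resonances", {
  offsets <- seq(108, 130, by = 0.25)
  sch <- cest_schedule(0.15, 25, offsets)
  res <- residue_spin_params(1, omega_ppm = c("15N" = 115),
                             dw_ppm = c("15N" = 4), r1 = 1.3, r2 = 12)
  prof <- simulate_cest(res, two_site_params(300, 0.09), f850n, sch)
  # on-resonance saturation can nutate z slightly below zero
  expect_true(all(prof >= -0.05 & prof <= 1 + 1e-9))
  expect_lt(abs(offsets[which.min(prof)] - 115), 0.26)
  away <- abs(offsets - 115) > 2
  minor <- offsets[away][which.min(prof[away])]
  expect_lt(abs(minor - 119), 0.26)
  # single state: only the major dip
  prof1 <- simulate_cest(res, two_site_params(300, 0), f850n, sch)
  away1 <- abs(offsets - 115) > 2
  expect_gt(min(prof1[away1]), 0.9)
  expect_lt(abs(offsets[which.min(prof1)] - 115), 0.26)
  # no saturation time, no dip
  expect_equal(simulate_cest(res, two_site_params(300, 0.09), f850n,
                             cest_schedule(0, 25, offsets)),
               rep(1, length(offsets)))
})

test_that("CEST dip positions are equivariant under a ppm reference shift", {
  offsets <- seq(108, 130, by = 0.5)
  res <- residue_spin_params(1, omega_ppm = c("15N" = 115),
                             dw_ppm = c("15N" = 4), r1 = 1.3, r2 = 12)
  p <- two_site_params(300, 0.09)
  prof <- simulate_cest(res, p, f850n, cest_schedule(0.15, 25, offsets))
  res_shift <- residue_spin_params(1, omega_ppm = c("15N" = 115 + 3),
                                   dw_ppm = c("15N" = 4), r1 = 1.3, r2 = 12)
  prof_shift <- simulate_cest(res_shift, p, f850n,
                              cest_schedule(0.15, 25, offsets + 3))
  expect_equal(prof, prof_shift, tolerance = 1e-10)
})

test_that("CEST propagation matches an independent stiff integrator", {
  offsets <- seq(110, 124, by = 1)
  sch <- cest_schedule(0.15, 25, offsets)
  res <- residue_spin_params(1, omega_ppm = c("15N" = 115),
                             dw_ppm = c("15N" = 4), r1 = 1.3, r2 = 12)
  p <- two_site_params(300, 0.09)
  prof <- simulate_cest(res, p, f850n, sch)
  oracle <- cest_ode_oracle(res, p, f850n, sch)
  expect_equal(prof, oracle, tolerance = 1e-6)
})

test_that("the proton dispersion engine uses the proton shift difference", {
  sch <- cpmg_schedule(0.04, nu_default)
  p <- two_site_params(400, 0.1)
  res <- residue_spin_params(1, omega_ppm = c("15N" = 118, "1HN" = 8.2),
                             dw_ppm = c("15N" = 4, "1HN" = 0), r2 = 15)
  r_h <- simulate_cpmg(res, p, f850h, sch)
  expect_equal(r_h, rep(15, length(nu_default)), tolerance = 1e-9)
  res$dw_ppm[["1HN"]] <- 0.5
  r_h2 <- simulate_cpmg(res, p, f850h, sch)
  expect_gt(r_h2[1] - r_h2[length(r_h2)], 1)
})
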