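test_that("Rex is the dispersion amplitude and drives residue selection", {
  d <- data.frame(residue_id = rep(1:2, each = 3),
                  nu_cpmg = rep(c(50, 200, 1000), 2),
                  r2eff = c(28, 22, 16, 15, 15, 15), err = 0.2)
  ds <- dispersion_dataset(d, f850n, cpmg_schedule(0.04, c(50, 200, 1000)))
  rex <- estimate_rex(ds)
  expect_equal(rex$rex[rex$residue_id == 1], 12)
  expect_equal(rex$rex[rex$residue_id == 2], 0)
  one <- dispersion_dataset(
    data.frame(residue_id = 1, nu_cpmg = 50, r2eff = 20, err = 0.2),
    f850n, cpmg_schedule(0.04, 50))
  expect_error(estimate_rex(one), class = "kexdyn_insufficient_data")
})

test_that("the Rex filter matches brute-force forward simulation", {
  spec <- truth_spec(two_site_params(400, 0.1015), n_residues = 12,
                     regions = list(switch_like = 3:8), noise = 0, seed = 5)
  obs <- generate_observations(spec, cpmg = list(
    list(field = f850n, schedule = cpmg_schedule(0.04, nu_default))))
  got <- estimate_rex(obs$dispersions[[1]])
  # oracle: forward-simulate each generated residue and threshold directly
  tr <- obs$truth
  want <- vapply(seq_len(nrow(tr)), function(i) {
    res <- residue_spin_params(i, dw_ppm = c("15N" = tr$dw_n[i]),
                               r2 = tr$r2_850[i])
    cv <- simulate_cpmg(res, spec$params, f850n,
                        cpmg_schedule(0.04, nu_default))
    cv[1] - cv[length(cv)] > 5
  }, logical(1))
  expect_identical(got$residue_id[got$rex > 5], tr$residue_id[want])
})

test_that("noiseless data are fit back to the generating parameters", {
  obs <- small_cpmg_study(two_site_params(400, 0.1015), n_residues = 8,
                          noise = 0, seed = 2,
                          fields = list(f850n, f600n))
  fit <- fit_global_two_state(obs$dispersions,
                              control = list(grid_kex = c(150, 800),
                                             grid_p1 = c(0.05, 0.15)))
  expect_lt(abs(fit$params$k_ex - 400) / 400, 1e-3)
  expect_lt(abs(fit$params$p1 - 0.1015) / 0.1015, 1e-3)
  expect_true(fit$converged)
  # microscopic rates stay consistent with the globals
  expect_equal(fit$params$k21 + fit$params$k12, fit$params$k_ex)
  # fitted |dw| match the generating values
  m <- merge(fit$residues, obs$truth, by = "residue_id")
  expect_lt(max(abs(abs(m$dw_15N) - abs(m$dw_n))), 0.01)
})

test_that("fits are invariant to residue and dataset ordering", {
  obs <- small_cpmg_study(two_site_params(350, 0.09), n_residues = 6,
                          noise = 0.02, seed = 9,
                          fields = list(f850n, f600n))
  init <- two_site_params(300, 0.07)
  f1 <- fit_global_two_state(obs$dispersions, init = init)
  # shuffle rows and swap dataset order
  shuf <- lapply(rev(obs$dispersions), function(ds) {
    set.seed(1); ds$data <- ds$data[sample(nrow(ds$data)), ]; ds
  })
  f2 <- fit_global_two_state(shuf, init = init)
  expect_equal(f1$params$k_ex, f2$params$k_ex, tolerance = 1e-6)
  expect_equal(f1$params$p1, f2$params$p1, tolerance = 1e-6)
  expect_equal(f1$residues$dw_15N, f2$residues$dw_15N, tolerance = 1e-6)
})

test_that("opposite shift-difference signs are CPMG-degenerate but CEST-distinct", {
  p <- two_site_params(300, 0.09)
  sch <- cpmg_schedule(0.04, nu_default)
  plus <- residue_spin_params(1, omega_ppm = c("15N" = 118),
                              dw_ppm = c("15N" = 3), r2 = 14)
  minus <- residue_spin_params(1, omega_ppm = c("15N" = 118),
                               dw_ppm = c("15N" = -3), r2 = 14)
  expect_equal(simulate_cpmg(plus, p, f850n, sch),
               simulate_cpmg(minus, p, f850n, sch), tolerance = 1e-10)
  cs <- cest_schedule(0.15, 25, seq(108, 128, 0.5))
  prof_p <- simulate_cest(plus, p, f850n, cs)
  prof_m <- simulate_cest(minus, p, f850n, cs)
  expect_gt(max(abs(prof_p - prof_m)), 0.1)
})

test_that("single-state data never produce a confident excited state", {
  spec <- truth_spec(two_site_params(400, 0.1), n_residues = 6,
                     regions = list(), noise = 0.02, seed = 3)
  obs <- generate_observations(spec, cpmg = list(
    list(field = f850n, schedule = cpmg_schedule(0.04, nu_default))))
  # flat profiles: everything falls below the Rex threshold
  expect_error(fit_global_two_state(obs$dispersions),
               class = "kexdyn_selection_error")
  # forcing a fit flags non-identifiability or returns a tiny population
  fit <- fit_global_two_state(obs$dispersions, rex_threshold = -1,
                              init = two_site_params(400, 0.1),
                              control = list(outer_maxit = 60))
  expect_true(fit$non_identifiable || fit$params$p1 < 0.02)
})

test_that("derived microscopic rates propagate the fitted covariance", {
  d <- derived_rates(two_site_params(400, 0.1015))
  expect_equal(d$value[d$rate == "k21"], 40.6)
  expect_equal(d$value[d$rate == "k12"], 359.4)
  d2 <- derived_rates(two_site_params(301, 0.09))
  expect_equal(d2$value, c(27.09, 273.91))
  d0 <- derived_rates(two_site_params(100, 0))
  expect_equal(d0$value, c(0, 100))
})

test_that("the residue bootstrap is deterministic and tight on clean data", {
  obs <- small_cpmg_study(two_site_params(400, 0.1), n_residues = 7,
                          noise = 0, seed = 6, fields = list(f850n))
  fit <- fit_global_two_state(obs$dispersions,
                              init = two_site_params(380, 0.09))
  b1 <- bootstrap_uncertainties(fit, n_replicates = 50, seed = 4)
  b2 <- bootstrap_uncertainties(fit, n_replicates = 50, seed = 4)
  expect_identical(b1$bootstrap$replicates, b2$bootstrap$replicates)
  # noiseless data: resampling residues moves nothing
  expect_lt(b1$bootstrap$sd[["k_ex"]] / fit$params$k_ex, 1e-3)
  expect_lt(b1$bootstrap$sd[["p1"]] / fit$params$p1, 1e-3)
  # derived-rate errors follow from the replicate covariance
  dr <- derived_rates(b1)
  expect_true(all(is.finite(dr$err)))
})

test_that("bootstrap spread scales with the measurement noise", {
  fits <- lapply(c(0.015, 0.03), function(noise) {
    obs <- small_cpmg_study(two_site_params(400, 0.1), n_residues = 7,
                            noise = noise, seed = 12, fields = list(f850n))
    fit <- fit_global_two_state(obs$dispersions,
                                init = two_site_params(380, 0.09),
                                control = list(outer_maxit = 80))
    bootstrap_uncertainties(fit, n_replicates = 50, seed = 2)
  })
  ratio <- fits[[2]]$bootstrap$sd[["k_ex"]] / fits[[1]]$bootstrap$sd[["k_ex"]]
  expect_gt(ratio, 1); expect_lt(ratio, 4)
})
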