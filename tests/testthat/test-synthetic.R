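test_that("generators are pure functions of spec and seed", {
  spec <- truth_spec(two_site_params(400, 0.1), n_residues = 20,
                     regions = list(switch_like = 5:12), seed = 3)
  t1 <- generate_exchange_truth(spec)
  t2 <- generate_exchange_truth(spec)
  expect_identical(t1, t2)
  o1 <- generate_observations(spec, cpmg = list(
    list(field = f850n, schedule = cpmg_schedule(0.04, nu_default))))
  o2 <- generate_observations(spec, cpmg = list(
    list(field = f850n, schedule = cpmg_schedule(0.04, nu_default))))
  expect_identical(o1$dispersions[[1]]$data, o2$dispersions[[1]]$data)
  # a different seed changes the draws
  spec2 <- truth_spec(two_site_params(400, 0.1), n_residues = 20,
                      regions = list(switch_like = 5:12), seed = 4)
  expect_false(identical(generate_exchange_truth(spec2), t1))
})

test_that("region structure and overlap validation", {
  expect_error(truth_spec(two_site_params(400, 0.1),
                          regions = list(a = 1:10, b = 5:12)), "overlap")
  spec <- truth_spec(two_site_params(400, 0.1), n_residues = 15,
                     regions = list(), seed = 1)
  tr <- generate_exchange_truth(spec)
  expect_true(all(abs(tr$dw_n) < 0.3))
})

test_that("drawn shift differences match the declared distributions", {
  spec <- truth_spec(two_site_params(400, 0.1), n_residues = 1000,
                     regions = list(big = 1:1000), seed = 6)
  tr <- generate_exchange_truth(spec)
  ks_n <- suppressWarnings(ks.test(abs(tr$dw_n), "punif", 1, 5))
  ks_hn <- suppressWarnings(ks.test(abs(tr$dw_hn), "punif", 0.1, 0.6))
  expect_gt(ks_n$p.value, 0.01)
  expect_gt(ks_hn$p.value, 0.01)
  expect_true(all(tr$r2_850 >= 12 & tr$r2_850 <= 20))
})

test_that("zero-noise observations equal the forward simulation exactly", {
  spec <- truth_spec(two_site_params(400, 0.1), n_residues = 6,
                     regions = list(switch_like = 2:4), noise = 0, seed = 2)
  obs <- generate_observations(
    spec,
    cpmg = list(list(field = f850n, schedule = cpmg_schedule(0.04, nu_default))),
    cest = list(list(field = f850n,
                     schedule = cest_schedule(0.15, 25, seq(104, 136, 2)))))
  tr <- obs$truth
  d <- obs$dispersions[[1]]$data
  for (rid in tr$residue_id) {
    res <- residue_spin_params(rid, omega_ppm = c("15N" = tr$omega_n[rid]),
                               dw_ppm = c("15N" = tr$dw_n[rid]),
                               r1 = tr$r1[rid], r2 = tr$r2_850[rid])
    expect_equal(d$r2eff[d$residue_id == rid],
                 simulate_cpmg(res, spec$params, f850n,
                               obs$dispersions[[1]]$schedule),
                 tolerance = 1e-10)
  }
  c1 <- obs$cests[[1]]$data
  rid <- 3
  res <- residue_spin_params(rid, omega_ppm = c("15N" = tr$omega_n[rid]),
                             dw_ppm = c("15N" = tr$dw_n[rid]),
                             r1 = tr$r1[rid], r2 = tr$r2_850[rid])
  expect_equal(c1$intensity[c1$residue_id == rid],
               simulate_cest(res, spec$params, f850n, obs$cests[[1]]$schedule),
               tolerance = 1e-10)
})

test_that("generated noise is unbiased", {
  # mean of noisy R2,eff minus truth across many realizations stays small
  sch <- cpmg_schedule(0.04, c(50, 100, 400, 1000))
  tr <- generate_exchange_truth(
    truth_spec(two_site_params(400, 0.1), n_residues = 6,
               regions = list(r = 1:4), seed = 1))
  truth_curves <- unlist(lapply(seq_len(nrow(tr)), function(i) {
    res <- residue_spin_params(i, dw_ppm = c("15N" = tr$dw_n[i]),
                               r2 = tr$r2_850[i])
    simulate_cpmg(res, two_site_params(400, 0.1), f850n, sch)
  }))
  devs <- vapply(1:200, function(s) {
    spec <- truth_spec(two_site_params(400, 0.1), n_residues = 6,
                       regions = list(r = 1:4), noise = 0.02, seed = s)
    obs <- generate_observations(spec, truth = tr,
                                 cpmg = list(list(field = f850n, schedule = sch)))
    mean(obs$dispersions[[1]]$data$r2eff - truth_curves)
  }, numeric(1))
  expect_lt(abs(mean(devs)), 0.05)
})

test_that("toy ensembles carry an exact analytic order-parameter truth", {
  toy <- generate_toy_ensemble(2, n_residues = 8,
                               rotate = list(list(residue = 5,
                                                  angles_deg = c(0, 90))))
  expect_equal(toy$s2_true$s2[toy$s2_true$residue_id == 5], 0.25,
               tolerance = 1e-12)
  one <- generate_toy_ensemble(1, n_residues = 5)
  expect_equal(one$s2_true$s2, rep(1, nrow(one$s2_true)), tolerance = 1e-12)
  # cross-module: the ensemble machinery reproduces the analytic truth
  toy3 <- generate_toy_ensemble(3, n_residues = 10, rotate = list(
    list(residue = 4, angles_deg = c(0, 30, 75)),
    list(residue = 7, angles_deg = c(20, 0, 50))))
  w <- c(0.5, 0.25, 0.25)
  s2_mod <- s2_from_ensemble(weighted_ensemble(toy3$conformers, w))
  s2_true <- s2_pair_sum(lapply(toy3$conformers, kexdyn:::nh_vectors), w)
  expect_equal(s2_mod$s2, s2_true, tolerance = 1e-9)
})
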