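test_that("amide hydrogens are built with ideal geometry", {
  cf <- build_amide_hydrogens(conformer(kexdyn:::ideal_backbone(5), "ideal"))
  a <- cf$atoms
  for (rid in 2:5) {
    n <- unlist(a[a$residue_id == rid & a$atom == "N", c("x", "y", "z")])
    h <- unlist(a[a$residue_id == rid & a$atom == "H", c("x", "y", "z")])
    ca <- unlist(a[a$residue_id == rid & a$atom == "CA", c("x", "y", "z")])
    cp <- unlist(a[a$residue_id == rid - 1 & a$atom == "C", c("x", "y", "z")])
    expect_equal(sqrt(sum((h - n)^2)), 1.02, tolerance = 1e-9)
    ang <- function(u, v) acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
    a1 <- ang(h - n, cp - n)
    a2 <- ang(h - n, ca - n)
    expect_equal(a1, a2, tolerance = 1e-6)   # bisector placement
    expect_gt(a1, 110); expect_lt(a1, 130)
  }
  # chain N-terminus is skipped
  expect_false(any(a$residue_id == 1 & a$atom == "H"))
})

test_that("prolines receive no amide hydrogen", {
  at <- kexdyn:::ideal_backbone(4)
  at$resname[at$residue_id == 3] <- "PRO"
  cf <- build_amide_hydrogens(conformer(at, "with-pro"))
  expect_false(any(cf$atoms$residue_id == 3 & cf$atoms$atom == "H"))
  expect_true(any(cf$atoms$residue_id == 2 & cf$atoms$atom == "H"))
})

test_that("hydrogen construction is rotation-equivariant", {
  base <- conformer(kexdyn:::ideal_backbone(4), "base")
  R <- random_rotation(99)
  rot <- rotate_conformer(base, R, shift = c(1, -2, 3))
  h1 <- build_amide_hydrogens(base)
  h2 <- build_amide_hydrogens(rot)
  xyz1 <- as.matrix(h1$atoms[h1$atoms$atom == "H", c("x", "y", "z")])
  xyz2 <- as.matrix(h2$atoms[h2$atoms$atom == "H", c("x", "y", "z")])
  expect_equal(sweep(xyz1 %*% t(R), 2, c(1, -2, 3), `+`), xyz2,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("superposition recovers rigid transformations exactly", {
  cf <- conformer(kexdyn:::ideal_backbone(6), "ref")
  # identity
  out <- superpose(list(cf, cf))
  expect_lt(attr(out, "rmsd")[2], 1e-12)
  # pure translation
  tr <- cf; tr$atoms[c("x", "y", "z")] <- tr$atoms[c("x", "y", "z")] + 5
  out <- superpose(list(cf, tr))
  expect_lt(attr(out, "rmsd")[2], 1e-12)
  # rotation + translation comes back to the reference coordinates
  rot <- rotate_conformer(cf, random_rotation(7), shift = c(3, 1, -4))
  out <- superpose(list(cf, rot))
  expect_lt(attr(out, "rmsd")[2], 1e-12)
  expect_equal(out[[2]]$atoms$x, cf$atoms$x, tolerance = 1e-9)
})

test_that("superposition is at least as good as a brute-force rotation search", {
  set.seed(14)
  A <- matrix(rnorm(12), 4, 3)
  B <- matrix(rnorm(12), 4, 3)
  k <- kexdyn:::kabsch(A, B)
  fitted <- sweep(sweep(A, 2, k$mobile_center) %*% t(k$R), 2, k$fixed_center, `+`)
  rmsd_kabsch <- sqrt(mean(rowSums((fitted - B)^2)))
  expect_lte(rmsd_kabsch, grid_rmsd(A, B) + 1e-12)
  tiny <- conformer(kexdyn:::ideal_backbone(1), "tiny")
  expect_error(superpose(list(tiny, tiny), residues = 1, atoms = c("N", "CA")),
               class = "kexdyn_superposition_error")
})

test_that("ensemble order parameters follow the orientational tensor formula", {
  # a single conformer is rigid by construction
  toy1 <- generate_toy_ensemble(1, n_residues = 6)
  s2 <- s2_from_ensemble(weighted_ensemble(toy1$conformers, 1))
  expect_equal(s2$s2, rep(1, nrow(s2)), tolerance = 1e-12)
  # two equal-weight conformers with perpendicular N-H vectors
  toy2 <- generate_toy_ensemble(2, n_residues = 6,
                                rotate = list(list(residue = 4,
                                                   angles_deg = c(0, 90))))
  s2 <- s2_from_ensemble(weighted_ensemble(toy2$conformers, c(0.5, 0.5)))
  expect_equal(s2$s2[s2$residue_id == 4], 0.25, tolerance = 1e-12)
  # isotropic vectors average to zero order
  set.seed(6)
  vecs <- lapply(1:400, function(i) {
    v <- rnorm(3); matrix(v / sqrt(sum(v^2)), 1, 3, dimnames = list("2", NULL))
  })
  s2_iso <- s2_pair_sum(vecs, rep(1 / 400, 400))
  expect_lt(abs(s2_iso), 0.05)
})

test_that("the tensor contraction equals the brute-force pair sum", {
  toy <- generate_toy_ensemble(4, n_residues = 10, rotate = list(
    list(residue = 4, angles_deg = c(0, 35, 80, 120)),
    list(residue = 7, angles_deg = c(10, 0, 55, 90))))
  w <- c(0.4, 0.3, 0.2, 0.1)
  s2_tensor <- s2_from_ensemble(weighted_ensemble(toy$conformers, w))
  s2_brute <- s2_pair_sum(lapply(toy$conformers, kexdyn:::nh_vectors), w)
  expect_equal(s2_tensor$s2, s2_brute, tolerance = 1e-12)
})

test_that("ensemble S2 is invariant under a common rigid rotation", {
  toy <- generate_toy_ensemble(3, n_residues = 8, rotate = list(
    list(residue = 5, angles_deg = c(0, 45, 100))))
  w <- c(0.5, 0.3, 0.2)
  s2_a <- s2_from_ensemble(weighted_ensemble(toy$conformers, w))
  R <- random_rotation(3)
  rot <- lapply(toy$conformers, rotate_conformer, R = R)
  s2_b <- s2_from_ensemble(weighted_ensemble(rot, w))
  expect_equal(s2_a$s2, s2_b$s2, tolerance = 1e-12)
})

test_that("duplicating a conformer and splitting its weight changes nothing", {
  toy <- generate_toy_ensemble(2, n_residues = 8, rotate = list(
    list(residue = 5, angles_deg = c(0, 70))))
  s2_a <- s2_from_ensemble(weighted_ensemble(toy$conformers, c(0.6, 0.4)))
  dup <- c(toy$conformers, toy$conformers[2])
  s2_b <- s2_from_ensemble(weighted_ensemble(dup, c(0.6, 0.25, 0.15)))
  expect_equal(s2_a$s2, s2_b$s2, tolerance = 1e-12)
})

test_that("population fitting recovers known weights", {
  toy <- generate_toy_ensemble(3, n_residues = 14, rotate = list(
    list(residue = 5, angles_deg = c(0, 60, 120)),
    list(residue = 8, angles_deg = c(0, 90, 30)),
    list(residue = 11, angles_deg = c(0, 40, 80))))
  w_true <- c(0.5, 0.3, 0.2)
  exp_prof <- s2_from_ensemble(weighted_ensemble(toy$conformers, w_true))
  set.seed(1)
  exp_prof$s2 <- pmin(1, exp_prof$s2 + rnorm(nrow(exp_prof), 0, 0.02))
  pf <- fit_populations(toy$conformers, exp_prof)
  expect_true(all(abs(pf$weights - w_true) <= 0.03))
  expect_equal(sum(pf$weights), 1, tolerance = 1e-9)
  expect_equal(nrow(pf$top), 10)

  # profile identical to candidate A gives all weight to A
  pure <- s2_from_ensemble(weighted_ensemble(toy$conformers, c(1, 0, 0)))
  pf1 <- fit_populations(toy$conformers, pure)
  expect_gt(pf1$weights[1], 0.99)

  # adding a candidate can only improve (or match) the achievable fit
  pf2 <- fit_populations(toy$conformers[1:2], exp_prof)
  expect_lte(pf$rmsd, pf2$rmsd + 1e-12)

  # indistinguishable candidates are reported as degenerate
  expect_warning(
    fit_populations(list(toy$conformers[[1]], toy$conformers[[1]]), exp_prof),
    "degenerate")
})
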