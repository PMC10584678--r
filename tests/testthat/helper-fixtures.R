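# Shared fixtures and independent oracles for the test suite.

f850n <- field_context(850, "15N")
f600n <- field_context(600, "15N")
f850h <- field_context(850, "1HN")

nu_default <- c(25, 50, 100, 200, 400, 600, 800, 1000)

# A small CPMG-only synthetic study (fast to fit).
small_cpmg_study <- function(params, n_residues = 8, noise = 0.02, seed = 1,
                             fields = list(f850n),
                             region = 2:min(6, n_residues - 1)) {
  spec <- truth_spec(params, n_residues = n_residues,
                     regions = list(switch_like = region),
                     noise = noise, seed = seed)
  generate_observations(
    spec,
    cpmg = lapply(fields, function(f)
      list(field = f, schedule = cpmg_schedule(0.04, nu_default))))
}

# Independent CEST oracle: direct numerical integration of the two-site
# Bloch-McConnell differential system with a stiff integrator.
cest_ode_oracle <- function(residue, params, field, schedule) {
  dg_all <- (residue$omega_ppm[[field$nucleus]] - schedule$offsets_ppm) *
    field$ppm2rad
  de_all <- (residue$omega_ppm[[field$nucleus]] + residue$dw_ppm[[field$nucleus]] -
               schedule$offsets_ppm) * field$ppm2rad
  w1 <- 2 * pi * schedule$b1_hz
  p1 <- params$p1; p2 <- 1 - p1
  k21 <- p1 * params$k_ex; k12 <- p2 * params$k_ex
  r1 <- residue$r1; r2 <- residue$r2
  vapply(seq_along(dg_all), function(i) {
    dg <- dg_all[i]; de <- de_all[i]
    deriv <- function(t, y, parms) {
      xg <- y[1]; yg <- y[2]; zg <- y[3]; xe <- y[4]; ye <- y[5]; ze <- y[6]
      list(c(
        -r2 * xg - dg * yg - k21 * xg + k12 * xe,
        dg * xg - r2 * yg - w1 * zg - k21 * yg + k12 * ye,
        w1 * yg - r1 * (zg - p2) - k21 * zg + k12 * ze,
        -r2 * xe - de * ye - k12 * xe + k21 * xg,
        de * xe - r2 * ye - w1 * ze - k12 * ye + k21 * yg,
        w1 * ye - r1 * (ze - p1) - k12 * ze + k21 * zg))
    }
    y0 <- c(0, 0, p2, 0, 0, p1)
    out <- deSolve::lsoda(y0, c(0, schedule$t_ex), deriv, NULL,
                          rtol = 1e-10, atol = 1e-12, maxsteps = 1e6)
    out[2, 4] / p2
  }, numeric(1))
}

# Brute-force rigid-body superposition oracle: best RMSD over a coarse
# random sample of rotations (upper bound on the optimum).
grid_rmsd <- function(mobile, fixed, n = 500, seed = 42) {
  set.seed(seed)
  mc <- sweep(mobile, 2, colMeans(mobile))
  fc <- sweep(fixed, 2, colMeans(fixed))
  best <- Inf
  for (i in seq_len(n)) {
    q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
    R <- matrix(c(
      1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]), 2 * (q[2] * q[4] + q[1] * q[3]),
      2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[1] * q[2]),
      2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)),
      3, 3, byrow = TRUE)
    v <- sqrt(mean(rowSums((mc %*% t(R) - fc)^2)))
    if (v < best) best <- v
  }
  best
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]), 2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)),
    3, 3, byrow = TRUE)
}

rotate_conformer <- function(conf, R, shift = c(0, 0, 0)) {
  xyz <- as.matrix(conf$atoms[c("x", "y", "z")]) %*% t(R)
  conf$atoms[c("x", "y", "z")] <- sweep(xyz, 2, shift, `+`)
  conf
}
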