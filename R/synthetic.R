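# Synthetic-data generators.  These emulate the statistical structure of a
# two-state exchanging GTPase study: globally shared (k_ex, p1),
# region-localized shift differences, Gaussian measurement noise on
# intensities and rates, NASR rate differences proportional to a ground
# truth S2 profile, and toy conformer ensembles with analytically known S2.
# All generators are pure functions of (spec, seed).

#' Ground-truth specification for a synthetic exchange study
#'
#' @param params A [two_site_params] object: the generating globals.
#' @param label Variant-like label.
#' @param n_residues Sequence length (default 169, so the 169-residue
#'   GTPase region presets apply unchanged).
#' @param regions Named list of residue ranges carrying large shift
#'   differences ("Switch-like", "P-loop-like"); must not overlap.
#' @param dw_n_range,dw_hn_range Magnitude ranges (ppm) for 15N / amide 1H
#'   shift differences inside the regions (signs drawn at random).
#' @param dw_background Upper bound (ppm) on |dw| outside the regions.
#' @param r2_range,r1_range Intrinsic rate ranges, 1/s.
#' @param noise Relative Gaussian noise amplitude on intensities and rates.
#' @param seed Integer seed; identical specs give identical outputs.
#' @return Object of class `truth_spec`.
#' @export
truth_spec <- function(params, label = "synthetic", n_residues = 169,
                       regions = list(ploop_like = 8:13, switch1_like = 29:38,
                                      switch2_like = 54:72),
                       dw_n_range = c(1, 5), dw_hn_range = c(0.1, 0.6),
                       dw_background = 0.3,
                       r2_range = c(12, 20), r1_range = c(1.0, 1.6),
                       noise = 0.02, seed = 1) {
  stopifnot(inherits(params, "two_site_params"))
  all_r <- unlist(regions)
  if (anyDuplicated(all_r))
    stop("region definitions overlap", call. = FALSE)
  if (length(all_r) > 0 && (min(all_r) < 1 || max(all_r) > n_residues))
    stop("regions outside 1..n_residues", call. = FALSE)
  structure(list(params = params, label = label, n_residues = n_residues,
                 regions = regions, dw_n_range = dw_n_range,
                 dw_hn_range = dw_hn_range, dw_background = dw_background,
                 r2_range = r2_range, r1_range = r1_range,
                 noise = noise, seed = as.integer(seed)),
            class = "truth_spec")
}

#' Draw per-residue ground-truth exchange parameters
#'
#' Inside the designated regions, |dw| is uniform in the spec's ranges with
#' random signs; outside, |dw| is uniform below the background bound.
#' Ground shifts and intrinsic rates are drawn uniformly in typical amide
#' windows.  Deterministic per seed.
#'
#' @param spec A [truth_spec].
#' @return Data frame with one row per residue: `residue_id`, `in_region`,
#'   `omega_n`, `omega_hn` (ppm), `dw_n`, `dw_hn` (signed ppm), `r1`,
#'   `r2_850`, `r2_600` (1/s).
#' @export
generate_exchange_truth <- function(spec) {
  stopifnot(inherits(spec, "truth_spec"))
  set.seed(child_seed(spec$seed, "exchange-truth"))
  n <- spec$n_residues
  in_region <- seq_len(n) %in% unlist(spec$regions)
  runifr <- function(n, r) stats::runif(n, r[1], r[2])
  sign_draw <- sample(c(-1, 1), n, replace = TRUE)
  dw_n <- ifelse(in_region,
                 sign_draw * runifr(n, spec$dw_n_range),
                 sign_draw * stats::runif(n, 0, spec$dw_background))
  sign_hn <- sample(c(-1, 1), n, replace = TRUE)
  dw_hn <- ifelse(in_region,
                  sign_hn * runifr(n, spec$dw_hn_range),
                  sign_hn * stats::runif(n, 0, spec$dw_background / 10))
  data.frame(
    residue_id = seq_len(n), in_region = in_region,
    omega_n = runifr(n, c(105, 130)), omega_hn = runifr(n, c(7, 9.5)),
    dw_n = dw_n, dw_hn = dw_hn,
    r1 = runifr(n, spec$r1_range),
    r2_850 = runifr(n, spec$r2_range),
    r2_600 = runifr(n, spec$r2_range)
  )
}

truth_residue <- function(tr, i) {
  residue_spin_params(
    tr$residue_id[i],
    omega_ppm = c("15N" = tr$omega_n[i], "1HN" = tr$omega_hn[i]),
    dw_ppm = c("15N" = tr$dw_n[i], "1HN" = tr$dw_hn[i]),
    r1 = tr$r1[i], r2 = tr$r2_850[i])
}

#' Generate noisy synthetic observations from a ground truth
#'
#' Noiseless forward curves from the Bloch-McConnell engine are perturbed
#' by the spec's noise model: relative Gaussian noise on CPMG signal
#' amplitudes (propagated through the log into R2,eff and its error) and
#' absolute Gaussian noise of the same amplitude on normalized CEST
#' intensities.
#'
#' @param spec A [truth_spec].
#' @param truth Data frame from [generate_exchange_truth()]; regenerated
#'   from the spec when omitted.
#' @param cpmg List of CPMG experiment descriptions, each a list with
#'   elements `field` ([field_context]) and `schedule` ([cpmg_schedule]).
#' @param cest Like `cpmg` but with [cest_schedule]s; `cest_residues`
#'   restricts which residues are observed by CEST (default: residues
#'   inside the truth regions).
#' @param cest_residues Optional integer vector.
#' @return List with `dispersions` (list of [dispersion_dataset]), `cests`
#'   (list of [cest_dataset]) and `truth`.
#' @export
generate_observations <- function(spec, truth = NULL,
                                  cpmg = list(), cest = list(),
                                  cest_residues = NULL) {
  stopifnot(inherits(spec, "truth_spec"))
  truth <- truth %||% generate_exchange_truth(spec)
  set.seed(child_seed(spec$seed, "observations"))
  noise <- spec$noise
  params <- spec$params

  dispersions <- lapply(cpmg, function(ex) {
    stopifnot(inherits(ex$field, "field_context"),
              inherits(ex$schedule, "cpmg_schedule"))
    rows <- lapply(seq_len(nrow(truth)), function(i) {
      res <- truth_residue(truth, i)
      if (ex$field$h1_mhz < 700) res$r2 <- res$r2_excited <- truth$r2_600[i]
      r2eff <- simulate_cpmg(res, params, ex$field, ex$schedule)
      i0 <- 1
      amp <- i0 * exp(-r2eff * ex$schedule$t_relax)
      amp_n <- pmax(amp * (1 + stats::rnorm(length(amp), 0, noise)), 1e-6)
      i0_n <- i0 * (1 + stats::rnorm(1, 0, noise))
      val <- r2eff_from_intensities(amp_n, i0_n, ex$schedule$t_relax,
                                    i_err = noise * amp, i0_err = noise * i0)
      data.frame(residue_id = truth$residue_id[i],
                 nu_cpmg = ex$schedule$nu_cpmg,
                 r2eff = as.numeric(val),
                 err = pmax(attr(val, "err"), 1e-9))
    })
    dispersion_dataset(do.call(rbind, rows), ex$field, ex$schedule,
                       variant = spec$label)
  })

  cest_residues <- cest_residues %||% truth$residue_id[truth$in_region]
  cests <- lapply(cest, function(ex) {
    stopifnot(inherits(ex$field, "field_context"),
              inherits(ex$schedule, "cest_schedule"))
    rows <- lapply(which(truth$residue_id %in% cest_residues), function(i) {
      res <- truth_residue(truth, i)
      prof <- simulate_cest(res, params, ex$field, ex$schedule)
      data.frame(residue_id = truth$residue_id[i],
                 offset_ppm = ex$schedule$offsets_ppm,
                 intensity = prof + stats::rnorm(length(prof), 0, noise),
                 err = rep(max(noise, 1e-6), length(prof)))
    })
    cest_dataset(do.call(rbind, rows), ex$field, ex$schedule,
                 variant = spec$label)
  })

  list(dispersions = dispersions, cests = cests, truth = truth)
}

#' Generate a ground-truth order-parameter profile
#'
#' A rigid baseline with flexible termini and designated low-S2 dips,
#' emulating the order-parameter signature of partially disordered Switch
#' regions.
#'
#' @param n_residues Sequence length.
#' @param dips Named list; each element is `list(range = , s2 = c(lo, hi))`
#'   giving residues whose S2 is drawn uniformly in `[lo, hi]`.
#' @param baseline Mean and sd of the rigid baseline.
#' @param n_terminal,c_terminal Number of floppy terminal residues.
#' @param seed Integer seed.
#' @return Data frame `residue_id`, `s2`.
#' @export
generate_s2_profile <- function(n_residues = 169,
                                dips = list(
                                  switch1_like = list(range = 30:38,
                                                      s2 = c(0.50, 0.68)),
                                  switch2_like = list(range = 60:65,
                                                      s2 = c(0.21, 0.37))),
                                baseline = c(0.85, 0.03),
                                n_terminal = 2, c_terminal = 3, seed = 1) {
  set.seed(child_seed(seed, "s2-profile"))
  s2 <- pmin(pmax(stats::rnorm(n_residues, baseline[1], baseline[2]),
                  0.65), 0.95)
  for (d in dips) {
    r <- intersect(d$range, seq_len(n_residues))
    s2[r] <- stats::runif(length(r), d$s2[1], d$s2[2])
  }
  if (n_terminal > 0)
    s2[seq_len(n_terminal)] <- stats::runif(n_terminal, 0.25, 0.55)
  if (c_terminal > 0)
    s2[n_residues - seq_len(c_terminal) + 1] <- stats::runif(c_terminal, 0.25, 0.55)
  data.frame(residue_id = seq_len(n_residues), s2 = s2)
}

#' Generate paired relaxation rates consistent with an S2 profile
#'
#' Nanoparticle-free rates come from the model-free expressions at the
#' profile's S2; nanoparticle rates add the linear NASR term
#' `dR2 = lambda * S2`.  Relative Gaussian noise is applied to all rates.
#'
#' @param s2_profile Data frame `residue_id`, `s2`.
#' @param lambda NASR scale factor, 1/s (default 30).
#' @param field A [field_context] (default 850 MHz, 15N).
#' @param tau_c Overall correlation time, s.
#' @param tau_e Internal correlation time, s.
#' @param noise Relative noise on rates.
#' @param seed Integer seed.
#' @return A [relaxation_pairs] object.
#' @export
generate_relaxation_pairs <- function(s2_profile, lambda = 30,
                                      field = field_context(850, "15N"),
                                      tau_c = 10e-9, tau_e = 50e-12,
                                      noise = 0.02, seed = 1) {
  set.seed(child_seed(seed, "nasr-pairs"))
  n <- nrow(s2_profile)
  rates <- lapply(s2_profile$s2, function(s2)
    lipari_szabo_rates(s2, tau_c, tau_e, field))
  r1 <- vapply(rates, `[[`, 0, "r1")
  r2 <- vapply(rates, `[[`, 0, "r2")
  dr2 <- lambda * s2_profile$s2
  noisy <- function(x) x * (1 + stats::rnorm(n, 0, noise))
  err <- function(x) pmax(noise, 1e-9) * x
  relaxation_pairs(data.frame(
    residue_id = s2_profile$residue_id,
    r1_free = noisy(r1), r1_free_err = err(r1),
    r2_free = noisy(r2), r2_free_err = err(r2),
    r1_np = noisy(r1), r1_np_err = err(r1),
    r2_np = noisy(r2 + dr2), r2_np_err = err(r2 + dr2)
  ), field = field)
}

#' Pair-sum closed form for ensemble order parameters
#'
#' `S2 = sum_jk w_j w_k P2(e_j . e_k)` with `P2(x) = (3 x^2 - 1) / 2`:
#' the brute-force average of the second Legendre polynomial over all
#' conformer pairs, algebraically equivalent to the orientational-tensor
#' contraction used by [s2_from_ensemble()].
#'
#' @param vectors List (one per conformer) of unit-vector matrices with
#'   matching rows.
#' @param weights Conformer weights.
#' @return Numeric S2 per row.
#' @export
s2_pair_sum <- function(vectors, weights) {
  n <- nrow(vectors[[1]])
  k <- length(vectors)
  s2 <- numeric(n)
  for (j in seq_len(k)) for (l in seq_len(k)) {
    dot <- rowSums(vectors[[j]] * vectors[[l]])
    s2 <- s2 + weights[j] * weights[l] * (3 * dot^2 - 1) / 2
  }
  unname(s2)
}

rotation_about <- function(axis, theta) {
  a <- unit(axis)
  c_ <- cos(theta); s_ <- sin(theta)
  outer(a, a) * (1 - c_) + diag(3) * c_ +
    matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3) * s_
}

# Ideal planar extended backbone: N, CA, C per residue laid out as an
# in-plane zig-zag (successive bonds alternate +/-30 degrees from x, so
# every internal angle is 120 degrees) with standard bond lengths.
ideal_backbone <- function(n_residues) {
  lens <- rep(c(1.458, 1.525, 1.329), n_residues)[seq_len(3 * n_residues - 1)]
  gamma <- pi / 6
  n_atoms <- 3 * n_residues
  pos <- matrix(0, n_atoms, 3)
  for (i in seq_len(n_atoms - 1)) {
    d <- if (i %% 2 == 1) c(cos(gamma), sin(gamma), 0) else c(cos(gamma), -sin(gamma), 0)
    pos[i + 1, ] <- pos[i, ] + lens[i] * d
  }
  data.frame(
    residue_id = rep(seq_len(n_residues), each = 3),
    resname = "ALA",
    atom = rep(c("N", "CA", "C"), n_residues),
    x = pos[, 1], y = pos[, 2], z = pos[, 3])
}

#' Generate a toy conformer ensemble with analytically known S2
#'
#' Builds identical ideal polyalanine backbones, places amide hydrogens,
#' then rotates the N-H vector of designated residues by specified angles
#' (about a fixed axis perpendicular to the original vector) in each
#' conformer.  Because the backbones coincide, superposition is the
#' identity and the analytic S2 follows from the pair-sum closed form
#' applied to the constructed vectors.
#'
#' @param n_conformers Number of conformers (>= 1).
#' @param n_residues Chain length (default 12).
#' @param rotate List of perturbations, each
#'   `list(residue = , angles_deg = )` with one angle per conformer.
#' @param weights Conformer weights (default equal).
#' @return List with `conformers` (list of [conformer]), `weights` and
#'   `s2_true` (data frame `residue_id`, `s2` over residues with N-H).
#' @export
generate_toy_ensemble <- function(n_conformers, n_residues = 12,
                                  rotate = list(), weights = NULL) {
  stopifnot(n_conformers >= 1)
  weights <- weights %||% rep(1 / n_conformers, n_conformers)
  base <- build_amide_hydrogens(conformer(ideal_backbone(n_residues), "toy"))
  confs <- lapply(seq_len(n_conformers), function(k) {
    cf <- base
    cf$label <- sprintf("toy%02d", k)
    for (rt in rotate) {
      stopifnot(length(rt$angles_deg) == n_conformers)
      rid <- rt$residue
      n_xyz <- atom_xyz(cf, rid, "N")
      h_xyz <- atom_xyz(cf, rid, "H")
      if (is.null(h_xyz)) next
      nh <- h_xyz - n_xyz
      axis <- unit(atom_xyz(cf, rid, "CA") - n_xyz -
                     sum((atom_xyz(cf, rid, "CA") - n_xyz) * unit(nh)) * unit(nh))
      R <- rotation_about(axis, rt$angles_deg[k] * pi / 180)
      h_new <- n_xyz + as.numeric(R %*% nh)
      i <- which(cf$atoms$residue_id == rid & cf$atoms$atom == "H")
      cf$atoms[i, c("x", "y", "z")] <- as.list(h_new)
    }
    cf
  })
  vecs <- lapply(confs, nh_vectors)
  s2_true <- data.frame(residue_id = as.integer(rownames(vecs[[1]])),
                        s2 = s2_pair_sum(vecs, weights))
  list(conformers = confs, weights = weights, s2_true = s2_true)
}
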