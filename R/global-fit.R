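# Global two-state fitting of CPMG + CEST data.
#
# The model is separable: for fixed global (k_ex, p1) the per-residue
# parameters (shift differences, ground shift, intrinsic rates) are
# independent across residues.  The fit therefore profiles the global
# parameters: an outer optimizer moves (k_ex, p1) while, at each step, small
# Levenberg-Marquardt fits solve each residue's local parameters.  Warm
# caches make repeated inner solves cheap, which also keeps the residue
# bootstrap affordable.

param_key_r2 <- function(nucleus, h1_mhz) sprintf("r2_%s_%g", nucleus, h1_mhz)

# Assemble per-residue observation blocks from the datasets.
build_blocks <- function(dispersions, cests) {
  blocks <- list()
  add <- function(rid, b) {
    k <- as.character(rid)
    blocks[[k]] <<- c(blocks[[k]], list(b))
  }
  for (ds in dispersions) {
    for (g in split(ds$data, ds$data$residue_id)) {
      add(g$residue_id[1], list(
        type = "cpmg", field = ds$field, schedule = ds$schedule,
        x = g$nu_cpmg, obs = g$r2eff, err = g$err))
    }
  }
  for (ds in cests) {
    for (g in split(ds$data, ds$data$residue_id)) {
      o <- order(g$offset_ppm)
      add(g$residue_id[1], list(
        type = "cest", field = ds$field, schedule = ds$schedule,
        x = g$offset_ppm[o], obs = g$intensity[o], err = g$err[o]))
    }
  }
  blocks
}

# Local parameter layout (names, bounds, cold-start values) for one residue.
local_layout <- function(blocks) {
  par <- lower <- upper <- numeric(0)
  has_cest <- any(vapply(blocks, function(b) b$type == "cest", TRUE))
  for (b in blocks) {
    nuc <- b$field$nucleus
    dwk <- paste0("dw_", nuc)
    if (!dwk %in% names(par)) {
      if (nuc == "15N") {
        par[dwk] <- 2
        lower[dwk] <- if (has_cest) -12 else 0
        upper[dwk] <- 12
      } else {
        par[dwk] <- 0.3
        lower[dwk] <- 0
        upper[dwk] <- 3
      }
    }
    r2k <- param_key_r2(nuc, b$field$h1_mhz)
    if (!r2k %in% names(par)) {
      par[r2k] <- 14; lower[r2k] <- 0.5; upper[r2k] <- 200
    }
    if (b$type == "cest") {
      if (!"omega_15N" %in% names(par)) {
        par["omega_15N"] <- mean(range(b$x))
        lower["omega_15N"] <- min(b$x) - 2
        upper["omega_15N"] <- max(b$x) + 2
      }
      if (!"r1" %in% names(par)) {
        par["r1"] <- 1.3; lower["r1"] <- 0.02; upper["r1"] <- 15
      }
    }
  }
  list(par = par, lower = lower, upper = upper, has_cest = has_cest)
}

# Data-driven cold start refinement.
cold_start <- function(par, blocks, k_ex, p1) {
  for (b in blocks) {
    nuc <- b$field$nucleus
    if (b$type == "cpmg") {
      r2k <- param_key_r2(nuc, b$field$h1_mhz)
      par[r2k] <- max(0.6, b$obs[which.max(b$x)])
      rex <- max(b$obs[which.min(b$x)] - b$obs[which.max(b$x)], 0.5)
      dw0 <- sqrt(rex * k_ex / (p1 * (1 - p1))) / b$field$ppm2rad
      cap <- if (nuc == "15N") c(0.3, 8) else c(0.05, 1.5)
      dwk <- paste0("dw_", nuc)
      if (par[[dwk]] >= 0)  # do not clobber a signed CEST-derived guess
        par[dwk] <- min(max(dw0, cap[1]), cap[2])
    } else {
      i_min <- which.min(b$obs)
      omega <- b$x[i_min]
      par["omega_15N"] <- omega
      away <- abs(b$x - omega) > 1.5
      if (any(away)) {
        j <- which(away)[which.min(b$obs[away])]
        depth <- 1 - b$obs[j]
        if (depth > 3 * stats::median(b$err))
          par["dw_15N"] <- b$x[j] - omega
      }
    }
  }
  par
}

block_model <- function(par, b, k_ex, p1) {
  nuc <- b$field$nucleus
  if (b$type == "cpmg") {
    as.numeric(cpmg_r2eff_cpp(par[[paste0("dw_", nuc)]] * b$field$ppm2rad,
                   par[[param_key_r2(nuc, b$field$h1_mhz)]],
                   par[[param_key_r2(nuc, b$field$h1_mhz)]],
                   k_ex, p1, b$schedule$t_relax, b$x, FALSE))
  } else {
    dg <- (par[["omega_15N"]] - b$x) * b$field$ppm2rad
    de <- (par[["omega_15N"]] + par[["dw_15N"]] - b$x) * b$field$ppm2rad
    r2 <- par[[param_key_r2(nuc, b$field$h1_mhz)]]
    as.numeric(cest_profile_cpp(dg, de, par[["r1"]], r2, par[["r1"]], r2,
                                k_ex, p1, b$schedule$t_ex,
                                2 * pi * b$schedule$b1_hz))
  }
}

inner_fit <- function(blocks, k_ex, p1, warm = NULL, maxiter = 40,
                      tol = 1e-8) {
  lay <- local_layout(blocks)
  par <- if (!is.null(warm)) warm else cold_start(lay$par, blocks, k_ex, p1)
  resid_fn <- function(p) {
    p <- stats::setNames(as.numeric(p), names(lay$par))
    unlist(lapply(blocks, function(b)
      (block_model(as.list(p), b, k_ex, p1) - b$obs) / b$err))
  }
  fit <- suppressWarnings(minpack.lm::nls.lm(
    par = par, lower = lay$lower, upper = lay$upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = maxiter, ptol = tol,
                                         ftol = tol)))
  list(par = stats::setNames(coef(fit), names(lay$par)),
       ssq = fit$deviance, n = sum(lengths(lapply(blocks, `[[`, "obs"))),
       npar = length(par))
}

profile_objective <- function(theta, blocks_by_res, warm_env, weights = NULL,
                              maxiter = 5, tol = 1e-6) {
  k_ex <- exp(theta[1])
  p1 <- stats::plogis(theta[2])
  ssq <- 0
  for (k in names(blocks_by_res)) {
    w <- if (is.null(weights)) 1 else weights[[k]] %||% 0
    if (w == 0 && !is.null(weights)) next
    st <- inner_fit(blocks_by_res[[k]], k_ex, p1, warm = warm_env[[k]],
                    maxiter = maxiter, tol = tol)
    warm_env[[k]] <- st$par
    ssq <- ssq + w * st$ssq
  }
  ssq
}

#' Global two-state fit of CPMG and CEST data
#'
#' Minimizes error-weighted residuals of the Bloch-McConnell forward model
#' jointly over the shared exchange parameters (`k_ex`, `p1`) and, per
#' residue, shift differences per nucleus, intrinsic R2 per (nucleus,
#' field), and (for CEST residues) the ground shift and R1.  Residues are
#' admitted through an Rex filter on the dispersion data (default
#' threshold 5 1/s).  CEST data determine the sign of the nitrogen shift
#' difference; residues with CPMG data only report `|dw|` and are flagged
#' sign-undetermined.
#'
#' The optimizer profiles the globals: a multi-start grid (log-spaced
#' `k_ex` in 50-3000 1/s crossed with `p1` in 0.02-0.2) seeds a
#' Nelder-Mead search of `(log k_ex, logit p1)`, with per-residue
#' Levenberg-Marquardt subfits solving the local parameters at each step.
#'
#' @param dispersions A [dispersion_dataset] or list of them.
#' @param cests Optional [cest_dataset] or list of them.
#' @param init Optional [two_site_params] starting point; skips the
#'   multi-start grid.
#' @param rex_threshold Minimum Rex (1/s) for a residue to enter the fit.
#' @param control List of optional knobs: `outer_maxit` (default 200),
#'   `grid_kex`, `grid_p1`, `inner_maxiter`, `reltol`.
#' @return An object of class `global_fit`: fitted [two_site_params],
#'   per-residue parameter table `residues`, reduced chi-square
#'   `chisq_red`, selection metadata, and flags.
#' @export
fit_global_two_state <- function(dispersions, cests = list(), init = NULL,
                                 rex_threshold = 5, control = list()) {
  if (inherits(dispersions, "dispersion_dataset")) dispersions <- list(dispersions)
  if (inherits(cests, "cest_dataset")) cests <- list(cests)
  if (length(dispersions) + length(cests) == 0)
    stop("at least one dataset is required", call. = FALSE)

  # residue selection by Rex filter on the dispersion data
  if (length(dispersions) > 0) {
    rex_all <- do.call(rbind, lapply(dispersions, estimate_rex))
    rex_max <- tapply(rex_all$rex, rex_all$residue_id, max)
    selected <- as.integer(names(rex_max)[rex_max > rex_threshold])
  } else {
    selected <- sort(unique(unlist(lapply(cests, function(d) d$data$residue_id))))
  }
  if (length(selected) == 0)
    stop_kexdyn(sprintf("no residue exceeds the Rex threshold of %g 1/s",
                        rex_threshold), "kexdyn_selection_error")

  keep <- function(ds) {
    ds$data <- ds$data[ds$data$residue_id %in% selected, , drop = FALSE]
    ds
  }
  blocks <- build_blocks(lapply(dispersions, keep), lapply(cests, keep))
  blocks <- blocks[order(as.integer(names(blocks)))]

  inner_maxiter <- control$inner_maxiter %||% 5
  outer_maxit <- control$outer_maxit %||% 120
  reltol <- control$reltol %||% 1e-7

  # multi-start over the global grid (each start cold), or user init
  if (is.null(init)) {
    grid_kex <- control$grid_kex %||% exp(seq(log(50), log(3000), length.out = 5))
    grid_p1 <- control$grid_p1 %||% c(0.02, 0.05, 0.1, 0.2)
    starts <- expand.grid(k_ex = grid_kex, p1 = grid_p1)
  } else {
    stopifnot(inherits(init, "two_site_params"))
    starts <- data.frame(k_ex = init$k_ex, p1 = init$p1)
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    env_i <- new.env(parent = emptyenv())
    th <- c(log(starts$k_ex[i]), stats::qlogis(starts$p1[i]))
    v <- profile_objective(th, blocks, env_i, maxiter = 12)
    if (is.null(best) || v < best$v) best <- list(th = th, v = v, env = env_i)
  }

  warm <- best$env
  opt <- stats::optim(best$th, profile_objective, blocks_by_res = blocks,
                      warm_env = warm, maxiter = inner_maxiter,
                      method = "Nelder-Mead",
                      control = list(maxit = outer_maxit, reltol = reltol))

  k_ex_hat <- exp(opt$par[1])
  p1_hat <- stats::plogis(opt$par[2])

  # final tight local solves at the optimum
  res_rows <- list()
  ssq <- 0; n_obs <- 0; n_par <- 2
  for (k in names(blocks)) {
    st <- inner_fit(blocks[[k]], k_ex_hat, p1_hat, warm = warm[[k]],
                    maxiter = 100, tol = 1e-8)
    warm[[k]] <- st$par
    ssq <- ssq + st$ssq; n_obs <- n_obs + st$n; n_par <- n_par + st$npar
    lay <- local_layout(blocks[[k]])
    row <- as.list(st$par)
    row$residue_id <- as.integer(k)
    row$sign_determined <- lay$has_cest
    if (!lay$has_cest && !is.null(row$dw_15N)) row$dw_15N <- abs(row$dw_15N)
    res_rows[[k]] <- row
  }
  cols <- unique(unlist(lapply(res_rows, names)))
  residues <- do.call(rbind, lapply(res_rows, function(r) {
    r[setdiff(cols, names(r))] <- NA
    as.data.frame(r[cols])
  }))
  residues <- residues[order(residues$residue_id),
                       c("residue_id", setdiff(cols, "residue_id"))]
  rownames(residues) <- NULL

  chisq_red <- ssq / max(n_obs - n_par, 1)
  non_identifiable <- p1_hat < 0.005 ||
    (all(is.na(residues$dw_15N)) || max(abs(residues$dw_15N), na.rm = TRUE) < 0.2)

  structure(list(
    params = two_site_params(k_ex_hat, min(p1_hat, 1 - 1e-12)),
    residues = residues,
    chisq_red = chisq_red, objective = opt$value,
    n_obs = n_obs, n_par = n_par,
    converged = opt$convergence == 0,
    non_identifiable = non_identifiable,
    selected = as.integer(names(blocks)),
    rex_threshold = rex_threshold,
    blocks = blocks, warm = as.list(warm),
    bootstrap = NULL
  ), class = "global_fit")
}

#' @export
print.global_fit <- function(x, ...) {
  cat("<global_fit>\n  ")
  print(x$params)
  cat(sprintf("  %d residues, %d observations, reduced chi-square %.3f\n",
              length(x$selected), x$n_obs, x$chisq_red))
  if (x$non_identifiable)
    cat("  WARNING: exchange parameters flagged non-identifiable\n")
  if (!is.null(x$bootstrap))
    cat(sprintf("  bootstrap: k_ex %.4g +/- %.2g, p1 %.4g +/- %.2g (%d replicates)\n",
                x$params$k_ex, x$bootstrap$sd[["k_ex"]],
                x$params$p1, x$bootstrap$sd[["p1"]],
                nrow(x$bootstrap$replicates)))
  invisible(x)
}

#' Bootstrap uncertainties for a global fit
#'
#' Resamples residues with replacement (keeping all observations of a
#' chosen residue together, which preserves within-profile correlation) and
#' refits the global parameters for each replicate, warm-starting from the
#' converged fit.  The spread of the replicate estimates gives the
#' parameter uncertainties.  Deterministic under a fixed seed.
#'
#' @param fit A converged [fit_global_two_state()] result.
#' @param n_replicates Number of bootstrap replicates (>= 50 recommended;
#'   fewer triggers a warning).
#' @param seed Integer seed (required for reproducibility).
#' @param outer_maxit Nelder-Mead iteration cap per replicate refit.
#' @return The fit with a `bootstrap` element: `replicates` (data frame of
#'   `k_ex`, `p1`, `k21`, `k12` per replicate), `sd`, `ci95` (2.5/97.5
#'   percentiles) and `cov` (covariance of `k_ex`, `p1`).
#' @export
bootstrap_uncertainties <- function(fit, n_replicates = 100, seed = 1,
                                    outer_maxit = 30) {
  stopifnot(inherits(fit, "global_fit"))
  if (n_replicates < 50)
    warning("fewer than 50 bootstrap replicates; uncertainties will be noisy",
            call. = FALSE)
  ids <- names(fit$blocks)
  if (length(ids) < 5)
    warning("fewer than 5 fitted residues; bootstrap is unreliable",
            call. = FALSE)
  set.seed(child_seed(seed, "bootstrap"))
  th0 <- c(log(fit$params$k_ex), stats::qlogis(fit$params$p1))
  reps <- matrix(NA_real_, n_replicates, 2)
  for (r in seq_len(n_replicates)) {
    draw <- sample(ids, length(ids), replace = TRUE)
    w <- as.list(table(draw))
    env_r <- list2env(fit$warm, parent = emptyenv())
    opt <- stats::optim(th0, profile_objective, blocks_by_res = fit$blocks,
                        warm_env = env_r, weights = w, maxiter = 4,
                        method = "Nelder-Mead",
                        control = list(maxit = outer_maxit, reltol = 1e-6))
    reps[r, ] <- c(exp(opt$par[1]), stats::plogis(opt$par[2]))
  }
  replicates <- data.frame(k_ex = reps[, 1], p1 = reps[, 2],
                           k21 = reps[, 2] * reps[, 1],
                           k12 = (1 - reps[, 2]) * reps[, 1])
  fit$bootstrap <- list(
    replicates = replicates,
    sd = vapply(replicates, stats::sd, numeric(1)),
    ci95 = vapply(replicates, stats::quantile, numeric(2),
                  probs = c(0.025, 0.975)),
    cov = stats::cov(replicates[, c("k_ex", "p1")])
  )
  fit
}

#' Microscopic rate constants with propagated uncertainties
#'
#' `k21 = p1 * k_ex` and `k12 = (1 - p1) * k_ex`.  When the fit carries
#' bootstrap results, errors are first-order propagated from the replicate
#' variances and covariance of `(k_ex, p1)`.
#'
#' @param fit A [fit_global_two_state()] result (possibly after
#'   [bootstrap_uncertainties()]) or a bare [two_site_params] object.
#' @return Data frame with columns `rate`, `value`, `err`.
#' @examples
#' derived_rates(two_site_params(400, 0.1015))  # k21 = 40.6, k12 = 359.4
#' @export
derived_rates <- function(fit) {
  if (inherits(fit, "two_site_params")) {
    p <- fit; V <- NULL
  } else {
    stopifnot(inherits(fit, "global_fit"))
    p <- fit$params
    V <- if (!is.null(fit$bootstrap)) fit$bootstrap$cov else NULL
  }
  value <- c(k21 = p$p1 * p$k_ex, k12 = (1 - p$p1) * p$k_ex)
  err <- c(k21 = NA_real_, k12 = NA_real_)
  if (!is.null(V)) {
    vk <- V["k_ex", "k_ex"]; vp <- V["p1", "p1"]; cvp <- V["k_ex", "p1"]
    err["k21"] <- sqrt(p$p1^2 * vk + p$k_ex^2 * vp + 2 * p$p1 * p$k_ex * cvp)
    err["k12"] <- sqrt((1 - p$p1)^2 * vk + p$k_ex^2 * vp -
                         2 * (1 - p$p1) * p$k_ex * cvp)
  }
  data.frame(rate = names(value), value = unname(value), err = unname(err))
}
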