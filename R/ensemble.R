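# Ensemble order parameters: back-calculation of N-H S2 from weighted
# multi-conformer coordinate sets, and fitting of conformer populations
# against an experimental S2 profile.

#' Conformer object
#'
#' A single all-atom (backbone) conformer: one row per atom with residue
#' number, residue name, atom name and coordinates in Angstrom.
#'
#' @param atoms Data frame with columns `residue_id`, `resname`, `atom`
#'   (`"N"`, `"CA"`, `"C"`, `"O"`, optionally `"H"`), `x`, `y`, `z`.
#' @param label Identifier (e.g. a PDB id).
#' @return Object of class `conformer`.
#' @export
conformer <- function(atoms, label = "conformer") {
  req <- c("residue_id", "resname", "atom", "x", "y", "z")
  if (!all(req %in% names(atoms)))
    stop("`atoms` must have columns ", paste(req, collapse = ", "), call. = FALSE)
  if (anyDuplicated(atoms[c("residue_id", "atom")]))
    stop("duplicated (residue_id, atom) entries", call. = FALSE)
  atoms$residue_id <- as.integer(atoms$residue_id)
  # peptide-geometry sanity: N-CA distances
  for (rid in intersect(atoms$residue_id[atoms$atom == "N"],
                        atoms$residue_id[atoms$atom == "CA"])) {
    n <- atoms[atoms$residue_id == rid & atoms$atom == "N", c("x", "y", "z")]
    ca <- atoms[atoms$residue_id == rid & atoms$atom == "CA", c("x", "y", "z")]
    d <- sqrt(sum((n - ca)^2))
    if (d < 1.2 || d > 1.8)
      warning(sprintf("%s: residue %d N-CA distance %.2f A is outside 1.2-1.8",
                      label, rid, d), call. = FALSE)
  }
  structure(list(label = label, atoms = atoms), class = "conformer")
}

atom_xyz <- function(conf, rid, atom) {
  a <- conf$atoms
  i <- which(a$residue_id == rid & a$atom == atom)
  if (length(i) != 1) return(NULL)
  as.numeric(a[i, c("x", "y", "z")])
}

unit <- function(v) v / sqrt(sum(v^2))

#' Build amide hydrogens on a backbone conformer
#'
#' Crystal structures lack amide protons; this places H 1.02 Angstrom from
#' N along the bisector of the external C(i-1)-N-CA angle (in the peptide
#' plane, roughly 119 degrees from both heavy-atom bonds).  Prolines and
#' the chain N-terminus are skipped; residues with missing backbone atoms
#' are left without H and reported in attribute `"skipped"`.
#'
#' @param conf A [conformer].
#' @return The conformer with `H` atoms added where possible.
#' @export
build_amide_hydrogens <- function(conf) {
  stopifnot(inherits(conf, "conformer"))
  a <- conf$atoms
  rids <- sort(unique(a$residue_id))
  skipped <- integer(0)
  new_rows <- list()
  for (rid in rids) {
    resname <- a$resname[a$residue_id == rid][1]
    if (identical(toupper(resname), "PRO")) next
    if (rid == min(rids)) { skipped <- c(skipped, rid); next }
    n <- atom_xyz(conf, rid, "N")
    ca <- atom_xyz(conf, rid, "CA")
    cprev <- atom_xyz(conf, rid - 1L, "C")
    if (is.null(n) || is.null(ca) || is.null(cprev)) {
      skipped <- c(skipped, rid); next
    }
    h <- n + 1.02 * unit(unit(n - cprev) + unit(n - ca))
    new_rows[[length(new_rows) + 1]] <- data.frame(
      residue_id = rid, resname = resname, atom = "H",
      x = h[1], y = h[2], z = h[3])
  }
  if (length(new_rows) > 0)
    conf$atoms <- rbind(a[a$atom != "H", , drop = FALSE],
                        do.call(rbind, new_rows))
  attr(conf, "skipped") <- skipped
  conf
}

conf_coords <- function(conf, residues, atoms) {
  rows <- conf$atoms[conf$atoms$residue_id %in% residues &
                       conf$atoms$atom %in% atoms, , drop = FALSE]
  rows <- rows[order(rows$residue_id, match(rows$atom, atoms)), , drop = FALSE]
  list(key = paste(rows$residue_id, rows$atom),
       xyz = as.matrix(rows[c("x", "y", "z")]))
}

# Kabsch rigid-body superposition: optimal rotation by SVD of the
# covariance of the centered coordinate sets.
kabsch <- function(mobile, fixed) {
  mc <- colMeans(mobile); fc <- colMeans(fixed)
  H <- t(sweep(mobile, 2, mc)) %*% sweep(fixed, 2, fc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, mobile_center = mc, fixed_center = fc)
}

#' Least-squares superposition of conformers
#'
#' Rigid-body superposition of each conformer onto a reference over a
#' shared atom selection (Kabsch/SVD solution).  The default selection is
#' the backbone N, CA, C of all residues present in every conformer minus
#' an `exclude` set; for a 169-residue GTPase the natural exclusion is the
#' mobile Switch regions and chain termini so that Switch motion does not
#' bias the common frame.
#'
#' @param conformers List of [conformer] objects.
#' @param reference Index of the reference conformer (default 1).
#' @param residues Residues used for the superposition; defaults to all
#'   residues shared by every conformer.
#' @param exclude Residues removed from the selection (default none).
#' @param atoms Atom names used (default `c("N", "CA", "C")`).
#' @return List of superposed conformers with per-conformer RMSD (Angstrom)
#'   in attribute `"rmsd"`.
#' @export
superpose <- function(conformers, reference = 1, residues = NULL,
                      exclude = integer(0), atoms = c("N", "CA", "C")) {
  stopifnot(length(conformers) >= 1)
  shared <- Reduce(intersect, lapply(conformers, function(cf)
    unique(cf$atoms$residue_id)))
  residues <- setdiff(residues %||% shared, exclude)
  ref <- conf_coords(conformers[[reference]], residues, atoms)
  rmsd <- numeric(length(conformers))
  out <- vector("list", length(conformers))
  for (i in seq_along(conformers)) {
    mob <- conf_coords(conformers[[i]], residues, atoms)
    common <- intersect(ref$key, mob$key)
    if (length(common) < 3)
      stop_kexdyn("fewer than 3 common atoms in the superposition selection",
                  "kexdyn_superposition_error")
    A <- mob$xyz[match(common, mob$key), , drop = FALSE]
    B <- ref$xyz[match(common, ref$key), , drop = FALSE]
    k <- kabsch(A, B)
    cf <- conformers[[i]]
    xyz <- as.matrix(cf$atoms[c("x", "y", "z")])
    xyz <- sweep(xyz, 2, k$mobile_center) %*% t(k$R)
    xyz <- sweep(xyz, 2, k$fixed_center, `+`)
    cf$atoms[c("x", "y", "z")] <- xyz
    fitted <- sweep(sweep(A, 2, k$mobile_center) %*% t(k$R), 2,
                    k$fixed_center, `+`)
    rmsd[i] <- sqrt(mean(rowSums((fitted - B)^2)))
    out[[i]] <- cf
  }
  attr(out, "rmsd") <- rmsd
  out
}

#' Weighted conformer ensemble
#'
#' @param conformers List of [conformer] objects (superposed, with amide
#'   hydrogens built).
#' @param weights Non-negative fractions summing to 1 (within 1e-9).
#' @return Object of class `weighted_ensemble`.
#' @export
weighted_ensemble <- function(conformers, weights) {
  stopifnot(length(conformers) == length(weights))
  if (any(weights < 0)) stop("weights must be >= 0", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-9)
    stop("weights must sum to 1 (within 1e-9)", call. = FALSE)
  structure(list(conformers = conformers, weights = as.numeric(weights)),
            class = "weighted_ensemble")
}

# Unit N-H vectors per residue for one conformer: rows named by residue.
nh_vectors <- function(conf) {
  a <- conf$atoms
  rids <- intersect(a$residue_id[a$atom == "N"], a$residue_id[a$atom == "H"])
  if (length(rids) == 0) return(matrix(numeric(0), 0, 3))
  v <- t(vapply(sort(rids), function(rid)
    unit(atom_xyz(conf, rid, "H") - atom_xyz(conf, rid, "N")),
    numeric(3)))
  rownames(v) <- sort(rids)
  v
}

#' Ensemble-averaged N-H order parameters
#'
#' For unit N-H vectors `e_k` with weights `w_k`,
#' `S2 = (3/2) * sum_ab (sum_k w_k e_a e_b)^2 - 1/2`
#' (the second-rank orientational tensor contraction).  Residues missing an
#' N-H vector in any conformer are omitted and listed in attribute
#' `"omitted"`.  Conformers must already share a common frame (see
#' [superpose()]).
#'
#' @param ensemble A [weighted_ensemble].
#' @return Data frame of class `order_param_profile`: `residue_id`, `s2`,
#'   `method = "ensemble"`.
#' @export
s2_from_ensemble <- function(ensemble) {
  stopifnot(inherits(ensemble, "weighted_ensemble"))
  vecs <- lapply(ensemble$conformers, nh_vectors)
  shared <- Reduce(intersect, lapply(vecs, rownames))
  all_res <- sort(unique(as.integer(unlist(lapply(vecs, rownames)))))
  omitted <- setdiff(all_res, as.integer(shared))
  w <- ensemble$weights
  s2 <- vapply(shared, function(r) {
    Tm <- matrix(0, 3, 3)
    for (k in seq_along(vecs)) {
      e <- vecs[[k]][r, ]
      Tm <- Tm + w[k] * tcrossprod(e)
    }
    1.5 * sum(Tm^2) - 0.5
  }, numeric(1))
  out <- data.frame(residue_id = as.integer(shared), s2 = unname(s2),
                    method = "ensemble")
  out <- out[order(out$residue_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "omitted") <- omitted
  class(out) <- c("order_param_profile", class(out))
  out
}

# Precompute, per conformer, the per-residue orientational tensors so that
# S2 for arbitrary weights is a cheap quadratic form.
ensemble_tensors <- function(conformers, residues) {
  lapply(conformers, function(cf) {
    v <- nh_vectors(cf)
    t(vapply(as.character(residues), function(r) as.numeric(tcrossprod(v[r, ])),
             numeric(9)))
  })
}

s2_for_weights <- function(tensors, w) {
  Tm <- Reduce(`+`, Map(`*`, tensors, w))
  1.5 * rowSums(Tm^2) - 0.5
}

#' Fit conformer populations against an experimental S2 profile
#'
#' Exhaustive grid search over the weight simplex (default 1% resolution)
#' minimizing the root-mean-square deviation between the ensemble
#' back-calculated S2 and the experimental profile over a residue mask,
#' optionally followed by continuous refinement from the grid optimum.
#' The top-scoring weight sets are reported as a degeneracy diagnostic.
#'
#' @param candidates List of [conformer] objects (superposed, hydrogens
#'   built).
#' @param experimental Data frame (`residue_id`, `s2`) of experimental
#'   order parameters.
#' @param mask Residue ids over which the RMSD is evaluated; defaults to
#'   all residues common to the candidates and the experimental profile.
#' @param step Grid resolution on the weights (default 0.01).
#' @param refine Continuous refinement after the grid search (default TRUE).
#' @param regions Optional named list of residue ranges for per-region RMSD
#'   reporting.
#' @param n_top Number of best grid points to report (default 10).
#' @return List of class `population_fit`: `weights`, `rmsd`, `top`
#'   (data frame of the best grid points), `region_rmsd`, `ensemble`.
#' @export
fit_populations <- function(candidates, experimental, mask = NULL,
                            step = 0.01, refine = TRUE, regions = NULL,
                            n_top = 10) {
  k <- length(candidates)
  if (k < 2) stop("at least 2 candidate conformers are required", call. = FALSE)
  vecs <- lapply(candidates, nh_vectors)
  shared <- as.integer(Reduce(intersect, lapply(vecs, rownames)))
  mask <- sort(intersect(mask %||% shared,
                         intersect(shared, experimental$residue_id)))
  if (length(mask) == 0)
    stop("experimental profile does not cover the mask", call. = FALSE)
  tensors <- ensemble_tensors(candidates, mask)
  s2_exp <- experimental$s2[match(mask, experimental$residue_id)]

  # degenerate when every candidate presents the same N-H orientations
  # (identical orientational tensors) over the masked residues
  tdist <- vapply(seq_len(k - 1), function(i)
    max(abs(tensors[[i]] - tensors[[i + 1]])), numeric(1))
  if (max(tdist) < 1e-9)
    warning("candidate conformers are indistinguishable over the mask; populations are degenerate",
            call. = FALSE)

  grid <- simplex_grid(k, step)
  rmsd <- apply(grid, 1, function(w)
    sqrt(mean((s2_for_weights(tensors, w) - s2_exp)^2)))
  ord <- order(rmsd)
  top <- data.frame(grid[ord[seq_len(min(n_top, nrow(grid)))], , drop = FALSE],
                    rmsd = rmsd[ord[seq_len(min(n_top, nrow(grid)))]])
  names(top)[seq_len(k)] <- vapply(candidates, `[[`, "", "label")

  w_best <- grid[ord[1], ]
  if (refine) {
    # softmax parametrization keeps the search on the simplex
    obj <- function(th) {
      w <- exp(c(th, 0)); w <- w / sum(w)
      sqrt(mean((s2_for_weights(tensors, w) - s2_exp)^2))
    }
    th0 <- log(pmax(w_best[-k], 1e-6) / max(w_best[k], 1e-6))
    if (length(th0) == 1) {
      opt <- stats::optimize(obj, lower = th0 - 2, upper = th0 + 2,
                             tol = 1e-10)
      opt <- list(par = opt$minimum, value = opt$objective)
    } else {
      opt <- stats::optim(th0, obj, method = "Nelder-Mead",
                          control = list(maxit = 400, reltol = 1e-10))
    }
    w_ref <- exp(c(opt$par, 0)); w_ref <- w_ref / sum(w_ref)
    if (opt$value <= min(rmsd)) w_best <- w_ref
  }
  w_best <- w_best / sum(w_best)
  names(w_best) <- vapply(candidates, `[[`, "", "label")
  best_rmsd <- sqrt(mean((s2_for_weights(tensors, w_best) - s2_exp)^2))

  region_rmsd <- NULL
  if (!is.null(regions)) {
    s2_fit <- s2_for_weights(tensors, w_best)
    region_rmsd <- vapply(regions, function(rr) {
      i <- mask %in% rr
      if (!any(i)) return(NA_real_)
      sqrt(mean((s2_fit[i] - s2_exp[i])^2))
    }, numeric(1))
  }
  structure(list(weights = w_best, rmsd = best_rmsd, top = top,
                 region_rmsd = region_rmsd, mask = mask,
                 ensemble = weighted_ensemble(candidates, unname(w_best))),
            class = "population_fit")
}

# All weight vectors of length k on the simplex with the given resolution.
simplex_grid <- function(k, step) {
  n <- round(1 / step)
  if (k == 2) {
    i <- 0:n
    return(cbind(i, n - i) / n)
  }
  rec <- function(k, n) {
    if (k == 1) return(matrix(n, 1, 1))
    do.call(rbind, lapply(0:n, function(i) cbind(i, rec(k - 1, n - i))))
  }
  unname(rec(k, n) / n)
}

#' @export
print.population_fit <- function(x, ...) {
  cat("<population_fit>\n  weights:",
      paste(sprintf("%s = %.1f%%", names(x$weights), 100 * x$weights),
            collapse = ", "),
      sprintf("\n  rmsd = %.4f over %d residues\n", x$rmsd, length(x$mask)))
  invisible(x)
}
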