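# Excited-state chemical-shift reconstruction and annotation.

#' Functional region presets for a 169-residue GTPase G-domain
#'
#' Two conventions are in common use for the Switch boundaries; both are
#' shipped.  `"correlation"` (Switch I 29-37, Switch II 59-78, effector
#' lobe 1-86) is the set used for region-wise shift correlations;
#' `"classic"` (Switch I 30-38, Switch II 60-76) is the structural
#' convention.  The P-loop is residues 10-17 in both.
#'
#' @param set `"correlation"` or `"classic"`.
#' @return Named list of integer residue ranges.
#' @export
gtpase_regions <- function(set = c("correlation", "classic")) {
  set <- match.arg(set)
  if (set == "correlation")
    list(ploop = 10:17, switch1 = 29:37, switch2 = 59:78, effector_lobe = 1:86)
  else
    list(ploop = 10:17, switch1 = 30:38, switch2 = 60:76, effector_lobe = 1:86)
}

#' Combined two-nucleus shift-difference metric
#'
#' `Delta = sqrt((dw_N / sigma_N)^2 + (dw_HN / sigma_HN)^2)`, where the
#' normalizers are the standard deviations of amide 15N and 1HN chemical
#' shifts (5.218 and 0.634 ppm).  Residues with `Delta > 0.2` are
#' conventionally classed as exchange-affected.
#'
#' @param dw_n 15N shift difference(s), ppm.
#' @param dw_hn Amide 1H shift difference(s), ppm.
#' @param sigma_n,sigma_hn Normalizing standard deviations, ppm.
#' @return Dimensionless Delta (vectorized).
#' @examples
#' combined_delta(5.218, 0.634)  # sqrt(2)
#' @export
combined_delta <- function(dw_n, dw_hn, sigma_n = 5.218, sigma_hn = 0.634) {
  sqrt((dw_n / sigma_n)^2 + (dw_hn / sigma_hn)^2)
}

#' Shift table constructor
#'
#' @param residue_id Integer positions.
#' @param nucleus One of `"15N"`, `"1HN"`, `"13CA"`, `"13CB"` per row.
#' @param shift Chemical shift, ppm.
#' @param source Provenance tag, e.g. `"GTP-ground"`, `"GDP-equilibrium"`,
#'   `"random-coil"`, `"excited-reconstructed"`.
#' @return Data frame of class `shift_table`.
#' @export
shift_table <- function(residue_id, nucleus, shift, source) {
  nuc_ok <- c("15N", "1HN", "13CA", "13CB")
  if (!all(nucleus %in% nuc_ok))
    stop("nucleus must be one of ", paste(nuc_ok, collapse = ", "), call. = FALSE)
  out <- data.frame(residue_id = as.integer(residue_id), nucleus = nucleus,
                    shift = as.numeric(shift), source = source)
  if (anyDuplicated(out[c("residue_id", "nucleus", "source")]))
    stop("one shift per (residue, nucleus, source)", call. = FALSE)
  win <- list("15N" = c(100, 140), "1HN" = c(5, 12))
  for (nuc in intersect(names(win), unique(out$nucleus))) {
    s <- out$shift[out$nucleus == nuc]
    if (any(s < win[[nuc]][1] | s > win[[nuc]][2]))
      warning(sprintf("%s shifts outside the physical window %g-%g ppm",
                      nuc, win[[nuc]][1], win[[nuc]][2]), call. = FALSE)
  }
  class(out) <- c("shift_table", class(out))
  out
}

#' Reconstruct excited-state shifts from a global fit
#'
#' `Omega_excited = Omega_ground + dw` per residue and nucleus, using only
#' residues whose shift-difference sign was determined (by CEST).
#' Sign-ambiguous residues and residues without a ground shift are listed
#' in attributes `"sign_ambiguous"` and `"unmatched"`.
#'
#' @param ground A [shift_table] of ground-state shifts.
#' @param fit A [fit_global_two_state()] result, or a data frame with
#'   columns `residue_id`, `dw_15N` and optionally `sign_determined`.
#' @return A [shift_table] with `source = "excited-reconstructed"`.
#' @export
reconstruct_excited_shifts <- function(ground, fit) {
  res <- if (inherits(fit, "global_fit")) fit$residues else fit
  if (!"sign_determined" %in% names(res)) res$sign_determined <- TRUE
  dw <- res[!is.na(res$dw_15N), c("residue_id", "dw_15N", "sign_determined")]
  ambiguous <- dw$residue_id[!dw$sign_determined]
  dw <- dw[dw$sign_determined, , drop = FALSE]
  g <- ground[ground$nucleus == "15N", , drop = FALSE]
  m <- merge(dw, g, by = "residue_id")
  unmatched <- setdiff(dw$residue_id, m$residue_id)
  out <- shift_table(m$residue_id, "15N", m$shift + m$dw_15N,
                     "excited-reconstructed")
  attr(out, "sign_ambiguous") <- ambiguous
  attr(out, "unmatched") <- unmatched
  out
}

#' Correlate two per-residue shift sets over a region
#'
#' Pairs values on `residue_id`, restricts to a region, and reports the
#' Pearson R-squared and root-mean-square difference.
#'
#' @param x,y Data frames with columns `residue_id`, `value` (ppm).
#' @param region Optional integer vector of residue ids (e.g. an entry of
#'   [gtpase_regions()]); `NULL` uses all paired residues.
#' @return List with `r2`, `rmsd` (ppm) and `n`.
#' @export
correlate_shift_sets <- function(x, y, region = NULL) {
  m <- merge(x, y, by = "residue_id", suffixes = c("_x", "_y"))
  if (!is.null(region)) m <- m[m$residue_id %in% region, , drop = FALSE]
  if (nrow(m) < 3)
    stop_kexdyn("fewer than 3 paired residues in the region",
                "kexdyn_insufficient_pairs")
  list(r2 = stats::cor(m$value_x, m$value_y)^2,
       rmsd = sqrt(mean((m$value_x - m$value_y)^2)),
       n = nrow(m))
}

#' Select effector-lobe residues with large shift differences
#'
#' Residues within the effector lobe (default 1-86) whose absolute 15N
#' shift difference strictly exceeds a threshold (default 0.5 ppm).
#'
#' @param dw Data frame with columns `residue_id`, `dw_15N` (ppm, sign
#'   irrelevant).
#' @param threshold Cut-off, ppm.
#' @param lobe Residue range of the lobe.
#' @return Integer vector of residue ids.
#' @export
effector_lobe_selection <- function(dw, threshold = 0.5, lobe = 1:86) {
  sel <- dw$residue_id %in% lobe & !is.na(dw$dw_15N) &
    abs(dw$dw_15N) > threshold
  sort(unique(as.integer(dw$residue_id[sel])))
}
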