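# Observation containers for the global fit.

#' CPMG relaxation dispersion dataset
#'
#' @param data Data frame with columns `residue_id`, `nu_cpmg`, `r2eff`,
#'   `err` (one row per residue x frequency; errors are one standard
#'   deviation and must be positive).
#' @param field A [field_context] giving the static field and nucleus.
#' @param schedule A [cpmg_schedule]; its `nu_cpmg` must cover the data.
#' @param variant Free-text sample label (e.g. `"WT"`, `"G12C"`,
#'   `"synthetic"`).
#' @return Object of class `dispersion_dataset`.
#' @export
dispersion_dataset <- function(data, field, schedule, variant = "synthetic") {
  stopifnot(inherits(field, "field_context"), inherits(schedule, "cpmg_schedule"))
  req <- c("residue_id", "nu_cpmg", "r2eff", "err")
  if (!all(req %in% names(data)))
    stop("`data` must have columns ", paste(req, collapse = ", "), call. = FALSE)
  if (any(data$err <= 0)) stop("all errors must be > 0", call. = FALSE)
  if (anyDuplicated(data[c("residue_id", "nu_cpmg")]))
    stop("duplicated (residue_id, nu_cpmg) rows", call. = FALSE)
  data$residue_id <- as.integer(data$residue_id)
  structure(list(data = data, field = field, schedule = schedule,
                 variant = variant),
            class = "dispersion_dataset")
}

#' CEST dataset
#'
#' @param data Data frame with columns `residue_id`, `offset_ppm`,
#'   `intensity` (normalized `I/I0`), `err`.
#' @param field A [field_context] (nucleus `"15N"` for amide nitrogen CEST).
#' @param schedule A [cest_schedule].
#' @param variant Sample label.
#' @return Object of class `cest_dataset`.
#' @export
cest_dataset <- function(data, field, schedule, variant = "synthetic") {
  stopifnot(inherits(field, "field_context"), inherits(schedule, "cest_schedule"))
  req <- c("residue_id", "offset_ppm", "intensity", "err")
  if (!all(req %in% names(data)))
    stop("`data` must have columns ", paste(req, collapse = ", "), call. = FALSE)
  if (any(!is.finite(data$intensity)))
    stop("intensities must be finite", call. = FALSE)
  if (any(data$err <= 0)) stop("all errors must be > 0", call. = FALSE)
  data$residue_id <- as.integer(data$residue_id)
  structure(list(data = data, field = field, schedule = schedule,
                 variant = variant),
            class = "cest_dataset")
}

#' Exchange amplitude Rex per residue
#'
#' `Rex = R2,eff(lowest nu_cpmg) - R2,eff(highest nu_cpmg)` for each residue
#' of a dispersion dataset.  Residues exceeding a threshold (study default
#' 5 1/s) are selected for the global fit.
#'
#' @param dataset A [dispersion_dataset].
#' @return Data frame with columns `residue_id`, `rex`.
#' @export
estimate_rex <- function(dataset) {
  stopifnot(inherits(dataset, "dispersion_dataset"))
  d <- dataset$data
  out <- lapply(split(d, d$residue_id), function(g) {
    if (length(unique(g$nu_cpmg)) < 2)
      stop_kexdyn(sprintf(
        "residue %d has fewer than 2 CPMG frequencies; Rex is undefined",
        g$residue_id[1]), "kexdyn_insufficient_data")
    data.frame(residue_id = g$residue_id[1],
               rex = g$r2eff[which.min(g$nu_cpmg)] -
                 g$r2eff[which.max(g$nu_cpmg)])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$residue_id), , drop = FALSE]
}
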