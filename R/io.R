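# Readers and writers.  All tabular formats are UTF-8 tab-separated files
# with a mandatory header row; lines starting with '#' are comments.
# Residue numbering is 1-based throughout; any renumbering happens at the
# PDB reader boundary.

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing) > 0)
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  d
}

write_tsv <- function(d, path, header_comment = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a dispersion dataset as TSV
#'
#' One row per residue x point with columns `residue_id`, `nucleus`,
#' `field_MHz` (1H frequency), `nu_cpmg_or_offset`, `value` (R2,eff, 1/s),
#' `error`.  The relaxation delay lives in the study manifest, so the
#' reader takes it as an argument.
#'
#' @param ds A [dispersion_dataset].
#' @param path File path.
#' @return `write_dispersion_tsv`: the path, invisibly.
#' @export
write_dispersion_tsv <- function(ds, path) {
  stopifnot(inherits(ds, "dispersion_dataset"))
  d <- data.frame(residue_id = ds$data$residue_id,
                  nucleus = ds$field$nucleus,
                  field_MHz = ds$field$h1_mhz,
                  nu_cpmg_or_offset = ds$data$nu_cpmg,
                  value = ds$data$r2eff, error = ds$data$err)
  write_tsv(d, path, sprintf("CPMG R2,eff; t_relax = %g s; variant = %s",
                             ds$schedule$t_relax, ds$variant))
}

#' @rdname write_dispersion_tsv
#' @param t_relax Relaxation delay, s.
#' @param variant Sample label.
#' @return `read_dispersion_tsv`: a list of [dispersion_dataset] (one per
#'   `(nucleus, field_MHz)` present in the file).
#' @export
read_dispersion_tsv <- function(path, t_relax, variant = "unknown") {
  d <- read_tsv_checked(path, c("residue_id", "nucleus", "field_MHz",
                                "nu_cpmg_or_offset", "value", "error"))
  lapply(split(d, paste(d$nucleus, d$field_MHz)), function(g) {
    dispersion_dataset(
      data.frame(residue_id = g$residue_id, nu_cpmg = g$nu_cpmg_or_offset,
                 r2eff = g$value, err = g$error),
      field_context(g$field_MHz[1], g$nucleus[1]),
      cpmg_schedule(t_relax, sort(unique(g$nu_cpmg_or_offset))),
      variant = variant)
  })
}

#' Write / read a CEST dataset as TSV
#'
#' Same column dialect as [write_dispersion_tsv()], with offsets (ppm) in
#' `nu_cpmg_or_offset` and normalized intensities in `value`.
#'
#' @param ds A [cest_dataset].
#' @param path File path.
#' @return `write_cest_tsv`: the path, invisibly.
#' @export
write_cest_tsv <- function(ds, path) {
  stopifnot(inherits(ds, "cest_dataset"))
  d <- data.frame(residue_id = ds$data$residue_id,
                  nucleus = ds$field$nucleus,
                  field_MHz = ds$field$h1_mhz,
                  nu_cpmg_or_offset = ds$data$offset_ppm,
                  value = ds$data$intensity, error = ds$data$err)
  write_tsv(d, path, sprintf("CEST I/I0; t_ex = %g s; B1 = %g Hz; variant = %s",
                             ds$schedule$t_ex, ds$schedule$b1_hz, ds$variant))
}

#' @rdname write_cest_tsv
#' @param t_ex Mixing time, s.
#' @param b1_hz Saturation field, Hz.
#' @param variant Sample label.
#' @return `read_cest_tsv`: a list of [cest_dataset].
#' @export
read_cest_tsv <- function(path, t_ex, b1_hz, variant = "unknown") {
  d <- read_tsv_checked(path, c("residue_id", "nucleus", "field_MHz",
                                "nu_cpmg_or_offset", "value", "error"))
  lapply(split(d, paste(d$nucleus, d$field_MHz)), function(g) {
    cest_dataset(
      data.frame(residue_id = g$residue_id, offset_ppm = g$nu_cpmg_or_offset,
                 intensity = g$value, err = g$error),
      field_context(g$field_MHz[1], g$nucleus[1]),
      cest_schedule(t_ex, b1_hz, sort(unique(g$nu_cpmg_or_offset))),
      variant = variant)
  })
}

#' Write / read paired relaxation rates as TSV
#'
#' Long format: one row per residue x condition with columns `residue_id`,
#' `condition` (`free` or `np`), `R1`, `R1_err`, `R2`, `R2_err`.  Residues
#' present in only one condition are excluded by the reader with a
#' message.
#'
#' @param pairs A [relaxation_pairs] object.
#' @param path File path.
#' @return `write_relaxation_tsv`: the path invisibly;
#'   `read_relaxation_tsv`: a [relaxation_pairs] object.
#' @export
write_relaxation_tsv <- function(pairs, path) {
  stopifnot(inherits(pairs, "relaxation_pairs"))
  d <- pairs$data
  long <- rbind(
    data.frame(residue_id = d$residue_id, condition = "free",
               R1 = d$r1_free, R1_err = d$r1_free_err,
               R2 = d$r2_free, R2_err = d$r2_free_err),
    data.frame(residue_id = d$residue_id, condition = "np",
               R1 = d$r1_np, R1_err = d$r1_np_err,
               R2 = d$r2_np, R2_err = d$r2_np_err))
  long <- long[order(long$residue_id, long$condition), ]
  write_tsv(long, path, "15N relaxation rates with (np) / without (free) nanoparticles")
}

#' @rdname write_relaxation_tsv
#' @param field Optional [field_context] recorded on the result.
#' @export
read_relaxation_tsv <- function(path, field = NULL) {
  d <- read_tsv_checked(path, c("residue_id", "condition", "R1", "R1_err",
                                "R2", "R2_err"))
  fr <- d[d$condition == "free", ]
  np <- d[d$condition == "np", ]
  common <- intersect(fr$residue_id, np$residue_id)
  dropped <- setdiff(union(fr$residue_id, np$residue_id), common)
  if (length(dropped) > 0)
    message(sprintf("%d residue(s) present in only one condition excluded: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  fr <- fr[match(common, fr$residue_id), ]
  np <- np[match(common, np$residue_id), ]
  relaxation_pairs(data.frame(
    residue_id = common,
    r1_free = fr$R1, r1_free_err = fr$R1_err,
    r2_free = fr$R2, r2_free_err = fr$R2_err,
    r1_np = np$R1, r1_np_err = np$R1_err,
    r2_np = np$R2, r2_np_err = np$R2_err), field = field)
}

#' Read a chemical-shift table (TSV or NMR-STAR)
#'
#' The TSV dialect has columns `residue_id`, `nucleus`, `shift` and
#' optionally `source`.  For NMR-STAR, the `_Atom_chem_shift` loop of a
#' deposition file is parsed; amide N/H and CA/CB entries are mapped onto
#' the package nuclei and all other atoms are skipped with a message.
#'
#' @param path File path.
#' @param dialect `"auto"` (by extension/content), `"tsv"` or `"nmrstar"`.
#' @param source Source tag applied when the file does not carry one.
#' @return A [shift_table].
#' @export
read_shift_table <- function(path, dialect = c("auto", "tsv", "nmrstar"),
                             source = "unknown") {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    head_lines <- readLines(path, n = 50, warn = FALSE)
    dialect <- if (any(grepl("_Atom_chem_shift", head_lines))) "nmrstar" else "tsv"
  }
  if (dialect == "tsv") {
    d <- read_tsv_checked(path, c("residue_id", "nucleus", "shift"))
    src <- if ("source" %in% names(d)) d$source else source
    return(shift_table(d$residue_id, d$nucleus, d$shift, src))
  }
  parse_nmrstar_shifts(path, source)
}

# Minimal NMR-STAR chemical-shift loop parser: locates the loop whose tags
# include _Atom_chem_shift.*, maps the tag order onto columns, and reads
# whitespace-separated rows until the loop terminator.
parse_nmrstar_shifts <- function(path, source) {
  lines <- readLines(path, warn = FALSE)
  i <- 1; n <- length(lines)
  repeat {
    loop_start <- which(trimws(lines[i:n]) == "loop_")
    if (length(loop_start) == 0)
      stop(sprintf("%s: no _Atom_chem_shift loop found", path), call. = FALSE)
    ls <- i + loop_start[1] - 1
    # collect tags
    j <- ls + 1
    tags <- character(0)
    while (j <= n && startsWith(trimws(lines[j]), "_")) {
      tags <- c(tags, trimws(lines[j])); j <- j + 1
    }
    if (any(grepl("^_Atom_chem_shift\\.", tags))) break
    i <- j
    if (i > n) stop(sprintf("%s: no _Atom_chem_shift loop found", path),
                    call. = FALSE)
  }
  col <- function(tag) {
    k <- which(tags == paste0("_Atom_chem_shift.", tag))
    if (length(k) == 0) NA_integer_ else k
  }
  seq_col <- col("Seq_ID")
  if (is.na(seq_col)) seq_col <- col("Comp_index_ID")
  atom_col <- col("Atom_ID")
  val_col <- col("Val")
  if (is.na(seq_col) || is.na(atom_col) || is.na(val_col))
    stop(sprintf("%s: _Atom_chem_shift loop lacks Seq_ID/Atom_ID/Val near line %d",
                 path, ls), call. = FALSE)
  rows <- list()
  k <- j
  while (k <= n) {
    t <- trimws(lines[k])
    if (t %in% c("stop_", "") || startsWith(t, "_") || t == "loop_") break
    f <- strsplit(t, "\\s+")[[1]]
    if (length(f) >= max(seq_col, atom_col, val_col))
      rows[[length(rows) + 1]] <- f[c(seq_col, atom_col, val_col)]
    k <- k + 1
  }
  if (length(rows) == 0)
    stop(sprintf("%s: empty _Atom_chem_shift loop at line %d", path, ls),
         call. = FALSE)
  m <- do.call(rbind, rows)
  nuc_map <- c(N = "15N", H = "1HN", HN = "1HN", CA = "13CA", CB = "13CB")
  nuc <- nuc_map[m[, 2]]
  skipped <- sum(is.na(nuc))
  if (skipped > 0)
    message(sprintf("%s: skipped %d shift(s) of unmapped atom types", path, skipped))
  keep <- !is.na(nuc)
  shift_table(as.integer(m[keep, 1]), unname(nuc[keep]),
              as.numeric(m[keep, 3]), source)
}

#' Write a shift table or order-parameter profile as TSV
#'
#' @param x A [shift_table] or `order_param_profile` data frame.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  write_tsv(as.data.frame(x), path)
}

#' Read an order-parameter profile TSV
#'
#' @param path File path (columns `residue_id`, `s2`, optionally `s2_err`,
#'   `method`).
#' @return Data frame of class `order_param_profile`.
#' @export
read_order_params <- function(path) {
  d <- read_tsv_checked(path, c("residue_id", "s2"))
  class(d) <- c("order_param_profile", class(d))
  d
}

#' Read a conformer from a PDB file
#'
#' Standard `ATOM` records; the first model of multi-model files; altloc
#' `'A'` (or blank) preferred; insertion codes are rejected with a clear
#' message.  Backbone atoms N, CA, C, O and amide H are kept.
#'
#' @param path PDB file path.
#' @param label Conformer label (default: file name without extension).
#' @return A [conformer].
#' @export
read_pdb_conformer <- function(path, label = NULL) {
  label <- label %||% sub("\\.pdb$", "", basename(path), ignore.case = TRUE)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  a <- pdb$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  if (nrow(a) == 0) stop(path, ": no ATOM records", call. = FALSE)
  if (any(!is.na(a$insert) & a$insert != ""))
    stop(path, ": insertion codes are not supported; renumber the file first",
         call. = FALSE)
  a <- a[is.na(a$alt) | a$alt %in% c("", "A"), , drop = FALSE]
  keep <- a$elety %in% c("N", "CA", "C", "O", "H", "HN")
  a <- a[keep, , drop = FALSE]
  elety <- ifelse(a$elety == "HN", "H", a$elety)
  conformer(data.frame(residue_id = a$resno, resname = a$resid,
                       atom = elety, x = a$x, y = a$y, z = a$z),
            label = label)
}

#' Write a global fit result (TSV + JSON)
#'
#' @param fit A [fit_global_two_state()] result.
#' @param dir Output directory (created if needed).
#' @return Invisible character vector of the files written.
#' @export
write_fit_result <- function(fit, dir) {
  stopifnot(inherits(fit, "global_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "residue_params.tsv")
  write_tsv(fit$residues, tsv, "per-residue parameters from the global two-state fit")
  glob <- list(k_ex = fit$params$k_ex, p1 = fit$params$p1,
               k21 = fit$params$k21, k12 = fit$params$k12,
               chisq_red = fit$chisq_red, n_obs = fit$n_obs,
               n_residues = length(fit$selected),
               converged = fit$converged,
               non_identifiable = fit$non_identifiable)
  if (!is.null(fit$bootstrap)) {
    glob$k_ex_err <- fit$bootstrap$sd[["k_ex"]]
    glob$p1_err <- fit$bootstrap$sd[["p1"]]
  }
  js <- file.path(dir, "global_params.json")
  jsonlite::write_json(glob, js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}

#' Read / write a study manifest and load a study
#'
#' The manifest is a YAML file describing a study directory: the variant
#' label, a `seed`, and an `experiments` list whose entries have `type`
#' (`cpmg`, `cest` or `relaxation`), `path` (relative to the manifest) and
#' the schedule context (`t_relax` for CPMG; `t_ex` and `b1` for CEST).
#'
#' @param path Manifest path.
#' @return `read_study_manifest`: the parsed list. `load_study`: a list
#'   with `dispersions`, `cests`, `relaxation` and `manifest`.
#' @export
read_study_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  m <- yaml::read_yaml(path)
  if (is.null(m$experiments)) stop("manifest lacks `experiments`", call. = FALSE)
  for (e in m$experiments) {
    f <- file.path(dirname(path), e$path)
    if (!file.exists(f)) stop("manifest references missing file: ", f, call. = FALSE)
  }
  m
}

#' @rdname read_study_manifest
#' @export
load_study <- function(path) {
  m <- read_study_manifest(path)
  base <- dirname(path)
  variant <- m$variant %||% "unknown"
  dispersions <- list(); cests <- list(); relaxation <- NULL
  for (e in m$experiments) {
    f <- file.path(base, e$path)
    if (e$type == "cpmg") {
      dispersions <- c(dispersions, read_dispersion_tsv(f, e$t_relax, variant))
    } else if (e$type == "cest") {
      cests <- c(cests, read_cest_tsv(f, e$t_ex, e$b1, variant))
    } else if (e$type == "relaxation") {
      relaxation <- read_relaxation_tsv(f)
    } else stop("unknown experiment type: ", e$type, call. = FALSE)
  }
  list(dispersions = dispersions, cests = cests, relaxation = relaxation,
       manifest = m)
}

#' Write a complete synthetic study directory
#'
#' Emits the TSV observation files, a YAML manifest and a JSON ground-truth
#' record, in the layout that [load_study()] reads back.
#'
#' @param obs Result of [generate_observations()].
#' @param dir Output directory.
#' @param seed Seed recorded in the manifest.
#' @return The manifest path, invisibly.
#' @export
write_study <- function(obs, dir, seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  experiments <- list()
  for (i in seq_along(obs$dispersions)) {
    ds <- obs$dispersions[[i]]
    fn <- sprintf("cpmg_%s_%g.tsv", ds$field$nucleus, ds$field$h1_mhz)
    write_dispersion_tsv(ds, file.path(dir, fn))
    experiments <- c(experiments, list(list(
      type = "cpmg", path = fn, t_relax = ds$schedule$t_relax)))
  }
  for (i in seq_along(obs$cests)) {
    ds <- obs$cests[[i]]
    fn <- sprintf("cest_%s_%g_b1_%g.tsv", ds$field$nucleus, ds$field$h1_mhz,
                  ds$schedule$b1_hz)
    write_cest_tsv(ds, file.path(dir, fn))
    experiments <- c(experiments, list(list(
      type = "cest", path = fn, t_ex = ds$schedule$t_ex,
      b1 = ds$schedule$b1_hz)))
  }
  variant <- if (length(obs$dispersions) > 0) obs$dispersions[[1]]$variant
             else if (length(obs$cests) > 0) obs$cests[[1]]$variant else "synthetic"
  manifest <- list(variant = variant, seed = seed, experiments = experiments,
                   package_version = as.character(utils::packageVersion("kexdyn")))
  mp <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, mp)
  jsonlite::write_json(obs$truth, file.path(dir, "truth.json"),
                       digits = NA, dataframe = "columns")
  invisible(mp)
}
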