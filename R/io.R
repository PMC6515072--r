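#' Write a dataset to delimited text files
#'
#' Emits the exchange formats the pipeline ingests: `spectra.csv` (long
#' format: `sample_id`, `wavelength_nm`, `absorbance`), `manifest.csv`, and
#' for synthetic datasets the ground truth (`truth_by_dose.csv`,
#' `truth_cp.csv`) in separate files so blind runs are possible, plus
#' `config.json`.
#'
#' @param ds a `synth_dataset` from [generate_experiment()] or any list with
#'   `spectra` and `manifest`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(is.list(ds), !is.null(ds$spectra), !is.null(ds$manifest))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  long <- do.call(rbind, lapply(ds$spectra, function(s) {
    data.frame(sample_id = s$sample_id, wavelength_nm = s$wavelength,
               absorbance = s$absorbance, stringsAsFactors = FALSE)
  }))
  paths <- c(
    spectra = file.path(dir, "spectra.csv"),
    manifest = file.path(dir, "manifest.csv")
  )
  utils::write.csv(long, paths["spectra"], row.names = FALSE)
  utils::write.csv(ds$manifest, paths["manifest"], row.names = FALSE)
  if (!is.null(ds$truth)) {
    paths["truth_by_dose"] <- file.path(dir, "truth_by_dose.csv")
    paths["truth_cp"] <- file.path(dir, "truth_cp.csv")
    utils::write.csv(ds$truth$by_dose, paths["truth_by_dose"], row.names = FALSE)
    utils::write.csv(ds$truth$cp_a520, paths["truth_cp"], row.names = FALSE)
  }
  if (!is.null(ds$config)) {
    paths["config"] <- file.path(dir, "config.json")
    cfg <- ds$config
    cfg$copigments <- as.data.frame(cfg$copigments)
    jsonlite::write_json(unclass(cfg), paths["config"], auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  }
  invisible(paths)
}

#' Load spectra + manifest and validate the pairing structure
#'
#' Reads the long-format spectra table and the manifest (file paths or
#' in-memory data frames), builds typed [vis_spectrum()] objects, and
#' validates: unique sample ids, known roles and families, every spectrum
#' referenced by the manifest present, and for every mix a resolvable blank
#' (same copigment, dose, pH, ethanol, replicate) and control (same pH,
#' ethanol, replicate). Violations are errors listing the offending rows;
#' negative absorbance produces warnings collected in the validation report.
#'
#' @param manifest path to `manifest.csv` or a data frame.
#' @param spectra path to `spectra.csv` (long format) or a data frame with
#'   columns `sample_id`, `wavelength_nm`, `absorbance`.
#' @param neg_tol absorbance below `-neg_tol` triggers a negative-absorbance
#'   warning (default 0.01 AU, the instrument noise floor: raw baselines
#'   legitimately dither a few milli-AU below zero).
#' @return List of class `copig_dataset`: `spectra` (named list of
#'   `vis_spectrum`), `manifest`, `warnings` (character vector).
#' @export
load_and_validate <- function(manifest, spectra, neg_tol = 0.01) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  if (is.character(spectra)) spectra <- utils::read.csv(spectra)
  need_m <- c("sample_id", "role", "copigment", "family", "dose_g_per_L",
              "pigment_mg_per_L", "pH", "ethanol_pct", "replicate")
  if (!all(need_m %in% names(manifest)))
    stop("manifest is missing column(s): ",
         paste(setdiff(need_m, names(manifest)), collapse = ", "))
  need_s <- c("sample_id", "wavelength_nm", "absorbance")
  if (!all(need_s %in% names(spectra)))
    stop("spectra table is missing column(s): ",
         paste(setdiff(need_s, names(spectra)), collapse = ", "))

  dup <- manifest$sample_id[duplicated(manifest$sample_id)]
  if (length(dup))
    stop("duplicated sample_id in manifest: ", paste(unique(dup), collapse = ", "))
  bad_role <- !manifest$role %in% c("mix", "blank", "control", "corrected")
  if (any(bad_role))
    stop("unknown role in manifest row(s): ",
         paste(which(bad_role), collapse = ", "))
  fam_ok <- c("PC/PD", "PF/PR", "GT", "ET", "reference")
  bad_fam <- !(is.na(manifest$family) | manifest$family %in% fam_ok)
  if (any(bad_fam))
    stop("unknown family in manifest row(s): ",
         paste(which(bad_fam), collapse = ", "),
         " (allowed: ", paste(fam_ok, collapse = ", "), ")")

  missing_spec <- setdiff(manifest$sample_id, unique(spectra$sample_id))
  if (length(missing_spec))
    stop("manifest rows without spectra: ", paste(missing_spec, collapse = ", "))

  # pairing checks: every mix needs a blank and a control
  keyb <- function(df) paste(df$copigment, df$dose_g_per_L, df$pH,
                             df$ethanol_pct, df$replicate)
  keyc <- function(df) paste(df$pH, df$ethanol_pct, df$replicate)
  mixes <- manifest[manifest$role == "mix", , drop = FALSE]
  blanks <- manifest[manifest$role == "blank", , drop = FALSE]
  ctrls <- manifest[manifest$role == "control", , drop = FALSE]
  no_blank <- !(keyb(mixes) %in% keyb(blanks))
  if (any(no_blank))
    stop("mix row(s) without a matching copigment blank: ",
         paste(mixes$sample_id[no_blank], collapse = ", "))
  no_ctrl <- !(keyc(mixes) %in% keyc(ctrls))
  if (any(no_ctrl))
    stop("mix row(s) without a matching pigment-only control: ",
         paste(mixes$sample_id[no_ctrl], collapse = ", "))

  warn <- character()
  sp <- split(spectra, spectra$sample_id)
  specs <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    d <- sp[[m$sample_id]]
    d <- d[order(d$wavelength_nm), , drop = FALSE]
    s <- vis_spectrum(
      m$sample_id, d$wavelength_nm, d$absorbance, role = m$role,
      copigment = if (is.na(m$copigment)) NA_character_ else as.character(m$copigment),
      family = if (is.na(m$family)) NA_character_ else as.character(m$family),
      dose_g_per_L = m$dose_g_per_L, pigment_mg_per_L = m$pigment_mg_per_L,
      pH = m$pH, ethanol_pct = m$ethanol_pct, replicate = m$replicate
    )
    if (any(s$absorbance < -neg_tol)) {
      s$flags <- union(s$flags, "negative_absorbance")
      warn <<- c(warn, sprintf("negative absorbance in '%s'", m$sample_id))
    }
    s
  })
  names(specs) <- manifest$sample_id
  structure(list(spectra = specs, manifest = manifest, warnings = warn),
            class = "copig_dataset")
}

#' Bundled reference Cp tables
#'
#' Three small delimited fixtures transcribed from the printed result tables
#' of a published study of oenological-tannin copigmentation of
#' malvidin-3-O-glucoside (36 commercial tannins plus an epicatechin
#' reference; raw spectra unpublished). They feed the aggregation and
#' counting operations and the acceptance checks.
#'
#' * `reference_cp_products()`: per-product colour results by botanical
#'   origin and tannin family (columns `family`, `origin`, `product`, then
#'   `A520`, `L`, `a`, `b`, `hab`, `Cab` each with an `_sd` companion).
#' * `reference_cp_ph()`: Cp and r-squared by pH level (3.1/3.5/3.9 at 12%
#'   ethanol) for five tannins plus epicatechin, long format.
#' * `reference_cp_ethanol()`: same at 10/12/14% ethanol, pH 3.5.
#'
#' Values are transcribed verbatim, including two internally atypical
#' printed entries (a quebracho b*/hue pair and one r-squared of 0.0885)
#' that are retained rather than corrected.
#'
#' @return A data frame.
#' @name reference-tables
NULL

ref_file <- function(f) {
  p <- system.file("extdata", f, package = "copigmentr")
  if (p == "") stop("bundled fixture not found: ", f)
  utils::read.csv(p, check.names = FALSE)
}

#' @rdname reference-tables
#' @export
reference_cp_products <- function() ref_file("cp_products.csv")

#' @rdname reference-tables
#' @export
reference_cp_ph <- function() ref_file("cp_by_ph.csv")

#' @rdname reference-tables
#' @export
reference_cp_ethanol <- function() ref_file("cp_by_ethanol.csv")
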