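#' Visible absorbance spectrum with sample metadata
#'
#' A `vis_spectrum` holds one absorbance curve (10 mm path, absorbance units)
#' on a strictly increasing wavelength grid inside 400-800 nm, together with
#' the sample manifest metadata the pipeline needs: role (mix, blank or
#' control), copigment identity and tannin family, dose, pigment
#' concentration, pH, ethanol content and replicate index.
#'
#' Coverage must include 420-700 nm; narrower curves cannot be resampled onto
#' the colorimetric grid and are rejected at construction.
#'
#' @param sample_id character scalar, unique sample identifier.
#' @param wavelength strictly increasing numeric vector, nm, within
#'   \[400, 800\].
#' @param absorbance numeric vector, same length as `wavelength`, AU.
#' @param role one of `"mix"`, `"blank"`, `"control"`, `"corrected"`.
#' @param copigment copigment identifier (`NA` for pigment-only controls).
#' @param family one of `"PC/PD"`, `"PF/PR"`, `"GT"`, `"ET"`, `"reference"`
#'   or `NA`.
#' @param dose_g_per_L copigment dose, g/L (0 for controls).
#' @param pigment_mg_per_L pigment concentration, mg/L.
#' @param pH,ethanol_pct solution condition.
#' @param replicate replicate index, integer >= 1.
#' @param flags character vector of warning flags attached to the sample.
#' @return An object of class `vis_spectrum`.
#' @examples
#' s <- vis_spectrum("ctrl", seq(400, 800, 5), rep(0.1, 81),
#'   role = "control", pigment_mg_per_L = 50, pH = 3.5, ethanol_pct = 12
#' )
#' a520(s)
#' @export
vis_spectrum <- function(sample_id, wavelength, absorbance,
                         role = c("mix", "blank", "control", "corrected"),
                         copigment = NA_character_, family = NA_character_,
                         dose_g_per_L = 0, pigment_mg_per_L = NA_real_,
                         pH = NA_real_, ethanol_pct = NA_real_,
                         replicate = 1L, flags = character()) {
  role <- match.arg(role)
  wavelength <- as.numeric(wavelength)
  absorbance <- as.numeric(absorbance)
  if (length(wavelength) != length(absorbance))
    stop("wavelength and absorbance must have the same length")
  if (length(wavelength) < 2)
    stop("a spectrum needs at least 2 points")
  if (any(diff(wavelength) <= 0))
    stop("wavelengths must be strictly increasing")
  if (min(wavelength) < 400 || max(wavelength) > 800)
    stop("wavelengths must lie within [400, 800] nm")
  if (min(wavelength) > 420 || max(wavelength) < 700)
    stop(sprintf(
      "spectrum '%s' covers %g-%g nm; coverage must include [420, 700] nm",
      sample_id, min(wavelength), max(wavelength)
    ))
  if (!all(is.finite(absorbance)))
    stop("absorbance values must be finite")
  fam_ok <- c("PC/PD", "PF/PR", "GT", "ET", "reference")
  if (!is.na(family) && !family %in% fam_ok)
    stop("family must be one of: ", paste(fam_ok, collapse = ", "))
  structure(
    list(
      sample_id = as.character(sample_id),
      wavelength = wavelength,
      absorbance = absorbance,
      meta = list(
        role = role, copigment = copigment, family = family,
        dose_g_per_L = as.numeric(dose_g_per_L),
        pigment_mg_per_L = as.numeric(pigment_mg_per_L),
        pH = as.numeric(pH), ethanol_pct = as.numeric(ethanol_pct),
        replicate = as.integer(replicate)
      ),
      flags = flags
    ),
    class = "vis_spectrum"
  )
}

#' @export
print.vis_spectrum <- function(x, ...) {
  m <- x$meta
  cat(sprintf(
    "<vis_spectrum> %s [%s] %g-%g nm (%d pts)\n  copigment=%s family=%s dose=%g g/L pH=%g EtOH=%g%% rep=%d%s\n",
    x$sample_id, m$role, min(x$wavelength), max(x$wavelength),
    length(x$wavelength), m$copigment, m$family, m$dose_g_per_L,
    m$pH, m$ethanol_pct, m$replicate,
    if (length(x$flags)) paste0("\n  flags: ", paste(x$flags, collapse = ", ")) else ""
  ))
  invisible(x)
}

#' Resample a spectrum onto an observer grid
#'
#' Linear interpolation of the absorbance curve at each grid wavelength.
#' Metadata and flags are preserved. The spectrum must cover the full grid
#' span; a coverage gap is an error naming the missing interval
#' (extrapolation is never performed).
#'
#' @param spec a [vis_spectrum()].
#' @param grid an [observer_grid()] (or any numeric wavelength vector).
#' @return A `vis_spectrum` sampled exactly on the grid wavelengths.
#' @export
resample_to_grid <- function(spec, grid) {
  stopifnot(inherits(spec, "vis_spectrum"))
  wl <- if (inherits(grid, "observer_grid")) grid$wavelength else as.numeric(grid)
  lo <- min(spec$wavelength); hi <- max(spec$wavelength)
  if (min(wl) < lo || max(wl) > hi) {
    miss <- character()
    if (min(wl) < lo) miss <- c(miss, sprintf("[%g, %g]", min(wl), lo))
    if (max(wl) > hi) miss <- c(miss, sprintf("[%g, %g]", hi, max(wl)))
    stop(sprintf(
      "spectrum '%s' does not cover the grid: missing span %s nm",
      spec$sample_id, paste(miss, collapse = " and ")
    ))
  }
  ab <- stats::approx(spec$wavelength, spec$absorbance, xout = wl,
                      method = "linear", rule = 1)$y
  out <- spec
  out$wavelength <- wl
  out$absorbance <- ab
  out
}

#' Absorbance at 520 nm
#'
#' Returns the measured value if 520 nm is sampled, otherwise the linear
#' interpolation between the neighbouring points. Measured visible curves are
#' smooth and dense, so linear interpolation is adequate.
#'
#' @param spec a [vis_spectrum()].
#' @param at wavelength in nm (default 520).
#' @return Absorbance (AU) at `at`.
#' @export
a520 <- function(spec, at = 520) {
  stopifnot(inherits(spec, "vis_spectrum"))
  if (min(spec$wavelength) > at || max(spec$wavelength) < at)
    stop(sprintf("spectrum '%s' has no coverage at %g nm", spec$sample_id, at))
  stats::approx(spec$wavelength, spec$absorbance, xout = at)$y
}
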