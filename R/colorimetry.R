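#' Beer-Lambert transmittance from absorbance
#'
#' `T = 10^(-A)` for a 10 mm path. Negative absorbance (possible after blank
#' subtraction) is accepted and yields `T > 1`; callers flag such samples
#' rather than clipping, so subtraction artifacts stay visible.
#'
#' @param a numeric absorbance (AU); must be finite.
#' @return Transmittance fraction(s).
#' @examples
#' absorbance_to_transmittance(c(0, 1, 2))
#' @export
absorbance_to_transmittance <- function(a) {
  if (!all(is.finite(a))) stop("absorbance must be finite")
  10^(-a)
}

#' Tristimulus values of a spectrum under an observer/illuminant grid
#'
#' Weighted summation on the grid,
#' `X = k * sum(T * S * xbar * w)` (likewise Y, Z), with trapezoidal
#' quadrature weights `w` (half step at the endpoints) and
#' `k = 100 / sum(S * ybar * w)` over the identical truncated grid, so a
#' unit-transmittance sample reproduces the whitepoint exactly.
#'
#' @param spec a [vis_spectrum()] already resampled on `grid` (its wavelengths
#'   must match the grid exactly; a mismatch is an error).
#' @param grid an [observer_grid()].
#' @return Named numeric `c(X, Y, Z)`.
#' @export
tristimulus <- function(spec, grid) {
  stopifnot(inherits(spec, "vis_spectrum"), inherits(grid, "observer_grid"))
  if (length(spec$wavelength) != nrow(grid) ||
      any(spec$wavelength != grid$wavelength))
    stop("spectrum is not sampled on the observer grid; resample_to_grid() first")
  tr <- absorbance_to_transmittance(spec$absorbance)
  w <- attr(grid, "weights")
  k <- attr(grid, "k")
  c(
    X = k * sum(tr * grid$power * grid$xbar * w),
    Y = k * sum(tr * grid$power * grid$ybar * w),
    Z = k * sum(tr * grid$power * grid$zbar * w)
  )
}

# CIE f() with the linear branch below (6/29)^3
lab_f <- function(t) {
  eps <- (6 / 29)^3
  ifelse(t > eps, t^(1 / 3), (841 / 108) * t + 4 / 29)
}

#' CIELAB coordinates from tristimulus values
#'
#' `L* = 116 f(Y/Yn) - 16`, `a* = 500 (f(X/Xn) - f(Y/Yn))`,
#' `b* = 200 (f(Y/Yn) - f(Z/Zn))` with the standard two-branch `f`.
#'
#' @param xyz named numeric `c(X, Y, Z)`.
#' @param whitepoint named numeric `c(X, Y, Z)`, all positive; defaults to the
#'   grid-consistent whitepoint when a grid is supplied instead.
#' @return Named numeric `c(L, a, b)`.
#' @export
xyz_to_lab <- function(xyz, whitepoint) {
  if (inherits(whitepoint, "observer_grid")) whitepoint <- attr(whitepoint, "whitepoint")
  if (any(!is.finite(xyz)) || any(!is.finite(whitepoint)))
    stop("non-finite tristimulus or whitepoint")
  if (any(whitepoint <= 0)) stop("whitepoint must be positive")
  fx <- lab_f(xyz[["X"]] / whitepoint[["X"]])
  fy <- lab_f(xyz[["Y"]] / whitepoint[["Y"]])
  fz <- lab_f(xyz[["Z"]] / whitepoint[["Z"]])
  c(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

#' Chroma and hue angle from a*, b*
#'
#' `C*ab = sqrt(a*^2 + b*^2)`; `hab` is the signed angle of `(a*, b*)` in
#' degrees in (-180, 180\] (atan2 convention, never wrapped to \[0, 360)),
#' matching the negative hue angles of red wine colour (a* > 0, b* < 0). An
#' achromatic point (`C*ab = 0`) has undefined hue, reported as `NA` rather
#' than a fabricated angle.
#'
#' @param a,b CIELAB a*, b*.
#' @return Named numeric `c(Cab, hab)`; `hab` is `NA` when `Cab == 0`.
#' @examples
#' chroma_hue(3, -4) # Cab 5, hab -53.13
#' @export
chroma_hue <- function(a, b) {
  cab <- sqrt(a^2 + b^2)
  hab <- ifelse(cab == 0, NA_real_, atan2(b, a) * 180 / pi)
  c(Cab = cab, hab = hab)
}

#' Full colour coordinates of one spectrum
#'
#' Resamples onto the grid, computes A520, tristimulus values, CIELAB, chroma
#' and hue. Negative absorbance anywhere on the grid adds a
#' `"negative_absorbance"` flag (transmittance above 1 is kept, not clipped).
#'
#' @param spec a [vis_spectrum()].
#' @param grid an [observer_grid()]; default `observer_grid()`.
#' @return One-row data frame: `sample_id`, `A520`, `X`, `Y`, `Z`, `L`, `a`,
#'   `b`, `Cab`, `hab`, `neg_absorbance`.
#' @export
spectrum_color <- function(spec, grid = observer_grid()) {
  rs <- resample_to_grid(spec, grid)
  xyz <- tristimulus(rs, grid)
  lab <- xyz_to_lab(xyz, attr(grid, "whitepoint"))
  ch <- chroma_hue(lab[["a"]], lab[["b"]])
  neg <- any(rs$absorbance < 0)
  data.frame(
    sample_id = spec$sample_id,
    A520 = a520(spec),
    X = xyz[["X"]], Y = xyz[["Y"]], Z = xyz[["Z"]],
    L = lab[["L"]], a = lab[["a"]], b = lab[["b"]],
    Cab = ch[["Cab"]], hab = ch[["hab"]],
    neg_absorbance = neg,
    stringsAsFactors = FALSE
  )
}
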