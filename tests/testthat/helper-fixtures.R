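# Shared fixtures built in code.

default_grid <- observer_grid()

flat_spectrum <- function(a, id = "flat", wl = seq(400, 800, by = 5)) {
  vis_spectrum(id, wl, rep(a, length(wl)), role = "control",
               pigment_mg_per_L = 50, pH = 3.5, ethanol_pct = 12)
}

gaussian_spectrum <- function(amp = 1, center = 520, width = 30,
                              wl = seq(400, 800, by = 1), id = "band") {
  vis_spectrum(id, wl, amp * exp(-(wl - center)^2 / (2 * width^2)),
               role = "control", pigment_mg_per_L = 50,
               pH = 3.5, ethanol_pct = 12)
}

# Independent tristimulus oracle: 1 nm trapezoidal integration of the same
# CMF/illuminant data, written without the package's summation code.
tristimulus_trapezoid <- function(absorbance_fun, wl_range = c(400, 780)) {
  wl <- seq(wl_range[1], wl_range[2], by = 1)
  tr <- 10^(-absorbance_fun(wl))
  xb <- copigmentr:::cmf_xbar(wl)
  yb <- copigmentr:::cmf_ybar(wl)
  zb <- copigmentr:::cmf_zbar(wl)
  S <- copigmentr:::d65_power(wl)
  trap <- function(y) sum((y[-1] + y[-length(y)]) / 2 * diff(wl))
  k <- 100 / trap(S * yb)
  c(X = k * trap(tr * S * xb), Y = k * trap(tr * S * yb),
    Z = k * trap(tr * S * zb))
}

# Tiny synthetic config for fast pipeline runs.
small_config <- function(..., seed = 11) {
  synth_config(
    conditions = data.frame(pH = 3.5, ethanol_pct = 12),
    wavelength = seq(400, 800, by = 5),
    seed = seed, ...
  )
}
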