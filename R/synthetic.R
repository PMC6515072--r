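#' Flavylium fraction at a given pH
#'
#' Fraction of the pigment in the coloured flavylium form under the hydration
#' equilibrium: `f = 1 / (1 + 10^(pH - pKh))`, strictly decreasing in pH.
#' This is the standard one-proton equilibrium stand-in for the bleaching of
#' anthocyanins at higher pH.
#'
#' @param pH solution pH.
#' @param pKh hydration constant (pH units); default 2.6, a literature-typical
#'   value for malvidin-3-O-glucoside.
#' @return Fraction in (0, 1).
#' @examples
#' flavylium_fraction(2.6) # 0.5
#' @export
flavylium_fraction <- function(pH, pKh = 2.6) {
  1 / (1 + 10^(pH - pKh))
}

#' Bound pigment fraction under a 1:1 binding isotherm
#'
#' `theta = K_eff * dose / (1 + K_eff * dose)` with
#' `K_eff = K0 * exp(-beta * (ethanol - 12))`: ethanol above the 12% baseline
#' weakens the copigmentation complex (for `beta > 0`), below strengthens it.
#' `theta(0) = 0`; `theta` increases with dose and decreases with ethanol.
#'
#' @param dose_g_per_L copigment dose, g/L, `>= 0`.
#' @param K0 binding strength at 12% ethanol, per (g/L), `>= 0`.
#' @param beta ethanol sensitivity, per percent ethanol.
#' @param ethanol_pct ethanol content, percent v/v.
#' @return Bound fraction in \[0, 1).
#' @export
bound_fraction <- function(dose_g_per_L, K0, beta = 0, ethanol_pct = 12) {
  if (any(dose_g_per_L < 0)) stop("dose must be >= 0")
  if (any(K0 < 0)) stop("K0 must be >= 0")
  keff <- K0 * exp(-beta * (ethanol_pct - 12))
  keff * dose_g_per_L / (1 + keff * dose_g_per_L)
}

#' Default synthetic copigment panel
#'
#' Six copigments mirroring the panel a pH/ethanol copigmentation study would
#' carry: a reference flavan-3-ol, two grape-derived condensed tannins, a
#' quebracho condensed tannin, a gallotannin and an ellagitannin. The
#' hyperchromic gains are anchored to the reported field magnitudes:
#' gallotannins about four times and ellagitannins about twice as effective
#' as condensed tannins, with hydrolysable tannins showing the larger
#' bathochromic displacement.
#'
#' @return Data frame with columns `copigment`, `family`, `K0`, `alpha_h`
#'   (hyperchromic gain per bound fraction), `delta_lambda` (bathochromic
#'   shift, nm per bound fraction), `blank_amp` (blank tail amplitude at
#'   400 nm, AU per g/L).
#' @export
default_copigments <- function() {
  data.frame(
    copigment = c("epicatechin", "grape-seed", "grape-skin", "quebracho",
                  "gallotannin", "ellagitannin"),
    family = c("reference", "PC/PD", "PC/PD", "PF/PR", "GT", "ET"),
    K0 = 0.6,
    alpha_h = c(0.60, 0.75, 0.85, 0.70, 3.00, 1.50),
    delta_lambda = c(3, 4, 4, 5, 8, 8),
    blank_amp = c(0.02, 0.10, 0.10, 0.12, 0.15, 0.15),
    stringsAsFactors = FALSE
  )
}

#' Configuration of the synthetic spectrum generator
#'
#' Ground-truth generative parameters for [generate_experiment()]. The
#' defaults state the study design being emulated: 50 mg/L pigment, doses
#' 0, 0.1, 0.2, 0.4 g/L (ratios 0/2/4/8), three replicates, and the star
#' condition grid (pH 3.1/3.5/3.9 at 12% ethanol; 10/12/14% ethanol at
#' pH 3.5), with a 520 nm pigment band and instrument-scale noise of
#' 0.002 AU.
#'
#' @param pigment_mg_per_L pigment concentration (default 50).
#' @param lambda_max band position of the free pigment, nm (default 520).
#' @param band_sigma Gaussian band width, nm (default 40).
#' @param band_amp band peak absorbance, AU per 50 mg/L of fully-flavylium
#'   pigment (default 2.8, giving a pH 3.5 control A520 near 0.3).
#' @param pKh flavylium hydration constant (default 2.6).
#' @param beta_ethanol ethanol sensitivity of binding, per percent
#'   (default 0.15).
#' @param copigments copigment panel data frame as in [default_copigments()].
#' @param blank_decay decay length of the copigment blank's short-wavelength
#'   tail, nm (default 60).
#' @param noise_sd i.i.d. Gaussian noise per wavelength point, AU
#'   (default 0.002).
#' @param replicates replicates per sample (default 3).
#' @param doses dose grid in g/L, must include 0 (default
#'   `c(0, 0.1, 0.2, 0.4)`).
#' @param conditions data frame of `pH`, `ethanol_pct` rows (default star
#'   grid).
#' @param wavelength measurement grid, nm (default `seq(400, 800, 2)`).
#' @param seed integer RNG seed (default 1).
#' @return List of class `synth_config`.
#' @export
synth_config <- function(pigment_mg_per_L = 50, lambda_max = 520,
                         band_sigma = 40, band_amp = 2.8, pKh = 2.6,
                         beta_ethanol = 0.15,
                         copigments = default_copigments(),
                         blank_decay = 60, noise_sd = 0.002, replicates = 3,
                         doses = c(0, 0.1, 0.2, 0.4),
                         conditions = data.frame(
                           pH = c(3.1, 3.5, 3.9, 3.5, 3.5),
                           ethanol_pct = c(12, 12, 12, 10, 14)
                         ),
                         wavelength = seq(400, 800, by = 2), seed = 1L) {
  stopifnot(
    pigment_mg_per_L > 0, band_sigma > 0, band_amp >= 0, blank_decay > 0,
    noise_sd >= 0, replicates >= 1, all(doses >= 0), 0 %in% doses,
    is.data.frame(conditions),
    all(c("pH", "ethanol_pct") %in% names(conditions)),
    is.data.frame(copigments),
    all(c("copigment", "family", "K0", "alpha_h", "delta_lambda",
          "blank_amp") %in% names(copigments)),
    all(copigments$K0 >= 0), all(copigments$blank_amp >= 0)
  )
  conditions <- unique(conditions[, c("pH", "ethanol_pct")])
  structure(
    list(
      pigment_mg_per_L = pigment_mg_per_L, lambda_max = lambda_max,
      band_sigma = band_sigma, band_amp = band_amp, pKh = pKh,
      beta_ethanol = beta_ethanol, copigments = copigments,
      blank_decay = blank_decay, noise_sd = noise_sd,
      replicates = as.integer(replicates), doses = sort(doses),
      conditions = conditions, wavelength = wavelength,
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

# Noiseless pigment band: amplitude scaled by pigment concentration,
# flavylium fraction and hyperchromic gain; position displaced by the
# bathochromic shift, both proportional to the bound fraction.
pigment_band <- function(wl, cfg, f_flav, theta, alpha_h, delta_lambda) {
  cfg$band_amp * (cfg$pigment_mg_per_L / 50) * f_flav * (1 + alpha_h * theta) *
    exp(-(wl - cfg$lambda_max - delta_lambda * theta)^2 / (2 * cfg$band_sigma^2))
}

# Coloured copigment blank: short-wavelength exponential tail.
blank_tail <- function(wl, dose, blank_amp, blank_decay) {
  dose * blank_amp * exp(-(wl - 400) / blank_decay)
}

#' Generate a synthetic copigmentation experiment
#'
#' Emulates the one-week endpoint measurement of a model-wine dose series:
#' for every condition and replicate a pigment-only control, and for every
#' copigment and positive dose a coloured copigment blank and a mix spectrum
#' (pigment band + blank tail), all with seeded i.i.d. Gaussian noise per
#' point. The mix and its blank carry independent noise, as two separately
#' measured cuvettes would.
#'
#' Ground truth is recorded alongside: the bound fraction at every dose and
#' the analytic Cp(A520) per copigment x condition, defined as the exact OLS
#' slope of the noiseless corrected A520 values on the ratio grid (the
#' estimand of the downstream pipeline at zero noise).
#'
#' @param cfg a [synth_config()].
#' @return List of class `synth_dataset`: `spectra` (named list of
#'   [vis_spectrum()]), `manifest` (data frame), `truth` (list with `by_dose`
#'   and `cp_a520` data frames), `config`.
#' @export
generate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  wl <- cfg$wavelength
  noise <- function() stats::rnorm(length(wl), 0, cfg$noise_sd)
  spectra <- list()
  manifest <- list()
  by_dose <- list()
  cp_true <- list()

  add <- function(id, ab, role, copigment, family, dose, rep) {
    spectra[[id]] <<- vis_spectrum(
      id, wl, ab, role = role, copigment = copigment, family = family,
      dose_g_per_L = dose, pigment_mg_per_L = cfg$pigment_mg_per_L,
      pH = ph, ethanol_pct = et, replicate = rep
    )
    manifest[[length(manifest) + 1]] <<- data.frame(
      sample_id = id, role = role, copigment = copigment, family = family,
      dose_g_per_L = dose, pigment_mg_per_L = cfg$pigment_mg_per_L,
      pH = ph, ethanol_pct = et, replicate = rep, stringsAsFactors = FALSE
    )
  }

  for (ci in seq_len(nrow(cfg$conditions))) {
    ph <- cfg$conditions$pH[ci]
    et <- cfg$conditions$ethanol_pct[ci]
    f_flav <- flavylium_fraction(ph, cfg$pKh)
    ctag <- sprintf("pH%.1f_et%g", ph, et)

    for (r in seq_len(cfg$replicates)) {
      ab <- pigment_band(wl, cfg, f_flav, 0, 0, 0) + noise()
      add(sprintf("%s_control_r%d", ctag, r), ab, "control",
          NA_character_, NA_character_, 0, r)
    }

    for (pi in seq_len(nrow(cfg$copigments))) {
      cp <- cfg$copigments[pi, ]
      doses <- cfg$doses
      theta <- bound_fraction(doses, cp$K0, cfg$beta_ethanol, et)
      # analytic truth: noiseless corrected A520 over the full dose grid
      a520_true <- vapply(theta, function(th) {
        pigment_band(520, cfg, f_flav, th, cp$alpha_h, cp$delta_lambda)
      }, numeric(1))
      ratio <- mass_ratio(doses, cfg$pigment_mg_per_L)
      slope <- sum((ratio - mean(ratio)) * (a520_true - mean(a520_true))) /
        sum((ratio - mean(ratio))^2)
      by_dose[[length(by_dose) + 1]] <- data.frame(
        copigment = cp$copigment, family = cp$family, pH = ph,
        ethanol_pct = et, dose_g_per_L = doses, ratio = ratio,
        theta = theta, a520_true = a520_true, stringsAsFactors = FALSE
      )
      cp_true[[length(cp_true) + 1]] <- data.frame(
        copigment = cp$copigment, family = cp$family, pH = ph,
        ethanol_pct = et, cp_a520_true = slope,
        keff_dmax = bound_fraction(max(doses), cp$K0, cfg$beta_ethanol, et) /
          (1 - bound_fraction(max(doses), cp$K0, cfg$beta_ethanol, et)),
        stringsAsFactors = FALSE
      )

      for (di in which(doses > 0)) {
        d <- doses[di]
        tail0 <- blank_tail(wl, d, cp$blank_amp, cfg$blank_decay)
        band <- pigment_band(wl, cfg, f_flav, theta[di], cp$alpha_h,
                             cp$delta_lambda)
        for (r in seq_len(cfg$replicates)) {
          dtag <- sprintf("%s_%s_d%g_r%d", ctag, cp$copigment, d, r)
          add(paste0(dtag, "_blank"), tail0 + noise(), "blank",
              cp$copigment, cp$family, d, r)
          add(paste0(dtag, "_mix"), band + tail0 + noise(), "mix",
              cp$copigment, cp$family, d, r)
        }
      }
    }
  }

  structure(
    list(
      spectra = spectra,
      manifest = do.call(rbind, manifest),
      truth = list(
        by_dose = do.call(rbind, by_dose),
        cp_a520 = do.call(rbind, cp_true)
      ),
      config = cfg
    ),
    class = "synth_dataset"
  )
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf(
    "<synth_dataset> %d spectra (%d mix, %d blank, %d control), %d conditions, seed %d\n",
    length(x$spectra), sum(x$manifest$role == "mix"),
    sum(x$manifest$role == "blank"), sum(x$manifest$role == "control"),
    nrow(x$config$conditions), x$config$seed
  ))
  invisible(x)
}
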