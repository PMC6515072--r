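Package: copigmentr
Title: Colorimetry and Copigmentation Effectiveness of Wine Model Solutions
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing anthocyanin-tannin copigmentation in model wine
    solutions from visible absorbance spectra. Converts blank-corrected spectra
    (400-800 nm) to A520 and CIELAB coordinates (L*, a*, b*, C*ab, hab) using
    embedded standard-observer and illuminant tables, estimates copigmentation
    effectiveness (Cp) as the slope of each colour parameter on the
    copigment/pigment mass ratio, classifies hyperchromic and bathochromic
    effects, aggregates products into botanical-origin and tannin-family
    summaries, runs the normality/homoscedasticity-gated group-comparison
    decision tree with compact letter displays, and performs PCA over the six
    colour variables. A seeded generator of synthetic malvidin-3-O-glucoside
    spectra with dose-dependent hyperchromic/bathochromic shifts, pH-dependent
    flavylium equilibrium, ethanol-attenuated binding and coloured copigment
    blanks provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
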