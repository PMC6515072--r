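test_that("resampling onto the observer grid is piecewise linear", {
  # identity: already on the grid
  s <- flat_spectrum(0.3)
  rs <- resample_to_grid(s, default_grid)
  expect_identical(rs$absorbance, rep(0.3, nrow(default_grid)))
  expect_identical(rs$meta, s$meta)

  # two points: linear interpolation
  s2 <- vis_spectrum("lin", c(400, 800), c(0, 0.8), role = "control")
  rs2 <- resample_to_grid(s2, c(500, 600))
  expect_equal(rs2$absorbance, c(0.2, 0.4))

  # random 1 nm spectrum onto the 5 nm grid matches a pointwise oracle
  set.seed(42)
  wl <- seq(400, 800, by = 1)
  ab <- cumsum(rnorm(length(wl), 0, 0.01)) + 0.5
  s3 <- vis_spectrum("rand", wl, ab, role = "control")
  rs3 <- resample_to_grid(s3, default_grid)
  oracle <- approx(wl, ab, xout = default_grid$wavelength)$y
  expect_equal(rs3$absorbance, oracle, tolerance = 1e-12)

  # coverage gap is an error naming the missing span
  s4 <- vis_spectrum("short", seq(420, 700, 5), rep(0.1, 57), role = "control")
  expect_error(resample_to_grid(s4, default_grid), "missing span")
})

test_that("absorbance/transmittance follows Beer-Lambert", {
  expect_equal(absorbance_to_transmittance(0), 1)
  expect_equal(absorbance_to_transmittance(1), 0.1)
  expect_equal(absorbance_to_transmittance(-0.05), 10^0.05)
  expect_error(absorbance_to_transmittance(NaN), "finite")
  expect_error(absorbance_to_transmittance(c(0.1, Inf)), "finite")
})

test_that("tristimulus reproduces the whitepoint and scalar factors", {
  wp <- attr(default_grid, "whitepoint")
  x0 <- tristimulus(resample_to_grid(flat_spectrum(0), default_grid), default_grid)
  expect_equal(x0, wp, tolerance = 1e-12)

  # wavelength-constant absorbance scales all channels by 10^-A
  x2 <- tristimulus(resample_to_grid(flat_spectrum(2), default_grid), default_grid)
  expect_equal(x2, 0.01 * wp, tolerance = 1e-12)

  # grid mismatch is an error
  expect_error(tristimulus(flat_spectrum(0, wl = seq(400, 800, 2)), default_grid),
               "resample")
})

test_that("5 nm rectangular summation agrees with a 1 nm trapezoid oracle", {
  for (amp in c(0.5, 1.0)) {
    for (width in c(25, 30, 50)) {
      fun <- function(wl) amp * exp(-(wl - 520)^2 / (2 * width^2))
      s <- gaussian_spectrum(amp = amp, width = width)
      got <- tristimulus(resample_to_grid(s, default_grid), default_grid)
      want <- tristimulus_trapezoid(fun)
      expect_equal(got, want, tolerance = 1e-3)
    }
  }
})

test_that("CIELAB conversion hits both branches of f()", {
  wp <- attr(default_grid, "whitepoint")
  expect_equal(xyz_to_lab(wp, wp), c(L = 100, a = 0, b = 0), tolerance = 1e-12)

  # flat A = 2: ratio 0.01 is above the cube-root threshold
  lab2 <- xyz_to_lab(0.01 * wp, wp)
  expect_equal(lab2[["L"]], 116 * 0.01^(1 / 3) - 16, tolerance = 1e-10)
  expect_equal(lab2[["L"]], 8.99, tolerance = 5e-3)
  expect_equal(lab2[["a"]], 0, tolerance = 1e-10)
  expect_equal(lab2[["b"]], 0, tolerance = 1e-10)

  # flat A = 3: ratio 0.001 is in the linear branch
  lab3 <- xyz_to_lab(0.001 * wp, wp)
  expect_equal(lab3[["L"]], 116 * ((841 / 108) * 0.001 + 4 / 29) - 16,
               tolerance = 1e-10)
  expect_equal(lab3[["L"]], 0.9033, tolerance = 5e-4)
  expect_equal(unname(lab3[c("a", "b")]), c(0, 0), tolerance = 1e-10)

  expect_error(xyz_to_lab(c(X = 1, Y = 1, Z = 1), c(X = 0, Y = 100, Z = 100)),
               "positive")
})

test_that("chroma and hue use the signed-angle convention", {
  ch <- chroma_hue(3, -4)
  expect_equal(ch[["Cab"]], 5)
  expect_equal(ch[["hab"]], atan2(-4, 3) * 180 / pi) # about -53.13, not 306.87
  expect_lt(ch[["hab"]], 0)

  expect_equal(chroma_hue(1, 0), c(Cab = 1, hab = 0))
  ch0 <- chroma_hue(0, 0)
  expect_equal(ch0[["Cab"]], 0)
  expect_true(is.na(ch0[["hab"]]))

  # the wine regime a* > 0, b* < 0 always yields negative hue
  set.seed(7)
  a <- runif(50, 0.1, 10); b <- -runif(50, 0.1, 10)
  h <- atan2(b, a) * 180 / pi
  expect_true(all(mapply(function(a, b) chroma_hue(a, b)[["hab"]], a, b) < 0))
  expect_equal(mapply(function(a, b) chroma_hue(a, b)[["hab"]], a, b), h)
})

test_that("a520 reads or interpolates at 520 nm", {
  s <- vis_spectrum("x", c(400, 520, 800), c(0, 0.35, 0), role = "control")
  expect_equal(a520(s), 0.35)

  s2 <- vis_spectrum("y", c(400, 518, 522, 800), c(0, 0.30, 0.40, 0),
                     role = "control")
  expect_equal(a520(s2), 0.35)

  set.seed(1)
  wl <- sort(c(400, runif(60, 401, 799), 800))
  ab <- runif(length(wl))
  s3 <- vis_spectrum("z", wl, ab, role = "control")
  expect_equal(a520(s3), approx(wl, ab, xout = 520)$y)
})

test_that("colorimetry invariants hold", {
  # self-consistent white
  cc <- spectrum_color(flat_spectrum(0), default_grid)
  expect_equal(cc$L, 100, tolerance = 1e-9)
  expect_lt(abs(cc$a), 1e-9)
  expect_lt(abs(cc$b), 1e-9)

  # neutral density: any constant absorbance is achromatic
  for (a in c(0.2, 1, 2.5)) {
    cc <- spectrum_color(flat_spectrum(a), default_grid)
    expect_lt(abs(cc$a), 1e-6)
    expect_lt(abs(cc$b), 1e-6)
    expect_lt(cc$Cab, 1e-6)
  }

  # monotonicity: adding a positive constant strictly decreases Y and L*
  s <- gaussian_spectrum(amp = 0.8, wl = seq(400, 800, 5))
  c1 <- spectrum_color(s, default_grid)
  s2 <- s; s2$absorbance <- s2$absorbance + 0.1
  c2 <- spectrum_color(s2, default_grid)
  expect_lt(c2$Y, c1$Y)
  expect_lt(c2$L, c1$L)

  # negative absorbance is kept and flagged, never clipped
  sneg <- flat_spectrum(-0.05)
  ccn <- spectrum_color(sneg, default_grid)
  expect_true(ccn$neg_absorbance)
  expect_gt(ccn$Y, 100)
})

test_that("spectrum construction enforces its invariants", {
  expect_error(vis_spectrum("a", c(500, 450), c(1, 1), role = "mix"),
               "increasing")
  expect_error(vis_spectrum("a", c(450, 450, 500), c(1, 1, 1), role = "mix"),
               "increasing")
  expect_error(vis_spectrum("a", c(450, 500), c(1, 1, 1), role = "mix"),
               "length")
  expect_error(vis_spectrum("a", 500, 1, role = "mix"), "2 points")
  expect_error(vis_spectrum("a", c(390, 700), c(1, 1), role = "mix"),
               "\\[400, 800\\]")
  expect_error(vis_spectrum("a", c(430, 700), c(1, 1), role = "mix"),
               "\\[420, 700\\]")
  expect_error(vis_spectrum("a", c(400, 800), c(1, NA), role = "mix"),
               "finite")
  expect_error(vis_spectrum("a", c(400, 800), c(1, 1), role = "mix",
                            family = "XX"), "family")
})
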