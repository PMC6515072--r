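test_that("blank subtraction is exact and guarded", {
  wl <- seq(400, 800, 5)
  band <- 0.5 * exp(-(wl - 520)^2 / (2 * 30^2))
  tail <- 0.2 * exp(-(wl - 400) / 60)
  mk <- function(id, ab, role) vis_spectrum(
    id, wl, ab, role = role, copigment = "ct", family = "GT",
    dose_g_per_L = 0.2, pigment_mg_per_L = 50, pH = 3.5, ethanol_pct = 12
  )
  mix <- mk("mix", band + tail, "mix")
  blank <- mk("blank", tail, "blank")
  zero <- mk("zero", rep(0, length(wl)), "blank")

  # blank of zero: corrected equals the mix
  expect_equal(subtract_blank(mix, zero)$absorbance, mix$absorbance)
  # self-subtraction: whole curve zero
  expect_equal(subtract_blank(mix, mix, check_meta = FALSE)$absorbance,
               rep(0, length(wl)))
  # additively constructed mix: recovers the pigment band exactly
  corr <- subtract_blank(mix, blank)
  expect_equal(corr$absorbance, band, tolerance = 1e-12)
  expect_identical(corr$meta$role, "corrected")

  # metadata mismatch
  blank2 <- blank; blank2$meta$dose_g_per_L <- 0.4
  expect_error(subtract_blank(mix, blank2), "metadata mismatch")
  # grid mismatch
  blank3 <- mk("b3", rep(0, 81), "blank")
  blank3$wavelength <- blank3$wavelength + 0 # same; now a truly different grid:
  blank4 <- vis_spectrum("b4", seq(400, 800, 2), rep(0, 201), role = "blank",
                         copigment = "ct", dose_g_per_L = 0.2,
                         pH = 3.5, ethanol_pct = 12)
  expect_error(subtract_blank(mix, blank4), "grid")

  # negative corrected values flagged, not clipped
  over <- mk("over", tail + 0.01, "blank")
  corr2 <- subtract_blank(mk("m2", tail, "mix"), over)
  expect_true("negative_absorbance" %in% corr2$flags)
  expect_true(all(corr2$absorbance < 0))
})

test_that("mass ratio follows the dose arithmetic", {
  expect_equal(mass_ratio(0.1, 50), 2)
  expect_equal(mass_ratio(0.4, 50), 8)
  expect_equal(mass_ratio(0, 50), 0)
  expect_equal(mass_ratio(c(0, 0.1, 0.2, 0.4), 50), c(0, 2, 4, 8))
  expect_error(mass_ratio(0.1, 0), "> 0")
  expect_error(mass_ratio(-0.1, 50), ">= 0")
})

test_that("Cp estimation matches closed forms and the OLS oracle", {
  # exact line through the origin of the dose series
  s <- data.frame(ratio = c(0, 2, 4, 8), replicate = 1,
                  A520 = c(0, 0.2, 0.4, 0.8))
  r <- estimate_cp(s, "A520")
  expect_equal(r$cp, 0.1, tolerance = 1e-12)
  expect_equal(r$r2, 1, tolerance = 1e-12)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  expect_equal(r$sd, 0)

  # constant response: zero slope, degenerate r2 marker
  s2 <- data.frame(ratio = c(0, 2, 4, 8), replicate = 1, A520 = 0.3)
  r2 <- estimate_cp(s2, "A520")
  expect_equal(r2$cp, 0)
  expect_true(is.na(r2$r2))
  expect_true("degenerate_r2" %in% r2$flags)

  # noisy line, 3 replicates: per-replicate OLS equals the
  # normal-equations oracle; Cp close to the generating slope
  set.seed(123)
  ratios <- c(0, 2, 4, 8)
  sim <- do.call(rbind, lapply(1:3, function(rep) {
    data.frame(ratio = ratios, replicate = rep,
               A520 = 0.1 + 0.05 * ratios + rnorm(4, 0, 0.005))
  }))
  rr <- estimate_cp(sim, "A520")
  oracle <- vapply(1:3, function(rep) {
    d <- sim[sim$replicate == rep, ]
    X <- cbind(1, d$ratio)
    solve(t(X) %*% X, t(X) %*% d$A520)[2] # normal equations
  }, numeric(1))
  expect_equal(unname(rr$replicate_slopes), oracle, tolerance = 1e-10)
  expect_equal(rr$cp, mean(oracle), tolerance = 1e-12)
  expect_equal(rr$sd, sd(oracle), tolerance = 1e-12)
  se <- 0.005 / sqrt(sum((ratios - mean(ratios))^2)) / sqrt(3)
  expect_lt(abs(rr$cp - 0.05), 3 * se)

  # all ratios identical is an error
  s3 <- data.frame(ratio = 4, replicate = 1:3, A520 = c(0.1, 0.2, 0.3))
  expect_error(estimate_cp(s3, "A520"), "distinct ratios")
})

test_that("Cp is offset-invariant and scales inversely with the ratio axis", {
  set.seed(5)
  base <- do.call(rbind, lapply(1:3, function(rep) {
    data.frame(ratio = c(0, 2, 4, 8), replicate = rep,
               y = rnorm(4))
  }))
  r0 <- estimate_cp(base, "y")
  for (k in c(-3, 0.7, 12)) {
    shifted <- base; shifted$y <- shifted$y + k
    expect_equal(estimate_cp(shifted, "y")$cp, r0$cp, tolerance = 1e-12)
  }
  for (c_ in c(0.5, 2, 10)) {
    scaled <- base; scaled$ratio <- scaled$ratio * c_
    expect_equal(estimate_cp(scaled, "y")$cp, r0$cp / c_, tolerance = 1e-12)
  }
})

test_that("effect classification follows the sign rules", {
  # gallotannin at pH 3.5 (printed values): hyperchromic and bathochromic
  cp <- c(A520 = 0.31, L = -4.14, a = 5.62, b = -3.41, hab = -16.75, Cab = 6.23)
  cl <- classify_effects(cp)
  expect_true(cl$hyperchromic)
  expect_true(cl$bathochromic)
  expect_false(cl$hypochromic)
  expect_setequal(cl$labels, c("hyperchromic", "bathochromic"))

  none <- classify_effects(setNames(rep(0, 6), names(effect_direction_rule())))
  expect_false(none$hyperchromic)
  expect_false(none$bathochromic)
  expect_length(none$labels, 0)

  rev <- classify_effects(c(A520 = -0.1, L = 2, a = -1, b = 0.5, hab = 3, Cab = -1))
  expect_true(rev$hypochromic)
  expect_true(rev$hypsochromic)

  expect_error(classify_effects(c(A520 = 1, L = -1)), "missing Cp")
})

test_that("best-copigment counting is strict about ties and completeness", {
  tbl <- expand.grid(condition = c("c1", "c2"), copigment = c("x", "y"),
                     parameter = c("A520", "L"), stringsAsFactors = FALSE)
  tbl$cp <- c(1, 0.5, -1, -0.5, -2, -1, 2, 1)[seq_len(nrow(tbl))]
  # make it explicit: x strictly better everywhere under the rule
  tbl$cp <- ifelse(tbl$parameter == "A520",
                   ifelse(tbl$copigment == "x", 1, 0.5),
                   ifelse(tbl$copigment == "x", -1, -0.5))
  res <- best_copigment_count(tbl, "x", condition_cols = "condition")
  expect_equal(res$wins, 4); expect_equal(res$total, 4)

  # exact tie counts against the focal and is reported
  tbl2 <- tbl; tbl2$cp[tbl2$parameter == "A520"] <- 1
  res2 <- best_copigment_count(tbl2, "x", condition_cols = "condition")
  expect_equal(res2$wins, 2)
  expect_equal(res2$ties, 2)

  # single copigment wins every cell
  solo <- tbl[tbl$copigment == "x", ]
  expect_equal(best_copigment_count(solo, "x", condition_cols = "condition")$wins, 4)

  # incomplete table errors
  expect_error(best_copigment_count(tbl[-1, ], "x", condition_cols = "condition"),
               "incomplete")
  expect_error(best_copigment_count(tbl, "zz", condition_cols = "condition"),
               "focal")
})

test_that("two-level aggregation matches hand-computed summaries", {
  prod <- reference_cp_products()
  tannins <- prod[prod$family != "reference", ]
  agg <- aggregate_family(tannins, value = "A520")

  ng <- agg$origin[agg$origin$origin == "nut_galls", ]
  v <- tannins$A520[tannins$origin == "nut_galls"]
  expect_equal(ng$mean, mean(v), tolerance = 1e-12)
  expect_equal(ng$sd, sd(v), tolerance = 1e-12)

  # balanced origins (GT: 4 + 4 products): two-level mean equals flat mean
  gt <- agg$family[agg$family$family == "GT", ]
  expect_equal(gt$mean, mean(tannins$A520[tannins$family == "GT"]),
               tolerance = 1e-12)

  # family ordering on A520 from the printed product rows
  fam <- setNames(agg$family$mean, agg$family$family)
  expect_true(fam[["GT"]] > fam[["ET"]])
  expect_true(fam[["ET"]] > fam[["PC/PD"]])
  expect_true(fam[["PC/PD"]] > fam[["PF/PR"]])

  # singleton group: SD 0 with flag
  df <- data.frame(product = c("p1", "p2", "p3"),
                   origin = c("o1", "o1", "o2"),
                   family = "GT", A520 = c(1, 2, 5))
  a2 <- aggregate_family(df)
  expect_true(a2$origin$singleton[a2$origin$origin == "o2"])
  expect_equal(a2$origin$sd[a2$origin$origin == "o2"], 0)

  expect_error(aggregate_family(df[0, ]), "empty")
  dupe <- rbind(df, df[1, ])
  expect_error(aggregate_family(dupe), "exactly once")
})
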