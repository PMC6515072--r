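#' Subtract a copigment blank from a mix spectrum
#'
#' The spectrum of the solution containing only the copigment is subtracted
#' pointwise from the spectrum of the corresponding copigment/pigment mix, to
#' remove the copigment's own colour. Both spectra must be on the same grid
#' (resample first) and must agree on copigment, dose, pH and ethanol.
#' Negative corrected absorbance is kept (never clipped) and flagged.
#'
#' @param mix,blank [vis_spectrum()] objects on identical wavelength grids.
#' @param check_meta compare copigment/dose/pH/ethanol metadata (default TRUE).
#' @return A `vis_spectrum` with role `"corrected"`; gains a
#'   `"negative_absorbance"` flag if any corrected value is below zero.
#' @export
subtract_blank <- function(mix, blank, check_meta = TRUE) {
  stopifnot(inherits(mix, "vis_spectrum"), inherits(blank, "vis_spectrum"))
  if (length(mix$wavelength) != length(blank$wavelength) ||
      any(mix$wavelength != blank$wavelength))
    stop("mix and blank are not on the same wavelength grid; resample first")
  if (check_meta) {
    for (f in c("copigment", "dose_g_per_L", "pH", "ethanol_pct")) {
      a <- mix$meta[[f]]; b <- blank$meta[[f]]
      same <- (is.na(a) && is.na(b)) || isTRUE(all.equal(a, b))
      if (!same)
        stop(sprintf(
          "metadata mismatch between mix '%s' and blank '%s' on '%s' (%s vs %s)",
          mix$sample_id, blank$sample_id, f, format(a), format(b)
        ))
    }
  }
  out <- mix
  out$absorbance <- mix$absorbance - blank$absorbance
  out$meta$role <- "corrected"
  if (any(out$absorbance < 0))
    out$flags <- union(out$flags, "negative_absorbance")
  out
}

#' Copigment/pigment mass-concentration ratio
#'
#' `ratio = dose (converted to mg/L) / pigment concentration (mg/L)`. The
#' study's arithmetic (0.1 g/L of tannin over 50 mg/L of pigment giving
#' ratio 2) forces the mass -- not molar -- convention.
#'
#' @param dose_g_per_L copigment dose, g/L, `>= 0`.
#' @param pigment_mg_per_L pigment concentration, mg/L, `> 0`.
#' @return Dimensionless mass ratio.
#' @examples
#' mass_ratio(c(0, 0.1, 0.2, 0.4), 50) # 0 2 4 8
#' @export
mass_ratio <- function(dose_g_per_L, pigment_mg_per_L) {
  if (any(pigment_mg_per_L <= 0)) stop("pigment concentration must be > 0")
  if (any(dose_g_per_L < 0)) stop("dose must be >= 0")
  dose_g_per_L * 1000 / pigment_mg_per_L
}

#' The six colour parameters and their greater-impact orientation
#'
#' Higher Cp means greater copigmentation impact for A520, a* and C*ab;
#' lower (more negative) Cp means greater impact for L*, b* and hab.
#'
#' @return Named numeric: `+1` (larger is better) or `-1` (smaller is better)
#'   for each of `A520`, `L`, `a`, `b`, `hab`, `Cab`.
#' @export
effect_direction_rule <- function() {
  c(A520 = 1, L = -1, a = 1, b = -1, hab = -1, Cab = 1)
}

#' Copigmentation effectiveness (Cp) of one colour parameter
#'
#' Cp is the slope of the straight line of a colour parameter on the
#' copigment/pigment ratio. The ratio-0 control is part of the dose series
#' and the intercept is free. Each replicate is fitted by ordinary least
#' squares; Cp is the mean of the replicate slopes and its SD the sample SD
#' across replicates (matching the mean +- SD of three replicates
#' convention). r-squared is reported for the pooled fit over all points.
#'
#' @param series data frame with columns `ratio`, `replicate` and the colour
#'   parameter column named in `parameter`.
#' @param parameter one of `"A520"`, `"L"`, `"a"`, `"b"`, `"hab"`, `"Cab"`
#'   (any numeric column of `series` works).
#' @return An object of class `cp_result`: list with `parameter`, `cp`,
#'   `sd`, `intercept` (pooled), `r2` (`NA` with a `degenerate_r2` flag for a
#'   zero-variance response), `n_rep`, `replicate_slopes`, `flags`.
#' @details Missing parameter values (e.g. the undefined hue of an achromatic
#'   point) are dropped with a flag rather than imputed; at least two
#'   distinct ratios per replicate must remain.
#' @examples
#' s <- data.frame(ratio = c(0, 2, 4, 8), replicate = 1, A520 = c(0, .2, .4, .8))
#' estimate_cp(s, "A520")$cp # 0.1
#' @export
estimate_cp <- function(series, parameter) {
  stopifnot(is.data.frame(series),
            all(c("ratio", "replicate", parameter) %in% names(series)))
  flags <- character()
  y <- series[[parameter]]
  if (anyNA(y)) {
    flags <- c(flags, "dropped_na_values")
    series <- series[!is.na(y), , drop = FALSE]
    y <- series[[parameter]]
  }
  x <- series$ratio
  if (any(x < 0)) stop("ratios must be nonnegative")
  if (length(unique(x)) < 2)
    stop("at least 2 distinct ratios are required to estimate Cp")

  ols <- function(xx, yy) {
    sxx <- sum((xx - mean(xx))^2)
    slope <- sum((xx - mean(xx)) * (yy - mean(yy))) / sxx
    c(slope = slope, intercept = mean(yy) - slope * mean(xx))
  }

  reps <- sort(unique(series$replicate))
  slopes <- vapply(reps, function(r) {
    sel <- series$replicate == r
    if (length(unique(x[sel])) < 2)
      stop(sprintf("replicate %s has fewer than 2 distinct ratios", format(r)))
    ols(x[sel], y[sel])[["slope"]]
  }, numeric(1))

  pooled <- ols(x, y)
  syy <- sum((y - mean(y))^2)
  if (syy == 0) {
    r2 <- NA_real_
    flags <- c(flags, "degenerate_r2")
  } else {
    fit <- pooled[["intercept"]] + pooled[["slope"]] * x
    r2 <- 1 - sum((y - fit)^2) / syy
  }
  structure(
    list(
      parameter = parameter,
      cp = mean(slopes),
      sd = if (length(slopes) > 1) stats::sd(slopes) else 0,
      intercept = pooled[["intercept"]],
      r2 = r2,
      n_rep = length(slopes),
      replicate_slopes = stats::setNames(slopes, reps),
      flags = flags
    ),
    class = "cp_result"
  )
}

#' @export
print.cp_result <- function(x, ...) {
  cat(sprintf(
    "<cp_result> %s: Cp = %.4g +- %.4g (n = %d), r2 = %s%s\n",
    x$parameter, x$cp, x$sd, x$n_rep,
    ifelse(is.na(x$r2), "NA (degenerate)", sprintf("%.4f", x$r2)),
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]") else ""
  ))
  invisible(x)
}

#' Cp table over copigments, conditions and colour parameters
#'
#' Builds the ratio series for every copigment x condition from a colour
#' table (corrected mixes plus the pigment-only controls at ratio 0, which
#' are shared by every copigment measured under the same condition and
#' replicate) and estimates Cp for each colour parameter.
#'
#' @param colors a colour table as returned by [color_table()]: one row per
#'   sample with columns `role`, `copigment`, `family`, `pH`, `ethanol_pct`,
#'   `replicate`, `ratio` and the colour parameters.
#' @param parameters colour parameter columns (default the six of
#'   [effect_direction_rule()]).
#' @return Data frame of class `cp_table` with columns `copigment`, `family`,
#'   `pH`, `ethanol_pct`, `parameter`, `cp`, `sd`, `r2`, `n_rep`, and
#'   attribute `replicate_slopes` (long data frame of per-replicate slopes,
#'   the input for the group-comparison stage).
#' @export
estimate_cp_table <- function(colors,
                              parameters = names(effect_direction_rule())) {
  need <- c("role", "copigment", "family", "pH", "ethanol_pct", "replicate", "ratio")
  stopifnot(is.data.frame(colors), all(need %in% names(colors)))
  mixes <- colors[colors$role == "corrected", , drop = FALSE]
  ctrls <- colors[colors$role == "control", , drop = FALSE]
  if (!nrow(mixes)) stop("no corrected mix rows in the colour table")

  key <- unique(mixes[, c("copigment", "family", "pH", "ethanol_pct")])
  out <- list(); rs <- list()
  for (i in seq_len(nrow(key))) {
    ki <- key[i, ]
    sel <- mixes$copigment == ki$copigment &
      mixes$pH == ki$pH & mixes$ethanol_pct == ki$ethanol_pct
    ser <- mixes[sel, , drop = FALSE]
    c0 <- ctrls[ctrls$pH == ki$pH & ctrls$ethanol_pct == ki$ethanol_pct, , drop = FALSE]
    ser <- rbind(ser[, c("ratio", "replicate", parameters)],
                 c0[, c("ratio", "replicate", parameters)])
    for (p in parameters) {
      r <- estimate_cp(ser, p)
      out[[length(out) + 1]] <- data.frame(
        copigment = ki$copigment, family = ki$family,
        pH = ki$pH, ethanol_pct = ki$ethanol_pct, parameter = p,
        cp = r$cp, sd = r$sd, r2 = r$r2, n_rep = r$n_rep,
        stringsAsFactors = FALSE
      )
      rs[[length(rs) + 1]] <- data.frame(
        copigment = ki$copigment, family = ki$family,
        pH = ki$pH, ethanol_pct = ki$ethanol_pct, parameter = p,
        replicate = as.integer(names(r$replicate_slopes)),
        slope = unname(r$replicate_slopes),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  attr(res, "replicate_slopes") <- do.call(rbind, rs)
  class(res) <- c("cp_table", "data.frame")
  res
}

#' Classify hyperchromic/hypochromic and bathochromic/hypsochromic effects
#'
#' A copigment is hyperchromic when Cp(A520) > 0 and Cp(L*) < 0 (more
#' absorbance, darker solution), hypochromic under the reversed signs, and
#' bathochromic when Cp(b*) < 0 (displacement toward blue), hypsochromic
#' when Cp(b*) > 0.
#'
#' @param cp named numeric of Cp values covering all six parameters of
#'   [effect_direction_rule()], or a [estimate_cp_table()] slice with columns
#'   `parameter` and `cp` for a single copigment x condition.
#' @return List with logical `hyperchromic`, `hypochromic`, `bathochromic`,
#'   `hypsochromic`, character `labels`, and the `cp` magnitudes used.
#' @examples
#' classify_effects(c(A520 = .31, L = -4.14, a = 5.62, b = -3.41,
#'                    hab = -16.75, Cab = 6.23))
#' @export
classify_effects <- function(cp) {
  if (is.data.frame(cp)) cp <- stats::setNames(cp$cp, cp$parameter)
  need <- names(effect_direction_rule())
  if (!all(need %in% names(cp)))
    stop("missing Cp for parameter(s): ",
         paste(setdiff(need, names(cp)), collapse = ", "))
  cp <- cp[need]
  hyper <- cp[["A520"]] > 0 && cp[["L"]] < 0
  hypo <- cp[["A520"]] < 0 && cp[["L"]] > 0
  batho <- cp[["b"]] < 0
  hypso <- cp[["b"]] > 0
  labels <- c(
    if (hyper) "hyperchromic", if (hypo) "hypochromic",
    if (batho) "bathochromic", if (hypso) "hypsochromic"
  )
  list(hyperchromic = hyper, hypochromic = hypo,
       bathochromic = batho, hypsochromic = hypso,
       labels = if (is.null(labels)) character() else labels,
       cp = cp)
}

#' Count the cells where a focal copigment is strictly best
#'
#' For every condition x parameter cell of a Cp table, the focal copigment
#' wins if its Cp is strictly better than every competitor under the
#' direction rule (larger for A520/a*/C*ab, smaller for L*/b*/hab). Ties for
#' best are conservative: counted as non-wins and reported separately.
#'
#' @param cp_tbl data frame with columns `condition` (or the columns named in
#'   `condition_cols`, pasted together), `copigment`, `parameter`, `cp`.
#' @param focal copigment id whose wins are counted.
#' @param rule orientation rule, default [effect_direction_rule()].
#' @param condition_cols columns defining a condition (default
#'   `"condition"` if present, else `c("pH", "ethanol_pct")`).
#' @return List: `wins`, `total`, `fraction`, `ties` (cells where the focal
#'   value equals the best competitor), and `cells` (per-cell detail).
#' @export
best_copigment_count <- function(cp_tbl, focal, rule = effect_direction_rule(),
                                 condition_cols = NULL) {
  stopifnot(is.data.frame(cp_tbl),
            all(c("copigment", "parameter", "cp") %in% names(cp_tbl)))
  if (is.null(condition_cols))
    condition_cols <- if ("condition" %in% names(cp_tbl)) "condition"
      else c("pH", "ethanol_pct")
  if (!all(condition_cols %in% names(cp_tbl)))
    stop("condition column(s) not found: ", paste(condition_cols, collapse = ", "))
  if (!focal %in% cp_tbl$copigment) stop("focal copigment not in table: ", focal)
  if (!all(cp_tbl$parameter %in% names(rule)))
    stop("direction rule does not cover parameter(s): ",
         paste(setdiff(unique(cp_tbl$parameter), names(rule)), collapse = ", "))

  cond <- do.call(paste, c(cp_tbl[condition_cols], sep = " / "))
  cell <- paste(cond, cp_tbl$parameter, sep = " | ")
  copigs <- unique(cp_tbl$copigment)
  tab <- table(cell, cp_tbl$copigment)
  if (any(tab != 1))
    stop("Cp table is incomplete or duplicated over condition x parameter x copigment cells")

  cells <- unique(cell)
  detail <- data.frame(cell = cells, win = FALSE, tie = FALSE,
                       stringsAsFactors = FALSE)
  for (i in seq_along(cells)) {
    sub <- cp_tbl[cell == cells[i], , drop = FALSE]
    orient <- rule[[sub$parameter[1]]]
    v <- orient * sub$cp # larger is always better after orientation
    f <- v[sub$copigment == focal]
    if (length(copigs) == 1) {
      detail$win[i] <- TRUE
    } else {
      best_other <- max(v[sub$copigment != focal])
      detail$win[i] <- f > best_other
      detail$tie[i] <- f == best_other
    }
  }
  list(
    wins = sum(detail$win), total = nrow(detail),
    fraction = mean(detail$win), ties = sum(detail$tie),
    cells = detail
  )
}

#' Two-level aggregation of product values into origins and families
#'
#' Origin summaries are the unweighted mean and sample SD (n - 1) of the
#' product values; family summaries are the unweighted mean and sample SD of
#' the origin means (the two-level convention, so each botanical origin
#' carries equal weight regardless of how many commercial products it
#' contributes). The flat across-product SD is also returned for reference.
#' Singleton groups get SD 0 and a flag.
#'
#' @param df data frame with columns `product`, `origin`, `family` and the
#'   value column named in `value`.
#' @param value name of the numeric column to aggregate (default `"A520"`).
#' @return List of two data frames: `origin` (`family`, `origin`, `mean`,
#'   `sd`, `n`, `singleton`) and `family` (`family`, `mean`, `sd` (two-level),
#'   `sd_flat`, `n_origins`, `n_products`).
#' @export
aggregate_family <- function(df, value = "A520") {
  stopifnot(is.data.frame(df),
            all(c("product", "origin", "family", value) %in% names(df)))
  if (!nrow(df)) stop("empty input")
  if (anyDuplicated(df$product))
    stop("each product must appear exactly once")
  map <- unique(df[, c("origin", "family")])
  if (anyDuplicated(map$origin))
    stop("each origin must belong to exactly one family")

  v <- df[[value]]
  osplit <- split(seq_len(nrow(df)), df$origin)
  origin <- do.call(rbind, lapply(names(osplit), function(o) {
    idx <- osplit[[o]]
    data.frame(
      family = df$family[idx[1]], origin = o,
      mean = mean(v[idx]),
      sd = if (length(idx) > 1) stats::sd(v[idx]) else 0,
      n = length(idx), singleton = length(idx) == 1,
      stringsAsFactors = FALSE
    )
  }))
  fsplit <- split(seq_len(nrow(origin)), origin$family)
  family <- do.call(rbind, lapply(names(fsplit), function(f) {
    idx <- fsplit[[f]]
    m <- origin$mean[idx]
    prod_v <- v[df$family == f]
    data.frame(
      family = f,
      mean = mean(m),
      sd = if (length(m) > 1) stats::sd(m) else 0,
      sd_flat = if (length(prod_v) > 1) stats::sd(prod_v) else 0,
      n_origins = length(m), n_products = length(prod_v),
      stringsAsFactors = FALSE
    )
  }))
  rownames(origin) <- rownames(family) <- NULL
  list(origin = origin, family = family)
}
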