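#' Levene's test for homogeneity of variance
#'
#' Classic Levene: one-way ANOVA on the absolute deviations of each value
#' from its group centre. `center = "mean"` is the classic form;
#' `center = "median"` gives the Brown-Forsythe variant.
#'
#' @param values numeric vector.
#' @param groups group labels (coerced to factor).
#' @param center `"mean"` or `"median"`.
#' @return List with `statistic` (F), `df`, and `p.value`.
#' @export
levene_test <- function(values, groups, center = c("mean", "median")) {
  center <- match.arg(center)
  g <- factor(groups)
  stopifnot(length(values) == length(g), nlevels(g) >= 2)
  ctr <- if (center == "mean") stats::ave(values, g)
    else stats::ave(values, g, FUN = stats::median)
  z <- abs(values - ctr)
  a <- stats::anova(stats::lm(z ~ g))
  list(statistic = a$`F value`[1],
       df = c(a$Df[1], a$Df[2]),
       p.value = a$`Pr(>F)`[1])
}

#' Choose the parametric or nonparametric comparison branch
#'
#' Mirrors the classical decision tree: Shapiro-Wilk for normality and
#' Levene's test for homoscedasticity, both at level `alpha`; the parametric
#' branch (ANOVA + Tukey) is taken only if both pass, otherwise the
#' nonparametric branch (Kruskal-Wallis + pairwise rank-sum). With the
#' typical n = 3 per group, per-group normality testing is vacuous, so
#' Shapiro-Wilk is applied to the pooled group-centred residuals by default.
#'
#' Degenerate inputs force the nonparametric branch with a flag: any
#' zero-variance group, or groups too small to test (n < 3).
#'
#' @param values numeric vector of replicate values.
#' @param groups group labels.
#' @param alpha significance level for both gate tests (default 0.05).
#' @param shapiro_on `"residuals"` (default) or `"pooled"` (raw values).
#' @param levene_center passed to [levene_test()].
#' @return List with `branch` (`"parametric"` or `"nonparametric"`),
#'   `shapiro_p`, `levene_p`, and `flags`.
#' @export
choose_branch <- function(values, groups, alpha = 0.05,
                          shapiro_on = c("residuals", "pooled"),
                          levene_center = "mean") {
  shapiro_on <- match.arg(shapiro_on)
  g <- factor(groups)
  stopifnot(length(values) == length(g))
  if (nlevels(g) < 2) stop("at least 2 groups are required")
  flags <- character()
  n_by <- tapply(values, g, length)
  v_by <- tapply(values, g, stats::var)

  if (any(n_by < 3)) {
    return(list(branch = "nonparametric", shapiro_p = NA_real_,
                levene_p = NA_real_,
                flags = "group_too_small_for_normality_test"))
  }
  if (any(v_by == 0)) {
    return(list(branch = "nonparametric", shapiro_p = NA_real_,
                levene_p = NA_real_, flags = "zero_variance_group"))
  }
  x <- if (shapiro_on == "residuals") values - stats::ave(values, g) else values
  sw <- stats::shapiro.test(x)$p.value
  lv <- levene_test(values, g, center = levene_center)$p.value
  branch <- if (sw >= alpha && lv >= alpha) "parametric" else "nonparametric"
  list(branch = branch, shapiro_p = sw, levene_p = lv, flags = flags)
}

#' Compact letter display from an adjusted p-value matrix
#'
#' Insert-and-absorb algorithm: start from one letter covering all groups;
#' for every significant pair sharing a letter, split that letter into two
#' (each excluding one member of the pair), then absorb any letter whose
#' group set is contained in another's. Groups share a letter if and only if
#' their adjusted pairwise p-value is `>= alpha`.
#'
#' @param pmat symmetric matrix of adjusted pairwise p-values with group
#'   names on both dimnames (diagonal ignored; `NA` treated as
#'   non-significant).
#' @param alpha significance level (default 0.05).
#' @return Named character vector of letter strings, one per group, in the
#'   row order of `pmat`.
#' @export
compact_letters <- function(pmat, alpha = 0.05) {
  stopifnot(is.matrix(pmat), nrow(pmat) == ncol(pmat))
  gn <- rownames(pmat)
  k <- length(gn)
  cols <- list(rep(TRUE, k)) # each column: logical membership over groups
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      p <- pmat[i, j]
      if (!is.na(p) && p < alpha) {
        newcols <- list()
        for (cc in cols) {
          if (cc[i] && cc[j]) {
            c1 <- cc; c1[i] <- FALSE
            c2 <- cc; c2[j] <- FALSE
            newcols <- c(newcols, list(c1, c2))
          } else newcols <- c(newcols, list(cc))
        }
        # absorb: drop any column contained in another
        keep <- rep(TRUE, length(newcols))
        for (a in seq_along(newcols)) {
          for (b in seq_along(newcols)) {
            if (a != b && keep[a] && keep[b] &&
                all(newcols[[a]] <= newcols[[b]]) &&
                !identical(newcols[[a]], newcols[[b]]))
              keep[a] <- FALSE
          }
        }
        newcols <- newcols[keep]
        # deduplicate identical columns
        cols <- unique(newcols)
      }
    }
  }
  # order letters by the first group they contain, for stable output
  first <- vapply(cols, function(cc) which(cc)[1], integer(1))
  cols <- cols[order(first)]
  letters_used <- letters[seq_along(cols)]
  out <- vapply(seq_len(k), function(i) {
    paste(letters_used[vapply(cols, `[`, logical(1), i)], collapse = "")
  }, character(1))
  stats::setNames(out, gn)
}

#' Omnibus and post-hoc comparison of groups with letters
#'
#' Runs the branch chosen by [choose_branch()] (or a caller-supplied one):
#' one-way ANOVA with Tukey HSD all-pairs comparisons on the parametric
#' branch, Kruskal-Wallis with pairwise two-sided rank-sum tests (Holm
#' adjustment by default; the multiplicity correction is configurable since
#' classical write-ups rarely state one) on the nonparametric branch.
#' Letters come from [compact_letters()] on the adjusted p matrix.
#'
#' @param values numeric vector of replicate values.
#' @param groups group labels.
#' @param branch `NULL` (decide via [choose_branch()]), `"parametric"` or
#'   `"nonparametric"`.
#' @param alpha significance level (default 0.05).
#' @param p_adjust adjustment method for pairwise rank-sum p-values
#'   (default `"holm"`); Tukey p-values are already family-wise adjusted.
#' @param ... passed to [choose_branch()].
#' @return Object of class `comparison_result`: list with `branch`,
#'   `shapiro_p`, `levene_p`, `omnibus_p`, `p_matrix` (adjusted), `letters`,
#'   `means`, `sds`, `n`, `flags`.
#' @export
compare_groups <- function(values, groups, branch = NULL, alpha = 0.05,
                           p_adjust = "holm", ...) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("at least 2 groups are required")
  stopifnot(length(values) == length(g))
  gate <- list(branch = branch, shapiro_p = NA_real_, levene_p = NA_real_,
               flags = character())
  if (is.null(branch)) gate <- choose_branch(values, g, alpha = alpha, ...)

  lev <- levels(g)
  pmat <- matrix(NA_real_, nlevels(g), nlevels(g), dimnames = list(lev, lev))
  if (gate$branch == "parametric") {
    # group labels may themselves contain "-" (e.g. "grape-seed"), which
    # would garble TukeyHSD's "a-b" row names; fit on safe internal labels
    gi <- factor(paste0("grp", as.integer(g)),
                 levels = paste0("grp", seq_len(nlevels(g))))
    fit <- stats::aov(values ~ gi)
    omnibus <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$gi
    for (rn in rownames(tk)) {
      pr <- as.integer(sub("grp", "", strsplit(rn, "-", fixed = TRUE)[[1]]))
      pmat[pr[1], pr[2]] <- pmat[pr[2], pr[1]] <- tk[rn, "p adj"]
    }
  } else {
    omnibus <- stats::kruskal.test(values, g)$p.value
    pw <- suppressWarnings(
      stats::pairwise.wilcox.test(values, g, p.adjust.method = p_adjust,
                                  exact = NULL)
    )$p.value
    for (rn in rownames(pw)) for (cn in colnames(pw)) {
      if (!is.na(pw[rn, cn]))
        pmat[rn, cn] <- pmat[cn, rn] <- pw[rn, cn]
    }
  }
  structure(
    list(
      branch = gate$branch, shapiro_p = gate$shapiro_p,
      levene_p = gate$levene_p, omnibus_p = omnibus,
      p_matrix = pmat,
      letters = compact_letters(pmat, alpha = alpha),
      means = tapply(values, g, mean),
      sds = tapply(values, g, stats::sd),
      n = tapply(values, g, length),
      alpha = alpha, flags = gate$flags
    ),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> branch = %s (Shapiro p = %s, Levene p = %s)\n",
              x$branch, format(x$shapiro_p, digits = 3),
              format(x$levene_p, digits = 3)))
  cat(sprintf("  omnibus p = %s\n", format(x$omnibus_p, digits = 4)))
  df <- data.frame(mean = as.numeric(x$means), sd = as.numeric(x$sds),
                   n = as.integer(x$n), letters = x$letters)
  rownames(df) <- names(x$letters)
  print(df, ...)
  invisible(x)
}

#' PCA of the colour variables
#'
#' Correlation PCA: each variable is standardised to zero mean and unit
#' variance (the six colour parameters live on incommensurable scales), then
#' decomposed by [stats::prcomp()]. A deterministic sign convention is
#' applied: within each component, the largest-magnitude loading is made
#' positive.
#'
#' @param x numeric matrix or data frame, observations x variables (>= 2 of
#'   each). A zero-variance variable is an error naming it.
#' @return Object of class `pca_result`: list with `loadings` (variables x
#'   components), `scores` (observations x components), `explained`
#'   (fractions summing to 1), `sdev`.
#' @export
run_pca <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("PCA input must be numeric")
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("PCA needs at least 2 observations and 2 variables")
  vars <- apply(x, 2, stats::var)
  if (any(vars == 0))
    stop("zero-variance variable(s): ",
         paste(colnames(x)[vars == 0], collapse = ", "))
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  structure(
    list(
      loadings = pc$rotation,
      scores = pc$x,
      explained = pc$sdev^2 / sum(pc$sdev^2),
      sdev = pc$sdev
    ),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result>\n  explained:",
      paste(sprintf("PC%d %.1f%%", seq_along(x$explained), 100 * x$explained),
            collapse = ", "), "\n")
  print(round(x$loadings, 3), ...)
  invisible(x)
}
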