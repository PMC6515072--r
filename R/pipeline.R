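#' Colour table of a validated dataset
#'
#' Applies blank subtraction and colorimetry to every mix (each corrected
#' against its matching copigment blank) and to every pigment-only control,
#' returning one row of colour coordinates per sample together with its
#' manifest metadata and copigment/pigment mass ratio. Blanks themselves are
#' not colour-rated.
#'
#' @param ds a `synth_dataset` ([generate_experiment()]) or `copig_dataset`
#'   ([load_and_validate()]).
#' @param grid an [observer_grid()].
#' @return Data frame: `sample_id`, `role` (`"corrected"` or `"control"`),
#'   `copigment`, `family`, `dose_g_per_L`, `ratio`, `pH`, `ethanol_pct`,
#'   `replicate`, `A520`, `L`, `a`, `b`, `Cab`, `hab`, `neg_absorbance`.
#' @export
color_table <- function(ds, grid = observer_grid()) {
  stopifnot(is.list(ds), !is.null(ds$spectra), !is.null(ds$manifest))
  man <- ds$manifest
  specs <- ds$spectra
  keyb <- paste(man$copigment, man$dose_g_per_L, man$pH, man$ethanol_pct,
                man$replicate)
  rows <- list()
  for (i in seq_len(nrow(man))) {
    m <- man[i, ]
    if (!m$role %in% c("mix", "control")) next
    s <- specs[[m$sample_id]]
    if (m$role == "mix") {
      j <- which(man$role == "blank" & keyb == keyb[i])
      if (length(j) != 1)
        stop(sprintf("mix '%s' resolves %d blanks; expected exactly 1",
                     m$sample_id, length(j)))
      b <- specs[[man$sample_id[j]]]
      s <- subtract_blank(resample_to_grid(s, grid),
                          resample_to_grid(b, grid))
    }
    cc <- spectrum_color(s, grid)
    rows[[length(rows) + 1]] <- data.frame(
      sample_id = m$sample_id,
      role = if (m$role == "mix") "corrected" else "control",
      copigment = m$copigment, family = m$family,
      dose_g_per_L = m$dose_g_per_L,
      ratio = mass_ratio(m$dose_g_per_L, m$pigment_mg_per_L),
      pH = m$pH, ethanol_pct = m$ethanol_pct, replicate = m$replicate,
      A520 = cc$A520, L = cc$L, a = cc$a, b = cc$b,
      Cab = cc$Cab, hab = cc$hab,
      neg_absorbance = cc$neg_absorbance || any(s$absorbance < 0),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

# Tiny FNV-1a hash of a string; used to stamp outputs with a config
# fingerprint without a hashing dependency.
fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte only (b < 256); keep arithmetic in exact doubles
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b)
    lo <- (h %% 65536) * 16777619
    hi <- ((h %/% 65536) * 16777619) %% 65536
    h <- (lo + hi * 65536) %% 4294967296
  }
  # h can exceed .Machine$integer.max; format as two 16-bit halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

write_output <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Chains the stages end-to-end: simulate (or load), colour, Cp, group
#' statistics and PCA, writing delimited outputs plus a short text report to
#' `out_dir`. Deterministic given the config (including its seed); every
#' output carries a header comment with the package version and a config
#' hash. Errors raised inside a stage are re-signalled with the stage name
#' attached.
#'
#' @param config either a [synth_config()] (the dataset is simulated), a
#'   list with elements `manifest` and `spectra` (file paths, passed to
#'   [load_and_validate()]), or a path to a JSON config file with a
#'   `simulate` block of [synth_config()] fields.
#' @param out_dir output directory; `NULL` to skip writing files.
#' @param alpha significance level for the statistics stage (default 0.05).
#' @return Invisibly, a result bundle: list with `colors`, `cp`,
#'   `replicate_slopes`, `stats` (per condition x parameter comparison of
#'   copigments on their replicate slopes), `pca`, `classification`,
#'   `config_hash`.
#' @export
run_pipeline <- function(config, out_dir = NULL, alpha = 0.05) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  if (is.character(config) && length(config) == 1) {
    raw <- jsonlite::read_json(config, simplifyVector = TRUE)
    if (!is.null(raw$simulate)) {
      sim <- raw$simulate
      if (!is.null(sim$conditions)) sim$conditions <- as.data.frame(sim$conditions)
      if (!is.null(sim$copigments)) sim$copigments <- as.data.frame(sim$copigments)
      config <- do.call(synth_config, sim)
    } else if (!is.null(raw$manifest)) {
      config <- raw
    } else stop("config file needs a 'simulate' block or 'manifest'/'spectra' paths")
  }

  cfg_json <- jsonlite::toJSON(
    if (inherits(config, "synth_config")) unclass(config) else config,
    auto_unbox = TRUE, digits = NA, dataframe = "rows", force = TRUE
  )
  hash <- fnv1a(as.character(cfg_json))
  header <- sprintf("# copigmentr %s | config_hash: %s",
                    as.character(utils::packageVersion("copigmentr")), hash)

  ds <- if (inherits(config, "synth_config")) {
    stage("simulate", generate_experiment(config))
  } else {
    stage("load", load_and_validate(config$manifest, config$spectra))
  }
  grid <- observer_grid()
  colors <- stage("color", color_table(ds, grid))
  cp <- stage("cp", estimate_cp_table(colors))
  slopes <- attr(cp, "replicate_slopes")

  # Group comparison: copigments compared within each condition x parameter
  # on their per-replicate Cp slopes.
  stats_tbl <- stage("stats", {
    keys <- unique(slopes[, c("pH", "ethanol_pct", "parameter")])
    out <- list()
    for (i in seq_len(nrow(keys))) {
      k <- keys[i, ]
      sub <- slopes[slopes$pH == k$pH & slopes$ethanol_pct == k$ethanol_pct &
                      slopes$parameter == k$parameter, ]
      if (length(unique(sub$copigment)) < 2) next
      cmp <- compare_groups(sub$slope, sub$copigment, alpha = alpha)
      out[[length(out) + 1]] <- data.frame(
        pH = k$pH, ethanol_pct = k$ethanol_pct, parameter = k$parameter,
        copigment = names(cmp$letters),
        mean_slope = as.numeric(cmp$means[names(cmp$letters)]),
        branch = cmp$branch, omnibus_p = cmp$omnibus_p,
        letters = unname(cmp$letters), stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  })

  # PCA observations: copigment x condition rows over the six Cp variables.
  pca <- stage("pca", {
    wide <- stats::reshape(
      cp[, c("copigment", "pH", "ethanol_pct", "parameter", "cp")],
      idvar = c("copigment", "pH", "ethanol_pct"),
      timevar = "parameter", direction = "wide"
    )
    names(wide) <- sub("^cp\\.", "", names(wide))
    mat <- as.matrix(wide[, names(effect_direction_rule())])
    rownames(mat) <- paste(wide$copigment, wide$pH, wide$ethanol_pct, sep = "_")
    list(result = run_pca(mat), observations = wide)
  })

  classification <- stage("classify", {
    keys <- unique(cp[, c("copigment", "pH", "ethanol_pct")])
    do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
      k <- keys[i, ]
      sub <- cp[cp$copigment == k$copigment & cp$pH == k$pH &
                  cp$ethanol_pct == k$ethanol_pct, ]
      cl <- classify_effects(sub)
      data.frame(k, hyperchromic = cl$hyperchromic,
                 hypochromic = cl$hypochromic,
                 bathochromic = cl$bathochromic,
                 hypsochromic = cl$hypsochromic,
                 stringsAsFactors = FALSE)
    }))
  })

  bundle <- list(colors = colors, cp = as.data.frame(cp),
                 replicate_slopes = slopes, stats = stats_tbl,
                 pca = pca$result, pca_observations = pca$observations,
                 classification = classification, config_hash = hash)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_output(colors, file.path(out_dir, "color_table.csv"), header)
    write_output(as.data.frame(cp), file.path(out_dir, "cp_table.csv"), header)
    write_output(stats_tbl, file.path(out_dir, "stats.csv"), header)
    write_output(classification, file.path(out_dir, "classification.csv"), header)
    sc <- data.frame(observation = rownames(pca$result$scores),
                     pca$result$scores, check.names = FALSE)
    ld <- data.frame(variable = rownames(pca$result$loadings),
                     pca$result$loadings, check.names = FALSE)
    write_output(sc, file.path(out_dir, "pca_scores.csv"), header)
    write_output(ld, file.path(out_dir, "pca_loadings.csv"), header)
    rep_lines <- c(
      header,
      sprintf("samples: %d colour-rated (%d corrected mixes, %d controls)",
              nrow(colors), sum(colors$role == "corrected"),
              sum(colors$role == "control")),
      sprintf("Cp estimates: %d (copigment x condition x parameter)", nrow(cp)),
      sprintf("PCA explained variance: %s",
              paste(sprintf("PC%d %.1f%%", seq_along(pca$result$explained),
                            100 * pca$result$explained), collapse = ", ")),
      "classification (per copigment x condition):",
      utils::capture.output(print(classification, row.names = FALSE))
    )
    writeLines(rep_lines, file.path(out_dir, "report.txt"))
  }
  invisible(bundle)
}

#' Command-line interface
#'
#' Subcommands: `simulate --config cfg.json --out dir` (write a synthetic
#' dataset), `run --config cfg.json --out dir` (full pipeline),
#' `cp --manifest m.csv --spectra s.csv --out dir` (load, colour, Cp),
#' `stats --cp-table cp.csv --out dir` and `pca --cp-table cp.csv --out dir`
#' (re-run the downstream stages from a written Cp table). Logging goes to
#' standard error.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return Invisibly, the result of the subcommand.
#' @export
copigment_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: copigmentr <simulate|run|cp|stats|pca> [--config f] [--manifest f]",
    "[--spectra f] [--cp-table f] [--out dir] [--seed n]"
  )
  if (!length(args)) stop(usage, call. = FALSE)
  cmd <- args[1]
  opts <- list()
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (i + 1 > length(args)) stop("missing value for --", key, call. = FALSE)
    opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  log_msg <- function(...) message("[copigmentr] ", sprintf(...))
  out <- opts[["out"]]

  res <- switch(cmd,
    simulate = {
      cfg <- if (!is.null(opts$config)) {
        raw <- jsonlite::read_json(opts$config, simplifyVector = TRUE)
        sim <- if (!is.null(raw$simulate)) raw$simulate else raw
        if (!is.null(sim$conditions)) sim$conditions <- as.data.frame(sim$conditions)
        if (!is.null(sim$copigments)) sim$copigments <- as.data.frame(sim$copigments)
        do.call(synth_config, sim)
      } else synth_config()
      if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
      log_msg("simulating (seed %d)", cfg$seed)
      ds <- generate_experiment(cfg)
      if (is.null(out)) stop("simulate needs --out", call. = FALSE)
      write_dataset(ds, out)
      log_msg("wrote %d spectra to %s", length(ds$spectra), out)
      ds
    },
    run = {
      if (is.null(opts$config)) stop("run needs --config", call. = FALSE)
      log_msg("running pipeline from %s", opts$config)
      run_pipeline(opts$config, out_dir = out)
    },
    cp = {
      if (is.null(opts$manifest) || is.null(opts$spectra))
        stop("cp needs --manifest and --spectra", call. = FALSE)
      ds <- load_and_validate(opts$manifest, opts$spectra)
      for (w in ds$warnings) log_msg("warning: %s", w)
      colors <- color_table(ds)
      cp <- estimate_cp_table(colors)
      if (!is.null(out)) {
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        utils::write.csv(colors, file.path(out, "color_table.csv"),
                         row.names = FALSE)
        utils::write.csv(as.data.frame(cp), file.path(out, "cp_table.csv"),
                         row.names = FALSE)
        log_msg("wrote colour and Cp tables to %s", out)
      }
      cp
    },
    stats = ,
    pca = {
      if (is.null(opts[["cp-table"]])) stop(cmd, " needs --cp-table", call. = FALSE)
      cp <- utils::read.csv(opts[["cp-table"]], comment.char = "#")
      if (cmd == "stats") {
        stop("stats from a written Cp table needs per-replicate slopes; ",
             "use 'run' on the full dataset", call. = FALSE)
      }
      wide <- stats::reshape(
        cp[, c("copigment", "pH", "ethanol_pct", "parameter", "cp")],
        idvar = c("copigment", "pH", "ethanol_pct"),
        timevar = "parameter", direction = "wide"
      )
      names(wide) <- sub("^cp\\.", "", names(wide))
      mat <- as.matrix(wide[, setdiff(names(wide),
                                      c("copigment", "pH", "ethanol_pct"))])
      rownames(mat) <- paste(wide$copigment, wide$pH, wide$ethanol_pct, sep = "_")
      p <- run_pca(mat)
      if (!is.null(out)) {
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        utils::write.csv(data.frame(observation = rownames(p$scores), p$scores),
                         file.path(out, "pca_scores.csv"), row.names = FALSE)
        utils::write.csv(data.frame(variable = rownames(p$loadings), p$loadings),
                         file.path(out, "pca_loadings.csv"), row.names = FALSE)
      }
      p
    },
    stop(usage, call. = FALSE)
  )
  invisible(res)
}
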