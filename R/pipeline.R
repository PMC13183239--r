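#' Pipeline configuration
#'
#' Collects every setting of the end-to-end analysis.  Exactly one input
#' source: either `simulate` (a [sim_config()]) or `files` (paths to a trait
#' CSV and a spectra CSV).  Stage order is fixed: derive traits, apply the
#' transform registry (with Shapiro-Wilk screening reported alongside),
#' mask outliers, then per trait and per split strategy: split, select the
#' component count by LOO PRESS, fit, evaluate, jackknife.  Outliers are
#' masked before splitting so both regimes see the same cleaned table.
#'
#' @param simulate optional [sim_config()].
#' @param files optional list with `traits` and `spectra` CSV paths (wide
#'   spectra layout).
#' @param window spectral window `c(lower, upper)` in nm.
#' @param step resampling step, nm.
#' @param outlier_factor IQR fence multiplier (see [iqr_outlier_filter()]).
#' @param registry transform registry (see [apply_transforms()]).
#' @param split_seeds named integer vector with entries `random` and
#'   `group_balanced`.
#' @param a_max_cap component-search cap.
#' @param selection component selection rule, `"onesigma"` or `"min"` (see
#'   [loo_press()]).
#' @param scale predictor scaling flag for [plsr()].
#' @param jackknife logical; compute intervals for successful models.
#' @param jk_B,jk_leave_frac jackknife settings.
#' @param out_dir output directory for the report bundle.
#' @export
pipeline_config <- function(simulate = NULL, files = NULL,
                            window = c(400, 2400), step = 1,
                            outlier_factor = 2,
                            registry = default_transform_registry(),
                            split_seeds = c(random = 101L, group_balanced = 202L),
                            a_max_cap = 15, selection = "onesigma",
                            scale = FALSE,
                            jackknife = TRUE, jk_B = 500, jk_leave_frac = 0.2,
                            out_dir = "vitispec_output") {
  if (is.null(simulate) == is.null(files)) {
    stop("exactly one input source required: 'simulate' or 'files'")
  }
  if (!is.null(simulate)) stopifnot(inherits(simulate, "sim_config"))
  if (!is.null(files)) stopifnot(all(c("traits", "spectra") %in% names(files)))
  stopifnot(length(window) == 2, window[1] < window[2],
            all(c("random", "group_balanced") %in% names(split_seeds)))
  structure(list(simulate = simulate, files = files, window = window,
                 step = step, outlier_factor = outlier_factor,
                 registry = registry, split_seeds = split_seeds,
                 a_max_cap = a_max_cap, selection = selection,
                 scale = scale, jackknife = jackknife,
                 jk_B = jk_B, jk_leave_frac = jk_leave_frac,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Mirrors [pipeline_config()]; the YAML may contain a `simulate:` block
#' (`seed`, `missing_rate`, `spectral_noise_sd`, optional `config` path to a
#' trait/link YAML) or a `files:` block (`traits`, `spectra`), plus any of
#' the scalar settings.
#'
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulate)) {
    s <- y$simulate
    spec_path <- if (!is.null(s$config)) s$config else
      system.file("extdata", "default_sim.yaml", package = "vitispec")
    args <- list(trait_specs = default_trait_specs(spec_path),
                 link_specs = default_spectral_links(spec_path))
    for (k in c("n_cultivars", "n_varieties", "rows_per_cultivar",
                "vines_per_row", "missing_rate", "spectral_noise_sd", "seed")) {
      if (!is.null(s[[k]])) args[[k]] <- s[[k]]
    }
    sim <- do.call(sim_config, args)
  }
  args <- list(simulate = sim, files = y$files)
  for (k in c("window", "step", "outlier_factor", "a_max_cap", "selection",
              "scale", "jackknife", "jk_B", "jk_leave_frac", "out_dir")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  if (!is.null(y$registry)) args$registry <- unlist(y$registry)
  if (!is.null(y$split_seeds)) args$split_seeds <- unlist(y$split_seeds)
  do.call(pipeline_config, args)
}

#' Run the full spectra-to-trait analysis
#'
#' Executes the whole protocol and writes a report bundle to
#' `config$out_dir`: `trait_summary.csv` (descriptive statistics and
#' Shapiro-Wilk screening per trait), `variance_components.csv`,
#' `anova.csv`, `cultivar_means.csv`, `model_results.csv` (one row per
#' trait x split: n_obs, n_cal, n_val, n_comp, RMSE, R2, %RMSE, status),
#' `vip.csv` (wavelength-level VIP per successful model),
#' `vip_regions.csv`, `intervals.csv` (per validation leaf), and
#' `manifest.json` (seeds, settings, outlier tallies, package version).
#' Every stage failure is rethrown with the stage name prefixed.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with all in-memory results: `table`
#'   (screened trait table), `spectra`, `summary`, `varcomp`, `anova`,
#'   `fits`, `results` (the model_results data.frame), `correlation`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage: %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  # --- input ---------------------------------------------------------------
  inp <- stage("input", {
    if (!is.null(config$simulate)) {
      simulate_vineyard(config$simulate)
    } else {
      list(traits = utils::read.csv(config$files$traits, stringsAsFactors = FALSE),
           spectra = read_spectra(config$files$spectra, layout = "wide"))
    }
  })
  table <- inp$traits
  say("input: %d leaves, %d trait columns", nrow(table), length(trait_columns(table)))

  spectra <- stage("spectra", {
    trim_and_resample(inp$spectra, config$window[1], config$window[2], config$step)
  })

  # --- derive + screen -----------------------------------------------------
  table <- stage("derive", {
    if (all(c("Amax", "gs", "E") %in% names(table))) derive_wue(table) else table
  })
  summary_raw <- stage("summarize", summarize_traits(table))
  table <- stage("transform", suppressWarnings(apply_transforms(table, config$registry)))
  table <- stage("outliers", mask_outliers(table, factor = config$outlier_factor))
  out_counts <- attr(table, "outlier_counts")
  say("outliers masked per trait: %s",
      paste(sprintf("%s=%d", names(out_counts), out_counts), collapse = ", "))
  summary_screened <- stage("summarize", summarize_traits(table))

  # --- hierarchy analyses (on raw-scale traits, pre-transform table) -------
  varcomp <- stage("variance components", {
    do.call(rbind, lapply(trait_columns(table), function(tr) {
      vc <- tryCatch(fit_variance_components(table, tr),
                     error = function(e) NULL)
      if (is.null(vc)) return(NULL)
      data.frame(trait = tr, level = vc$level, proportion = vc$proportion,
                 method = attr(vc, "method"), stringsAsFactors = FALSE)
    }))
  })
  anova_tab <- stage("anova", {
    do.call(rbind, lapply(trait_columns(table), function(tr) {
      a <- tryCatch(anova_tukey(table, tr), error = function(e) NULL)
      if (is.null(a)) return(NULL)
      data.frame(trait = tr, f = a$f, p = a$p, degenerate = a$degenerate,
                 n_pairwise = if (is.null(a$pairwise)) 0L else nrow(a$pairwise),
                 stringsAsFactors = FALSE)
    }))
  })
  cmeans <- stage("cultivar means", cultivar_means(table))

  # --- per-trait models under both split regimes ---------------------------
  specs <- list(
    random = split_spec("random", seed = config$split_seeds[["random"]]),
    cultivar = split_spec("group_balanced", group = "cultivar",
                          seed = config$split_seeds[["group_balanced"]])
  )
  fits <- list()
  rows <- list()
  for (split_name in names(specs)) {
    for (tr in trait_columns(table)) {
      fit <- stage(sprintf("model %s/%s", split_name, tr), {
        fit_trait_model(spectra, table, tr, specs[[split_name]],
                        a_max_cap = config$a_max_cap,
                        selection = config$selection, scale = config$scale,
                        jackknife = config$jackknife, jk_B = config$jk_B,
                        jk_leave_frac = config$jk_leave_frac)
      })
      fit$split <- split_name
      fits[[paste(split_name, tr, sep = ".")]] <- fit
      rows[[length(rows) + 1L]] <- data.frame(
        split = split_name, trait = tr, status = fit$status,
        n_obs = fit$n_obs, n_cal = fit$n_cal, n_val = fit$n_val,
        n_comp = fit$cv$selected,
        rmse = if (fit$status == "ok") fit$metrics$rmse else NA_real_,
        r2 = if (fit$status == "ok") fit$metrics$r2 else NA_real_,
        pct_rmse = if (fit$status == "ok") fit$metrics$pct_rmse else NA_real_,
        stringsAsFactors = FALSE
      )
      say("model %s/%s: %s", split_name, tr,
          if (fit$status == "ok")
            sprintf("%d comps, R2 = %.3f", fit$cv$selected, fit$metrics$r2)
          else fit$status)
    }
  }
  results <- do.call(rbind, rows)

  correlation <- stage("correlation", {
    tryCatch(correlate_r2_cv(results, summary_screened),
             error = function(e) NULL)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("vitispec")),
    input = if (!is.null(config$simulate)) "simulate" else "files",
    sim_seed = if (!is.null(config$simulate)) config$simulate$seed else NULL,
    split_seeds = as.list(config$split_seeds),
    window = config$window, step = config$step,
    outlier_factor = config$outlier_factor,
    outliers_removed = as.list(out_counts),
    a_max_cap = config$a_max_cap, selection = config$selection,
    scale = config$scale,
    jackknife = list(enabled = config$jackknife, B = config$jk_B,
                     leave_frac = config$jk_leave_frac),
    n_leaves = nrow(table),
    traits = trait_columns(table)
  )

  # --- report bundle -------------------------------------------------------
  stage("report", {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(df, f) utils::write.csv(df, file.path(config$out_dir, f),
                                          row.names = FALSE)
    w(summary_screened, "trait_summary.csv")
    w(varcomp, "variance_components.csv")
    w(anova_tab, "anova.csv")
    w(cmeans, "cultivar_means.csv")
    w(results, "model_results.csv")
    vip_rows <- do.call(rbind, lapply(fits, function(f) {
      if (f$status != "ok") return(NULL)
      data.frame(split = f$split, trait = f$trait,
                 wavelength_nm = spectra$wavelengths, vip = unname(f$vip),
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(vip_rows)) w(vip_rows, "vip.csv")
    region_rows <- do.call(rbind, lapply(fits, function(f) {
      if (f$status != "ok") return(NULL)
      cbind(split = f$split, trait = f$trait, f$vip_regions)
    }))
    if (!is.null(region_rows)) w(region_rows, "vip_regions.csv")
    int_rows <- do.call(rbind, lapply(fits, function(f) {
      if (f$status != "ok" || is.null(f$jackknife)) return(NULL)
      cbind(split = f$split, trait = f$trait, f$jackknife$intervals)
    }))
    if (!is.null(int_rows)) w(int_rows, "intervals.csv")
    if (!is.null(correlation)) w(correlation, "r2_cv_correlation.csv")
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  say("report written to %s", config$out_dir)

  invisible(list(table = table, spectra = spectra, summary = summary_screened,
                 summary_raw = summary_raw, varcomp = varcomp,
                 anova = anova_tab, cultivar_means = cmeans, fits = fits,
                 results = results, correlation = correlation,
                 manifest = manifest))
}
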