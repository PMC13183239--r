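#' Calibration/validation split specification
#'
#' Two regimes: `"random"` draws the calibration set completely at random
#' (`n_cal = floor(fraction * n)`), letting cultivar representation drift;
#' `"group_balanced"` reserves `ceil((1 - fraction) * n_k)` validation leaves
#' within every group (cultivar), so both sets represent every cultivar.
#'
#' @param strategy `"random"` or `"group_balanced"`.
#' @param fraction calibration fraction, in (0, 1); default 0.8.
#' @param group grouping column name (required for `"group_balanced"`).
#' @param seed integer RNG seed for the draw.
#' @export
split_spec <- function(strategy = c("random", "group_balanced"),
                       fraction = 0.8, group = NULL, seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(fraction > 0, fraction < 1)
  if (strategy == "group_balanced" && is.null(group)) {
    stop("group_balanced splitting needs a 'group' column")
  }
  structure(list(strategy = strategy, fraction = fraction, group = group,
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Split leaf ids into calibration and validation sets
#'
#' @param table leaf table with a `leaf_id` column (and the group column for
#'   balanced splits).
#' @param spec a [split_spec()].
#' @return list with `calibration` and `validation` character vectors of leaf
#'   ids; together they partition the table's ids.
#' @export
split_data <- function(table, spec) {
  stopifnot(inherits(spec, "split_spec"))
  ids <- table$leaf_id
  n <- length(ids)
  if (n < 10) stop("need at least 10 observations to split")
  set.seed(spec$seed)
  if (spec$strategy == "random") {
    n_cal <- floor(spec$fraction * n)
    cal <- sort(sample(ids, n_cal))
    list(calibration = cal, validation = sort(setdiff(ids, cal)))
  } else {
    groups <- split(ids, table[[spec$group]])
    sizes <- lengths(groups)
    if (any(sizes < 2)) {
      stop(sprintf("group '%s' has a single member; cannot balance the split",
                   names(groups)[which(sizes < 2)[1]]))
    }
    val <- unlist(lapply(groups, function(g) {
      n_val <- ceiling((1 - spec$fraction) * length(g))
      sample(g, n_val)
    }), use.names = FALSE)
    list(calibration = sort(setdiff(ids, val)), validation = sort(val))
  }
}

#' Leave-one-out PRESS over candidate component counts
#'
#' For each candidate count `a = 0..a_max`, computes the prediction residual
#' sum of squares \eqn{PRESS(a) = \sum_i (y_i - \hat y_{-i,a})^2} where
#' \eqn{\hat y_{-i,a}} is the prediction for observation i from a PLSR model
#' fitted without it (a = 0 is the leave-one-out mean).  One model is fitted
#' per held-out observation (n fits), each evaluated at every count.  The
#' selected count is the argmin, ties broken towards fewer components; a
#' selection of 0 means no latent component explains the covariance between
#' spectra and trait, and is flagged as a model failure rather than an error.
#'
#' Two selection rules are available.  `"min"` is the strict argmin described
#' above.  `"onesigma"` is the one-standard-error parsimony convention common
#' in chemometric component selection: the smallest count whose mean squared
#' LOO error lies within one standard error of the global minimum.  The
#' strict argmin is unstable when the PRESS curve is nearly flat past its
#' elbow — sampling fluctuations can push the literal minimum far to the
#' right — so the protocol layer uses `"onesigma"` by default.
#'
#' @param x_cal calibration predictor matrix.
#' @param y_cal calibration response.
#' @param a_max largest candidate count; needs `nrow(x_cal) >= a_max + 2`.
#' @param scale passed to [plsr()].
#' @param selection `"min"` (strict PRESS argmin) or `"onesigma"`.
#' @return object of class `"cv_result"`: list with `press` (named vector
#'   over a = 0..a_max), `selected`, `failed`, `selection`, `loo_residuals`
#'   (n x (a_max+1) matrix of held-out residuals) and `sigma_loo` (per-count
#'   sd of held-out residuals).
#' @export
loo_press <- function(x_cal, y_cal, a_max, scale = FALSE,
                      selection = c("min", "onesigma")) {
  selection <- match.arg(selection)
  x_cal <- as.matrix(x_cal)
  n <- nrow(x_cal)
  if (n < a_max + 2) stop(sprintf("n_cal = %d too small for a_max = %d", n, a_max))
  res <- matrix(NA_real_, n, a_max + 1)
  for (i in seq_len(n)) {
    fit <- plsr(x_cal[-i, , drop = FALSE], y_cal[-i], ncomp = a_max, scale = scale)
    res[i, 1] <- y_cal[i] - mean(y_cal[-i])
    for (a in seq_len(a_max)) {
      res[i, a + 1] <- y_cal[i] - predict(fit, x_cal[i, , drop = FALSE], ncomp = a)
    }
  }
  press <- colSums(res^2)
  names(press) <- paste0("a", 0:a_max)
  # standard error of PRESS itself: PRESS = sum of n squared LOO residuals,
  # so se(PRESS) = sd(res^2) * sqrt(n)
  se <- if (selection == "onesigma") apply(res^2, 2, stats::sd) * sqrt(n) else NULL
  sel <- select_components(press, se = se)
  structure(list(press = press, selected = sel$selected,
                 failed = sel$failed, selection = selection,
                 loo_residuals = res,
                 sigma_loo = apply(res, 2, stats::sd)),
            class = "cv_result")
}

#' Component count minimizing PRESS
#'
#' Selection rule shared by the protocol: the candidate counts are
#' `0..(length(press) - 1)` in vector order; the argmin wins, ties going to
#' the smallest count, and a winner of 0 (the intercept-only model) is a
#' model failure: no latent component explains the covariance.  When `se`
#' (the standard error of each mean squared LOO error) is supplied, the
#' one-standard-error convention applies instead: the smallest count whose
#' PRESS is within `se[argmin]` of the minimum.
#'
#' @param press numeric vector of PRESS values for counts 0, 1, 2, ...
#' @param se optional standard errors of the PRESS values themselves (same
#'   length), switching on the one-sigma rule.
#' @return list with `selected` (integer count) and `failed` flag.
#' @export
select_components <- function(press, se = NULL) {
  stopifnot(length(press) >= 1, all(is.finite(press)), all(press >= 0))
  amin <- unname(which.min(press))  # which.min returns the first minimum
  selected <- amin - 1L
  if (!is.null(se)) {
    stopifnot(length(se) == length(press), all(is.finite(se)))
    selected <- unname(which(press <= press[amin] + se[amin])[1]) - 1L
  }
  list(selected = selected, failed = selected == 0L)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("LOO PRESS component selection: selected %d component(s)%s\n",
              x$selected,
              if (x$failed) " [FAILED: no latent component explains the covariance]" else ""))
  print(round(x$press, 4))
  invisible(x)
}

#' Validation metrics for predicted trait values
#'
#' Out-of-sample \eqn{R^2 = 1 - SS_{res}/SS_{tot}} (which is negative when the
#' model predicts worse than the validation mean), RMSE in trait units,
#' percent RMSE normalized by the observed validation range
#' (`100 * rmse / (max(obs) - min(obs))`), and mean bias.
#'
#' @param observed,predicted numeric vectors of equal length >= 2.
#' @param trait optional trait label carried through.
#' @return one-row data.frame: `trait`, `n`, `r2`, `rmse`, `pct_rmse`,
#'   `bias`.  Constant observations make `r2` (and `pct_rmse`) `NA` with a
#'   warning.
#' @export
evaluate <- function(observed, predicted, trait = NA_character_) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  ok <- !is.na(observed) & !is.na(predicted)
  o <- observed[ok]
  p <- predicted[ok]
  ss_res <- sum((o - p)^2)
  ss_tot <- sum((o - mean(o))^2)
  rmse <- sqrt(mean((o - p)^2))
  rng <- max(o) - min(o)
  if (ss_tot == 0) {
    warning("constant observed values: R^2 undefined")
    r2 <- NA_real_
  } else {
    r2 <- 1 - ss_res / ss_tot
  }
  data.frame(trait = trait, n = length(o), r2 = r2, rmse = rmse,
             pct_rmse = if (rng > 0) 100 * rmse / rng else NA_real_,
             bias = mean(p - o))
}

#' Jackknife-style uncertainty for PLSR predictions
#'
#' Repeated-subsample jackknife: the model is refitted `B` times, each on a
#' random `(1 - leave_frac)` share of the calibration rows, at a fixed
#' component count.  Reported per band: the percentile envelope of the
#' coefficients; per validation leaf: the mean prediction, a 95% confidence
#' interval (2.5/97.5 percentiles of the B predictions, sampling uncertainty
#' of the calibration) and a 95% prediction interval (the CI widened by
#' +/- 1.96 x the leave-one-out residual sd at that component count, adding
#' irreducible observation noise).  The classical delete-one jackknife is the
#' special case `mode = "delete_one"` (B = n, each fit dropping one row).
#'
#' @param x_cal,y_cal calibration data.
#' @param ncomp component count (from [loo_press()]).
#' @param x_val validation predictor matrix.
#' @param B number of refits (ignored for `mode = "delete_one"`).
#' @param leave_frac fraction of calibration rows left out per refit.
#' @param seed RNG seed.
#' @param scale passed to [plsr()].
#' @param sigma_resid residual sd used for the prediction interval; default
#'   recomputes the LOO residual sd at `ncomp`.
#' @param mode `"subsample"` (default) or `"delete_one"`.
#' @return list with `coef_envelope` (data.frame: band, lower, median,
#'   upper), `intervals` (data.frame per validation leaf: mean prediction,
#'   `ci_lower`, `ci_upper`, `pi_lower`, `pi_upper`), `sigma_resid`, `B`.
#' @export
jackknife_uncertainty <- function(x_cal, y_cal, ncomp, x_val, B = 500,
                                  leave_frac = 0.2, seed = 1L, scale = FALSE,
                                  sigma_resid = NULL, mode = c("subsample", "delete_one")) {
  mode <- match.arg(mode)
  x_cal <- as.matrix(x_cal)
  x_val <- as.matrix(x_val)
  n <- nrow(x_cal)
  stopifnot(ncomp >= 1)
  if (mode == "subsample") {
    n_drop <- max(1L, floor(leave_frac * n))
    if (B < 1) stop("B must be at least 1")
    if (B * leave_frac < 1) stop("B * leave_frac must be at least 1")
  }
  if (is.null(sigma_resid)) {
    cv <- loo_press(x_cal, y_cal, a_max = ncomp, scale = scale)
    sigma_resid <- cv$sigma_loo[ncomp + 1]
  }
  set.seed(seed)
  draws <- if (mode == "delete_one") {
    lapply(seq_len(n), function(i) setdiff(seq_len(n), i))
  } else {
    lapply(seq_len(B), function(b) sort(sample(n, n - n_drop)))
  }
  preds <- matrix(NA_real_, length(draws), nrow(x_val))
  coefs <- matrix(NA_real_, length(draws), ncol(x_cal))
  for (b in seq_along(draws)) {
    idx <- draws[[b]]
    fit <- plsr(x_cal[idx, , drop = FALSE], y_cal[idx], ncomp = ncomp, scale = scale)
    preds[b, ] <- predict(fit, x_val, ncomp = ncomp)
    coefs[b, ] <- coef(fit, ncomp = ncomp, raw = FALSE)
  }
  qc <- apply(coefs, 2, stats::quantile, probs = c(0.025, 0.5, 0.975), names = FALSE)
  qp <- apply(preds, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  band <- colnames(x_cal)
  if (is.null(band)) band <- paste0("band_", seq_len(ncol(x_cal)))
  intervals <- data.frame(
    leaf_id = if (!is.null(rownames(x_val))) rownames(x_val) else seq_len(nrow(x_val)),
    mean_pred = colMeans(preds),
    ci_lower = qp[1, ], ci_upper = qp[2, ],
    pi_lower = qp[1, ] - 1.96 * sigma_resid,
    pi_upper = qp[2, ] + 1.96 * sigma_resid,
    stringsAsFactors = FALSE
  )
  list(coef_envelope = data.frame(band = band, lower = qc[1, ],
                                  median = qc[2, ], upper = qc[3, ],
                                  stringsAsFactors = FALSE),
       intervals = intervals, sigma_resid = unname(sigma_resid),
       B = length(draws))
}

#' Per-region VIP summary
#'
#' Aggregates VIP scores over the named spectral windows (VIS, RED_EDGE, NIR,
#' SWIR1, SWIR2); the red edge is counted separately even though it lies
#' inside VIS.  Regions with no band on the model grid are omitted.
#'
#' @param vip_scores numeric VIP vector.
#' @param wavelengths matching wavelengths, nm.
#' @param regions region table as from [spectral_regions()].
#' @return data.frame: `region`, `n_bands`, `mean_vip`, `max_vip`,
#'   `frac_ge_0.8`, `frac_ge_1`.
#' @export
vip_region_summary <- function(vip_scores, wavelengths,
                               regions = spectral_regions()) {
  stopifnot(length(vip_scores) == length(wavelengths))
  out <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
    in_r <- wavelengths >= regions$lower[i] & wavelengths <= regions$upper[i]
    if (!any(in_r)) return(NULL)
    v <- vip_scores[in_r]
    data.frame(region = regions$name[i], n_bands = sum(in_r),
               mean_vip = mean(v), max_vip = max(v),
               frac_ge_0.8 = mean(v >= 0.8), frac_ge_1 = mean(v >= 1),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Correlate model skill with trait variability
#'
#' Pearson correlation between each trait's coefficient of variation and its
#' validation R^2, per data-splitting strategy.  A negative correlation means
#' more variable traits were predicted *worse* under that regime.
#'
#' @param model_results data.frame with columns `trait`, `split`, `r2` (one
#'   row per trait x split), e.g. from [run_pipeline()] or
#'   [reference_plsr_results()].
#' @param trait_summaries data.frame with columns `trait` and `cv`, e.g. from
#'   [summarize_traits()] or [reference_trait_stats()].
#' @return data.frame: `split`, `n_traits`, `pearson_r`, `p_value`.
#' @export
correlate_r2_cv <- function(model_results, trait_summaries) {
  stopifnot(all(c("trait", "split", "r2") %in% names(model_results)),
            all(c("trait", "cv") %in% names(trait_summaries)))
  out <- do.call(rbind, lapply(split(model_results, model_results$split), function(mr) {
    m <- merge(mr, trait_summaries[, c("trait", "cv")], by = "trait")
    m <- m[!is.na(m$r2) & !is.na(m$cv), ]
    if (nrow(m) < 3) stop("need at least 3 traits with both R^2 and CV")
    ct <- stats::cor.test(m$cv, m$r2, method = "pearson")
    data.frame(split = mr$split[1], n_traits = nrow(m),
               pearson_r = unname(ct$estimate), p_value = ct$p.value,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Fit the full spectra-to-trait protocol for one trait
#'
#' Runs the complete per-trait recipe: drop leaves with a missing trait
#' value, split into calibration/validation, select the component count by
#' leave-one-out PRESS, fit the final model on the calibration set, evaluate
#' on the validation set, compute VIP scores and region summaries, and
#' (optionally) jackknife uncertainty intervals.  A PRESS selection of 0 is
#' reported as status `"no latent component"` with no model metrics, matching
#' how non-converging trait models should be surfaced rather than dropped.
#'
#' @param spectra a [spectra_set()] on the modelling grid.
#' @param table leaf trait table (leaf ids must match the spectra).
#' @param trait trait column name.
#' @param spec a [split_spec()].
#' @param a_max_cap cap on the component search (default 15); the search
#'   upper bound is `min(a_max_cap, n_cal - 2)`.
#' @param selection component selection rule (see [loo_press()]); the
#'   protocol defaults to the parsimonious `"onesigma"` convention.
#' @param scale passed to [plsr()].
#' @param jackknife logical; compute uncertainty intervals.
#' @param jk_B,jk_leave_frac jackknife settings.
#' @return object of class `"trait_model_fit"`: list with `trait`, `split`
#'   (strategy), `status`, `n_obs`, `n_cal`, `n_val`, `cv` (the
#'   [loo_press()] result), `model`, `metrics`, `vip`, `vip_regions`,
#'   `jackknife`, `validation` (data.frame leaf_id/observed/predicted).
#' @export
fit_trait_model <- function(spectra, table, trait, spec,
                            a_max_cap = 15, selection = "onesigma",
                            scale = FALSE,
                            jackknife = TRUE, jk_B = 500, jk_leave_frac = 0.2) {
  stopifnot(inherits(spectra, "spectra_set"), inherits(spec, "split_spec"))
  v <- table[[trait]]
  if (is.null(v)) stop(sprintf("trait '%s' not in table", trait))
  keep <- !is.na(v) & table$leaf_id %in% spectra$leaf_ids
  sub <- table[keep, , drop = FALSE]
  ids <- split_data(sub, spec)
  x <- spectra$reflectance[match(sub$leaf_id, spectra$leaf_ids), , drop = FALSE]
  rownames(x) <- sub$leaf_id
  y <- stats::setNames(sub[[trait]], sub$leaf_id)
  x_cal <- x[ids$calibration, , drop = FALSE]
  y_cal <- y[ids$calibration]
  x_val <- x[ids$validation, , drop = FALSE]
  y_val <- y[ids$validation]

  a_max <- min(a_max_cap, length(y_cal) - 2)
  cv <- loo_press(x_cal, y_cal, a_max = a_max, scale = scale,
                  selection = selection)
  base <- list(trait = trait, split = spec$strategy,
               n_obs = nrow(sub), n_cal = length(y_cal), n_val = length(y_val),
               cv = cv)
  if (cv$failed) {
    return(structure(c(base, list(status = "no latent component", model = NULL,
                                  metrics = NULL, vip = NULL,
                                  vip_regions = NULL, jackknife = NULL,
                                  validation = NULL)),
                     class = "trait_model_fit"))
  }
  model <- plsr(x_cal, y_cal, ncomp = cv$selected, scale = scale)
  pred <- predict(model, x_val)
  metrics <- evaluate(y_val, pred, trait = trait)
  v_scores <- vip(model)
  jk <- NULL
  if (jackknife) {
    jk <- jackknife_uncertainty(x_cal, y_cal, ncomp = cv$selected,
                                x_val = x_val, B = jk_B,
                                leave_frac = jk_leave_frac,
                                seed = spec$seed + 1L, scale = scale,
                                sigma_resid = cv$sigma_loo[cv$selected + 1])
  }
  structure(c(base, list(
    status = "ok", model = model, metrics = metrics, vip = v_scores,
    vip_regions = vip_region_summary(v_scores, spectra$wavelengths),
    jackknife = jk,
    validation = data.frame(leaf_id = names(y_val), observed = unname(y_val),
                            predicted = pred, stringsAsFactors = FALSE)
  )), class = "trait_model_fit")
}

#' @export
print.trait_model_fit <- function(x, ...) {
  cat(sprintf("trait '%s' [%s split]: ", x$trait, x$split))
  if (x$status != "ok") {
    cat(sprintf("status: %s (selected 0 components)\n", x$status))
  } else {
    cat(sprintf("%d components; validation R^2 = %.3f, RMSE = %.4g, %%RMSE = %.1f\n",
                x$cv$selected, x$metrics$r2, x$metrics$rmse, x$metrics$pct_rmse))
  }
  invisible(x)
}
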