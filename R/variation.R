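#' Nested variance-component partitioning for one trait
#'
#' Estimates the share of trait variance attributable to each level of the
#' cultivar hierarchy — origin (warm/cool provenance), red/white colour,
#' cultivar identity and planting row — plus an unexplained leaf-level
#' residual.  The hierarchy is treated as strictly nested (row within
#' cultivar within colour within origin): colour units are coded
#' `origin:colour` and row units `cultivar:row`, so an effect is drawn per
#' nested unit, never shared across branches.
#'
#' Variances are estimated by restricted maximum likelihood (random-intercept
#' model via \pkg{lme4}); REML keeps them non-negative, and proportions are
#' the variances normalized by their total (components + residual), so they
#' sum to 1 exactly.  Degenerate designs (a single unit at every requested
#' level, or zero trait variance) fall back to a method-of-moments one-way
#' estimator or to a residual-only answer.
#'
#' @param table leaf trait table with metadata columns `origin`, `colour`,
#'   `cultivar`, `row`.
#' @param trait trait column name.
#' @param nesting which levels to include, in nesting order; any subset of
#'   `c("origin", "red_white", "cultivar", "row")`.
#' @return object of class `"variance_components"`: data.frame with columns
#'   `level` and `proportion` (levels plus `"residual"`), plus attribute
#'   `"variances"` (the raw REML variances) and `"method"`.
#' @export
fit_variance_components <- function(table, trait,
                                    nesting = c("origin", "red_white",
                                                "cultivar", "row")) {
  nesting <- match.arg(nesting, several.ok = TRUE)
  v <- table[[trait]]
  if (is.null(v)) stop(sprintf("trait '%s' not in table", trait))
  keep <- !is.na(v)
  if (sum(keep) < 10) stop("need at least 10 non-missing trait values")
  d <- table[keep, , drop = FALSE]
  d$..y <- v[keep]

  units <- list(
    origin = d$origin,
    red_white = if (!is.null(d$origin)) paste(d$origin, d$colour, sep = ":") else d$colour,
    cultivar = d$cultivar,
    row = paste(d$cultivar, d$row, sep = ":")
  )
  for (lv in nesting) {
    if (is.null(units[[lv]]) || anyNA(units[[lv]])) {
      stop(sprintf("metadata for level '%s' missing from table", lv))
    }
  }
  # check the metadata really nests: each child unit maps to one parent unit
  ord <- c("origin", "red_white", "cultivar", "row")
  present <- ord[ord %in% nesting]
  if (length(present) > 1) {
    for (i in seq_len(length(present) - 1)) {
      parent <- units[[present[i]]]
      child <- units[[present[i + 1]]]
      if (any(tapply(parent, child, function(u) length(unique(u))) > 1)) {
        stop(sprintf("metadata not nested: level '%s' crosses '%s' units",
                     present[i + 1], present[i]))
      }
    }
  }
  usable <- present[vapply(present, function(lv) length(unique(units[[lv]])) >= 2,
                           logical(1))]

  finish <- function(vars, resid, method) {
    all_levels <- c(nesting, "residual")
    out <- stats::setNames(numeric(length(all_levels)), all_levels)
    out[names(vars)] <- pmax(vars, 0)
    out["residual"] <- max(resid, 0)
    tot <- sum(out)
    prop <- if (tot > 0) out / tot else c(stats::setNames(rep(0, length(nesting)), nesting),
                                          residual = 1)
    structure(data.frame(level = names(prop), proportion = unname(prop),
                         row.names = NULL),
              variances = out, method = method, trait = trait,
              class = c("variance_components", "data.frame"))
  }

  if (length(usable) == 0 || stats::var(d$..y) == 0) {
    return(finish(numeric(0), stats::var(d$..y), "residual-only"))
  }

  for (lv in usable) d[[paste0("..u_", lv)]] <- factor(units[[lv]])
  form <- stats::as.formula(paste(
    "..y ~ 1 +", paste(sprintf("(1 | ..u_%s)", usable), collapse = " + ")))
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::lmer(form, data = d, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE))
    )),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    vc <- as.data.frame(lme4::VarCorr(fit))
    resid <- vc$vcov[vc$grp == "Residual"]
    vars <- stats::setNames(vc$vcov[vc$grp != "Residual"],
                            sub("^\\.\\.u_", "", vc$grp[vc$grp != "Residual"]))
    return(finish(vars, resid, "REML"))
  }
  # method-of-moments fallback: one-way EMS on the innermost usable level
  inner <- usable[length(usable)]
  f <- factor(units[[inner]])
  ms <- stats::anova(stats::lm(d$..y ~ f))
  k <- nlevels(f)
  n0 <- (sum(keep) - sum(base::table(f)^2) / sum(keep)) / (k - 1)
  var_b <- (ms$`Mean Sq`[1] - ms$`Mean Sq`[2]) / n0
  finish(stats::setNames(max(var_b, 0), inner), ms$`Mean Sq`[2],
         "method-of-moments")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("Variance components for '%s' (%s):\n",
              attr(x, "trait"), attr(x, "method")))
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' One-way ANOVA across cultivars with Tukey HSD
#'
#' Tests whether a trait differs among cultivars and reports all pairwise
#' cultivar contrasts with Tukey honestly-significant-difference adjusted
#' p-values (studentized-range distribution), together with per-cultivar
#' means and standard errors.
#'
#' @param table leaf trait table with a `cultivar` column.
#' @param trait trait column name.
#' @return object of class `"anova_tukey"`: list with `trait`, `f`, `p`,
#'   `df`, `pairwise` (data.frame: comparison, diff, lwr, upr, p_adj),
#'   `group_stats` (cultivar, n, mean, se) and `degenerate` flag (TRUE when
#'   the within-group variance is zero everywhere, where the F test is
#'   undefined).
#' @export
anova_tukey <- function(table, trait) {
  v <- table[[trait]]
  if (is.null(v)) stop(sprintf("trait '%s' not in table", trait))
  keep <- !is.na(v) & !is.na(table$cultivar)
  d <- data.frame(y = v[keep], cultivar = factor(table$cultivar[keep]))
  counts <- base::table(d$cultivar)
  if (nlevels(d$cultivar) < 2 || sum(counts >= 2) < 2) {
    stop("need at least 2 cultivars with at least 2 leaves each")
  }
  gs <- do.call(rbind, lapply(split(d$y, d$cultivar), function(y) {
    data.frame(n = length(y), mean = mean(y),
               se = if (length(y) >= 2) stats::sd(y) / sqrt(length(y)) else NA_real_)
  }))
  gs <- cbind(cultivar = rownames(gs), gs)
  rownames(gs) <- NULL

  within_ss <- sum(unlist(lapply(split(d$y, d$cultivar),
                                 function(y) sum((y - mean(y))^2))))
  if (within_ss == 0) {
    return(structure(list(trait = trait, f = NA_real_, p = NA_real_,
                          df = c(nlevels(d$cultivar) - 1, nrow(d) - nlevels(d$cultivar)),
                          pairwise = NULL, group_stats = gs, degenerate = TRUE),
                     class = "anova_tukey"))
  }
  fit <- stats::aov(y ~ cultivar, data = d)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$cultivar
  pw <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                   lwr = tk[, "lwr"], upr = tk[, "upr"],
                   p_adj = tk[, "p adj"], row.names = NULL)
  structure(list(trait = trait, f = an$`F value`[1], p = an$`Pr(>F)`[1],
                 df = an$Df, pairwise = pw, group_stats = gs,
                 degenerate = FALSE),
            class = "anova_tukey")
}

#' @export
print.anova_tukey <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("ANOVA for '%s': degenerate (zero within-cultivar variance)\n",
                x$trait))
  } else {
    cat(sprintf("ANOVA for '%s': F(%d, %d) = %.3f, p = %.3g; %d Tukey contrasts\n",
                x$trait, x$df[1], x$df[2], x$f, x$p, nrow(x$pairwise)))
  }
  invisible(x)
}

#' Per-cultivar trait means with standard errors
#'
#' Mean and standard error (sd / sqrt(n)) per cultivar for every trait
#' column, missing-aware.  Ratio traits (the WUE pair) are averaged over
#' per-leaf ratios, not recomputed as ratios of cultivar means.
#'
#' @param table leaf trait table.
#' @param traits trait column names.
#' @return data.frame in long form: `cultivar`, `trait`, `n`, `mean`, `se`
#'   (`se` is `NA` for a single observation).
#' @export
cultivar_means <- function(table, traits = trait_columns(table)) {
  if (nrow(table) == 0) stop("empty table")
  out <- do.call(rbind, lapply(traits, function(tr) {
    pieces <- lapply(split(table[[tr]], table$cultivar), function(y) {
      y <- y[!is.na(y)]
      data.frame(trait = tr, n = length(y),
                 mean = if (length(y)) mean(y) else NA_real_,
                 se = if (length(y) >= 2) stats::sd(y) / sqrt(length(y)) else NA_real_)
    })
    cbind(cultivar = names(pieces), do.call(rbind, pieces))
  }))
  rownames(out) <- NULL
  out[order(out$trait, out$cultivar), ]
}
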