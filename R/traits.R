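#' Derive water-use efficiency traits
#'
#' Adds intrinsic water-use efficiency `WUE_intr = Amax / gs`
#' (umol CO2 mol-1 H2O) and instantaneous water-use efficiency
#' `WUE_inst = Amax / E` (umol CO2 mmol-1 H2O) to a leaf trait table.
#' Missing components propagate; a zero denominator makes the derived cell
#' missing with a warning (the ratio is undefined, not infinite, for a closed
#' stoma reading of zero conductance).
#'
#' Existing `WUE_intr` / `WUE_inst` columns are recomputed only when
#' `overwrite = TRUE`; simulated tables already carry them as first-class
#' traits.
#'
#' @param table data.frame with columns `Amax`, `gs`, `E`.
#' @param overwrite recompute even if the derived columns exist.
#' @return the table with `WUE_intr` and `WUE_inst` columns.
#' @export
derive_wue <- function(table, overwrite = FALSE) {
  need <- c("Amax", "gs", "E")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop(sprintf("missing columns: %s", paste(miss, collapse = ", ")))
  ratio <- function(num, den, nm) {
    zero <- !is.na(den) & den == 0
    if (any(zero)) {
      warning(sprintf("%s undefined for %d leaf/leaves with zero denominator; set missing",
                      nm, sum(zero)))
      den[zero] <- NA_real_
    }
    num / den
  }
  if (overwrite || !"WUE_intr" %in% names(table)) {
    table$WUE_intr <- ratio(table$Amax, table$gs, "WUE_intr")
  }
  if (overwrite || !"WUE_inst" %in% names(table)) {
    table$WUE_inst <- ratio(table$Amax, table$E, "WUE_inst")
  }
  table
}

#' Derive leaf morphology traits from mass and area
#'
#' `LMA = dry mass (g) / area (m^2)` and
#' `LDMC = dry mass (mg) / saturated fresh mass (g)`.
#'
#' @param dry_mass_g leaf dry mass, g.
#' @param fresh_mass_g leaf saturated (fresh) mass, g.
#' @param area_cm2 leaf area, cm^2.
#' @return data.frame with columns `LMA` (g m-2) and `LDMC` (mg g-1).
#' @examples
#' derive_morphology(1.4, 5, 200)  # LMA 70 g m-2, LDMC 280 mg g-1
#' @export
derive_morphology <- function(dry_mass_g, fresh_mass_g, area_cm2) {
  n <- max(length(dry_mass_g), length(fresh_mass_g), length(area_cm2))
  dry_mass_g <- rep_len(dry_mass_g, n)
  fresh_mass_g <- rep_len(fresh_mass_g, n)
  area_cm2 <- rep_len(area_cm2, n)
  ok <- !is.na(dry_mass_g) & !is.na(fresh_mass_g) & !is.na(area_cm2)
  if (any(ok & (dry_mass_g <= 0 | fresh_mass_g <= 0 | area_cm2 <= 0))) {
    stop("masses and area must be positive")
  }
  if (any(ok & dry_mass_g > fresh_mass_g)) {
    stop("dry mass exceeds fresh mass")
  }
  data.frame(LMA = dry_mass_g / (area_cm2 * 1e-4),
             LDMC = dry_mass_g * 1000 / fresh_mass_g)
}

#' Summary statistics for one trait
#'
#' Mean, SD, median, MAD, range, coefficient of variation and a Shapiro-Wilk
#' normality test.  The MAD is reported unscaled (median absolute deviation
#' from the median, no 1.4826 consistency factor); set `mad_constant` for the
#' scaled convention.  CV uses the absolute mean so that negative-valued
#' traits (water potential, d13C) get a positive percentage.
#'
#' @param values numeric vector; missing values dropped.
#' @param mad_constant multiplier for the MAD (1 = unscaled; 1.4826 for
#'   normal-consistent).
#' @return one-row data.frame: `n`, `mean`, `sd`, `median`, `mad`, `min`,
#'   `max`, `cv` (%), `shapiro_w`, `shapiro_p` (Shapiro-Wilk requires
#'   3 <= n <= 5000 and non-constant values; otherwise NA).
#' @export
summarize_trait <- function(values, mad_constant = 1) {
  v <- values[!is.na(values)]
  if (length(v) == 0) stop("all values missing")
  m <- mean(v)
  s <- if (length(v) >= 2) stats::sd(v) else NA_real_
  med <- stats::median(v)
  sw_w <- sw_p <- NA_real_
  if (length(v) >= 3 && length(v) <= 5000 && isTRUE(s > 0)) {
    sw <- stats::shapiro.test(v)
    sw_w <- unname(sw$statistic)
    sw_p <- sw$p.value
  }
  data.frame(
    n = length(v), mean = m, sd = s, median = med,
    mad = stats::median(abs(v - med)) * mad_constant,
    min = min(v), max = max(v),
    cv = if (m != 0) 100 * s / abs(m) else NA_real_,
    shapiro_w = sw_w, shapiro_p = sw_p
  )
}

#' Summary statistics for every trait column
#'
#' @param table leaf trait table.
#' @param traits trait column names (default: all numeric non-metadata
#'   columns).
#' @param ... passed to [summarize_trait()].
#' @return data.frame, one row per trait, with a leading `trait` column.
#' @export
summarize_traits <- function(table, traits = trait_columns(table), ...) {
  out <- do.call(rbind, lapply(traits, function(tr) {
    cbind(trait = tr, summarize_trait(table[[tr]], ...))
  }))
  rownames(out) <- NULL
  out
}

.metadata_columns <- c("leaf_id", "cultivar", "variety", "origin", "colour",
                       "row", "vine")

#' Trait columns of a leaf table
#'
#' All numeric columns that are not sampling metadata (`leaf_id`, `cultivar`,
#' `variety`, `origin`, `colour`, `row`, `vine`).
#' @param table leaf trait table.
#' @export
trait_columns <- function(table) {
  cand <- setdiff(names(table), .metadata_columns)
  cand[vapply(table[cand], is.numeric, logical(1))]
}

#' Interquartile-range outlier mask
#'
#' Flags values outside `[Q1 - factor * IQR, Q3 + factor * IQR]` with
#' quartiles by the linear-interpolation (type 7) convention.  The default
#' factor of 2 is the looser fence appropriate for traits with moderate to
#' low variability; only individual cells are masked, never whole leaves.
#'
#' @param values numeric vector (NAs pass through as `NA` in the mask).
#' @param factor fence multiplier, > 0 (may be `Inf`).
#' @return logical vector, `TRUE` = keep, `FALSE` = outlier, `NA` where the
#'   input is missing.
#' @export
iqr_outlier_filter <- function(values, factor = 2) {
  stopifnot(factor > 0)
  obs <- values[!is.na(values)]
  if (length(obs) < 4) stop("need at least 4 non-missing values for IQR fences")
  q <- stats::quantile(obs, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - factor * iqr
  hi <- q[2] + factor * iqr
  if (is.infinite(factor)) {
    lo <- -Inf
    hi <- Inf
  }
  ifelse(is.na(values), NA, values >= lo & values <= hi)
}

#' Mask outlying trait cells in a table
#'
#' Applies [iqr_outlier_filter()] per trait column, setting flagged cells to
#' `NA`.  The per-trait removal tally is attached as attribute
#' `"outlier_counts"`.
#'
#' @param table leaf trait table.
#' @param traits columns to screen.
#' @param factor fence multiplier.
#' @return the table with outliers blanked.
#' @export
mask_outliers <- function(table, traits = trait_columns(table), factor = 2) {
  counts <- stats::setNames(integer(length(traits)), traits)
  for (tr in traits) {
    keep <- iqr_outlier_filter(table[[tr]], factor = factor)
    drop <- !is.na(keep) & !keep
    counts[tr] <- sum(drop)
    table[[tr]][drop] <- NA_real_
  }
  attr(table, "outlier_counts") <- counts
  table
}

#' Default trait transform registry
#'
#' Which traits enter the models log-transformed.  Normality screening of the
#' reference campaign supports a natural-log transform for the strongly
#' right-skewed traits `WUE_inst`, `WUE_intr`, `Area`, `LDMC` and `LMA`;
#' everything else stays on the raw scale.
#' @return named character vector mapping trait -> `"identity"` or `"log"`.
#' @export
default_transform_registry <- function() {
  c(E = "identity", Amax = "identity", gs = "identity", N = "identity",
    C = "identity", d13C = "identity", Psi_pd = "identity",
    WUE_intr = "log", WUE_inst = "log", Area = "log", LDMC = "log",
    LMA = "log")
}

#' Apply a transform registry to a trait table
#'
#' Log transforms use the natural log; log-transformed columns are renamed
#' with a `"log-"` prefix.  Non-positive values cannot be logged and become
#' missing with a warning.  Traits absent from the registry are left alone.
#'
#' @param table leaf trait table.
#' @param registry named character vector trait -> `"identity"` | `"log"`,
#'   default [default_transform_registry()].
#' @return the transformed table.
#' @export
apply_transforms <- function(table, registry = default_transform_registry()) {
  bad <- setdiff(unname(registry), c("identity", "log"))
  if (length(bad)) stop(sprintf("unknown transform(s): %s", paste(bad, collapse = ", ")))
  for (tr in intersect(names(registry), names(table))) {
    if (registry[[tr]] == "log") {
      v <- table[[tr]]
      nonpos <- !is.na(v) & v <= 0
      if (any(nonpos)) {
        warning(sprintf("log of non-positive value(s) in '%s': %d cell(s) set missing",
                        tr, sum(nonpos)))
        v[nonpos] <- NA_real_
      }
      table[[tr]] <- log(v)
      names(table)[names(table) == tr] <- paste0("log-", tr)
    }
  }
  table
}

#' Packaged published reference tables
#'
#' `reference_trait_stats()` returns published descriptive statistics and
#' hierarchical variance proportions for 12 leaf traits measured on 178
#' grapevine leaves across 12 cultivars; `reference_plsr_results()` returns
#' the matching published PLSR validation results per trait and data-splitting
#' strategy.  These printed values seed the simulator defaults and feed the
#' cross-table correlation of trait variability with model skill
#' ([correlate_r2_cv()]).
#' @return data.frame.
#' @export
reference_trait_stats <- function() {
  utils::read.csv(system.file("extdata", "reference_trait_stats.csv",
                              package = "vitispec"), stringsAsFactors = FALSE)
}

#' @rdname reference_trait_stats
#' @export
reference_plsr_results <- function() {
  utils::read.csv(system.file("extdata", "reference_plsr_results.csv",
                              package = "vitispec"), stringsAsFactors = FALSE)
}
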