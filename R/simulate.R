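#' Simulation configuration for the synthetic vineyard
#'
#' Builds the configuration driving [generate_traits()] and
#' [generate_spectra()].  Defaults emulate the sampling design of a
#' single-farm cultivar trial: 12 cultivars belonging to 7 varieties (each
#' variety one colour and one origin class), 3 planting rows x 5 vines per
#' cultivar, one leaf per vine (180 leaves before missingness), trait means
#' and dispersions seeded from published descriptive statistics for grapevine
#' leaves, and hierarchical variance proportions per trait (origin, red/white,
#' cultivar, row, residual).
#'
#' Each trait is simulated as
#' `mean + origin + colour + cultivar + row + leaf`, every effect drawn once
#' per grouping unit from a zero-mean normal whose variance is the configured
#' proportion of `total_sd^2`.  Spectra are a fixed smooth leaf baseline
#' modulated by Gaussian absorption features whose depth tracks the z-score
#' of a linked trait (see [spectral_link()]), plus white noise.
#'
#' @param n_cultivars,n_varieties,rows_per_cultivar,vines_per_row design
#'   counts; `n_varieties <= n_cultivars`.
#' @param trait_specs named list; each element a list with `mean`, `total_sd`
#'   and `proportions` (named numeric with any of `origin`, `red_white`,
#'   `cultivar`, `row`; shortfall from 1 is the leaf-level residual).
#'   Default: [default_trait_specs()].
#' @param missing_rate probability that a single trait cell is missing
#'   (missing completely at random, independently per trait, so per-trait
#'   sample sizes differ as in real campaigns).
#' @param spectral_noise_sd sd of additive reflectance noise per band.
#' @param nuisance list of leaf-level trait-independent spectral variation
#'   sds: `amplitude_sd` (multiplicative scattering amplitude),
#'   `water_sd` (optical depth on the 1450/1940 nm water bands) and
#'   `tilt_sd` (smooth spectral slope).  These emulate structural and
#'   hydration differences between leaves that carry no trait signal; they,
#'   not the per-band noise, are what bound achievable retrieval skill,
#'   because independent band noise averages out over 2001 bands.  Set all
#'   to 0 for an idealized forward model.
#' @param link_specs list of [spectral_link()] objects.  Default:
#'   [default_spectral_links()], which deliberately leaves `d13C` without an
#'   absorption feature so that spectra carry no signal for it.
#' @param seed integer RNG seed used by the generators.
#' @return object of class `"sim_config"`.
#' @export
sim_config <- function(n_cultivars = 12, n_varieties = 7,
                       rows_per_cultivar = 3, vines_per_row = 5,
                       trait_specs = default_trait_specs(),
                       missing_rate = 0.03,
                       spectral_noise_sd = 0.004,
                       nuisance = list(amplitude_sd = 0.05, water_sd = 0.05,
                                       tilt_sd = 0.03),
                       link_specs = default_spectral_links(),
                       seed = 1L) {
  stopifnot(n_cultivars >= 1, n_varieties >= 1, n_varieties <= n_cultivars,
            rows_per_cultivar >= 1, vines_per_row >= 1,
            missing_rate >= 0, missing_rate < 1, spectral_noise_sd >= 0)
  levels_ok <- c("origin", "red_white", "cultivar", "row")
  for (tr in names(trait_specs)) {
    sp <- trait_specs[[tr]]
    if (!all(c("mean", "total_sd") %in% names(sp))) {
      stop(sprintf("trait_specs[['%s']] needs 'mean' and 'total_sd'", tr))
    }
    pr <- sp$proportions
    if (is.null(pr)) pr <- numeric(0)
    if (length(pr) && (is.null(names(pr)) || !all(names(pr) %in% levels_ok))) {
      stop(sprintf("trait_specs[['%s']]: proportions must be named among %s",
                   tr, paste(levels_ok, collapse = ", ")))
    }
    if (any(pr < 0)) stop(sprintf("trait_specs[['%s']]: negative proportion", tr))
    if (sum(pr) > 1 + 1e-9) {
      stop(sprintf("trait_specs[['%s']]: variance proportions sum to %.3f > 1",
                   tr, sum(pr)))
    }
  }
  for (lk in link_specs) {
    if (!inherits(lk, "spectral_link")) stop("link_specs must be spectral_link objects")
  }
  structure(list(
    n_cultivars = as.integer(n_cultivars), n_varieties = as.integer(n_varieties),
    rows_per_cultivar = as.integer(rows_per_cultivar),
    vines_per_row = as.integer(vines_per_row),
    trait_specs = trait_specs, missing_rate = missing_rate,
    spectral_noise_sd = spectral_noise_sd,
    nuisance = utils::modifyList(list(amplitude_sd = 0, water_sd = 0, tilt_sd = 0),
                                 as.list(nuisance)),
    link_specs = link_specs,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d cultivars / %d varieties, %d rows x %d vines ",
                     "(%d leaves), %d traits, %d spectral links, seed %d\n"),
              x$n_cultivars, x$n_varieties, x$rows_per_cultivar, x$vines_per_row,
              x$n_cultivars * x$rows_per_cultivar * x$vines_per_row,
              length(x$trait_specs), length(x$link_specs), x$seed))
  invisible(x)
}

#' A trait-to-spectrum absorption link
#'
#' Forward-model element tying one trait to the spectra: a Gaussian absorption
#' feature at `center_wavelength` whose optical depth is
#' `strength * z(trait)`, with `z` the trait z-score across leaves.
#'
#' @param trait_id trait column name.
#' @param center_wavelength nm, within 400-2400.
#' @param width Gaussian sd, nm, > 0.
#' @param strength absorbance units per trait z-score (may be negative).
#' @export
spectral_link <- function(trait_id, center_wavelength, width, strength) {
  stopifnot(center_wavelength >= 400, center_wavelength <= 2400, width > 0)
  structure(list(trait_id = trait_id, center_wavelength = center_wavelength,
                 width = width, strength = strength),
            class = "spectral_link")
}

#' Default per-trait simulation parameters
#'
#' Means, total standard deviations and hierarchical variance proportions for
#' the 12 leaf traits handled by the package (gas exchange: E, Amax, gs;
#' chemistry: N, C, d13C; water relations: Psi_pd, WUE_intr, WUE_inst;
#' morphology: Area, LDMC, LMA).  Values are read from the packaged YAML file
#' `extdata/default_sim.yaml`, which encodes published descriptive statistics
#' for field-grown grapevine leaves (n = 178 across 12 cultivars): for traits
#' summarized by median and coefficient of variation the simulator seeds the
#' mean with the median and the sd with CV x median / 100.
#'
#' @param path optional alternative YAML file with the same structure.
#' @return named list of trait specs as consumed by [sim_config()].
#' @export
default_trait_specs <- function(path = system.file("extdata", "default_sim.yaml",
                                                   package = "vitispec")) {
  cfg <- yaml::read_yaml(path)
  lapply(cfg$traits, function(sp) {
    list(mean = sp$mean, total_sd = sp$total_sd,
         proportions = unlist(sp$proportions))
  })
}

#' Default trait-to-spectrum links
#'
#' Absorption features placed in the windows where each trait plausibly
#' expresses optically: chlorophyll-linked traits on the red edge, water
#' status on the 1450/1940 nm water bands, dry-matter traits in the SWIR.
#' `d13C` is intentionally absent: an isotopic signature has no direct
#' optical expression, so spectra carry no retrievable signal for it and the
#' modelling protocol should report a component count of zero.
#'
#' @param path optional alternative YAML file (`links:` section).
#' @return list of [spectral_link()] objects.
#' @export
default_spectral_links <- function(path = system.file("extdata", "default_sim.yaml",
                                                      package = "vitispec")) {
  cfg <- yaml::read_yaml(path)
  lapply(cfg$links, function(lk) {
    spectral_link(lk$trait_id, lk$center_wavelength, lk$width, lk$strength)
  })
}

# Variety roster emulating a single-farm cultivar trial.  Colour is fixed per
# variety; origin (warm/cool growing region of the variety's provenance) is an
# arbitrary binary label at variety level.
.default_varieties <- data.frame(
  variety = c("CabernetFranc", "CabernetSauvignon", "Merlot", "PinotNoir",
              "Riesling", "SauvignonBlanc", "Viognier"),
  colour = c("red", "red", "red", "red", "white", "white", "white"),
  origin = c("cool", "warm", "warm", "cool", "cool", "cool", "warm"),
  stringsAsFactors = FALSE
)

.cultivar_roster <- function(n_cultivars, n_varieties) {
  if (n_cultivars == 12 && n_varieties == 7) {
    data.frame(
      cultivar = c("CF314", "CF327", "CS29", "CS412", "M181", "M348",
                   "PN828", "PN89", "R171", "R23", "SB906", "V642"),
      variety = .default_varieties$variety[c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 6, 7)],
      stringsAsFactors = FALSE
    )
  } else {
    variety <- paste0("variety_", sprintf("%02d", rep_len(seq_len(n_varieties), n_cultivars)))
    data.frame(cultivar = sprintf("cv_%02d", seq_len(n_cultivars)),
               variety = sort(variety), stringsAsFactors = FALSE)
  }
}

.variety_meta <- function(varieties) {
  known <- match(varieties, .default_varieties$variety)
  if (!anyNA(known)) {
    data.frame(variety = varieties,
               colour = .default_varieties$colour[known],
               origin = .default_varieties$origin[known],
               stringsAsFactors = FALSE)
  } else {
    k <- length(varieties)
    data.frame(variety = varieties,
               colour = rep_len(c("red", "white"), k),
               origin = rep_len(c("warm", "warm", "cool", "cool"), k),
               stringsAsFactors = FALSE)
  }
}

#' Generate a cultivar-structured leaf trait table
#'
#' Simulates one leaf per vine across the configured design.  For each trait,
#' the value is `mean + origin effect + colour effect + cultivar effect + row
#' effect + leaf residual`; each effect is drawn once per grouping unit from a
#' zero-mean normal with variance `proportion * total_sd^2` (rows are coded
#' unique within cultivar, colour within origin, matching a strictly nested
#' hierarchy).  Trait cells are then blanked completely at random at
#' `missing_rate`.
#'
#' The complete (pre-missingness) values are kept in the attribute
#' `"complete"` so that spectra can be simulated from the latent truth.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `leaf_id`, `cultivar`, `variety`, `origin`,
#'   `colour`, `row`, `vine` and one column per trait.
#' @export
generate_traits <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  roster <- .cultivar_roster(config$n_cultivars, config$n_varieties)
  vmeta <- .variety_meta(unique(roster$variety))
  roster <- merge(roster, vmeta, by = "variety", sort = FALSE)

  grid <- expand.grid(vine = seq_len(config$vines_per_row),
                      row = seq_len(config$rows_per_cultivar),
                      cultivar = roster$cultivar,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$cultivar, roster$cultivar), grid$row, grid$vine), ]
  meta <- roster[match(grid$cultivar, roster$cultivar), ]
  df <- data.frame(
    leaf_id = sprintf("leaf_%03d", seq_len(nrow(grid))),
    cultivar = grid$cultivar, variety = meta$variety,
    origin = meta$origin, colour = meta$colour,
    row = paste0("R", grid$row), vine = grid$vine,
    stringsAsFactors = FALSE
  )
  n <- nrow(df)
  # unit codings for the nested hierarchy
  u_origin <- df$origin
  u_colour <- paste(df$origin, df$colour, sep = ":")
  u_cult <- df$cultivar
  u_row <- paste(df$cultivar, df$row, sep = ":")

  complete <- df
  for (tr in names(config$trait_specs)) {
    sp <- config$trait_specs[[tr]]
    pr <- c(origin = 0, red_white = 0, cultivar = 0, row = 0)
    pr[names(sp$proportions)] <- sp$proportions
    p_res <- max(0, 1 - sum(pr))
    draw <- function(units, prop) {
      lev <- unique(units)
      eff <- stats::rnorm(length(lev), 0, sqrt(prop) * sp$total_sd)
      eff[match(units, lev)]
    }
    val <- sp$mean +
      draw(u_origin, pr[["origin"]]) +
      draw(u_colour, pr[["red_white"]]) +
      draw(u_cult, pr[["cultivar"]]) +
      draw(u_row, pr[["row"]]) +
      stats::rnorm(n, 0, sqrt(p_res) * sp$total_sd)
    complete[[tr]] <- val
    obs <- val
    if (config$missing_rate > 0) {
      obs[stats::runif(n) < config$missing_rate] <- NA_real_
    }
    df[[tr]] <- obs
  }
  attr(df, "complete") <- complete
  df
}

#' Smooth leaf reflectance baseline template
#'
#' Reads the packaged 2001-point baseline spectrum (400-2400 nm at 1 nm):
#' low visible reflectance with a green peak, a red-edge rise to the NIR
#' plateau, and water absorption dips near 1450 and 1940 nm with a declining
#' SWIR tail.  The template is a synthetic construction produced by
#' [make_baseline_template()]; it is shaped like a healthy leaf spectrum but
#' is not a measurement.
#'
#' @param wavelengths grid to interpolate the template onto (nm).
#' @return numeric reflectance vector on `wavelengths`.
#' @export
baseline_reflectance <- function(wavelengths = 400:2400) {
  path <- system.file("extdata", "baseline_template.csv", package = "vitispec")
  tpl <- utils::read.csv(path)
  stats::approx(tpl$wavelength_nm, tpl$reflectance, xout = wavelengths,
                rule = 2)$y
}

#' Construct the synthetic baseline template analytically
#'
#' Parametric recipe behind the packaged template: a logistic red edge between
#' a pigment-absorbing visible region (with a Gaussian green peak at 550 nm)
#' and a NIR plateau, multiplied by Gaussian water/dry-matter absorptions at
#' 970, 1200, 1450, 1940 and 2300 nm.  Exists so the packaged CSV is fully
#' reproducible from code.
#'
#' @param wavelengths grid, nm.
#' @return numeric reflectance vector.
#' @export
make_baseline_template <- function(wavelengths = 400:2400) {
  wl <- wavelengths
  g <- function(c, s) exp(-((wl - c)^2) / (2 * s^2))
  edge <- stats::plogis((wl - 715) / 16)
  vis <- 0.05 + 0.10 * g(550, 40)
  r0 <- vis * (1 - edge) + 0.48 * edge
  absorb <- 1 - 0.10 * g(970, 30) - 0.16 * g(1200, 45) -
    0.55 * g(1450, 55) - 0.72 * g(1940, 85) - 0.38 * g(2300, 160)
  pmin(pmax(r0 * absorb, 0.01), 1)
}

#' Generate trait-linked reflectance spectra
#'
#' Per leaf: `reflectance(lambda) = baseline(lambda) *
#' exp(-sum_links strength * z(trait) * gaussian(lambda; center, width)) +
#' noise`, clipped to [0, 1], on the 400-2400 nm grid at 1 nm.  Trait
#' z-scores use the latent complete values stored by [generate_traits()] when
#' available (missingness should not silently erase optical signal); a leaf
#' whose trait is genuinely absent contributes z = 0.
#'
#' @param traits trait table from [generate_traits()].
#' @param config the same [sim_config()].
#' @return a [spectra_set()].
#' @export
generate_spectra <- function(traits, config) {
  stopifnot(inherits(config, "sim_config"))
  complete <- attr(traits, "complete")
  src <- if (!is.null(complete)) complete else traits
  for (lk in config$link_specs) {
    if (!lk$trait_id %in% names(src)) {
      stop(sprintf("spectral link references unknown trait '%s'", lk$trait_id))
    }
  }
  set.seed(config$seed + 1L)
  wl <- 400:2400
  base <- baseline_reflectance(wl)
  n <- nrow(src)
  od <- matrix(0, n, length(wl))  # optical depth per leaf x band
  for (lk in config$link_specs) {
    v <- src[[lk$trait_id]]
    mu <- mean(v, na.rm = TRUE)
    sd_v <- stats::sd(v, na.rm = TRUE)
    z <- if (is.na(sd_v) || sd_v == 0) rep(0, n) else (v - mu) / sd_v
    z[is.na(z)] <- 0
    shape <- exp(-((wl - lk$center_wavelength)^2) / (2 * lk$width^2))
    od <- od + (lk$strength * z) %o% shape
  }
  nu <- config$nuisance
  if (nu$water_sd > 0) {
    wshape <- exp(-((wl - 1450)^2) / (2 * 60^2)) + exp(-((wl - 1940)^2) / (2 * 80^2))
    od <- od + stats::rnorm(n, 0, nu$water_sd) %o% wshape
  }
  refl <- sweep(exp(-od), 2, base, "*")
  if (nu$amplitude_sd > 0) {
    refl <- refl * (1 + stats::rnorm(n, 0, nu$amplitude_sd))
  }
  if (nu$tilt_sd > 0) {
    refl <- refl * (1 + stats::rnorm(n, 0, nu$tilt_sd) %o% ((wl - 1400) / 1000))
  }
  if (config$spectral_noise_sd > 0) {
    refl <- refl + matrix(stats::rnorm(length(refl), 0, config$spectral_noise_sd),
                          nrow = n)
  }
  refl <- pmin(pmax(refl, 0), 1)
  spectra_set(wl, refl, traits$leaf_id)
}

#' Simulate a complete synthetic vineyard data set
#'
#' Convenience wrapper running [generate_traits()] then [generate_spectra()].
#' @param config a [sim_config()].
#' @return list with elements `traits` (data.frame) and `spectra`
#'   ([spectra_set()]).
#' @export
simulate_vineyard <- function(config = sim_config()) {
  traits <- generate_traits(config)
  spectra <- generate_spectra(traits, config)
  list(traits = traits, spectra = spectra)
}
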