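test_that("the design produces the configured leaf count and metadata", {
  cfg <- sim_config(seed = 5)
  tab <- generate_traits(cfg)
  expect_equal(nrow(tab), 12 * 3 * 5)
  expect_equal(length(unique(tab$cultivar)), 12)
  expect_equal(length(unique(tab$variety)), 7)
  expect_setequal(unique(tab$colour), c("red", "white"))
  # each variety maps to one colour and one origin
  per_var <- tapply(paste(tab$colour, tab$origin), tab$variety,
                    function(x) length(unique(x)))
  expect_true(all(per_var == 1))
  # every cultivar has rows_per_cultivar x vines_per_row leaves
  expect_true(all(table(tab$cultivar) == 15))
})

test_that("generation is bit-reproducible under a fixed seed", {
  cfg <- sim_config(seed = 99, missing_rate = 0.05)
  s1 <- simulate_vineyard(cfg)
  s2 <- simulate_vineyard(cfg)
  expect_identical(s1$traits, s2$traits)
  expect_identical(s1$spectra$reflectance, s2$spectra$reflectance)
})

test_that("degenerate variance configurations behave as specified", {
  # all cultivar: every leaf of a cultivar identical
  cfg <- sim_config(
    trait_specs = list(t1 = list(mean = 10, total_sd = 2,
                                 proportions = c(cultivar = 1))),
    link_specs = list(), missing_rate = 0, seed = 3)
  tab <- generate_traits(cfg)
  spread <- tapply(tab$t1, tab$cultivar, function(v) diff(range(v)))
  expect_true(all(spread == 0))
  # proportions > 1 rejected
  expect_error(
    sim_config(trait_specs = list(t1 = list(mean = 0, total_sd = 1,
                                            proportions = c(cultivar = 0.7,
                                                            row = 0.5)))),
    "sum")
  expect_error(
    sim_config(trait_specs = list(t1 = list(mean = 0, total_sd = 1,
                                            proportions = c(bogus = 0.5)))),
    "named")
})

test_that("pure-residual traits show no systematic cultivar signal", {
  cfg <- sim_config(
    trait_specs = list(t1 = list(mean = 0, total_sd = 1, proportions = NULL)),
    link_specs = list(), missing_rate = 0, seed = 21)
  tab <- generate_traits(cfg)
  # between-cultivar variance of cultivar means ~ total_sd^2 / n_per_cultivar
  vm <- var(tapply(tab$t1, tab$cultivar, mean))
  expect_lt(vm, 4 * 1 / 15)  # well below any systematic effect
  vc <- fit_variance_components(tab, "t1", nesting = "cultivar")
  expect_lte(vc$proportion[vc$level == "cultivar"], 0.05)
})

test_that("method-of-moments recovery of a configured cultivar share", {
  # 200 replicates, cultivar 0.5 / residual 0.5: mean EMS estimate within 0.05
  set.seed(123)
  est <- replicate(200, {
    tab <- toy_leaf_table(k = 12, m = 15, cult_sd = sqrt(0.5),
                          resid_sd = sqrt(0.5), seed = sample.int(1e6, 1))
    ms <- anova(lm(y ~ cultivar, data = tab))$`Mean Sq`
    max((ms[1] - ms[2]) / 15, 0)
  })
  expect_lt(abs(mean(est) - 0.5), 0.05)
})

test_that("empirical variance proportions converge to the configuration", {
  set.seed(31)
  props <- replicate(50, {
    cfg <- sim_config(
      trait_specs = list(t1 = list(mean = 5, total_sd = 1,
                                   proportions = c(cultivar = 0.6))),
      link_specs = list(), missing_rate = 0, seed = sample.int(1e6, 1))
    tab <- generate_traits(cfg)
    vc <- fit_variance_components(tab, "t1", nesting = "cultivar")
    vc$proportion[vc$level == "cultivar"]
  })
  expect_lt(abs(mean(props) - 0.6), 0.1)
})

test_that("spectra respect physical bounds and the configured grid", {
  sim <- simulate_vineyard(sim_config(seed = 11))
  expect_true(all(sim$spectra$reflectance >= 0 & sim$spectra$reflectance <= 1))
  expect_equal(sim$spectra$wavelengths, 400:2400)
  expect_equal(sim$spectra$leaf_ids, sim$traits$leaf_id)
})

test_that("zero-strength links leave every leaf on the shared baseline", {
  cfg <- single_link_config(strength = 0)
  sim <- simulate_vineyard(cfg)
  expect_lt(max(apply(sim$spectra$reflectance, 2, function(col) diff(range(col)))),
            1e-12)
  expect_equal(unname(sim$spectra$reflectance[1, ]),
               baseline_reflectance(400:2400), tolerance = 1e-9)
})

test_that("a link to an unknown trait is rejected", {
  cfg <- single_link_config()
  tab <- generate_traits(cfg)
  cfg$link_specs <- list(spectral_link("nope", 700, 30, 0.1))
  expect_error(generate_spectra(tab, cfg), "unknown trait 'nope'")
})

test_that("noiseless single-link retrieval is near perfect with one component", {
  cfg <- single_link_config(seed = 6)
  sim <- simulate_vineyard(cfg)
  keep <- !is.na(sim$traits$N)
  x <- sim$spectra$reflectance
  fit <- plsr(x, sim$traits$N, ncomp = 1)
  m <- evaluate(sim$traits$N, predict(fit, x))
  expect_gte(m$r2, 0.99)
})

test_that("heavier band noise degrades validation skill", {
  r2_at <- function(noise) {
    sim <- simulate_vineyard(single_link_config(noise = noise, seed = 17))
    fit <- fit_trait_model(sim$spectra, sim$traits, "N",
                           split_spec("random", seed = 4),
                           a_max_cap = 4, jackknife = FALSE)
    fit$metrics$r2
  }
  expect_gt(r2_at(0.002), r2_at(0.02))
})
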