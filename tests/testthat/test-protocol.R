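test_that("random splits use the floor-0.8 rule and partition the ids", {
  for (n in c(173, 172, 163, 160, 23)) {
    tab <- data.frame(leaf_id = sprintf("id_%03d", seq_len(n)))
    sp <- split_data(tab, split_spec("random", seed = 2))
    expect_equal(length(sp$calibration), floor(0.8 * n))
    expect_equal(length(sp$validation), n - floor(0.8 * n))
    expect_setequal(c(sp$calibration, sp$validation), tab$leaf_id)
    expect_length(intersect(sp$calibration, sp$validation), 0)
  }
})

test_that("group-balanced splits reserve ceil(0.2 * n_k) per cultivar", {
  sizes <- c(15, 15, 15, 15, 15, 15, 14, 14, 14, 14, 14, 13)  # sums to 173
  tab <- data.frame(
    leaf_id = sprintf("id_%03d", seq_len(sum(sizes))),
    cultivar = rep(sprintf("cv_%02d", seq_along(sizes)), times = sizes))
  sp <- split_data(tab, split_spec("group_balanced", group = "cultivar", seed = 3))
  expect_equal(length(sp$validation), 36)  # 12 groups x 3
  per_group <- table(tab$cultivar[tab$leaf_id %in% sp$validation])
  expect_true(all(per_group == 3))
  expect_setequal(c(sp$calibration, sp$validation), tab$leaf_id)
  # every group keeps at least one validation member
  expect_equal(length(per_group), 12L)
})

test_that("a singleton group is refused by name", {
  tab <- data.frame(leaf_id = sprintf("id_%02d", 1:11),
                    cultivar = c(rep("big", 10), "lonely"))
  expect_error(split_data(tab, split_spec("group_balanced", group = "cultivar")),
               "lonely")
  expect_error(split_data(tab[1:5, ], split_spec("random")), "at least 10")
  expect_error(split_spec("group_balanced"), "group")
  expect_error(split_spec("random", fraction = 1.2))
})

test_that("component selection takes the PRESS argmin, ties to fewer, 0 = failure", {
  s <- select_components(c(5, 3, 4))
  expect_equal(s$selected, 1L)
  expect_false(s$failed)
  s0 <- select_components(c(3, 3, 4))
  expect_equal(s0$selected, 0L)
  expect_true(s0$failed)
  expect_equal(select_components(c(9))$selected, 0L)
})

test_that("LOO PRESS equals a brute-force refit loop", {
  for (seed in 1:20) {
    pr <- rand_problem(10, 6, seed + 200)
    cv <- loo_press(pr$x, pr$y, a_max = 3)
    brute <- sapply(0:3, function(a) {
      sum(sapply(seq_len(10), function(i) {
        if (a == 0) return((pr$y[i] - mean(pr$y[-i]))^2)
        f <- plsr(pr$x[-i, , drop = FALSE], pr$y[-i], ncomp = a)
        (pr$y[i] - predict(f, pr$x[i, , drop = FALSE], ncomp = a))^2
      }))
    })
    expect_equal(unname(cv$press), brute, tolerance = 1e-10)
    expect_equal(cv$selected, which.min(brute) - 1L)
  }
})

test_that("n_cal too small for the component search is an error", {
  pr <- rand_problem(5, 6, 1)
  expect_error(loo_press(pr$x, pr$y, a_max = 4), "too small")
})

test_that("validation metrics match hand-computed cases, negatives included", {
  perfect <- evaluate(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$pct_rmse, 0)
  m <- evaluate(c(1, 2, 3), c(2, 2, 2))
  expect_equal(m$r2, 0)
  expect_equal(m$rmse, sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(m$pct_rmse, 100 * sqrt(2 / 3) / 2, tolerance = 1e-9)
  neg <- evaluate(c(1, 2, 3), c(3, 1, 2))
  expect_equal(neg$r2, -2)
  expect_warning(evaluate(c(2, 2, 2), c(1, 2, 3)), "constant")
})

test_that("jackknife intervals collapse on noiseless rank-1 data", {
  set.seed(12)
  x <- matrix(rnorm(60 * 20), 60, 20)
  beta <- rnorm(20)
  beta <- beta / sqrt(sum(beta^2))
  x <- (x %*% beta) %*% t(beta)  # rank 1
  y <- as.numeric(x %*% beta)
  jk <- jackknife_uncertainty(x[1:40, ], y[1:40], ncomp = 1,
                              x_val = x[41:60, ], B = 120, seed = 9)
  width <- jk$intervals$ci_upper - jk$intervals$ci_lower
  expect_lt(max(width), 1e-6)
  expect_lt(jk$sigma_resid, 1e-6)
})

test_that("delete-one jackknife runs and B * leave_frac is validated", {
  pr <- rand_problem(25, 10, 301)
  jk <- jackknife_uncertainty(pr$x[1:20, ], pr$y[1:20], ncomp = 2,
                              x_val = pr$x[21:25, ], mode = "delete_one")
  expect_equal(jk$B, 20)
  expect_true(all(jk$intervals$pi_lower <= jk$intervals$ci_lower))
  expect_error(jackknife_uncertainty(pr$x[1:20, ], pr$y[1:20], ncomp = 1,
                                     x_val = pr$x[21:25, ], B = 2,
                                     leave_frac = 0.1),
               "leave_frac")
})

test_that("prediction intervals achieve near-nominal coverage on simulated leaves", {
  set.seed(44)
  cover <- replicate(8, {
    cfg <- single_link_config(noise = 0.004, seed = sample.int(1e6, 1),
                              nuisance = list(amplitude_sd = 0.02,
                                              water_sd = 0.02, tilt_sd = 0.01))
    sim <- simulate_vineyard(cfg)
    ids <- split_data(sim$traits, split_spec("random", seed = 1))
    x <- sim$spectra$reflectance
    rownames(x) <- sim$traits$leaf_id
    y <- setNames(sim$traits$N, sim$traits$leaf_id)
    jk <- jackknife_uncertainty(x[ids$calibration, ], y[ids$calibration],
                                ncomp = 2, x_val = x[ids$validation, ],
                                B = 100, seed = 2)
    yv <- y[ids$validation]
    mean(yv >= jk$intervals$pi_lower & yv <= jk$intervals$pi_upper)
  })
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 1.00)
})

test_that("VIP region summaries aggregate per window and omit empty regions", {
  wl <- 400:2400
  flat <- rep(1, length(wl))
  s <- vip_region_summary(flat, wl)
  expect_setequal(s$region, c("VIS", "RED_EDGE", "NIR", "SWIR1", "SWIR2"))
  expect_true(all(s$mean_vip == 1))
  expect_true(all(s$frac_ge_0.8 == 1))
  # VIS-only grid: other regions omitted
  s2 <- vip_region_summary(rep(1, 101), 400:500)
  expect_setequal(s2$region, "VIS")
})

test_that("a spectral link on the red edge puts the VIP maximum there", {
  cfg <- single_link_config(strength = 0.08, noise = 0.002, seed = 23)
  cfg$link_specs <- list(spectral_link("N", 700, 20, 0.08))
  sim <- simulate_vineyard(cfg)
  fit <- fit_trait_model(sim$spectra, sim$traits, "N",
                         split_spec("random", seed = 7), a_max_cap = 4,
                         jackknife = FALSE)
  s <- fit$vip_regions
  # the global VIP peak lies inside the red-edge window (shared with VIS)
  expect_equal(s$max_vip[s$region == "RED_EDGE"], max(s$max_vip))
  peak_wl <- sim$spectra$wavelengths[which.max(fit$vip)]
  expect_gte(peak_wl, 680)
  expect_lte(peak_wl, 750)
})

test_that("skill-variability correlations: exact cases and the reference tables", {
  mr <- data.frame(trait = c("a", "b", "c"), split = "random",
                   r2 = c(0.5, 0.3, 0.1))
  ts <- data.frame(trait = c("a", "b", "c"), cv = c(10, 20, 30))
  expect_equal(correlate_r2_cv(mr, ts)$pearson_r, -1, tolerance = 1e-12)
  expect_error(correlate_r2_cv(mr[1:2, ], ts), "at least 3")
  ref <- correlate_r2_cv(reference_plsr_results(), reference_trait_stats())
  expect_true(all(ref$pearson_r < 0))
  expect_lt(ref$pearson_r[ref$split == "cultivar"],
            ref$pearson_r[ref$split == "random"])
})

test_that("the end-to-end chain is reproducible and flags unlinked traits", {
  cfg <- single_link_config(noise = 0.003, seed = 31)
  # add an unlinked trait: no covariance with the spectra
  cfg$trait_specs$inert <- list(mean = 0, total_sd = 1,
                                proportions = c(cultivar = 0.3))
  sim <- simulate_vineyard(cfg)
  sp <- split_spec("random", seed = 13)
  f1 <- fit_trait_model(sim$spectra, sim$traits, "N", sp, a_max_cap = 5,
                        jk_B = 50)
  f2 <- fit_trait_model(sim$spectra, sim$traits, "N", sp, a_max_cap = 5,
                        jk_B = 50)
  expect_identical(f1$metrics, f2$metrics)
  expect_identical(f1$jackknife$intervals, f2$jackknife$intervals)
  expect_equal(f1$n_cal + f1$n_val, f1$n_obs)
  inert <- fit_trait_model(sim$spectra, sim$traits, "inert", sp, a_max_cap = 5,
                           jackknife = FALSE)
  expect_equal(inert$status, "no latent component")
  expect_equal(inert$cv$selected, 0L)
  expect_null(inert$metrics)
})
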