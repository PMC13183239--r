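# Shared fixtures, all generated in code.

# Random regression problem with mild structure.
rand_problem <- function(n, p, seed) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  y <- as.numeric(x %*% rnorm(p, sd = 0.5)) + rnorm(n, sd = 0.3)
  list(x = x, y = y)
}

# A minimal leaf table with nested metadata: k cultivars x m leaves,
# cultivar-level and residual variance only.
toy_leaf_table <- function(k = 12, m = 15, cult_sd = 0, resid_sd = 1,
                           mean = 10, seed = 1) {
  set.seed(seed)
  cultivar <- rep(sprintf("cv_%02d", seq_len(k)), each = m)
  eff <- rnorm(k, 0, cult_sd)[rep(seq_len(k), each = m)]
  data.frame(
    leaf_id = sprintf("leaf_%03d", seq_len(k * m)),
    cultivar = cultivar,
    variety = cultivar,
    origin = rep(c("warm", "cool"), length.out = k)[rep(seq_len(k), each = m)],
    colour = rep(c("red", "white"), length.out = k)[rep(seq_len(k), each = m)],
    row = rep(paste0("R", rep(1:3, length.out = m)), times = k),
    vine = rep(seq_len(m), times = k),
    y = mean + eff + rnorm(k * m, 0, resid_sd),
    stringsAsFactors = FALSE
  )
}

# Small single-trait simulation: one linked trait on a narrow grid-friendly
# problem, used for retrieval tests.  noise/nuisance default to zero.
single_link_config <- function(strength = 0.08, noise = 0, seed = 1,
                               nuisance = list(amplitude_sd = 0, water_sd = 0,
                                               tilt_sd = 0),
                               missing_rate = 0, n_cultivars = 10,
                               vines_per_row = 4) {
  sim_config(
    n_cultivars = n_cultivars, n_varieties = 5, rows_per_cultivar = 3,
    vines_per_row = vines_per_row,
    trait_specs = list(N = list(mean = 2.75, total_sd = 0.35,
                                proportions = c(cultivar = 0.4))),
    missing_rate = missing_rate, spectral_noise_sd = noise,
    nuisance = nuisance,
    link_specs = list(spectral_link("N", 710, 35, strength)),
    seed = seed
  )
}

# Compact pipeline configuration: three traits (two optically linked, one
# deliberately inert), a visible-range window and a light jackknife, so the
# full orchestration runs in seconds.
small_pipeline_config <- function(out_dir, seed = 5, jackknife = TRUE) {
  sim <- sim_config(
    n_cultivars = 10, n_varieties = 5, rows_per_cultivar = 3, vines_per_row = 5,
    trait_specs = list(
      N = list(mean = 2.75, total_sd = 0.35, proportions = c(cultivar = 0.4)),
      Area = list(mean = 150, total_sd = 34, proportions = c(cultivar = 0.3)),
      inert = list(mean = 0, total_sd = 1, proportions = c(cultivar = 0.3))
    ),
    missing_rate = 0.02, spectral_noise_sd = 0.004,
    link_specs = list(spectral_link("N", 710, 35, 0.06),
                      spectral_link("Area", 550, 45, 0.05)),
    seed = seed)
  pipeline_config(simulate = sim, window = c(400, 900),
                  registry = c(Area = "log"), a_max_cap = 5,
                  jackknife = jackknife, jk_B = 40, out_dir = out_dir)
}

# Vector with an exact sample mean and sd (two points), for CV arithmetic.
two_point_sample <- function(mean, sd) {
  c(mean - sd / sqrt(2), mean + sd / sqrt(2))
}
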