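test_that("full-rank PLSR reproduces ordinary least squares fitted values", {
  for (seed in 1:5) {
    pr <- rand_problem(8, 4, seed)
    fit <- plsr(pr$x, pr$y, ncomp = 4)
    ols <- lm.fit(cbind(1, pr$x), pr$y)
    expect_lt(max(abs(fitted(fit) - ols$fitted.values)), 1e-8)
  }
})

test_that("single-predictor PLSR collapses to the simple regression slope", {
  set.seed(3)
  x <- matrix(rnorm(30), 30, 1)
  y <- 2 * x[, 1] + rnorm(30)
  fit <- plsr(x, y, ncomp = 1)
  b <- coef(fit)
  expect_equal(unname(b[1]), cov(x[, 1], y) / var(x[, 1]), tolerance = 1e-10)
  expect_equal(unname(vip(fit)), 1)
})

test_that("a constant response yields zero coefficients and constant predictions", {
  set.seed(4)
  x <- matrix(rnorm(40), 10, 4)
  fit <- plsr(x, rep(7, 10), ncomp = 2)
  expect_true(fit$zero_variance_y)
  expect_true(all(fit$coefficients == 0))
  expect_equal(predict(fit, x), rep(7, 10))
})

test_that("prediction identities: centering and the mean row", {
  pr <- rand_problem(15, 6, 11)
  fit <- plsr(pr$x, pr$y, ncomp = 3)
  expect_equal(mean(predict(fit, pr$x)), mean(pr$y), tolerance = 1e-10)
  expect_equal(predict(fit, matrix(colMeans(pr$x), 1)), mean(pr$y),
               tolerance = 1e-10)
})

test_that("predictions are invariant to a consistent band permutation", {
  pr <- rand_problem(12, 8, 21)
  perm <- sample(8)
  f1 <- plsr(pr$x, pr$y, ncomp = 3)
  f2 <- plsr(pr$x[, perm], pr$y, ncomp = 3)
  xnew <- matrix(rnorm(5 * 8), 5, 8)
  expect_equal(predict(f1, xnew), predict(f2, xnew[, perm]), tolerance = 1e-10)
})

test_that("calibration RSS is non-increasing in component count", {
  pr <- rand_problem(20, 10, 31)
  fit <- plsr(pr$x, pr$y, ncomp = 8)
  rss <- vapply(1:8, function(a) sum((pr$y - predict(fit, pr$x, ncomp = a))^2),
                numeric(1))
  expect_true(all(diff(rss) <= 1e-10))
})

test_that("centering-only fits ignore band offsets; scaled fits ignore band affine maps", {
  pr <- rand_problem(18, 5, 41)
  shift <- matrix(rep(c(5, -3, 0.5, 100, -20), each = 18), 18, 5)
  f0 <- plsr(pr$x, pr$y, ncomp = 3)
  f1 <- plsr(pr$x + shift, pr$y, ncomp = 3)
  expect_equal(fitted(f0), fitted(f1), tolerance = 1e-8)
  mult <- c(2, 0.1, 5, 1, 0.01)
  f2 <- plsr(pr$x, pr$y, ncomp = 3, scale = TRUE)
  f3 <- plsr(sweep(pr$x, 2, mult, "*") + shift, pr$y, ncomp = 3, scale = TRUE)
  expect_equal(fitted(f2), fitted(f3), tolerance = 1e-8)
})

test_that("weights are unit norm and scores mutually orthogonal", {
  pr <- rand_problem(25, 12, 51)
  fit <- plsr(pr$x, pr$y, ncomp = 6)
  expect_equal(unname(colSums(fit$weights^2)), rep(1, 6), tolerance = 1e-10)
  g <- crossprod(fit$scores)
  g <- g / sqrt(tcrossprod(diag(g)))
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
})

test_that("coefficients reproduce the deflation-recursion fitted values", {
  pr <- rand_problem(16, 9, 61)
  fit <- plsr(pr$x, pr$y, ncomp = 4)
  for (a in 1:4) {
    via_scores <- mean(pr$y) +
      fit$scores[, 1:a, drop = FALSE] %*% fit$y_loadings[1:a]
    expect_equal(predict(fit, pr$x, ncomp = a), as.numeric(via_scores),
                 tolerance = 1e-8)
  }
})

test_that("VIP identities hold: unit mean square and the orthonormal case", {
  for (seed in 1:5) {
    pr <- rand_problem(15, 20, seed + 70)
    fit <- plsr(pr$x, pr$y, ncomp = 4)
    expect_equal(mean(vip(fit)^2), 1, tolerance = 1e-8)
  }
  # orthonormal mean-zero predictors (Helmert contrasts), response driven by
  # the first column only: the weight vector is e1, so VIP = (sqrt(p), 0, ...)
  x <- contr.helmert(5)
  x <- sweep(x, 2, sqrt(colSums(x^2)), "/")
  y <- 3 * x[, 1]
  fit <- plsr(x, y, ncomp = 1)
  expect_equal(unname(vip(fit)), c(2, 0, 0, 0), tolerance = 1e-6)
})

test_that("ncomp beyond min(n-1, p) is rejected", {
  pr <- rand_problem(6, 4, 81)
  expect_error(plsr(pr$x, pr$y, ncomp = 6), "ncomp")
  expect_error(plsr(pr$x[, 1:2], pr$y, ncomp = 3), "ncomp")
})

test_that("predictions agree with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  for (seed in 1:3) {
    pr <- rand_problem(20, 50, seed + 90)
    colnames(pr$x) <- paste0("b", 1:50)
    ref <- mixOmics::pls(pr$x, pr$y, ncomp = 5, scale = FALSE,
                         mode = "regression")
    fit <- plsr(pr$x, pr$y, ncomp = 5)
    xnew <- matrix(rnorm(8 * 50), 8, 50, dimnames = list(NULL, colnames(pr$x)))
    ref_pred <- predict(ref, xnew)$predict[, 1, 5]
    expect_lt(max(abs(predict(fit, xnew) - ref_pred)), 1e-6)
  }
})

test_that("JSON serialization round-trips predictions exactly", {
  pr <- rand_problem(14, 7, 101)
  fit <- plsr(pr$x, pr$y, ncomp = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_plsr_json(fit, path)
  back <- read_plsr_json(path)
  xnew <- matrix(rnorm(4 * 7), 4, 7)
  expect_equal(predict(back, xnew), predict(fit, xnew), tolerance = 1e-12)
  expect_equal(coef(back), coef(fit), tolerance = 1e-12)
})

test_that("simulate() draws around the fitted values at the residual scale", {
  pr <- rand_problem(30, 5, 111)
  fit <- plsr(pr$x, pr$y, ncomp = 3)
  sims <- simulate(fit, nsim = 200, seed = 5)
  expect_equal(dim(sims), c(30, 200))
  expect_equal(rowMeans(as.matrix(sims)), fit$fitted.values, tolerance = 0.5)
})
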