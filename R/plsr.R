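#' Partial least squares regression by NIPALS
#'
#' Fits a univariate-response PLS regression model with the orthogonal-scores
#' (NIPALS) algorithm.  Predictors are mean-centred; optionally each predictor
#' is also scaled to unit variance.  For a single response the weight update
#' has a closed form (no inner iteration), and response-side deflation is
#' omitted because it does not change the fit: after predictor deflation the
#' removed part of the response is orthogonal to every remaining predictor
#' column, so the algorithm is equivalent to SIMPLS for univariate responses.
#'
#' The returned object stores, per component: the unit-norm predictor weight
#' vector, predictor loading, response loading and score sum of squares,
#' together with regression coefficient vectors for every component count
#' `1..ncomp`, so predictions can be made at any truncation without refitting.
#'
#' Reflectance spectra share units across bands, so the default is centring
#' without unit-variance scaling, the usual convention in leaf spectroscopy;
#' set `scale = TRUE` for predictors on heterogeneous scales.
#'
#' @param x numeric matrix of predictors (observations x variables), no
#'   missing values.  Column names (e.g. `"wl_0700"`) are retained on
#'   coefficients and VIP scores.
#' @param y numeric response vector, `length(y) == nrow(x)`.
#' @param ncomp number of latent components, at most `min(nrow(x) - 1, ncol(x))`.
#' @param scale logical; scale predictors to unit variance (constant columns
#'   are left unscaled).
#' @return An object of class `"plsr"`: a list with elements `x_center`,
#'   `x_scale`, `y_center`, `weights` (p x A, unit-norm columns), `loadings`
#'   (p x A), `y_loadings` (length A), `score_ss` (length A, \eqn{t_a'atop t_a}),
#'   `scores` (n x A), `coefficients` (p x A; column a is the coefficient
#'   vector using components 1..a, on the centred/scaled predictor scale),
#'   `intercepts` (length A, for raw predictors), `ncomp`, `fitted.values`,
#'   `residuals`, `y`, and `zero_variance_y` flag.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), 20, 10)
#' y <- x[, 1] - 0.5 * x[, 2] + rnorm(20, sd = 0.1)
#' fit <- plsr(x, y, ncomp = 3)
#' fit
#' head(vip(fit))
#' @seealso [vip()], [predict.plsr()], [loo_press()]
#' @export
plsr <- function(x, y, ncomp, scale = FALSE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  n <- nrow(x)
  p <- ncol(x)
  if (length(y) != n) stop("length(y) must equal nrow(x)")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed in x or y")
  if (ncomp < 1) stop("ncomp must be at least 1")
  if (ncomp > min(n - 1, p)) {
    stop(sprintf("ncomp = %d exceeds min(n - 1, p) = %d", ncomp, min(n - 1, p)))
  }

  x_center <- colMeans(x)
  xc <- sweep(x, 2, x_center, "-")
  if (scale) {
    x_scale <- apply(x, 2, stats::sd)
    x_scale[x_scale == 0] <- 1
    xc <- sweep(xc, 2, x_scale, "/")
  } else {
    x_scale <- rep(1, p)
  }
  y_center <- mean(y)
  yc <- y - y_center

  zero_y <- isTRUE(all.equal(stats::var(y), 0)) || stats::var(y) == 0

  W <- matrix(0, p, ncomp)   # unit-norm weights
  P <- matrix(0, p, ncomp)   # predictor loadings
  Q <- numeric(ncomp)        # response loadings
  TT <- matrix(0, n, ncomp)  # scores
  ss <- numeric(ncomp)       # score sums of squares t'a t_a
  B <- matrix(0, p, ncomp)   # coefficients (centred scale) per component count
  R <- matrix(0, p, ncomp)   # projection weights W (P'W)^-1, built recursively

  actual <- 0L
  if (!zero_y) {
    Xa <- xc
    b_run <- numeric(p)
    for (a in seq_len(ncomp)) {
      w <- crossprod(Xa, yc)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-12) break  # no remaining covariance: stop early
      w <- w / nw
      t_a <- Xa %*% w
      tt <- sum(t_a^2)
      if (tt < 1e-12) break
      p_a <- crossprod(Xa, t_a) / tt
      q_a <- sum(yc * t_a) / tt
      # r_a = w_a - sum_{j<a} (p_j' w_a) r_j  gives coefficients without solve()
      r_a <- w
      if (a > 1L) {
        proj <- crossprod(P[, seq_len(a - 1L), drop = FALSE], w)
        r_a <- r_a - R[, seq_len(a - 1L), drop = FALSE] %*% proj
      }
      W[, a] <- w
      P[, a] <- p_a
      Q[a] <- q_a
      TT[, a] <- t_a
      ss[a] <- tt
      R[, a] <- r_a
      b_run <- b_run + as.numeric(r_a) * q_a
      B[, a] <- b_run
      Xa <- Xa - tcrossprod(t_a, p_a)
      actual <- a
    }
  }
  if (actual < ncomp) {
    if (!zero_y && actual == 0L) zero_y <- TRUE
    if (actual > 0L && actual < ncomp) {
      # pad trailing counts with the last attainable coefficient vector
      for (a in seq(actual + 1L, ncomp)) B[, a] <- B[, actual]
    }
  }

  dimnames(B) <- list(colnames(x), paste0("ncomp", seq_len(ncomp)))
  rownames(W) <- rownames(P) <- colnames(x)

  # intercepts on the raw predictor scale per component count
  bc <- B / x_scale
  intercepts <- y_center - as.numeric(crossprod(x_center, bc))

  fitted <- as.numeric(x %*% bc[, ncomp]) + intercepts[ncomp]

  structure(list(
    x_center = x_center, x_scale = x_scale, y_center = y_center,
    weights = W, loadings = P, y_loadings = Q, score_ss = ss,
    scores = TT, projection = R,
    coefficients = B, intercepts = intercepts,
    ncomp = ncomp, ncomp_fitted = actual,
    scale = scale, zero_variance_y = zero_y,
    fitted.values = fitted, residuals = y - fitted, y = y,
    wavelengths = .parse_band_wavelengths(colnames(x)),
    call = match.call()
  ), class = "plsr")
}

.parse_band_wavelengths <- function(nm) {
  if (is.null(nm)) return(NULL)
  wl <- suppressWarnings(as.numeric(sub("^wl_0*", "", nm)))
  if (anyNA(wl)) NULL else wl
}

#' @export
print.plsr <- function(x, ...) {
  cat("Partial least squares regression (NIPALS, univariate response)\n")
  cat(sprintf("  predictors: %d bands; observations: %d; components: %d%s\n",
              nrow(x$coefficients), length(x$y), x$ncomp,
              if (x$ncomp_fitted < x$ncomp)
                sprintf(" (%d attainable)", x$ncomp_fitted) else ""))
  cat(sprintf("  predictor scaling: %s\n",
              if (x$scale) "centred, unit variance" else "centred only"))
  if (x$zero_variance_y) {
    cat("  response has zero variance: all coefficients are 0\n")
  } else {
    sstot <- sum((x$y - mean(x$y))^2)
    r2 <- 1 - sum(x$residuals^2) / sstot
    cat(sprintf("  calibration R^2 at %d components: %.4f\n", x$ncomp, r2))
  }
  invisible(x)
}

#' @export
summary.plsr <- function(object, ...) {
  a <- seq_len(object$ncomp)
  sstot <- sum((object$y - mean(object$y))^2)
  ssy_a <- object$y_loadings^2 * object$score_ss  # response SS captured per component
  ssx <- colSums(object$loadings^2) * object$score_ss
  out <- data.frame(
    ncomp = a,
    ss_y = ssy_a,
    cum_r2_cal = if (sstot > 0) cumsum(ssy_a) / sstot else rep(NA_real_, length(a)),
    ss_x = ssx
  )
  structure(list(table = out, model = object), class = "summary.plsr")
}

#' @export
print.summary.plsr <- function(x, ...) {
  print(x$model)
  cat("\nPer-component response sum of squares captured:\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Regression coefficients of a PLSR model
#'
#' @param object a fitted [plsr()] model.
#' @param ncomp component count to extract (default: the model's maximum).
#' @param raw logical; if `TRUE`, coefficients are returned on the raw
#'   predictor scale with the intercept as attribute `"intercept"`; otherwise
#'   on the centred/scaled scale used internally.
#' @param ... unused.
#' @export
coef.plsr <- function(object, ncomp = object$ncomp, raw = TRUE, ...) {
  stopifnot(ncomp >= 1, ncomp <= object$ncomp)
  b <- object$coefficients[, ncomp]
  if (raw) {
    b <- b / object$x_scale
    attr(b, "intercept") <- object$intercepts[ncomp]
  }
  b
}

#' Predict trait values from new spectra
#'
#' @param object a fitted [plsr()] model.
#' @param newdata matrix of predictors on the model's band grid (same columns,
#'   same order).  Defaults to the calibration matrix implied by the stored
#'   scores, so `predict(fit)` equals `fitted(fit)`.
#' @param ncomp component count to use.
#' @param ... unused.
#' @export
predict.plsr <- function(object, newdata = NULL, ncomp = object$ncomp, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != nrow(object$coefficients)) {
    stop(sprintf("newdata has %d bands but the model was fitted on %d",
                 ncol(newdata), nrow(object$coefficients)))
  }
  cn_m <- rownames(object$coefficients)
  cn_n <- colnames(newdata)
  if (!is.null(cn_m) && !is.null(cn_n) && !identical(cn_m, cn_n)) {
    stop("newdata band names do not match the model's band grid")
  }
  b <- object$coefficients[, ncomp] / object$x_scale
  as.numeric(newdata %*% b) + object$intercepts[ncomp]
}

#' @export
fitted.plsr <- function(object, ...) object$fitted.values

#' @export
residuals.plsr <- function(object, ...) object$residuals

#' Simulate responses from a fitted PLSR model
#'
#' Draws `nsim` response vectors as fitted values plus Gaussian noise with the
#' calibration residual standard deviation.
#' @param object a fitted [plsr()] model.
#' @param nsim number of simulated response vectors.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @export
simulate.plsr <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(object$y)
  df <- max(1, n - object$ncomp - 1)
  sigma <- sqrt(sum(object$residuals^2) / df)
  out <- as.data.frame(replicate(nsim, object$fitted.values + stats::rnorm(n, sd = sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot PLSR coefficients or VIP scores across the spectrum
#'
#' @param x a fitted [plsr()] model.
#' @param type `"coefficients"` or `"vip"`.
#' @param ncomp component count for coefficients.
#' @param ... passed to [graphics::plot()].
#' @export
plot.plsr <- function(x, type = c("coefficients", "vip"), ncomp = x$ncomp, ...) {
  type <- match.arg(type)
  wl <- x$wavelengths
  if (is.null(wl)) wl <- seq_len(nrow(x$coefficients))
  if (type == "coefficients") {
    graphics::plot(wl, coef(x, ncomp = ncomp, raw = FALSE), type = "l",
                   xlab = "wavelength (nm)", ylab = "PLSR coefficient", ...)
  } else {
    graphics::plot(wl, vip(x), type = "l",
                   xlab = "wavelength (nm)", ylab = "VIP score", ...)
    graphics::abline(h = c(0.8, 1), lty = c(2, 3), col = "grey40")
  }
  invisible(x)
}

#' Variable importance in projection (VIP) scores
#'
#' Wold's VIP for each predictor band:
#' \deqn{VIP_j = \sqrt{p \sum_a SSY_a w_{ja}^2 / \sum_a SSY_a}}
#' where the weights are unit-norm and \eqn{SSY_a = q_a^2 t_a' t_a} is the
#' response sum of squares captured by component \eqn{a} (score sum of squares
#' times squared response loading).  The squared scores average to 1 across
#' bands, so 1 is the natural reference; 0.8 and 1.0 are the conventional
#' thresholds for influential bands.
#'
#' @param object a fitted [plsr()] model with at least one attainable
#'   component.
#' @param ncomp number of components to accumulate (default all fitted).
#' @return numeric vector of VIP scores, one per band.
#' @export
vip <- function(object, ncomp = object$ncomp_fitted) {
  if (!inherits(object, "plsr")) stop("vip() expects a 'plsr' model")
  if (object$ncomp_fitted < 1 || object$zero_variance_y) {
    stop("VIP is undefined for a model with no attainable components")
  }
  a <- seq_len(min(ncomp, object$ncomp_fitted))
  ssy <- object$y_loadings[a]^2 * object$score_ss[a]
  w2 <- object$weights[, a, drop = FALSE]^2
  p <- nrow(w2)
  out <- sqrt(p * as.numeric(w2 %*% ssy) / sum(ssy))
  names(out) <- rownames(object$weights)
  out
}

#' Serialize a PLSR model to JSON
#'
#' Writes the centring constants, weights, loadings and coefficient matrix to
#' a self-contained JSON document that [read_plsr_json()] restores to a model
#' usable with [predict.plsr()].
#'
#' @param object a fitted [plsr()] model.
#' @param path output file path.
#' @export
write_plsr_json <- function(object, path) {
  stopifnot(inherits(object, "plsr"))
  payload <- object[c("x_center", "x_scale", "y_center", "weights", "loadings",
                      "y_loadings", "score_ss", "coefficients", "intercepts",
                      "ncomp", "ncomp_fitted", "scale", "zero_variance_y")]
  payload$band_names <- rownames(object$coefficients)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_plsr_json
#' @param path path to a JSON file written by [write_plsr_json()].
#' @export
read_plsr_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- length(payload$x_center)
  fix <- function(m) {
    m <- if (is.matrix(m)) m else matrix(unlist(m), nrow = p, byrow = TRUE)
    storage.mode(m) <- "double"
    matrix(m, nrow = p)
  }
  obj <- list(
    x_center = as.numeric(payload$x_center),
    x_scale = as.numeric(payload$x_scale),
    y_center = payload$y_center,
    weights = fix(payload$weights), loadings = fix(payload$loadings),
    y_loadings = as.numeric(payload$y_loadings),
    score_ss = as.numeric(payload$score_ss),
    coefficients = fix(payload$coefficients),
    intercepts = as.numeric(payload$intercepts),
    ncomp = payload$ncomp, ncomp_fitted = payload$ncomp_fitted,
    scale = payload$scale, zero_variance_y = payload$zero_variance_y,
    fitted.values = NULL, residuals = NULL, y = NULL
  )
  if (!is.null(payload$band_names)) {
    rownames(obj$coefficients) <- payload$band_names
    rownames(obj$weights) <- payload$band_names
    obj$wavelengths <- .parse_band_wavelengths(payload$band_names)
  }
  class(obj) <- "plsr"
  obj
}
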