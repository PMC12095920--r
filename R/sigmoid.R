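#' Sigmoidal transition between two straight lines
#'
#' Evaluates the standard two-baseline sigmoid used to extract aggregation
#' half-times from ThT traces:
#' \deqn{F(t) = (m_1 t + n_1)(1 - L) + (m_2 t + n_2) L,\quad
#'       L = \frac{1}{1 + e^{k (t_{0.5} - t)}}}
#' so that for `k > 0` the curve rises from the pre-transition baseline
#' `m1*t + n1` to the post-transition baseline `m2*t + n2`, crossing the
#' mean of the two lines exactly at `t = t05`. The logistic is evaluated
#' via [stats::plogis()] so large `|k*(t05-t)|` saturates to 0/1 instead
#' of overflowing.
#'
#' @param t Time(s) in hours.
#' @param m1,n1 Slope (a.u./h) and intercept (a.u.) of the pre-transition
#'   baseline.
#' @param m2,n2 Slope and intercept of the post-transition baseline.
#' @param k Transition steepness, 1/h (reported in the literature with
#'   hour units; dimensional consistency requires 1/h).
#' @param t05 Transition midpoint (half-time), hours.
#' @return Fluorescence value(s), arbitrary units.
#' @export
eval_sigmoid <- function(t, m1, n1, m2, n2, k, t05) {
  L <- stats::plogis(k * (t - t05))
  (m1 * t + n1) * (1 - L) + (m2 * t + n2) * L
}

new_sigmoid_fit <- function(coefs, se, covariance, rmse, converged,
                            t_range, diagnostics = NULL) {
  structure(
    list(m1 = coefs[["m1"]], n1 = coefs[["n1"]], m2 = coefs[["m2"]],
         n2 = coefs[["n2"]], k = coefs[["k"]], t05 = coefs[["t05"]],
         se = se, covariance = covariance, rmse = rmse,
         converged = converged, t_range = t_range,
         diagnostics = diagnostics),
    class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf(
    "<sigmoid_fit> t05 = %.4g +/- %.2g h, k = %.4g +/- %.2g 1/h (1/k = %.4g h)\n",
    x$t05, x$se[["t05"]], x$k, x$se[["k"]], 1 / x$k))
  cat(sprintf("  baselines: pre %.3g*t + %.3g, post %.3g*t + %.3g; rmse %.3g; %s\n",
              x$m1, x$n1, x$m2, x$n2, x$rmse,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

# Data-driven starting values: t05 at half-maximal normalized signal, k from
# the steepest finite-difference slope, baselines from the first/last 10%.
sigmoid_start <- function(t, y) {
  n <- length(t)
  nb <- max(2L, floor(0.1 * n))
  pre <- stats::lm.fit(cbind(1, t[seq_len(nb)]), y[seq_len(nb)])$coefficients
  post_idx <- seq(n - nb + 1L, n)
  post <- stats::lm.fit(cbind(1, t[post_idx]), y[post_idx])$coefficients
  y0 <- min(y); y1 <- max(y)
  yn <- (y - y0) / max(y1 - y0, .Machine$double.eps)
  t05 <- t[which.min(abs(yn - 0.5))]
  dy <- diff(yn) / diff(t)
  # logistic of unit amplitude has max slope k/4
  k <- 4 * max(abs(dy), na.rm = TRUE)
  if (!is.finite(k) || k <= 0) k <- 1
  c(m1 = unname(pre[2]), n1 = unname(pre[1]),
    m2 = unname(post[2]), n2 = unname(post[1]),
    k = k, t05 = t05)
}

#' Fit the two-baseline sigmoid to an averaged curve
#'
#' Nonlinear least squares of [eval_sigmoid()] with deterministic,
#' data-driven starting values; up to three restarts with jittered starts
#' (seeded RNG) before giving up. Standard errors come from the
#' Jacobian-based covariance scaled by residual variance; a
#' `scaleOffset` is used so noiseless (zero-residual) curves converge
#' cleanly.
#'
#' @param curve An [averaged_curve()] (or anything with `$times` and
#'   `$mean_fluorescence`), >= 7 points spanning both baselines.
#' @param init Optional named vector overriding the automatic start
#'   (`m1, n1, m2, n2, k, t05`).
#' @return A `sigmoid_fit` object: coefficients, per-parameter standard
#'   errors, covariance, `rmse`, and a `converged` flag (non-convergence is
#'   reported, not thrown).
#' @export
fit_sigmoid <- function(curve, init = NULL) {
  t <- curve$times
  y <- curve$mean_fluorescence
  if (length(t) < 7L)
    stop("need at least 7 points to fit the two-baseline sigmoid")
  start <- sigmoid_start(t, y)
  if (!is.null(init)) start[names(init)] <- init
  dat <- data.frame(t = t, y = y)
  amp <- max(abs(y), 1e-12)
  # near-zero starts give nls a numerically zero Jacobian column
  tiny <- abs(start) < 1e-6 * amp
  start[tiny] <- 1e-6 * amp

  try_fit <- function(st) {
    tryCatch(
      stats::nls(
        y ~ eval_sigmoid(t, m1, n1, m2, n2, k, t05),
        data = dat, start = as.list(st), algorithm = "port",
        lower = c(m1 = -Inf, n1 = -Inf, m2 = -Inf, n2 = -Inf,
                  k = 1e-8, t05 = min(t)),
        upper = c(m1 = Inf, n1 = Inf, m2 = Inf, n2 = Inf,
                  k = Inf, t05 = max(t)),
        control = stats::nls.control(maxiter = 200, scaleOffset = amp,
                                     warnOnly = FALSE)),
      error = function(e) e)
  }

  fit <- try_fit(start)
  attempts <- 1L
  if (inherits(fit, "error")) {
    # jittered restarts, deterministic
    rng <- local({ set.seed(20260909L); function(n) stats::runif(n, 0.5, 2) })
    for (i in 1:3) {
      st <- start
      st[c("k", "t05")] <- st[c("k", "t05")] * rng(2)
      st["t05"] <- min(max(st["t05"], min(t)), max(t))
      fit <- try_fit(st)
      attempts <- attempts + 1L
      if (!inherits(fit, "error")) break
    }
  }
  if (inherits(fit, "error")) {
    return(new_sigmoid_fit(
      coefs = as.list(start),
      se = stats::setNames(rep(NA_real_, 6), names(start)),
      covariance = NULL, rmse = NA_real_, converged = FALSE,
      t_range = range(t),
      diagnostics = list(message = conditionMessage(fit),
                         attempts = attempts)))
  }
  cf <- stats::coef(fit)
  res <- stats::residuals(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  if (is.null(vc)) {
    # perfect (zero-residual) fits can defeat nls's internal Cholesky;
    # fall back on a central-difference Jacobian at the solution
    J <- vapply(seq_along(cf), function(i) {
      h <- pmax(abs(cf[i]), 1e-4) * 1e-6
      up <- cf; dn <- cf
      up[i] <- up[i] + h; dn[i] <- dn[i] - h
      (eval_sigmoid(t, up[1], up[2], up[3], up[4], up[5], up[6]) -
         eval_sigmoid(t, dn[1], dn[2], dn[3], dn[4], dn[5], dn[6])) / (2 * h)
    }, numeric(length(t)))
    sigma2 <- sum(res^2) / max(length(t) - length(cf), 1L)
    vc <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
  }
  se <- if (is.null(vc)) rep(NA_real_, length(cf)) else sqrt(pmax(diag(vc), 0))
  names(se) <- names(cf)
  new_sigmoid_fit(
    coefs = as.list(cf), se = se, covariance = vc,
    rmse = sqrt(mean(res^2)), converged = fit$convInfo$isConv,
    t_range = range(t), diagnostics = list(attempts = attempts))
}

#' Z-test comparison of two fitted half-times
#'
#' `Z = |t05_a - t05_b| / sqrt(se_a^2 + se_b^2)`, with a two-sided p-value
#' under a standard normal null. p-values below double-precision underflow
#' are reported as the underflow bound with `p_is_bound = TRUE` (a
#' "vanishingly small" p needs a printable representation).
#'
#' @param fit_a,fit_b Converged `sigmoid_fit` objects with positive
#'   `se["t05"]`.
#' @return List with elements `Z`, `p`, `p_is_bound`, `log10_p`.
#' @export
compare_halftimes <- function(fit_a, fit_b) {
  for (f in list(fit_a, fit_b)) {
    if (!isTRUE(f$converged)) stop("both fits must have converged")
    if (!is.finite(f$se[["t05"]]) || f$se[["t05"]] <= 0)
      stop("both fits need a positive standard error on t05")
  }
  Z <- abs(fit_a$t05 - fit_b$t05) /
    sqrt(fit_a$se[["t05"]]^2 + fit_b$se[["t05"]]^2)
  logp <- stats::pnorm(-Z, log.p = TRUE) + log(2)
  p <- exp(logp)
  bound <- p == 0
  if (bound) p <- .Machine$double.xmin
  list(Z = Z, p = p, p_is_bound = bound, log10_p = logp / log(10))
}

#' Half-time scaling with monomer concentration
#'
#' Ordinary least squares of `log10(t05)` on `log10(conc)`. The slope
#' diagnoses the aggregation mechanism: about -1/2 for fragmentation,
#' -nc/2 for nucleation-elongation, -(n2+1)/2 for secondary nucleation,
#' near 0 for saturating elongation plus fragmentation.
#'
#' @param concs Monomer concentrations, uM (> 0), one per fit.
#' @param fits List of converged `sigmoid_fit` objects (or a numeric vector
#'   of half-times in hours).
#' @return A `scaling_fit`: `log_conc`, `log_t05`, `slope`, `slope_se`,
#'   `intercept`, `r_squared`.
#' @export
halftime_scaling <- function(concs, fits) {
  t05 <- if (is.numeric(fits)) fits else {
    stopifnot(all(vapply(fits, inherits, logical(1), "sigmoid_fit")))
    if (!all(vapply(fits, function(f) isTRUE(f$converged), logical(1))))
      stop("all fits must have converged")
    vapply(fits, function(f) f$t05, numeric(1))
  }
  if (length(concs) != length(t05)) stop("one concentration per fit required")
  if (length(unique(concs)) < 3L)
    stop("need at least 3 distinct concentrations")
  if (any(concs <= 0) || any(t05 <= 0))
    stop("concentrations and half-times must be positive")
  lx <- log10(concs); ly <- log10(t05)
  fit <- stats::lm(ly ~ lx)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((ly - mean(ly))^2)
  # a numerically exact fit (incl. constant t05) counts as fully explained
  r2 <- if (ss_res <= 1e-25 || ss_tot <= 1e-25) 1
        else 1 - ss_res / ss_tot
  n <- length(lx)
  sigma2 <- ss_res / max(n - 2L, 1L)
  slope_se <- sqrt(sigma2 / sum((lx - mean(lx))^2))
  structure(
    list(log_conc = lx, log_t05 = ly,
         slope = unname(stats::coef(fit)[2]),
         slope_se = slope_se,
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2),
    class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit> slope = %.3f +/- %.3f, r^2 = %.4f (n = %d)\n",
              x$slope, x$slope_se, x$r_squared, length(x$log_conc)))
  invisible(x)
}
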