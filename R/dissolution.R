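#' Dissolution profile
#'
#' A sampled cumulative dissolution curve: percent of dose released at each
#' time point, for one formulation unit (vessel) or a mean curve.
#'
#' @param times Sampling times in hours, strictly increasing.
#' @param released Percent of dose released at each time, in `[0, 100]`,
#'   non-decreasing (tolerance 1e-9).
#' @param label Free-text label.
#' @return An object of class `dissolution_profile`.
#' @export
dissolution_profile <- function(times, released, label = "") {
  stopifnot(is.numeric(times), is.numeric(released),
            length(times) == length(released), length(times) >= 1)
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing")
  if (any(released < -1e-9) || any(released > 100 + 1e-9))
    stop("`released` must lie in [0, 100]")
  if (any(diff(released) < -1e-9))
    stop("`released` must be non-decreasing")
  structure(
    list(times = as.numeric(times),
         released = pmin(pmax(as.numeric(released), 0), 100),
         label = label),
    class = "dissolution_profile")
}

#' @export
print.dissolution_profile <- function(x, ...) {
  cat("<dissolution_profile>", if (nzchar(x$label)) x$label else "(unnamed)",
      "\n  ", length(x$times), " points, ",
      sprintf("%.3g h to %.3g h, final release %.1f%%\n",
              min(x$times), max(x$times), max(x$released)), sep = "")
  invisible(x)
}

#' Weibull release parameters
#'
#' Parameters of the empirical cumulative release function
#' `F(t) = f_max * (1 - exp(-((t - t_lag)^beta) / alpha))`.
#'
#' @param f_max Asymptotic release, percent, in `(0, 100]`.
#' @param alpha Scale parameter (h^beta), positive.
#' @param beta Shape parameter, positive.
#' @param t_lag Lag time before release starts, hours, non-negative.
#' @return An object of class `weibull_params`.
#' @export
weibull_params <- function(f_max, alpha, beta, t_lag = 0) {
  stopifnot(is.numeric(f_max), is.numeric(alpha), is.numeric(beta),
            is.numeric(t_lag))
  if (f_max <= 0 || f_max > 100) stop("`f_max` must be in (0, 100]")
  if (alpha <= 0) stop("`alpha` must be positive")
  if (beta <= 0) stop("`beta` must be positive")
  if (t_lag < 0) stop("`t_lag` must be non-negative")
  structure(list(f_max = f_max, alpha = alpha, beta = beta, t_lag = t_lag),
            class = "weibull_params")
}

#' @export
print.weibull_params <- function(x, ...) {
  cat(sprintf("<weibull_params> f_max %.4g%%, alpha %.4g, beta %.4g, t_lag %.4g h\n",
              x$f_max, x$alpha, x$beta, x$t_lag))
  invisible(x)
}

#' Evaluate a Weibull release curve
#'
#' @param params A [weibull_params()] object.
#' @param t Times in hours, non-negative.
#' @return Percent released at each time.
#' @export
weibull_release <- function(params, t) {
  stopifnot(inherits(params, "weibull_params"), is.numeric(t))
  if (any(t < 0)) stop("`t` must be non-negative")
  te <- pmax(t - params$t_lag, 0)
  ifelse(te > 0,
         params$f_max * (1 - exp(-(te ^ params$beta) / params$alpha)),
         0)
}

#' Fit the Weibull release function to a dissolution profile
#'
#' Least-squares fit of the four-parameter Weibull cumulative release curve.
#' A linearized fit (`log(-log(1 - F/f_max))` on `log t`) seeds a
#' Levenberg-Marquardt refinement.
#'
#' @param profile A [dissolution_profile()] with at least 4 points.
#' @param fix_fmax Optionally fix the asymptote (percent); otherwise fitted.
#' @param fit_tlag If `TRUE` the lag time is fitted too; default holds it at 0.
#' @return A [weibull_params()] with attributes `rss` (residual sum of
#'   squares) and `convergence`.
#' @export
fit_weibull <- function(profile, fix_fmax = NULL, fit_tlag = FALSE) {
  stopifnot(inherits(profile, "dissolution_profile"))
  t <- profile$times
  y <- profile$released
  if (length(t) < 4) stop("at least 4 sampled points are required")
  if (max(y) <= 0) stop("profile shows no release; nothing to fit")

  fmax0 <- if (is.null(fix_fmax)) min(max(y) * 1.02, 100) else fix_fmax
  # linearized start values from interior points
  ok <- y > 0.005 * fmax0 & y < 0.995 * fmax0 & t > 0
  if (sum(ok) >= 2) {
    z <- log(-log(1 - y[ok] / fmax0))
    lf <- stats::lm(z ~ log(t[ok]))
    beta0 <- max(unname(coef(lf)[2]), 0.05)
    alpha0 <- exp(-unname(coef(lf)[1]))
  } else {
    beta0 <- 1
    alpha0 <- max(t[which.max(y >= 0.63 * fmax0)], 1)
  }

  dat <- data.frame(t = t, y = y)
  fmax_term <- if (is.null(fix_fmax)) "fmax" else "fix_fmax"
  tlag_term <- if (fit_tlag) "tlag" else "0"
  form <- stats::as.formula(
    sprintf("y ~ %s * (1 - exp(-(pmax(t - %s, 1e-12) ^ beta) / alpha))",
            fmax_term, tlag_term),
    env = environment())
  start <- list(alpha = alpha0, beta = beta0)
  lower <- c(alpha = 1e-6, beta = 1e-3)
  upper <- c(alpha = 1e6, beta = 50)
  if (is.null(fix_fmax)) {
    start$fmax <- fmax0
    lower <- c(lower, fmax = max(y))
    upper <- c(upper, fmax = 100)
  }
  if (fit_tlag) {
    start$tlag <- 0
    lower <- c(lower, tlag = 0)
    upper <- c(upper, tlag = max(t))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = dat, start = start,
                      lower = lower[names(start)], upper = upper[names(start)],
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop("Weibull fit failed to converge: ", conditionMessage(fit),
         " (start: alpha=", signif(alpha0, 4), ", beta=", signif(beta0, 4), ")")
  cf <- coef(fit)
  out <- weibull_params(
    f_max = if (is.null(fix_fmax)) unname(cf["fmax"]) else fix_fmax,
    alpha = unname(cf["alpha"]),
    beta  = unname(cf["beta"]),
    t_lag = if (fit_tlag) unname(cf["tlag"]) else 0)
  attr(out, "rss") <- sum(stats::resid(fit)^2)
  attr(out, "convergence") <- fit$convInfo$isConv
  out
}

#' f2 dissolution similarity factor
#'
#' `f2 = 50 * log10(100 / sqrt(1 + mean((R - T)^2)))`.  Values above 50 are
#' conventionally read as similar curves; identical curves give 100.  All
#' sampled points are used (no 85%-release cutoff) unless
#' `drop_after_85 = TRUE`.
#'
#' @param reference,test [dissolution_profile()] objects sampled on the same
#'   time grid.
#' @param drop_after_85 Apply the convention of dropping points after both
#'   profiles exceed 85% release (keeping the first such point). Default off.
#' @return The f2 value (scalar).
#' @export
similarity_f2 <- function(reference, test, drop_after_85 = FALSE) {
  stopifnot(inherits(reference, "dissolution_profile"),
            inherits(test, "dissolution_profile"))
  if (length(reference$times) != length(test$times) ||
      any(abs(reference$times - test$times) > 1e-9))
    stop("profiles must be sampled on the same time grid")
  r <- reference$released
  tt <- test$released
  if (drop_after_85) {
    over <- r > 85 & tt > 85
    if (any(over)) {
      keep <- seq_len(min(which(over)))
      r <- r[keep]; tt <- tt[keep]
    }
  }
  50 * log10(100 / sqrt(1 + mean((r - tt)^2)))
}

#' Bootstrap f2 with percentile confidence interval
#'
#' Resamples formulation units (vessels) with replacement on each side,
#' computes f2 of the resampled mean profiles, and returns the median with
#' the 5th/95th percentile interval.
#'
#' @param reference_units,test_units Lists of [dissolution_profile()] objects
#'   (>= 2 per side) on a common time grid.
#' @param n_boot Number of bootstrap resamples; fewer than 100 triggers a
#'   warning about unstable percentiles.
#' @param seed Integer seed; results are reproducible given the seed.
#' @return A list with `estimate` (median), `ci` (5th/95th percentiles),
#'   `f2_of_means` (plain f2 of the observed mean profiles) and `samples`.
#' @export
bootstrap_f2 <- function(reference_units, test_units, n_boot = 1000, seed = 1) {
  stopifnot(is.list(reference_units), is.list(test_units),
            length(reference_units) >= 2, length(test_units) >= 2)
  if (n_boot < 100)
    warning("n_boot < 100: percentile interval will be unstable")
  grid <- reference_units[[1]]$times
  relmat <- function(units) {
    m <- vapply(units, function(u) {
      if (length(u$times) != length(grid) || any(abs(u$times - grid) > 1e-9))
        stop("all units must share one time grid")
      u$released
    }, numeric(length(grid)))
    t(m)  # units x times
  }
  R <- relmat(reference_units)
  T_ <- relmat(test_units)
  f2_of <- function(rm, tm) {
    50 * log10(100 / sqrt(1 + mean((colMeans(rm) - colMeans(tm))^2)))
  }
  set.seed(seed)
  samples <- vapply(seq_len(n_boot), function(b) {
    ri <- sample.int(nrow(R), replace = TRUE)
    ti <- sample.int(nrow(T_), replace = TRUE)
    f2_of(R[ri, , drop = FALSE], T_[ti, , drop = FALSE])
  }, numeric(1))
  list(estimate = median(samples),
       ci = unname(quantile(samples, c(0.05, 0.95))),
       f2_of_means = f2_of(R, T_),
       samples = samples)
}

#' Generate noisy dissolution replicates
#'
#' Synthetic formulation units: the noiseless Weibull curve perturbed by
#' multiplicative lognormal noise (mean-preserving), clipped to `[0, 100]`
#' and monotonized by cumulative maximum.
#'
#' @param params A [weibull_params()] object.
#' @param cv Coefficient of variation of the multiplicative noise, percent.
#' @param n_units Number of units.
#' @param grid Sampling times (hours).
#' @param seed Integer seed.
#' @return A list of [dissolution_profile()] objects.
#' @export
generate_dissolution_replicates <- function(params, cv, n_units,
                                            grid = default_dissolution_grid(),
                                            seed = 1) {
  stopifnot(cv >= 0, n_units >= 1)
  base <- weibull_release(params, grid)
  sdlog <- sqrt(log(1 + (cv / 100)^2))
  set.seed(seed)
  lapply(seq_len(n_units), function(i) {
    noise <- if (cv > 0)
      exp(rnorm(length(grid), -sdlog^2 / 2, sdlog)) else rep(1, length(grid))
    y <- cummax(pmin(pmax(base * noise, 0), 100))
    dissolution_profile(grid, y, label = sprintf("unit_%d", i))
  })
}

#' Default dissolution sampling grid
#'
#' 0.5, 1, 2, ..., 12 hours.  The completion-time convention of the virtual
#' formulation rules (100% at 12 h) refers to this grid.
#' @return Numeric vector of times in hours.
#' @export
default_dissolution_grid <- function() c(0.5, 1:12)
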