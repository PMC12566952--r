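#' Weibull dissolution parameters
#'
#' Parameterizes the empirical Weibull release function
#' \deqn{F(t) = 1 - \exp\!\left(-\ln 2 \left(\frac{t - t_{lag}}{t_{d50}}\right)^{b}\right)}
#' by the time to 50\% dissolution rather than the raw scale parameter, so
#' the "50\% dissolved time" of a release specification can be used
#' verbatim. Internally the raw scale is \eqn{a = t_{d50}^b / \ln 2}.
#'
#' @param td50 Time (minutes, after the lag) at which 50\% of the dose has
#'   dissolved. Must be > 0.
#' @param shape Dimensionless shape parameter \eqn{b}; 1 gives first-order
#'   release, > 1 sigmoidal, < 1 parabolic. Must be > 0.
#' @param tlag Lag time (minutes) before release starts. Must be >= 0.
#' @return An object of class `weibull_params`.
#' @examples
#' weibull_params(td50 = 9.7, shape = 1.37)
#' @export
weibull_params <- function(td50, shape, tlag = 0) {
  stopifnot(is.numeric(td50), length(td50) == 1L, is.finite(td50),
            is.numeric(shape), length(shape) == 1L, is.finite(shape),
            is.numeric(tlag), length(tlag) == 1L, is.finite(tlag))
  if (td50 <= 0) stop("'td50' must be > 0")
  if (shape <= 0) stop("'shape' must be > 0")
  if (tlag < 0) stop("'tlag' must be >= 0")
  structure(list(td50 = td50, shape = shape, tlag = tlag),
            class = "weibull_params")
}

#' @export
print.weibull_params <- function(x, ...) {
  cat(sprintf("Weibull release: td50 = %g min, shape = %g, tlag = %g min\n",
              x$td50, x$shape, x$tlag))
  invisible(x)
}

#' Fraction of dose dissolved at time t
#'
#' Evaluates the cumulative Weibull release function. Returns 0 at or
#' before the lag time and approaches 1 as `t` grows; by construction
#' `weibull_fraction(tlag + td50, p)` is exactly 0.5.
#'
#' @param t Time(s) in minutes (vectorized).
#' @param p A [weibull_params()] object.
#' @return Fraction dissolved in \[0, 1\].
#' @examples
#' p <- weibull_params(td50 = 9.7, shape = 1.37)
#' weibull_fraction(9.7, p)   # 0.5
#' @export
weibull_fraction <- function(t, p) {
  stopifnot(inherits(p, "weibull_params"), is.numeric(t), all(is.finite(t)))
  tt <- pmax(t - p$tlag, 0)
  1 - exp(-log(2) * (tt / p$td50)^p$shape)
}

#' Instantaneous release hazard of the Weibull function
#'
#' The hazard form \eqn{h(t) = f(t) / (1 - F(t))} of the Weibull release
#' function, i.e. the first-order rate constant (1/min) at which the
#' remaining undissolved pool dissolves. Coupling `dS/dt = -h(t) S` in an
#' ODE system reproduces `weibull_fraction()` exactly when no solubility
#' cap binds, which is what the absorption engine relies on.
#'
#' For `shape < 1` the hazard diverges as `t` approaches `tlag`; it is
#' capped at `hmax` to keep stiff integrators stable (the cap is far above
#' any physically meaningful release rate and does not perturb profiles
#' with shape near or above 1).
#'
#' @inheritParams weibull_fraction
#' @param hmax Upper cap on the returned rate constant (1/min).
#' @return Release rate constant(s), 1/min; 0 for `t <= tlag`.
#' @export
weibull_hazard <- function(t, p, hmax = 1e3) {
  stopifnot(inherits(p, "weibull_params"), is.numeric(t), all(is.finite(t)))
  tt <- t - p$tlag
  h <- ifelse(tt > 0,
              log(2) * p$shape / p$td50 * (pmax(tt, 0) / p$td50)^(p$shape - 1),
              0)
  pmin(h, hmax)
}

#' In vitro dissolution profile
#'
#' A validated container for one dissolution run: percent of dose
#' dissolved at strictly increasing sampling times in one medium.
#'
#' @param times Sampling times, minutes, strictly increasing, length >= 3.
#' @param pct_dissolved Percent dissolved at each time; finite, within
#'   \[0, 105\] (small analytical overshoot above 100\% is tolerated).
#' @param medium_ph pH of the dissolution medium.
#' @param label Free-text batch/formulation identifier.
#' @return An object of class `dissolution_profile`; also a data.frame
#'   with columns `time_min` and `pct_dissolved`.
#' @export
dissolution_profile <- function(times, pct_dissolved, medium_ph = NA_real_,
                                label = "") {
  stopifnot(is.numeric(times), is.numeric(pct_dissolved))
  if (length(times) != length(pct_dissolved))
    stop("'times' and 'pct_dissolved' must have equal length")
  if (length(times) < 3L) stop("need at least 3 sampling points")
  if (any(!is.finite(times)) || any(!is.finite(pct_dissolved)))
    stop("times and percents must be finite")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (any(pct_dissolved < 0) || any(pct_dissolved > 105))
    stop("'pct_dissolved' must lie in [0, 105]")
  structure(data.frame(time_min = times, pct_dissolved = pct_dissolved),
            medium_ph = medium_ph, label = label,
            class = c("dissolution_profile", "data.frame"))
}

#' Read / write dissolution profiles as CSV
#'
#' CSV layout: columns `time_min, pct_dissolved, medium_pH, label`, header
#' required, UTF-8. A file may hold several profiles distinguished by the
#' (`medium_pH`, `label`) pair.
#'
#' @param path File path.
#' @return `read_dissolution_csv()` returns a list of
#'   [dissolution_profile()] objects, one per (`medium_pH`, `label`).
#' @export
read_dissolution_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_min", "pct_dissolved", "medium_pH", "label")
  if (!all(need %in% names(d)))
    stop("dissolution CSV must have columns: ", paste(need, collapse = ", "))
  key <- interaction(d$medium_pH, d$label, drop = TRUE)
  lapply(split(d, key), function(g) {
    g <- g[order(g$time_min), ]
    dissolution_profile(g$time_min, g$pct_dissolved,
                        medium_ph = g$medium_pH[1], label = g$label[1])
  })
}

#' @param profiles A `dissolution_profile` or list of them.
#' @rdname read_dissolution_csv
#' @export
write_dissolution_csv <- function(profiles, path) {
  if (inherits(profiles, "dissolution_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    data.frame(time_min = p$time_min, pct_dissolved = p$pct_dissolved,
               medium_pH = attr(p, "medium_ph"), label = attr(p, "label"))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Fit the Weibull release function to a dissolution profile
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) of the Weibull
#' release curve to observed percent-dissolved data. Multi-start: td50 is
#' initialized at the sampling time whose observed value is nearest 50\%
#' and additionally from a small grid around it; shape starts at 1. The
#' lag time is held at 0 unless `free_tlag = TRUE`.
#'
#' @param profile A [dissolution_profile()].
#' @param weighting `"none"` (ordinary least squares) or `"relative"`
#'   (weights 1/max(obs,1)^2, emphasizing early, low-percent points).
#' @param free_tlag Estimate the lag time as well (default fixed at 0).
#' @return A list with `params` ([weibull_params()]), `rss`, `r_squared`,
#'   `fitted` (percent at the profile times), and `converged`.
#' @examples
#' p <- weibull_params(77.22, 1.06)
#' prof <- dissolution_profile(c(5, 10, 15, 30, 45, 60, 90, 120, 180, 240),
#'                             100 * weibull_fraction(
#'                               c(5, 10, 15, 30, 45, 60, 90, 120, 180, 240), p))
#' fit_weibull(prof)$params
#' @export
fit_weibull <- function(profile, weighting = c("none", "relative"),
                        free_tlag = FALSE) {
  stopifnot(inherits(profile, "dissolution_profile"))
  weighting <- match.arg(weighting)
  t <- profile$time_min
  y <- profile$pct_dissolved
  usable <- y > 0
  if (sum(usable) < 3L)
    stop("need at least 3 post-lag points with nonzero dissolution")
  if (all(y == 0)) stop("all-zero dissolution profile cannot be fitted")

  w <- if (weighting == "relative") 1 / pmax(y, 1)^2 else rep(1, length(y))

  # td50 start: time at which the profile is nearest 50% dissolved
  td50_0 <- t[which.min(abs(y - 50))]
  if (td50_0 <= 0) td50_0 <- stats::median(t)
  starts <- expand.grid(td50 = unique(pmax(td50_0 * c(0.5, 1, 2), 1e-3)),
                        shape = c(0.7, 1, 1.5))

  model <- if (free_tlag) {
    y ~ 100 * (1 - exp(-log(2) * (pmax(t - tlag, 0) / td50)^shape))
  } else {
    y ~ 100 * (1 - exp(-log(2) * (t / td50)^shape))
  }
  lower <- c(td50 = 1e-6, shape = 1e-3)
  upper <- c(td50 = 1e5, shape = 20)
  if (free_tlag) {
    lower <- c(lower, tlag = 0)
    upper <- c(upper, tlag = max(t))
  }

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- list(td50 = starts$td50[i], shape = starts$shape[i])
    if (free_tlag) st$tlag <- 0
    fit <- tryCatch(
      minpack.lm::nlsLM(model, data = data.frame(t = t, y = y),
                        start = st, lower = lower, upper = upper,
                        weights = w,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(w * stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("Weibull fit did not converge from starting values td50=",
         signif(td50_0, 4), ", shape=1")

  cf <- stats::coef(best$fit)
  pars <- weibull_params(cf[["td50"]], cf[["shape"]],
                         tlag = if (free_tlag) cf[["tlag"]] else 0)
  fitted_pct <- 100 * weibull_fraction(t, pars)
  rss <- sum((y - fitted_pct)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else ifelse(rss < 1e-12, 1, NA_real_)
  list(params = pars, rss = rss, r_squared = r2, fitted = fitted_pct,
       converged = TRUE)
}

#' f2 dissolution-profile similarity factor
#'
#' The regulatory similarity factor
#' \deqn{f_2 = 50 \log_{10}\!\left(100 \left[1 + \frac{1}{n}\sum_i (R_i - T_i)^2\right]^{-1/2}\right)}
#' between two profiles sampled on an identical time grid. Following
#' common regulatory guidance, once **both** profiles exceed 85\%
#' dissolved, only the first such point is retained. f2 >= 50 is the
#' conventional similarity criterion; identical profiles give 100.
#'
#' @param ref,test [dissolution_profile()] objects on identical time grids.
#' @return List with `f2`, `n_points` used, and `dropped` (times removed
#'   by the 85\% rule).
#' @export
f2_similarity <- function(ref, test) {
  stopifnot(inherits(ref, "dissolution_profile"),
            inherits(test, "dissolution_profile"))
  if (length(ref$time_min) != length(test$time_min) ||
      any(ref$time_min != test$time_min))
    stop("profiles must share an identical time grid")
  r <- ref$pct_dissolved
  s <- test$pct_dissolved
  over <- r > 85 & s > 85
  keep <- rep(TRUE, length(r))
  if (any(over)) {
    first <- which(over)[1]
    if (first < length(r)) keep[(first + 1):length(r)] <- FALSE
  }
  if (sum(keep) < 3L)
    stop("fewer than 3 usable points after the 85% rule")
  msd <- mean((r[keep] - s[keep])^2)
  f2 <- 50 * log10(100 / sqrt(1 + msd))
  list(f2 = f2, n_points = sum(keep),
       dropped = ref$time_min[!keep])
}
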