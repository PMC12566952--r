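#' Non-compartmental PK metrics
#'
#' Cmax (maximum concentration), Tmax (first time attaining it) and
#' AUC0-t by the linear trapezoidal rule to the last sampling time.
#'
#' @param profile A [simulate_subject()] profile, or any data.frame with
#'   columns `time_h` and `conc_ng_ml` (times increasing, conc >= 0).
#' @return List of class `pk_metrics`: `cmax` (ng/mL), `tmax` (h),
#'   `auc_0t` (ng*h/mL).
#' @export
nca_metrics <- function(profile) {
  stopifnot(is.data.frame(profile),
            all(c("time_h", "conc_ng_ml") %in% names(profile)))
  t <- profile$time_h
  c <- profile$conc_ng_ml
  if (length(t) < 2L) stop("need at least 2 time points")
  if (any(diff(t) <= 0)) stop("times must be strictly increasing")
  if (any(c < 0)) stop("negative concentrations")
  if (all(c == 0)) {
    warning("all-zero concentration profile; metrics are zero")
    return(structure(list(cmax = 0, tmax = t[1], auc_0t = 0),
                     class = "pk_metrics"))
  }
  cmax <- max(c)
  tmax <- t[which.max(c)]           # first time attaining the maximum
  auc <- sum(diff(t) * (utils::head(c, -1) + utils::tail(c, -1)) / 2)
  structure(list(cmax = cmax, tmax = tmax, auc_0t = auc),
            class = "pk_metrics")
}

#' Model-validation error metrics
#'
#' Prediction error `PE = |predicted - observed| / observed` and fold
#' error `FE = predicted / observed`, with the conventional acceptance
#' thresholds PE <= 20\% and 0.5 <= FE <= 2 ("within two-fold"). The two
#' are algebraically linked: `PE = |FE - 1|`.
#'
#' @param predicted,observed Positive scalars on the same scale.
#' @return `prediction_error()`: list `pe`, `pass_pe` (pe <= 0.20);
#'   `fold_error()`: list `fe`, `pass_fe` (fe <= 2).
#' @export
prediction_error <- function(predicted, observed) {
  if (observed <= 0) stop("'observed' must be > 0")
  pe <- abs(predicted - observed) / observed
  list(pe = pe, pass_pe = pe <= 0.20)
}

#' @rdname prediction_error
#' @export
fold_error <- function(predicted, observed) {
  if (observed <= 0) stop("'observed' must be > 0")
  fe <- predicted / observed
  list(fe = fe, pass_fe = fe <= 2)
}

#' Test/reference ratio in percent
#'
#' `100 * t / r`, the geometric-mean-ratio arithmetic used in
#' bioequivalence reporting; reported rounded to 2 decimals.
#'
#' @param t_value,r_value Positive test and reference values.
#' @return Percent ratio rounded to 2 decimals.
#' @examples
#' gmr_ratio_percent(1263.52, 1215.67)  # 103.94
#' @export
gmr_ratio_percent <- function(t_value, r_value) {
  stopifnot(t_value > 0, r_value > 0)
  round(100 * t_value / r_value, 2)
}

#' 2x2 crossover bioequivalence analysis
#'
#' Fits the standard fixed-effects crossover ANOVA to the log-transformed
#' metric, `log(y) ~ sequence + period + treatment + subject`, and
#' reports the geometric mean ratio (test/reference) with its 90\%
#' confidence interval from the within-subject residual (Schuirmann's
#' two one-sided tests framework): BE passes when the CI lies within
#' 80.00-125.00\%. For balanced complete data this coincides with the
#' paired-t analysis of period differences.
#'
#' @param design A [assign_crossover()] design.
#' @param metrics Data.frame with one row per subject-period:
#'   `subject_id, period` and the metric columns `cmax` and/or `auc_0t`
#'   (positive).
#' @param metric Which metric to analyze: `"cmax"` or `"auc_0t"`.
#' @param limits BE acceptance bounds in percent.
#' @return Object of class `be_result`: `metric`, `gmr_pct`, `ci90`
#'   (length-2, percent), `pass`, `n_subjects`, `df`.
#' @export
be_crossover_analysis <- function(design, metrics,
                                  metric = c("cmax", "auc_0t"),
                                  limits = c(80, 125)) {
  metric <- match.arg(metric)
  stopifnot(inherits(design, "crossover_design"))
  keep <- c("subject_id", "period",
            intersect(c("cmax", "auc_0t", "tmax"), names(metrics)))
  tab <- merge(design$table, metrics[keep], by = c("subject_id", "period"))
  y <- tab[[metric]]
  if (any(!is.finite(y) | y <= 0)) stop("metric values must be positive")

  complete <- table(tab$subject_id)
  incomplete <- names(complete)[complete < 2L]
  if (length(incomplete)) {
    warning("dropping subjects missing a period: ",
            paste(incomplete, collapse = ", "))
    tab <- tab[!tab$subject_id %in% incomplete, ]
  }
  n_seq <- table(unique(tab[c("subject_id", "sequence")])$sequence)
  if (length(n_seq) < 2L || any(n_seq < 3L))
    stop("need at least 3 subjects per sequence")

  tab$l <- log(tab[[metric]])
  tab$subject_id <- factor(tab$subject_id)
  tab$sequence <- factor(tab$sequence)
  tab$period <- factor(tab$period)
  tab$treatment <- factor(tab$treatment, levels = c("R", "T"))
  fit <- stats::lm(l ~ sequence + period + treatment + subject_id,
                   data = tab)
  est <- stats::coef(fit)[["treatmentT"]]
  # a saturated fit (all T == R) triggers a harmless "perfect fit" warning
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit)))[["treatmentT"]])
  df <- fit$df.residual
  tcrit <- stats::qt(0.95, df)
  ci <- est + c(-1, 1) * tcrit * se
  # a saturated fit (zero residual) gives NaN se; the point estimate is exact
  if (!is.finite(se)) ci <- c(est, est)

  gmr <- 100 * exp(est)
  ci_pct <- 100 * exp(ci)
  structure(list(metric = metric, gmr_pct = gmr, ci90 = ci_pct,
                 pass = ci_pct[1] >= limits[1] && ci_pct[2] <= limits[2],
                 n_subjects = nlevels(tab$subject_id), df = df),
            class = "be_result")
}

#' @export
print.be_result <- function(x, ...) {
  cat(sprintf("BE (%s): GMR %.2f%%, 90%% CI %.2f-%.2f%% -> %s\n",
              x$metric, round(x$gmr_pct, 2), round(x$ci90[1], 2),
              round(x$ci90[2], 2), if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}
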