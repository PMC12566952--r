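make_subjects <- function(n) lapply(seq_len(n), function(i) list(id = i))

test_that("nca_metrics matches geometric oracles", {
  # constant concentration c over [0, T]: auc = c*T, cmax = c, tmax = 0
  p <- data.frame(time_h = c(0, 6, 12), conc_ng_ml = c(5, 5, 5))
  m <- nca_metrics(p)
  expect_equal(m$auc_0t, 5 * 12)
  expect_equal(m$cmax, 5)
  expect_equal(m$tmax, 0)
  # triangle 0 -> c at T/2 -> 0 at T: auc = c*T/2
  tri <- data.frame(time_h = c(0, 4, 8), conc_ng_ml = c(0, 10, 0))
  expect_equal(nca_metrics(tri)$auc_0t, 10 * 8 / 2)
  expect_equal(nca_metrics(tri)$tmax, 4)
  # single nonzero point among zeros: the two adjacent trapezoid panels
  sp <- data.frame(time_h = c(0, 1, 2, 3), conc_ng_ml = c(0, 0, 6, 0))
  expect_equal(nca_metrics(sp)$auc_0t, (1 * 6 / 2) + (1 * 6 / 2))
  # trapezoid is exact for piecewise-linear profiles
  pw <- data.frame(time_h = c(0, 1, 3, 7), conc_ng_ml = c(0, 4, 2, 0))
  expect_equal(nca_metrics(pw)$auc_0t,
               (0 + 4) / 2 * 1 + (4 + 2) / 2 * 2 + (2 + 0) / 2 * 4)
})

test_that("nca_metrics handles degenerate inputs per contract", {
  expect_warning(m <- nca_metrics(
    data.frame(time_h = 0:2, conc_ng_ml = c(0, 0, 0))), "all-zero")
  expect_equal(m$auc_0t, 0)
  expect_error(nca_metrics(data.frame(time_h = c(0, 1),
                                      conc_ng_ml = c(0, -1))), "negative")
  expect_error(nca_metrics(data.frame(time_h = c(1, 1),
                                      conc_ng_ml = c(0, 1))), "increasing")
})

test_that("prediction and fold error reproduce worked values", {
  # the 7% over-prediction row
  expect_equal(fold_error(1.07 * 350, 350)$fe, 1.07)
  expect_equal(prediction_error(1.07 * 350, 350)$pe, 0.07)
  # exact prediction
  expect_equal(fold_error(42, 42)$fe, 1)
  expect_equal(prediction_error(42, 42)$pe, 0)
  # the 20% under-prediction rows sit exactly at the PE threshold
  pe <- prediction_error(0.80 * 68, 68)
  expect_equal(pe$pe, 0.20)
  expect_true(pe$pass_pe)
  expect_true(fold_error(0.80 * 68, 68)$pass_fe)
  expect_error(prediction_error(1, 0), "observed")
})

test_that("pe = |fe - 1| identically", {
  set.seed(31)
  for (i in 1:50) {
    obs <- runif(1, 0.1, 1000)
    pred <- obs * exp(rnorm(1, 0, 0.5))
    expect_equal(prediction_error(pred, obs)$pe,
                 abs(fold_error(pred, obs)$fe - 1))
  }
})

test_that("gmr_ratio_percent reproduces printed ratio arithmetic", {
  expect_identical(gmr_ratio_percent(1263.52, 1215.67), 103.94)
  expect_identical(gmr_ratio_percent(55.32, 67.44), 82.03)
  expect_identical(gmr_ratio_percent(123.4, 123.4), 100)
  expect_error(gmr_ratio_percent(-1, 2))
})

test_that("crossover BE analysis matches the paired-difference formula oracle", {
  set.seed(77)
  n <- 8
  subj <- make_subjects(n)
  des <- assign_crossover(subj, seed = 11L)
  met <- merge(des$table[c("subject_id", "period", "treatment")],
               data.frame(subject_id = rep(1:n, each = 2),
                          period = rep(1:2, n)),
               by = c("subject_id", "period"))
  met$cmax <- exp(rnorm(nrow(met), log(100), 0.2))
  met$auc_0t <- met$cmax * 5

  res <- be_crossover_analysis(des, met, metric = "cmax")

  # independent oracle: period differences, pooled across sequences
  l <- log(met$cmax)
  d <- tapply(seq_len(nrow(met)), met$subject_id, function(ix) {
    ix <- ix[order(met$period[ix])]
    l[ix[1]] - l[ix[2]]
  })
  seqs <- des$sequence[as.character(names(d))]
  # d = T - R in TR, R - T in RT
  d_tr <- d[seqs == "TR"]; d_rt <- d[seqs == "RT"]
  delta <- (mean(d_tr) - mean(d_rt)) / 2
  s2 <- (sum((d_tr - mean(d_tr))^2) + sum((d_rt - mean(d_rt))^2)) /
    (length(d_tr) + length(d_rt) - 2)
  se <- sqrt(s2 / 4 * (1 / length(d_tr) + 1 / length(d_rt)))
  df <- length(d_tr) + length(d_rt) - 2
  ci <- 100 * exp(delta + c(-1, 1) * qt(0.95, df) * se)

  expect_equal(res$gmr_pct, 100 * exp(delta), tolerance = 1e-10)
  expect_equal(res$ci90, ci, tolerance = 1e-10)
  expect_equal(res$df, df)
})

test_that("BE analysis is scale-invariant and reciprocal under label swap", {
  set.seed(13)
  n <- 10
  subj <- make_subjects(n)
  des <- assign_crossover(subj, seed = 21L)
  met <- des$table[c("subject_id", "period", "treatment")]
  met$cmax <- exp(rnorm(nrow(met), log(50), 0.15))
  met$auc_0t <- met$cmax

  r1 <- be_crossover_analysis(des, met, "cmax")
  met2 <- met; met2$cmax <- met$cmax * 1234.5
  r2 <- be_crossover_analysis(des, met2, "cmax")
  expect_equal(r1$gmr_pct, r2$gmr_pct, tolerance = 1e-12)
  expect_equal(r1$ci90, r2$ci90, tolerance = 1e-10)

  # swap T and R labels: GMR -> 1/GMR, CI reflected about 100%
  des_sw <- des
  des_sw$sequence <- ifelse(des$sequence == "TR", "RT", "TR")
  names(des_sw$sequence) <- names(des$sequence)
  des_sw$table$treatment <- ifelse(des$table$treatment == "T", "R", "T")
  des_sw$table$sequence <- ifelse(des$table$sequence == "TR", "RT", "TR")
  r3 <- be_crossover_analysis(des_sw, met, "cmax")
  expect_equal(r3$gmr_pct, 100 * 100 / r1$gmr_pct, tolerance = 1e-10)
  expect_equal(sort(r3$ci90), sort(100 * 100 / r1$ci90), tolerance = 1e-8)
})

test_that("identical T and R metrics give GMR 100 with zero width and pass", {
  n <- 6
  subj <- make_subjects(n)
  des <- assign_crossover(subj, seed = 2L)
  met <- des$table[c("subject_id", "period", "treatment")]
  met$cmax <- rep(exp(rnorm(n, log(80), 0.3)), each = 2)  # same per subject
  met$auc_0t <- met$cmax
  r <- be_crossover_analysis(des, met, "cmax")
  expect_equal(r$gmr_pct, 100, tolerance = 1e-12)
  expect_equal(r$ci90, c(100, 100), tolerance = 1e-10)
  expect_true(r$pass)
})

test_that("BE analysis enforces minimum data requirements", {
  subj <- make_subjects(4)
  des <- assign_crossover(subj, seed = 3L)
  met <- des$table[c("subject_id", "period", "treatment")]
  met$cmax <- rep(100, nrow(met))
  met$auc_0t <- met$cmax
  expect_error(be_crossover_analysis(des, met, "cmax"), "3 subjects")
  # a subject missing one period is dropped with a warning
  subj8 <- make_subjects(8)
  des8 <- assign_crossover(subj8, seed = 3L)
  met8 <- des8$table[c("subject_id", "period", "treatment")]
  set.seed(1); met8$cmax <- exp(rnorm(16, log(10), 0.1))
  met8$auc_0t <- met8$cmax
  met8 <- met8[-1, ]
  expect_warning(r <- be_crossover_analysis(des8, met8, "cmax"),
                 "missing a period")
  expect_equal(r$n_subjects, 7)
})
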