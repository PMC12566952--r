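#' Explore the dissolution safe space over the 50%-dissolution time
#'
#' Systematically varies the test formulation's td50 (shape and lag held
#' at the test formulation's values), runs a virtual BE trial at each
#' point against the fixed reference formulation, and reports the
#' contiguous td50 region within which both Cmax and AUC0-t pass the
#' 80.00-125.00\% criterion. The same virtual population, design and
#' reference-arm simulations are reused at every point, so differences
#' between points are formulation-driven only.
#'
#' Search: a coarse grid scan (default 5-min spacing, always including
#' the reference td50), then bisection to `refine_to` (default 1 min)
#' at each pass/fail transition.
#'
#' @param config Study config ([study_preset()] shape).
#' @param td50_range `c(low, high)` search range, minutes; must bracket
#'   the reference td50.
#' @param n,seed,subjects,design,wsv,t_grid_h As for [run_vbe()].
#' @param coarse_step Coarse grid spacing, minutes.
#' @param refine_to Boundary resolution, minutes.
#' @return Object of class `safe_space_result`: `grid` (data.frame with
#'   td50, GMR and CI per metric, pass), `lower_bound_td50`,
#'   `upper_bound_td50` (outermost passing td50; range ends mean the
#'   boundary is open/outside the searched range), `lower_open`,
#'   `upper_open`, `failing_metric_slow`, `failing_metric_fast` (the
#'   metric whose CI is outside bounds just beyond each boundary, NA if
#'   open), `empty` (no passing point).
#' @export
explore_safe_space <- function(config, td50_range, n = 24, seed = 1L,
                               subjects = NULL, design = NULL,
                               coarse_step = 5, refine_to = 1,
                               wsv = TRUE,
                               t_grid_h = seq(0, 48, by = 0.1)) {
  stopifnot(length(td50_range) == 2L, td50_range[1] > 0,
            td50_range[1] < td50_range[2])
  ref_td50 <- config$ref_form$td50
  if (ref_td50 < td50_range[1] || ref_td50 > td50_range[2])
    stop("'td50_range' must bracket the reference td50 (", ref_td50, ")")

  if (is.null(subjects))
    subjects <- sample_population(population_spec(n = n, seed = seed),
                                  wsv = wsv)
  if (is.null(design)) design <- assign_crossover(subjects, seed = seed + 1L)
  ref_metrics <- simulate_design_cells(subjects, design, config,
                                       config$ref_form, "R", t_grid_h)

  evaluated <- new.env(parent = emptyenv())
  eval_point <- function(td50) {
    key <- sprintf("%.6f", td50)
    if (!is.null(evaluated[[key]])) return(evaluated[[key]])
    form <- weibull_params(td50, config$test_form$shape,
                           config$test_form$tlag)
    v <- run_vbe(config, test_form = form, subjects = subjects,
                 design = design, ref_metrics = ref_metrics,
                 t_grid_h = t_grid_h)
    row <- data.frame(
      td50 = td50,
      gmr_cmax = v$be$cmax$gmr_pct,
      ci_lo_cmax = v$be$cmax$ci90[1], ci_hi_cmax = v$be$cmax$ci90[2],
      pass_cmax = v$be$cmax$pass,
      gmr_auc = v$be$auc_0t$gmr_pct,
      ci_lo_auc = v$be$auc_0t$ci90[1], ci_hi_auc = v$be$auc_0t$ci90[2],
      pass_auc = v$be$auc_0t$pass,
      pass = v$pass)
    evaluated[[key]] <- row
    row
  }

  grid <- sort(unique(c(seq(td50_range[1], td50_range[2], by = coarse_step),
                        td50_range[2], ref_td50)))
  for (g in grid) eval_point(g)

  collect <- function() {
    df <- do.call(rbind, as.list(evaluated))
    df[order(df$td50), ]
  }

  # bisect each pass/fail transition down to refine_to
  refine <- function() {
    df <- collect()
    trans <- which(diff(df$pass) != 0)
    any_new <- FALSE
    for (i in trans) {
      lo <- df$td50[i]; hi <- df$td50[i + 1]
      if (hi - lo > refine_to) {
        eval_point(round((lo + hi) / 2, 6))
        any_new <- TRUE
      }
    }
    any_new
  }
  while (refine()) {}

  df <- collect()
  rownames(df) <- NULL
  passing <- df$td50[df$pass]
  if (length(passing) == 0L) {
    res <- list(grid = df, empty = TRUE,
                lower_bound_td50 = NA_real_, upper_bound_td50 = NA_real_,
                lower_open = FALSE, upper_open = FALSE,
                failing_metric_slow = NA_character_,
                failing_metric_fast = NA_character_)
    class(res) <- "safe_space_result"
    return(res)
  }
  lower <- min(passing)
  upper <- max(passing)

  failing_metric <- function(td50_fail) {
    r <- df[df$td50 == td50_fail, ]
    bad <- c(cmax = !r$pass_cmax, auc_0t = !r$pass_auc)
    if (!any(bad)) return(NA_character_)
    paste(names(bad)[bad], collapse = "+")
  }
  below <- df$td50[!df$pass & df$td50 < lower]
  above <- df$td50[!df$pass & df$td50 > upper]
  res <- list(
    grid = df, empty = FALSE,
    lower_bound_td50 = lower, upper_bound_td50 = upper,
    lower_open = length(below) == 0L,    # passes down to the range edge
    upper_open = length(above) == 0L,
    failing_metric_fast = if (length(below)) failing_metric(max(below))
                          else NA_character_,
    failing_metric_slow = if (length(above)) failing_metric(min(above))
                          else NA_character_)
  class(res) <- "safe_space_result"
  res
}

#' @export
print.safe_space_result <- function(x, ...) {
  if (x$empty) {
    cat("Safe space: EMPTY (no passing td50 in the searched range)\n")
    return(invisible(x))
  }
  cat(sprintf("Safe space: td50 in [%g, %g] min (%s, %s)\n",
              x$lower_bound_td50, x$upper_bound_td50,
              if (x$lower_open) "open below" else
                paste0("fast-side failure: ", x$failing_metric_fast),
              if (x$upper_open) "open above" else
                paste0("slow-side failure: ", x$failing_metric_slow)))
  invisible(x)
}
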