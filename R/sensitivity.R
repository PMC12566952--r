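#' Local relative sensitivity coefficient
#'
#' \deqn{S = \frac{\Delta PK}{\Delta P} \cdot \frac{P}{PK}}
#' the relative output change per relative input change. A coefficient of
#' -1.0 means a 10\% increase in the input produces a proportional 10\%
#' decrease in the output; +0.5 means a 10\% increase produces only a
#' 5\% increase.
#'
#' @param pk_base,pk_pert Output (e.g. Cmax, AUC) at the base and
#'   perturbed parameter value; `pk_base` > 0.
#' @param p_base,p_pert Base and perturbed parameter values;
#'   `p_base` > 0, `p_pert != p_base`.
#' @return Dimensionless sensitivity coefficient (sign carries the
#'   direction of the effect).
#' @examples
#' sensitivity_coefficient(100, 90, 1, 1.1)   # -1
#' sensitivity_coefficient(100, 105, 1, 1.1)  # +0.5
#' @export
sensitivity_coefficient <- function(pk_base, pk_pert, p_base, p_pert) {
  stopifnot(is.finite(pk_base), is.finite(pk_pert),
            is.finite(p_base), is.finite(p_pert))
  if (pk_base <= 0) stop("'pk_base' must be > 0")
  if (p_base <= 0) stop("'p_base' must be > 0")
  if (p_pert == p_base) stop("'p_pert' must differ from 'p_base'")
  ((pk_pert - pk_base) / (p_pert - p_base)) * (p_base / pk_base)
}

# get/set a numeric scalar inside a nested config by "a.b.c" path
.cfg_get <- function(cfg, path) {
  x <- cfg
  for (k in strsplit(path, ".", fixed = TRUE)[[1]]) {
    if (is.null(x[[k]])) stop("unknown config path: ", path)
    x <- x[[k]]
  }
  if (!is.numeric(x) || length(x) != 1L)
    stop("config path '", path, "' is not a numeric scalar")
  x
}
.cfg_set <- function(cfg, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  rec <- function(x, ks) {
    cls <- class(x)
    if (length(ks) == 1L) x[[ks]] <- value
    else x[[ks[1]]] <- rec(x[[ks[1]]], ks[-1])
    class(x) <- cls
    x
  }
  rec(cfg, keys)
}

#' One-at-a-time local sensitivity analysis
#'
#' Perturbs each named model parameter by a relative step (default +10\%;
#' optionally a central +/- step), re-simulates, and computes the
#' relative sensitivity coefficient of each PK output. Parameters with
#' |S| < 0.05 for every output are flagged as excluded (the screening
#' rule used to pick virtual-population variants). Simulation failures
#' on a perturbed point mark that row failed and the run continues.
#'
#' @param config A [study_preset()]-shaped list (`drug`, `phys`, `disp`,
#'   `dose_mg`, and the formulation in `test_form`).
#' @param parameters Character vector of config paths, e.g.
#'   `"phys.sitt"`, `"phys.segment_ph.jejunum"`, `"disp.cl_hepatic"`,
#'   `"test_form.td50"`, `"drug.elimination.tsmax_spec"`.
#' @param perturbation Relative step (default 0.10).
#' @param outputs PK outputs to score.
#' @param central Use a central difference (simulate at both +step and
#'   -step) instead of the one-sided +step.
#' @param threshold Exclusion threshold on |S| (default 0.05).
#' @param t_grid_h Simulation grid.
#' @return data.frame of class `sensitivity_table`: one row per
#'   (parameter, output) with `s`, `included`, `failed`, plus a
#'   per-parameter rank by max |S|.
#' @export
run_sensitivity <- function(config, parameters, perturbation = 0.10,
                            outputs = c("cmax", "auc_0t", "tmax"),
                            central = FALSE, threshold = 0.05,
                            t_grid_h = seq(0, 48, by = 0.1)) {
  outputs <- match.arg(outputs, c("cmax", "auc_0t", "tmax"),
                       several.ok = TRUE)
  simulate_cfg <- function(cfg) {
    sys <- assemble_odes(cfg$drug, cfg$test_form, cfg$phys, cfg$disp,
                         cfg$dose_mg)
    nca_metrics(simulate_subject(sys, t_grid_h = t_grid_h))
  }
  base_pk <- simulate_cfg(config)

  rows <- list()
  for (p in parameters) {
    res <- tryCatch({
      p0 <- .cfg_get(config, p)
      up <- simulate_cfg(.cfg_set(config, p, p0 * (1 + perturbation)))
      lo <- if (central)
        simulate_cfg(.cfg_set(config, p, p0 * (1 - perturbation)))
      else NULL
      s <- vapply(outputs, function(o) {
        if (central)
          sensitivity_coefficient(base_pk[[o]], up[[o]], p0,
                                  p0 * (1 + perturbation)) / 2 +
            sensitivity_coefficient(base_pk[[o]], lo[[o]], p0,
                                    p0 * (1 - perturbation)) / 2
        else
          sensitivity_coefficient(base_pk[[o]], up[[o]], p0,
                                  p0 * (1 + perturbation))
      }, numeric(1))
      data.frame(parameter = p, output = outputs, s = unname(s),
                 failed = FALSE)
    }, error = function(e) {
      data.frame(parameter = p, output = outputs, s = NA_real_,
                 failed = TRUE)
    })
    rows[[p]] <- res
  }
  tab <- do.call(rbind, rows)
  tab$included <- !tab$failed & abs(tab$s) >= threshold
  # failed parameters have all-NA scores; they rank last
  max_abs <- suppressWarnings(tapply(abs(tab$s), tab$parameter, max,
                                     na.rm = TRUE))
  max_abs[!is.finite(max_abs)] <- -Inf
  tab$rank <- rank(-max_abs, ties.method = "min")[tab$parameter]
  rownames(tab) <- NULL
  class(tab) <- c("sensitivity_table", "data.frame")
  attr(tab, "threshold") <- threshold
  attr(tab, "perturbation") <- perturbation
  tab
}

#' Simulate every cell of a crossover design for one formulation arm
#'
#' Runs the subject-period simulations of the rows of the design table
#' carrying the given treatment label, using each subject's period GI
#' state and constant disposition, and returns NCA metrics per cell.
#'
#' @param subjects [sample_population()] list.
#' @param design [assign_crossover()] design.
#' @param config Study config (`drug`, `disp`, `dose_mg`).
#' @param form [weibull_params()] of the administered formulation.
#' @param treatment `"T"` or `"R"`: which design rows to simulate.
#' @param t_grid_h Simulation grid.
#' @return data.frame: `subject_id, period, treatment, cmax, tmax,
#'   auc_0t`.
#' @export
simulate_design_cells <- function(subjects, design, config, form,
                                  treatment,
                                  t_grid_h = seq(0, 48, by = 0.1)) {
  by_id <- stats::setNames(subjects,
                           vapply(subjects, `[[`, numeric(1), "id"))
  rows <- design$table[design$table$treatment == treatment, ]
  out <- lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    s <- by_id[[as.character(r$subject_id)]]
    g <- if (r$gi_state == 1L) s$gi_state_1 else s$gi_state_2
    m <- tryCatch({
      sys <- assemble_odes(config$drug, form, g, config$disp,
                           config$dose_mg)
      nca_metrics(simulate_subject(sys, t_grid_h = t_grid_h))
    }, error = function(e)
      stop("simulation failed for subject ", r$subject_id, " period ",
           r$period, " (", treatment, "): ", conditionMessage(e)))
    data.frame(subject_id = r$subject_id, period = r$period,
               treatment = treatment, cmax = m$cmax, tmax = m$tmax,
               auc_0t = m$auc_0t)
  })
  do.call(rbind, out)
}

#' Run a virtual bioequivalence trial for one API
#'
#' Simulates every (subject, period, treatment) cell of a 2x2 crossover
#' with the subject's period-specific GI state, runs NCA, and performs
#' the crossover BE analysis for Cmax and AUC0-t. Deterministic given
#' the seed (which drives population sampling and sequence assignment
#' when they are not supplied).
#'
#' @param config Study config ([study_preset()] shape).
#' @param test_form,ref_form [weibull_params()] for the two arms
#'   (default: the config's).
#' @param n Population size (used only when `subjects` is NULL).
#' @param seed Integer seed.
#' @param subjects,design Optional pre-built population and design
#'   (reused across calls, e.g. by the safe-space scan).
#' @param ref_metrics Optional precomputed reference-arm cell metrics
#'   (from [simulate_design_cells()]), reused by the safe-space scan.
#' @param wsv Within-subject GI variability (see [sample_population()]).
#' @param t_grid_h Simulation grid.
#' @return Object of class `vbe_result`: `be` (list of `cmax` and
#'   `auc_0t` [be_crossover_analysis()] results), `pass` (both metrics),
#'   `metrics` (per-cell table), `n`, `seed`.
#' @export
run_vbe <- function(config, test_form = config$test_form,
                    ref_form = config$ref_form, n = 24, seed = 1L,
                    subjects = NULL, design = NULL, ref_metrics = NULL,
                    wsv = TRUE, t_grid_h = seq(0, 48, by = 0.1)) {
  if (is.null(subjects)) {
    subjects <- sample_population(population_spec(n = n, seed = seed),
                                  wsv = wsv)
  }
  if (is.null(design)) design <- assign_crossover(subjects, seed = seed + 1L)
  t_cells <- simulate_design_cells(subjects, design, config, test_form,
                                   "T", t_grid_h)
  r_cells <- if (is.null(ref_metrics))
    simulate_design_cells(subjects, design, config, ref_form, "R",
                          t_grid_h)
  else ref_metrics
  cells <- rbind(t_cells, r_cells)
  be <- lapply(c(cmax = "cmax", auc_0t = "auc_0t"), function(m)
    be_crossover_analysis(design, cells, metric = m))
  structure(list(be = be, pass = all(vapply(be, `[[`, logical(1), "pass")),
                 metrics = cells, n = length(subjects), seed = seed),
            class = "vbe_result")
}

#' @export
print.vbe_result <- function(x, ...) {
  cat(sprintf("VBE trial, n = %d subjects:\n", x$n))
  for (b in x$be) print(b)
  cat(sprintf("overall: %s\n", if (x$pass) "BIOEQUIVALENT" else "NOT BE"))
  invisible(x)
}

#' Fixed-dose-combination verdict over several APIs
#'
#' A combination product is bioequivalent only if every metric of every
#' component passes; one failing component fails the whole product.
#'
#' @param ... [run_vbe()] results, one per API.
#' @return Logical: TRUE iff Cmax and AUC pass for every component.
#' @export
fdc_verdict <- function(...) {
  all(vapply(list(...), function(v) {
    stopifnot(inherits(v, "vbe_result"))
    v$pass
  }, logical(1)))
}
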