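#' Virtual population specification
#'
#' Ranges for the sampled GI physiology parameters and the demographics
#' recorded as metadata. Defaults emulate a fasted healthy adult Asian
#' population of 100 subjects aged 18-60, BMI 19-27, with GI parameter
#' ranges spanning typical fasted physiology.
#'
#' @param n Number of subjects (even, >= 2; sequence balance).
#' @param parameter_ranges Named list of `c(low, high)` uniform ranges
#'   over: segment pH (`ph_stomach`, ..., `ph_rectum`), `get_liquid`,
#'   `get_solid`, `sitt`, `litt` (minutes).
#' @param age_range,bmi_range Demographic metadata ranges.
#' @param seed Integer RNG seed.
#' @return Object of class `population_spec`.
#' @export
population_spec <- function(n = 100,
                            parameter_ranges = default_gi_ranges(),
                            age_range = c(18, 60),
                            bmi_range = c(19, 27),
                            seed = 1L) {
  stopifnot(n >= 2, n %% 2 == 0)
  for (nm in names(parameter_ranges)) {
    b <- parameter_ranges[[nm]]
    if (length(b) != 2L || !(b[1] < b[2]))
      stop("range for '", nm, "' must be c(low, high) with low < high")
  }
  need <- c(paste0("ph_", gi_segment_names),
            "get_liquid", "get_solid", "sitt", "litt")
  if (!all(need %in% names(parameter_ranges)))
    stop("parameter_ranges must cover: ", paste(need, collapse = ", "))
  structure(list(n = as.integer(n), parameter_ranges = parameter_ranges,
                 age_range = age_range, bmi_range = bmi_range,
                 seed = as.integer(seed)),
            class = "population_spec")
}

#' Default GI parameter ranges for the fasted virtual population
#'
#' Uniform sampling ranges: segment pH windows around the fasted
#' defaults, gastric emptying 10-30 min (liquid) / 15-60 min
#' (undisintegrated solid), small-intestinal transit 2-5 h, colonic
#' transit 10-40 h.
#' @return Named list of `c(low, high)` ranges.
#' @export
default_gi_ranges <- function() {
  list(ph_stomach = c(1.3, 2.5), ph_duodenum = c(5.8, 6.5),
       ph_jejunum = c(6.0, 7.0), ph_ileum = c(6.8, 7.5),
       ph_colon = c(5.5, 7.0), ph_rectum = c(6.5, 7.5),
       get_liquid = c(10, 30), get_solid = c(15, 60),
       sitt = c(120, 300), litt = c(600, 2400))
}

.draw_gi_state <- function(ranges, base = gi_physiology()) {
  u <- function(nm) stats::runif(1, ranges[[nm]][1], ranges[[nm]][2])
  ph <- vapply(paste0("ph_", gi_segment_names), u, numeric(1))
  names(ph) <- gi_segment_names
  gi_physiology(segment_ph = ph,
                get_liquid = u("get_liquid"), get_solid = u("get_solid"),
                sitt = u("sitt"), litt = u("litt"),
                segment_volumes = base$segment_volumes,
                segment_surface_area = base$segment_surface_area,
                sitt_split = base$sitt_split, litt_split = base$litt_split)
}

#' Sample a virtual population
#'
#' Draws `n` virtual subjects. Each subject carries two GI physiology
#' states (the within-subject variability entering the crossover: one
#' state per period) drawn independently and uniformly within the spec's
#' ranges, demographics drawn uniformly as metadata, and a disposition
#' held constant across periods. Bit-reproducible for a fixed seed.
#'
#' @param spec A [population_spec()].
#' @param wsv Draw the two GI states independently (`TRUE`, default —
#'   within-subject variability on) or copy state 1 into state 2
#'   (`FALSE`; every subject then presents identical physiology in both
#'   periods, useful for exactness checks).
#' @return List of `virtual_subject` objects: `id`, `gi_state_1`,
#'   `gi_state_2`, `age`, `bmi`.
#' @export
sample_population <- function(spec, wsv = TRUE) {
  stopifnot(inherits(spec, "population_spec"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(spec$seed)
  lapply(seq_len(spec$n), function(i) {
    g1 <- .draw_gi_state(spec$parameter_ranges)
    g2 <- if (wsv) .draw_gi_state(spec$parameter_ranges) else g1
    structure(list(id = i, gi_state_1 = g1, gi_state_2 = g2,
                   age = stats::runif(1, spec$age_range[1], spec$age_range[2]),
                   bmi = stats::runif(1, spec$bmi_range[1], spec$bmi_range[2])),
              class = "virtual_subject")
  })
}

#' Assign a 2x2 crossover design with GI subgroups
#'
#' Randomly splits the subjects into two balanced sequences, TR and RT
#' (test-then-reference and the reverse), labels the GI subgroups (GI1 =
#' period-1 state, GI2 = period-2 state within each sequence), and
#' enumerates the (subject, period, treatment, GI state) table: period 1
#' uses each subject's `gi_state_1`, period 2 `gi_state_2`.
#'
#' @param subjects A [sample_population()] list (even length).
#' @param seed Integer RNG seed for the sequence randomization.
#' @return Object of class `crossover_design`: `sequence` (named by
#'   subject id), `table` (one row per subject-period: `subject_id,
#'   sequence, period, treatment, gi_state`), `n`.
#' @export
assign_crossover <- function(subjects, seed = 1L) {
  n <- length(subjects)
  if (n %% 2 != 0) stop("need an even number of subjects")
  ids <- vapply(subjects, `[[`, numeric(1), "id")
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  tr_ids <- sort(sample(ids, n / 2))
  seqs <- ifelse(ids %in% tr_ids, "TR", "RT")
  names(seqs) <- ids

  tab <- do.call(rbind, lapply(seq_along(ids), function(i) {
    sq <- seqs[[i]]
    data.frame(subject_id = ids[i], sequence = sq, period = c(1L, 2L),
               treatment = if (sq == "TR") c("T", "R") else c("R", "T"),
               gi_state = c(1L, 2L))
  }))
  structure(list(sequence = seqs, table = tab, n = n),
            class = "crossover_design")
}

#' @export
print.crossover_design <- function(x, ...) {
  cat(sprintf("2x2 crossover: %d subjects (%d TR / %d RT)\n", x$n,
              sum(x$sequence == "TR"), sum(x$sequence == "RT")))
  invisible(x)
}

#' Export the design and sampled GI parameters as data.frames
#'
#' One row per subject-period with the sampled GI parameters of the
#' period's GI state, suitable for CSV export.
#'
#' @param subjects A [sample_population()] list.
#' @param design A [assign_crossover()] design.
#' @return data.frame.
#' @export
population_table <- function(subjects, design) {
  by_id <- stats::setNames(subjects,
                           vapply(subjects, `[[`, numeric(1), "id"))
  rows <- lapply(seq_len(nrow(design$table)), function(r) {
    row <- design$table[r, ]
    s <- by_id[[as.character(row$subject_id)]]
    g <- if (row$gi_state == 1L) s$gi_state_1 else s$gi_state_2
    cbind(row,
          as.data.frame(as.list(stats::setNames(
            g$segment_ph, paste0("ph_", gi_segment_names)))),
          data.frame(get_liquid = g$get_liquid, get_solid = g$get_solid,
                     sitt = g$sitt, litt = g$litt,
                     age = s$age, bmi = s$bmi))
  })
  do.call(rbind, rows)
}
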