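#' Residual-error model for synthetic data
#'
#' Additive Gaussian noise for dissolution percent points; combined
#' proportional + additive error for plasma concentrations
#' (`c_obs = c (1 + eps_prop) + eps_add`, floored at 0) — the
#' conventional bioanalytical residual-error form.
#'
#' @param dissolution_sd Additive SD on percent-dissolved points.
#' @param pk_proportional_cv Proportional CV on concentrations.
#' @param pk_additive_sd Additive SD on concentrations, ng/mL.
#' @param seed Integer RNG seed.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(dissolution_sd = 2, pk_proportional_cv = 0.10,
                        pk_additive_sd = 0.5, seed = 1L) {
  stopifnot(dissolution_sd >= 0, pk_proportional_cv >= 0,
            pk_additive_sd >= 0)
  structure(list(dissolution_sd = dissolution_sd,
                 pk_proportional_cv = pk_proportional_cv,
                 pk_additive_sd = pk_additive_sd, seed = as.integer(seed)),
            class = "noise_model")
}

#' In vitro sampling schedules (minutes)
#'
#' The paddle-method sampling grids: 6 points to 60 min for a
#' fast-dissolving API, 10 points to 240 min for a slow one.
#' @param schedule `"metformin"`, `"glyburide"`, or `"custom"` (then
#'   `times` must be given).
#' @param times Custom sampling times, minutes.
#' @return Numeric vector of sampling times.
#' @export
dissolution_schedule <- function(schedule = c("metformin", "glyburide",
                                              "custom"),
                                 times = NULL) {
  schedule <- match.arg(schedule)
  switch(schedule,
         metformin = c(5, 10, 15, 30, 45, 60),
         glyburide = c(5, 10, 15, 30, 45, 60, 90, 120, 180, 240),
         custom = {
           if (is.null(times)) stop("custom schedule needs 'times'")
           times
         })
}

#' Generate noisy in vitro dissolution profiles
#'
#' Emulates a three-medium paddle dissolution test (pH 1.2 / 4.5 / 6.8,
#' 1000 mL, 37 C, 50 rpm): percent dissolved is the Weibull curve plus
#' additive Gaussian noise, clipped to \[0, 105\]. Seeded and
#' bit-reproducible.
#'
#' @param p A [weibull_params()] release specification.
#' @param schedule Sampling schedule (see [dissolution_schedule()]).
#' @param noise A [noise_model()].
#' @param media_ph Media pH values (one profile per medium).
#' @param label Batch label prefix.
#' @param times Custom sampling times when `schedule = "custom"`.
#' @return List of [dissolution_profile()] objects, one per medium.
#' @export
synth_dissolution <- function(p, schedule = "metformin",
                              noise = noise_model(),
                              media_ph = c(1.2, 4.5, 6.8),
                              label = "batch", times = NULL) {
  stopifnot(inherits(p, "weibull_params"), inherits(noise, "noise_model"))
  tt <- dissolution_schedule(schedule, times)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(noise$seed)
  lapply(media_ph, function(ph) {
    pct <- 100 * weibull_fraction(tt, p) +
      stats::rnorm(length(tt), 0, noise$dissolution_sd)
    dissolution_profile(tt, pmin(pmax(pct, 0), 105), medium_ph = ph,
                        label = label)
  })
}

#' Generate a synthetic "observed" clinical PK dataset
#'
#' Sub-samples a true (simulated) concentration profile at the 22-point
#' clinical schedule and applies the residual-error model, flooring at
#' zero. With zero noise this is an exact sub-sampling.
#'
#' @param profile A [simulate_subject()] profile covering 0-48 h.
#' @param noise A [noise_model()].
#' @param n_subjects Number of noisy replicate subjects to emit.
#' @return data.frame: `subject_id, time_h, conc_ng_ml` (22 rows per
#'   subject).
#' @export
synth_observed_pk <- function(profile, noise = noise_model(),
                              n_subjects = 1L) {
  stopifnot(inherits(profile, "concentration_profile"),
            inherits(noise, "noise_model"))
  sched <- clinical_schedule_h
  idx <- match(sched, profile$time_h)
  if (anyNA(idx))
    stop("profile must contain the 22-point clinical schedule times")
  ctrue <- profile$conc_ng_ml[idx]
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(noise$seed)
  do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    cobs <- ctrue * (1 + stats::rnorm(length(ctrue), 0,
                                      noise$pk_proportional_cv)) +
      stats::rnorm(length(ctrue), 0, noise$pk_additive_sd)
    data.frame(subject_id = s, time_h = sched,
               conc_ng_ml = pmax(cobs, 0))
  }))
}

#' Build a self-contained demo study bundle
#'
#' Generates everything the workflow needs for one API — noisy
#' three-medium dissolution CSVs for test and reference batches, a
#' synthetic observed clinical dataset, the study configuration — writes
#' them under `out_dir`, and returns the bundle with a manifest of file
#' checksums. Same seed, same checksums.
#'
#' @param seed Integer seed driving every generator.
#' @param drug `"metformin"` or `"glyburide"`.
#' @param out_dir Directory to write CSVs into (created if needed);
#'   `NULL` keeps the bundle in memory only.
#' @param n_observed Subjects in the synthetic observed dataset.
#' @return List: `config` (the [study_preset()]), `dissolution_test`,
#'   `dissolution_ref` (profile lists), `observed` (data.frame),
#'   `manifest` (file -> md5, when files were written).
#' @export
make_demo_study <- function(seed = 42L, drug = "metformin",
                            out_dir = NULL, n_observed = 12L) {
  cfg <- study_preset(drug)
  sched <- if (drug == "metformin") "metformin" else "glyburide"
  add_sd <- if (drug == "metformin") 5 else 0.5
  nm_t <- noise_model(seed = seed, pk_additive_sd = add_sd)
  nm_r <- noise_model(seed = seed + 1L, pk_additive_sd = add_sd)
  nm_o <- noise_model(seed = seed + 2L, pk_additive_sd = add_sd)

  diss_t <- synth_dissolution(cfg$test_form, sched, nm_t, label = "test")
  diss_r <- synth_dissolution(cfg$ref_form, sched, nm_r, label = "reference")
  true_prof <- simulate_subject(
    assemble_odes(cfg$drug, cfg$ref_form, cfg$phys, cfg$disp, cfg$dose_mg))
  observed <- synth_observed_pk(true_prof, nm_o, n_subjects = n_observed)

  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    f1 <- file.path(out_dir, paste0(drug, "_dissolution_test.csv"))
    f2 <- file.path(out_dir, paste0(drug, "_dissolution_reference.csv"))
    f3 <- file.path(out_dir, paste0(drug, "_observed_pk.csv"))
    write_dissolution_csv(diss_t, f1)
    write_dissolution_csv(diss_r, f2)
    utils::write.csv(observed, f3, row.names = FALSE)
    manifest <- data.frame(file = basename(c(f1, f2, f3)),
                           md5 = unname(tools::md5sum(c(f1, f2, f3))))
  }
  list(config = cfg, dissolution_test = diss_t, dissolution_ref = diss_r,
       observed = observed, manifest = manifest)
}
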