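test_that("assemble_odes validates configuration and zero dose", {
  cfg <- linear_config()
  expect_error(assemble_odes(cfg$drug, cfg$test_form, cfg$phys, cfg$disp,
                             dose_mg = 0), "dose")
  # renal drug without a secretion scale is rejected
  met <- metformin_drug()
  expect_error(assemble_odes(met, weibull_params(10, 1.2),
                             gi_physiology(), disposition_params(vc = 50),
                             dose_mg = 500),
               "secretion_scale")
})

test_that("mass-balance ledger closes on random configurations", {
  set.seed(2024)
  for (i in 1:20) {
    cfg <- random_config()
    sys <- assemble_odes(cfg$drug, cfg$test_form, cfg$phys, cfg$disp,
                         cfg$dose_mg)
    prof <- simulate_subject(sys, t_grid_h = fast_grid)
    led <- mass_balance(prof)
    expect_lt(max(abs(led$total - 1)), 1e-6)
    expect_true(all(prof$conc_ng_ml >= 0))
    expect_equal(prof$conc_ng_ml[1], 0)
  }
})

test_that("iv bolus reduction matches the one-compartment closed form", {
  # one compartment (vp = 0, q = 0), linear clearance CL = 10 L/h on
  # unbound = total (fu = 1): AUC0-inf = Dose/CL, C0 = Dose/Vc
  drug <- linear_drug(cl_plasma = 10)
  disp <- disposition_params(vc = 30, vp = 0, q = 0, cl_hepatic = 10)
  sys <- assemble_odes(drug, weibull_params(10, 1), gi_physiology(),
                       disp, dose_mg = 100, route = "iv")
  prof <- simulate_subject(sys, t_grid_h = seq(0, 48, by = 0.05))
  m <- nca_metrics(prof)
  expect_equal(m$cmax, 100 / 30 * 1000, tolerance = 1e-3)       # ng/mL
  expect_equal(m$auc_0t, 100 / 10 * 1000, tolerance = 1e-3)     # ng*h/mL
  expect_equal(m$tmax, 0)
})

test_that("hazard-only release reproduces the Weibull curve before transit", {
  # no transit (enormous residence times), no absorption, cap off:
  # the luminal dissolved fraction is exactly F(t)
  drug <- drug_parameters("inert", mw = 200, logp = 0, pka_list = list(),
                          ref_solubility = 1e-6, ref_ph = 7,
                          peff_trans = 0, fu = 1,
                          elimination = list(type = "hepatic_linear",
                                             cl_plasma = 5))
  phys <- gi_physiology(get_liquid = 1e7, get_solid = 1e7,
                        sitt = 3e7, litt = 4e7)
  form <- weibull_params(td50 = 40, shape = 1.3)
  sys <- assemble_odes(drug, form, phys,
                       disposition_params(vc = 10, cl_hepatic = 5),
                       dose_mg = 50, solubility_cap = FALSE)
  prof <- simulate_subject(sys, t_grid_h = seq(0, 8, by = 0.1))
  led <- mass_balance(prof)
  expect_equal(led$luminal_dissolved,
               weibull_fraction(led$time_h * 60, form), tolerance = 1e-6)
})

test_that("dose linearity holds in the linear regime", {
  cfg <- linear_config()
  auc <- sapply(c(100, 200), function(d) {
    sys <- assemble_odes(cfg$drug, cfg$test_form, cfg$phys, cfg$disp, d)
    nca_metrics(simulate_subject(sys, t_grid_h = fast_grid))$auc_0t
  })
  expect_equal(auc[2], 2 * auc[1], tolerance = 1e-3)
})

test_that("luminal concentrations never exceed solubility beyond tolerance", {
  cfg <- study_preset("glyburide")
  sys <- assemble_odes(cfg$drug, cfg$ref_form, cfg$phys, cfg$disp,
                       cfg$dose_mg)
  prof <- simulate_subject(sys, t_grid_h = fast_grid, keep_states = TRUE)
  st <- attr(prof, "states")
  seg <- sys$segments
  s_umol <- solubility_at_ph(cfg$drug, seg$ph) * 1e6 / cfg$drug$mw
  for (i in seq_len(nrow(seg))) {
    conc <- st[[paste0("diss_", seg$segment[i])]] / seg$volume_l[i]
    expect_true(all(conc <= s_umol[i] * (1 + 1e-4)),
                label = paste("supersaturation overshoot in",
                              seg$segment[i]))
  }
})

test_that("slower dissolution lowers exposure for a dissolution-limited drug", {
  cfg <- study_preset("glyburide")
  m <- lapply(c(10, 77.22), function(td) {
    f <- weibull_params(td, cfg$test_form$shape)
    sys <- assemble_odes(cfg$drug, f, cfg$phys, cfg$disp, cfg$dose_mg)
    nca_metrics(simulate_subject(sys, t_grid_h = seq(0, 48, by = 0.1)))
  })
  expect_gt(m[[1]]$cmax, m[[2]]$cmax)
  expect_gt(m[[1]]$auc_0t, m[[2]]$auc_0t)
})

test_that("calibrate_disposition is deterministic and degenerate at n_iter = 1", {
  cfg <- linear_config()
  targets <- list(cmax_ref = 1000, auc_ref = 8000)
  space <- list(vc = c(10, 100), cl_hepatic = c(2, 40))
  one_a <- suppressWarnings(
    calibrate_disposition(cfg$drug, cfg$test_form, cfg$phys, cfg$dose_mg,
                          targets, space, n_iter = 1, seed = 3,
                          base_disp = cfg$disp, t_grid_h = fast_grid))
  one_b <- suppressWarnings(
    calibrate_disposition(cfg$drug, cfg$test_form, cfg$phys, cfg$dose_mg,
                          targets, space, n_iter = 1, seed = 3,
                          base_disp = cfg$disp, t_grid_h = fast_grid))
  expect_identical(one_a$disp, one_b$disp)
  expect_identical(one_a$achieved, one_b$achieved)
  expect_equal(one_a$n_iter, 1)
})

test_that("calibrate_disposition recovers self-generated targets within 2%", {
  cfg <- linear_config()
  truth <- disposition_params(vc = 25, vp = 20, q = 10, cl_hepatic = 12)
  sys <- assemble_odes(cfg$drug, cfg$test_form, cfg$phys, truth,
                       cfg$dose_mg)
  m <- nca_metrics(simulate_subject(sys, t_grid_h = fast_grid))
  cal <- calibrate_disposition(
    cfg$drug, cfg$test_form, cfg$phys, cfg$dose_mg,
    targets = list(cmax_ref = m$cmax, auc_ref = m$auc_0t),
    search_space = list(vc = c(12, 50), cl_hepatic = c(6, 24)),
    n_iter = 150, seed = 5,
    base_disp = disposition_params(vc = 25, vp = 20, q = 10,
                                   cl_hepatic = 12),
    t_grid_h = fast_grid)
  expect_true(cal$converged)
  expect_lt(abs(cal$rel_error[["cmax"]]), 0.02)
  expect_lt(abs(cal$rel_error[["auc"]]), 0.02)
})
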