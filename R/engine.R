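#' Reduced systemic disposition parameters
#'
#' A two-compartment disposition standing in for whole-body physiology:
#' central and peripheral volumes with an inter-compartment flow, plus
#' the elimination constants that bridge the drug's specific rates to
#' amount rates. For a renally secreted drug the saturable tubular
#' secretion rate is `secretion_scale * tsmax_spec * Cu / (km + Cu)`
#' (umol/min, `Cu = fu * Cplasma`), optionally plus glomerular
#' filtration `gfr * fu * Cplasma`. For a hepatically cleared drug the
#' rate is `cl_hepatic * Cu` with `cl_hepatic` in L/h.
#'
#' `secretion_scale` (L) and the transporter `capacity_scale` are the two
#' calibrated bridging constants of the reduced model; they make the
#' simulator-internal specific units of the published optimized values
#' dimensionally concrete.
#'
#' @param vc Central volume, L (> 0).
#' @param vp Peripheral volume, L (>= 0).
#' @param q Inter-compartment flow, L/h (>= 0).
#' @param cl_hepatic Hepatic plasma clearance on unbound drug, L/h
#'   (hepatic route; NA otherwise).
#' @param secretion_scale Converts the specific tubular-secretion rate
#'   (umol/L/min) to an amount rate, L (renal route; NA otherwise).
#' @param gfr_filtration Include the glomerular filtration term.
#' @param gfr Glomerular filtration rate, L/min.
#' @return Object of class `disposition_params`.
#' @export
disposition_params <- function(vc, vp = 0, q = 0,
                               cl_hepatic = NA_real_,
                               secretion_scale = NA_real_,
                               gfr_filtration = FALSE, gfr = 0.12) {
  stopifnot(vc > 0, vp >= 0, q >= 0, gfr >= 0)
  if (!is.na(cl_hepatic)) stopifnot(cl_hepatic >= 0)
  if (!is.na(secretion_scale)) stopifnot(secretion_scale >= 0)
  structure(list(vc = vc, vp = vp, q = q, cl_hepatic = cl_hepatic,
                 secretion_scale = secretion_scale,
                 gfr_filtration = gfr_filtration, gfr = gfr),
            class = "disposition_params")
}

# state layout for the 16-state system (amounts, umol)
.state_names <- c(paste0("solid_", gi_segment_names),
                  paste0("diss_", gi_segment_names),
                  "central", "peripheral", "eliminated", "fecal")

#' Assemble the oral-absorption ODE system for one subject
#'
#' Builds the right-hand side of the luminal + systemic mass-balance
#' system: per GI segment a solid and a dissolved pool, then central and
#' peripheral disposition compartments and cumulative eliminated / fecal
#' ledgers (16 states, amounts in umol, time in minutes).
#'
#' Fluxes per segment i:
#' \itemize{
#'   \item dissolution: `h(t) * solid_i * (1 - c_i / S(pH_i))` with the
#'     Weibull hazard `h(t)`; the bracket caps dissolution at the
#'     pH-dependent solubility and turns negative (precipitation back to
#'     the solid pool) if the dissolved pool is supersaturated,
#'   \item transit: first-order flow to the next segment, with separate
#'     gastric emptying rates for solid and dissolved pools; rectal
#'     outflow accumulates as fecal loss,
#'   \item absorption (disabled in the stomach by default): passive
#'     `Peff * SA * c / 1000` plus saturable carrier flux, into the
#'     central compartment.
#' }
#' The right-hand side sums to zero identically, so the dose-fraction
#' ledger closes by construction.
#'
#' @param drug A [drug_parameters()].
#' @param form A [weibull_params()] release specification.
#' @param phys A [gi_physiology()].
#' @param disp A [disposition_params()]; must carry the constants for the
#'   drug's elimination route.
#' @param dose_mg Oral dose, mg (> 0 for `route = "oral"`).
#' @param route `"oral"` (dose starts as gastric solid) or `"iv"` (dose
#'   placed in the central compartment; GI states stay empty).
#' @param absorb_segments Segments allowed to absorb; default all but the
#'   stomach.
#' @param solubility_cap Apply the luminal solubility cap (disable only
#'   for diagnostic runs; the hazard-only system then reproduces the
#'   Weibull cumulative curve exactly).
#' @return Object of class `pbbm_system`: the RHS closure, initial
#'   state, and the assembled segment table.
#' @export
assemble_odes <- function(drug, form, phys, disp, dose_mg,
                          route = c("oral", "iv"),
                          absorb_segments = setdiff(gi_segment_names,
                                                    "stomach"),
                          solubility_cap = TRUE) {
  route <- match.arg(route)
  stopifnot(inherits(drug, "drug_parameters"),
            inherits(form, "weibull_params"),
            inherits(phys, "gi_physiology"),
            inherits(disp, "disposition_params"),
            dose_mg >= 0)
  if (route == "oral" && dose_mg <= 0) stop("oral dose must be > 0")
  elim_type <- drug$elimination$type
  if (elim_type == "renal_mm" && is.na(disp$secretion_scale))
    stop("renal_mm drug needs disposition 'secretion_scale'")
  cl_hep <- if (!is.na(disp$cl_hepatic)) disp$cl_hepatic
            else drug$elimination$cl_plasma
  if (elim_type == "hepatic_linear" && (is.null(cl_hep) || is.na(cl_hep)))
    stop("hepatic_linear drug needs a hepatic clearance")

  seg <- build_gi_segments(phys)
  n <- nrow(seg)
  k_liq <- 1 / seg$residence_min
  k_sol <- 1 / seg$residence_solid_min
  vol <- seg$volume_l
  sa <- seg$surface_cm2
  # segment solubility in umol/L: g/L * 1e6 / (g/mol)
  s_umol <- solubility_at_ph(drug, seg$ph) * 1e6 / drug$mw
  absorb <- seg$segment %in% absorb_segments
  dose_umol <- dose_mg * 1000 / drug$mw
  vp_eff <- max(disp$vp, 1e-12)   # inert when q = 0

  tk <- drug$transporter
  carrier_vmax <- if (is.null(tk)) rep(0, n) else
    tk$vmax * tk$capacity_scale * unname(tk$rel_expression[seg$segment])

  rhs <- function(t, y, parms) {
    solid <- y[1:n]
    diss <- y[(n + 1):(2 * n)]
    ac <- y[2 * n + 1]
    ap <- y[2 * n + 2]

    conc <- diss / vol                       # umol/L
    h <- weibull_hazard(t, form)
    cap <- if (solubility_cap) 1 - conc / s_umol else 1
    dflux <- h * solid * cap                 # umol/min, can be < 0

    out_sol <- k_sol * solid
    out_liq <- k_liq * diss

    a_pass <- ifelse(absorb, passive_flux(drug$peff_trans, sa, pmax(conc, 0)),
                     0)
    a_carr <- if (is.null(tk)) rep(0, n) else {
      cpos <- pmax(conc, 0)
      cn <- cpos^tk$hill_n
      ifelse(absorb & cpos > 0,
             carrier_vmax * cn / (tk$km^tk$hill_n + cn), 0)
    }
    a_tot <- a_pass + a_carr

    dsolid <- -dflux - out_sol + c(0, out_sol[-n])
    ddiss <- dflux - out_liq - a_tot + c(0, out_liq[-n])

    cc <- ac / disp$vc
    cp <- ap / vp_eff
    cu <- drug$fu * cc
    elim <- if (elim_type == "renal_mm") {
      mm <- disp$secretion_scale * drug$elimination$tsmax_spec *
        cu / (drug$elimination$km + cu)
      mm + if (disp$gfr_filtration) disp$gfr * drug$fu * cc else 0
    } else {
      cl_hep / 60 * cu                       # L/h -> L/min
    }
    dist <- disp$q / 60 * (cc - cp)
    dac <- sum(a_tot) - elim - dist
    dap <- dist
    delim <- elim
    dfecal <- out_sol[n] + out_liq[n]

    list(c(dsolid, ddiss, dac, dap, delim, dfecal))
  }

  y0 <- stats::setNames(numeric(2 * n + 4), .state_names)
  if (route == "oral") y0[["solid_stomach"]] <- dose_umol
  else y0[["central"]] <- dose_umol

  structure(list(rhs = rhs, y0 = y0, drug = drug, form = form,
                 phys = phys, disp = disp, dose_mg = dose_mg,
                 dose_umol = dose_umol, route = route, segments = seg,
                 n_seg = n),
            class = "pbbm_system")
}

#' The 22-point clinical sampling schedule (hours)
#'
#' Pre-dose plus 21 post-dose samples to 48 h, the grid of the underlying
#' crossover study design.
#' @export
clinical_schedule_h <- c(0, 0.25, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4, 4.5, 5,
                         6, 6.5, 7, 7.5, 8, 10, 12, 24, 36, 48)

#' Integrate one subject's concentration-time profile
#'
#' Runs the stiff integrator (lsoda) over the assembled system and
#' returns the plasma concentration profile together with a dose-fraction
#' mass-balance ledger at every output time.
#'
#' @param system A [assemble_odes()] system.
#' @param t_grid_h Output times, hours (default: 0 to 48 h, 0.1 h steps
#'   merged with the 22-point clinical schedule).
#' @param rtol,atol Integrator tolerances.
#' @param keep_states Attach the full state matrix (umol per pool at
#'   every output time) as attribute `"states"`.
#' @return Object of class `concentration_profile`: data.frame with
#'   `time_h`, `conc_ng_ml`, plus attributes `drug`, `dose_mg`, and
#'   `mass_balance` (fractions: residual solid, luminal dissolved,
#'   systemic, eliminated, fecal; sums to 1 within solver tolerance).
#' @export
simulate_subject <- function(system, t_grid_h = NULL,
                             rtol = 1e-8, atol = 1e-10,
                             keep_states = FALSE) {
  stopifnot(inherits(system, "pbbm_system"))
  if (is.null(t_grid_h))
    t_grid_h <- sort(unique(c(seq(0, 48, by = 0.1), clinical_schedule_h)))
  stopifnot(all(diff(t_grid_h) > 0), t_grid_h[1] >= 0)
  t_min <- t_grid_h * 60
  if (t_min[1] > 0) t_min <- c(0, t_min)

  sol <- deSolve::lsoda(y = system$y0, times = t_min, func = system$rhs,
                        parms = NULL, rtol = rtol, atol = atol,
                        maxsteps = 50000)
  if (attr(sol, "istate")[1] < 0)
    stop("integrator failure at t = ", utils::tail(sol[, 1], 1),
         " min; last state: ",
         paste(signif(utils::tail(sol, 1)[-1], 4), collapse = ", "))
  sol <- as.data.frame(sol)
  sol <- sol[match(t_grid_h * 60, sol$time), ]

  n <- system$n_seg
  dose <- system$dose_umol
  conc_ng_ml <- sol$central / system$disp$vc * system$drug$mw  # umol/L * g/mol = ng/mL
  conc_ng_ml <- pmax(conc_ng_ml, 0)

  solid_cols <- paste0("solid_", gi_segment_names)
  diss_cols <- paste0("diss_", gi_segment_names)
  ledger <- data.frame(
    time_h = t_grid_h,
    residual_solid = rowSums(sol[solid_cols]) / dose,
    luminal_dissolved = rowSums(sol[diss_cols]) / dose,
    systemic = (sol$central + sol$peripheral) / dose,
    eliminated = sol$eliminated / dose,
    fecal = sol$fecal / dose)
  ledger$total <- rowSums(ledger[, -1])

  out <- structure(data.frame(time_h = t_grid_h, conc_ng_ml = conc_ng_ml),
                   drug = system$drug$name, dose_mg = system$dose_mg,
                   mass_balance = ledger,
                   class = c("concentration_profile", "data.frame"))
  if (keep_states) attr(out, "states") <- sol
  out
}

#' Dose-fraction mass-balance ledger of a simulated profile
#' @param profile A [simulate_subject()] result.
#' @return The ledger data.frame (see [simulate_subject()]).
#' @export
mass_balance <- function(profile) {
  stopifnot(inherits(profile, "concentration_profile"))
  attr(profile, "mass_balance")
}

#' Calibrate the reduced disposition by Monte-Carlo random search
#'
#' Samples candidate disposition (and transporter capacity) parameters
#' log-uniformly within a bounded search space, simulates each candidate,
#' and keeps the candidate minimizing the summed squared log-error of
#' (Cmax, AUC0-t) against the reference targets. Deterministic for a
#' fixed seed.
#'
#' @param drug,form,phys As for [assemble_odes()].
#' @param dose_mg Oral dose, mg.
#' @param targets `list(cmax_ref = ng/mL, auc_ref = ng*h/mL)`, both > 0.
#' @param search_space Named list of `c(low, high)` bounds (low > 0) over
#'   any of `vc, vp, q, cl_hepatic, secretion_scale, capacity_scale`.
#' @param n_iter Number of random candidates.
#' @param seed RNG seed.
#' @param base_disp Baseline [disposition_params()] supplying any field
#'   not searched.
#' @param t_grid_h Simulation grid for candidate evaluation (coarser
#'   grids speed the search; NCA uses this grid).
#' @return List: `disp` (best [disposition_params()]), `capacity_scale`,
#'   `achieved` (cmax, auc), `rel_error` (signed relative errors),
#'   `loss`, `converged` (both |rel errors| <= 0.5), `n_iter`. If no
#'   candidate lands within 50\% of both targets a warning reports the
#'   best-so-far.
#' @export
calibrate_disposition <- function(drug, form, phys, dose_mg, targets,
                                  search_space, n_iter = 200, seed = 1,
                                  base_disp = NULL,
                                  t_grid_h = seq(0, 48, by = 0.25)) {
  stopifnot(targets$cmax_ref > 0, targets$auc_ref > 0, n_iter >= 1)
  allowed <- c("vc", "vp", "q", "cl_hepatic", "secretion_scale",
               "capacity_scale")
  if (!all(names(search_space) %in% allowed))
    stop("search_space names must be among: ", paste(allowed, collapse = ", "))
  for (b in search_space)
    if (length(b) != 2L || b[1] <= 0 || b[2] <= b[1])
      stop("each search_space entry must be c(low, high) with 0 < low < high")
  if (is.null(base_disp)) base_disp <- disposition_params(vc = 50)

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)

  # random search in log space, with the sampling box shrunk around the
  # incumbent every quarter of the budget (still plain seeded Monte Carlo)
  box <- lapply(search_space, log)
  draw <- function() lapply(box, function(b)
    exp(stats::runif(1, b[1], b[2])))
  phase <- max(1L, n_iter %/% 4L)

  best <- NULL
  best_cand <- NULL
  for (i in seq_len(n_iter)) {
    if (i %% phase == 0L && !is.null(best_cand)) {
      box <- mapply(function(b, center) {
        hw <- (b[2] - b[1]) / 4
        c(log(center) - hw, log(center) + hw)
      }, box, best_cand[names(box)], SIMPLIFY = FALSE)
    }
    cand <- draw()
    d <- base_disp
    for (nm in intersect(names(cand),
                         c("vc", "vp", "q", "cl_hepatic", "secretion_scale")))
      d[[nm]] <- cand[[nm]]
    class(d) <- "disposition_params"
    dr <- drug
    if (!is.null(cand$capacity_scale) && !is.null(dr$transporter))
      dr$transporter$capacity_scale <- cand$capacity_scale
    met <- tryCatch({
      sys <- assemble_odes(dr, form, phys, d, dose_mg)
      nca_metrics(simulate_subject(sys, t_grid_h = t_grid_h))
    }, error = function(e) NULL)
    if (is.null(met) || met$cmax <= 0 || met$auc_0t <= 0) next
    loss <- log(met$cmax / targets$cmax_ref)^2 +
      log(met$auc_0t / targets$auc_ref)^2
    if (is.null(best) || loss < best$loss) {
      best <- list(disp = d, capacity_scale = cand$capacity_scale,
                   achieved = met, loss = loss, iter = i)
      best_cand <- cand
    }
  }
  if (is.null(best)) stop("no candidate simulated successfully")
  rel <- c(cmax = best$achieved$cmax / targets$cmax_ref - 1,
           auc = best$achieved$auc_0t / targets$auc_ref - 1)
  converged <- all(abs(rel) <= 0.5)
  if (!converged)
    warning(sprintf(
      "no candidate within 50%% of targets after %d iterations; best-so-far rel errors: cmax %+.1f%%, auc %+.1f%%",
      n_iter, 100 * rel[1], 100 * rel[2]))
  list(disp = best$disp, capacity_scale = best$capacity_scale,
       achieved = best$achieved, rel_error = rel, loss = best$loss,
       converged = converged, n_iter = n_iter)
}

# save/restore the global RNG state without touching it when absent
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
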