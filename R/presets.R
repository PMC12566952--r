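#' Bundled drug presets: a metformin + glyburide combination tablet
#'
#' Published physicochemical and ADME constants for the two APIs of a
#' 500 mg / 2.5 mg immediate-release metformin-glyburide tablet, with the
#' package's calibrated reduced-disposition parameters.
#'
#' Metformin (BCS III): freely soluble strong base, very low passive
#' permeability, apical carrier-mediated (PMAT) uptake with Hill
#' kinetics, negligible protein binding, eliminated unchanged by
#' saturable renal tubular secretion plus glomerular filtration.
#'
#' Glyburide (BCS II): weak acid (pKa 5.3) with strongly pH-dependent
#' solubility anchored at pH 8.31, high permeability, 99\% protein
#' bound, eliminated by linear hepatic clearance of the unbound drug.
#'
#' For metformin's tubular-secretion capacity two published optimized
#' values circulate (85.42 and 68.42 umol/L/min); both ship as named
#' variants, default `"table"` = 85.42.
#'
#' @param tsmax_variant Which optimized TSmax_spec to use: `"table"`
#'   (85.42 umol/L/min) or `"text"` (68.42).
#' @param capacity_scale Carrier capacity bridging constant (umol/min
#'   per native vmax unit); default is the calibrated value.
#' @return A [drug_parameters()] object.
#' @export
metformin_drug <- function(tsmax_variant = c("table", "text"),
                           capacity_scale = 0.4437) {
  tsmax_variant <- match.arg(tsmax_variant)
  tsmax <- c(table = 85.42, text = 68.42)[[tsmax_variant]]
  drug_parameters(
    name = "metformin", mw = 129.16, logp = -1.43,
    pka_list = list(list(value = 2.8, type = "base"),
                    list(value = 11.5, type = "base")),
    ref_solubility = 350.9, ref_ph = 6.8,
    peff_trans = 5.80e-8, fu = 1,
    transporter = transporter_kinetics(
      vmax = 53.36, km = 1320, hill_n = 2.64,
      capacity_scale = capacity_scale),
    elimination = list(type = "renal_mm", tsmax_spec = tsmax, km = 65.6))
}

#' @rdname metformin_drug
#' @export
glyburide_drug <- function() {
  drug_parameters(
    name = "glyburide", mw = 494, logp = 3.75,
    pka_list = list(list(value = 5.3, type = "acid")),
    ref_solubility = 2.06e-3, ref_ph = 8.31,
    peff_trans = 6.27e-5, fu = 0.01,
    elimination = list(type = "hepatic_linear", cl_plasma = 330.2))
}

#' Release (Weibull) presets for the test and reference formulations
#'
#' Fitted release parameters of the combination tablet: metformin test
#' td50 9.7 min / shape 1.37, reference 10 min / 1.22; glyburide test
#' 77.22 min / 1.06, reference 82.78 min / 1.10. Lag 0 throughout.
#'
#' @param drug `"metformin"` or `"glyburide"`.
#' @param arm `"test"` or `"reference"`.
#' @return A [weibull_params()] object.
#' @export
formulation_preset <- function(drug = c("metformin", "glyburide"),
                               arm = c("test", "reference")) {
  drug <- match.arg(drug)
  arm <- match.arg(arm)
  p <- list(
    metformin = list(test = c(9.7, 1.37), reference = c(10, 1.22)),
    glyburide = list(test = c(77.22, 1.06), reference = c(82.78, 1.10)))
  v <- p[[drug]][[arm]]
  weibull_params(td50 = v[1], shape = v[2])
}

#' Full study configuration preset for one API
#'
#' Bundles drug, formulation pair, default fasted physiology, calibrated
#' disposition and label dose into the configuration consumed by the
#' simulation, sensitivity, VBE and safe-space drivers. Disposition
#' values are the package's Monte-Carlo calibration results against the
#' reference-arm geometric means (Cmax 1215.67 ng/mL, AUC 5770.53
#' ng.h/mL for metformin; 67.44 ng/mL, 408.98 ng.h/mL for glyburide).
#'
#' @param drug `"metformin"` or `"glyburide"`.
#' @return List: `drug`, `test_form`, `ref_form`, `phys`, `disp`,
#'   `dose_mg`.
#' @export
study_preset <- function(drug = c("metformin", "glyburide")) {
  drug <- match.arg(drug)
  if (drug == "metformin") {
    list(drug = metformin_drug(),
         test_form = formulation_preset("metformin", "test"),
         ref_form = formulation_preset("metformin", "reference"),
         phys = gi_physiology(),
         disp = disposition_params(vc = 211.4, vp = 32.74, q = 31.73,
                                   secretion_scale = 1.038,
                                   gfr_filtration = TRUE),
         dose_mg = 500)
  } else {
    list(drug = glyburide_drug(),
         test_form = formulation_preset("glyburide", "test"),
         ref_form = formulation_preset("glyburide", "reference"),
         phys = gi_physiology(),
         disp = disposition_params(vc = 2.308, vp = 27.99, q = 0.7167,
                                   cl_hepatic = 330.2),
         dose_mg = 2.5)
  }
}
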