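#' Saturable carrier (transporter) kinetics
#'
#' Hill-type uptake kinetics for an apical intestinal carrier. `vmax` is a
#' specific capacity in the carrier's native (software-internal) unit; it
#' is made dimensionally concrete by `capacity_scale` (umol/min per unit
#' of `vmax`), one of the two calibrated bridging constants of the reduced
#' model.
#'
#' @param vmax Specific transport capacity (native unit, >= 0).
#' @param km Half-saturation luminal concentration, umol/L (> 0).
#' @param hill_n Hill coefficient (> 0); 1 recovers Michaelis-Menten.
#' @param rel_expression Named numeric vector of per-segment relative
#'   expression multipliers over the GI segments (see [gi_segment_names]);
#'   nonnegative, conventionally summing to 1 over the small intestine.
#' @param capacity_scale umol/min carried per unit of `vmax` at
#'   saturation (calibrated; dimensionless bridging constant x flow).
#' @return Object of class `transporter_kinetics`.
#' @export
transporter_kinetics <- function(vmax, km, hill_n = 1,
                                 rel_expression = NULL,
                                 capacity_scale = 1) {
  stopifnot(is.numeric(vmax), vmax >= 0, is.numeric(km), km > 0,
            is.numeric(hill_n), hill_n > 0, capacity_scale >= 0)
  if (is.null(rel_expression)) {
    rel_expression <- c(stomach = 0, duodenum = 0.1, jejunum = 0.45,
                        ileum = 0.45, colon = 0.1, rectum = 0)
  }
  if (!all(gi_segment_names %in% names(rel_expression)))
    stop("'rel_expression' must name all segments: ",
         paste(gi_segment_names, collapse = ", "))
  if (any(rel_expression < 0)) stop("'rel_expression' must be >= 0")
  structure(list(vmax = vmax, km = km, hill_n = hill_n,
                 rel_expression = rel_expression[gi_segment_names],
                 capacity_scale = capacity_scale),
            class = "transporter_kinetics")
}

#' Drug physicochemical and ADME parameters
#'
#' Container for the compound-specific constants of one active
#' pharmaceutical ingredient: physicochemistry (MW, logP, ionization),
#' a reference-pH solubility anchor, intestinal transcellular
#' permeability, plasma protein binding, optional carrier-mediated
#' uptake, and the elimination route.
#'
#' @param name Compound name.
#' @param mw Molecular weight, g/mol (> 0).
#' @param logp Octanol-water log partition coefficient (recorded).
#' @param pka_list List of `list(value=, type=)` entries with `type` in
#'   `"acid"`/`"base"`; may be empty (pH-independent solubility).
#' @param ref_solubility Solubility at `ref_ph`, g/L (> 0).
#' @param ref_ph pH at which `ref_solubility` was measured.
#' @param peff_trans Intestinal transcellular permeability, cm/min (>= 0).
#' @param fu Fraction unbound in plasma, in (0, 1\].
#' @param transporter Optional [transporter_kinetics()].
#' @param elimination Either `list(type="renal_mm", tsmax_spec=, km=)`
#'   (tubular-secretion Michaelis-Menten, umol/L/min and umol/L) or
#'   `list(type="hepatic_linear", cl_plasma=)` (L/h on unbound plasma
#'   concentration).
#' @return Object of class `drug_parameters`.
#' @seealso [metformin_drug()], [glyburide_drug()] for ready presets.
#' @export
drug_parameters <- function(name, mw, logp, pka_list = list(),
                            ref_solubility, ref_ph,
                            peff_trans, fu,
                            transporter = NULL, elimination) {
  stopifnot(is.numeric(mw), mw > 0, is.numeric(ref_solubility),
            ref_solubility > 0, is.numeric(peff_trans), peff_trans >= 0,
            is.numeric(fu), fu > 0, fu <= 1)
  for (pk in pka_list) {
    if (!is.list(pk) || !all(c("value", "type") %in% names(pk)) ||
        !pk$type %in% c("acid", "base"))
      stop("each pka_list entry needs fields value and type ('acid'|'base')")
  }
  if (!is.null(transporter))
    stopifnot(inherits(transporter, "transporter_kinetics"))
  if (!is.list(elimination) || is.null(elimination$type) ||
      !elimination$type %in% c("renal_mm", "hepatic_linear"))
    stop("elimination must be renal_mm or hepatic_linear")
  if (elimination$type == "renal_mm")
    stopifnot(elimination$tsmax_spec > 0, elimination$km > 0)
  if (elimination$type == "hepatic_linear")
    stopifnot(elimination$cl_plasma > 0)
  structure(list(name = name, mw = mw, logp = logp, pka_list = pka_list,
                 ref_solubility = ref_solubility, ref_ph = ref_ph,
                 peff_trans = peff_trans, fu = fu,
                 transporter = transporter, elimination = elimination),
            class = "drug_parameters")
}

#' @export
print.drug_parameters <- function(x, ...) {
  cat(sprintf("Drug: %s (MW %.2f g/mol, logP %.2f, fu %.3g)\n",
              x$name, x$mw, x$logp, x$fu))
  cat(sprintf("  solubility %.3g g/L at pH %.2f; Peff %.3g cm/min\n",
              x$ref_solubility, x$ref_ph, x$peff_trans))
  cat(sprintf("  elimination: %s\n", x$elimination$type))
  invisible(x)
}

#' pH-dependent aqueous solubility (Henderson-Hasselbalch)
#'
#' Scales the reference solubility anchor with ionization. For a
#' monoprotic weak acid \eqn{S(pH) = S_0 (1 + 10^{pH - pKa})}, for a weak
#' base \eqn{S(pH) = S_0 (1 + 10^{pKa - pH})}, where the intrinsic
#' (unionized) solubility \eqn{S_0} is solved from the (ref_ph,
#' ref_solubility) anchor. Multiple ionization centers multiply their
#' enhancement factors. A drug with no pKa has constant solubility.
#'
#' @param drug A [drug_parameters()] object.
#' @param ph pH value(s) in \[0, 14\].
#' @return Solubility in g/L (same length as `ph`).
#' @export
solubility_at_ph <- function(drug, ph) {
  stopifnot(inherits(drug, "drug_parameters"), is.numeric(ph))
  if (any(ph < 0 | ph > 14)) stop("pH must lie in [0, 14]")
  enh <- function(p) {   # ionization enhancement factor at pH p
    f <- 1
    for (pk in drug$pka_list) {
      f <- f * if (pk$type == "acid") 1 + 10^(p - pk$value)
               else 1 + 10^(pk$value - p)
    }
    f
  }
  s0 <- drug$ref_solubility / enh(drug$ref_ph)
  s0 * vapply(ph, enh, numeric(1))
}

#' Carrier-mediated absorption rate (Hill kinetics)
#'
#' \eqn{rate = V_{max,eff} \, c^n / (K_m^n + c^n)} with
#' \eqn{V_{max,eff} = vmax \cdot rel\_expression(segment) \cdot capacity\_scale}.
#'
#' @param k A [transporter_kinetics()] object.
#' @param c_lumen Luminal concentration, umol/L (>= 0, vectorized).
#' @param segment Segment name (see [gi_segment_names]).
#' @return Absorption rate, umol/min.
#' @export
carrier_flux <- function(k, c_lumen, segment) {
  stopifnot(inherits(k, "transporter_kinetics"))
  if (any(c_lumen < 0)) stop("negative luminal concentration")
  if (!segment %in% gi_segment_names) stop("unknown segment: ", segment)
  vmax_eff <- k$vmax * k$rel_expression[[segment]] * k$capacity_scale
  cn <- c_lumen^k$hill_n
  ifelse(c_lumen == 0, 0, vmax_eff * cn / (k$km^k$hill_n + cn))
}

#' Passive transcellular absorption rate (sink conditions)
#'
#' Linear flux law \eqn{rate = P_{eff} \cdot SA \cdot c / 1000} with
#' permeability in cm/min, surface area in cm2 and concentration in
#' umol/L, giving umol/min (the 1000 converts cm3 to L).
#'
#' @param peff Effective transcellular permeability, cm/min.
#' @param sa Absorptive surface area, cm2.
#' @param c_lumen Luminal concentration, umol/L.
#' @return Absorption rate, umol/min.
#' @export
passive_flux <- function(peff, sa, c_lumen) {
  stopifnot(peff >= 0, sa >= 0, all(c_lumen >= 0))
  peff * sa * c_lumen / 1000
}
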