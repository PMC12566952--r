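# default fasted-state segment physiology; all overridable via
# gi_physiology() arguments. Surface areas are effective mucosal areas
# (villi-amplified in the small intestine), cm2.
.default_ph <- c(stomach = 1.8, duodenum = 6.0, jejunum = 6.5,
                 ileum = 7.0, colon = 6.5, rectum = 6.8)
.default_volumes <- c(stomach = 0.05, duodenum = 0.03, jejunum = 0.10,
                      ileum = 0.10, colon = 0.05, rectum = 0.01)
.default_sa <- c(stomach = 5e2, duodenum = 2e5, jejunum = 9e5,
                 ileum = 9e5, colon = 5e4, rectum = 1e3)

#' Gastrointestinal physiology for one state of one subject
#'
#' Per-segment pH, fluid volumes and absorptive surface areas together
#' with the transit-time parameters of the six-segment chain: gastric
#' emptying of liquid (dissolved) and of the undisintegrated solid
#' fraction, small-intestinal transit time (split across duodenum /
#' jejunum / ileum) and large-intestinal transit time (colon + rectum).
#'
#' @param segment_ph Named vector of pH per segment, each in \[1, 9\].
#' @param get_liquid Gastric emptying time for dissolved drug, min.
#' @param get_solid Gastric emptying time for the undisintegrated solid
#'   fraction, min.
#' @param sitt Small-intestinal transit time, min.
#' @param litt Large-intestinal (colon + rectum) transit time, min.
#' @param segment_volumes Named vector of luminal fluid volumes, L.
#' @param segment_surface_area Named vector of absorptive areas, cm2.
#' @param sitt_split Fractions of `sitt` spent in duodenum/jejunum/ileum.
#' @param litt_split Fractions of `litt` spent in colon/rectum.
#' @return Object of class `gi_physiology`.
#' @export
gi_physiology <- function(segment_ph = .default_ph,
                          get_liquid = 15, get_solid = 30,
                          sitt = 210, litt = 1500,
                          segment_volumes = .default_volumes,
                          segment_surface_area = .default_sa,
                          sitt_split = c(duodenum = 0.10, jejunum = 0.45,
                                         ileum = 0.45),
                          litt_split = c(colon = 0.80, rectum = 0.20)) {
  for (v in list(segment_ph, segment_volumes, segment_surface_area)) {
    if (!all(gi_segment_names %in% names(v)))
      stop("segment maps must name all of: ",
           paste(gi_segment_names, collapse = ", "))
  }
  if (any(segment_ph < 1 | segment_ph > 9)) stop("segment pH must be in [1, 9]")
  stopifnot(get_liquid > 0, get_solid > 0, sitt > 0, litt > 0,
            all(segment_volumes > 0), all(segment_surface_area > 0),
            abs(sum(sitt_split) - 1) < 1e-9, abs(sum(litt_split) - 1) < 1e-9)
  structure(list(segment_ph = segment_ph[gi_segment_names],
                 get_liquid = get_liquid, get_solid = get_solid,
                 sitt = sitt, litt = litt,
                 segment_volumes = segment_volumes[gi_segment_names],
                 segment_surface_area = segment_surface_area[gi_segment_names],
                 sitt_split = sitt_split, litt_split = litt_split),
            class = "gi_physiology")
}

#' Build the ordered GI segment chain with transit rates
#'
#' Expands a [gi_physiology()] into the six-segment series used by the
#' ODE engine. Residence times: stomach uses `get_liquid` for the
#' dissolved pool and `get_solid` for the solid pool; the small
#' intestine splits `sitt` 10:45:45 over duodenum:jejunum:ileum by
#' default and the large intestine splits `litt` 80:20 over colon:rectum.
#' Each segment's first-order outflow rate is 1/residence.
#'
#' @param phys A [gi_physiology()].
#' @return A data.frame with one row per segment: `segment, ph, volume_l,
#'   surface_cm2, residence_min` (liquid-phase) and `residence_solid_min`
#'   (differing from liquid only in the stomach).
#' @export
build_gi_segments <- function(phys) {
  stopifnot(inherits(phys, "gi_physiology"))
  res <- c(stomach = phys$get_liquid,
           duodenum = phys$sitt * phys$sitt_split[["duodenum"]],
           jejunum = phys$sitt * phys$sitt_split[["jejunum"]],
           ileum = phys$sitt * phys$sitt_split[["ileum"]],
           colon = phys$litt * phys$litt_split[["colon"]],
           rectum = phys$litt * phys$litt_split[["rectum"]])
  res_solid <- res
  res_solid[["stomach"]] <- phys$get_solid
  data.frame(segment = gi_segment_names,
             ph = unname(phys$segment_ph),
             volume_l = unname(phys$segment_volumes),
             surface_cm2 = unname(phys$segment_surface_area),
             residence_min = unname(res),
             residence_solid_min = unname(res_solid),
             row.names = NULL)
}
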