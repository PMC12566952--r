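# shared fixtures: small, fast configurations built in code

# coarse simulation grid for tests that do not need Cmax precision
fast_grid <- seq(0, 48, by = 0.25)

# a simple one-compartment, linear-clearance drug with pH-independent
# high solubility: behaves linearly (no carrier, no MM, cap never binds)
linear_drug <- function(cl_plasma = 10) {
  drug_parameters(name = "probe", mw = 200, logp = 1,
                  pka_list = list(),
                  ref_solubility = 100, ref_ph = 7,
                  peff_trans = 5e-4, fu = 1,
                  elimination = list(type = "hepatic_linear",
                                     cl_plasma = cl_plasma))
}

linear_config <- function(cl_plasma = 10, vc = 30) {
  list(drug = linear_drug(cl_plasma),
       test_form = weibull_params(td50 = 20, shape = 1.2),
       ref_form = weibull_params(td50 = 20, shape = 1.2),
       phys = gi_physiology(),
       disp = disposition_params(vc = vc, vp = 20, q = 10,
                                 cl_hepatic = cl_plasma),
       dose_mg = 100)
}

# random valid configuration for property sweeps (seeded by caller)
random_config <- function() {
  ph <- c(stomach = runif(1, 1.3, 2.5), duodenum = runif(1, 5.8, 6.5),
          jejunum = runif(1, 6.0, 7.0), ileum = runif(1, 6.8, 7.5),
          colon = runif(1, 5.5, 7.0), rectum = runif(1, 6.5, 7.5))
  phys <- gi_physiology(segment_ph = ph,
                        get_liquid = runif(1, 10, 30),
                        get_solid = runif(1, 15, 60),
                        sitt = runif(1, 120, 300),
                        litt = runif(1, 600, 2400))
  drug <- drug_parameters(
    name = "rand", mw = runif(1, 100, 500), logp = 0,
    pka_list = if (runif(1) < 0.5)
      list(list(value = runif(1, 3, 8),
                type = sample(c("acid", "base"), 1)))
    else list(),
    ref_solubility = 10^runif(1, -3, 2), ref_ph = runif(1, 5, 8),
    peff_trans = 10^runif(1, -7, -3), fu = runif(1, 0.05, 1),
    elimination = list(type = "hepatic_linear",
                       cl_plasma = runif(1, 2, 50)))
  list(drug = drug,
       test_form = weibull_params(td50 = runif(1, 5, 120),
                                  shape = runif(1, 0.8, 2)),
       phys = phys,
       disp = disposition_params(vc = runif(1, 5, 100),
                                 vp = runif(1, 5, 100),
                                 q = runif(1, 1, 50),
                                 cl_hepatic = runif(1, 2, 50)),
       dose_mg = runif(1, 1, 500))
}
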