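# Shared fixtures: small surfaces and tables built in code.

# A single-genus surface with controllable amplitudes and noise.
# `dominant_amp` applies to co2_pct; all other factors get `other_amp`.
tiny_surface <- function(design = build_design(), genus = "Testus",
                         dominant_amp = 0.6, other_amp = 0.2,
                         noise_sd = 0, responses = c("biomass"),
                         bounds = c(0, 10), base = 2) {
  colour_levels <- design_levels(design, "light_colour")
  rs <- lapply(responses, function(rn) {
    effects <- lapply(design_factors(design), function(f) {
      amp <- if (f == "co2_pct") dominant_amp else other_amp
      if (f == "light_colour") {
        stats::setNames(c(amp, amp * 0.3, amp * 0.15, 0), colour_levels)
      } else {
        opt <- design_baseline(design)[[f]]
        list(optimum = opt, amplitude = amp)
      }
    })
    names(effects) <- design_factors(design)
    list(base = base, effects = effects, noise_sd = noise_sd, bounds = bounds)
  })
  names(rs) <- responses
  genus_surface(genus, design, rs)
}

# A surface list whose table carries all nine response columns (needed by
# functions that assume the full schema).
tiny_full_surface <- function(design = build_design(), noise_sd = 0) {
  tiny_surface(design, responses = response_names(), noise_sd = noise_sd)
}

# Small complete experiment table (one genus, zero noise unless stated).
tiny_table <- function(seed = 1, noise_sd = 0, replicates = 2,
                       design = build_design()) {
  generate_experiment(design, list(tiny_full_surface(design, noise_sd)),
                      replicates = replicates, seed = seed)
}

expect_tibble_equal <- function(a, b, tol = 1e-12) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tol)
}
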