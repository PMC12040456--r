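test_that("zero-noise generation reproduces surface values exactly", {
  design <- build_design()
  surface <- tiny_full_surface(design, noise_sd = 0)
  tab <- generate_experiment(design, list(surface), replicates = 2, seed = 3)
  for (i in sample.int(nrow(tab), 10)) {
    cond <- as.list(tab[i, design_factors(design)])
    for (rn in response_names()) {
      expect_equal(tab[[rn]][i], surface_value(surface, rn, cond))
    }
  }
})

test_that("row counts follow the OFAT combinatorics", {
  tab <- generate_experiment(replicates = 3, seed = 1)
  expect_equal(nrow(tab), 20 * 3 * 5)  # levels x replicates x genera
  expect_equal(length(unique(tab$genus)), 5)
  counts <- table(tab$genus, tab$varied_factor)
  expect_true(all(counts == 4 * 3))
})

test_that("identical seeds give identical tables; different seeds differ", {
  a <- generate_experiment(replicates = 3, seed = 11)
  b <- generate_experiment(replicates = 3, seed = 11)
  c <- generate_experiment(replicates = 3, seed = 12)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("seed and valid surfaces are required", {
  expect_error(generate_experiment(replicates = 3), "seed")
  expect_error(generate_experiment(replicates = 0, seed = 1), ">= 1")
  d_small <- build_design(overrides = list(co2_pct = list(levels = c(5, 7))))
  # surface built on the full design references levels the small design lacks
  expect_error(
    generate_experiment(d_small, list(tiny_full_surface(build_design())),
                        replicates = 2, seed = 1),
    "levels absent"
  )
})

test_that("no generated response leaves its declared bounds", {
  design <- build_design()
  # noise large relative to the bounds so clipping must engage
  surface <- tiny_surface(design, noise_sd = 5, responses = response_names(),
                          bounds = c(0, 4), base = 1,
                          dominant_amp = 1, other_amp = 0.3)
  tab <- generate_experiment(design, list(surface), replicates = 10, seed = 5)
  for (rn in response_names()) {
    expect_true(all(tab[[rn]] >= 0 & tab[[rn]] <= 4))
  }
  # and the default study surfaces keep biomass inside 0.2-2.1 g/l
  def <- generate_experiment(replicates = 3, seed = 2)
  expect_true(all(def$biomass >= 0.2 & def$biomass <= 2.1))
})

test_that("per-condition means recover the noiseless surface", {
  design <- build_design()
  surface <- default_surfaces(design)[["Chlorella"]]
  tab <- generate_experiment(design, list(surface), replicates = 200,
                             seed = 42)
  grouped <- dplyr::group_by(tab,
                             dplyr::across(dplyr::all_of(design_factors(design))))
  for (rn in c("biomass", "protein", "na")) {
    sd_n <- surface$responses[[rn]]$noise_sd
    sums <- dplyr::summarise(grouped, m = mean(.data[[rn]]),
                             n = dplyr::n(), .groups = "drop")
    for (i in seq_len(nrow(sums))) {
      cond <- as.list(sums[i, design_factors(design)])
      expected <- surface_value(surface, rn, cond)
      expect_lt(abs(sums$m[i] - expected), 3 * sd_n / sqrt(200))
    }
  }
})

test_that("planted truth reports dominance and observable optimum", {
  design <- build_design()
  s <- tiny_surface(design, dominant_amp = 1, other_amp = 0.1)
  tt <- planted_truth(list(s))
  expect_equal(tt$dominant_factor, "co2_pct")
  # optimum is the all-baseline condition for this surface
  expect_equal(tt$co2_pct, 9)
  expect_equal(tt$light_colour, "white")
  expect_equal(tt$optimum_value,
               surface_value(s, "biomass", design_baseline(design)))

  # equal amplitudes tie-break to the first factor in design order
  s_tie <- tiny_surface(design, dominant_amp = 0.2, other_amp = 0.2)
  expect_equal(planted_truth(list(s_tie))$dominant_factor, "co2_pct")

  # a surface with effects in a single factor names that factor
  s_one <- tiny_surface(design, dominant_amp = 0, other_amp = 0)
  s_one$responses$biomass$effects$pH$amplitude <- 0.5
  expect_equal(planted_truth(list(s_one))$dominant_factor, "pH")

  expect_error(planted_truth(list()), "non-empty")
})

test_that("default surfaces carry the planted study structure", {
  truth <- planted_truth(default_surfaces())
  expect_equal(nrow(truth), 5 * 9)
  # dominant factor is 3x the others by construction
  s <- default_surfaces()[["Closterium"]]
  amps <- vapply(design_factors(s$design), function(f) {
    phycofactor:::effect_amplitude(s, "biomass", f)
  }, numeric(1))
  expect_equal(unname(max(amps) / sort(amps, decreasing = TRUE)[2]), 3,
               tolerance = 1e-9)
  # every planted optimum differs from baseline in at most one factor,
  # so it is observable under the OFAT layout
  base <- design_baseline(build_design())
  fx <- names(base)
  for (i in seq_len(nrow(truth))) {
    diffs <- sum(vapply(fx, function(f) {
      !identical(truth[[f]][i], base[[f]])
    }, logical(1)))
    expect_lte(diffs, 1)
  }
})
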