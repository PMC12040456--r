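test_that("indicator columns pool into their source factor before normalizing", {
  raw <- c(colA = 0.3, colB = 0.3, colC = 0.2, colD = 0.2)
  cmap <- c(colA = "light_colour", colB = "light_colour",
            colC = "pH", colD = "co2_pct")
  prof <- impurity_importance(raw, cmap, genus = "g", response = "r")
  expect_equal(unname(prof$scores[c("light_colour", "pH", "co2_pct")]),
               c(0.6, 0.2, 0.2))
  expect_equal(sum(prof$scores), 1, tolerance = 1e-9)
  expect_false(prof$no_signal)
  expect_error(impurity_importance(raw, cmap[1:3]), "does not cover")
})

test_that("profiles normalize to one on fitted ensembles", {
  tab <- generate_experiment(replicates = 3, seed = 20)
  prof <- factor_importance(tab, "Chlorella", "biomass", seed = 1)
  expect_equal(sum(prof$scores), 1, tolerance = 1e-9)
  expect_true(all(prof$scores >= 0))
  expect_named(prof$scores, design_factors(build_design()))
})

test_that("a constant target yields a flagged all-zero profile", {
  tab <- tiny_table(seed = 5, noise_sd = 0, replicates = 2)
  tab$biomass <- 1  # no signal at all
  prof <- factor_importance(tab, "Testus", "biomass", seed = 1)
  expect_true(prof$no_signal)
  expect_equal(unname(prof$scores), rep(0, 5))
})

test_that("top-factor ranking uses design-order tie-breaking", {
  p1 <- impurity_importance(c(a = 0.61, b = 0.22, c = 0.17),
                            c(a = "co2_pct", b = "light_intensity_lux",
                              c = "pH"), genus = "g1", response = "biomass")
  expect_equal(rank_factors(list(p1))$top_factor, "co2_pct")

  tied <- impurity_importance(c(a = 0.5, b = 0.5),
                              c(a = "temperature_C", b = "pH"),
                              genus = "g", response = "r")
  expect_equal(rank_factors(list(tied))$top_factor, "temperature_C")

  single <- impurity_importance(c(a = 1), c(a = "pH"),
                                genus = "g", response = "r")
  expect_equal(rank_factors(list(single))$top_factor, "pH")
  expect_error(rank_factors(list()), "non-empty")
})

test_that("profile averaging is idempotent, symmetric and matches the oracle", {
  mk <- function(scores, genus) {
    impurity_importance(stats::setNames(scores, paste0("c", seq_along(scores))),
                        stats::setNames(paste0("f", seq_along(scores)),
                                        paste0("c", seq_along(scores))),
                        genus = genus, response = "biomass")
  }
  p <- mk(c(0.7, 0.3), "a")
  same <- average_profiles(list(p, p))
  expect_equal(same$scores, p$scores)
  expect_equal(same$genus, "average")

  opp <- average_profiles(list(mk(c(1, 0), "a"), mk(c(0, 1), "b")))
  expect_equal(unname(opp$scores), c(0.5, 0.5))

  withr::local_seed(7)
  profs <- lapply(1:5, function(i) {
    v <- runif(4)
    mk(v / sum(v), paste0("g", i))
  })
  avg <- average_profiles(profs)
  manual <- colMeans(do.call(rbind, lapply(profs, `[[`, "scores")))
  expect_equal(avg$scores, manual / sum(manual), tolerance = 1e-12)

  bad <- mk(c(0.5, 0.5), "x")
  bad$response <- "lipid"
  expect_error(average_profiles(list(p, bad)), "mix responses")
})

test_that("noiseless data recovers the planted optimum exactly", {
  design <- build_design()
  tab <- tiny_table(seed = 2, noise_sd = 0, replicates = 2)
  oc <- find_optimal_conditions(tab, "biomass", "Testus", design)
  base <- design_baseline(design)
  for (f in design_factors(design)) {
    expect_identical(oc[[f]], base[[f]])
  }
  expect_equal(oc$n_obs, 5 * 2)  # baseline condition shared by all series
  expect_equal(oc$mean_response,
               surface_value(tiny_full_surface(design), "biomass", base))
  expect_error(find_optimal_conditions(tab, "biomass", "Klingon"), "unknown genus")
  expect_error(find_optimal_conditions(tab, "unobtainium", "Testus"),
               "unknown response")
})

test_that("exact mean ties resolve to the design-order smallest condition", {
  design <- build_design()
  tab <- tiny_table(seed = 2, noise_sd = 0, replicates = 1)
  # force every condition to the same response value
  tab$biomass <- 1
  oc <- find_optimal_conditions(tab, "biomass", "Testus", design)
  # smallest condition in design-order lexicographic terms: first level of
  # the first factor, baselines elsewhere
  expect_equal(oc$co2_pct, 5)
  expect_equal(oc$temperature_C, 30)
  expect_equal(oc$light_colour, "white")
})

test_that("the full importance report covers all genera, responses and the average", {
  tab <- generate_experiment(replicates = 3, seed = 30)
  spec <- make_model("random_forest", list(num_trees = 50))
  rep <- importance_report(tab, spec = spec, seed = 2)
  expect_setequal(unique(rep$profiles$genus),
                  c(sort(unique(tab$genus)), "average"))
  expect_setequal(unique(rep$profiles$response), response_names())
  sums <- tapply(rep$profiles$score,
                 paste(rep$profiles$genus, rep$profiles$response), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_equal(nrow(rep$top_factors), 6 * 9)
})
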