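random_groups <- function(n_per = 8, g = 3, p = 4, shift = 0) {
  grp <- rep(paste0("g", seq_len(g)), each = n_per)
  y <- matrix(rnorm(n_per * g * p), n_per * g, p)
  y[grp == "g2", 1] <- y[grp == "g2", 1] + shift
  out <- as.data.frame(y)
  names(out) <- paste0("r", seq_len(p))
  out$grp <- grp
  out
}

test_that("H + E recovers the total SSCP (brute-force oracle)", {
  withr::local_seed(21)
  tab <- random_groups(n_per = 7, g = 3, p = 4, shift = 1)
  resp <- paste0("r", 1:4)
  pair <- sscp(tab, resp, "grp")
  y <- as.matrix(tab[resp])
  total <- crossprod(sweep(y, 2, colMeans(y)))  # direct summation
  expect_equal(pair$H + pair$E, total, ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(pair$df_h, 2)
  expect_equal(pair$df_e, nrow(tab) - 3)
  expect_equal(pair$H, t(pair$H))
  expect_equal(pair$E, t(pair$E))
})

test_that("equal group means give a zero hypothesis matrix", {
  tab <- data.frame(r1 = rep(c(1, 2), 3), r2 = rep(c(0, 4), 3),
                    grp = rep(c("a", "b", "c"), each = 2))
  pair <- sscp(tab, c("r1", "r2"), "grp")
  expect_equal(pair$H, matrix(0, 2, 2), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("one response reduces to the univariate between-group SS", {
  withr::local_seed(5)
  tab <- random_groups(n_per = 6, g = 2, p = 1, shift = 2)
  pair <- sscp(tab, "r1", "grp")
  fit <- stats::aov(r1 ~ grp, data = tab)
  ss <- summary(fit)[[1]][["Sum Sq"]]
  expect_equal(unname(pair$H[1, 1]), ss[1], tolerance = 1e-10)
  expect_equal(unname(pair$E[1, 1]), ss[2], tolerance = 1e-10)
})

test_that("group structure is validated", {
  tab <- data.frame(r1 = 1:4, grp = c("a", "a", "a", "a"))
  expect_error(sscp(tab, "r1", "grp"), "2 groups")
  tab2 <- data.frame(r1 = 1:4, grp = c("a", "a", "a", "b"))
  expect_error(sscp(tab2, "r1", "grp"), "2 observations")
})

test_that("the four statistics match the stats::manova oracle", {
  withr::local_seed(33)
  for (rep in 1:5) {
    tab <- random_groups(n_per = 8, g = 3, p = 4, shift = runif(1, 0, 2))
    resp <- paste0("r", 1:4)
    res <- manova_tests(sscp(tab, resp, "grp"))
    fit <- stats::manova(as.matrix(tab[resp]) ~ grp, data = tab)
    for (nm in c(Wilks = "Wilks", Pillai = "Pillai",
                 `Hotelling-Lawley` = "Hotelling-Lawley", Roy = "Roy")) {
      ref <- summary(fit, test = nm)$stats[1, ]
      mine <- res$tests[res$tests$statistic == nm, ]
      expect_equal(mine$value, unname(ref[2]), tolerance = 1e-8)
      expect_equal(mine$F, unname(ref[3]), tolerance = 1e-8)
      expect_equal(mine$df1, unname(ref[4]), tolerance = 1e-8)
      expect_equal(mine$df2, unname(ref[5]), tolerance = 1e-8)
      expect_equal(mine$p, unname(ref[6]), tolerance = 1e-8)
    }
  }
})

test_that("Wilks equals the determinant ratio and the eigen identity holds", {
  withr::local_seed(8)
  for (rep in 1:20) {
    tab <- random_groups(n_per = 6, g = 3, p = 3, shift = runif(1, 0, 3))
    pair <- sscp(tab, paste0("r", 1:3), "grp")
    res <- manova_tests(pair)
    wilks <- res$tests$value[res$tests$statistic == "Wilks"]
    expect_equal(wilks, det(pair$E) / det(pair$H + pair$E), tolerance = 1e-10)
    expect_equal(wilks * prod(1 + res$eigenvalues), 1, tolerance = 1e-10)
  }
})

test_that("a null effect yields (1, 0, 0, 0) and p near 1", {
  tab <- data.frame(r1 = rep(c(1, 2, 3), 3), r2 = rep(c(0, 4, 1), 3),
                    grp = rep(c("a", "b", "c"), each = 3))
  res <- manova_tests(sscp(tab, c("r1", "r2"), "grp"))
  vals <- stats::setNames(res$tests$value, res$tests$statistic)
  expect_equal(unname(vals["Wilks"]), 1, tolerance = 1e-12)
  expect_equal(unname(vals["Pillai"]), 0, tolerance = 1e-12)
  expect_equal(unname(vals["Hotelling-Lawley"]), 0, tolerance = 1e-12)
  expect_equal(unname(vals["Roy"]), 0, tolerance = 1e-12)
  expect_true(all(res$tests$p > 0.999))
})

test_that("with one response all four F values equal the ANOVA F", {
  withr::local_seed(13)
  tab <- random_groups(n_per = 7, g = 3, p = 1, shift = 1.5)
  res <- manova_tests(sscp(tab, "r1", "grp"))
  f_uni <- summary(stats::aov(r1 ~ grp, data = tab))[[1]][["F value"]][1]
  expect_equal(res$tests$F, rep(f_uni, 4), tolerance = 1e-10)
})

test_that("statistics are scale equivariant and monotone in evidence", {
  withr::local_seed(55)
  tab <- random_groups(n_per = 6, g = 3, p = 3, shift = 1)
  resp <- paste0("r", 1:3)
  res1 <- manova_tests(sscp(tab, resp, "grp"))
  scaled <- tab
  scaled[resp] <- scaled[resp] * 7.3
  res2 <- manova_tests(sscp(scaled, resp, "grp"))
  expect_equal(res1$tests$value, res2$tests$value, tolerance = 1e-10)

  # growing a group-mean shift strengthens the evidence monotonically
  base <- random_groups(n_per = 6, g = 2, p = 3, shift = 0)
  vals <- sapply(c(0.5, 1, 2), function(s) {
    shifted <- base
    shifted[shifted$grp == "g2", resp] <-
      sweep(as.matrix(shifted[shifted$grp == "g2", resp]), 2, rep(s, 3), "+")
    manova_tests(sscp(shifted, resp, "grp"))$tests$value
  })
  expect_true(all(diff(vals[1, ]) <= 0))  # Wilks decreases
  expect_true(all(diff(vals[2, ]) >= 0))  # Pillai increases
  expect_true(all(diff(vals[3, ]) >= 0))  # Hotelling-Lawley increases
  expect_true(all(diff(vals[4, ]) >= 0))  # Roy increases
})

test_that("singular error matrices are reported, not regularized", {
  tab <- data.frame(r1 = c(1, 2, 3, 4, 5, 6),
                    grp = rep(c("a", "b"), each = 3))
  tab$r2 <- tab$r1 * 2  # exactly collinear responses
  pair <- sscp(tab, c("r1", "r2"), "grp")
  expect_error(manova_tests(pair), "singular")
})

test_that("per-genus MANOVA covers every genus plus the pooled run", {
  tab <- generate_experiment(replicates = 3, seed = 14)
  res <- manova_by_genus(tab)
  expect_setequal(unique(res$genus), c(sort(unique(tab$genus)), "all"))
  expect_equal(nrow(res), 6 * 4)
  # the planted factor structure is strongly significant everywhere
  expect_true(all(res$p < 1e-6))
})
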