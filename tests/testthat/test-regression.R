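# Depression regressions: averaging, OLS, and the slope/interaction tests.

make_summarized <- function(df) {
  class(df) <- c("summarized_dataset", "data.frame")
  df
}

# noiseless summarized dataset from an explicit ploidy-model truth
noiseless_ploidy_cells <- function(b0 = 5, b1 = -0.3, b2 = 0, b3 = 0) {
  cells <- expand.grid(field = 1, genotype = "G1", ploidy = 0:1,
                       lineage = 1:3, generation = c(0, 1, 3, 5, 7))
  cells$year <- 2009
  cells$trait <- "y"
  cells$mean_value <- b0 + b1 * cells$generation + b2 * cells$ploidy +
    b3 * cells$generation * cells$ploidy
  make_summarized(cells)
}

test_that("averaging collapses plants to cell means with the right cardinality", {
  d <- data.frame(year = 2009, field = 1, genotype = "G1", ploidy = 0,
                  lineage = 1, generation = 0, plant_id = 1:3, trait = "y",
                  value = c(10, 12, 14))
  s <- average_replicates(d)
  expect_equal(nrow(s), 1)
  expect_equal(s$mean_value, 12)
  expect_equal(s$n_plants, 3)
  # single-plant cell passes its value through
  s1 <- average_replicates(d[1, ])
  expect_equal(s1$mean_value, 10)
  # minimal trial: 1080 plant records -> 90 cells (30 per lineage)
  tm <- trait_model("additive_dosage", effect = rep(0.1, 5), sigma_e = 0.2)
  full <- generate_field_dataset(trial_design(traits = "y"), tm, seed = 8)
  sf <- average_replicates(full)
  expect_equal(nrow(sf), 90)
  expect_equal(nrow(sf[sf$lineage == 1, ]), 30)
})

test_that("noiseless constructions are interpolated exactly", {
  s <- noiseless_ploidy_cells(b0 = 5, b1 = -0.3)
  f <- fit_ploidy_model(s, "y")
  est <- stats::setNames(f$coefficients$estimate, f$coefficients$term)
  expect_equal(unname(est["generation"]), -0.3, tolerance = 1e-12)
  expect_equal(unname(est["ploidy"]), 0, tolerance = 1e-12)
  expect_equal(unname(est["generation:ploidy"]), 0, tolerance = 1e-12)
  s2 <- noiseless_ploidy_cells(b0 = 5, b1 = -0.3, b3 = -0.1)
  f2 <- fit_ploidy_model(s2, "y")
  est2 <- stats::setNames(f2$coefficients$estimate, f2$coefficients$term)
  expect_equal(unname(est2["generation:ploidy"]), -0.1, tolerance = 1e-12)
})

test_that("OLS coefficients reproduce the normal-equations oracle", {
  set.seed(99)
  for (i in 1:5) {
    cells <- expand.grid(field = 1, genotype = "G1", ploidy = 0:1,
                         lineage = 1:3, generation = c(0, 1, 3, 5, 7))
    cells$year <- 2009; cells$trait <- "y"
    cells$mean_value <- stats::rnorm(nrow(cells))
    f <- fit_ploidy_model(make_summarized(cells), "y")
    X <- cbind(1, cells$generation, cells$ploidy,
               cells$generation * cells$ploidy)
    beta <- oracle_ols(X, cells$mean_value)
    expect_equal(f$coefficients$estimate, beta, tolerance = 1e-10)
  }
})

test_that("fits are invariant to record order and centering the generation", {
  set.seed(3)
  cells <- noiseless_ploidy_cells()
  cells$mean_value <- cells$mean_value + stats::rnorm(nrow(cells), 0, 0.2)
  f <- fit_ploidy_model(cells, "y")
  shuffled <- cells[sample(nrow(cells)), ]
  fs <- fit_ploidy_model(make_summarized(shuffled), "y")
  expect_equal(f$coefficients, fs$coefficients, tolerance = 1e-10)
  centered <- cells
  centered$generation <- centered$generation - mean(unique(c(0, 1, 3, 5, 7)))
  # centering is not a legal generation coding for the schema check, so fit
  # directly: slope and interaction must be unchanged, intercept terms not
  fc <- stats::lm(mean_value ~ generation * ploidy, centered)
  est <- stats::setNames(f$coefficients$estimate, f$coefficients$term)
  expect_equal(unname(stats::coef(fc)["generation"]),
               unname(est["generation"]), tolerance = 1e-10)
  expect_equal(unname(stats::coef(fc)["generation:ploidy"]),
               unname(est["generation:ploidy"]), tolerance = 1e-10)
})

test_that("genotype model recovers per-genotype slope differences exactly", {
  cells <- expand.grid(field = 1, genotype = c("A", "B"), ploidy = 1,
                       lineage = 1:3, generation = c(0, 1, 3, 5, 7),
                       stringsAsFactors = FALSE)
  cells$year <- 2009; cells$trait <- "y"
  slopes <- c(A = -0.3, B = -0.5)
  cells$mean_value <- 5 + slopes[cells$genotype] * cells$generation
  f <- fit_genotype_model(make_summarized(cells), "y")
  est <- stats::setNames(f$coefficients$estimate, f$coefficients$term)
  expect_equal(unname(est["generation"]), -0.3, tolerance = 1e-12)
  expect_equal(unname(est["generation:genoB"]), -0.2, tolerance = 1e-12)
  # identical slopes -> zero interaction and a joint F of 0 (p = 1)
  cells$mean_value <- 5 - 0.3 * cells$generation
  f0 <- fit_genotype_model(make_summarized(cells), "y")
  est0 <- stats::setNames(f0$coefficients$estimate, f0$coefficients$term)
  expect_equal(unname(est0["generation:genoB"]), 0, tolerance = 1e-12)
  it <- test_interaction(f0)
  expect_equal(it$p_value, 1)
})

test_that("depression and interaction decisions handle signs and boundaries", {
  s <- noiseless_ploidy_cells(b1 = -0.3)
  dep <- test_depression(fit_ploidy_model(s, "y"))
  expect_true(dep$depression_present)
  expect_equal(dep$p_one_sided, 0)
  s_up <- noiseless_ploidy_cells(b1 = +0.2)
  expect_false(test_depression(fit_ploidy_model(s_up, "y"))$depression_present)
  s_flat <- noiseless_ploidy_cells(b1 = 0)
  dep0 <- test_depression(fit_ploidy_model(s_flat, "y"))
  expect_false(dep0$depression_present)  # strict inequality at the boundary
  # noiseless beta3 = 0 -> statistic 0, p = 1; beta3 != 0 -> p = 0
  it0 <- test_interaction(fit_ploidy_model(noiseless_ploidy_cells(b3 = 0), "y"))
  expect_equal(it0$p_value, 1)
  it1 <- test_interaction(fit_ploidy_model(noiseless_ploidy_cells(b3 = -0.1),
                                           "y"))
  expect_equal(it1$p_value, 0)
})

test_that("rank-deficient or degenerate designs are explicit errors", {
  s <- noiseless_ploidy_cells()
  one_gen <- make_summarized(s[s$generation == 3, ])
  expect_error(fit_ploidy_model(one_gen, "y"), "generations")
  one_ploidy <- make_summarized(s[s$ploidy == 0, ])
  expect_error(fit_ploidy_model(one_ploidy, "y"), "ploidies")
  expect_error(fit_genotype_model(s, "y"), "genotypes")
  expect_error(average_replicates(s[0, c("year", "field", "genotype",
                                         "ploidy", "lineage", "generation",
                                         "trait", "mean_value")]))
})

test_that("the beta3 t-test is calibrated near the nominal level (short run)", {
  n_rep <- 300
  rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    d <- generate_linear_dataset(beta0 = 5, beta1 = -0.3, beta2 = 0.2,
                                 beta3 = 0, sigma_e = 0.5, seed = 5000 + i)
    s <- average_replicates(d)
    rej[i] <- test_interaction(fit_ploidy_model(s, "trait", field = 1))$p_value < 0.05
  }
  # binomial 99% band around 0.05 at 300 replicates
  expect_lt(abs(mean(rej) - 0.05), 0.033)
})
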