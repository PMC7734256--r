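# Exact single-locus selfing genetics.

test_that("gamete distributions reproduce the exact textbook fractions", {
  # duplex, no double reduction: enumerate the C(4,2) = 6 pairs of AABB
  g <- gamete_distribution(locus_genotype(4, 2))
  expect_identical(g$num, c(1, 4, 1))
  expect_identical(g$den, 6)
  # homozygote emits only AA regardless of alpha
  hom <- gamete_distribution(locus_genotype(4, 4),
                             segregation_model("double_reduction", 1/6))
  expect_equal(unname(probabilities(hom)), c(0, 0, 1))
  # maximal double reduction: P(AA) = a/2 + (1-a)/6 = 2/9 at a = 1/6
  dr <- gamete_distribution(locus_genotype(4, 2),
                            segregation_model("double_reduction", 1/6))
  expect_equal(probabilities(dr)[["2"]], 2/9)
  # forced unlike-bivalent duplex: 1:2:1
  fb <- gamete_distribution(locus_genotype(4, 2),
                            segregation_model("forced_unlike_bivalent"))
  expect_identical(fb$num, c(1, 2, 1))
  expect_identical(fb$den, 4)
  expect_equal(unname(probabilities(fb)), oracle_forced_duplex())
  # diploid heterozygote: 1/2, 1/2
  expect_equal(unname(probabilities(gamete_distribution(locus_genotype(2, 1)))),
               c(1/2, 1/2))
})

test_that("tetraploid gamete distributions match exhaustive chromosome enumeration", {
  for (d in 0:4) {
    for (a in c(0, 1/12, 1/6)) {
      m <- if (a == 0) segregation_model() else
        segregation_model("double_reduction", a)
      expect_equal(
        unname(probabilities(gamete_distribution(locus_genotype(4, d), m))),
        oracle_gamete_tetraploid(d, a),
        tolerance = 1e-12,
        info = sprintf("dosage %d, alpha %.4f", d, a))
    }
  }
})

test_that("selfed-progeny distributions give the classical series", {
  # duplex, alpha = 0: 1:8:18:8:1 over dosages, AAAA at 1/36
  pd <- selfing_progeny_distribution(locus_genotype(4, 2))
  expect_identical(pd$num, c(1, 8, 18, 8, 1))
  expect_identical(pd$den, 36)
  expect_equal(probabilities(pd)[["4"]], 1/36)
  # diploid heterozygote: 1/4, 1/2, 1/4 -> half the progeny homozygous
  pd2 <- selfing_progeny_distribution(locus_genotype(2, 1))
  expect_identical(pd2$num, c(1, 2, 1))
  expect_identical(pd2$den, 4)
  # forced unlike-bivalent duplex: total homozygotes 1/8
  pf <- selfing_progeny_distribution(locus_genotype(4, 2),
                                     segregation_model("forced_unlike_bivalent"))
  expect_equal(probabilities(pf)[["0"]] + probabilities(pf)[["4"]], 1/8)
})

test_that("allele exchange mirrors gamete and progeny distributions", {
  for (p in c(2, 4)) for (d in 0:p) {
    a <- probabilities(gamete_distribution(locus_genotype(p, d)))
    b <- probabilities(gamete_distribution(locus_genotype(p, p - d)))
    expect_equal(unname(a), rev(unname(b)))
    pa <- probabilities(selfing_progeny_distribution(locus_genotype(p, d)))
    pb <- probabilities(selfing_progeny_distribution(locus_genotype(p, p - d)))
    expect_equal(unname(pa), rev(unname(pb)))
  }
})

test_that("transition matrices are row stochastic with absorbing homozygotes", {
  M2 <- selfing_transition_matrix(2)
  expect_equal(as.matrix(M2),
               rbind(c(1, 0, 0), c(1/4, 1/2, 1/4), c(0, 0, 1)),
               ignore_attr = TRUE)
  for (m in list(segregation_model(),
                 segregation_model("double_reduction", 1/12),
                 segregation_model("forced_unlike_bivalent"))) {
    M <- as.matrix(selfing_transition_matrix(4, m))
    expect_equal(rowSums(M), rep(1, 5), ignore_attr = TRUE)
    expect_equal(M[1, ], c(1, 0, 0, 0, 0), ignore_attr = TRUE)
    expect_equal(M[5, ], c(0, 0, 0, 0, 1), ignore_attr = TRUE)
  }
  # triplex row: gametes of AAAB are {1: 1/2, 2: 1/2}; self-convolve
  M4 <- as.matrix(selfing_transition_matrix(4))
  expect_equal(M4["3", ], c(0, 0, 9, 18, 9) / 36, ignore_attr = TRUE)
})

test_that("homozygosis trajectories match the exact chain values", {
  h2 <- homozygosis_trajectory(locus_genotype(2, 1), generations = 7)
  expect_equal(h2$P_heterozygous[1], 1)
  expect_equal(h2$P_fixed_A[2] + h2$P_fixed_B[2], 1/2)
  expect_equal(h2$P_heterozygous[8], 1/128)
  h4 <- homozygosis_trajectory(locus_genotype(4, 2), generations = 7)
  expect_equal(h4$P_fixed_A[2], 1/36)
  expect_equal(h4$P_heterozygous[1], 1)
  expect_true(attr(h4, "trajectory")$exact)
  # partition sums to one everywhere
  for (h in list(h2, h4))
    expect_equal(h$P_fixed_A + h$P_fixed_B + h$P_heterozygous,
                 rep(1, nrow(h)))
})

test_that("heterozygosity is non-increasing under every mode", {
  models <- list(segregation_model(),
                 segregation_model("double_reduction", 1/24),
                 segregation_model("double_reduction", 1/6),
                 segregation_model("forced_unlike_bivalent"))
  for (m in models) {
    h <- homozygosis_trajectory(locus_genotype(4, 2), m, generations = 12)
    expect_true(all(diff(h$P_heterozygous) <= 1e-12))
  }
  # and decays towards zero
  expect_lt(homozygosis_trajectory(locus_genotype(4, 2),
                                   generations = 60)$P_heterozygous[61], 1e-4)
})

test_that("tetraploid homozygosis is strictly slower than diploid for all alpha", {
  h2 <- homozygosis_trajectory(locus_genotype(2, 1), generations = 10)
  fixed2 <- h2$P_fixed_A + h2$P_fixed_B
  for (a in c(0, 1/24, 1/12, 1/6)) {
    m <- if (a == 0) segregation_model() else
      segregation_model("double_reduction", a)
    h4 <- homozygosis_trajectory(locus_genotype(4, 2), m, generations = 10)
    fixed4 <- h4$P_fixed_A + h4$P_fixed_B
    expect_true(all(fixed4[-1] < fixed2[-1]),
                info = sprintf("alpha = %.4f", a))
  }
})

test_that("class ratios scale to the smallest palindromic integers", {
  expect_identical(unname(expected_class_ratio()), c(1L, 8L, 18L, 8L, 1L))
  expect_identical(
    unname(expected_class_ratio(segregation_model("forced_unlike_bivalent"))),
    c(1L, 4L, 6L, 4L, 1L))
  r <- expected_class_ratio(segregation_model("double_reduction", 1/12))
  expect_identical(unname(r), rev(unname(r)))
})

test_that("invalid genotypes and models are rejected", {
  expect_error(locus_genotype(3, 1), "ploidy")
  expect_error(locus_genotype(4, 5), "dosage")
  expect_error(segregation_model("double_reduction", 0.2), "1/6")
  expect_error(segregation_model("random_chromosome", 0.1), "alpha")
  expect_error(gamete_distribution(locus_genotype(2, 1),
                                   segregation_model("forced_unlike_bivalent")),
               "tetraploid")
})
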