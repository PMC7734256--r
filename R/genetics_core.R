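# Exact single-locus genetics of selfing at ploidy 2 and 4.
#
# A biallelic locus (alleles A and B) is tracked by the dosage of A.  Gametes
# of a tetraploid carry two chromosomes; three segregation models are
# supported:
#
#   random_chromosome      tetrasomic segregation with the centromere as the
#                          marker: 2 of the 4 homologues drawn without
#                          replacement (alpha = 0)
#   double_reduction       with probability alpha one homologue is drawn and
#                          duplicated into the gamete (sister-derived copies
#                          travel together); otherwise as above.  alpha is the
#                          classical double-reduction coefficient, 0..1/6.
#   forced_unlike_bivalent unlike homologues pair preferentially into
#                          bivalents that disjoin independently at random.
#                          For a duplex (AABB) this gives gametes 1:2:1 and a
#                          total homozygous-progeny frequency of 1/8 per
#                          generation, vs 1/2 in a diploid.

#' Genotype of one biallelic locus
#'
#' @param ploidy Integer, 2 (diploid) or 4 (autotetraploid).
#' @param dosage Integer count of the reference allele A, between 0 and
#'   `ploidy`.  A diploid heterozygote is `locus_genotype(2, 1)`; the duplex
#'   tetraploid AABB is `locus_genotype(4, 2)`.
#' @return An object of class `locus_genotype`.
#' @examples
#' locus_genotype(4, 2)  # duplex AABB
#' @export
locus_genotype <- function(ploidy, dosage) {
  if (length(ploidy) != 1L || !ploidy %in% c(2, 4))
    stop("ploidy must be 2 or 4")
  if (length(dosage) != 1L || dosage != round(dosage) ||
      dosage < 0 || dosage > ploidy)
    stop("dosage must be an integer in 0..ploidy")
  structure(list(ploidy = as.integer(ploidy), dosage = as.integer(dosage)),
            class = "locus_genotype")
}

#' @export
print.locus_genotype <- function(x, ...) {
  cat(sprintf("<locus_genotype> ploidy %d, dosage %d (%s)\n",
              x$ploidy, x$dosage,
              paste0(strrep("A", x$dosage), strrep("B", x$ploidy - x$dosage))))
  invisible(x)
}

#' Segregation model for gamete formation
#'
#' @param mode One of `"random_chromosome"` (tetrasomic, no double reduction),
#'   `"double_reduction"` (two-branch mixture with coefficient `alpha`), or
#'   `"forced_unlike_bivalent"` (unlike homologues pair preferentially, each
#'   bivalent disjoining independently at random).
#' @param alpha Double-reduction coefficient, a probability in \[0, 1/6\].
#'   Only used in `double_reduction` mode; `random_chromosome` is the
#'   `alpha = 0` special case.  `alpha` is rationalised internally so all
#'   downstream probabilities are exact fractions.
#' @return An object of class `segregation_model`.
#' @examples
#' segregation_model()                              # tetrasomic, alpha = 0
#' segregation_model("double_reduction", alpha = 1/6)
#' @export
segregation_model <- function(mode = c("random_chromosome", "double_reduction",
                                       "forced_unlike_bivalent"),
                              alpha = 0) {
  mode <- match.arg(mode)
  if (length(alpha) != 1L || !is.finite(alpha) || alpha < 0)
    stop("alpha must be a single probability in [0, 1/6]")
  fr <- .as_fraction(alpha)
  if (6 * fr[["num"]] > fr[["den"]])
    stop("alpha must not exceed 1/6 (maximal double reduction)")
  if (mode != "double_reduction" && alpha != 0)
    stop("alpha is only meaningful in double_reduction mode")
  structure(list(mode = mode,
                 alpha = unname(fr[["num"]] / fr[["den"]]),
                 alpha_frac = fr),
            class = "segregation_model")
}

#' @export
print.segregation_model <- function(x, ...) {
  cat(sprintf("<segregation_model> %s", x$mode))
  if (x$mode == "double_reduction")
    cat(sprintf(", alpha = %s", .frac_chr(x$alpha_frac[["num"]],
                                          x$alpha_frac[["den"]])))
  cat("\n")
  invisible(x)
}

#' Exact gamete dosage distribution
#'
#' Distribution of the reference-allele dosage in one gamete produced by a
#' genotype under a segregation model.  Diploid gametes carry one chromosome,
#' tetraploid gametes two.  All probabilities are exact fractions.
#'
#' In `double_reduction` mode the gamete is formed, with probability `alpha`,
#' by drawing one homologue uniformly and duplicating it, and otherwise by
#' drawing 2 of the 4 homologues without replacement.  In
#' `forced_unlike_bivalent` mode unlike homologues pair wherever possible and
#' each bivalent sends one member to the gamete independently; for dosages 1
#' and 3 this coincides with random chromosome segregation, and for the
#' duplex it gives the 1:2:1 gamete ratio.
#'
#' @param genotype A [locus_genotype()].
#' @param model A [segregation_model()].
#' @return An [exact_dist()] over gamete dosages `0:(ploidy/2)`.
#' @examples
#' gamete_distribution(locus_genotype(4, 2))  # 1/6, 4/6, 1/6
#' @export
gamete_distribution <- function(genotype, model = segregation_model()) {
  stopifnot(inherits(genotype, "locus_genotype"),
            inherits(model, "segregation_model"))
  d <- genotype$dosage
  if (genotype$ploidy == 2L) {
    if (model$mode == "forced_unlike_bivalent")
      stop("forced_unlike_bivalent is a tetraploid pairing model")
    return(exact_dist(c(2 - d, d), 2, 0:1))
  }
  if (model$mode == "forced_unlike_bivalent") {
    num <- switch(as.character(d),
                  "0" = c(4, 0, 0),
                  "1" = c(2, 2, 0),
                  "2" = c(1, 2, 1),
                  "3" = c(0, 2, 2),
                  "4" = c(0, 0, 4))
    return(exact_dist(num, 4, 0:2))
  }
  # hypergeometric branch: 2 of 4 homologues without replacement (/6)
  hyper <- choose(d, 0:2) * choose(4 - d, 2 - (0:2))
  # double-reduction branch: one homologue duplicated (/4)
  dr <- c(4 - d, 0, d)
  an <- model$alpha_frac[["num"]]
  ad <- model$alpha_frac[["den"]]
  num <- (ad - an) * 2 * hyper + an * 3 * dr
  exact_dist(num, 12 * ad, 0:2)
}

#' Exact selfed-progeny dosage distribution
#'
#' Distribution of progeny dosage after one generation of self-pollination:
#' the sum of two independent gametes drawn from [gamete_distribution()].
#' For the duplex tetraploid with `alpha = 0` this is the classical
#' 1:8:18:8:1 series over dosages 4..0, with homozygote AAAA at 1/36; the
#' diploid heterozygote gives 1/4, 1/2, 1/4.
#'
#' @inheritParams gamete_distribution
#' @return An [exact_dist()] over progeny dosages `0:ploidy`.
#' @examples
#' selfing_progeny_distribution(locus_genotype(4, 2))
#' @export
selfing_progeny_distribution <- function(genotype, model = segregation_model()) {
  g <- gamete_distribution(genotype, model)
  pd <- .dist_convolve(g, g)
  # embed on the full 0:ploidy support
  support <- 0:genotype$ploidy
  num <- numeric(length(support))
  num[pd$support + 1L] <- pd$num
  exact_dist(num, pd$den, support)
}

#' Selfing transition matrix over dosage states
#'
#' Row-stochastic matrix of one generation of selfing: row `d` is the
#' selfed-progeny distribution of a genotype with dosage `d`.  States 0 and
#' `ploidy` are absorbing.  Entries are exact: the object stores integer
#' numerators over a common denominator.
#'
#' @param ploidy 2 or 4.
#' @param model A [segregation_model()].
#' @return An object of class `transition_matrix` with fields `num`
#'   (integer matrix), `den` (scalar) and `ploidy`; `as.matrix()` returns the
#'   numeric matrix.
#' @examples
#' as.matrix(selfing_transition_matrix(2))
#' @export
selfing_transition_matrix <- function(ploidy, model = segregation_model()) {
  if (!ploidy %in% c(2, 4)) stop("ploidy must be 2 or 4")
  states <- 0:ploidy
  rows <- lapply(states, function(d)
    selfing_progeny_distribution(locus_genotype(ploidy, d), model))
  den <- Reduce(.lcm2, vapply(rows, `[[`, numeric(1), "den"))
  num <- t(vapply(rows, function(r) r$num * (den / r$den),
                  numeric(length(states))))
  dimnames(num) <- list(states, states)
  structure(list(num = num, den = den, ploidy = as.integer(ploidy)),
            class = "transition_matrix")
}

#' @export
as.matrix.transition_matrix <- function(x, ...) x$num / x$den

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> ploidy %d, common denominator %s\n",
              x$ploidy, format(x$den)))
  fr <- matrix(.frac_chr(x$num, x$den), nrow(x$num),
               dimnames = dimnames(x$num))
  print(fr, quote = FALSE)
  invisible(x)
}

#' Dosage distribution across generations of selfing
#'
#' Iterates the selfing chain from a starting genotype, returning the full
#' dosage distribution at every generation 0..T.  Arithmetic is exact
#' rational while the common denominator stays below 2^51; past that point
#' (possible for double-reduction coefficients with large denominators at
#' deep generations) the iteration continues in double precision, which is
#' accurate to ~1e-16.
#'
#' @param start A [locus_genotype()] for generation 0.
#' @param model A [segregation_model()].
#' @param generations Number of selfing generations T (>= 0).
#' @return A list of class `dosage_trajectory`: `distribution` is a
#'   `(T+1) x (ploidy+1)` numeric matrix (rows = generations 0..T), `exact`
#'   says whether every step was rational, `num`/`den` hold the exact
#'   numerators and per-generation denominators when `exact` is `TRUE`.
#' @export
dosage_trajectory <- function(start, model = segregation_model(),
                              generations = 7) {
  stopifnot(inherits(start, "locus_genotype"),
            generations >= 0, generations == round(generations))
  Tn <- as.integer(generations)
  M <- selfing_transition_matrix(start$ploidy, model)
  k <- start$ploidy + 1L
  dist <- matrix(NA_real_, Tn + 1L, k, dimnames = list(0:Tn, 0:start$ploidy))
  num <- matrix(NA_real_, Tn + 1L, k)
  den <- rep(NA_real_, Tn + 1L)
  v_num <- numeric(k); v_num[start$dosage + 1L] <- 1
  v_den <- 1
  exact <- TRUE
  v_float <- v_num
  dist[1L, ] <- v_num
  num[1L, ] <- v_num; den[1L] <- 1
  if (Tn > 0) for (t in 1:Tn) {
    if (exact && v_den * M$den <= .RAT_MAX) {
      v_num <- as.numeric(v_num %*% M$num)
      v_den <- v_den * M$den
      g <- .gcd(c(v_num, v_den))
      v_num <- v_num / g
      v_den <- v_den / g
      dist[t + 1L, ] <- v_num / v_den
      num[t + 1L, ] <- v_num; den[t + 1L] <- v_den
      v_float <- v_num / v_den
    } else {
      if (exact) {
        exact <- FALSE
        num[] <- NA_real_; den[] <- NA_real_
      }
      v_float <- as.numeric(v_float %*% M$num) / M$den
      dist[t + 1L, ] <- v_float
    }
  }
  structure(list(distribution = dist,
                 exact = exact,
                 num = if (exact) num else NULL,
                 den = if (exact) den else NULL,
                 ploidy = start$ploidy,
                 generations = 0:Tn,
                 model = model),
            class = "dosage_trajectory")
}

#' Homozygosis trajectory under repeated selfing
#'
#' Per-generation partition of the chain's mass into fixation for A (dosage
#' = ploidy), fixation for B (dosage = 0), and remaining heterozygosity.
#' For the diploid heterozygote the heterozygous mass halves each generation
#' ((1/2)^t); for the duplex tetraploid with `alpha = 0` the first-generation
#' fixation probability per allele is 1/36, and homozygosis is strictly
#' slower than in the diploid at every generation.
#'
#' @inheritParams dosage_trajectory
#' @return A data frame with columns `generation`, `P_fixed_A`, `P_fixed_B`,
#'   `P_heterozygous`; the underlying [dosage_trajectory()] is attached as
#'   attribute `"trajectory"`.
#' @examples
#' homozygosis_trajectory(locus_genotype(2, 1), generations = 3)
#' @export
homozygosis_trajectory <- function(start, model = segregation_model(),
                                   generations = 7) {
  tr <- dosage_trajectory(start, model, generations)
  d <- tr$distribution
  out <- data.frame(
    generation = tr$generations,
    P_fixed_A = d[, ncol(d)],
    P_fixed_B = d[, 1L],
    P_heterozygous = rowSums(d[, -c(1L, ncol(d)), drop = FALSE]),
    row.names = NULL
  )
  attr(out, "trajectory") <- tr
  out
}

#' Smallest-integer progeny class ratio for a duplex start
#'
#' Selfed progeny of a duplex tetraploid fall into five parental-constitution
#' classes (4:0, 3:1, 2:2, 1:3, 0:4 copies of allele A vs B).  This scales
#' the exact progeny distribution to its smallest integer ratio — 1:8:18:8:1
#' under random chromosome segregation, 1:4:6:4:1 under forced unlike-bivalent
#' pairing.  The ratio is palindromic by allele-exchange symmetry.
#'
#' @param model A [segregation_model()].
#' @return A named integer vector over classes `4:0 .. 0:4`.
#' @examples
#' expected_class_ratio()  # 1 8 18 8 1
#' @export
expected_class_ratio <- function(model = segregation_model()) {
  pd <- selfing_progeny_distribution(locus_genotype(4, 2), model)
  num <- rev(pd$num)  # class 4:0 first (dosage 4 of allele A)
  ratio <- num / .gcd(num)
  stats::setNames(as.integer(ratio), c("4:0", "3:1", "2:2", "1:3", "0:4"))
}
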