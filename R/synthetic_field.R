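# Synthetic field-trial generator.
#
# Emulates the structure of the inbreeding trial: a randomized complete
# block design with 3 fields (blocks), diploid and tetraploid versions of
# each hybrid genotype, three selfing lineages per genotype, plants measured
# at generations 0 (F1), 1, 3, 5 and 7, at most 12 plants per row, and nine
# phenotypes.  Plant genotypes come from the selfing simulator; trait values
# are produced under one of three genetic architectures so the regression
# stage can be exercised against known truth.

#' The nine measured phenotypes
#'
#' Names of the phenotypes recorded in the field trial, used as the default
#' trait list of [trial_design()].
#'
#' @return A character vector of length 9.
#' @export
maize_traits <- function() {
  c("flowering time", "silk emergence time", "ear length",
    "tassel branch number", "4th week height", "6th week height",
    "adult plant height", "length of the 5th leaf from the top",
    "width of the 5th leaf from the top")
}

#' Genetic architecture mapping dosages to a trait value
#'
#' Three competing architectures:
#' * `recessive_complementation` — a locus contributes `effect` iff at least
#'   one functional (A) allele is present; fully recessive deleterious B.
#'   This is the classical model under which inbreeding depression should be
#'   much slower in tetraploids.
#' * `additive_dosage` — contribution `effect * dosage / ploidy`; since the
#'   mean allele frequency is conserved under selfing, expected trait values
#'   are then identical for matched diploids and tetraploids at every
#'   generation.
#' * `partial_dominance` — blend `effect * ((1 - h) * dosage / ploidy +
#'   h * (dosage >= 1))`, with `h = 0` additive and `h = 1` fully recessive.
#'
#' @param architecture One of the three architectures above.
#' @param effect Positive per-locus effect sizes `a_l`; length sets the
#'   number of loci.
#' @param h Dominance degree in \[0, 1\] (`partial_dominance` only; supplying
#'   it for another architecture warns and ignores it).
#' @param baseline Trait value when no locus contributes.
#' @param sigma_e Environmental (plant-level) Gaussian noise sd, >= 0.
#' @param block_effects Additive per-field shifts (recycled to the number of
#'   fields at generation time); default 0.
#' @return An object of class `trait_model`.
#' @export
trait_model <- function(architecture = c("recessive_complementation",
                                         "additive_dosage",
                                         "partial_dominance"),
                        effect = rep(1, 10), h = 0.5, baseline = 0,
                        sigma_e = 0, block_effects = 0) {
  architecture <- match.arg(architecture)
  if (any(effect <= 0)) stop("per-locus effects must be positive")
  if (sigma_e < 0) stop("sigma_e must be >= 0")
  if (h < 0 || h > 1) stop("h must lie in [0, 1]")
  if (!missing(h) && architecture != "partial_dominance")
    warning("h is ignored outside partial_dominance")
  structure(list(architecture = architecture, effect = effect, h = h,
                 baseline = baseline, sigma_e = sigma_e,
                 block_effects = block_effects),
            class = "trait_model")
}

# per-locus contribution weight as a function of dosage 0..ploidy,
# per unit effect
.dosage_weight <- function(tm, ploidy) {
  d <- 0:ploidy
  switch(tm$architecture,
         recessive_complementation = as.numeric(d >= 1),
         additive_dosage = d / ploidy,
         partial_dominance = (1 - tm$h) * d / ploidy + tm$h * (d >= 1))
}

#' Trait value of one or more plants
#'
#' Deterministic genetic value `baseline + sum_l contribution(l)` plus any
#' noise supplied by the caller.
#'
#' @param dosages Integer vector of per-locus dosages for one plant, or a
#'   plants x loci matrix.
#' @param ploidy 2 or 4.
#' @param tm A [trait_model()]; `length(tm$effect)` must match the number of
#'   loci.
#' @param noise Additive noise, recycled over plants (default 0).
#' @return Numeric trait value(s), one per plant.
#' @examples
#' tm <- trait_model("recessive_complementation", effect = rep(1, 3), baseline = 10)
#' trait_value(c(2, 2, 2), 4, tm)  # all complemented: 13
#' @export
trait_value <- function(dosages, ploidy, tm, noise = 0) {
  if (is.vector(dosages)) dosages <- matrix(dosages, 1L)
  if (ncol(dosages) != length(tm$effect))
    stop("number of loci in dosages does not match length(effect)")
  if (any(dosages < 0 | dosages > ploidy))
    stop("dosages out of range for ploidy ", ploidy)
  w <- .dosage_weight(tm, ploidy)
  genetic <- matrix(w[dosages + 1L], nrow(dosages)) %*% tm$effect
  as.numeric(tm$baseline + genetic + noise)
}

#' Design of a synthetic field trial
#'
#' @param genotypes Either a character vector of hybrid labels (each grown at
#'   both ploidies) or a data frame with columns `genotype` and `ploidy`
#'   (2 or 4) listing the grown entries.
#' @param n_fields Number of fields/blocks (default 3).
#' @param n_lineages Selfing lineages per entry (default 3).
#' @param generations Recorded generations (default `c(0, 1, 3, 5, 7)`).
#' @param plants_per_row Plants measured per row, 1..12 (default 12).
#' @param traits Trait names (default the nine of [maize_traits()]).
#' @param year Passthrough label; one year per generated dataset.
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(genotypes = "W22/B73", n_fields = 3, n_lineages = 3,
                         generations = c(0, 1, 3, 5, 7), plants_per_row = 12,
                         traits = maize_traits(), year = 2009) {
  if (is.character(genotypes))
    genotypes <- data.frame(genotype = rep(genotypes, each = 2),
                            ploidy = rep(c(2, 4), length(genotypes)))
  stopifnot(is.data.frame(genotypes),
            all(c("genotype", "ploidy") %in% names(genotypes)),
            all(genotypes$ploidy %in% c(2, 4)))
  if (plants_per_row < 1 || plants_per_row > 12)
    stop("plants_per_row must lie in 1..12")
  if (n_fields < 1 || n_lineages < 1) stop("counts must be positive")
  structure(list(genotypes = genotypes, n_fields = as.integer(n_fields),
                 n_lineages = as.integer(n_lineages),
                 generations = sort(unique(as.integer(generations))),
                 plants_per_row = as.integer(plants_per_row),
                 traits = traits, year = year),
            class = "trial_design")
}

#' Generate a synthetic field-trial dataset
#'
#' Runs the selfing simulator once per (genotype x ploidy x lineage): the
#' lineage descends by single-seed descent from the fully heterozygous F1,
#' and the plants measured in each field at a recorded generation `t > 0`
#' are independent selfed offspring of the lineage's generation `t - 1`
#' parent (generation-0 plants all carry the F1 genotype).  Every plant is
#' scored for every trait under that trait's model, with independent
#' Gaussian noise and additive field (block) effects.
#'
#' @param design A [trial_design()].
#' @param trait_models A single [trait_model()] (used for every trait) or a
#'   named list with one model per trait in `design$traits`.  All models
#'   must agree on the number of loci.
#' @param model A [segregation_model()] governing tetraploid gametes (the
#'   diploid side always segregates disomically).
#' @param seed Mandatory RNG seed.
#' @param w_het,pollen_only Gametophytic selection, as in [sim_config()].
#' @return A long data frame with the canonical schema
#'   `year, field, genotype, ploidy, lineage, generation, plant_id, trait,
#'   value`, where `ploidy` is the 0/1 indicator (0 = diploid,
#'   1 = tetraploid) used by the regression models.
#' @examples
#' d <- generate_field_dataset(
#'   trial_design(traits = "ear length"),
#'   trait_model("additive_dosage", effect = rep(0.2, 5), baseline = 10),
#'   seed = 1)
#' nrow(d)  # 3 fields x 2 ploidies x 3 lineages x 5 generations x 12 plants
#' @export
generate_field_dataset <- function(design, trait_models,
                                   model = segregation_model(), seed,
                                   w_het = 1, pollen_only = FALSE) {
  stopifnot(inherits(design, "trial_design"))
  if (missing(seed)) stop("seed is required")
  if (inherits(trait_models, "trait_model"))
    trait_models <- stats::setNames(
      rep(list(trait_models), length(design$traits)), design$traits)
  if (!all(design$traits %in% names(trait_models)))
    stop("trait_models must be named after every design trait")
  n_loci <- unique(vapply(trait_models, function(tm) length(tm$effect),
                          integer(1)))
  if (length(n_loci) != 1L)
    stop("all trait models must use the same number of loci")
  set.seed(seed)
  max_t <- max(design$generations)
  np <- design$plants_per_row
  rec <- list(); ri <- 1L
  for (gi in seq_len(nrow(design$genotypes))) {
    p <- design$genotypes$ploidy[gi]
    glab <- design$genotypes$genotype[gi]
    dmodel <- if (p == 2L) segregation_model() else model
    egg <- .gamete_prob_matrix(p, dmodel, if (pollen_only) 1 else w_het)
    pol <- .gamete_prob_matrix(p, dmodel, w_het)
    for (lin in seq_len(design$n_lineages)) {
      # single-seed descent chain shared by all fields (same seed lot)
      chain <- matrix(NA_integer_, max_t + 1L, n_loci)
      chain[1L, ] <- rep(p / 2, n_loci)
      if (max_t > 0) for (t in 1:max_t)
        chain[t + 1L, ] <- .draw_offspring(chain[t, ], 1L, egg, pol)
      for (f in seq_len(design$n_fields)) {
        for (t in design$generations) {
          genomes <- if (t == 0L)
            matrix(rep(p / 2, np * n_loci), np, n_loci)
          else
            .draw_offspring(chain[t, ], np, egg, pol)
          for (tr in design$traits) {
            tm <- trait_models[[tr]]
            blocks <- rep_len(tm$block_effects, design$n_fields)
            noise <- stats::rnorm(np, 0, tm$sigma_e) + blocks[f]
            rec[[ri]] <- data.frame(
              year = design$year, field = f, genotype = glab,
              ploidy = as.integer(p == 4L), lineage = lin, generation = t,
              plant_id = seq_len(np), trait = tr,
              value = trait_value(genomes, p, tm, noise))
            ri <- ri + 1L
          }
        }
      }
    }
  }
  out <- do.call(rbind, rec)
  rownames(out) <- NULL
  out
}

#' Generate a trial dataset from an explicit linear truth
#'
#' Diagnostic generator for the regression stage: plant-level values are
#' drawn directly from a known linear model with Gaussian noise, using the
#' trial's design (fields, lineages, generations, plants per row), so that
#' type-I error and parameter recovery of the depression regressions can be
#' checked against exact truth.
#'
#' With `genotype_slopes = NULL` one genotype is grown at both ploidies and
#' the cell mean is `beta0 + beta1 * gen + beta2 * ploidy + beta3 * gen *
#' ploidy` (`ploidy` the 0/1 indicator).  With a named `genotype_slopes`
#' vector, the listed genotypes are grown at a single ploidy and the mean is
#' `beta0 + slope[genotype] * gen`.
#'
#' @param beta0,beta1,beta2,beta3 Linear-model truth.
#' @param genotype_slopes Optional named numeric vector of per-genotype
#'   slopes.
#' @param ploidy Ploidy level used with `genotype_slopes` (2 or 4).
#' @param n_fields,n_lineages,generations,plants_per_row,year As in
#'   [trial_design()].
#' @param sigma_e Plant-level Gaussian noise sd.
#' @param trait Trait label for the output records.
#' @param seed Mandatory RNG seed.
#' @return A long data frame with the canonical field-dataset schema.
#' @export
generate_linear_dataset <- function(beta0 = 5, beta1 = -0.3, beta2 = 0,
                                    beta3 = 0, genotype_slopes = NULL,
                                    ploidy = 4, n_fields = 3, n_lineages = 3,
                                    generations = c(0, 1, 3, 5, 7),
                                    plants_per_row = 12, sigma_e = 0.5,
                                    trait = "trait", year = 2009, seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  if (is.null(genotype_slopes)) {
    cells <- expand.grid(field = seq_len(n_fields), genotype = "G1",
                         ploidy = c(0L, 1L), lineage = seq_len(n_lineages),
                         generation = generations,
                         stringsAsFactors = FALSE)
    cells$mu <- beta0 + beta1 * cells$generation + beta2 * cells$ploidy +
      beta3 * cells$generation * cells$ploidy
  } else {
    stopifnot(!is.null(names(genotype_slopes)))
    cells <- expand.grid(field = seq_len(n_fields),
                         genotype = names(genotype_slopes),
                         ploidy = as.integer(ploidy == 4),
                         lineage = seq_len(n_lineages),
                         generation = generations,
                         stringsAsFactors = FALSE)
    cells$mu <- beta0 + genotype_slopes[cells$genotype] * cells$generation
  }
  out <- cells[rep(seq_len(nrow(cells)), each = plants_per_row), ]
  out$plant_id <- rep(seq_len(plants_per_row), nrow(cells))
  out$year <- year
  out$trait <- trait
  out$value <- out$mu + stats::rnorm(nrow(out), 0, sigma_e)
  out$mu <- NULL
  rownames(out) <- NULL
  out[, c("year", "field", "genotype", "ploidy", "lineage", "generation",
          "plant_id", "trait", "value")]
}

#' Expected noiseless trait trajectory under selfing
#'
#' Expected trait value per generation computed from the exact selfing chain
#' (no simulation): `baseline + sum_l effect_l * E[weight(dosage_l, t)]`
#' with the dosage distribution from [dosage_trajectory()].  Under
#' `recessive_complementation` this equals
#' `baseline + sum(effect) * P(dosage >= 1 at t)`; under `additive_dosage`
#' it is constant in `t` (allele frequency is a martingale under selfing).
#'
#' @param tm A [trait_model()].
#' @param ploidy 2 or 4 (start is the fully heterozygous F1).
#' @param model A [segregation_model()].
#' @param generations Generations at which to evaluate.
#' @return A data frame with columns `generation`, `expected_value`.
#' @export
expected_trait_trajectory <- function(tm, ploidy,
                                      model = segregation_model(),
                                      generations = c(0, 1, 3, 5, 7)) {
  stopifnot(inherits(tm, "trait_model"))
  tr <- dosage_trajectory(locus_genotype(ploidy, ploidy / 2), model,
                          max(generations))
  w <- .dosage_weight(tm, ploidy)
  ew <- as.numeric(tr$distribution %*% w)
  data.frame(generation = generations,
             expected_value = tm$baseline +
               sum(tm$effect) * ew[generations + 1L])
}

#' Expected depression slope of the noiseless trajectory
#'
#' Least-squares slope of the expected trait value on generation number,
#' the noiseless analogue of the depression coefficient beta1.
#'
#' @inheritParams expected_trait_trajectory
#' @return The scalar slope.
#' @export
expected_depression_slope <- function(tm, ploidy,
                                      model = segregation_model(),
                                      generations = c(0, 1, 3, 5, 7)) {
  tt <- expected_trait_trajectory(tm, ploidy, model, generations)
  unname(stats::coef(stats::lm(expected_value ~ generation, tt))[2])
}

#' Write / read a field dataset as CSV
#'
#' The canonical schema (`year, field, genotype, ploidy, lineage,
#' generation, plant_id, trait, value`) round-trips unchanged.  A comment
#' header records the package version and, when given, the generating seed.
#'
#' @param d A field dataset data frame.
#' @param path Output path.
#' @param seed Optional seed to record in the metadata header.
#' @return `path`, invisibly.
#' @export
write_field_dataset <- function(d, path, seed = NULL) {
  .check_field_schema(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# polyself field dataset, version ",
                      as.character(utils::packageVersion("polyself"))),
               if (!is.null(seed)) paste0("# seed: ", seed)), con)
  utils::write.csv(d, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_field_dataset
#' @export
read_field_dataset <- function(path) {
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  .check_field_schema(d)
  d
}

.check_field_schema <- function(d) {
  need <- c("year", "field", "genotype", "ploidy", "lineage", "generation",
            "plant_id", "trait", "value")
  if (!is.data.frame(d) || !all(need %in% names(d)))
    stop("field dataset must have columns ", paste(need, collapse = ", "))
  if (!all(d$generation %in% c(0, 1, 3, 5, 7)))
    stop("generation codes must be drawn from {0, 1, 3, 5, 7}")
  if (!all(d$ploidy %in% c(0, 1)))
    stop("ploidy must be the 0/1 indicator (0 = diploid, 1 = tetraploid)")
  invisible(d)
}
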