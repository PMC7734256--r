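# Forward Monte-Carlo simulation of multilocus selfing lineages.
#
# Each lineage descends by single-seed descent: every generation two gametes
# are drawn per locus (independently across loci; no linkage map) from the
# exact distributions of genetics_core, and one selfed offspring continues
# the lineage.  Optional gametophytic selection up-weights heterozygous
# tetraploid gametes (dosage 1, i.e. AB) by a factor w_het, on both the egg
# and pollen side by default or on the pollen side only.

#' Configuration of a selfing simulation
#'
#' @param ploidy 2 or 4.
#' @param n_loci Number of independently segregating loci (no linkage).
#' @param start_dosage Starting dosage per locus; default `ploidy / 2`
#'   (fully heterozygous F1: diploid AB or duplex AABB), recycled to
#'   `n_loci`.
#' @param model A [segregation_model()], shared by all loci, or a list of
#'   one model per locus (per-locus double-reduction coefficients).
#' @param n_lineages Number of replicate selfing lineages (field default 3).
#' @param generations Generations at which states are recorded; the
#'   trial's selfing series is `c(0, 1, 3, 5, 7)`.
#' @param w_het Gametophytic selection weight: relative success of
#'   heterozygous (AB) tetraploid gametes, 1 = neutral, > 1 slows
#'   homozygosis.  Ignored at ploidy 2 (one-chromosome gametes cannot be
#'   heterozygous).
#' @param pollen_only Apply `w_het` to the pollen-side gamete only.
#' @param seed Mandatory RNG seed: every run is reproducible.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(ploidy, n_loci = 1L, start_dosage = NULL,
                       model = segregation_model(), n_lineages = 3L,
                       generations = c(0, 1, 3, 5, 7),
                       w_het = 1, pollen_only = FALSE, seed) {
  if (missing(seed)) stop("seed is required for reproducibility")
  if (!ploidy %in% c(2, 4)) stop("ploidy must be 2 or 4")
  if (n_loci < 1 || n_lineages < 1) stop("counts must be positive")
  if (w_het < 0) stop("w_het must be >= 0")
  if (is.null(start_dosage)) start_dosage <- ploidy / 2
  start_dosage <- rep_len(start_dosage, n_loci)
  if (any(start_dosage < 0 | start_dosage > ploidy))
    stop("start_dosage must lie in 0..ploidy")
  if (inherits(model, "segregation_model")) model <- list(model)
  if (!all(vapply(model, inherits, logical(1), "segregation_model")))
    stop("model must be a segregation_model or a list of them")
  if (!length(model) %in% c(1L, n_loci))
    stop("provide one model, or one per locus")
  locus_model <- rep_len(seq_along(model), n_loci)
  if (length(model) == 1L) locus_model <- rep(1L, n_loci)
  generations <- sort(unique(as.integer(generations)))
  if (any(generations < 0)) stop("generations must be >= 0")
  structure(list(ploidy = as.integer(ploidy), n_loci = as.integer(n_loci),
                 start_dosage = as.integer(start_dosage), model = model,
                 locus_model = locus_model,
                 n_lineages = as.integer(n_lineages),
                 generations = generations, w_het = w_het,
                 pollen_only = isTRUE(pollen_only),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# gamete sampling table: rows = parent dosage 0..ploidy, cols = gamete dosage
# 0..ploidy/2; optionally reweighted for gametophytic selection
.gamete_prob_matrix <- function(ploidy, model, w_het = 1) {
  half <- ploidy / 2
  tab <- t(vapply(0:ploidy, function(d)
    unname(probabilities(gamete_distribution(locus_genotype(ploidy, d), model))),
    numeric(half + 1)))
  if (ploidy == 4L && w_het != 1) {
    tab[, 2L] <- tab[, 2L] * w_het
    rs <- rowSums(tab)
    if (any(rs == 0))
      stop("w_het = 0 leaves some genotype with no admissible gamete")
    tab <- tab / rs
  }
  tab
}

# sample one gamete dosage per entry of an integer dosage matrix
.sample_gametes <- function(D, tab) {
  out <- D
  half <- ncol(tab) - 1L
  for (d in unique(as.vector(D))) {
    idx <- which(D == d)
    out[idx] <- sample.int(half + 1L, length(idx), replace = TRUE,
                           prob = tab[d + 1L, ]) - 1L
  }
  out
}

# draw n selfed offspring of one parent dosage vector
.draw_offspring <- function(parent, n, egg_tab, pollen_tab) {
  P <- matrix(rep(parent, each = n), n, length(parent))
  .sample_gametes(P, egg_tab) + .sample_gametes(P, pollen_tab)
}

#' Simulate selfing lineages
#'
#' Runs the forward simulation described in [sim_config()].  At each
#' generation every lineage produces one selfed offspring per locus-set
#' (single-seed descent) which becomes the next parent.
#'
#' @param config A [sim_config()].
#' @return A long data frame of class `lineage_trajectory` with columns
#'   `lineage`, `generation`, `locus`, `dosage`, carrying the config as
#'   attribute `"config"`.
#' @examples
#' tr <- simulate_lineages(sim_config(4, n_lineages = 50, seed = 1))
#' summarize_heterozygosity(tr)
#' @export
simulate_lineages <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  p <- config$ploidy
  max_t <- max(config$generations)
  D <- matrix(rep(config$start_dosage, each = config$n_lineages),
              config$n_lineages, config$n_loci)
  groups <- split(seq_len(config$n_loci), config$locus_model)
  tabs <- lapply(names(groups), function(m) {
    mod <- config$model[[as.integer(m)]]
    list(egg = .gamete_prob_matrix(p, mod,
                                   if (config$pollen_only) 1 else config$w_het),
         pollen = .gamete_prob_matrix(p, mod, config$w_het))
  })
  rec <- vector("list", length(config$generations))
  rec_i <- 1L
  snapshot <- function(t, D) {
    data.frame(lineage = rep(seq_len(nrow(D)), ncol(D)),
               generation = t,
               locus = rep(seq_len(ncol(D)), each = nrow(D)),
               dosage = as.vector(D))
  }
  if (0L %in% config$generations) {
    rec[[rec_i]] <- snapshot(0L, D)
    rec_i <- rec_i + 1L
  }
  if (max_t > 0) for (t in 1:max_t) {
    for (gi in seq_along(groups)) {
      cols <- groups[[gi]]
      sub <- D[, cols, drop = FALSE]
      g1 <- .sample_gametes(sub, tabs[[gi]]$egg)
      g2 <- .sample_gametes(sub, tabs[[gi]]$pollen)
      D[, cols] <- g1 + g2
    }
    if (t %in% config$generations) {
      rec[[rec_i]] <- snapshot(t, D)
      rec_i <- rec_i + 1L
    }
  }
  out <- do.call(rbind, rec)
  attr(out, "config") <- config
  class(out) <- c("lineage_trajectory", "data.frame")
  out
}

#' Summarize heterozygosity and fixation across lineages
#'
#' Averages over lineages and loci at each recorded generation.  With
#' `by_lineage = TRUE`, per-lineage fractions are returned for dispersion
#' checks.
#'
#' @param traj A `lineage_trajectory` from [simulate_lineages()].
#' @param by_lineage Keep lineages separate instead of averaging over them.
#' @return A data frame with columns `generation` (and `lineage` if
#'   requested), `het_fraction`, `fixed_A_fraction`, `fixed_B_fraction`.
#' @export
summarize_heterozygosity <- function(traj, by_lineage = FALSE) {
  stopifnot(inherits(traj, "lineage_trajectory"), nrow(traj) > 0)
  p <- attr(traj, "config")$ploidy
  traj <- as.data.frame(traj)
  traj$het <- traj$dosage > 0 & traj$dosage < p
  traj$fixA <- traj$dosage == p
  traj$fixB <- traj$dosage == 0
  by <- if (by_lineage) list(generation = traj$generation,
                             lineage = traj$lineage)
        else list(generation = traj$generation)
  out <- aggregate(traj[, c("het", "fixA", "fixB")], by, mean)
  names(out)[names(out) == "het"] <- "het_fraction"
  names(out)[names(out) == "fixA"] <- "fixed_A_fraction"
  names(out)[names(out) == "fixB"] <- "fixed_B_fraction"
  out[order(out$generation), , drop = FALSE]
}
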