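# Inbreeding-depression regressions.
#
# Two fixed-effects OLS models on cell means (plants averaged within a
# field x genotype x ploidy x lineage x generation cell; lineages stay as
# rows):
#
#   y = b0 + b1 gen + b2 ploidy + b3 (gen x ploidy) + e     (ploidy model)
#   y = b0 + b1 gen + b2 geno  + b3 (gen x geno)  + e       (genotype model)
#
# with gen numeric in {0,1,3,5,7}, ploidy the 0/1 indicator and geno dummy
# coded (reference = first label alphabetically).  Inbreeding depression in
# a trait means b1 < 0; the ploidy/genotype questions are answered by
# testing b3 = 0 (t test in the scalar case, joint F over the dummy vector).

#' Average plants within trial cells
#'
#' Arithmetic mean of plant-level values within each
#' (year x field x genotype x ploidy x lineage x generation x trait) cell —
#' the "biological replicates" are the plants of one row.  Missing plants
#' simply reduce a cell's n; cells with no plants do not appear.
#'
#' @param d A field dataset in the canonical long schema.
#' @return A data frame of class `summarized_dataset` with the cell keys and
#'   columns `mean_value`, `n_plants`.
#' @export
average_replicates <- function(d) {
  .check_field_schema(d)
  if (nrow(d) == 0) stop("no records to summarize")
  keys <- list(year = d$year, field = d$field, genotype = d$genotype,
               ploidy = d$ploidy, lineage = d$lineage,
               generation = d$generation, trait = d$trait)
  out <- aggregate(list(mean_value = d$value), keys, mean)
  nn <- aggregate(list(n_plants = d$value), keys, length)
  out$n_plants <- nn$n_plants
  out <- out[order(out$trait, out$field, out$genotype, out$ploidy,
                   out$lineage, out$generation), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("summarized_dataset", "data.frame")
  out
}

# residual scale below which a fit is treated as an exact interpolation
# (zero-residual fits are legitimate inputs; silence lm's perfect-fit warning)
.is_exact_fit <- function(fit) {
  suppressWarnings(summary(fit)$sigma) <
    1e-10 * (mean(abs(stats::fitted(fit))) + 1)
}

.coef_table <- function(fit) {
  sm <- suppressWarnings(summary(fit))$coefficients
  est <- sm[, 1]; se <- sm[, 2]
  if (.is_exact_fit(fit)) {
    # zero-residual interpolation: coefficients are exact, tests degenerate
    scale <- mean(abs(stats::fitted(fit))) + 1
    zero <- abs(est) < 1e-8 * scale
    est[zero] <- 0
    se[] <- 0
    t <- ifelse(zero, 0, sign(est) * Inf)
    p <- ifelse(zero, 1, 0)
  } else {
    t <- est / se
    p <- 2 * stats::pt(-abs(t), stats::df.residual(fit))
  }
  data.frame(term = rownames(sm), estimate = unname(est), se = unname(se),
             t = unname(t), p = unname(p), row.names = NULL)
}

.subset_summarized <- function(d, trait, field = NULL, year = NULL) {
  stopifnot(inherits(d, "summarized_dataset") || is.data.frame(d))
  sub <- d[d$trait == trait, , drop = FALSE]
  if (!is.null(field)) sub <- sub[sub$field == field, , drop = FALSE]
  if (!is.null(year)) sub <- sub[sub$year == year, , drop = FALSE]
  if (nrow(sub) == 0) stop("no summarized records for that trait/field/year")
  sub
}

#' Fit the ploidy-interaction depression model
#'
#' OLS of cell-mean trait value on `generation * ploidy` with generation
#' numeric and ploidy the 0/1 indicator.  The coefficient of `generation` is
#' the diploid depression slope; the `generation:ploidy` interaction is the
#' tetraploid-minus-diploid slope difference whose null `beta3 = 0` carries
#' the study's ploidy question.
#'
#' @param d A [average_replicates()] result (or compatible data frame).
#' @param trait Trait to analyze.
#' @param field Optional single field (fields are analyzed separately by
#'   default in the workflow; `NULL` pools them).
#' @param year Optional year filter.
#' @return An object of class `depression_fit` with a tidy coefficient
#'   table (`term, estimate, se, t, p`), the underlying `lm` fit, and for
#'   the genotype model a joint interaction F test.
#' @export
fit_ploidy_model <- function(d, trait, field = NULL, year = NULL) {
  sub <- .subset_summarized(d, trait, field, year)
  if (length(unique(sub$ploidy)) < 2)
    stop("both ploidies must be present")
  if (length(unique(sub$generation)) < 2)
    stop("at least two distinct generations are required")
  fit <- stats::lm(mean_value ~ generation * ploidy, data = sub)
  if (any(is.na(stats::coef(fit)))) stop("design matrix is rank deficient")
  structure(list(model = "ploidy_interaction",
                 coefficients = .coef_table(fit),
                 fit = fit, data = sub, trait = trait, field = field,
                 year = year, residual_df = stats::df.residual(fit),
                 interaction_terms = "generation:ploidy"),
            class = "depression_fit")
}

#' Fit the genotype-interaction depression model
#'
#' OLS of cell-mean trait value on `generation * genotype` within one
#' ploidy, genotype dummy-coded against the alphabetically first label.
#' The interaction null `beta3 = 0` (all dummies jointly) is tested by an F
#' test comparing against the no-interaction model.
#'
#' @inheritParams fit_ploidy_model
#' @param ploidy Ploidy subset: 0/2 for diploid, 1/4 for tetraploid, or
#'   `NULL` to use all rows as given.
#' @return A `depression_fit`; see [fit_ploidy_model()].
#' @export
fit_genotype_model <- function(d, trait, field = NULL, year = NULL,
                               ploidy = NULL) {
  sub <- .subset_summarized(d, trait, field, year)
  if (!is.null(ploidy)) {
    ind <- if (ploidy %in% c(4, 1)) 1L else 0L
    sub <- sub[sub$ploidy == ind, , drop = FALSE]
  }
  if (length(unique(sub$genotype)) < 2)
    stop("at least two genotypes are required")
  if (length(unique(sub$generation)) < 2)
    stop("at least two distinct generations are required")
  sub$geno <- factor(sub$genotype)  # reference = first level alphabetically
  fit <- stats::lm(mean_value ~ generation * geno, data = sub)
  if (any(is.na(stats::coef(fit)))) stop("design matrix is rank deficient")
  reduced <- stats::lm(mean_value ~ generation + geno, data = sub)
  an <- stats::anova(reduced, fit)
  joint <- list(F = an$F[2], df1 = an$Df[2], df2 = an$Res.Df[2],
                p_value = an$`Pr(>F)`[2])
  if (.is_exact_fit(fit)) {
    # zero-residual interpolation: the F ratio is 0/0 noise
    ints <- grep("generation:geno", names(stats::coef(fit)))
    exact_zero <- all(abs(stats::coef(fit)[ints]) <
                        1e-8 * (mean(abs(stats::fitted(fit))) + 1))
    joint$F <- if (exact_zero) 0 else Inf
    joint$p_value <- if (exact_zero) 1 else 0
  }
  structure(list(model = "genotype_interaction",
                 coefficients = .coef_table(fit),
                 fit = fit, data = sub, trait = trait, field = field,
                 year = year, residual_df = stats::df.residual(fit),
                 interaction_terms = grep("generation:geno",
                                          names(stats::coef(fit)),
                                          value = TRUE),
                 joint_interaction = joint),
            class = "depression_fit")
}

#' @export
print.depression_fit <- function(x, ...) {
  cat(sprintf("<depression_fit> %s | trait: %s%s\n", x$model, x$trait,
              if (!is.null(x$field)) paste0(" | field ", x$field) else ""))
  print(transform(x$coefficients, estimate = signif(estimate, 5),
                  se = signif(se, 4), t = signif(t, 4), p = signif(p, 4)))
  if (!is.null(x$joint_interaction))
    cat(sprintf("Joint interaction F(%d, %d) = %.4f, p = %.4f\n",
                x$joint_interaction$df1, x$joint_interaction$df2,
                x$joint_interaction$F, x$joint_interaction$p_value))
  invisible(x)
}

#' Test for inbreeding depression (beta1 < 0)
#'
#' Depression is present in a trait when the generation slope is negative.
#' Reports the estimate, the two-sided p of the slope, and a one-sided test
#' of `beta1 < 0`; the flag requires a strictly negative estimate.
#'
#' @param fit A `depression_fit`.
#' @param level One-sided significance level (default 0.05).
#' @return A list of class `decision_record`: `estimate`, `p_two_sided`,
#'   `p_one_sided`, `depression_present`.
#' @export
test_depression <- function(fit, level = 0.05) {
  stopifnot(inherits(fit, "depression_fit"))
  row <- fit$coefficients[fit$coefficients$term == "generation", ]
  t <- row$t
  p_one <- if (is.infinite(t)) as.numeric(t > 0) else
    stats::pt(t, fit$residual_df)
  structure(list(test = "depression", term = "generation",
                 estimate = row$estimate, p_two_sided = row$p,
                 p_one_sided = p_one,
                 depression_present = row$estimate < 0 && p_one < level,
                 level = level),
            class = "decision_record")
}

#' Test the slope-interaction null (beta3 = 0)
#'
#' For the ploidy model, a two-sided t test of the single
#' `generation:ploidy` coefficient; for the genotype model, the joint F test
#' over all `generation:geno` dummies.  Raw p-values are reported; apply
#' [stats::p.adjust()] (e.g. Benjamini-Hochberg) across traits and fields if
#' a correction is wanted — the workflow reports raw values by default.
#'
#' @param fit A `depression_fit`.
#' @param level Significance level for the presence flag (default 0.05).
#' @return A list of class `decision_record` with `statistic`, `df`,
#'   `p_value`, `interaction_present`.
#' @export
test_interaction <- function(fit, level = 0.05) {
  stopifnot(inherits(fit, "depression_fit"))
  if (fit$model == "ploidy_interaction") {
    row <- fit$coefficients[fit$coefficients$term == "generation:ploidy", ]
    out <- list(test = "interaction", type = "t",
                statistic = row$t, df = fit$residual_df,
                estimate = row$estimate, p_value = row$p)
  } else {
    j <- fit$joint_interaction
    out <- list(test = "interaction", type = "F",
                statistic = j$F, df = c(j$df1, j$df2), p_value = j$p_value)
  }
  out$interaction_present <- out$p_value < level
  out$level <- level
  structure(out, class = "decision_record")
}

#' @export
print.decision_record <- function(x, ...) {
  cat(sprintf("<decision_record> %s test\n", x$test))
  for (nm in setdiff(names(x), c("test", "level"))) {
    v <- unlist(x[[nm]])
    if (is.numeric(v)) v <- signif(v, 5)
    cat(sprintf("  %s: %s\n", nm, paste(v, collapse = ", ")))
  }
  invisible(x)
}
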