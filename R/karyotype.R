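# Segregation analysis of karyotyped selfed-tetraploid progeny.
#
# Each complete chromosome set of a selfed W22/B73-style tetraploid is
# classified by its parental constitution (4:0, 3:1, 2:2, 1:3, 0:4 copies of
# parent A vs parent B) and the tallies are tested against the tetrasomic
# expectation 1:8:18:8:1 by a Pearson chi-square goodness-of-fit test, with
# an exact/Monte-Carlo multinomial cross-check for the small expected counts
# in the extreme classes.

KARYO_CLASSES <- c("4:0", "3:1", "2:2", "1:3", "0:4")

#' Tally over the five parental-constitution classes
#'
#' @param counts Non-negative integer counts in class order
#'   `4:0, 3:1, 2:2, 1:3, 0:4` (parent A first).  Names, if present, must
#'   match that order.
#' @return A named integer vector of class `class_tally`.
#' @examples
#' class_tally(c(6, 20, 41, 23, 2))  # n = 92
#' @export
class_tally <- function(counts) {
  if (length(counts) != 5L || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be five non-negative integers over classes ",
         paste(KARYO_CLASSES, collapse = ", "))
  if (!is.null(names(counts)) && !identical(names(counts), KARYO_CLASSES))
    stop("names must be ", paste(KARYO_CLASSES, collapse = ", "))
  if (sum(counts) < 1) stop("tally must contain at least one record")
  structure(stats::setNames(as.integer(counts), KARYO_CLASSES),
            class = "class_tally")
}

#' @export
print.class_tally <- function(x, ...) {
  cat("<class_tally> n =", sum(x), "\n")
  print(stats::setNames(as.integer(x), names(x)))
  excl <- attr(x, "excluded")
  if (!is.null(excl) && excl > 0)
    cat(excl, "incomplete/unassignable record(s) excluded\n")
  invisible(x)
}

#' Read a karyotype table or pre-tallied class counts
#'
#' Two CSV dialects are accepted (comma-separated, header required, `#`
#' comment lines ignored): per-record with columns
#' `plant_id, chromosome, n_parentA, n_parentB` (one row per complete
#' chromosome set), or pre-tallied with columns `class, count` where class is
#' one of `4:0 .. 0:4`.
#'
#' @param path Path to the CSV file.
#' @param pretallied Force the pre-tallied dialect; by default it is detected
#'   from the header.
#' @return A `karyotype_table` data frame (per-record dialect) or a
#'   [class_tally()] (pre-tallied dialect).
#' @export
read_karyotype_table <- function(path, pretallied = FALSE) {
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (pretallied || all(c("class", "count") %in% names(d))) {
    if (!all(c("class", "count") %in% names(d)))
      stop("pre-tallied file needs columns class, count")
    bad <- setdiff(d$class, KARYO_CLASSES)
    if (length(bad)) stop("unknown class label(s): ", paste(bad, collapse = ", "))
    counts <- stats::setNames(rep(0L, 5L), KARYO_CLASSES)
    counts[d$class] <- as.integer(d$count)
    return(class_tally(counts))
  }
  need <- c("plant_id", "chromosome", "n_parentA", "n_parentB")
  if (!all(need %in% names(d)))
    stop("per-record file needs columns ", paste(need, collapse = ", "))
  structure(d[, need], class = c("karyotype_table", "data.frame"))
}

#' Tally parental-constitution classes from per-record karyotypes
#'
#' One tally unit per retained (plant, chromosome) record, keyed by
#' `n_parentA : n_parentB`.  Records whose counts do not sum to 4 (incomplete
#' or unassignable chromosome sets) are excluded before tallying, mirroring
#' the exclusion rule of the source analysis; the number excluded is attached
#' as attribute `"excluded"` and warned about.
#'
#' @param x A `karyotype_table` (or data frame with columns `n_parentA`,
#'   `n_parentB`), or an existing [class_tally()] (returned unchanged).
#' @param strict If `TRUE`, any invalid record is an error instead of an
#'   exclusion.
#' @return A [class_tally()].
#' @export
tally_classes <- function(x, strict = FALSE) {
  if (inherits(x, "class_tally")) return(x)
  stopifnot(is.data.frame(x), all(c("n_parentA", "n_parentB") %in% names(x)))
  a <- x$n_parentA
  b <- x$n_parentB
  ok <- !is.na(a) & !is.na(b) & (a + b == 4) & a >= 0 & b >= 0
  if (strict && any(!ok))
    stop(sum(!ok), " record(s) with parental counts not summing to 4")
  if (any(!ok))
    warning(sum(!ok), " incomplete/unassignable record(s) excluded")
  key <- paste(a[ok], b[ok], sep = ":")
  counts <- vapply(KARYO_CLASSES, function(cl) sum(key == cl), integer(1))
  out <- class_tally(counts)
  attr(out, "excluded") <- sum(!ok)
  out
}

#' Pearson chi-square goodness of fit to a segregation ratio
#'
#' Tests observed class counts against expected proportions given as an
#' integer ratio (default the tetrasomic 1:8:18:8:1).  Expected counts are
#' used unrounded; degrees of freedom are `classes - 1` (no parameters are
#' estimated); no continuity correction is applied.  For the worked dataset
#' (6, 20, 41, 23, 2) the statistic is 5.63 on 4 df, p = 0.23.
#'
#' @param tally A [class_tally()] or plain vector of counts.
#' @param ratio Positive expected ratio, same length as `tally`.
#' @return An object of class `gof_result` with fields `statistic`, `df`,
#'   `p_value`, `expected`, `observed`, `ratio`.
#' @examples
#' chi_square_gof(class_tally(c(6, 20, 41, 23, 2)))
#' @export
chi_square_gof <- function(tally, ratio = c(1, 8, 18, 8, 1)) {
  obs <- as.numeric(tally)
  if (length(obs) != length(ratio))
    stop("tally and ratio must have the same length")
  if (any(ratio <= 0)) stop("ratio entries must be positive")
  n <- sum(obs)
  if (n <= 0) stop("total count must be positive")
  expected <- n * ratio / sum(ratio)
  statistic <- sum((obs - expected)^2 / expected)
  df <- length(obs) - 1L
  structure(list(statistic = statistic,
                 df = df,
                 p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
                 expected = expected,
                 observed = obs,
                 ratio = ratio),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat("Chi-square goodness of fit to ratio",
      paste(x$ratio, collapse = ":"), "\n")
  tab <- rbind(observed = x$observed, expected = round(x$expected, 3))
  colnames(tab) <- if (length(x$observed) == 5L) KARYO_CLASSES else
    seq_along(x$observed)
  print(tab)
  cat(sprintf("X-squared = %.4f, df = %d, p = %.4f\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Exact / Monte-Carlo multinomial goodness-of-fit p-value
#'
#' Cross-check of [chi_square_gof()] for small expected counts: the p-value
#' is `P(X2(T) >= X2(observed))` for tallies `T ~ multinomial(n, ratio)`.
#' For small `n` all compositions are enumerated (exact); otherwise a seeded
#' Monte-Carlo sample is used, with the add-one estimator
#' `(1 + #exceedances) / (n_sim + 1)`.
#'
#' @inheritParams chi_square_gof
#' @param method `"auto"` (enumerate when the outcome space is small),
#'   `"enumerate"`, or `"montecarlo"`.
#' @param n_sim Number of Monte-Carlo draws.
#' @param seed Optional seed for the Monte-Carlo fallback.
#' @return A list with `p_value`, `statistic`, `method`, and `n_sim` (MC only).
#' @export
exact_multinomial_pvalue <- function(tally, ratio = c(1, 8, 18, 8, 1),
                                     method = c("auto", "enumerate",
                                                "montecarlo"),
                                     n_sim = 1e5, seed = NULL) {
  method <- match.arg(method)
  obs <- as.numeric(tally)
  k <- length(obs)
  stopifnot(length(ratio) == k, all(ratio > 0))
  n <- sum(obs)
  prob <- ratio / sum(ratio)
  expected <- n * prob
  stat <- function(x) sum((x - expected)^2 / expected)
  obs_stat <- stat(obs)
  n_outcomes <- choose(n + k - 1, k - 1)
  if (method == "auto")
    method <- if (n_outcomes <= 5e4) "enumerate" else "montecarlo"
  if (method == "enumerate") {
    if (n_outcomes > 2e6) stop("outcome space too large to enumerate; ",
                               "use method = 'montecarlo'")
    comps <- .compositions(n, k)
    lp <- lgamma(n + 1) - rowSums(lgamma(comps + 1)) +
      comps %*% log(prob)
    stats_all <- colSums((t(comps) - expected)^2 / expected)
    p <- sum(exp(lp)[stats_all >= obs_stat - 1e-9])
    return(list(p_value = p, statistic = obs_stat, method = "enumerate"))
  }
  if (!is.null(seed)) set.seed(seed)
  draws <- stats::rmultinom(n_sim, n, prob)
  stats_all <- colSums((draws - expected)^2 / expected)
  p <- (1 + sum(stats_all >= obs_stat - 1e-9)) / (n_sim + 1)
  list(p_value = p, statistic = obs_stat, method = "montecarlo", n_sim = n_sim)
}

# all compositions of n into k non-negative parts, as a matrix
.compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, 1L, 1L))
  out <- vector("list", n + 1L)
  for (first in 0:n) {
    rest <- .compositions(n - first, k - 1L)
    out[[first + 1L]] <- cbind(first, rest)
  }
  m <- do.call(rbind, out)
  dimnames(m) <- NULL
  m
}
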