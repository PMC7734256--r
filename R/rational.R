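# Exact rational arithmetic for segregation distributions.
#
# Gamete and progeny probabilities are ratios of small integers, and the
# selfing chain stays rational whenever the double-reduction coefficient is
# rational.  Probabilities are stored as integer numerators over a shared
# denominator, held in doubles (exact below 2^53) and gcd-reduced after every
# operation.  Trajectory code checks .RAT_MAX before each step and falls back
# to floating point if the denominator would grow past it.

.RAT_MAX <- 2^51

.gcd2 <- function(a, b) {
  a <- abs(round(a)); b <- abs(round(b))
  while (b > 0.5) {
    tmp <- b
    b <- a %% b
    a <- tmp
  }
  a
}

.gcd <- function(x) {
  x <- x[x != 0]
  if (length(x) == 0L) return(1)
  Reduce(.gcd2, x)
}

.lcm2 <- function(a, b) a / .gcd2(a, b) * b

# continued-fraction rationalisation of a numeric; exact for inputs that are
# double representations of small fractions (1/6, 1/24, ...)
.as_fraction <- function(x, tol = 1e-9, max_den = 1e6) {
  stopifnot(is.numeric(x), length(x) == 1L, is.finite(x))
  if (abs(x - round(x)) < tol) return(c(num = round(x), den = 1))
  p0 <- 0; q0 <- 1
  p1 <- 1; q1 <- 0
  r <- x
  for (i in 1:64) {
    a <- floor(r)
    p2 <- a * p1 + p0
    q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1
    p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - x) < tol) break
    if (abs(r - a) < 1e-12) break
    r <- 1 / (r - a)
  }
  if (abs(p1 / q1 - x) > tol)
    stop("cannot represent ", x, " as a fraction with denominator <= ", max_den)
  c(num = p1, den = q1)
}

.frac_chr <- function(num, den) {
  out <- character(length(num))
  for (i in seq_along(num)) {
    g <- .gcd(c(num[i], den))
    n <- num[i] / g
    d <- den / g
    out[i] <- if (d == 1) format(n) else paste0(format(n), "/", format(d))
  }
  out
}

#' Exact discrete probability distribution
#'
#' A distribution over integer support stored as integer numerators over a
#' common denominator, so that segregation probabilities carry no floating
#' error.  Used for gamete and selfed-progeny dosage distributions.
#'
#' @param num Non-negative integer numerators, one per support point.
#' @param den Positive integer common denominator; `sum(num)` must equal `den`.
#' @param support Integer support (e.g. gamete dosages `0:2`).
#' @return An object of class `exact_dist` with fields `num`, `den`, `support`.
#' @examples
#' exact_dist(c(1, 4, 1), 6, 0:2)
#' @export
exact_dist <- function(num, den, support) {
  stopifnot(length(num) == length(support), length(den) == 1L)
  num <- round(num); den <- round(den)
  if (den <= 0) stop("denominator must be positive")
  if (any(num < 0)) stop("numerators must be non-negative")
  if (sum(num) != den) stop("numerators must sum to the denominator")
  g <- .gcd(c(num, den))
  structure(
    list(num = num / g, den = den / g, support = as.integer(support)),
    class = "exact_dist"
  )
}

#' @export
print.exact_dist <- function(x, ...) {
  cat("Exact distribution over dosages", paste(range(x$support), collapse = ".."), "\n")
  fr <- .frac_chr(x$num, x$den)
  for (i in seq_along(x$support))
    cat(sprintf("  %d: %s\n", x$support[i], fr[i]))
  invisible(x)
}

#' Numeric probabilities of an exact distribution
#'
#' @param x An `exact_dist`.
#' @return A named numeric vector of probabilities (names are support values).
#' @export
probabilities <- function(x) {
  stopifnot(inherits(x, "exact_dist"))
  stats::setNames(x$num / x$den, x$support)
}

# convolution of two exact distributions (sum of independent draws)
.dist_convolve <- function(x, y) {
  lo <- min(x$support) + min(y$support)
  hi <- max(x$support) + max(y$support)
  support <- lo:hi
  num <- numeric(length(support))
  for (i in seq_along(x$support)) {
    for (j in seq_along(y$support)) {
      k <- x$support[i] + y$support[j] - lo + 1L
      num[k] <- num[k] + x$num[i] * y$num[j]
    }
  }
  exact_dist(num, x$den * y$den, support)
}
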