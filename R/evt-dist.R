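#' Extreme-value limit distributions
#'
#' Density, distribution, and quantile functions for the three possible
#' non-degenerate limit laws of normalized maxima (the Trinity Theorem):
#' Gumbel, `exp(-exp(-z))`; Frechet, `exp(-z^-alpha)` on `z > 0`; and the
#' reversed Weibull, `exp(-(-z)^alpha)` on `z <= 0`, each with
#' `z = (x - location) / scale`. Densities are the analytic derivatives of
#' the CDFs.
#'
#' @param x,q Quantiles.
#' @param p Probabilities.
#' @param shape Shape parameter `alpha`; required positive for the Frechet
#'   and reversed-Weibull families.
#' @param location Location, same units as `x` (ms in this package).
#' @param scale Scale, positive, same units as `x`.
#' @return Numeric vector of densities, probabilities, or quantiles.
#' @name evt_distributions
NULL

check_scale <- function(scale) {
  if (any(!is.finite(scale)) || any(scale <= 0)) {
    stop("`scale` must be positive and finite", call. = FALSE)
  }
}
check_shape <- function(shape, min = 0) {
  if (is.null(shape) || any(!is.finite(shape)) || any(shape <= min)) {
    stop("`shape` must be positive and finite", call. = FALSE)
  }
}

#' @rdname evt_distributions
#' @export
pgumbel <- function(q, location = 0, scale = 1) {
  check_scale(scale)
  exp(-exp(-(q - location) / scale))
}

#' @rdname evt_distributions
#' @export
dgumbel <- function(x, location = 0, scale = 1) {
  check_scale(scale)
  z <- (x - location) / scale
  exp(-z - exp(-z)) / scale
}

#' @rdname evt_distributions
#' @export
qgumbel <- function(p, location = 0, scale = 1) {
  check_scale(scale)
  stopifnot(all(p >= 0 & p <= 1))
  location - scale * log(-log(p))
}

#' @rdname evt_distributions
#' @export
pfrechet <- function(q, shape, location = 0, scale = 1) {
  check_scale(scale); check_shape(shape)
  z <- (q - location) / scale
  ifelse(z <= 0, 0, exp(-z^(-shape)))
}

#' @rdname evt_distributions
#' @export
dfrechet <- function(x, shape, location = 0, scale = 1) {
  check_scale(scale); check_shape(shape)
  z <- (x - location) / scale
  ifelse(z <= 0, 0, (shape / scale) * z^(-shape - 1) * exp(-z^(-shape)))
}

#' @rdname evt_distributions
#' @export
qfrechet <- function(p, shape, location = 0, scale = 1) {
  check_scale(scale); check_shape(shape)
  stopifnot(all(p >= 0 & p <= 1))
  location + scale * (-log(p))^(-1 / shape)
}

#' @rdname evt_distributions
#' @export
prweibull <- function(q, shape, location = 0, scale = 1) {
  check_scale(scale); check_shape(shape)
  z <- (q - location) / scale
  ifelse(z >= 0, 1, exp(-(-z)^shape))
}

#' @rdname evt_distributions
#' @export
drweibull <- function(x, shape, location = 0, scale = 1) {
  check_scale(scale); check_shape(shape)
  z <- (x - location) / scale
  ifelse(z >= 0, 0, (shape / scale) * (-z)^(shape - 1) * exp(-(-z)^shape))
}

#' Dispatch CDF / PDF by family name
#'
#' Convenience wrappers used by the fitting layer: `evt_cdf` and `evt_pdf`
#' select among the Gumbel, Frechet, and reversed-Weibull functions.
#' `shape` is ignored for the Gumbel family.
#'
#' @param x Quantiles.
#' @param family `"gumbel"`, `"frechet"`, or `"weibull"` (reversed Weibull).
#' @inheritParams evt_distributions
#' @return Probabilities (`evt_cdf`) or densities per ms (`evt_pdf`).
#' @export
evt_cdf <- function(x, family = c("gumbel", "frechet", "weibull"),
                    shape = NULL, location = 0, scale = 1) {
  family <- match.arg(family)
  switch(family,
    gumbel = pgumbel(x, location, scale),
    frechet = pfrechet(x, shape, location, scale),
    weibull = prweibull(x, shape, location, scale))
}

#' @rdname evt_cdf
#' @export
evt_pdf <- function(x, family = c("gumbel", "frechet", "weibull"),
                    shape = NULL, location = 0, scale = 1) {
  family <- match.arg(family)
  switch(family,
    gumbel = dgumbel(x, location, scale),
    frechet = dfrechet(x, shape, location, scale),
    weibull = drweibull(x, shape, location, scale))
}

#' Distribution of the maximum of n i.i.d. draws
#'
#' If each of `n` independent draws has CDF `F`, their maximum has CDF
#' `F(x)^n`. This is the exact finite-n law that the extreme-value limits
#' approximate, and it serves as the brute-force oracle for the convergence
#' checks.
#'
#' @param population_cdf Function mapping reals to probabilities in `[0, 1]`.
#' @param n Block size (number of draws), integer `>= 1`.
#' @param x Evaluation point(s).
#' @return `population_cdf(x)^n`.
#' @export
max_distribution_cdf <- function(population_cdf, n, x) {
  stopifnot(is.function(population_cdf))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != trunc(n)) {
    stop("`n` must be a single integer >= 1", call. = FALSE)
  }
  population_cdf(x)^n
}

#' Norming constants for the exponential and Pareto domains of attraction
#'
#' The sequences `(a_n, b_n)` for which `F^n(a_n x + b_n)` converges to a
#' standard extreme-value law: for a standard exponential population,
#' `(1, log n)` (Gumbel limit); for a standard Pareto population with tail
#' index `alpha`, `(n^(1/alpha), 0)` (Frechet limit).
#'
#' @param population `"exponential"` or `"pareto"`.
#' @param n Block size, integer `>= 1`.
#' @param alpha Tail index; required for `population = "pareto"`.
#' @return An object of class `norming_constants`: list with `a_n > 0` and
#'   `b_n`.
#' @export
norming_constants <- function(population = c("exponential", "pareto"),
                              n, alpha = NULL) {
  population <- match.arg(population)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != trunc(n)) {
    stop("`n` must be a single integer >= 1", call. = FALSE)
  }
  nc <- if (population == "exponential") {
    list(a_n = 1, b_n = log(n))
  } else {
    if (is.null(alpha)) {
      stop("`alpha` is required for the Pareto population", call. = FALSE)
    }
    check_shape(alpha)
    list(a_n = n^(1 / alpha), b_n = 0)
  }
  nc$population <- population
  nc$n <- as.integer(n)
  structure(nc, class = "norming_constants")
}

#' @export
print.norming_constants <- function(x, ...) {
  cat(sprintf("<norming_constants> %s, n = %d: a_n = %.6g, b_n = %.6g\n",
              x$population, x$n, x$a_n, x$b_n))
  invisible(x)
}
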