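#' Create a reproducible random stream
#'
#' A `random_stream` is a self-contained random-number generator state based
#' on the L'Ecuyer-CMRG generator. Draws taken from a stream advance only that
#' stream; the global `.Random.seed` is saved and restored around every draw,
#' so streams never interfere with each other or with user code. Two streams
#' built from the same seed yield identical draw sequences.
#'
#' Independent substreams for per-trial simulation are derived with
#' [substream()], which jumps ahead along the L'Ecuyer-CMRG stream sequence
#' (each jump is 2^127 steps, so substreams never overlap in practice).
#'
#' @param seed Non-negative integer seed.
#' @return An object of class `random_stream` (an environment holding the
#'   generator state).
#' @seealso [substream()], [stream_uniform()]
#' @examples
#' s <- make_stream(7)
#' stream_uniform(s, 3)
#' @export
make_stream <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed < 0 ||
      seed != trunc(seed)) {
    stop("`seed` must be a single non-negative integer", call. = FALSE)
  }
  state <- with_preserved_rng({
    suppressWarnings(RNGkind("L'Ecuyer-CMRG"))
    set.seed(as.integer(seed))
    get(".Random.seed", envir = globalenv())
  })
  stream <- new.env(parent = emptyenv())
  stream$seed <- as.integer(seed)
  stream$origin <- state # state at creation; substreams jump from here
  stream$state <- state
  class(stream) <- "random_stream"
  stream
}

#' Derive an independent substream
#'
#' Returns a new stream obtained by jumping `k` stream increments ahead of
#' `stream`'s creation state. The result depends only on (`seed`, `k`), so
#' trial `k` of a simulation is individually reproducible without replaying
#' trials `1..k-1`.
#'
#' @param stream A [random_stream][make_stream].
#' @param k Positive integer substream index.
#' @return A new `random_stream`.
#' @export
substream <- function(stream, k) {
  stopifnot(inherits(stream, "random_stream"))
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k != trunc(k)) {
    stop("`k` must be a single positive integer", call. = FALSE)
  }
  state <- stream$origin
  for (i in seq_len(k)) state <- parallel::nextRNGStream(state)
  sub <- new.env(parent = emptyenv())
  sub$seed <- stream$seed
  sub$origin <- state
  sub$state <- state
  class(sub) <- "random_stream"
  sub
}

#' Draw uniforms from a stream
#'
#' Draws lie in the half-open interval (0, 1]: zero is excluded by
#' construction (`1 - runif()`), so logarithms and negative powers of the
#' draws are always finite. This matters for the inverse-transform samplers.
#'
#' @param stream A [random_stream][make_stream].
#' @param n Number of draws.
#' @return Numeric vector of `n` values in (0, 1].
#' @export
stream_uniform <- function(stream, n) {
  stopifnot(inherits(stream, "random_stream"), n >= 0)
  if (n == 0) return(numeric(0))
  with_preserved_rng({
    assign(".Random.seed", stream$state, envir = globalenv())
    u <- 1 - stats::runif(n)
    stream$state <- get(".Random.seed", envir = globalenv())
    u
  })
}

#' @export
print.random_stream <- function(x, ...) {
  cat("<random_stream> seed =", x$seed, "\n")
  invisible(x)
}

# Evaluate `expr` without disturbing the caller's RNG state.
with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  expr
}

#' Specify the stochastic time-constant law
#'
#' The membrane time constant of the stochastic LIF model is redrawn after
#' every spike from a law xi(mu, sigma). Three families are supported:
#'
#' * `"fixed"` — degenerate: always `mu` (recovers the deterministic model;
#'   `sigma` is ignored).
#' * `"exponential"` — shifted exponential, `mu + scale * Exp(1)`, sampled by
#'   inverse transform as `(-1/sigma) * log(U) + mu`.
#' * `"pareto"` — Pareto with lower endpoint `mu` and tail index `sigma`,
#'   sampled as `mu * U^(-1/sigma)`; survival `P(X > x) = (mu/x)^sigma`.
#'
#' For the exponential family the role of `sigma` is governed by
#' `convention`: `"literal"` (default) treats `sigma` as a rate, so the
#' exponential scale is `1/sigma`; `"scale"` treats `sigma` itself as the
#' scale in ms. Both choices give a shifted exponential, so every
#' extreme-value conclusion downstream holds under either; they differ only
#' in the width of the interval law.
#'
#' @param family One of `"fixed"`, `"exponential"`, `"pareto"`.
#' @param mu Location (lower endpoint) in ms; must be positive.
#' @param sigma Rate/shape parameter; must be positive. Ignored for
#'   `family = "fixed"`.
#' @param convention `"literal"` or `"scale"`; exponential family only.
#' @return An object of class `time_constant_model`.
#' @examples
#' tc <- time_constant_model("exponential", mu = 20, sigma = 5)
#' sample_xi(tc, make_stream(1), n = 5)
#' @export
time_constant_model <- function(family = c("fixed", "exponential", "pareto"),
                                mu = 20, sigma = 5,
                                convention = c("literal", "scale")) {
  family <- match.arg(family)
  convention <- match.arg(convention)
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(sigma), length(sigma) == 1L, is.finite(sigma))
  if (mu <= 0) stop("`mu` must be positive (ms)", call. = FALSE)
  if (family != "fixed" && sigma <= 0) {
    stop("`sigma` must be positive", call. = FALSE)
  }
  if (family == "pareto" && sigma <= 1) {
    warning("Pareto with sigma <= 1 has infinite mean; sampling proceeds",
            call. = FALSE)
  }
  structure(
    list(family = family, mu = mu, sigma = sigma, convention = convention),
    class = "time_constant_model"
  )
}

#' @export
print.time_constant_model <- function(x, ...) {
  cat("<time_constant_model>", x$family, " mu =", x$mu, "ms")
  if (x$family != "fixed") cat("  sigma =", x$sigma)
  if (x$family == "exponential") cat("  [", x$convention, "convention ]")
  cat("\n")
  invisible(x)
}

# Exponential scale implied by the model's sigma convention (ms).
xi_exp_scale <- function(model) {
  if (model$convention == "literal") 1 / model$sigma else model$sigma
}

#' Inverse-transform sampler, shifted-exponential family
#'
#' Maps a uniform draw `u` in (0, 1] to `mu + scale * (-log(u))`, where the
#' scale is `1/sigma` under the literal convention and `sigma` under the
#' scale convention. Results are always `>= mu`.
#'
#' @param model A [time_constant_model()] with `family = "exponential"`.
#' @param u Uniform draw(s) in (0, 1].
#' @return Sampled time(s) in ms.
#' @export
sample_exponential_xi <- function(model, u) {
  stopifnot(inherits(model, "time_constant_model"))
  if (model$family != "exponential") {
    stop("model family must be 'exponential'", call. = FALSE)
  }
  check_unit_interval(u)
  model$mu - xi_exp_scale(model) * log(u)
}

#' Inverse-transform sampler, Pareto family
#'
#' Maps a uniform draw `u` in (0, 1] to `mu * u^(-1/sigma)`, a Pareto
#' variate with lower endpoint `mu` and tail index `sigma`:
#' `P(X > x) = (mu/x)^sigma` for `x >= mu`.
#'
#' @inheritParams sample_exponential_xi
#' @param model A [time_constant_model()] with `family = "pareto"`.
#' @return Sampled time(s) in ms.
#' @export
sample_pareto_xi <- function(model, u) {
  stopifnot(inherits(model, "time_constant_model"))
  if (model$family != "pareto") {
    stop("model family must be 'pareto'", call. = FALSE)
  }
  check_unit_interval(u)
  model$mu * u^(-1 / model$sigma)
}

#' Sample time constants from a model
#'
#' Dispatches on the model family: `fixed` returns `mu` deterministically,
#' the other families draw uniforms from `stream` and apply their
#' inverse-transform sampler.
#'
#' @param model A [time_constant_model()].
#' @param stream A [random_stream][make_stream]; unused for `family = "fixed"`.
#' @param n Number of samples.
#' @return Numeric vector of `n` times in ms, all `>= mu`.
#' @export
sample_xi <- function(model, stream, n = 1) {
  stopifnot(inherits(model, "time_constant_model"))
  switch(model$family,
    fixed = rep(model$mu, n),
    exponential = sample_exponential_xi(model, stream_uniform(stream, n)),
    pareto = sample_pareto_xi(model, stream_uniform(stream, n)),
    stop("unknown family: ", model$family, call. = FALSE)
  )
}

check_unit_interval <- function(u) {
  if (any(!is.finite(u)) || any(u <= 0) || any(u > 1)) {
    stop("uniform draws must lie in (0, 1]", call. = FALSE)
  }
  invisible(u)
}
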