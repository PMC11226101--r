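#' Per-trial block maxima
#'
#' Collects the maximum inter-spike interval of each trial (one block per
#' trial). Empty trials carry no maximum and are skipped; their count is
#' recorded. Block sizes are random (the spike count varies trial to trial),
#' so the average block size is reported for transparency.
#'
#' @param trains A list of `spike_train` objects, or a list of numeric
#'   interval vectors.
#' @param block_description Free-text provenance note.
#' @return An object of class `maxima_sample`: `values` (one maximum per
#'   retained block, ms), `m` (retained block count), `mean_block_size`,
#'   `skipped` (empty-block count), `block_description`.
#' @export
block_maxima <- function(trains, block_description = "max interval per trial") {
  stopifnot(is.list(trains))
  intervals <- lapply(trains, function(tr) {
    if (inherits(tr, "spike_train")) tr$intervals else as.numeric(tr)
  })
  sizes <- lengths(intervals)
  keep <- sizes > 0
  if (!any(keep)) stop("all blocks are empty", call. = FALSE)
  values <- unname(vapply(intervals[keep], max, numeric(1)))
  if (any(values <= 0)) stop("intervals must be positive", call. = FALSE)
  new_maxima_sample(values, mean_block_size = mean(sizes[keep]),
                    skipped = sum(!keep),
                    block_description = block_description)
}

new_maxima_sample <- function(values, mean_block_size = NA_real_,
                              skipped = 0L,
                              block_description = "") {
  structure(list(values = values, m = length(values),
                 mean_block_size = mean_block_size,
                 skipped = as.integer(skipped),
                 block_description = block_description),
            class = "maxima_sample")
}

#' @export
print.maxima_sample <- function(x, ...) {
  cat(sprintf("<maxima_sample> m = %d (%s)\n", x$m, x$block_description))
  cat(sprintf("  range [%.4g, %.4g] ms, mean block size %.3g, %d skipped\n",
              min(x$values), max(x$values), x$mean_block_size, x$skipped))
  invisible(x)
}

#' Sum-to-one histogram
#'
#' Right-open bins `[edge_i, edge_{i+1})` of constant width starting at
#' `floor(min(values))` (or a caller-supplied origin), extended until the
#' largest value falls strictly inside the last bin. Masses are counts
#' divided by the total, so they sum to one exactly.
#'
#' @param values Nonempty numeric vector (ms).
#' @param bin_width Bin width, ms; defaults to 1 (the integration step).
#' @param origin Left edge of the first bin; defaults to `floor(min(values))`.
#' @return An object of class `normalized_histogram`: `bin_edges`, `masses`,
#'   `bin_width`.
#' @export
normalized_histogram <- function(values, bin_width = 1, origin = NULL) {
  if (length(values) == 0) stop("`values` must be nonempty", call. = FALSE)
  stopifnot(is.numeric(bin_width), bin_width > 0, all(is.finite(values)))
  if (is.null(origin)) origin <- floor(min(values))
  if (origin > min(values)) {
    stop("`origin` must not exceed the smallest value", call. = FALSE)
  }
  n_bins <- max(1L, ceiling((max(values) - origin) / bin_width))
  # right-open bins: a value landing on the last edge needs one more bin
  if (max(values) >= origin + n_bins * bin_width) n_bins <- n_bins + 1L
  edges <- origin + bin_width * (0:n_bins)
  counts <- tabulate(findInterval(values, edges, left.open = FALSE),
                     nbins = n_bins)
  structure(list(bin_edges = edges, masses = counts / length(values),
                 bin_width = bin_width),
            class = "normalized_histogram")
}

#' Bin centers of a normalized histogram
#' @param h A [normalized_histogram()].
#' @return Midpoints of the bins, ms.
#' @export
bin_centers <- function(h) {
  stopifnot(inherits(h, "normalized_histogram"))
  (h$bin_edges[-1] + h$bin_edges[-length(h$bin_edges)]) / 2
}

#' @export
print.normalized_histogram <- function(x, ...) {
  cat(sprintf(
    "<normalized_histogram> %d bins of %g ms on [%g, %g), total mass %g\n",
    length(x$masses), x$bin_width, min(x$bin_edges), max(x$bin_edges),
    sum(x$masses)))
  invisible(x)
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`, with the total sum of squares taken about the mean
#' of the observed values. Requires at least 3 points and non-degenerate
#' observations.
#'
#' @param observed,predicted Equal-length numeric vectors (histogram masses).
#' @return R-squared, at most 1 (can be negative for fits worse than the
#'   mean).
#' @export
r_squared <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  if (length(observed) < 3) {
    stop("need at least 3 points for R-squared", call. = FALSE)
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    stop("observed values have zero variance", call. = FALSE)
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Kolmogorov-Smirnov distance to a reference CDF
#'
#' The supremum distance between the empirical CDF of `values` and `cdf`,
#' evaluated at the sample points (where the supremum of a step function
#' against a continuous CDF is attained).
#'
#' @param values Nonempty numeric sample.
#' @param cdf Reference CDF as a function.
#' @return Sup-distance in `[0, 1]`.
#' @export
ks_distance <- function(values, cdf) {
  stopifnot(length(values) > 0, is.function(cdf))
  x <- sort(values)
  n <- length(x)
  f <- cdf(x)
  max(abs((1:n) / n - f), abs(f - (0:(n - 1)) / n))
}

#' Fit an extreme-value law to block maxima
#'
#' Two estimation routes:
#'
#' * `method = "histogram_ls"` (default): nonlinear least squares matching
#'   each bin mass of the sum-to-one histogram to
#'   `evt_pdf(center) * bin_width`. This mirrors fitting a curve through the
#'   plotted histogram. Free parameters: (location, scale) for Gumbel;
#'   (shape, location, scale) for Frechet.
#' * `method = "mle"`: maximize the log-density of the raw maxima. The
#'   statistically preferable route; R-squared is then computed post hoc
#'   against the histogram at `bin_width`.
#'
#' Starting values use Gumbel moment matching (`scale0 = sd * sqrt(6) / pi`,
#' `location0 = mean - 0.5772 * scale0`) and, for the Frechet family,
#' log-moment matching with the location initialized at 0 (the natural
#' centering for maxima of Pareto-type intervals). On non-convergence the
#' optimizer restarts from jittered starts (scale halved and doubled); if
#' all restarts fail an error carrying the optimizer diagnostics is raised.
#' A sample with zero variance cannot be fitted and raises a
#' degenerate-sample error.
#'
#' @param data A [maxima_sample][block_maxima], a raw numeric vector of
#'   maxima, or (for `histogram_ls` only) a [normalized_histogram()].
#' @param family `"gumbel"` or `"frechet"`.
#' @param method `"histogram_ls"` or `"mle"`.
#' @param bin_width Histogram bin width, ms, used when a histogram must be
#'   built from raw maxima.
#' @return An object of class `evt_fit`: `family`, `shape_alpha` (`NA` for
#'   Gumbel), `location`, `scale`, `r_squared`, `method`, `m`, plus the
#'   Kolmogorov-Smirnov distance `ks` of the raw maxima to the fitted CDF
#'   when raw maxima were supplied.
#' @export
fit_extreme <- function(data, family = c("gumbel", "frechet"),
                        method = c("histogram_ls", "mle"),
                        bin_width = 1) {
  family <- match.arg(family)
  method <- match.arg(method)

  values <- NULL
  hist <- NULL
  if (inherits(data, "maxima_sample")) {
    values <- data$values
  } else if (inherits(data, "normalized_histogram")) {
    hist <- data
  } else if (is.numeric(data)) {
    values <- as.numeric(data)
  } else {
    stop("`data` must be maxima, a numeric vector, or a histogram",
         call. = FALSE)
  }
  if (!is.null(values)) {
    if (length(values) < 3) stop("too few maxima to fit", call. = FALSE)
    if (stats::sd(values) == 0) {
      stop("degenerate sample: all block maxima are identical; ",
           "an extreme-value fit is not meaningful", call. = FALSE)
    }
    hist <- normalized_histogram(values, bin_width)
  }
  if (is.null(values) && method == "mle") {
    stop("`mle` needs raw maxima, not a histogram", call. = FALSE)
  }

  fit <- if (method == "histogram_ls") {
    fit_histogram_ls(hist, family)
  } else {
    fit_mle(values, family)
  }

  predicted <- evt_pdf(bin_centers(hist), family, shape = fit$shape,
                       location = fit$location, scale = fit$scale) *
    hist$bin_width
  r2 <- r_squared(hist$masses, predicted)

  ks <- if (!is.null(values)) {
    ks_distance(values, function(x) {
      evt_cdf(x, family, shape = fit$shape,
              location = fit$location, scale = fit$scale)
    })
  } else NA_real_

  structure(list(family = family,
                 shape_alpha = if (family == "gumbel") NA_real_ else fit$shape,
                 location = fit$location, scale = fit$scale,
                 r_squared = r2, ks = ks, method = method,
                 m = if (is.null(values)) NA_integer_ else length(values),
                 objective = fit$objective,
                 convergence = fit$convergence),
            class = "evt_fit")
}

#' @export
print.evt_fit <- function(x, ...) {
  cat(sprintf("<evt_fit> %s (%s)\n", x$family, x$method))
  if (x$family != "gumbel") cat(sprintf("  shape alpha %.5g\n", x$shape_alpha))
  cat(sprintf("  location %.5g ms, scale %.5g ms\n", x$location, x$scale))
  cat(sprintf("  R-squared %.5f", x$r_squared))
  if (is.finite(x$ks)) cat(sprintf(", KS %.5f", x$ks))
  cat("\n")
  invisible(x)
}

# --- internal fitting machinery ---------------------------------------------

# moment-matching starts; for frechet, log-moment matching with location 0
start_values <- function(family, mean_x, sd_x, values = NULL) {
  if (family == "gumbel") {
    s0 <- max(sd_x * sqrt(6) / pi, .Machine$double.eps)
    list(location = mean_x - 0.5772156649 * s0, scale = s0)
  } else {
    if (!is.null(values) && all(values > 0)) {
      lx <- log(values)
      a0 <- pi / (stats::sd(lx) * sqrt(6))
      s0 <- exp(mean(lx) - 0.5772156649 / a0)
    } else {
      # histogram route: moments of log at bin centers are supplied as
      # mean_x, sd_x by the caller
      a0 <- pi / (sd_x * sqrt(6))
      s0 <- exp(mean_x - 0.5772156649 / a0)
    }
    list(shape = max(a0, 0.2), location = 0, scale = s0)
  }
}

optim_with_restarts <- function(par, fn, jitter_idx) {
  best <- NULL
  tried <- list()
  for (f in c(1, 0.5, 2)) {
    p0 <- par
    p0[jitter_idx] <- p0[jitter_idx] + log(f)
    o <- tryCatch(
      stats::optim(p0, fn, method = "Nelder-Mead",
                   control = list(maxit = 20000, reltol = 1e-14)),
      error = function(e) NULL)
    tried <- c(tried, list(o))
    if (!is.null(o) && is.finite(o$value)) {
      if (is.null(best) || o$value < best$value) best <- o
      if (o$convergence == 0) break
    }
  }
  if (is.null(best)) {
    stop("extreme-value fit failed to converge after restarts; ",
         "diagnostics: ", paste(vapply(tried, function(o) {
           if (is.null(o)) "error" else paste0("conv=", o$convergence)
         }, character(1)), collapse = ", "), call. = FALSE)
  }
  best
}

fit_histogram_ls <- function(hist, family) {
  ctr <- bin_centers(hist)
  mass <- hist$masses
  w <- hist$bin_width
  mean_h <- sum(ctr * mass)
  sd_h <- sqrt(max(sum(ctr^2 * mass) - mean_h^2, .Machine$double.eps))

  if (family == "gumbel") {
    st <- start_values("gumbel", mean_h, sd_h)
    obj <- function(p) {
      pred <- dgumbel(ctr, location = p[1], scale = exp(p[2])) * w
      sum((mass - pred)^2)
    }
    o <- optim_with_restarts(c(st$location, log(st$scale)), obj, 2L)
    list(shape = NULL, location = o$par[1], scale = exp(o$par[2]),
         objective = o$value, convergence = o$convergence)
  } else {
    pos <- mass > 0 & ctr > 0
    lm_ <- sum(log(ctr[pos]) * mass[pos]) / sum(mass[pos])
    ls_ <- sqrt(max(sum(log(ctr[pos])^2 * mass[pos]) / sum(mass[pos]) -
                      lm_^2, 1e-6))
    st <- start_values("frechet", lm_, ls_)
    obj <- function(p) {
      pred <- dfrechet(ctr, shape = exp(p[1]), location = p[2],
                       scale = exp(p[3])) * w
      sum((mass - pred)^2)
    }
    o <- optim_with_restarts(c(log(st$shape), st$location, log(st$scale)),
                             obj, c(1L, 3L))
    list(shape = exp(o$par[1]), location = o$par[2], scale = exp(o$par[3]),
         objective = o$value, convergence = o$convergence)
  }
}

fit_mle <- function(values, family) {
  if (family == "gumbel") {
    st <- start_values("gumbel", mean(values), stats::sd(values))
    nll <- function(p) {
      s <- exp(p[2])
      z <- (values - p[1]) / s
      length(values) * log(s) + sum(z) + sum(exp(-z))
    }
    o <- optim_with_restarts(c(st$location, log(st$scale)), nll, 2L)
    list(shape = NULL, location = o$par[1], scale = exp(o$par[2]),
         objective = o$value, convergence = o$convergence)
  } else {
    xmin <- min(values)
    st <- start_values("frechet", NA, NA, values = values)
    # location parameterized as xmin - exp(eta) so it stays below the sample
    eta0 <- log(max(xmin - st$location, .Machine$double.eps))
    nll <- function(p) {
      a <- exp(p[1]); loc <- xmin - exp(p[2]); s <- exp(p[3])
      y <- (values - loc) / s
      if (any(y <= 0)) return(Inf)
      -sum(log(a / s) + (-a - 1) * log(y) - y^(-a))
    }
    o <- optim_with_restarts(c(log(st$shape), eta0, log(st$scale)), nll,
                             c(1L, 3L))
    list(shape = exp(o$par[1]), location = xmin - exp(o$par[2]),
         scale = exp(o$par[3]),
         objective = o$value, convergence = o$convergence)
  }
}
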