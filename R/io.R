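# Times are serialized with 9 decimal places (ns resolution on a ms scale)
# and masses with 17 significant digits, so write -> read -> write is
# byte-identical.
fmt_ms <- function(x) sprintf("%.9f", x)
fmt_mass <- function(x) sprintf("%.17g", x)

#' Write and read block maxima as CSV
#'
#' Columns `trial_id`, `d_max_ms`; times fixed to 9 decimal places so the
#' round trip is lossless at that precision.
#'
#' @param x A [maxima_sample][block_maxima] or an `experiment_result`.
#' @param path Output path.
#' @return `path` (writer) or a `maxima_sample` (reader), invisibly for the
#'   writer.
#' @export
write_maxima_csv <- function(x, path) {
  if (inherits(x, "experiment_result")) x <- x$maxima
  stopifnot(inherits(x, "maxima_sample"))
  df <- data.frame(trial_id = seq_along(x$values),
                   d_max_ms = fmt_ms(x$values))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_maxima_csv
#' @export
read_maxima_csv <- function(path) {
  if (!file.exists(path)) {
    stop("maxima file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path)
  need <- c("trial_id", "d_max_ms")
  if (!all(need %in% names(df))) {
    stop("maxima CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  new_maxima_sample(as.numeric(df$d_max_ms),
                    block_description = paste("loaded from", path))
}

#' Write and read a normalized histogram as CSV
#'
#' Columns `bin_left_ms`, `bin_right_ms`, `mass`.
#'
#' @param h A [normalized_histogram()] or an `experiment_result`.
#' @param path Output path.
#' @return `path` (writer) or a `normalized_histogram` (reader).
#' @export
write_histogram_csv <- function(h, path) {
  if (inherits(h, "experiment_result")) h <- h$histogram
  stopifnot(inherits(h, "normalized_histogram"))
  edges <- h$bin_edges
  df <- data.frame(bin_left_ms = fmt_ms(edges[-length(edges)]),
                   bin_right_ms = fmt_ms(edges[-1]),
                   mass = fmt_mass(h$masses))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_histogram_csv
#' @export
read_histogram_csv <- function(path) {
  if (!file.exists(path)) {
    stop("histogram file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path)
  need <- c("bin_left_ms", "bin_right_ms", "mass")
  if (!all(need %in% names(df))) {
    stop("histogram CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  edges <- c(as.numeric(df$bin_left_ms), as.numeric(df$bin_right_ms)[nrow(df)])
  structure(list(bin_edges = edges, masses = as.numeric(df$mass),
                 bin_width = edges[2] - edges[1]),
            class = "normalized_histogram")
}

#' Write spike trains as CSV
#'
#' Long format, one row per spike: `trial_id`, `spike_time_ms`,
#' `interval_ms`.
#'
#' @param trains A list of `spike_train` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trains_csv <- function(trains, path) {
  stopifnot(is.list(trains))
  rows <- lapply(trains, function(tr) {
    stopifnot(inherits(tr, "spike_train"))
    if (length(tr$spike_times) == 0) return(NULL)
    data.frame(trial_id = tr$trial_id,
               spike_time_ms = fmt_ms(tr$spike_times),
               interval_ms = fmt_ms(tr$intervals))
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(trial_id = integer(0), spike_time_ms = character(0),
                     interval_ms = character(0))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trains_csv
#' @export
read_trains_csv <- function(path) {
  if (!file.exists(path)) {
    stop("spike-train file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path)
  need <- c("trial_id", "spike_time_ms", "interval_ms")
  if (!all(need %in% names(df))) {
    stop("spike-train CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$spike_time_ms <- as.numeric(df$spike_time_ms)
  df$interval_ms <- as.numeric(df$interval_ms)
  df
}

#' Write an experiment report as JSON
#'
#' A machine-readable record of one experiment: resolved configuration,
#' fitted parameters, goodness of fit, and diagnostics.
#'
#' @param result An `experiment_result` from [run_experiment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(result, path) {
  stopifnot(inherits(result, "experiment_result"))
  fit <- result$fit
  report <- list(
    schema_version = "1",
    generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config_to_list(result$config),
    fit = list(family = fit$family,
               shape_alpha = if (is.na(fit$shape_alpha)) NULL else
                 fit$shape_alpha,
               location_ms = fit$location,
               scale_ms = fit$scale,
               r_squared = fit$r_squared,
               ks_distance = fit$ks,
               method = fit$method),
    maxima = list(m = result$maxima$m,
                  mean_block_size = result$maxima$mean_block_size,
                  min_ms = min(result$maxima$values),
                  max_ms = max(result$maxima$values)),
    diagnostics = result$diagnostics)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Generate small deterministic fixture files
#'
#' Synthetic data files for tests and examples: `"tiny_train"` — a 10-spike
#' train in the spike-train CSV layout; `"gumbel_maxima"` — 500 draws from
#' Gumbel(location 40 ms, scale 5 ms); `"frechet_maxima"` — 500 draws from
#' Frechet(shape 20, location 0, scale 28 ms). Identical seed, identical
#' file.
#'
#' @param kind One of `"tiny_train"`, `"gumbel_maxima"`, `"frechet_maxima"`.
#' @param seed Non-negative integer seed.
#' @param dir Output directory.
#' @return The written file path.
#' @export
make_fixture <- function(kind = c("tiny_train", "gumbel_maxima",
                                  "frechet_maxima"),
                         seed = 0, dir = tempdir()) {
  kind <- match.arg(kind)
  stream <- make_stream(seed)
  path <- file.path(dir, sprintf("%s_seed%d.csv", kind, seed))
  if (kind == "tiny_train") {
    tr <- simulate_trial(lif_parameters(),
                         time_constant_model("exponential", 20, 5),
                         synapse_model(), stream, mode = "direct")
    tr$spike_times <- tr$spike_times[1:10]
    tr$intervals <- tr$intervals[1:10]
    write_trains_csv(list(tr), path)
  } else if (kind == "gumbel_maxima") {
    x <- qgumbel(stream_uniform(stream, 500), location = 40, scale = 5)
    write_maxima_csv(new_maxima_sample(x, block_description = "synthetic"),
                     path)
  } else {
    x <- qfrechet(stream_uniform(stream, 500), shape = 20, location = 0,
                  scale = 28)
    write_maxima_csv(new_maxima_sample(x, block_description = "synthetic"),
                     path)
  }
  path
}
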