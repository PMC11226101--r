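#' Load an experiment configuration from YAML
#'
#' The configuration file mirrors [experiment_config()]: optional top-level
#' keys `lif`, `tc`, `syn` (each a mapping of the corresponding constructor
#' arguments), and scalar keys `mode`, `trials_m`, `master_seed`,
#' `fit_family`, `fit_method`, `bin_width`, `allow_family_mismatch`. Omitted
#' keys take the package defaults (the standard constants); unknown keys are
#' rejected by name so typos cannot silently change an experiment.
#'
#' @param path Path to a YAML file.
#' @return A validated [experiment_config()].
#' @seealso [save_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  config_from_list(raw)
}

config_from_list <- function(raw) {
  known <- c("lif", "tc", "syn", "mode", "trials_m", "master_seed",
             "fit_family", "fit_method", "bin_width",
             "allow_family_mismatch")
  check_keys(raw, known, "top level")
  check_keys(raw$lif, c("v_rest", "v_reset", "v_init", "theta", "r",
                        "i_ext", "dt", "n_steps"), "lif")
  check_keys(raw$tc, c("family", "mu", "sigma", "convention"), "tc")
  check_keys(raw$syn, c("tau_s", "i_s0", "enabled"), "syn")

  args <- list(
    lif = do.call(lif_parameters, raw$lif %||% list()),
    tc = do.call(time_constant_model, raw$tc %||% list()),
    syn = do.call(synapse_model, raw$syn %||% list()))
  for (k in c("mode", "trials_m", "master_seed", "fit_family", "fit_method",
              "bin_width", "allow_family_mismatch")) {
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  }
  do.call(experiment_config, args)
}

check_keys <- function(x, known, where) {
  if (is.null(x)) return(invisible())
  bad <- setdiff(names(x), known)
  if (length(bad)) {
    stop(sprintf("unknown configuration key%s at %s: %s",
                 if (length(bad) > 1) "s" else "", where,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# full echo of a config as plain lists (YAML/JSON serializable)
config_to_list <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  list(
    lif = config$lif[c("v_rest", "v_reset", "v_init", "theta", "r", "i_ext",
                       "dt", "n_steps")],
    tc = config$tc[c("family", "mu", "sigma", "convention")],
    syn = config$syn[c("tau_s", "i_s0", "enabled")],
    mode = config$mode,
    trials_m = config$trials_m,
    master_seed = config$master_seed,
    fit_family = config$fit_family,
    fit_method = config$fit_method,
    bin_width = config$bin_width,
    allow_family_mismatch = config$allow_family_mismatch)
}

#' Save an experiment configuration to YAML
#'
#' Writes the full resolved configuration (all defaults made explicit), so
#' the file reloads to an identical experiment.
#'
#' @param config An [experiment_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}
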