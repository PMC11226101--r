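#' Leaky integrate-and-fire parameters
#'
#' Bundles the electrophysiological constants and the integration grid of the
#' threshold-and-reset membrane equation
#' `xi dV/dt = -(V - v_rest) + r * i_ext`. With `r` in MOhm and `i_ext` in nA
#' the drive `r * i_ext` is in mV (12 mV for the defaults), so the membrane
#' relaxes toward `v_rest + r * i_ext`. A spike is possible only when that
#' asymptote exceeds the threshold `theta`; the constructor records this as
#' `can_spike`.
#'
#' Defaults are the standard single-neuron constants used throughout the
#' package: rest/reset at -65 mV, threshold -55 mV, 1 MOhm, 12 nA, forward
#' Euler at `dt` = 1 ms for `n_steps` = 1000 steps (1000 ms per trial).
#'
#' @param v_rest Resting potential, mV.
#' @param v_reset Post-spike reset potential, mV.
#' @param v_init Initial potential, mV.
#' @param theta Firing threshold, mV.
#' @param r Membrane resistance, MOhm.
#' @param i_ext Constant external current, nA.
#' @param dt Euler time step, ms.
#' @param n_steps Number of integration steps per trial.
#' @return An object of class `lif_parameters`.
#' @export
lif_parameters <- function(v_rest = -65, v_reset = -65, v_init = -65,
                           theta = -55, r = 1, i_ext = 12,
                           dt = 1, n_steps = 1000) {
  stopifnot(is.numeric(dt), dt > 0, is.numeric(n_steps), n_steps >= 1,
            n_steps == trunc(n_steps), r > 0)
  p <- list(v_rest = v_rest, v_reset = v_reset, v_init = v_init,
            theta = theta, r = r, i_ext = i_ext,
            dt = dt, n_steps = as.integer(n_steps))
  p$drive <- r * i_ext # mV
  p$can_spike <- (v_rest + p$drive) > theta
  structure(p, class = "lif_parameters")
}

#' @export
print.lif_parameters <- function(x, ...) {
  cat("<lif_parameters>\n")
  cat(sprintf("  v_rest %g  v_reset %g  v_init %g  theta %g (mV)\n",
              x$v_rest, x$v_reset, x$v_init, x$theta))
  cat(sprintf("  r %g MOhm  i_ext %g nA  (drive %g mV, %s)\n",
              x$r, x$i_ext, x$drive,
              if (x$can_spike) "can spike" else "silent"))
  cat(sprintf("  dt %g ms x %d steps = %g ms per trial\n",
              x$dt, x$n_steps, x$dt * x$n_steps))
  invisible(x)
}

#' One forward-Euler step of the membrane equation
#'
#' Returns `v + (dt/xi) * (-(v - v_rest) + r * i_ext)`. The asymptote
#' `v_rest + r * i_ext` is a fixed point; for `dt < xi` the iterates approach
#' it monotonically without overshoot.
#'
#' @param v Membrane potential, mV (vectorized).
#' @param xi Current membrane time constant, ms; must be positive.
#' @param p A [lif_parameters()] object.
#' @return Updated potential(s), mV.
#' @export
euler_step <- function(v, xi, p) {
  stopifnot(inherits(p, "lif_parameters"))
  if (any(xi <= 0)) stop("time constant `xi` must be positive", call. = FALSE)
  v + (p$dt / xi) * (-(v - p$v_rest) + p$drive)
}

#' Closed-form first-passage time of the deterministic membrane equation
#'
#' For a neuron started at `v_init = v_reset = v_rest`, the continuous-time
#' solution reaches the threshold after
#' `xi * log(drive / (drive - (theta - v_rest)))`, with `drive = r * i_ext`.
#' Under the default constants this is `xi * log 6`. Used as the reference
#' period for the discretized simulator.
#'
#' @param xi Membrane time constant, ms.
#' @param p A [lif_parameters()] object with `v_rest + r * i_ext > theta`.
#' @return Threshold-crossing time, ms.
#' @export
analytic_first_spike_time <- function(xi, p) {
  stopifnot(inherits(p, "lif_parameters"), xi > 0)
  gap <- p$theta - p$v_rest
  if (p$drive <= gap) {
    stop("silent neuron: asymptote v_rest + r*i_ext does not exceed theta",
         call. = FALSE)
  }
  xi * log(p$drive / (p$drive - gap))
}

#' Exponential synapse model
#'
#' After each spike the synaptic current decays as
#' `i_s(t) = i_s0 * exp(-t / tau_s)`. The simulator uses this as a gating
#' condition: a new spike is registered only once the current has decayed
#' below `omega = i_s0 * exp(-1)`, i.e. once `tau_s` ms have elapsed since
#' the previous spike. `tau_s` defaults to 2 ms: synaptic decay is fast
#' relative to the membrane relaxation, so under the default constants the
#' gate never alters a spike time.
#'
#' @param tau_s Synaptic decay time constant, ms.
#' @param i_s0 Current immediately after a spike (arbitrary units).
#' @param enabled If `FALSE` the gate is ignored by the simulator.
#' @return An object of class `synapse_model`.
#' @export
synapse_model <- function(tau_s = 2, i_s0 = 1, enabled = TRUE) {
  stopifnot(is.numeric(tau_s), tau_s > 0, is.numeric(i_s0), i_s0 > 0,
            is.logical(enabled))
  structure(list(tau_s = tau_s, i_s0 = i_s0, enabled = enabled,
                 omega = i_s0 * exp(-1)),
            class = "synapse_model")
}

#' Synaptic current at a given time since the last spike
#'
#' @param syn A [synapse_model()].
#' @param t_since_spike Elapsed time since the last spike, ms (vectorized,
#'   non-negative).
#' @return Current in the units of `i_s0`.
#' @export
synapse_current <- function(syn, t_since_spike) {
  stopifnot(inherits(syn, "synapse_model"))
  if (any(t_since_spike < 0)) {
    stop("`t_since_spike` must be non-negative", call. = FALSE)
  }
  syn$i_s0 * exp(-t_since_spike / syn$tau_s)
}

#' Inter-spike intervals from spike times
#'
#' First differences of the spike times, prepended with `T_1 - 0`: the first
#' interval is measured from the trial start. Because trials begin at the
#' reset potential, the first cycle is statistically identical to later
#' ones, which makes the from-zero convention exact rather than approximate.
#'
#' @param spike_times Strictly increasing spike times, ms.
#' @param from_zero Include `T_1 - 0` as the first interval (default `TRUE`).
#' @return Numeric vector of intervals, ms.
#' @export
extract_intervals <- function(spike_times, from_zero = TRUE) {
  if (length(spike_times) == 0) return(numeric(0))
  if (any(!is.finite(spike_times)) || any(spike_times <= 0)) {
    stop("spike times must be finite and positive", call. = FALSE)
  }
  if (is.unsorted(spike_times, strictly = TRUE)) {
    stop("spike times must be strictly increasing", call. = FALSE)
  }
  if (from_zero) diff(c(0, spike_times)) else diff(spike_times)
}

new_spike_train <- function(trial_id, spike_times, mode, dt, t_total,
                            xi_draws = NULL, params_digest = "") {
  structure(
    list(trial_id = as.integer(trial_id),
         spike_times = spike_times,
         intervals = extract_intervals(spike_times),
         mode = mode, dt = dt, t_total = t_total,
         xi_draws = xi_draws, params_digest = params_digest),
    class = "spike_train"
  )
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> trial %d (%s mode): %d spikes in %g ms",
              x$trial_id, x$mode, length(x$spike_times), x$t_total))
  if (length(x$intervals)) {
    cat(sprintf(", max interval %.4g ms", max(x$intervals)))
  }
  cat("\n")
  invisible(x)
}

params_digest <- function(p, tc, syn, mode) {
  paste0(mode, "|lif:", paste(c(p$v_rest, p$v_reset, p$v_init, p$theta,
                                p$r, p$i_ext, p$dt, p$n_steps), collapse = ","),
         "|tc:", tc$family, ",", tc$mu, ",", tc$sigma, ",", tc$convention,
         "|syn:", syn$tau_s, ",", syn$i_s0, ",", syn$enabled)
}

#' Simulate one trial of the stochastic LIF neuron
#'
#' Two complementary generation modes are provided:
#'
#' * `mode = "direct"` (default): the inter-spike intervals `d_i` are drawn
#'   directly from the time-constant law xi(mu, sigma) and accumulated into
#'   spike times until the trial length `n_steps * dt` is exceeded. This
#'   realizes the interval law exactly and is the mode used for the
#'   extreme-value experiments.
#' * `mode = "ode"`: forward-Euler integration of the membrane equation on
#'   the `dt` grid. Whenever `V > theta` (strictly) and the synapse gate is
#'   open (gate disabled, or the synaptic current since the previous spike
#'   has decayed below `omega`), a spike is recorded, `V` is reset, the
#'   synapse clock restarts, and a fresh xi is drawn. Spike times are grid
#'   multiples of `dt`; each interval is the deterministic crossing time of
#'   its drawn xi (about `xi * log 6` under the default constants), so the
#'   interval distribution is the xi law rescaled.
#'
#' A configuration that cannot reach threshold yields an empty spike train
#' with a warning (not an error), so parameter sweeps do not abort.
#'
#' @param p [lif_parameters()].
#' @param tc [time_constant_model()].
#' @param syn [synapse_model()]; only consulted in `"ode"` mode.
#' @param stream [random_stream][make_stream] supplying the uniforms.
#' @param mode `"direct"` or `"ode"`.
#' @param trial_id Integer label stored on the result.
#' @return A `spike_train` with fields `spike_times`, `intervals` (from-zero
#'   convention), `xi_draws`, and provenance metadata.
#' @export
simulate_trial <- function(p, tc, syn = synapse_model(), stream,
                           mode = c("direct", "ode"), trial_id = 1L) {
  stopifnot(inherits(p, "lif_parameters"), inherits(tc, "time_constant_model"),
            inherits(syn, "synapse_model"), inherits(stream, "random_stream"))
  mode <- match.arg(mode)
  t_total <- p$n_steps * p$dt
  digest <- params_digest(p, tc, syn, mode)

  if (mode == "direct") {
    # every xi draw is >= mu, so ceiling(t_total/mu) + 1 draws always cover
    # the trial; surplus draws are discarded
    k <- ceiling(t_total / tc$mu) + 1
    d <- sample_xi(tc, stream, k)
    ts <- cumsum(d)
    spike_times <- ts[ts <= t_total]
    if (length(spike_times) == 0) {
      warning("no spikes within the trial window (mu exceeds trial length?)",
              call. = FALSE)
    }
    return(new_spike_train(trial_id, spike_times, mode, p$dt, t_total,
                           xi_draws = d[seq_along(spike_times)],
                           params_digest = digest))
  }

  # ode mode
  if (!p$can_spike) {
    warning("silent neuron: v_rest + r*i_ext <= theta; returning empty train",
            call. = FALSE)
    return(new_spike_train(trial_id, numeric(0), mode, p$dt, t_total,
                           xi_draws = numeric(0), params_digest = digest))
  }
  v <- p$v_init
  xi <- sample_xi(tc, stream, 1)
  xi_used <- xi
  last_spike <- -Inf
  spike_times <- numeric(0)
  coef <- p$dt / xi # recomputed only when xi changes
  for (k in seq_len(p$n_steps)) {
    v <- v + coef * (-(v - p$v_rest) + p$drive)
    t <- k * p$dt
    if (v > p$theta) {
      gate <- !syn$enabled ||
        synapse_current(syn, t - last_spike) < syn$omega
      if (gate) {
        spike_times <- c(spike_times, t)
        v <- p$v_reset
        last_spike <- t
        xi <- sample_xi(tc, stream, 1)
        xi_used <- c(xi_used, xi)
        coef <- p$dt / xi
      }
    }
  }
  new_spike_train(trial_id, spike_times, mode, p$dt, t_total,
                  xi_draws = xi_used[seq_along(spike_times)],
                  params_digest = digest)
}
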