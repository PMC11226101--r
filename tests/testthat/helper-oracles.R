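# Independent reference implementations used as oracles. These deliberately
# re-derive results with the plainest possible code, separate from the
# package's internals.

# scalar forward-Euler threshold-reset recurrence on the dt grid, fixed xi,
# no synapse gate
recurrence_spike_times <- function(xi, p) {
  v <- p$v_init
  spikes <- numeric(0)
  for (k in seq_len(p$n_steps)) {
    v <- v + (p$dt / xi) * (-(v - p$v_rest) + p$r * p$i_ext)
    if (v > p$theta) {
      spikes <- c(spikes, k * p$dt)
      v <- p$v_reset
    }
  }
  spikes
}

# steps until the recurrence first crosses theta from v_init (one period)
recurrence_period <- function(xi, p, max_steps = 1e6) {
  v <- p$v_init
  for (k in seq_len(max_steps)) {
    v <- v + (p$dt / xi) * (-(v - p$v_rest) + p$r * p$i_ext)
    if (v > p$theta) return(k * p$dt)
  }
  stop("no crossing within max_steps")
}

# brute-force Monte-Carlo block maxima from a quantile function
mc_block_maxima <- function(m, n, qfun) {
  val <- qfun(stats::runif(m))
  for (j in seq_len(n - 1)) val <- pmax(val, qfun(stats::runif(m)))
  val
}
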