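# Synthetic signals, spike trains and brute-force oracles used to test the
# analysis pipeline without running network simulations.

# run a block with a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Deterministic tone mixture
#'
#' Sum of sinusoids plus an optional linear trend and Gaussian noise with a
#' stated seed; the workhorse fixture for the spectral pipeline.
#'
#' @param components Data frame with columns `freq` (Hz), `amp`, and
#'   optionally `phase` (rad).
#' @param duration Length (ms).
#' @param fs Sampling frequency (Hz).
#' @param noise_sd Gaussian noise standard deviation.
#' @param trend Linear trend slope (units per second).
#' @param seed RNG seed for the noise stream.
#' @return Numeric series of `duration/1000 * fs` samples.
#' @export
make_tone_mixture <- function(components, duration = 6000, fs = 10000,
                              noise_sd = 0, trend = 0, seed = 1234) {
  if (fs <= 0) stop("fs must be positive")
  n <- round(duration / 1000 * fs)
  t <- seq_len(n) / fs
  x <- numeric(n)
  if (!is.null(components) && nrow(components) > 0) {
    if (is.null(components$phase)) components$phase <- 0
    for (i in seq_len(nrow(components)))
      x <- x + components$amp[i] *
        sin(2 * pi * components$freq[i] * t + components$phase[i])
  }
  x <- x + trend * t
  if (noise_sd > 0)
    x <- x + .with_seed(seed, rnorm(n, sd = noise_sd))
  x
}

#' Deterministic spike train
#'
#' @param pattern `list(type = "regular", interval = )` or
#'   `list(type = "burst", n = , intra = , inter = )` (ms).
#' @param duration Length (ms).
#' @return Spike times (ms).
#' @export
make_spike_train <- function(pattern, duration = 1000) {
  if (is.null(pattern) || is.null(pattern$type)) return(numeric(0))
  if (pattern$type == "regular") {
    if (pattern$interval <= 0) stop("interval must be positive")
    seq(pattern$interval, duration, by = pattern$interval)
  } else if (pattern$type == "burst") {
    if (pattern$intra <= 0 || pattern$inter <= 0)
      stop("intervals must be positive")
    starts <- seq(0, duration, by = pattern$inter)
    t <- as.numeric(outer(seq_len(pattern$n) - 1, starts,
                          function(i, s) s + i * pattern$intra))
    sort(t[t <= duration & t >= 0])
  } else stop("unknown pattern type: ", pattern$type)
}

#' Brute-force synapse oracle
#'
#' Fine-step explicit (midpoint) integration of the two-state scheme
#' ds/dt = alpha C (1 - s) - beta s, with C = C_max while any transmitter
#' pulse is active (a pulse spans `[t_spike, t_spike + C_dur]`; later spikes
#' retrigger and extend the window) and 0 otherwise.  Independent of the
#' closed-form [s_profile()] and of the compiled engine.
#'
#' @param spec A [synapse_spec()].
#' @param spike_times Presynaptic spike times (ms).
#' @param horizon Integration horizon (ms).
#' @param dt Oracle step (ms); keep at or below 0.001 for oracle precision
#'   (fast saturating synapses with alpha C_max near 10 /ms warrant 1e-4).
#' @param s0 Initial open fraction.
#' @return Data frame `time`, `s`.
#' @export
synapse_oracle <- function(spec, spike_times, horizon, dt = 0.001, s0 = 0) {
  n <- round(horizon / dt)
  t <- (seq_len(n + 1) - 1) * dt
  pulse_end <- -Inf
  s <- numeric(n + 1)
  s[1] <- s0
  k <- 1
  spike_times <- sort(spike_times)
  for (i in seq_len(n)) {
    ti <- t[i]
    while (k <= length(spike_times) && spike_times[k] <= ti + 1e-12) {
      pulse_end <- spike_times[k] + spec$C_dur
      k <- k + 1
    }
    # C held over [ti, ti+dt) as in the square-pulse protocol
    C <- if (ti < pulse_end - 1e-12) spec$C_max else 0
    f <- function(x) spec$alpha * C * (1 - x) - spec$beta * x
    half <- s[i] + dt / 2 * f(s[i])
    s[i + 1] <- s[i] + dt * f(half)
  }
  data.frame(time = t, s = s)
}
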