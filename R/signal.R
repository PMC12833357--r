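# Point-source LFP and the spectral pipeline: detrend + 1-15 Hz zero-phase
# Butterworth filtering, Welch PSD (Hann window, 20,000-sample segments,
# 1,000-sample overlap at fs = 10 kHz, i.e. 0.5 Hz bins), band powers and
# spindle/SWD state labels.

#' Electrode geometry for the point-source LFP
#'
#' The recorded cells of each layer-5 population are arranged on a line
#' `spacing` um apart with a virtual electrode `offset` um perpendicular to
#' the line's center.
#'
#' @param n_per_pop Integer vector: number of recorded cells per population
#'   (one entry per line).
#' @param spacing Inter-cell spacing (um).
#' @param offset Electrode offset from the line center (um).
#' @param Re Extracellular resistivity (Ohm cm).
#' @return List of class `thalnet_lfpgeom` with `r_cm` (distance of every
#'   recorded cell from the electrode, cm) and `Re`.
#' @export
lfp_geometry <- function(n_per_pop, spacing = 20, offset = 50, Re = 230) {
  r <- unlist(lapply(n_per_pop, function(n) {
    x <- (seq_len(n) - (n + 1) / 2) * spacing
    sqrt(x^2 + offset^2)
  }), use.names = FALSE)
  if (any(r <= 0)) stop("all source-electrode distances must be positive")
  structure(list(r_cm = r * 1e-4, Re = Re), class = "thalnet_lfpgeom")
}

#' Point-source local field potential
#'
#' V_ext(t) = (Re / 4 pi) * sum_i I_i(t) / r_i, treating each cell's total
#' postsynaptic current as a point source.
#'
#' @param currents Matrix of postsynaptic currents (nA), one column per
#'   recorded cell, or a `thalnet_sim` (whose per-receptor currents onto the
#'   LFP subset are summed).
#' @param geometry A [lfp_geometry()]; defaults to the simulation's recorded
#'   subset when `currents` is a `thalnet_sim`.
#' @return LFP series in volts.
#' @examples
#' # single 1 nA source at 50 um: about 3.66 uV
#' compute_lfp(matrix(1), lfp_geometry(1))
#' @export
compute_lfp <- function(currents, geometry = NULL) {
  if (inherits(currents, "thalnet_sim")) {
    sim <- currents
    if (is.null(geometry)) {
      npop <- as.integer(table(factor(sim$lfp_cells$class,
                                      levels = unique(sim$lfp_cells$class))))
      geometry <- lfp_geometry(npop)
    }
    currents <- sim$isyn$ampa + sim$isyn$gabaa + sim$isyn$gabab
  }
  currents <- as.matrix(currents)
  if (ncol(currents) != length(geometry$r_cm))
    stop("geometry does not match the number of recorded cells")
  amps <- currents * 1e-9  # nA -> A
  as.numeric(amps %*% (1 / geometry$r_cm)) * geometry$Re / (4 * pi)
}

#' Detrend and band-pass filter an LFP trace
#'
#' Removes a linear trend, then applies a zero-phase Butterworth band-pass
#' between 1 and 15 Hz, implemented as a cascade of an order-`order`
#' high-pass and an order-`order` low-pass, each run forward-backward
#' (a single band-pass of this relative bandwidth is numerically unstable in
#' transfer-function form at fs = 10 kHz).
#'
#' @param x LFP series.
#' @param fs Sampling frequency (Hz).
#' @param low,high Cutoff frequencies (Hz).
#' @param order Butterworth order of each cascade stage.
#' @return Filtered series, same length as `x`.
#' @export
preprocess <- function(x, fs = 10000, low = 1, high = 15, order = 4) {
  n <- length(x)
  if (n < 3 * fs / low / 10) stop("series too short for filter warm-up")
  tt <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, tt), x)
  x <- fit$residuals
  hp <- signal::butter(order, low / (fs / 2), type = "high")
  lp <- signal::butter(order, high / (fs / 2), type = "low")
  x <- signal::filtfilt(hp, x)
  x <- signal::filtfilt(lp, x)
  as.numeric(x)
}

#' Welch power spectral density
#'
#' Hann-windowed segments with the stated segment length and overlap,
#' averaged one-sided periodograms.  With the defaults (20,000 samples at
#' 10 kHz) the frequency resolution is 0.5 Hz.
#'
#' @param x Series (filtered LFP or synthetic signal).
#' @param fs Sampling frequency (Hz).
#' @param nperseg Segment length in samples.
#' @param overlap Overlap between consecutive segments in samples.
#' @return Data frame of class `thalnet_psd` with `freq` (Hz) and `power`
#'   (V^2/Hz density units).
#' @export
welch_psd <- function(x, fs = 10000, nperseg = 20000, overlap = 1000) {
  n <- length(x)
  if (n < nperseg) stop("input shorter than one Welch segment")
  step <- nperseg - overlap
  starts <- seq(1, n - nperseg + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nperseg - 1) / (nperseg - 1))  # Hann
  norm <- fs * sum(w^2)
  nfreq <- nperseg %/% 2 + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1)] * w
    X <- fft(seg)[seq_len(nfreq)]
    p <- (Mod(X)^2) / norm
    p[2:(nfreq - 1)] <- 2 * p[2:(nfreq - 1)]
    acc <- acc + p
  }
  out <- data.frame(freq = (seq_len(nfreq) - 1) * fs / nperseg,
                    power = acc / length(starts))
  class(out) <- c("thalnet_psd", "data.frame")
  attr(out, "fs") <- fs
  attr(out, "nperseg") <- nperseg
  out
}

# trapezoidal integral of the PSD over [f1, f2]
.band_power <- function(psd, f1, f2) {
  sel <- psd$freq >= f1 - 1e-9 & psd$freq <= f2 + 1e-9
  f <- psd$freq[sel]
  p <- psd$power[sel]
  if (length(f) < 2) return(0)
  sum(diff(f) * (head(p, -1) + tail(p, -1)) / 2)
}

#' Band powers, peak frequency and state label of a PSD
#'
#' Integrates the PSD over the SWD band (2.5-5 Hz) and the spindle band
#' (7-10 Hz), normalizes by the total 1-15 Hz power, and labels the state:
#' `spindle` when the peak lies in 7-10 Hz and the spindle band strictly
#' dominates, `SWD` when the peak lies in 2.5-5 Hz and the SWD band strictly
#' dominates, otherwise `intermediate`.  Peak ties resolve to the lowest
#' frequency bin.
#'
#' @param psd A [welch_psd()] result covering 1-15 Hz.
#' @param swd_band,spindle_band,total_band Frequency ranges (Hz).
#' @return List of class `thalnet_spectrum`: `peak_frequency`, `swd_power`,
#'   `spindle_power` (band integrals), `swd_rel`, `spindle_rel` (fractions of
#'   the total band), `state`.
#' @export
band_metrics <- function(psd, swd_band = c(2.5, 5), spindle_band = c(7, 10),
                         total_band = c(1, 15)) {
  if (nrow(psd) == 0) stop("empty PSD")
  if (max(psd$freq) < total_band[2]) stop("PSD does not cover the total band")
  sel <- psd$freq >= total_band[1] - 1e-9 & psd$freq <= total_band[2] + 1e-9
  sub <- psd[sel, ]
  peak <- sub$freq[which.max(sub$power)]  # which.max: first (lowest) bin wins
  swd <- .band_power(psd, swd_band[1], swd_band[2])
  spn <- .band_power(psd, spindle_band[1], spindle_band[2])
  tot <- .band_power(psd, total_band[1], total_band[2])
  swd_rel <- if (tot > 0) swd / tot else 0
  spn_rel <- if (tot > 0) spn / tot else 0
  state <- "intermediate"
  if (peak >= spindle_band[1] && peak <= spindle_band[2] && spn_rel > swd_rel)
    state <- "spindle"
  else if (peak >= swd_band[1] && peak <= swd_band[2] && swd_rel > spn_rel)
    state <- "SWD"
  structure(list(peak_frequency = peak, swd_power = swd, spindle_power = spn,
                 swd_rel = swd_rel, spindle_rel = spn_rel, state = state),
            class = "thalnet_spectrum")
}

#' @export
print.thalnet_spectrum <- function(x, ...) {
  cat(sprintf("state: %s  peak: %.1f Hz\n", x$state, x$peak_frequency))
  cat(sprintf("  SWD band (2.5-5 Hz):     %.3g V^2 (rel %.3f)\n",
              x$swd_power, x$swd_rel))
  cat(sprintf("  spindle band (7-10 Hz):  %.3g V^2 (rel %.3f)\n",
              x$spindle_power, x$spindle_rel))
  invisible(x)
}

#' Short-time spectrogram
#'
#' Hann-windowed short-time power map with the same window family as
#' [welch_psd()].
#'
#' @param x Series.
#' @param fs Sampling frequency (Hz).
#' @param window Window length in samples.
#' @param hop Hop between window starts in samples.
#' @return List with `time` (s, window centers), `freq` (Hz), `power`
#'   (matrix, frequency x time).
#' @export
spectrogram <- function(x, fs = 10000, window = 20000, hop = 5000) {
  n <- length(x)
  if (n < window) stop("input shorter than one window")
  starts <- seq(1, n - window + 1, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, window - 1) / (window - 1))
  norm <- fs * sum(w^2)
  nfreq <- window %/% 2 + 1
  pow <- matrix(0, nfreq, length(starts))
  for (k in seq_along(starts)) {
    seg <- x[starts[k]:(starts[k] + window - 1)] * w
    X <- fft(seg)[seq_len(nfreq)]
    p <- (Mod(X)^2) / norm
    p[2:(nfreq - 1)] <- 2 * p[2:(nfreq - 1)]
    pow[, k] <- p
  }
  list(time = (starts - 1 + window / 2) / fs,
       freq = (seq_len(nfreq) - 1) * fs / window,
       power = pow)
}
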