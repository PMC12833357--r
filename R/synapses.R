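# Two-state kinetic receptor model.  A presynaptic spike releases a square
# transmitter pulse of concentration C_max lasting C_dur ms; the fraction of
# open channels s(t) relaxes toward s_inf = alpha*C_max/(alpha*C_max + beta)
# with time constant tau_s = 1/(alpha*C_max + beta) during the pulse and
# decays as exp(-beta*t) afterwards.

#' Construct a synapse specification
#'
#' @param receptor `"AMPA"`, `"GABAA"` or `"GABAB"`.
#' @param g_syn Maximal synaptic conductance (uS), shared by the whole
#'   projection and divided by the in-degree per edge.
#' @param alpha Forward (binding) rate, (ms mM)^-1.
#' @param beta Backward (unbinding) rate, ms^-1.
#' @param C_dur Transmitter pulse duration (ms); 0.3 ms for Control synapses.
#' @param C_max Maximal transmitter concentration (mM).
#' @param E_syn Reversal potential (mV); defaults 0 (AMPA), -85 (GABAA),
#'   -95 (GABAB).
#' @param variant `"Control"` or `"post-ALLO"`.
#' @param gaba_scale Mutation scaling in (0,1\] applied to cortical GABAA
#'   maximal conductance.
#' @return List of class `thalnet_synapse`.
#' @export
synapse_spec <- function(receptor = c("AMPA", "GABAA", "GABAB"),
                         g_syn, alpha, beta, C_dur = 0.3, C_max = 0.5,
                         E_syn = NULL, variant = "Control", gaba_scale = 1) {
  receptor <- match.arg(receptor)
  if (is.null(E_syn))
    E_syn <- switch(receptor, AMPA = 0, GABAA = -85, GABAB = -95)
  if (g_syn < 0) stop("g_syn must be non-negative")
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be positive")
  if (C_dur <= 0 || C_max <= 0) stop("C_dur and C_max must be positive")
  if (gaba_scale <= 0 || gaba_scale > 1) stop("gaba_scale must be in (0,1]")
  structure(list(receptor = receptor, g_syn = g_syn, alpha = alpha,
                 beta = beta, C_dur = C_dur, C_max = C_max, E_syn = E_syn,
                 variant = variant, gaba_scale = gaba_scale),
            class = "thalnet_synapse")
}

#' Steady-state open fraction during a transmitter pulse
#' @param spec A [synapse_spec()].
#' @return alpha*C_max / (alpha*C_max + beta), in (0,1).
#' @export
s_inf <- function(spec) {
  ac <- spec$alpha * spec$C_max
  ac / (ac + spec$beta)
}

#' Relaxation time constant during a transmitter pulse
#' @param spec A [synapse_spec()].
#' @return 1 / (alpha*C_max + beta) in ms.
#' @export
tau_s <- function(spec) 1 / (spec$alpha * spec$C_max + spec$beta)

#' Closed-form open fraction after a single presynaptic spike
#'
#' For `0 <= t < C_dur` the channel relaxes toward [s_inf()]; for
#' `t >= C_dur` the pulse-end value decays as exp(-beta (t - C_dur)).
#'
#' @param spec A [synapse_spec()].
#' @param s0 Open fraction at the spike arrival, in \[0,1\].
#' @param t Time since spike arrival (ms), vectorized; must be >= 0.
#' @return Open fraction in \[0,1\].
#' @export
s_profile <- function(spec, s0, t) {
  if (any(t < 0)) stop("t must be non-negative")
  if (s0 < 0 || s0 > 1) stop("s0 must be in [0,1]")
  si <- s_inf(spec)
  ts <- tau_s(spec)
  send <- si + (s0 - si) * exp(-spec$C_dur / ts)
  ifelse(t < spec$C_dur,
         si + (s0 - si) * exp(-t / ts),
         send * exp(-spec$beta * (t - spec$C_dur)))
}

#' Synaptic current of one edge
#'
#' @param spec A [synapse_spec()].
#' @param s Open fraction in \[0,1\].
#' @param V Postsynaptic voltage (mV).
#' @param n_in In-degree of the projection; the edge weight is
#'   `g_syn/n_in` (times the mutation scale for cortical GABAA synapses).
#' @return Current in nA (uS x mV); converted to a density by the compartment
#'   area inside the membrane equation.
#' @export
synaptic_current <- function(spec, s, V, n_in = 1) {
  if (any(s < 0 | s > 1)) stop("s must be in [0,1]")
  scale <- if (spec$receptor == "GABAA") spec$gaba_scale else 1
  (spec$g_syn / n_in) * scale * s * (V - spec$E_syn)
}

#' Apply the allopregnanolone transform to a GABAA synapse
#'
#' Allopregnanolone (ALLO), a positive allosteric modulator of the GABAA
#' receptor, is modeled as fixed multiplicative changes of the kinetic
#' parameters: alpha x 1.58, beta x 0.74, g_max x 1.11, C_dur x 1.14.
#' The transform is deliberately non-idempotent: a synapse already in the
#' post-ALLO state cannot be transformed again.
#'
#' @param spec A Control GABAA [synapse_spec()].
#' @return The post-ALLO spec.
#' @export
apply_allo <- function(spec) {
  if (spec$receptor != "GABAA") stop("ALLO transform applies to GABAA synapses only")
  if (spec$variant != "Control") stop("synapse is already post-ALLO")
  spec$alpha <- 1.58 * spec$alpha
  spec$beta <- 0.74 * spec$beta
  spec$g_syn <- 1.11 * spec$g_syn
  spec$C_dur <- 1.14 * spec$C_dur
  spec$variant <- "post-ALLO"
  spec
}

#' Apply the GABRG2-type mutation scaling to a cortical GABAA synapse
#'
#' Loss-of-function mutations of the GABAA receptor gamma-2 subunit are
#' modeled as a reduction of the maximal GABAA conductance onto cortical
#' pyramidal neurons (RS, IB, NRS) to a fraction of baseline.
#'
#' @param spec A GABAA [synapse_spec()] targeting a cortical pyramidal class.
#' @param fraction Remaining conductance fraction, in (0,1\].
#' @return The spec with `gaba_scale` set.
#' @export
apply_mutation <- function(spec, fraction) {
  if (spec$receptor != "GABAA")
    stop("mutation scaling applies to GABAA synapses only")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0,1]")
  spec$gaba_scale <- fraction
  spec
}
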