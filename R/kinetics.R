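# Gating-kinetics registry.  Each entry is a voltage-dependent gate with a
# steady state x_inf(V) in [0,1] and a time constant tau(V) in ms (> 0).
# Cortical entries follow the Traub-type single-compartment reduction;
# thalamic entries (tcna/tck/it/its/htc and the reticular variants) follow
# the Destexhe-type relay/reticular models.  The rate functions themselves
# are evaluated in compiled code; this file exposes them to R.

.kin_ids <- c(
  naf_m = 0L, naf_h = 1L, nap_m = 2L, kdr_m = 3L, ka_m = 4L, ka_h = 5L,
  k2_m = 6L, k2_h = 7L, km_m = 8L, kc_m = 9L, cat_m = 10L, cat_h = 11L,
  cal_m = 12L, ar_m = 13L,
  tcna_m = 14L, tcna_h = 15L, tck_n = 16L,
  rena_m = 17L, rena_h = 18L, rek_n = 19L,
  it_m = 20L, it_h = 21L, its_m = 22L, its_h = 23L, htc_m = 24L, htc2_m = 25L
)

.kin_id <- function(name) {
  if (is.null(name) || is.na(name)) return(-1L)
  id <- .kin_ids[name]
  if (is.na(id)) stop("unknown kinetics entry: ", name)
  unname(id)
}

#' Names of all registered gating-kinetics entries
#' @return Character vector of gate names (activation `_m`, inactivation `_h`).
#' @export
list_kinetics <- function() names(.kin_ids)

#' Look up a gating-kinetics entry
#'
#' Returns the registered gate as a pair of vectorized functions of membrane
#' voltage: `steady_state(V)` (dimensionless, in \[0,1\]) and
#' `time_constant(V)` (ms, strictly positive).
#'
#' @param name One of [list_kinetics()].
#' @return A list of class `thalnet_kinetics` with elements `name`,
#'   `steady_state` and `time_constant`.
#' @examples
#' kin <- gating_kinetics("it_m")
#' kin$steady_state(c(-80, -60, -40))
#' @export
gating_kinetics <- function(name) {
  id <- .kin_id(name)
  structure(list(
    name = name,
    steady_state = function(V) cpp_kin_inf(id, as.numeric(V)),
    time_constant = function(V) cpp_kin_tau(id, as.numeric(V))
  ), class = "thalnet_kinetics")
}

#' Advance a gate variable by one time step
#'
#' First-order relaxation dx/dt = (x_inf(V) - x) / tau(V), integrated with the
#' exact-exponential update (default) or a plain explicit Euler step.
#'
#' @param kinetics A [gating_kinetics()] object.
#' @param gate Current gate value in \[0,1\].
#' @param V Membrane voltage (mV), held fixed over the step.
#' @param dt Step size (ms), must be positive.
#' @param method `"exponential"` (exact for fixed V) or `"euler"`.
#' @return Updated gate value, guaranteed to stay in \[0,1\] for the
#'   exponential method.
#' @export
gate_step <- function(kinetics, gate, V, dt, method = c("exponential", "euler")) {
  method <- match.arg(method)
  if (any(dt <= 0)) stop("dt must be positive")
  if (any(gate < 0 | gate > 1)) stop("gate value must be in [0,1]")
  xinf <- kinetics$steady_state(V)
  tau <- kinetics$time_constant(V)
  if (method == "exponential") {
    gate + (xinf - gate) * (1 - exp(-dt / tau))
  } else {
    gate + dt * (xinf - gate) / tau
  }
}
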