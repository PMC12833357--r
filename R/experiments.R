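# Scenario driver: the experiment matrix over layer-5 composition, cortical
# GABAA fraction, the ALLO transform and frontocortical enhancement.

#' Define a scenario
#'
#' @param nIB,nRS Layer-5 composition (sum 100).
#' @param gaba_fraction Cortical GABAA fraction of baseline, in (0,1].
#' @param allo Apply the post-ALLO transform to all GABAA synapses.
#' @param enhancement `(F_IBIB, F_IBNRS, F_NRSIB)`, each >= 1.
#' @param label Optional label; autogenerated when `NULL`.
#' @return List of class `thalnet_scenario`.
#' @export
scenario <- function(nIB = 75, nRS = 100 - nIB, gaba_fraction = 1,
                     allo = FALSE, enhancement = c(1, 1, 1), label = NULL) {
  if (nIB + nRS != 100) stop("layer-5 composition nIB + nRS must equal 100")
  if (gaba_fraction <= 0 || gaba_fraction > 1)
    stop("gaba_fraction must be in (0,1]")
  if (is.null(label)) {
    label <- sprintf("%d-%d gaba=%g%s%s", nIB, nRS, gaba_fraction,
                     if (allo) " ALLO" else "",
                     if (any(enhancement > 1))
                       paste0(" enh=(", paste(enhancement, collapse = ","), ")")
                     else "")
  }
  structure(list(nIB = nIB, nRS = nRS, gaba_fraction = gaba_fraction,
                 allo = allo, enhancement = enhancement, label = label),
            class = "thalnet_scenario")
}

#' Run one scenario end to end
#'
#' Builds the network for the scenario, runs the settle-stimulate-record
#' protocol, computes the point-source LFP from the recorded layer-5 subset,
#' filters it, and summarizes the Welch PSD into band powers, the peak
#' network frequency and a spindle/SWD state label.
#'
#' @param s A [scenario()].
#' @param protocol A [default_protocol()].
#' @param keep_sim Attach the full simulation object to the result.
#' @return A `thalnet_spectrum` (see [band_metrics()]) with added fields
#'   `scenario`, `psd`, and optionally `sim`.
#' @export
run_scenario <- function(s, protocol = default_protocol(), keep_sim = FALSE) {
  stopifnot(inherits(s, "thalnet_scenario"))
  cfg <- network_config(nIB = s$nIB, nRS = s$nRS,
                        gaba_fraction = s$gaba_fraction, allo = s$allo,
                        enhancement = s$enhancement)
  net <- build_network(cfg)
  sim <- run_network(net, protocol)
  lfp <- compute_lfp(sim)
  filt <- preprocess(lfp, fs = 1000 / protocol$record_dt)
  psd <- welch_psd(filt, fs = 1000 / protocol$record_dt)
  out <- band_metrics(psd)
  out$scenario <- s
  out$psd <- psd
  if (keep_sim) out$sim <- sim
  out
}

#' Sweep cortical GABAA conductance
#'
#' Runs one Control-synapse scenario per conductance fraction and collates
#' peak frequency, SWD-band relative power and the state label.
#'
#' @param nIB,nRS Layer-5 composition.
#' @param fractions Conductance fractions in (0,1], any order.
#' @param enhancement Enhancement factors.
#' @param protocol A [default_protocol()].
#' @param runner Scenario runner (injectable for caching); must accept
#'   `(scenario, protocol)`.
#' @return Data frame of class `thalnet_sweep` with one ascending row per
#'   fraction: `gaba_fraction`, `peak_frequency`, `swd_rel`, `state`.
#' @export
sweep_gaba <- function(nIB = 75, nRS = 100 - nIB,
                       fractions = seq(0.1, 1, length.out = 10),
                       enhancement = c(1, 1, 1),
                       protocol = default_protocol(),
                       runner = run_scenario) {
  if (length(fractions) == 0) stop("empty fraction list")
  if (any(fractions <= 0 | fractions > 1)) stop("fractions must be in (0,1]")
  fractions <- sort(fractions)
  rows <- lapply(fractions, function(f) {
    r <- runner(scenario(nIB = nIB, nRS = nRS, gaba_fraction = f,
                         enhancement = enhancement), protocol)
    data.frame(gaba_fraction = f, peak_frequency = r$peak_frequency,
               swd_rel = r$swd_rel, state = r$state,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("thalnet_sweep", "data.frame")
  out
}

#' Post-ALLO remission matrix
#'
#' Runs the composition x connectivity matrix: each layer-5 composition is
#' initialized in the diseased state (10% cortical GABAA), the post-ALLO
#' transform is applied to every GABAA synapse, and the resulting state label
#' records whether the discharge resolves back to a spindle state.
#'
#' @param compositions List of `c(nIB, nRS)` pairs.
#' @param enhancements Named list of enhancement factor triplets.
#' @param gaba_fraction Diseased-state cortical GABAA fraction.
#' @param protocol A [default_protocol()].
#' @param runner Scenario runner (injectable for caching).
#' @return Data frame: `composition`, `connectivity`, `state`,
#'   `peak_frequency`, `spindle_rel`, `swd_rel`.
#' @export
remission_matrix <- function(compositions = list(c(75, 25), c(5, 95),
                                                 c(95, 5), c(50, 50)),
                             enhancements = list(baseline = c(1, 1, 1),
                                                 enhanced = c(7, 5, 3)),
                             gaba_fraction = 0.1,
                             protocol = default_protocol(),
                             runner = run_scenario) {
  rows <- list()
  for (comp in compositions) {
    for (en in names(enhancements)) {
      r <- runner(scenario(nIB = comp[1], nRS = comp[2],
                           gaba_fraction = gaba_fraction, allo = TRUE,
                           enhancement = enhancements[[en]]), protocol)
      rows[[length(rows) + 1]] <- data.frame(
        composition = paste0(comp[1], "-", comp[2]), connectivity = en,
        state = r$state, peak_frequency = r$peak_frequency,
        spindle_rel = r$spindle_rel, swd_rel = r$swd_rel,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
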