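# Cell templates: channel inventories, conductance densities and membrane
# parameters for the six cell classes.  Channel inventories follow the
# membrane equations of the network model exactly (cortical cells carry the
# full Traub-type set; TC carries Leak/KLeak/Naf/K/CaT/h; RE carries
# Leak/Naf/K/CaT).  Densities are calibration choices of the reduced
# single-compartment models (see the methods vignette) and are overridable.

.cell_classes <- c("RS", "IB", "NRS", "LTS", "TC", "RE")

#' Cell classes of the network
#' @return Character vector: RS, IB, NRS (cortical pyramidal), LTS (cortical
#'   interneuron), TC (thalamocortical relay), RE (thalamic reticular).
#' @export
cell_classes <- function() .cell_classes

# one channel row
.chan <- function(name, g_max, E_rev, N = 0L, M = 0L, act = NA, inact = NA,
                  ca_mode = 0L, is_ca = 0L) {
  data.frame(name = name, g_max = g_max, E_rev = E_rev, N = as.integer(N),
             M = as.integer(M), act = as.character(act),
             inact = as.character(inact), ca_mode = as.integer(ca_mode),
             is_ca = as.integer(is_ca), stringsAsFactors = FALSE)
}

# full cortical inventory with class-specific densities (S/cm^2)
.cortical_channels <- function(d) {
  rbind(
    .chan("Leak", d[["Leak"]], -67),
    .chan("Naf",  d[["Naf"]],   50, 3L, 1L, "naf_m", "naf_h"),
    .chan("Nap",  d[["Nap"]],   50, 1L, 0L, "nap_m"),
    .chan("Ka",   d[["Ka"]],   -95, 4L, 1L, "ka_m", "ka_h"),
    .chan("K2",   d[["K2"]],   -95, 1L, 1L, "k2_m", "k2_h"),
    .chan("Kdr",  d[["Kdr"]],  -95, 4L, 0L, "kdr_m"),
    .chan("Km",   d[["Km"]],   -95, 1L, 0L, "km_m"),
    .chan("Kc",   d[["Kc"]],   -95, 1L, 0L, "kc_m", NA, 1L),
    .chan("Kahp", d[["Kahp"]], -95, 1L, 0L, NA, NA, 2L),
    .chan("CaT",  d[["CaT"]],  125, 2L, 1L, "cat_m", "cat_h", 0L, 1L),
    .chan("CaL",  d[["CaL"]],  125, 2L, 0L, "cal_m", NA, 0L, 1L),
    .chan("h",    d[["h"]],    -35, 1L, 0L, "ar_m")
  )
}

.default_densities <- list(
  RS = c(Leak = 1e-4, Naf = 0.08, Nap = 3.2e-4, Ka = 0.008, K2 = 2e-4,
         Kdr = 0.06, Km = 6e-3, Kc = 8e-3, Kahp = 2.5e-3, CaT = 2e-4,
         CaL = 6e-4, h = 2.5e-5),
  IB = c(Leak = 1e-4, Naf = 0.08, Nap = 6e-4, Ka = 0.006, K2 = 2e-4,
         Kdr = 0.05, Km = 3e-3, Kc = 8e-3, Kahp = 1.2e-3, CaT = 1.5e-3,
         CaL = 1.2e-3, h = 2.5e-5),
  NRS = c(Leak = 1e-4, Naf = 0.08, Nap = 3.2e-4, Ka = 0.008, K2 = 2e-4,
          Kdr = 0.06, Km = 3e-3, Kc = 6e-3, Kahp = 1.6e-3, CaT = 2e-4,
          CaL = 6e-4, h = 2.5e-5),
  LTS = c(Leak = 1e-4, Naf = 0.08, Nap = 2e-4, Ka = 0.006, K2 = 2e-4,
          Kdr = 0.06, Km = 1e-3, Kc = 4e-3, Kahp = 3e-4, CaT = 8e-4,
          CaL = 4e-4, h = 2.5e-5)
)

#' Build the template for one cell class
#'
#' A template bundles membrane capacitance, compartment area, channel
#' inventory, calcium-pool parameters and the holding current. Channel
#' conductance densities may be overridden per channel.
#'
#' @param cell_class One of [cell_classes()].
#' @param densities Named numeric vector of conductance-density overrides
#'   (S/cm^2) applied on top of the class defaults, e.g. `c(CaT = 0)`.
#' @param area Compartment area in cm^2 (default: cylindrical soma with
#'   length = diameter = 100 um).
#' @param I_hold Holding current in nA, or `NA` to leave it for calibration
#'   (cortical classes; thalamic membrane equations carry no holding term and
#'   default to 0).
#' @return A list of class `thalnet_cell` with fields `cell_class`, `Cm`
#'   (uF/cm^2), `area`, `channels` (data frame), `I_hold`, `ca_phi`,
#'   `ca_tau` (ms) and `v_init` (mV).
#' @export
cell_template <- function(cell_class, densities = NULL,
                          area = pi * 1e-4, I_hold = NULL) {
  cell_class <- match.arg(cell_class, .cell_classes)
  if (area <= 0) stop("area must be positive")
  cortical <- cell_class %in% c("RS", "IB", "NRS", "LTS")
  if (cortical) {
    d <- .default_densities[[cell_class]]
    if (!is.null(densities)) d[names(densities)] <- densities
    channels <- .cortical_channels(d)
    Cm <- if (cell_class == "LTS") 1.0 else 0.9
    v_init <- -65
    ca_phi <- 1
  } else if (cell_class == "TC") {
    d <- c(Leak = 1e-5, KLeak = 7e-6, Naf = 0.09, K = 0.012, CaT = 3.5e-3,
           h = 3e-5)
    if (!is.null(densities)) d[names(densities)] <- densities
    channels <- rbind(
      .chan("Leak",  d[["Leak"]],  -70),
      .chan("KLeak", d[["KLeak"]], -100),
      .chan("Naf",   d[["Naf"]],    50, 3L, 1L, "tcna_m", "tcna_h"),
      .chan("K",     d[["K"]],    -100, 4L, 0L, "tck_n"),
      .chan("CaT",   d[["CaT"]],   120, 2L, 1L, "it_m", "it_h", 0L, 1L),
      .chan("h",     d[["h"]],     -43, 1L, 0L, "htc_m")
    )
    Cm <- 1.0
    v_init <- -68
    ca_phi <- 0
  } else { # RE
    d <- c(Leak = 5e-5, Naf = 0.1, K = 0.01, CaT = 3e-3)
    if (!is.null(densities)) d[names(densities)] <- densities
    channels <- rbind(
      .chan("Leak", d[["Leak"]], -80),
      .chan("Naf",  d[["Naf"]],   50, 3L, 1L, "rena_m", "rena_h"),
      .chan("K",    d[["K"]],  -100, 4L, 0L, "rek_n"),
      .chan("CaT",  d[["CaT"]],  120, 2L, 1L, "its_m", "its_h", 0L, 1L)
    )
    Cm <- 1.0
    v_init <- -78
    ca_phi <- 0
  }
  if (any(channels$g_max < 0)) stop("negative g_max in channel table")
  if (is.null(I_hold)) I_hold <- if (cortical) NA_real_ else 0
  structure(list(
    cell_class = cell_class, Cm = Cm, area = area, channels = channels,
    I_hold = I_hold, ca_phi = ca_phi, ca_tau = 100, v_init = v_init
  ), class = "thalnet_cell")
}

#' Ionic current density of one channel
#'
#' Evaluates g_max * m^N * h^M * (V - E_rev).  Positive values are outward;
#' the membrane equation subtracts ionic currents.
#'
#' @param channel A single-row channel data frame (one row of a template's
#'   `channels`) or a list with `g_max` (S/cm^2), `E_rev` (mV), `N`, `M`.
#' @param V Membrane voltage (mV).
#' @param m,h Gate values in \[0,1\].
#' @return Current density in mA/cm^2.
#' @examples
#' ch <- list(g_max = 0.01, E_rev = -90, N = 3, M = 1)
#' ionic_current(ch, V = -60, m = 0.5, h = 1)  # 0.0375
#' @export
ionic_current <- function(channel, V, m = 1, h = 1) {
  if (channel$g_max < 0) stop("negative g_max")
  if (any(m < 0 | m > 1) || any(h < 0 | h > 1)) stop("gates must be in [0,1]")
  channel$g_max * m^channel$N * h^channel$M * (V - channel$E_rev)
}

# convert a template to the compiled-engine parameter bundle
.class_params <- function(tpl) {
  ch <- tpl$channels
  mat <- cbind(
    ch$g_max, ch$E_rev, ch$N, ch$M,
    vapply(ch$act, .kin_id, integer(1)),
    vapply(ch$inact, .kin_id, integer(1)),
    ch$ca_mode, ch$is_ca
  )
  ih <- tpl$I_hold
  if (is.na(ih)) ih <- 0
  list(Cm = tpl$Cm, area = tpl$area, I_hold = ih, ca_phi = tpl$ca_phi,
       ca_tau = tpl$ca_tau, v_init = tpl$v_init, chan = mat)
}

#' Simulate one isolated cell
#'
#' Runs a template as a one-cell network with optional injected current
#' steps.  Used for calibration, phenotype checks and rebound-burst tests.
#'
#' @param template A [cell_template()] (or a class name).
#' @param duration Simulated time in ms.
#' @param steps Data frame of current steps with columns `on`, `off` (ms) and
#'   `amp` (nA), or `NULL`.
#' @param dt Integration step (ms).
#' @param record_dt Recording step (ms).
#' @return List with `time` (ms), `V` (mV), `spikes` (ms).
#' @export
run_cell <- function(template, duration = 1000, steps = NULL, dt = 0.025,
                     record_dt = 0.1) {
  if (is.character(template)) template <- cell_template(template)
  if (is.na(template$I_hold)) template$I_hold <- 0
  if (is.null(steps)) steps <- data.frame(on = numeric(), off = numeric(),
                                          amp = numeric())
  res <- cpp_run_network(
    cell_class = 0L, class_params = list(.class_params(template)),
    e_pre = integer(), e_post = integer(), e_w = numeric(),
    e_proj = integer(),
    proj_par = matrix(0, 0, 8),
    dt = dt, settle = 0, record = duration, record_dt = record_dt,
    stim_gid = rep(0L, nrow(steps)), stim_amp = as.numeric(steps$amp),
    stim_on = as.numeric(steps$on), stim_off = as.numeric(steps$off),
    vrec_gid = 0L, lfprec_gid = integer(),
    spike_thresh = 0, refractory = 2, v_abort = 150
  )
  list(time = seq(0, duration - record_dt, by = record_dt),
       V = as.numeric(res$V), spikes = res$spike_t)
}

# Bisection on I_hold so the isolated cell's mean membrane potential settles
# at `target` mV.  For targets below the cell's rheobase range this is a
# quiescent resting potential; for the suprathreshold operating points used
# by the default network it is the mean of the firing trajectory.
.calibrate_hold <- function(template, target, lo = -1.5, hi = 1.5,
                            tol = 0.1, maxit = 40, duration = 800) {
  rest_v <- function(ih) {
    template$I_hold <- ih
    out <- run_cell(template, duration = duration)
    mean(tail(out$V, 1000))
  }
  flo <- rest_v(lo); fhi <- rest_v(hi)
  if ((flo - target) * (fhi - target) > 0)
    return(if (abs(flo - target) < abs(fhi - target)) lo else hi)
  for (i in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    fm <- rest_v(mid)
    if (abs(fm - target) < tol) return(mid)
    if ((fm - target) * (flo - target) > 0) { lo <- mid; flo <- fm }
    else hi <- mid
  }
  mid
}

#' Calibrate the holding current of a cortical template
#'
#' Finds, by bisection, the constant injected current that holds the isolated
#' cell at a target resting potential.  Thalamic classes carry no holding
#' term in their membrane equations and are returned unchanged.
#'
#' @param template A [cell_template()].
#' @param target Target resting potential (mV); default -65 for cortical
#'   classes.
#' @param duration Length of each calibration run (ms); slow conductances
#'   (anomalous rectifier, slowly inactivating K) equilibrate over seconds,
#'   so precise subthreshold holding warrants 3000 ms or more.
#' @return The template with `I_hold` (nA) filled in.
#' @export
calibrate_hold <- function(template, target = -65, duration = 800) {
  if (!template$cell_class %in% c("RS", "IB", "NRS", "LTS")) return(template)
  key <- paste0(template$cell_class, ":", target, ":", duration, ":",
                paste(signif(template$channels$g_max, 8), collapse = ","))
  cache <- .thalnet_env$hold_cache
  if (is.null(cache)) cache <- .thalnet_env$hold_cache <- new.env()
  if (!is.null(cache[[key]])) {
    template$I_hold <- cache[[key]]
    return(template)
  }
  ih <- .calibrate_hold(template, target, duration = duration)
  cache[[key]] <- ih
  template$I_hold <- ih
  template$v_init <- target
  template
}

#' Classify the firing pattern of a trace or spike train
#'
#' Labels activity as `regular_spiking`, `bursting` or `silent` from the
#' inter-spike-interval (ISI) distribution: a cell is called bursting when at
#' least `burst_frac` of its ISIs are shorter than `intra_max` ms while the
#' distribution also contains ISIs longer than `inter_min` ms (the standard
#' ISI-bimodality heuristic).
#'
#' @param voltage Voltage trace (mV), regularly sampled, or `NULL` when
#'   `spike_times` is given directly.
#' @param dt Sampling step of `voltage` (ms).
#' @param threshold Spike threshold (mV).
#' @param spike_times Optional explicit spike times (ms), bypassing detection.
#' @param intra_max,inter_min,burst_frac Classifier criteria (ms, ms,
#'   fraction).
#' @return One of `"regular_spiking"`, `"bursting"`, `"silent"`.
#' @export
classify_firing <- function(voltage = NULL, dt = 0.1, threshold = 0,
                            spike_times = NULL, intra_max = 15,
                            inter_min = 50, burst_frac = 0.3) {
  if (is.null(spike_times)) {
    if (is.null(voltage) || length(voltage) == 0)
      stop("empty voltage trace")
    spike_times <- detect_spikes(voltage, dt = dt, threshold = threshold)
  }
  if (length(spike_times) < 2) {
    return(if (length(spike_times) == 0) "silent" else "regular_spiking")
  }
  isi <- diff(sort(spike_times))
  if (mean(isi < intra_max) >= burst_frac && any(isi > inter_min))
    "bursting"
  else
    "regular_spiking"
}
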