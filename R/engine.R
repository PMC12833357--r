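# Simulation protocol and the R-side wrapper around the compiled integrator.

#' Simulation protocol
#'
#' Settle-stimulate-record protocol: the network integrates for
#' `settle` ms to reach steady state (discarded), then a current stimulus is
#' applied to five layer-6 NRS cells at the start of the recorded window.
#'
#' @param settle Settle window (ms), discarded from recordings.
#' @param record Recorded window (ms); at least 4000 ms so that the Welch
#'   analysis has two full segments at 10 kHz.
#' @param dt Integration step (ms); must divide `record_dt`.
#' @param record_dt Recording step (ms); default 0.1 (10 kHz).
#' @param stim_targets 1-based NRS indices receiving the stimulus, or `NULL`
#'   for the five cells nearest the line's center.
#' @param stim_amp Stimulus amplitude (nA).
#' @param stim_dur Stimulus duration (ms).
#' @return List of class `thalnet_protocol`.
#' @export
default_protocol <- function(settle = 2000, record = 6000, dt = 0.025,
                             record_dt = 0.1, stim_targets = NULL,
                             stim_amp = 1, stim_dur = 100) {
  if (record < 4000)
    stop("record must be >= 4000 ms (two Welch segments at 10 kHz)")
  if (dt <= 0) stop("dt must be positive")
  m <- record_dt / dt
  if (abs(m - round(m)) > 1e-9) stop("dt must divide record_dt")
  structure(list(settle = settle, record = record, dt = dt,
                 record_dt = record_dt, stim_targets = stim_targets,
                 stim_amp = stim_amp, stim_dur = stim_dur),
            class = "thalnet_protocol")
}

# evenly spaced 1-based indices for the recorded LFP subset
.even_subset <- function(n, k) unique(round(seq(1, n, length.out = min(k, n))))

#' Run the network simulation
#'
#' Integrates the coupled membrane/gate/synapse system with the fixed-step
#' compiled engine, applies the stimulation protocol, and records voltages
#' (a configurable subset; default cell index 1 of each population), all
#' spikes, and per-receptor synaptic currents onto the layer-5 LFP subset.
#' Identical inputs give bitwise-identical outputs; no random numbers are
#' used anywhere.
#'
#' @param network A [build_network()] object.
#' @param protocol A [default_protocol()].
#' @param vrec Data frame (`class`, `idx`) of cells whose voltage to record,
#'   or `NULL` for the first cell of each population.
#' @return List of class `thalnet_sim`: `time` (ms within the recorded
#'   window), `V` (matrix, mV), `spikes` (data frame `cell_class`,
#'   `cell_idx`, `t` in absolute simulation time), `isyn` (list of nA
#'   matrices `ampa`, `gabaa`, `gabab` for the LFP subset), `lfp_cells`,
#'   `protocol`, `fingerprint`.
#' @export
run_network <- function(network, protocol = default_protocol(), vrec = NULL) {
  stopifnot(inherits(network, "thalnet_network"))
  counts <- network$counts
  gid0 <- network$gid0
  classes <- names(counts)

  cell_class <- rep(seq_along(counts) - 1L, counts)
  class_params <- lapply(network$cells, .class_params)

  ed <- network$edges
  pre_gid <- gid0[ed$pre_class] + ed$pre_idx - 1L
  post_gid <- gid0[ed$post_class] + ed$post_idx - 1L
  ord <- order(ed$proj, post_gid, pre_gid)
  ed <- ed[ord, ]
  pre_gid <- pre_gid[ord]
  post_gid <- post_gid[ord]
  ncell <- sum(counts)

  pr <- network$projections
  rec_id <- c(AMPA = 0, GABAA = 1, GABAB = 2)
  proj_par <- cbind(pr$s_inf, pr$tau_s, pr$beta, pr$C_dur, pr$E_syn,
                    rec_id[pr$receptor], gid0[pr$post], counts[pr$post])

  stim_targets <- protocol$stim_targets
  if (is.null(stim_targets)) {
    ctr <- (counts[["NRS"]] + 1) / 2
    stim_targets <- round(ctr) + (-2:2)
  }
  stim_gid <- gid0[["NRS"]] + as.integer(stim_targets) - 1L
  stim_on <- rep(protocol$settle, length(stim_gid))
  stim_off <- stim_on + protocol$stim_dur
  stim_amp <- rep(protocol$stim_amp, length(stim_gid))

  if (is.null(vrec))
    vrec <- data.frame(class = classes, idx = 1L)
  vrec_gid <- gid0[vrec$class] + vrec$idx - 1L

  lfp_cells <- do.call(rbind, lapply(c("RS", "IB"), function(cl) {
    idx <- .even_subset(counts[[cl]], network$config$lfp_n)
    data.frame(class = cl, idx = idx, gid = gid0[[cl]] + idx - 1L)
  }))

  res <- cpp_run_network(
    cell_class = cell_class, class_params = class_params,
    e_pre = as.integer(pre_gid), e_post = as.integer(post_gid),
    e_w = ed$weight, e_proj = as.integer(ed$proj - 1L),
    proj_par = proj_par,
    dt = protocol$dt, settle = protocol$settle, record = protocol$record,
    record_dt = protocol$record_dt,
    stim_gid = as.integer(stim_gid), stim_amp = stim_amp,
    stim_on = stim_on, stim_off = stim_off,
    vrec_gid = as.integer(vrec_gid),
    lfprec_gid = as.integer(lfp_cells$gid),
    spike_thresh = 0, refractory = 2, v_abort = 150)

  gid_class <- rep(classes, counts)
  gid_idx <- unlist(lapply(counts, seq_len), use.names = FALSE)
  spikes <- data.frame(cell_class = gid_class[res$spike_gid + 1L],
                       cell_idx = gid_idx[res$spike_gid + 1L],
                       t = res$spike_t, stringsAsFactors = FALSE)

  V <- res$V
  colnames(V) <- paste0(vrec$class, ".", vrec$idx)
  fp <- paste0("nIB=", counts[["IB"]], ";gaba=", network$config$gaba_fraction,
               ";allo=", network$config$allo, ";enh=",
               paste(network$config$enhancement, collapse = ","),
               ";settle=", protocol$settle, ";record=", protocol$record,
               ";dt=", protocol$dt)
  structure(list(
    time = seq(0, protocol$record - protocol$record_dt,
               by = protocol$record_dt),
    V = V, spikes = spikes,
    isyn = list(ampa = res$isyn_ampa, gabaa = res$isyn_gabaa,
                gabab = res$isyn_gabab),
    lfp_cells = lfp_cells, protocol = protocol, fingerprint = fp
  ), class = "thalnet_sim")
}

#' Detect spikes in a voltage trace
#'
#' Upward threshold crossings with a refractory merge window.
#'
#' @param voltage Voltage trace (mV), uniformly sampled.
#' @param dt Sampling step (ms).
#' @param threshold Crossing threshold (mV).
#' @param refractory Minimum separation (ms); later crossings within the
#'   window are merged into the preceding event.
#' @return Spike times (ms, time of first suprathreshold sample).
#' @export
detect_spikes <- function(voltage, dt = 0.1, threshold = 0, refractory = 2) {
  n <- length(voltage)
  if (n < 2) return(numeric(0))
  up <- which(voltage[-1] >= threshold & voltage[-n] < threshold)
  if (length(up) == 0) return(numeric(0))
  t <- up * dt
  # sequential refractory merge
  out <- numeric(0)
  last <- -Inf
  for (ti in t) {
    if (ti - last >= refractory) {
      out <- c(out, ti)
      last <- ti
    }
  }
  out
}

#' Pairwise population synchrony of a spike raster
#'
#' Mean pairwise Pearson correlation of binned spike counts across cells, a
#' simple synchrony statistic for comparing network states.
#'
#' @param spikes Spike data frame from [run_network()].
#' @param t_range Length-2 window (ms, absolute simulation time).
#' @param bin Bin width (ms).
#' @param classes Cell classes to include.
#' @return Mean pairwise correlation (cells with no spikes are skipped);
#'   `NA` if fewer than two active cells.
#' @export
spike_synchrony <- function(spikes, t_range, bin = 5,
                            classes = c("RS", "IB", "NRS")) {
  sp <- spikes[spikes$cell_class %in% classes &
                 spikes$t >= t_range[1] & spikes$t < t_range[2], ]
  if (nrow(sp) == 0) return(NA_real_)
  nbin <- floor((t_range[2] - t_range[1]) / bin)
  key <- paste(sp$cell_class, sp$cell_idx)
  cells <- unique(key)
  if (length(cells) < 2) return(NA_real_)
  counts <- vapply(cells, function(k) {
    b <- floor((sp$t[key == k] - t_range[1]) / bin) + 1
    tabulate(b[b >= 1 & b <= nbin], nbins = nbin)
  }, numeric(nbin))
  active <- apply(counts, 2, sd) > 0
  counts <- counts[, active, drop = FALSE]
  if (ncol(counts) < 2) return(NA_real_)
  cm <- suppressWarnings(stats::cor(counts))
  mean(cm[upper.tri(cm)], na.rm = TRUE)
}
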