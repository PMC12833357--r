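# Network construction: populations on a line, layer-dependent in-degrees,
# nearest-neighbour connectivity, weight normalization g_syn/nPrePost, and
# the configuration axes (layer-5 composition, cortical GABAA scaling, ALLO,
# frontocortical enhancement).

#' Read the synaptic parameter tables
#'
#' Reads the maximal-conductance (uS), binding-rate ((ms mM)^-1) and
#' unbinding-rate (ms^-1) tables shipped with the package (or user copies in
#' the same layout: rows = presynaptic class, columns = postsynaptic class;
#' the g_max table carries one row per receptor for dual GABAA/GABAB
#' projections, and the GABAB rows share their rates with the GABAA partner).
#'
#' @param dir Directory holding `synaptic_gmax.tsv`, `synaptic_alpha.tsv`,
#'   `synaptic_beta.tsv`; defaults to the package copies.
#' @return List with data frames `gmax`, `alpha`, `beta`.
#' @export
read_synapse_tables <- function(dir = NULL) {
  path <- function(f) {
    if (is.null(dir)) system.file("extdata", f, package = "thalnet")
    else file.path(dir, f)
  }
  list(gmax = read.delim(path("synaptic_gmax.tsv"), check.names = FALSE),
       alpha = read.delim(path("synaptic_alpha.tsv"), check.names = FALSE),
       beta = read.delim(path("synaptic_beta.tsv"), check.names = FALSE))
}

#' Write the synaptic parameter tables
#' @param dir Output directory.
#' @param tables As returned by [read_synapse_tables()].
#' @return Invisibly, the file paths written.
#' @export
write_synapse_tables <- function(dir, tables = read_synapse_tables()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(gmax = "synaptic_gmax.tsv", alpha = "synaptic_alpha.tsv",
             beta = "synaptic_beta.tsv")
  out <- character(0)
  for (nm in names(files)) {
    f <- file.path(dir, files[[nm]])
    write.table(tables[[nm]], f, sep = "\t", quote = FALSE, row.names = FALSE)
    out <- c(out, f)
  }
  invisible(out)
}

#' Population layout of the network
#'
#' Layer 5 always holds 100 pyramidal cells split between intrinsically
#' bursting (IB) and regular spiking (RS); the other populations are fixed
#' (75 layer-6 NRS, 100 LTS, 100 TC, 100 RE), for 475 cells in total.
#'
#' @param nIB,nRS Layer-5 composition; must sum to 100.
#' @return Named integer vector of population sizes in class order
#'   RS, IB, NRS, LTS, TC, RE.
#' @export
population_layout <- function(nIB = 75, nRS = 100 - nIB) {
  if (nIB + nRS != 100) stop("layer-5 composition nIB + nRS must equal 100")
  if (nIB < 1 || nRS < 1) stop("each layer-5 population needs at least one cell")
  c(RS = as.integer(nRS), IB = as.integer(nIB), NRS = 75L, LTS = 100L,
    TC = 100L, RE = 100L)
}

#' Per-postsynaptic-cell in-degree of a projection
#'
#' The published in-degree table for the default layout is reproduced exactly
#' by `min(base, ceiling(base * n_pre / n_post))` clamped to `[1, n_pre]`,
#' where `base` is 11 within the cortex or within the thalamus and 21 between
#' them.  The same rule regenerates in-degrees for non-default layer-5
#' compositions.
#'
#' @param base Connection radius in index units (11 or 21).
#' @param n_pre,n_post Population sizes.
#' @return Integer in-degree.
#' @export
in_degree <- function(base, n_pre, n_post) {
  if (n_pre < 1 || n_post < 1) stop("population sizes must be >= 1")
  k <- min(base, ceiling(base * n_pre / n_post))
  as.integer(max(1, min(k, n_pre)))
}

#' Nearest-neighbour edges of one projection
#'
#' Each postsynaptic cell receives exactly `n_in` edges from the `n_in`
#' presynaptic cells nearest in normalized line position (index/(count-1)),
#' ties broken toward the lower index, with no wraparound and no self-edges
#' for recurrent projections.
#'
#' @param n_pre,n_post Population sizes.
#' @param n_in In-degree (from [in_degree()]).
#' @param recurrent `TRUE` when pre and post are the same population.
#' @return Integer matrix with columns `pre`, `post` (1-based indices),
#'   `n_post * n_in` rows.
#' @export
connect <- function(n_pre, n_post, n_in, recurrent = FALSE) {
  if (n_in > n_pre) stop("in-degree exceeds presynaptic population size")
  if (recurrent && n_in > n_pre - 1)
    stop("in-degree exceeds available non-self presynaptic cells")
  pos <- function(n) if (n == 1) 0.5 else (seq_len(n) - 1) / (n - 1)
  pp <- pos(n_pre)
  qq <- pos(n_post)
  pre <- integer(n_post * n_in)
  post <- integer(n_post * n_in)
  for (j in seq_len(n_post)) {
    d <- abs(pp - qq[j])
    cand <- order(d, seq_len(n_pre))
    if (recurrent) cand <- cand[cand != j]
    idx <- cand[seq_len(n_in)]
    rows <- ((j - 1) * n_in + 1):(j * n_in)
    pre[rows] <- idx
    post[rows] <- j
  }
  cbind(pre = pre, post = post)
}

# the full projection set: pre, post, receptor, base radius
.projection_table <- function() {
  p <- function(pre, post, receptor, base)
    data.frame(pre = pre, post = post, receptor = receptor, base = base,
               stringsAsFactors = FALSE)
  rbind(
    p("RS", "RS", "AMPA", 11), p("RS", "IB", "AMPA", 11),
    p("RS", "NRS", "AMPA", 11), p("RS", "LTS", "AMPA", 11),
    p("IB", "RS", "AMPA", 11), p("IB", "IB", "AMPA", 11),
    p("IB", "NRS", "AMPA", 11), p("IB", "LTS", "AMPA", 11),
    p("NRS", "RS", "AMPA", 11), p("NRS", "IB", "AMPA", 11),
    p("NRS", "NRS", "AMPA", 11), p("NRS", "LTS", "AMPA", 11),
    p("NRS", "TC", "AMPA", 21), p("NRS", "RE", "AMPA", 21),
    p("LTS", "RS", "GABAA", 11), p("LTS", "RS", "GABAB", 11),
    p("LTS", "IB", "GABAA", 11), p("LTS", "IB", "GABAB", 11),
    p("LTS", "NRS", "GABAA", 11), p("LTS", "NRS", "GABAB", 11),
    p("TC", "RS", "AMPA", 21), p("TC", "IB", "AMPA", 21),
    p("TC", "NRS", "AMPA", 21), p("TC", "LTS", "AMPA", 21),
    p("TC", "RE", "AMPA", 11),
    p("RE", "TC", "GABAA", 11), p("RE", "TC", "GABAB", 11),
    p("RE", "RE", "GABAA", 11)
  )
}

#' Network configuration
#'
#' The four experiment axes: layer-5 composition, cortical GABAA conductance
#' fraction (disease axis), the ALLO transform flag, and frontocortical
#' enhancement factors for the IB->IB, IB->NRS and NRS->IB conductances.
#'
#' @param nIB,nRS Layer-5 composition (sum 100).
#' @param gaba_fraction Cortical GABAA conductance as a fraction of baseline,
#'   in (0,1\].
#' @param allo Apply the post-ALLO transform to every GABAA synapse.
#' @param enhancement Numeric length-3 vector `(F_IBIB, F_IBNRS, F_NRSIB)`,
#'   each >= 1.
#' @param tables Synaptic parameter tables ([read_synapse_tables()]).
#' @param gabab_alpha,gabab_beta Kinetic rates for GABAB synapses
#'   ((ms mM)^-1, ms^-1).  GABAB inhibition is metabotropic and an order of
#'   magnitude slower than GABAA; the defaults give a ~150 ms decay.  Set to
#'   `NA` to fall back to the GABAA partner rates from the tables.
#' @param lfp_n Number of layer-5 cells per population recorded for the LFP.
#' @param cell_overrides Named list of [cell_template()] objects replacing
#'   the defaults, keyed by class.
#' @return List of class `thalnet_config`.
#' @export
network_config <- function(nIB = 75, nRS = 100 - nIB, gaba_fraction = 1,
                           allo = FALSE, enhancement = c(1, 1, 1),
                           tables = read_synapse_tables(), lfp_n = 10,
                           cell_overrides = list(),
                           gabab_alpha = NA, gabab_beta = NA) {
  if (gaba_fraction <= 0 || gaba_fraction > 1)
    stop("gaba_fraction must be in (0,1]")
  if (length(enhancement) != 3 || any(enhancement < 1))
    stop("enhancement must be three factors >= 1")
  names(enhancement) <- c("IBIB", "IBNRS", "NRSIB")
  structure(list(counts = population_layout(nIB, nRS),
                 gaba_fraction = gaba_fraction, allo = allo,
                 enhancement = enhancement, tables = tables, lfp_n = lfp_n,
                 cell_overrides = cell_overrides,
                 gabab_alpha = gabab_alpha, gabab_beta = gabab_beta),
            class = "thalnet_config")
}

#' Scale frontocortical conductances of a configuration
#'
#' Multiplies the IB->IB, IB->NRS and NRS->IB maximal conductances by the
#' given factors, modelling the increased frontocortical connectivity seen in
#' treatment non-responders.
#'
#' @param config A [network_config()].
#' @param F_IBIB,F_IBNRS,F_NRSIB Factors >= 1.
#' @return The updated configuration.
#' @export
apply_enhancement <- function(config, F_IBIB = 7, F_IBNRS = 5, F_NRSIB = 3) {
  stopifnot(inherits(config, "thalnet_config"))
  f <- c(F_IBIB, F_IBNRS, F_NRSIB)
  if (any(f < 1)) stop("enhancement factors must be >= 1")
  config$enhancement <- config$enhancement * f
  names(config$enhancement) <- c("IBIB", "IBNRS", "NRSIB")
  config
}

# look up one parameter from a wide table; errors on absent projections
.tab_lookup <- function(tab, pre, post, receptor = NULL) {
  if ("receptor" %in% names(tab)) {
    row <- tab[tab$pre == pre & tab$receptor == receptor, , drop = FALSE]
  } else {
    row <- tab[tab$pre == pre, , drop = FALSE]
    if (nrow(row) > 1) row <- row[1, , drop = FALSE]
  }
  if (nrow(row) != 1 || !post %in% names(row))
    stop("no table entry for projection ", pre, "->", post)
  val <- row[[post]]
  if (is.na(val)) stop("projection ", pre, "->", post, " is absent")
  val
}

#' Build the network
#'
#' Realizes the full projection set (all AMPA projections, the dual
#' GABAA/GABAB LTS->pyramidal and RE->TC projections, RE->RE GABAA; LTS
#' receives AMPA only and the only cortical input to the thalamus is
#' NRS->TC / NRS->RE), computes in-degrees with [in_degree()], assigns edge
#' weights `g_syn / n_in` (times mutation scale and enhancement factor where
#' applicable), applies the ALLO transform when configured, and calibrates
#' cortical holding currents.  Construction is fully deterministic.
#'
#' @param config A [network_config()].
#' @return List of class `thalnet_network`: `config`, `counts`, `gid0`
#'   (0-based block offsets per class), `cells` (templates), `projections`
#'   (data frame with kinetics and weights), `edges` (data frame
#'   `pre_class`, `pre_idx`, `post_class`, `post_idx`, `receptor`, `weight`).
#' @export
build_network <- function(config = network_config()) {
  stopifnot(inherits(config, "thalnet_config"))
  counts <- config$counts
  classes <- names(counts)
  gid0 <- c(0, cumsum(counts))[seq_along(counts)]
  names(gid0) <- classes

  targets <- c(RS = -65, IB = -65, NRS = -65, LTS = -56)
  cells <- lapply(classes, function(cl) {
    tpl <- config$cell_overrides[[cl]]
    if (is.null(tpl)) tpl <- cell_template(cl)
    if (cl %in% names(targets) && is.na(tpl$I_hold))
      tpl <- calibrate_hold(tpl, targets[[cl]])
    tpl
  })
  names(cells) <- classes

  ptab <- .projection_table()
  tabs <- config$tables
  specs <- vector("list", nrow(ptab))
  n_in <- integer(nrow(ptab))
  g_eff <- numeric(nrow(ptab))
  for (i in seq_len(nrow(ptab))) {
    pre <- ptab$pre[i]; post <- ptab$post[i]; rec <- ptab$receptor[i]
    g <- .tab_lookup(tabs$gmax, pre, post, rec)
    a <- .tab_lookup(tabs$alpha, pre, post)
    b <- .tab_lookup(tabs$beta, pre, post)
    if (rec == "GABAB" && !is.na(config$gabab_alpha)) {
      a <- config$gabab_alpha
      b <- config$gabab_beta
    }
    sp <- synapse_spec(rec, g, a, b)
    # GABRG2-type scaling: cortical pyramidal GABAA targets only
    if (rec == "GABAA" && post %in% c("RS", "IB", "NRS") &&
        config$gaba_fraction < 1)
      sp <- apply_mutation(sp, config$gaba_fraction)
    if (config$allo && rec == "GABAA") sp <- apply_allo(sp)
    enh <- 1
    key <- paste0(pre, post)
    if (key %in% names(config$enhancement))
      enh <- config$enhancement[[key]]
    n_in[i] <- in_degree(ptab$base[i], counts[[pre]], counts[[post]])
    # recurrent projections exclude the self-edge, so at most n_pre - 1 inputs
    if (pre == post) n_in[i] <- min(n_in[i], counts[[pre]] - 1L)
    g_eff[i] <- sp$g_syn * sp$gaba_scale * enh
    specs[[i]] <- sp
  }

  edges <- vector("list", nrow(ptab))
  for (i in seq_len(nrow(ptab))) {
    pre <- ptab$pre[i]; post <- ptab$post[i]
    em <- connect(counts[[pre]], counts[[post]], n_in[i],
                  recurrent = pre == post)
    edges[[i]] <- data.frame(
      proj = i, pre_class = pre, pre_idx = em[, "pre"],
      post_class = post, post_idx = em[, "post"],
      receptor = ptab$receptor[i], weight = g_eff[i] / n_in[i],
      stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, edges)

  projections <- cbind(ptab, n_in = n_in, g_eff = g_eff,
                       s_inf = vapply(specs, s_inf, numeric(1)),
                       tau_s = vapply(specs, tau_s, numeric(1)),
                       beta = vapply(specs, function(s) s$beta, numeric(1)),
                       C_dur = vapply(specs, function(s) s$C_dur, numeric(1)),
                       E_syn = vapply(specs, function(s) s$E_syn, numeric(1)))

  structure(list(config = config, counts = counts, gid0 = gid0,
                 cells = cells, projections = projections, edges = edges,
                 synapses = specs),
            class = "thalnet_network")
}

#' @export
print.thalnet_network <- function(x, ...) {
  cat("thalnet network:", sum(x$counts), "cells (",
      paste(names(x$counts), x$counts, sep = "=", collapse = ", "), ")\n")
  cat("  edges:", nrow(x$edges), " projections:", nrow(x$projections), "\n")
  cat("  cortical GABAA fraction:", x$config$gaba_fraction,
      " ALLO:", x$config$allo, "\n")
  cat("  enhancement (IBIB, IBNRS, NRSIB):",
      paste(x$config$enhancement, collapse = ", "), "\n")
  invisible(x)
}
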