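## Functional-consequence protocols: EPSP transfer and dendritic delay,
## synapse-count-to-spike curves, axonal conduction velocity, and the
## fixed-membrane-time-constant control.

default_glu_synapse <- function() list(ampa = ampa_kinetics(),
                                       nmda = nmda_kinetics())

## build a passive (optionally active-soma) cable for an experiment
experiment_cable <- function(morph, cm, rm, ra, e_pas, F, spine_start_um,
                             rule, hh = NULL) {
  comps <- apply_spine_correction(discretize(morph, rule), F, spine_start_um)
  build_cable(comps, passive_params(cm, rm, ra, e_pas), hh = hh)
}

## most distal terminal section of a given kind
most_distal_section <- function(morph, kind, rule = dx_rule(fixed_um = 25)) {
  comps <- discretize(morph, rule)
  sel <- comps$kind == kind
  if (!any(sel)) stop("no sections of kind ", kind)
  comps$section_id[sel][which.max(comps$path_um[sel])]
}

#' EPSP transfer from a dendritic spine to the soma
#'
#' Places an explicit two-compartment spine on the most distal apical and
#' most distal basal terminal, activates an AMPA+NMDA synapse on the spine
#' head, and reports the local (spine-head) and somatic peak EPSP and the
#' dendritic delay (somatic minus local peak time) for each Cm condition
#' with the other cable parameters fixed.
#'
#' @param morph a [morphology()] object.
#' @param cm_values specific capacitance conditions, uF/cm^2.
#' @param rm,ra fixed passive parameters.
#' @param rm_values optional per-condition Rm vector (same length as
#'   `cm_values`), used by the fixed-tau control.
#' @param e_pas resting potential, mV.
#' @param F,spine_start_um spine correction.
#' @param rule discretization rule.
#' @param synapse list with `ampa` and `nmda` [syn_kinetics()] (either may
#'   be `NULL`).
#' @param t_stop_ms,dt simulation length and step.
#' @return data frame: one row per (site, Cm) with local and somatic peak
#'   EPSP (mV), peak times and dendritic delay (ms), plus a `spike` flag
#'   (a spike during this passive protocol indicates misconfiguration).
#' @export
epsp_transfer <- function(morph, cm_values = c(0.45, 0.9), rm = 38907,
                          ra = 203, rm_values = NULL, e_pas = -85,
                          F = 1.9, spine_start_um = 60, rule = dx_rule(),
                          synapse = default_glu_synapse(),
                          t_stop_ms = 150, dt = 0.025) {
  if (is.null(rm_values)) rm_values <- rep(rm, length(cm_values))
  out <- list()
  for (site in c("apical", "basal")) {
    sec <- most_distal_section(morph, site)
    sp <- add_spine(morph, sec)
    for (i in seq_along(cm_values)) {
      cable <- experiment_cable(sp$morph, cm_values[i], rm_values[i], ra,
                                e_pas, F, spine_start_um, rule)
      events <- syn_events(sp$head_id, onset = 5, synapse)
      tr <- simulate(cable, synapse_protocol(events), dt = dt,
                     t_stop = t_stop_ms,
                     record = list("soma", list(section = sp$head_id,
                                                pos = 0.5)))
      vs <- tr$v_mV[, 1] - tr$v_mV[1, 1]
      vl <- tr$v_mV[, 2] - tr$v_mV[1, 2]
      out[[length(out) + 1L]] <- data.frame(
        site = site, cm = cm_values[i], rm = rm_values[i],
        local_peak_mV = max(vl), soma_peak_mV = max(vs),
        local_peak_t_ms = tr$time_ms[which.max(vl)],
        soma_peak_t_ms = tr$time_ms[which.max(vs)],
        delay_ms = tr$time_ms[which.max(vs)] - tr$time_ms[which.max(vl)],
        spike = length(detect_spikes(tr)) > 0)
    }
  }
  do.call(rbind, out)
}

syn_events <- function(head_ids, onset, synapse, as_comps = FALSE) {
  ks <- list()
  locs <- list()
  ons <- numeric(0)
  for (h in head_ids) {
    for (k in synapse) {
      if (is.null(k)) next
      ks[[length(ks) + 1L]] <- k
      locs[[length(locs) + 1L]] <- if (as_comps) h
                                   else list(section = h, pos = 0.5)
      ons <- c(ons, onset)
    }
  }
  df <- data.frame(onset_ms = ons)
  df$location <- locs
  df$kinetics <- ks
  df
}

#' Synapse count needed for a somatic spike
#'
#' Distributes `N` explicit spinous synapses uniformly per unit dendritic
#' length over the spine territory (path distance >= `spine_start_um`),
#' activates them simultaneously on an active-soma model, and estimates
#' `p(spike | N)` over repeated random placements; `N50` is obtained by
#' linear interpolation of the probability curve.
#'
#' @param morph a [morphology()] object.
#' @param cm,rm,ra,e_pas,F,spine_start_um,rule cable setup as in
#'   [epsp_transfer()].
#' @param hh a [hh_channels()] somatic spike mechanism.
#' @param N_grid synapse counts to probe.
#' @param n_trials random placements per count (1000 in the full
#'   protocol; reduce for quick runs).
#' @param synapse AMPA/NMDA kinetics per synapse.
#' @param onset_ms activation time, ms.
#' @param t_stop_ms,dt simulation length and step.
#' @param seed RNG seed (placements are reproducible bit-for-bit).
#' @return list: `curve` (data frame `N`, `p_spike`), `n50`, `seed`.
#' @export
synapses_to_spike <- function(morph, cm = 0.45, rm = 38907, ra = 203,
                              e_pas = -85, F = 1.9, spine_start_um = 60,
                              rule = dx_rule(), hh = hh_channels(),
                              N_grid = c(0, 25, 50, 100, 150, 200, 300),
                              n_trials = 1000,
                              synapse = default_glu_synapse(),
                              onset_ms = 5, t_stop_ms = 40, dt = 0.025,
                              seed = 1) {
  ## candidate attachment points: dendritic terminal positions weighted by
  ## length within the spine territory
  comps0 <- apply_spine_correction(discretize(morph, rule), F, spine_start_um)
  cand <- which(comps0$kind %in% DENDRITE_KINDS &
                  comps0$path_um >= spine_start_um)
  if (length(cand) == 0L) stop("no dendritic membrane beyond spine_start_um")
  p_spike <- numeric(length(N_grid))
  with_seed(seed, {
    for (gi in seq_along(N_grid)) {
      N <- N_grid[gi]
      if (N == 0) { p_spike[gi] <- 0; next }
      hits <- 0L
      for (trial in seq_len(n_trials)) {
        at <- sample(cand, N, replace = TRUE,
                     prob = comps0$length_um[cand])
        ## one explicit spine per synapse at the sampled compartments
        sp <- attach_spines(comps0, at)
        cable <- build_cable(sp$comps, passive_params(cm, rm, ra, e_pas),
                             hh = hh)
        tr <- simulate(cable,
                       synapse_protocol(syn_events(sp$head_comps, onset_ms,
                                                   synapse, as_comps = TRUE)),
                       dt = dt, t_stop = t_stop_ms, settle_ms = 20)
        if (length(detect_spikes(tr)) > 0) hits <- hits + 1L
      }
      p_spike[gi] <- hits / n_trials
    }
  })
  curve <- data.frame(N = N_grid, p_spike = p_spike)
  list(curve = curve, n50 = interp_n50(curve), seed = seed)
}

interp_n50 <- function(curve) {
  p <- curve$p_spike; N <- curve$N
  i <- which(p >= 0.5)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) return(N[1])
  N[i - 1] + (0.5 - p[i - 1]) / (p[i] - p[i - 1]) * (N[i] - N[i - 1])
}

#' Axonal conduction velocity versus specific capacitance
#'
#' Attaches an unmyelinated axon (default 6 mm, 1 um), elicits a single
#' spike with a somatic pulse, and measures velocity from the
#' maximal-dV/dt times at two axonal sites bracketing 1 mm from the soma.
#'
#' @param morph a [morphology()] object (an axon is added).
#' @param cm_values Cm conditions, uF/cm^2.
#' @param rm,ra,e_pas,F,spine_start_um,rule cable setup.
#' @param rm_values optional per-condition Rm (fixed-tau control).
#' @param axon_rm membrane resistivity of the axon itself, Ohm cm^2;
#'   defaults to `rm`. The axon keeps its stated passive properties when
#'   the cell membrane's Rm is varied (e.g. in the fixed-tau control only
#'   the somatodendritic Rm is halved).
#' @param hh a [hh_channels()] (somatic + axonal densities).
#' @param axon_length_um,axon_diam_um axon geometry.
#' @param sites_um the two measurement distances along the axon, um.
#' @param stim somatic current pulse used to trigger the spike.
#' @param dt,t_stop_ms integration parameters.
#' @return data frame `cm`, `rm`, `velocity_m_s`; percent change between
#'   the first and last condition in attribute `"pct_increase"`.
#' @export
axon_velocity <- function(morph, cm_values = c(0.45, 0.9), rm = 38907,
                          ra = 203, rm_values = NULL, axon_rm = NULL,
                          e_pas = -85, F = 1.9,
                          spine_start_um = 60, rule = dx_rule(),
                          hh = hh_channels(),
                          axon_length_um = 6000, axon_diam_um = 1,
                          sites_um = c(900, 1100),
                          stim = current_step(1.5, delay_ms = 5, dur_ms = 2),
                          dt = 0.025, t_stop_ms = 40) {
  ax <- add_axon(morph, axon_length_um, axon_diam_um)
  if (is.null(rm_values)) rm_values <- rep(rm, length(cm_values))
  vel <- numeric(length(cm_values))
  for (i in seq_along(cm_values)) {
    cable <- experiment_cable(ax$morph, cm_values[i], rm_values[i], ra,
                              e_pas, F, spine_start_um, rule, hh = hh)
    if (!is.null(axon_rm)) {
      is_ax <- cable$comps$kind == "axon"
      cable$g_pas_uS[is_ax] <- cable$comps$area_um2[is_ax] *
        (1e-2 / axon_rm + hh$gl * 1e-6)
    }
    pos <- sites_um / axon_length_um
    tr <- simulate(cable, stim, dt = dt, t_stop = t_stop_ms,
                   record = list(list(section = ax$axon_id, pos = pos[1]),
                                 list(section = ax$axon_id, pos = pos[2])))
    ta <- list(time_ms = tr$time_ms, v_mV = tr$v_mV[, 1])
    tb <- list(time_ms = tr$time_ms, v_mV = tr$v_mV[, 2])
    ## snap the nominal separation to the actual compartment centres
    ca <- resolve_location(cable, list(section = ax$axon_id, pos = pos[1]))
    cb <- resolve_location(cable, list(section = ax$axon_id, pos = pos[2]))
    d_um <- abs(cable$comps$path_um[cb] - cable$comps$path_um[ca])
    vel[i] <- conduction_velocity(ta, tb, d_um)
  }
  out <- data.frame(cm = cm_values, rm = rm_values, velocity_m_s = vel)
  attr(out, "pct_increase") <- 100 * (vel[1] / vel[length(vel)] - 1)
  out
}

#' Fixed membrane-time-constant control
#'
#' Re-runs the EPSP-transfer comparison with tau_m held fixed across the
#' two Cm conditions by a compensating change in Rm (doubling Cm halves
#' Rm), separating capacitance-specific effects from time-constant
#' effects.
#'
#' @param morph a [morphology()] object.
#' @param cm_pair the two Cm conditions.
#' @param rm_at_low Rm paired with the low-Cm condition, Ohm cm^2.
#' @param ... forwarded to [epsp_transfer()].
#' @return list: `tau_m_ms` (identical across conditions by construction),
#'   `epsp` (the [epsp_transfer()] table under the fixed-tau pairing).
#' @export
fixed_tau_control <- function(morph, cm_pair = c(0.45, 0.9),
                              rm_at_low = 38907, ...) {
  rm_values <- rm_at_low * cm_pair[1] / cm_pair
  tau <- cm_pair * rm_values / 1000
  epsp <- epsp_transfer(morph, cm_values = cm_pair, rm_values = rm_values,
                        ...)
  list(tau_m_ms = tau, epsp = epsp)
}
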