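## Simulation layer: assemble the compartmental system, run stimulus
## protocols through the C++ Crank-Nicolson/Hines core, record voltages,
## detect spikes, measure conduction velocity.

#' Build a simulatable cable from compartments and mechanisms
#'
#' Converts the geometric compartment table into the per-node electrical
#' vectors the integrator needs. The spine correction enters here: each
#' compartment's capacitance is multiplied and its leak conductance
#' divided-by-Rm scaled by its `spine_factor` (Cm * F, Rm / F).
#'
#' @param comps compartment table from [discretize()] (optionally after
#'   [apply_spine_correction()]).
#' @param passive a [passive_params()]; its `rm` is ignored when
#'   `rm_nonuniform` is supplied.
#' @param rm_nonuniform optional [nonuniform_rm()] evaluated at each
#'   compartment's path distance.
#' @param ih optional [ih_distribution()]; apical compartments follow the
#'   exponential distance rule, soma and basal the somatic density, axon
#'   and explicit spines carry none.
#' @param hh optional [hh_channels()]; applied to soma (somatic densities)
#'   and axon (axonal densities) compartments only.
#' @return object of class `cable` (list of per-node vectors plus the
#'   compartment table for location lookup).
#' @export
build_cable <- function(comps, passive, rm_nonuniform = NULL, ih = NULL,
                        hh = NULL) {
  n <- nrow(comps)
  f <- comps$spine_factor
  area <- comps$area_um2
  rm <- if (is.null(rm_nonuniform)) rep(passive$rm, n)
        else rm_profile(comps$path_um, rm_nonuniform)

  cap_nF <- passive$cm * f * area * 1e-5          # uF/cm^2 * um^2 -> nF
  g_pas_uS <- area * f * 1e-2 / rm                # um^2 / (Ohm cm^2) -> uS
  g_ax_uS <- ifelse(comps$parent > 0,
                    1 / (passive$ra * comps$ra_unit_Mohm), 0)

  g_na <- g_k <- g_h <- numeric(n)
  if (!is.null(hh)) {
    is_soma <- comps$kind == "soma"
    is_axon <- comps$kind == "axon"
    g_na[is_soma] <- hh$gna_soma * area[is_soma] * 1e-6   # pS/um^2*um^2 -> uS
    g_k[is_soma]  <- hh$gk_soma  * area[is_soma] * 1e-6
    g_na[is_axon] <- hh$gna_axon * area[is_axon] * 1e-6
    g_k[is_axon]  <- hh$gk_axon  * area[is_axon] * 1e-6
    ## the spike mechanism's own leak (at e_pas) on HH-bearing membrane
    hhm <- is_soma | is_axon
    g_pas_uS[hhm] <- g_pas_uS[hhm] + hh$gl * area[hhm] * 1e-6
  }
  if (!is.null(ih) && ih$g_soma > 0) {
    dens <- numeric(n)
    ap <- comps$kind == "apical"
    fl <- comps$kind %in% c("soma", "basal")
    dens[ap] <- ih_density(comps$path_um[ap], ih$g_soma, "apical")
    dens[fl] <- ih$g_soma
    g_h <- dens * area * 1e-5                      # mS/cm^2 * um^2 -> uS
  }

  structure(list(
    parent = as.integer(comps$parent) - 1L,  # 0-based, root -1
    cap_nF = cap_nF, g_pas_uS = g_pas_uS,
    e_pas_mV = rep(passive$e_pas, n), g_ax_uS = g_ax_uS,
    g_na_uS = g_na, g_k_uS = g_k, g_h_uS = g_h,
    e_na_mV = if (is.null(hh)) 50 else hh$e_na,
    e_k_mV = if (is.null(hh)) -85 else hh$e_k,
    e_h_mV = if (is.null(ih)) -45 else ih$e_h,
    na_m_shift_mV = if (is.null(hh)) numeric(n) else
      ifelse(comps$kind == "soma", hh$m_shift_mV, 0),
    comps = comps, passive = passive,
    has_ih = !is.null(ih) && ih$g_soma > 0,
    has_hh = !is.null(hh)), class = "cable")
}

#' Resolve a recording/stimulation location to a compartment index
#'
#' Locations are `list(section = id, pos = x)` (snapped to the nearest
#' compartment centre on that section), a bare compartment index, or the
#' string `"soma"`.
#'
#' @param cable a [build_cable()] object (or a compartment table).
#' @param loc location specifier.
#' @return integer compartment index.
#' @export
resolve_location <- function(cable, loc) {
  comps <- if (inherits(cable, "cable")) cable$comps else cable
  if (is.character(loc) && loc == "soma")
    return(comps$comp[match("soma", comps$kind)])
  if (is.numeric(loc) && length(loc) == 1L) return(as.integer(loc))
  rows <- which(comps$section_id == loc$section)
  if (length(rows) == 0L) stop("no compartments on section ", loc$section)
  rows[which.min(abs(comps$pos[rows] - loc$pos))]
}

#' Somatic current-pulse protocol
#' @param amp_nA pulse amplitude, nA.
#' @param delay_ms onset time, ms.
#' @param dur_ms pulse duration, ms.
#' @param location location specifier (default `"soma"`).
#' @export
current_step <- function(amp_nA, delay_ms = 10, dur_ms = 2, location = "soma") {
  stopifnot(dur_ms > 0)
  structure(list(kind = "current_pulse", amp_nA = amp_nA, delay_ms = delay_ms,
                 dur_ms = dur_ms, location = location), class = "protocol")
}

#' Synapse-activation protocol
#' @param events data frame with columns `location` (list of location
#'   specifiers or compartment indices), `onset_ms`, and a `kinetics` list
#'   column of [syn_kinetics()] objects.
#' @export
synapse_protocol <- function(events) {
  stopifnot(all(events$onset_ms >= 0))
  structure(list(kind = "synapse_activation", events = events),
            class = "protocol")
}

empty_stim_df <- function()
  data.frame(node0 = integer(0), amp_nA = numeric(0), delay_ms = numeric(0),
             dur_ms = numeric(0))

empty_syn_df <- function()
  data.frame(node0 = integer(0), onset_ms = numeric(0), gmax_uS = numeric(0),
             tau_rise = numeric(0), tau_decay = numeric(0), norm = numeric(0),
             e_syn_mV = numeric(0), nmda = integer(0), gamma = numeric(0),
             mg_mM = numeric(0), mg_n = numeric(0))

#' Simulate a protocol on a cable
#'
#' Integrates the compartmental cable equation
#' `C dV/dt = -I_ion - I_axial + I_inj` with Crank-Nicolson time stepping
#' and a direct Hines tree solve; gating variables advance on a staggered
#' half-step grid. The initial condition is `V = e_pas` with gates at
#' steady state; when Ih is present a 200 ms settling pre-run precedes the
#' protocol (Ih shifts the resting potential).
#'
#' @param cable a [build_cable()] object.
#' @param protocol a [current_step()], [synapse_protocol()], list of
#'   protocols, or `NULL` for no stimulus.
#' @param dt time step, ms.
#' @param t_stop simulated time, ms.
#' @param record list of location specifiers to record (default soma).
#' @param settle_ms settling pre-run; `NULL` = 200 ms if Ih or HH present
#'   else 0.
#' @param v_init initial potential; default `e_pas`.
#' @param check_balance also track the worst per-step charge-balance
#'   residual (diagnostic; slows the run).
#' @return object of class `voltage_trace`: `time_ms`, matrix `v_mV`
#'   (one column per recorded location), `stimulus` metadata.
#' @export
simulate <- function(cable, protocol = NULL, dt = 0.025, t_stop = 100,
                     record = list("soma"), settle_ms = NULL, v_init = NULL,
                     check_balance = FALSE) {
  stopifnot(inherits(cable, "cable"), dt > 0)
  protos <- if (is.null(protocol)) list()
            else if (inherits(protocol, "protocol")) list(protocol)
            else protocol
  stim <- empty_stim_df(); syn <- empty_syn_df()
  for (p in protos) {
    if (p$kind == "current_pulse") {
      stim <- rbind(stim, data.frame(
        node0 = resolve_location(cable, p$location) - 1L,
        amp_nA = p$amp_nA, delay_ms = p$delay_ms, dur_ms = p$dur_ms))
    } else {
      ev <- p$events
      ks <- ev$kinetics
      syn <- rbind(syn, data.frame(
        node0 = vapply(ev$location, function(l)
          resolve_location(cable, l), integer(1)) - 1L,
        onset_ms = ev$onset_ms,
        gmax_uS = vapply(ks, function(k) k$g_max, numeric(1)) * 1e-3,
        tau_rise = vapply(ks, function(k) k$tau_rise, numeric(1)),
        tau_decay = vapply(ks, function(k) k$tau_decay, numeric(1)),
        norm = vapply(ks, syn_norm, numeric(1)),
        e_syn_mV = vapply(ks, function(k) k$e_syn, numeric(1)),
        nmda = vapply(ks, function(k)
          as.integer(k$voltage_dependent), integer(1)),
        gamma = vapply(ks, function(k) k$gamma, numeric(1)),
        mg_mM = vapply(ks, function(k) k$mg_mM, numeric(1)),
        mg_n = vapply(ks, function(k) k$mg_n, numeric(1))))
    }
  }
  if (is.null(settle_ms))
    settle_ms <- if (cable$has_ih || cable$has_hh) 200 else 0
  if (is.null(v_init)) v_init <- cable$passive$e_pas
  rec_idx <- vapply(record, function(l) resolve_location(cable, l), integer(1))

  out <- .simulate_cable_cpp(cable, stim, syn, dt, t_stop, v_init,
                             rec_idx - 1L, settle_ms, check_balance)
  v <- out$v_mV
  colnames(v) <- vapply(seq_along(record), function(i) {
    l <- record[[i]]
    if (is.character(l)) l
    else if (is.numeric(l)) paste0("comp", l)
    else paste0("sec", l$section, "@", signif(l$pos, 3))
  }, character(1))
  structure(list(time_ms = out$time_ms, v_mV = v,
                 stimulus = list(stim = stim, n_synapses = nrow(syn)),
                 dt = dt, max_balance_resid = out$max_balance_resid),
            class = "voltage_trace")
}

#' Detect somatic spikes as upward threshold crossings
#'
#' @param trace a `voltage_trace` (first recorded column used) or a list
#'   with `time_ms` and a voltage vector `v_mV`.
#' @param threshold_mV crossing threshold (default 0 mV).
#' @param column which recorded column to scan.
#' @return numeric vector of crossing times (linear interpolation between
#'   samples); empty when subthreshold.
#' @export
detect_spikes <- function(trace, threshold_mV = 0, column = 1) {
  v <- if (is.matrix(trace$v_mV)) trace$v_mV[, column] else trace$v_mV
  t <- trace$time_ms
  i <- which(v[-length(v)] < threshold_mV & v[-1] >= threshold_mV)
  if (length(i) == 0L) return(numeric(0))
  t[i] + (threshold_mV - v[i]) / (v[i + 1] - v[i]) * (t[i + 1] - t[i])
}

#' Axonal conduction velocity from two recording sites
#'
#' Velocity is the site separation divided by the difference in spike
#' times, each taken as the time of maximal dV/dt around the (single)
#' spike at that site.
#'
#' @param trace_a,trace_b traces at the proximal and distal site, each
#'   containing exactly one spike.
#' @param distance_um separation between the sites, um.
#' @return velocity in m/s.
#' @export
conduction_velocity <- function(trace_a, trace_b, distance_um) {
  t_of_max_dvdt <- function(tr) {
    v <- if (is.matrix(tr$v_mV)) tr$v_mV[, 1] else tr$v_mV
    if (length(detect_spikes(tr)) != 1L)
      stop("conduction velocity needs exactly one spike per site")
    dv <- diff(v) / diff(tr$time_ms)
    tm <- (tr$time_ms[-1] + tr$time_ms[-length(tr$time_ms)]) / 2
    i <- which.max(dv)
    if (i > 1 && i < length(dv)) {
      ## parabolic refinement of the dV/dt peak (sub-step resolution)
      a <- dv[i - 1]; b <- dv[i]; c <- dv[i + 1]
      den <- a - 2 * b + c
      if (den < 0) return(tm[i] + 0.5 * (a - c) / den * (tm[2] - tm[1]))
    }
    tm[i]
  }
  dt_ms <- t_of_max_dvdt(trace_b) - t_of_max_dvdt(trace_a)
  if (dt_ms <= 0) stop("no resolvable propagation delay between the sites")
  (distance_um * 1e-6) / (dt_ms * 1e-3)   # m/s
}

#' Attach an unmyelinated axon to the soma
#'
#' Adds a straight cylindrical axon section to the morphology (default
#' 6 mm long, 1 um diameter) for conduction-velocity protocols.
#'
#' @param morph a [morphology()] object.
#' @param length_um axon length, um.
#' @param diam_um axon diameter, um.
#' @return list `morph` and `axon_id`.
#' @export
add_axon <- function(morph, length_um = 6000, diam_um = 1) {
  soma <- morph$sections[[as.character(morph$soma_id)]]
  base <- soma$points[1, 1:3]
  ids <- vapply(morph$sections, function(s) s$id, integer(1))
  axon_id <- max(ids) + 1L
  pts <- rbind(c(base + c(0, 0, 0), diam_um),
               c(base + c(0, -length_um, 0), diam_um))
  ax <- section(axon_id, "axon", pts, parent = morph$soma_id)
  list(morph = morphology(unname(c(morph$sections, list(ax))),
                          metadata = morph$metadata),
       axon_id = axon_id)
}
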