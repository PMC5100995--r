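## Membrane mechanisms: passive parameters, non-uniform Rm, Ih density,
## Hodgkin-Huxley channels, kinetic AMPA/NMDA synapses, explicit spines.

#' Passive membrane parameters
#'
#' @param cm specific membrane capacitance, uF/cm^2.
#' @param rm specific membrane resistivity, Ohm cm^2.
#' @param ra axial (cytoplasmic) resistivity, Ohm cm.
#' @param e_pas leak reversal (resting) potential, mV.
#' @return object of class `passive_params`; the membrane time constant
#'   `tau_m = rm * cm` (ms) is available via [tau_m()].
#' @export
passive_params <- function(cm = 0.45, rm = 38907, ra = 203, e_pas = -70) {
  stopifnot(cm > 0, rm > 0, ra > 0)
  structure(list(cm = cm, rm = rm, ra = ra, e_pas = e_pas),
            class = "passive_params")
}

#' Membrane time constant
#' @param params a [passive_params()].
#' @return tau_m in ms (`rm` Ohm cm^2 x `cm` uF/cm^2 / 1000).
#' @export
tau_m <- function(params) params$rm * params$cm / 1000

#' Sigmoidal non-uniform membrane resistivity profile
#'
#' `Rm(dis) = Rm_end + (Rm_soma - Rm_end) / (1 + exp((dis - d_half)/steep))`,
#' a smooth transition from the somatic to the distal value with midpoint
#' `d_half` and width `steep` (50 um by default).
#'
#' @param rm_soma,rm_end somatic and distal Rm, Ohm cm^2.
#' @param d_half midpoint distance, um.
#' @param steep transition width, um; must be non-zero.
#' @export
nonuniform_rm <- function(rm_soma, rm_end, d_half, steep = 50) {
  stopifnot(rm_soma > 0, rm_end > 0, d_half >= 0)
  if (steep == 0) stop("steep = 0 makes the Rm profile a step; not allowed")
  structure(list(rm_soma = rm_soma, rm_end = rm_end, d_half = d_half,
                 steep = steep), class = "nonuniform_rm")
}

#' Evaluate the non-uniform Rm profile
#' @param dis_um physical path distance from the soma, um (vectorised).
#' @param params a [nonuniform_rm()].
#' @return Rm in Ohm cm^2.
#' @export
rm_profile <- function(dis_um, params) {
  stopifnot(all(dis_um >= 0))
  params$rm_end + (params$rm_soma - params$rm_end) /
    (1 + exp((dis_um - params$d_half) / params$steep))
}

#' Ih channel-density distribution
#'
#' Somatic and basal compartments carry the somatic density `g_soma`; in
#' the apical tree the density grows exponentially with path distance,
#' `g(dis) = g_soma * (-0.8696 + 2.087 * exp(dis/323))`.
#'
#' @param g_soma somatic density, mS/cm^2 (0 = passive model).
#' @param e_h Ih reversal potential, mV.
#' @export
ih_distribution <- function(g_soma = 0, e_h = -45) {
  if (g_soma < 0) stop("g_soma must be >= 0")
  structure(list(g_soma = g_soma, e_h = e_h), class = "ih_distribution")
}

#' Evaluate the Ih density at a path distance
#' @param dis_um path distance from the soma, um (vectorised).
#' @param g_soma somatic density, mS/cm^2.
#' @param domain `"somatic"`/`"basal"` (flat) or `"apical"` (exponential).
#' @return density in mS/cm^2.
#' @export
ih_density <- function(dis_um, g_soma, domain = c("somatic", "basal", "apical")) {
  domain <- match.arg(domain)
  if (g_soma < 0) stop("g_soma must be >= 0")
  stopifnot(all(dis_um >= 0))
  if (domain == "apical")
    g_soma * (-0.8696 + 2.087 * exp(dis_um / 323))
  else
    rep(g_soma, length(dis_um))
}

#' Hodgkin-Huxley channel densities
#'
#' Standard squid-axon kinetics with the sodium activation curve shifted
#' along the voltage axis. Defaults give a somatic spike mechanism
#' (8000/3200 pS/um^2 Na/K) with the activation V1/2 moved 8 mV toward
#' hyperpolarized potentials; the axonal variant uses 200/100 pS/um^2.
#'
#' @param gna_soma,gk_soma somatic maximal densities, pS/um^2.
#' @param gna_axon,gk_axon axonal maximal densities, pS/um^2.
#' @param m_shift_mV shift of the Na activation midpoint (mV, negative =
#'   hyperpolarizing); applies to activation only, on the soma (the axon
#'   keeps standard kinetics).
#' @param e_na,e_k reversal potentials, mV.
#' @param gl mechanism leak density, pS/um^2 (the classic spike mechanism
#'   carries its own leak, here 3 pS/um^2 = 0.3 mS/cm^2), referenced to
#'   the cell's resting potential. Without it the sodium window current of
#'   the high-density soma has no stable resting point.
#' @export
hh_channels <- function(gna_soma = 8000, gk_soma = 3200,
                        gna_axon = 200, gk_axon = 100,
                        m_shift_mV = -8, e_na = 50, e_k = -85, gl = 3) {
  stopifnot(gna_soma >= 0, gk_soma >= 0, gna_axon >= 0, gk_axon >= 0,
            gl >= 0)
  structure(list(gna_soma = gna_soma, gk_soma = gk_soma,
                 gna_axon = gna_axon, gk_axon = gk_axon,
                 m_shift_mV = m_shift_mV, e_na = e_na, e_k = e_k, gl = gl),
            class = "hh_channels")
}

#' Steady-state HH sodium activation
#'
#' Exposed for inspection/testing of the voltage shift; matches the gating
#' used inside the solver.
#' @param v_mV membrane potential, mV (vectorised).
#' @param m_shift_mV activation shift, mV.
#' @return m_inf in (0, 1).
#' @export
hh_m_inf <- function(v_mV, m_shift_mV = 0) {
  u <- v_mV - m_shift_mV
  vtrap <- function(x, y) ifelse(abs(x / y) < 1e-6, y * (1 - x / y / 2),
                                 x / (exp(x / y) - 1))
  a <- 0.1 * vtrap(-(u + 40), 10)
  b <- 4 * exp(-(u + 65) / 18)
  a / (a + b)
}

#' Two-state kinetic synapse parameters
#'
#' Double-exponential conductance normalised to peak at `g_max`.
#' [ampa_kinetics()] and [nmda_kinetics()] give the standard glutamatergic
#' pair: AMPA 0.3/1.8 ms, 0.7 nS; NMDA 3/70 ms, 1.4 nS with the
#' sigmoidal magnesium block (gamma = 0.08 /mV, [Mg] = 1 mM, n = 1/3.57).
#'
#' @param tau_rise,tau_decay rise and decay time constants, ms
#'   (`tau_decay > tau_rise > 0`).
#' @param g_max peak conductance, nS.
#' @param e_syn synaptic reversal potential, mV.
#' @param voltage_dependent apply the magnesium block?
#' @param gamma voltage sensitivity of the block, 1/mV.
#' @param mg_mM extracellular magnesium concentration, mM.
#' @param mg_n block scale factor, 1/mM.
#' @export
syn_kinetics <- function(tau_rise, tau_decay, g_max, e_syn = 0,
                         voltage_dependent = FALSE, gamma = 0.08,
                         mg_mM = 1, mg_n = 1 / 3.57) {
  if (!(tau_decay > tau_rise && tau_rise > 0))
    stop("need tau_decay > tau_rise > 0 (equal time constants are singular)")
  structure(list(tau_rise = tau_rise, tau_decay = tau_decay, g_max = g_max,
                 e_syn = e_syn, voltage_dependent = voltage_dependent,
                 gamma = gamma, mg_mM = mg_mM, mg_n = mg_n),
            class = "syn_kinetics")
}

#' @rdname syn_kinetics
#' @export
ampa_kinetics <- function(g_max = 0.7) syn_kinetics(0.3, 1.8, g_max)

#' @rdname syn_kinetics
#' @export
nmda_kinetics <- function(g_max = 1.4)
  syn_kinetics(3, 70, g_max, voltage_dependent = TRUE)

#' Time of peak synaptic conductance
#' @param k a [syn_kinetics()].
#' @return t_peak in ms:
#'   `tau_rise*tau_decay/(tau_decay - tau_rise) * log(tau_decay/tau_rise)`.
#' @export
syn_tpeak <- function(k) {
  k$tau_rise * k$tau_decay / (k$tau_decay - k$tau_rise) *
    log(k$tau_decay / k$tau_rise)
}

## normalisation so the time envelope peaks at g_max
syn_norm <- function(k) {
  tp <- syn_tpeak(k)
  1 / (exp(-tp / k$tau_decay) - exp(-tp / k$tau_rise))
}

#' Synaptic conductance at time t
#'
#' `g = B(V) * g_max * N * (exp(-t/tau_decay) - exp(-t/tau_rise))` with
#' `t` measured from synapse onset; `B = 1` for voltage-independent
#' synapses, otherwise the magnesium block [mg_block()].
#'
#' @param t_ms time since onset, ms (vectorised, >= 0).
#' @param v_mV membrane potential for the block, mV.
#' @param k a [syn_kinetics()].
#' @return conductance in nS.
#' @export
synaptic_conductance <- function(t_ms, v_mV = 0, k) {
  stopifnot(all(t_ms >= 0))
  B <- if (k$voltage_dependent) mg_block(v_mV, k) else 1
  B * k$g_max * syn_norm(k) * (exp(-t_ms / k$tau_decay) - exp(-t_ms / k$tau_rise))
}

#' Magnesium block of the NMDA conductance
#'
#' `B(V) = 1 / (1 + exp(-gamma V) * [Mg] * n)`: fully relieved at
#' depolarized potentials, partial at rest.
#'
#' @param v_mV membrane potential, mV (vectorised).
#' @param k a [syn_kinetics()] with `voltage_dependent = TRUE` (its gamma,
#'   Mg and n fields are used).
#' @return B in (0, 1].
#' @export
mg_block <- function(v_mV, k) {
  1 / (1 + exp(-k$gamma * v_mV) * k$mg_mM * k$mg_n)
}

#' Explicit spine geometry
#'
#' Two-compartment spine: cylindrical neck plus an isopotential head whose
#' membrane area is specified directly.
#'
#' @param neck_length_um neck length, um.
#' @param neck_diam_um neck diameter, um.
#' @param head_area_um2 head membrane area, um^2.
#' @export
spine_model <- function(neck_length_um = 1.35, neck_diam_um = 0.25,
                        head_area_um2 = 2.8) {
  stopifnot(neck_length_um > 0, neck_diam_um > 0, head_area_um2 > 0)
  structure(list(neck_length_um = neck_length_um, neck_diam_um = neck_diam_um,
                 head_area_um2 = head_area_um2), class = "spine_model")
}

#' Spine neck axial resistance
#'
#' `R = Ra L / (pi (d/2)^2)` for the cylindrical neck, in MOhm.
#'
#' @param ra axial resistivity, Ohm cm.
#' @param spine a [spine_model()].
#' @return resistance in MOhm.
#' @export
spine_neck_resistance <- function(ra, spine = spine_model()) {
  stopifnot(ra > 0)
  ## Ohm cm * um / um^2 -> 1e-2 MOhm
  1e-2 * ra * spine$neck_length_um / (pi * (spine$neck_diam_um / 2)^2)
}
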