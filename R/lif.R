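#' Leaky integrate-and-fire neuron configuration
#'
#' Parameters of the point-neuron model used throughout the network. The
#' membrane potential obeys \eqn{\tau_m dv/dt = -v(t) + R I(t)} and is reset
#' to \code{v_r} whenever it reaches \code{v_th}. All voltages and currents
#' are dimensionless; times are in milliseconds.
#'
#' @param v_th firing threshold (default 0.1)
#' @param v_r reset potential (default 0)
#' @param tau_m membrane time constant in ms (default 20)
#' @param R membrane resistance (default 1)
#' @return an object of class \code{lif_config}
#' @export
lif_config <- function(v_th = 0.1, v_r = 0, tau_m = 20, R = 1) {
  stopifnot(v_th > v_r, tau_m > 0, R > 0)
  structure(list(v_th = v_th, v_r = v_r, tau_m = tau_m, R = R),
            class = "lif_config")
}

#' Spike-timing-dependent plasticity configuration
#'
#' Exponential pair-based STDP window. A postsynaptic spike \eqn{\Delta t}
#' ms after a presynaptic spike potentiates the synapse by
#' \eqn{A_+ e^{-\Delta t/\tau_+}}; the reverse order depresses it by
#' \eqn{A_- e^{-\Delta t/\tau_-}}.
#'
#' @param a_plus LTP learning rate (default 0.925)
#' @param a_minus LTD learning rate (default 0.9)
#' @param tau_plus LTP time constant, ms (default 20)
#' @param tau_minus LTD time constant, ms (default 20)
#' @return an object of class \code{stdp_config}
#' @export
stdp_config <- function(a_plus = 0.925, a_minus = 0.9,
                        tau_plus = 20, tau_minus = 20) {
  stopifnot(a_plus > 0, a_minus > 0, tau_plus > 0, tau_minus > 0)
  structure(list(a_plus = a_plus, a_minus = a_minus,
                 tau_plus = tau_plus, tau_minus = tau_minus),
            class = "stdp_config")
}

#' One forward-Euler step of a LIF population
#'
#' Advances a vector of membrane potentials by one time step under the given
#' total input current, emitting spikes where the threshold is reached and
#' resetting those neurons. This is the reference update; the compiled engine
#' applies the identical rule.
#'
#' @param v numeric vector of membrane potentials
#' @param I_total numeric vector (or scalar) of total input currents
#' @param cfg a [lif_config()]
#' @param dt time step in ms
#' @return list with elements \code{v} (updated potentials) and
#'   \code{spiked} (logical vector)
#' @export
#' @examples
#' lif_step(0, 2, lif_config(), dt = 1)  # reaches threshold and fires
lif_step <- function(v, I_total, cfg = lif_config(), dt = 0.1) {
  stopifnot(dt > 0, all(is.finite(I_total)))
  v <- v + (dt / cfg$tau_m) * (-v + cfg$R * I_total)
  if (any(!is.finite(v))) stop("non-finite membrane potential")
  spiked <- v >= cfg$v_th
  v[spiked] <- cfg$v_r
  list(v = v, spiked = spiked)
}

#' STDP weight change for a single spike pair
#'
#' Sign convention follows the causal rule: a postsynaptic spike after the
#' presynaptic spike (\code{delta_t > 0}) strengthens the synapse, the
#' reverse order weakens it. Simultaneous spikes (\code{delta_t == 0})
#' produce no change and are handled by the caller.
#'
#' @param delta_t signed delay in ms from presynaptic to postsynaptic spike
#' @param cfg a [stdp_config()]
#' @return weight change (arbitrary units)
#' @export
#' @examples
#' stdp_delta(20)   #  0.925 * exp(-1)
#' stdp_delta(-20)  # -0.9   * exp(-1)
stdp_delta <- function(delta_t, cfg = stdp_config()) {
  ifelse(delta_t > 0,  cfg$a_plus  * exp(-abs(delta_t) / cfg$tau_plus),
  ifelse(delta_t < 0, -cfg$a_minus * exp(-abs(delta_t) / cfg$tau_minus), 0))
}

#' Phasic dopamine concentration after a punishment event
#'
#' \eqn{DA(t) = DA_{peak} e^{-(t - t_{pun})/\tau_t}}: the dopamine level jumps
#' to its peak at the moment of punishment and decays exponentially.
#'
#' @param t current time, ms (must be \code{>= t_pun})
#' @param t_pun time the punishment occurred, ms
#' @param da_peak maximum phasic concentration (default 10)
#' @param tau_t decay constant, ms (default 2)
#' @return dopamine concentration at \code{t}
#' @export
#' @examples
#' da_level(2, 0)  # one decay constant: 10 * exp(-1)
da_level <- function(t, t_pun, da_peak = 10, tau_t = 2) {
  if (any(t < t_pun)) stop("t must be >= t_pun")
  da_peak * exp(-(t - t_pun) / tau_t)
}
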