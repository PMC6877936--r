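#' Synaptic conductance elicited by one presynaptic spike
#'
#' The conductance is zero until the synaptic delay has elapsed, then jumps
#' to `gmax` and decays exponentially with `tau_decay`:
#' `g(t) = gmax * exp(-(t - t_s - t_delay)/tau_decay)` for
#' `t >= t_s + t_delay`.
#'
#' @param t Evaluation time (ms).
#' @param spike_time Presynaptic spike time (ms).
#' @param gmax Maximum conductance (nS).
#' @param t_delay Synaptic delay (ms, default 2).
#' @param tau_decay Decay time constant (ms, default 6).
#' @return Conductance (nS), vectorised over `t`.
#' @export
#' @examples
#' conductance_at(12, 10, gmax = 10) # onset: exactly gmax
conductance_at <- function(t, spike_time, gmax,
                           t_delay = SYN_T_DELAY, tau_decay = SYN_TAU_DECAY) {
  stopifnot(is.finite(t), is.finite(spike_time), gmax >= 0,
            t_delay >= 0, tau_decay > 0)
  dtise <- t - spike_time - t_delay
  ifelse(dtise < 0, 0, gmax * exp(-dtise / tau_decay))
}

#' Total synaptic current from summed receptor conductances
#'
#' Uses the driving-force convention `I = g * (E_syn - V_m)` under which
#' AMPA input (`E = 0` mV) depolarises any neuron below 0 mV and GABA input
#' (`E = -80` mV) hyperpolarises any neuron above -80 mV. The result enters
#' the membrane equation with a positive sign.
#'
#' @param g_exc Summed AMPA conductance (nS).
#' @param g_inh Summed GABA conductance (nS).
#' @param Vm Membrane voltage (mV).
#' @return Current (pA).
#' @export
synaptic_current <- function(g_exc, g_inh, Vm) {
  stopifnot(all(g_exc >= 0), all(g_inh >= 0))
  g_exc * (E_AMPA - Vm) + g_inh * (E_GABA - Vm)
}

#' Effective maximum conductance of a (possibly plastic) synapse
#'
#' Plastic synapses (the perforant path, LEC -> GC) scale their `gmax` by a
#' dimensionless weight in `[0, w_max]`; all other synapses have an implicit
#' weight of 1.
#'
#' @param gmax Pathway maximum conductance (nS).
#' @param weight Plastic weight (use 1 for non-plastic synapses).
#' @return Conductance (nS).
#' @export
effective_gmax <- function(gmax, weight = 1) {
  stopifnot(gmax >= 0, weight >= 0)
  gmax * weight
}

#' STDP weight update for one spike pairing
#'
#' Soft-bounded pair rule: a causal pairing (pre before post) potentiates by
#' `(w_max - w) * eta_plus * exp(-|dt|/tau_plus)`; an acausal pairing (post
#' before pre) depresses by `w * eta_minus * exp(-|dt|/tau_minus)`. The
#' returned increment always keeps `w + dw` inside `[0, w_max]`.
#'
#' @param w Current weight, in `[0, w_max]`.
#' @param dt_pre_to_post Signed pre-to-post delay (ms); positive values are
#'   causal pairings, negative values acausal.
#' @param params An [stdp_params()] object.
#' @return Weight increment `dw`.
#' @export
#' @examples
#' stdp_delta(1, 20, stdp_params())  # causal at tau_plus: +0.1 * e^-1
stdp_delta <- function(w, dt_pre_to_post, params = stdp_params()) {
  if (w < 0 || w > params$w_max) {
    stop("weight outside [0, w_max]", call. = FALSE)
  }
  if (dt_pre_to_post == 0) return(0)
  if (dt_pre_to_post > 0) {
    (params$w_max - w) * params$eta_plus * exp(-abs(dt_pre_to_post) / params$tau_plus)
  } else {
    -w * params$eta_minus * exp(-abs(dt_pre_to_post) / params$tau_minus)
  }
}

#' Apply STDP to a pre/post spike-train pair
#'
#' Replays the reduced nearest-neighbour pairing scheme in event order: each
#' post spike pairs (potentiation) with the most recent strictly-earlier pre
#' spike, each pre spike pairs (depression) with the most recent
#' strictly-earlier post spike, and every spike contributes at most one
#' pairing in each direction (a pre spike already consumed by a potentiation
#' pairing is not re-used by later post spikes, and vice versa — this keeps
#' a postsynaptic burst from multiplying the effect of a single presynaptic
#' spike). Coincident spikes do not pair. This is the same rule the network
#' engine applies online on the perforant path.
#'
#' @param w0 Initial weight.
#' @param pre_spikes,post_spikes Numeric vectors of spike times (ms).
#' @param params An [stdp_params()] object.
#' @return Final weight in `[0, w_max]`.
#' @export
apply_stdp <- function(w0, pre_spikes, post_spikes, params = stdp_params()) {
  if (w0 < 0 || w0 > params$w_max) stop("weight outside [0, w_max]", call. = FALSE)
  ev <- data.frame(
    t = c(as.numeric(pre_spikes), as.numeric(post_spikes)),
    is_pre = rep(c(TRUE, FALSE), c(length(pre_spikes), length(post_spikes)))
  )
  ev <- ev[order(ev$t), , drop = FALSE]
  w <- w0
  last_pre <- -Inf
  last_post <- -Inf
  pot_used <- -Inf # pre spike time already consumed by a potentiation
  dep_used <- -Inf # post spike time already consumed by a depression
  for (i in seq_len(nrow(ev))) {
    t <- ev$t[i]
    if (ev$is_pre[i]) {
      if (is.finite(last_post) && t > last_post && last_post > dep_used) {
        w <- w + stdp_delta(w, -(t - last_post), params)
        dep_used <- last_post
      }
      last_pre <- t
    } else {
      if (is.finite(last_pre) && t > last_pre && last_pre > pot_used) {
        w <- w + stdp_delta(w, t - last_pre, params)
        pot_used <- last_pre
      }
      last_post <- t
    }
  }
  min(max(w, 0), params$w_max)
}
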