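#' AdEx membrane derivative
#'
#' Right-hand side of the adaptive exponential integrate-and-fire model:
#' \deqn{C_m dV_m/dt = g_l(E_l - V_m) + g_l \Delta_T e^{(V_m - V_T)/\Delta_T}
#'       + I_{syn} + I_{inj} - w}
#' \deqn{\tau_w dw/dt = \alpha (V_m - E_l) - w}
#' With `DeltaT = 0` (granule cells) the exponential term is dropped — the
#' hard-threshold limit. The exponent argument is capped at +10 to keep the
#' value finite in pathological states.
#'
#' @param Vm Membrane voltage (mV).
#' @param w Adaptation current (pA).
#' @param params One-row data frame of AdEx parameters (see
#'   [neuron_params()]).
#' @param I_syn Total synaptic current (pA).
#' @param I_inj Injected current (pA).
#' @return Named numeric vector `c(dVm = mV/ms, dw = pA/ms)`.
#' @export
#' @examples
#' adex_derivative(-64, 0, neuron_params("MC"))
adex_derivative <- function(Vm, w, params, I_syn = 0, I_inj = 0) {
  if (!all(is.finite(c(Vm, w, I_syn, I_inj)))) {
    stop("non-finite neuron state or input", call. = FALSE)
  }
  p <- check_neuron_params(params)
  expterm <- 0
  if (p$DeltaT > 0) {
    expterm <- p$gl * p$DeltaT * exp(min((Vm - p$Vthr) / p$DeltaT, 10))
  }
  # Cm is in nF while currents are pA and time ms: pA/(1000 nF) = mV/ms
  dVm <- (p$gl * (p$El - Vm) + expterm + I_syn + I_inj - w) / (1000 * p$Cm)
  dw <- (p$alpha * (Vm - p$El) - w) / p$tau_w
  c(dVm = dVm, dw = dw)
}

#' One forward-Euler integration step with spike detection and reset
#'
#' Advances `(Vm, w)` by `dt` and applies the spike rule: when the updated
#' voltage reaches threshold, the voltage is reset to `Vreset` and the
#' adaptation current is incremented by `b`. There is no refractory period;
#' the reset alone limits firing.
#'
#' @inheritParams adex_derivative
#' @param dt Step size (ms), must be positive.
#' @return List with `Vm`, `w` and logical `spiked`.
#' @export
adex_step <- function(Vm, w, params, I_syn = 0, I_inj = 0, dt = 0.1) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  d <- adex_derivative(Vm, w, params, I_syn, I_inj)
  Vm2 <- Vm + dt * d[["dVm"]]
  w2 <- w + dt * d[["dw"]]
  spiked <- Vm2 >= params$Vthr
  if (spiked) {
    Vm2 <- params$Vreset
    w2 <- w2 + params$b
  }
  list(Vm = Vm2, w = w2, spiked = spiked)
}

#' Single-neuron voltage trace under constant current
#'
#' Convenience driver used for integrator validation: integrates one AdEx
#' neuron under a constant injected current and returns its spike times.
#'
#' @inheritParams adex_step
#' @param t_max Simulated time (ms).
#' @return Numeric vector of spike times (ms).
#' @export
adex_spike_times <- function(params, I_inj, t_max, dt = 0.1) {
  n <- ceiling(t_max / dt)
  Vm <- params$El
  w <- 0
  out <- numeric(0)
  # flat loop (not adex_step) so the 1 microsecond reference stays tractable
  p <- check_neuron_params(params)
  has_exp <- p$DeltaT > 0
  for (s in seq_len(n)) {
    expterm <- if (has_exp) {
      p$gl * p$DeltaT * exp(min((Vm - p$Vthr) / p$DeltaT, 10))
    } else 0
    dVm <- (p$gl * (p$El - Vm) + expterm + I_inj - w) / (1000 * p$Cm)
    dw <- (p$alpha * (Vm - p$El) - w) / p$tau_w
    Vm <- Vm + dt * dVm
    w <- w + dt * dw
    if (Vm >= p$Vthr) {
      Vm <- p$Vreset
      w <- w + p$b
      out <- c(out, s * dt)
    }
  }
  out
}
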