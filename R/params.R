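#' Default AdEx parameters for the four dentate gyrus cell types
#'
#' Returns the per-cell-type membrane parameters of the adaptive exponential
#' integrate-and-fire model: granule cells (GC), mossy cells (MC), basket
#' cells (BC) and HIPP cells (HC). Granule cells have a slope factor of 0,
#' i.e. the hard-threshold (leaky integrate-and-fire) limit of AdEx.
#'
#' @return A tibble with one row per cell type and columns `cell_type`,
#'   `El` (resting potential, mV), `gl` (leak conductance, nS), `Cm`
#'   (membrane capacitance, nF), `Vreset` (mV), `Vthr` (threshold, mV),
#'   `DeltaT` (slope factor, mV), `alpha` (adaptation coupling, nS),
#'   `tau_w` (adaptation time constant, ms), `b` (spike-triggered adaptation
#'   increment, pA).
#' @export
#' @examples
#' neuron_param_table()
neuron_param_table <- function() {
  tibble::tribble(
    ~cell_type,  ~El,    ~gl,    ~Cm,   ~Vreset, ~Vthr, ~DeltaT, ~alpha, ~tau_w, ~b,
    "GC",       -87.0,  0.030, 0.0067, -74.0,   -56.0,  0.0,     2.0,    45.0,  45.0,
    "MC",       -64.0,  4.530, 0.6210, -49.0,   -42.0,  2.0,     2.0,   180.0,  82.9,
    "BC",       -52.0, 18.054, 0.1793, -45.0,   -39.0,  2.0,     0.1,   100.0,  20.5,
    "HC",       -59.0,  1.930, 0.0584, -56.0,   -50.0,  2.0,     0.82,   93.0,  15.0
  )
}

#' AdEx parameters for one cell type
#'
#' @param cell_type One of `"GC"`, `"MC"`, `"BC"`, `"HC"`.
#' @return A one-row tibble (see [neuron_param_table()]).
#' @export
neuron_params <- function(cell_type = c("GC", "MC", "BC", "HC")) {
  cell_type <- match.arg(cell_type)
  dplyr::filter(neuron_param_table(), .data$cell_type == !!cell_type)
}

check_neuron_params <- function(p) {
  stopifnot(p$gl > 0, p$Cm > 0, p$Vreset < p$Vthr, p$DeltaT >= 0, p$tau_w > 0)
  invisible(p)
}

# Synaptic constants shared by every pathway (ms / mV).
SYN_T_DELAY <- 2
SYN_TAU_DECAY <- 6
E_AMPA <- 0
E_GABA <- -80

#' Layer sizes for the three network size presets
#'
#' @return Tibble with columns `preset`, `n_lec`, `n_gc`, `n_mc`, `n_bc`,
#'   `n_hc` and `ng_max` (the largest neurogenesis rate, neurons/s, explored
#'   at that scale).
#' @export
layer_size_table <- function() {
  tibble::tribble(
    ~preset,   ~n_lec, ~n_gc, ~n_mc, ~n_bc, ~n_hc, ~ng_max,
    "200gc",      100,   200,    50,    25,    50,       5,
    "400gc",      200,   400,   100,    50,   100,      10,
    "1000gc",     500,  1000,   250,   125,   250,      25
  )
}

#' Maximum synaptic conductances per pathway for a network size preset
#'
#' Pathways are read presynaptic -> postsynaptic. The perforant path
#' (LEC -> GC) is the plastic pathway; BC -> GC and HC -> GC are GABAergic,
#' everything else is AMPA.
#'
#' @param preset `"200gc"`, `"400gc"` or `"1000gc"`.
#' @return Tibble with columns `pathway`, `pre_type`, `post_type`, `gmax`
#'   (nS), `receptor` and `plastic`.
#' @export
gmax_table <- function(preset = c("200gc", "400gc", "1000gc")) {
  preset <- match.arg(preset)
  g <- switch(preset,
    "200gc"  = c(10.0, 12.0,  6.0, 1.0, 1.0, 0.2, 120.0, 20.0),
    "400gc"  = c( 6.0,  8.0, 10.0, 0.4, 1.0, 0.1, 120.0, 30.0),
    "1000gc" = c( 3.1,  5.0, 12.0, 0.1, 1.0, 0.1, 120.0, 20.0)
  )
  tibble::tibble(
    pathway = c("LEC->GC", "LEC->BC", "GC->MC", "GC->HC",
                "MC->GC", "MC->HC", "BC->GC", "HC->GC"),
    pre_type = c("LEC", "LEC", "GC", "GC", "MC", "MC", "BC", "HC"),
    post_type = c("GC", "BC", "MC", "HC", "GC", "HC", "GC", "GC"),
    gmax = g,
    receptor = c("AMPA", "AMPA", "AMPA", "AMPA", "AMPA", "AMPA", "GABA", "GABA"),
    plastic = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)
  )
}

#' Default connection probabilities per pathway
#'
#' The anatomical projection ratios of the circuit are not constrained by the
#' membrane or conductance tables, so they are exposed as configuration. The
#' defaults below were calibrated once so that granule cell coding stays
#' sparse (under 20% of mature GCs recruited by a 1 s stimulus); see the
#' methods vignette.
#'
#' @return Named numeric vector keyed by pathway.
#' @export
default_conn_prob <- function() {
  c("LEC->GC" = 0.03, "LEC->BC" = 0.3, "GC->MC" = 0.05, "GC->HC" = 0.2,
    "MC->GC" = 0.01, "MC->HC" = 0.2, "BC->GC" = 0.4, "HC->GC" = 0.4)
}

#' STDP parameters for the perforant path
#'
#' Soft-bounded pair-based spike-timing-dependent plasticity: potentiation is
#' proportional to `(w_max - w)`, depression to `w`, so weights stay in
#' `[0, w_max]` structurally.
#'
#' @param eta_plus,eta_minus Learning rates for potentiation / depression.
#' @param tau_plus,tau_minus Pairing time constants (ms).
#' @param w_max Maximum weight (dimensionless multiplier on `gmax`).
#' @return A list of class `stdp_params`.
#' @export
stdp_params <- function(eta_plus = 0.1, eta_minus = 0.1,
                        tau_plus = 20, tau_minus = 12, w_max = 2) {
  stopifnot(eta_plus > 0, eta_minus > 0, tau_plus > 0, tau_minus > 0, w_max > 0)
  structure(list(eta_plus = eta_plus, eta_minus = eta_minus,
                 tau_plus = tau_plus, tau_minus = tau_minus, w_max = w_max),
            class = "stdp_params")
}

#' Five-stage maturation schedule for newborn granule cells
#'
#' Newborn GCs pass through five equal-duration stages from birth to
#' maturity. Developing stages receive an extra injected current, attenuated
#' inhibitory conductance, and preferential wiring to the LEC neurons active
#' at birth / stage transition; stages 4 and 5 are identical (sustained
#' mature state).
#'
#' @param maturation_period Total maturation time in seconds (default 5).
#' @return List with `n_stages`, `stage_duration` (s), `inj_current` (pA per
#'   stage), `inh_atten` (multiplier on GABA conductance per stage) and
#'   `ec_connect_ratio` (fraction of currently active LEC neurons wired at
#'   each stage entry).
#' @export
maturation_schedule <- function(maturation_period = 5) {
  stopifnot(maturation_period > 0)
  list(
    n_stages = 5L,
    stage_duration = maturation_period / 5,
    inj_current = c(100, 50, 20, 0, 0),
    inh_atten = c(0.2, 0.6, 0.8, 1.0, 1.0),
    ec_connect_ratio = c(0.4, 0.3, 0.2, 0.1, 0.1)
  )
}
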