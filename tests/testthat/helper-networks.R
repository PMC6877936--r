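# Shared fixtures: tiny hand-built networks and spike-train utilities.

# A network of one LEC Poisson source driving one granule cell through a
# single plastic synapse. Strong enough that most presynaptic spikes evoke
# postsynaptic firing, which exercises both STDP branches.
micro_net <- function(gmax = 10, weight = 1, lec_rate = 20) {
  cfg <- network_config("200gc")
  neurons <- dplyr::bind_rows(
    dgsnn:::make_neuron_rows("LEC", 1L, 1L),
    dgsnn:::make_neuron_rows("GC", 1L, 2L, stage = 5L)
  )
  synapses <- tibble::tibble(
    pre = 1L, post = 2L, pathway = "LEC->GC", receptor = "AMPA",
    gmax = gmax, weight = weight, plastic = TRUE,
    pot_used = -1e18, dep_used = -1e18
  )
  net <- structure(list(config = cfg, neurons = neurons, synapses = synapses,
                        time_ms = 0), class = "dg_network")
  net <- reset_dynamics(net)
  attr(net, "lec_rate") <- lec_rate
  net
}

micro_pattern <- function(net, rate) {
  p <- new_pattern("A", 1L, 1L, rate_active = rate)
  p
}

# Independent event-by-event replay of the reduced nearest-neighbour STDP
# rule, written as an explicit state machine (the oracle for apply_stdp and
# for the engine's online updates).
stdp_replay_oracle <- function(w, pre, post, par = stdp_params()) {
  events <- data.frame(
    t = c(pre, post),
    pre = rep(c(TRUE, FALSE), c(length(pre), length(post)))
  )
  events <- events[order(events$t, !events$pre), ]
  lp <- NA_real_; lq <- NA_real_      # last pre / post spike
  up <- NA_real_; uq <- NA_real_      # consumed pre / post spike
  for (i in seq_len(nrow(events))) {
    t <- events$t[i]
    if (events$pre[i]) {
      usable <- !is.na(lq) && t > lq && (is.na(uq) || lq > uq)
      if (usable) {
        w <- w - w * par$eta_minus * exp(-(t - lq) / par$tau_minus)
        uq <- lq
      }
      lp <- t
    } else {
      usable <- !is.na(lp) && t > lp && (is.na(up) || lp > up)
      if (usable) {
        w <- w + (par$w_max - w) * par$eta_plus * exp(-(t - lp) / par$tau_plus)
        up <- lp
      }
      lq <- t
    }
  }
  min(max(w, 0), par$w_max)
}
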