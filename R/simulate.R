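active_pattern_at <- function(protocol, t_s) {
  hit <- which(protocol$onset - 1e-9 <= t_s & t_s < protocol$onset + protocol$duration - 1e-9)
  if (length(hit) == 0) NA_character_ else protocol$pattern_id[hit[1]]
}

pattern_lookup <- function(patterns) {
  if (inherits(patterns, "concept_pattern")) patterns <- list(patterns)
  ids <- vapply(patterns, function(p) p$id, "")
  stats::setNames(patterns, ids)
}

run_engine_chunk <- function(net, lec_rate, t0_ms, t1_ms, plasticity_on,
                             I_inj, inh_atten, record_spikes = TRUE) {
  dt <- net$config$dt
  n_steps <- round((t1_ms - t0_ms) / dt)
  if (n_steps <= 0) {
    return(list(net = net, spikes = NULL))
  }
  syn <- net$synapses
  stdp <- net$config$stdp
  par <- as.matrix(net$neurons[, c("El", "gl", "Cm", "Vreset", "Vthr",
                                   "DeltaT", "alpha", "tau_w", "b")])
  par[is.na(par)] <- 0
  res <- sim_chunk_cpp(
    layer = layer_code(net$neurons$type), par = par,
    Vm0 = net$state$Vm, w0 = net$state$w,
    I_inj = I_inj, inh_atten = inh_atten, lec_rate = lec_rate,
    pre = syn$pre, post = syn$post, gmax = syn$gmax, weight0 = syn$weight,
    receptor = ifelse(syn$receptor == "GABA", 1L, 0L), plastic = syn$plastic,
    dt = dt, n_steps = n_steps, step0 = round(t0_ms / dt),
    delay_steps = round(net$config$t_delay / dt),
    tau_decay = net$config$tau_decay, plasticity_on = plasticity_on,
    eta_plus = stdp$eta_plus, eta_minus = stdp$eta_minus,
    tau_plus = stdp$tau_plus, tau_minus = stdp$tau_minus, w_max = stdp$w_max,
    g_exc0 = net$state$g_exc, g_inh0 = net$state$g_inh,
    buf_exc0 = net$state$buf_exc, buf_inh0 = net$state$buf_inh,
    last_spike0 = net$state$last_spike,
    pot_used0 = syn$pot_used, dep_used0 = syn$dep_used,
    record_spikes = record_spikes
  )
  net$synapses$weight <- res$weight
  net$synapses$pot_used <- res$pot_used
  net$synapses$dep_used <- res$dep_used
  net$state$Vm <- res$Vm
  net$state$w <- res$w
  net$state$g_exc <- res$g_exc
  net$state$g_inh <- res$g_inh
  net$state$buf_exc <- res$buf_exc
  net$state$buf_inh <- res$buf_inh
  net$state$last_spike <- res$last_spike
  net$time_ms <- t1_ms
  spikes <- if (length(res$spike_id)) {
    tibble::tibble(neuron_id = res$spike_id, time_ms = res$spike_t)
  } else NULL
  list(net = net, spikes = spikes)
}

#' Run a stimulus protocol through the network
#'
#' The main simulation loop. At every integration step LEC neurons emit
#' Poisson spikes at the rate implied by the currently active pattern (or
#' the background rate), delayed conductance increments are delivered, all
#' AdEx neurons are integrated, spikes are detected and reset, and — if
#' enabled — perforant-path STDP, newborn-GC births and maturation-stage
#' transitions are applied. Births occur at `round(rate * duration)` evenly
#' spaced times within each stimulus window.
#'
#' Uses the current RNG state; call `set.seed()` first for reproducibility
#' (identical config, protocol and seed give identical spike records).
#'
#' @param net A `dg_network` from [build_network()].
#' @param protocol Protocol tibble (`pattern_id`, `onset`, `duration`), e.g.
#'   from [pair_protocol()] or [context_protocol()].
#' @param patterns List of `concept_pattern`s covering every id in the
#'   protocol.
#' @param plasticity Apply STDP on the perforant path?
#' @param neurogenesis Allow births and maturation-stage transitions?
#' @param t_end Optional simulation horizon (s); defaults to the end of the
#'   last stimulus.
#' @param record_spikes Keep spike records (disable to save memory in long
#'   training runs where only the final network matters).
#' @return List with `net` (the updated network) and `spikes` (tibble
#'   `neuron_id`, `layer`, `time_ms`).
#' @export
simulate_network <- function(net, protocol, patterns, plasticity = TRUE,
                             neurogenesis = TRUE, t_end = NULL,
                             record_spikes = TRUE) {
  stopifnot(inherits(net, "dg_network"))
  protocol <- check_protocol(protocol)
  pats <- pattern_lookup(patterns)
  missing <- setdiff(protocol$pattern_id, names(pats))
  if (length(missing)) {
    stop("protocol references unknown patterns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dt <- net$config$dt
  horizon_s <- if (is.null(t_end)) max(protocol$onset + protocol$duration) else t_end
  horizon_ms <- round(horizon_s * 1000 / dt) * dt
  rate <- net$config$neurogenesis_rate

  events <- tibble::tibble(time_s = numeric(0), type = character(0))
  if (neurogenesis && rate > 0) {
    births <- unlist(lapply(seq_len(nrow(protocol)), function(i) {
      neurogenesis_births(rate, protocol$onset[i], protocol$duration[i])
    }))
    births <- births[births * 1000 < horizon_ms]
    if (length(births)) {
      events <- dplyr::bind_rows(events,
        tibble::tibble(time_s = births, type = "birth"))
    }
    # stage transitions of cells already present
    sched <- net$config$schedule
    dev <- net$neurons$birth_time[net$neurons$type == "GC" &
                                    !is.na(net$neurons$birth_time) &
                                    net$neurons$stage < sched$n_stages]
    trans <- c(
      if (length(dev)) outer(dev, sched$stage_duration * (1:4), "+"),
      if (length(births)) outer(births, sched$stage_duration * (1:4), "+")
    )
    trans <- trans[trans * 1000 < horizon_ms & trans > net$time_ms / 1000]
    if (length(trans)) {
      events <- dplyr::bind_rows(events,
        tibble::tibble(time_s = trans, type = "stage"))
    }
  }
  # stimulus boundaries are also chunk boundaries (LEC rate changes)
  bounds <- unique(c(protocol$onset, protocol$onset + protocol$duration))
  events <- dplyr::bind_rows(events,
    tibble::tibble(time_s = bounds, type = "boundary"))
  events$time_ms <- round(events$time_s * 1000 / dt) * dt
  events <- events[events$time_ms > net$time_ms & events$time_ms <= horizon_ms, ]
  events <- events[order(events$time_ms, events$type != "birth"), ]

  bg <- net$config$rate_background
  chunk_spikes <- list()
  cur_ms <- net$time_ms
  ev_times <- unique(c(events$time_ms, horizon_ms))
  for (ev_ms in ev_times) {
    mid_s <- (cur_ms + ev_ms) / 2000
    pid <- active_pattern_at(protocol, mid_s)
    lec_rate <- numeric(nrow(net$neurons))
    lec_idx <- which(net$neurons$type == "LEC")
    lec_rate[lec_idx] <- bg
    if (!is.na(pid)) lec_rate[lec_idx] <- pattern_rates(pats[[pid]])
    sv <- stage_vectors(net)
    res <- run_engine_chunk(net, lec_rate, cur_ms, ev_ms, plasticity,
                            sv$I_inj, sv$inh_atten, record_spikes)
    net <- res$net
    if (!is.null(res$spikes)) chunk_spikes[[length(chunk_spikes) + 1L]] <- res$spikes
    cur_ms <- ev_ms
    # events scheduled exactly at this boundary
    here <- events[abs(events$time_ms - ev_ms) < dt / 2, ]
    if (nrow(here) && neurogenesis) {
      t_s <- ev_ms / 1000
      pid_now <- active_pattern_at(protocol, t_s + dt / 2000)
      active <- if (is.na(pid_now)) integer(0) else pats[[pid_now]]$active
      for (k in seq_len(nrow(here))) {
        if (here$type[k] == "birth") {
          net <- add_newborn_gc(net, t_s, active)
          if (isTRUE(getOption("dgsnn.verbose"))) {
            message(sprintf("t=%.3fs birth: GC %d (%d active LEC)", t_s,
                            max(net$neurons$id), length(active)))
          }
        } else if (here$type[k] == "stage") {
          net <- advance_maturation(net, t_s + 1e-9, active)
          if (isTRUE(getOption("dgsnn.verbose"))) {
            message(sprintf("t=%.3fs stage transitions advanced", t_s))
          }
        }
      }
    }
  }
  spikes <- if (length(chunk_spikes)) {
    sp <- dplyr::bind_rows(chunk_spikes)
    sp$layer <- net$neurons$type[match(sp$neuron_id, net$neurons$id)]
    sp[, c("neuron_id", "layer", "time_ms")]
  } else {
    tibble::tibble(neuron_id = integer(0), layer = character(0),
                   time_ms = numeric(0))
  }
  list(net = net, spikes = spikes)
}

#' Test-phase response of the network to one concept
#'
#' Presents a single pattern for `duration` seconds from a reset dynamic
#' state, with plasticity, neurogenesis and maturation frozen, and returns
#' the LEC and GC rate vectors over the full presentation.
#'
#' @param net A trained `dg_network`.
#' @param pattern A `concept_pattern`.
#' @param duration Presentation length (s).
#' @return List with `lec` and `gc` rate tibbles (see [rate_vector()]) and
#'   the raw `spikes`.
#' @export
test_response <- function(net, pattern, duration = 1) {
  net <- reset_dynamics(net)
  protocol <- tibble::tibble(pattern_id = pattern$id, onset = 0,
                             duration = duration)
  res <- simulate_network(net, protocol, list(pattern), plasticity = FALSE,
                          neurogenesis = FALSE)
  win <- c(0, duration * 1000)
  list(
    lec = rate_vector(res$spikes, res$net, "LEC", win),
    gc = rate_vector(res$spikes, res$net, "GC", win),
    spikes = res$spikes
  )
}
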