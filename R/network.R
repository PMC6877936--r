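#' Network configuration
#'
#' Bundles the layer sizes, pathway conductances and probabilities,
#' neurogenesis settings and integration step for one simulation. Defaults
#' follow the published parameter tables for the chosen size preset.
#'
#' @param preset Size preset: `"200gc"`, `"400gc"` or `"1000gc"`.
#' @param neurogenesis_rate Newborn GCs per second of stimulus (neurons/s).
#' @param maturation_period Total newborn maturation time (s).
#' @param conn_prob Optional named vector overriding entries of
#'   [default_conn_prob()].
#' @param gmax Optional named vector (by pathway) overriding [gmax_table()].
#' @param stdp An [stdp_params()] object.
#' @param dt Integration step (ms).
#' @param sparsity LEC coding sparsity (fraction of active neurons).
#' @param rate_active,rate_background LEC firing rates (Hz).
#' @return A list of class `dg_config`.
#' @export
network_config <- function(preset = "200gc", neurogenesis_rate = 0,
                           maturation_period = 5, conn_prob = NULL,
                           gmax = NULL, stdp = stdp_params(), dt = 0.1,
                           sparsity = 0.1, rate_active = 40,
                           rate_background = 0.1) {
  sizes <- layer_size_table()
  if (!preset %in% sizes$preset) {
    stop("unknown preset '", preset, "'; valid presets: ",
         paste(sizes$preset, collapse = ", "), call. = FALSE)
  }
  if (neurogenesis_rate < 0) stop("neurogenesis_rate must be >= 0", call. = FALSE)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  sz <- sizes[sizes$preset == preset, ]
  gt <- gmax_table(preset)
  if (!is.null(gmax)) {
    bad <- setdiff(names(gmax), gt$pathway)
    if (length(bad)) stop("unknown pathway in gmax: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    gt$gmax[match(names(gmax), gt$pathway)] <- unname(gmax)
  }
  cp <- default_conn_prob()
  if (!is.null(conn_prob)) {
    bad <- setdiff(names(conn_prob), names(cp))
    if (length(bad)) stop("unknown pathway in conn_prob: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    cp[names(conn_prob)] <- conn_prob
  }
  if (any(cp < 0 | cp > 1)) stop("connection probabilities must be in [0,1]",
                                 call. = FALSE)
  structure(list(
    preset = preset,
    n_lec = sz$n_lec, n_gc = sz$n_gc, n_mc = sz$n_mc, n_bc = sz$n_bc,
    n_hc = sz$n_hc,
    neurogenesis_rate = neurogenesis_rate,
    schedule = maturation_schedule(maturation_period),
    gmax_table = gt, conn_prob = cp, stdp = stdp, dt = dt,
    t_delay = SYN_T_DELAY, tau_decay = SYN_TAU_DECAY,
    sparsity = sparsity, rate_active = rate_active,
    rate_background = rate_background
  ), class = "dg_config")
}

#' @export
print.dg_config <- function(x, ...) {
  cat(sprintf(
    "<dg_config preset=%s LEC=%d GC=%d MC=%d BC=%d HC=%d ng=%g/s maturation=%gs dt=%gms>\n",
    x$preset, x$n_lec, x$n_gc, x$n_mc, x$n_bc, x$n_hc,
    x$neurogenesis_rate, x$schedule$stage_duration * 5, x$dt))
  invisible(x)
}

layer_code <- function(type) {
  match(type, c("LEC", "GC", "MC", "BC", "HC")) - 1L
}

make_neuron_rows <- function(type, n, start_id, birth_time = NA_real_,
                             stage = NA_integer_) {
  if (type == "LEC") {
    tibble::tibble(
      id = start_id + seq_len(n) - 1L, type = type,
      El = NA_real_, gl = NA_real_, Cm = NA_real_, Vreset = NA_real_,
      Vthr = NA_real_, DeltaT = NA_real_, alpha = NA_real_, tau_w = NA_real_,
      b = NA_real_, stage = NA_integer_, birth_time = NA_real_
    )
  } else {
    p <- neuron_params(type)
    tibble::tibble(
      id = start_id + seq_len(n) - 1L, type = type,
      El = p$El, gl = p$gl, Cm = p$Cm, Vreset = p$Vreset, Vthr = p$Vthr,
      DeltaT = p$DeltaT, alpha = p$alpha, tau_w = p$tau_w, b = p$b,
      stage = stage, birth_time = birth_time
    )
  }
}

wire_pathway <- function(pre_ids, post_ids, pathway, gt, p, weight = 1) {
  if (p <= 0 || length(pre_ids) == 0 || length(post_ids) == 0) {
    return(NULL)
  }
  row <- gt[gt$pathway == pathway, ]
  if (nrow(row) != 1) stop("unknown pathway: ", pathway, call. = FALSE)
  grid <- expand.grid(pre = pre_ids, post = post_ids)
  keep <- if (p >= 1) rep(TRUE, nrow(grid)) else stats::runif(nrow(grid)) < p
  grid <- grid[keep, , drop = FALSE]
  if (nrow(grid) == 0) return(NULL)
  tibble::tibble(
    pre = as.integer(grid$pre), post = as.integer(grid$post),
    pathway = pathway, receptor = row$receptor, gmax = row$gmax,
    weight = if (row$plastic) weight else 1, plastic = row$plastic,
    pot_used = -1e18, dep_used = -1e18
  )
}

#' Build a dentate gyrus network
#'
#' Creates the layers (LEC as Poisson spike sources, GC/MC/BC/HC as AdEx
#' neurons) and wires the eight pathways of the circuit — LEC->GC (plastic,
#' AMPA), LEC->BC, GC->MC, GC->HC, MC->GC, MC->HC (AMPA) and BC->GC, HC->GC
#' (GABA) — connecting each potential (pre, post) pair independently with the
#' pathway's probability. All initial GCs are mature (stage 5). Uses the
#' current RNG state; seed with `set.seed()` for reproducibility.
#'
#' @param config A [network_config()] object.
#' @return An object of class `dg_network`.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "dg_config"))
  neurons <- dplyr::bind_rows(
    make_neuron_rows("LEC", config$n_lec, 1L),
    make_neuron_rows("GC", config$n_gc, config$n_lec + 1L, stage = 5L),
    make_neuron_rows("MC", config$n_mc, config$n_lec + config$n_gc + 1L),
    make_neuron_rows("BC", config$n_bc,
                     config$n_lec + config$n_gc + config$n_mc + 1L),
    make_neuron_rows("HC", config$n_hc,
                     config$n_lec + config$n_gc + config$n_mc + config$n_bc + 1L)
  )
  ids <- split(neurons$id, neurons$type)
  gt <- config$gmax_table
  cp <- config$conn_prob
  synapses <- dplyr::bind_rows(
    wire_pathway(ids$LEC, ids$GC, "LEC->GC", gt, cp[["LEC->GC"]]),
    wire_pathway(ids$LEC, ids$BC, "LEC->BC", gt, cp[["LEC->BC"]]),
    wire_pathway(ids$GC, ids$MC, "GC->MC", gt, cp[["GC->MC"]]),
    wire_pathway(ids$GC, ids$HC, "GC->HC", gt, cp[["GC->HC"]]),
    wire_pathway(ids$MC, ids$GC, "MC->GC", gt, cp[["MC->GC"]]),
    wire_pathway(ids$MC, ids$HC, "MC->HC", gt, cp[["MC->HC"]]),
    wire_pathway(ids$BC, ids$GC, "BC->GC", gt, cp[["BC->GC"]]),
    wire_pathway(ids$HC, ids$GC, "HC->GC", gt, cp[["HC->GC"]])
  )
  net <- structure(list(
    config = config, neurons = neurons, synapses = synapses, time_ms = 0
  ), class = "dg_network")
  reset_dynamics(net)
}

#' @export
print.dg_network <- function(x, ...) {
  n_dev <- sum(x$neurons$type == "GC" & !is.na(x$neurons$birth_time))
  cat(sprintf(
    "<dg_network %s: %d neurons (%d GCs, %d adult-born), %d synapses, t=%.1f ms>\n",
    x$config$preset, nrow(x$neurons),
    sum(x$neurons$type == "GC"), n_dev, nrow(x$synapses), x$time_ms))
  invisible(x)
}

#' Reset the dynamic state of a network
#'
#' Sets every membrane voltage to its resting potential, zeroes adaptation
#' currents, synaptic conductances and delay buffers, and clears spike
#' history. Structure (neurons, synapses, plastic weights, maturation
#' stages) is untouched.
#'
#' @param net A `dg_network`.
#' @return The network with fresh dynamic state and `time_ms = 0`.
#' @export
reset_dynamics <- function(net) {
  n <- nrow(net$neurons)
  delay_steps <- round(net$config$t_delay / net$config$dt)
  net$state <- list(
    Vm = ifelse(is.na(net$neurons$El), 0, net$neurons$El),
    w = numeric(n),
    g_exc = numeric(n), g_inh = numeric(n),
    buf_exc = matrix(0, n, delay_steps), buf_inh = matrix(0, n, delay_steps),
    last_spike = rep(-1e18, n)
  )
  if (!is.null(net$synapses) && nrow(net$synapses)) {
    net$synapses$pot_used <- -1e18
    net$synapses$dep_used <- -1e18
  }
  net$time_ms <- 0
  net
}

grow_state <- function(state, k) {
  n_old <- length(state$Vm)
  state$Vm <- c(state$Vm, numeric(k))
  state$w <- c(state$w, numeric(k))
  state$g_exc <- c(state$g_exc, numeric(k))
  state$g_inh <- c(state$g_inh, numeric(k))
  state$buf_exc <- rbind(state$buf_exc, matrix(0, k, ncol(state$buf_exc)))
  state$buf_inh <- rbind(state$buf_inh, matrix(0, k, ncol(state$buf_inh)))
  state$last_spike <- c(state$last_spike, rep(-1e18, k))
  state
}

#' Birth times implied by the neurogenesis rate within a stimulus window
#'
#' With the default `"even"` scheme the number of births is deterministic,
#' `round(rate * duration)`, and the births are evenly spaced (window
#' midpoint convention) within the stimulus — the rate is a rate, not a
#' point process, and this removes one variance source. A `"poisson"`
#' scheme (count drawn from a Poisson law, times uniform in the window) is
#' available for users who want birth-count variability. No births occur
#' outside stimulus windows.
#'
#' @param rate Neurogenesis rate (neurons per second of stimulus).
#' @param stimulus_onset Stimulus onset (s).
#' @param stimulus_duration Stimulus duration (s).
#' @param scheme `"even"` (deterministic, default) or `"poisson"`.
#' @return Numeric vector of birth times (s).
#' @export
neurogenesis_births <- function(rate, stimulus_onset, stimulus_duration,
                                scheme = c("even", "poisson")) {
  stopifnot(rate >= 0, stimulus_duration > 0)
  scheme <- match.arg(scheme)
  if (scheme == "poisson") {
    k <- stats::rpois(1, rate * stimulus_duration)
    if (k == 0) return(numeric(0))
    return(stimulus_onset + sort(stats::runif(k)) * stimulus_duration)
  }
  k <- round(rate * stimulus_duration)
  if (k == 0) return(numeric(0))
  stimulus_onset + (seq_len(k) - 0.5) / k * stimulus_duration
}

stage_of_age <- function(age_s, schedule) {
  stg <- findInterval(age_s, schedule$stage_duration * (1:4)) + 1L
  pmin(stg, schedule$n_stages)
}

#' Add one newborn granule cell
#'
#' Appends a stage-1 GC: its perforant-path afferents are wired to a random
#' `ceiling(ratio_1 * |active|)` subset of the currently active LEC neurons
#' (plastic, weight 1); its efferents (GC->MC, GC->HC) and inhibitory
#' afferents (BC->GC, HC->GC) use the standard pathway probabilities.
#'
#' @param net A `dg_network`.
#' @param t_s Birth time (s).
#' @param active_lec Indices of the LEC neurons active at birth.
#' @return The grown network (invisibly unchanged if `active_lec` is empty,
#'   with a warning).
#' @export
add_newborn_gc <- function(net, t_s, active_lec) {
  if (length(active_lec) == 0) {
    warning("newborn requested outside a stimulus; skipping", call. = FALSE)
    return(net)
  }
  cfg <- net$config
  new_id <- max(net$neurons$id) + 1L
  row <- make_neuron_rows("GC", 1L, new_id, birth_time = t_s, stage = 1L)
  net$neurons <- dplyr::bind_rows(net$neurons, row)
  ids <- split(net$neurons$id, net$neurons$type)
  gt <- cfg$gmax_table
  cp <- cfg$conn_prob
  ratio1 <- cfg$schedule$ec_connect_ratio[1]
  k <- ceiling(ratio1 * length(active_lec))
  lec_pre <- sample(active_lec, min(k, length(active_lec)))
  syn_new <- dplyr::bind_rows(
    tibble::tibble(
      pre = as.integer(lec_pre), post = new_id, pathway = "LEC->GC",
      receptor = "AMPA", gmax = gt$gmax[gt$pathway == "LEC->GC"],
      weight = 1, plastic = TRUE, pot_used = -1e18, dep_used = -1e18),
    wire_pathway(new_id, ids$MC, "GC->MC", gt, cp[["GC->MC"]]),
    wire_pathway(new_id, ids$HC, "GC->HC", gt, cp[["GC->HC"]]),
    wire_pathway(ids$BC, new_id, "BC->GC", gt, cp[["BC->GC"]]),
    wire_pathway(ids$HC, new_id, "HC->GC", gt, cp[["HC->GC"]])
  )
  net$synapses <- dplyr::bind_rows(net$synapses, syn_new)
  net$state <- grow_state(net$state, 1L)
  net$state$Vm[length(net$state$Vm)] <- row$El
  net
}

#' Advance maturation stages of developing granule cells
#'
#' Updates the stage of every adult-born GC from its age at time `t_s`
#' (stages never decrease; stage 5 is absorbing). A cell entering a new
#' stage during a stimulus gains perforant-path afferents from
#' `ceiling(ratio_stage * |active|)` of the currently active LEC neurons,
#' skipping neurons already presynaptic to it.
#'
#' @param net A `dg_network`.
#' @param t_s Current time (s).
#' @param active_lec Indices of currently active LEC neurons (may be empty).
#' @return The updated network.
#' @export
advance_maturation <- function(net, t_s, active_lec = integer(0)) {
  sched <- net$config$schedule
  dev <- which(net$neurons$type == "GC" & !is.na(net$neurons$birth_time) &
                 net$neurons$stage < sched$n_stages)
  if (length(dev) == 0) return(net)
  age <- t_s - net$neurons$birth_time[dev]
  new_stage <- pmax(stage_of_age(age, sched), net$neurons$stage[dev])
  changed <- which(new_stage > net$neurons$stage[dev])
  if (length(changed) == 0) return(net)
  gt <- net$config$gmax_table
  gmax_pp <- gt$gmax[gt$pathway == "LEC->GC"]
  for (j in changed) {
    i <- dev[j]
    gc_id <- net$neurons$id[i]
    net$neurons$stage[i] <- new_stage[j]
    if (length(active_lec) > 0) {
      ratio <- sched$ec_connect_ratio[new_stage[j]]
      k <- ceiling(ratio * length(active_lec))
      cand <- sample(active_lec, min(k, length(active_lec)))
      existing <- net$synapses$pre[net$synapses$post == gc_id &
                                     net$synapses$pathway == "LEC->GC"]
      cand <- setdiff(cand, existing)
      if (length(cand) > 0) {
        net$synapses <- dplyr::bind_rows(net$synapses, tibble::tibble(
          pre = as.integer(cand), post = gc_id, pathway = "LEC->GC",
          receptor = "AMPA", gmax = gmax_pp, weight = 1, plastic = TRUE,
          pot_used = -1e18, dep_used = -1e18))
      }
    }
  }
  net
}

# Stage-dependent per-neuron vectors consumed by the engine: the extra
# depolarising current and the attenuated inhibition of each developing GC's
# current maturation stage. These are properties of the cell's stage, so
# they persist in the test phase (where stages are frozen but not erased).
stage_vectors <- function(net) {
  n <- nrow(net$neurons)
  I_inj <- numeric(n)
  atten <- rep(1, n)
  sched <- net$config$schedule
  gc_dev <- which(net$neurons$type == "GC" & !is.na(net$neurons$stage))
  stg <- net$neurons$stage[gc_dev]
  I_inj[gc_dev] <- sched$inj_current[stg]
  atten[gc_dev] <- sched$inh_atten[stg]
  list(I_inj = I_inj, inh_atten = atten)
}
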