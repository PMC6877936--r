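#' Deterministic per-cell seed for a sweep design point
#'
#' Stable hash of the base seed and the design coordinates, kept below
#' 2^31 so it is a valid R integer seed on every platform.
#'
#' @param base_seed Integer base seed.
#' @param rate,interval,similarity Design coordinates.
#' @param run Replicate index.
#' @return Integer seed.
#' @export
cell_seed <- function(base_seed, rate, interval, similarity, run) {
  v <- c(base_seed, round(rate * 1000), round(interval * 1000),
         round(similarity * 1000), run)
  h <- 0
  for (x in v) h <- (h * 31 + (x %% 65536) + 7) %% 2147483629
  as.integer(h + 1)
}

#' One training/test trial of the pairwise separation experiment
#'
#' Builds a fresh network, trains it on a pair of concepts with the given
#' input similarity and onset-to-onset time interval (plasticity and
#' neurogenesis on), then tests each concept with plasticity and
#' neurogenesis disabled. Input (EC) and output (GC) coding similarities are
#' cosine similarities of the test-phase rate vectors; the pattern
#' separation index compares them.
#'
#' @param config A [network_config()] (its `neurogenesis_rate` is used).
#' @param time_interval Onset-to-onset interval between the two stimuli (s).
#' @param input_similarity Target binary-code similarity of the pair.
#' @param seed Integer seed for this trial.
#' @param stim_duration Stimulus duration (s); defaults to one maturation
#'   stage (1 s for a 5 s maturation period).
#' @return One-row tibble: `neurogenesis_rate`, `time_interval`,
#'   `input_similarity`, `seed`, `sim_ec`, `sim_gc`, `psi`, `n_gc`.
#' @export
run_pair_trial <- function(config, time_interval, input_similarity, seed,
                           stim_duration = config$schedule$stage_duration) {
  set.seed(seed)
  net <- build_network(config)
  pair <- make_pattern_pair(config$n_lec, config$sparsity, input_similarity,
                            config$rate_active, config$rate_background)
  protocol <- pair_protocol(pair[[1]], pair[[2]], duration = stim_duration,
                            time_interval = time_interval)
  train <- simulate_network(net, protocol, pair, plasticity = TRUE,
                            neurogenesis = TRUE, record_spikes = FALSE)
  ra <- test_response(train$net, pair[[1]], duration = stim_duration)
  rb <- test_response(train$net, pair[[2]], duration = stim_duration)
  sim_ec <- cosine_similarity(ra$lec$rate, rb$lec$rate)
  sim_gc <- cosine_similarity(ra$gc$rate, rb$gc$rate)
  tibble::tibble(
    neurogenesis_rate = config$neurogenesis_rate,
    time_interval = time_interval,
    input_similarity = input_similarity,
    seed = seed, sim_ec = sim_ec, sim_gc = sim_gc,
    psi = psi(sim_ec, sim_gc),
    n_gc = sum(train$net$neurons$type == "GC")
  )
}

#' Factorial sweep over neurogenesis rate, time interval and similarity
#'
#' Runs [run_pair_trial()] over the full factorial design with `n_runs`
#' seeded replicates per cell; per-cell seeds derive deterministically from
#' `base_seed` via [cell_seed()], and every trial uses a fresh network.
#'
#' @param rates Neurogenesis rates (neurons/s).
#' @param intervals Onset-to-onset time intervals (s).
#' @param similarities Input similarities (fractions).
#' @param n_runs Replicates per design cell.
#' @param base_seed Base seed.
#' @param preset Network size preset.
#' @param maturation_period Maturation period (s).
#' @param ... Further arguments to [network_config()].
#' @return Object of class `psi_sweep`: the per-trial records are in
#'   `$records` and via [tidy()]; [glance()] gives per-cell means and SDs.
#' @export
run_psi_sweep <- function(rates = 0:5, intervals = 1:5,
                          similarities = seq(0, 0.9, 0.1), n_runs = 10,
                          base_seed = 1, preset = "200gc",
                          maturation_period = 5, ...) {
  stopifnot(length(rates) > 0, length(intervals) > 0,
            length(similarities) > 0, n_runs >= 1)
  design <- tidyr::expand_grid(rate = rates, interval = intervals,
                               similarity = similarities, run = seq_len(n_runs))
  records <- purrr::pmap(design, function(rate, interval, similarity, run) {
    cfg <- network_config(preset = preset, neurogenesis_rate = rate,
                          maturation_period = maturation_period, ...)
    run_pair_trial(cfg, interval, similarity,
                   cell_seed(base_seed, rate, interval, similarity, run))
  })
  records <- dplyr::bind_rows(records)
  records$run <- design$run
  structure(list(records = records, base_seed = base_seed, preset = preset),
            class = "psi_sweep")
}

#' @export
print.psi_sweep <- function(x, ...) {
  cat(sprintf("<psi_sweep: %d trials, preset %s, base seed %d>\n",
              nrow(x$records), x$preset, x$base_seed))
  print(glance(x), n = 10)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-trial records of a PSI sweep
#' @param x A `psi_sweep`.
#' @param ... Unused.
#' @return Tibble with one row per trial.
#' @export
tidy.psi_sweep <- function(x, ...) x$records

#' Per-cell summary of a PSI sweep
#' @param x A `psi_sweep`.
#' @param ... Unused.
#' @return Tibble of means and SDs per (rate, interval, similarity) cell.
#' @export
glance.psi_sweep <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$records, .data$neurogenesis_rate, .data$time_interval,
                    .data$input_similarity),
    n = dplyr::n(),
    mean_psi = mean(.data$psi), sd_psi = stats::sd(.data$psi),
    mean_sim_ec = mean(.data$sim_ec), mean_sim_gc = mean(.data$sim_gc),
    .groups = "drop")
}

#' PSI against input similarity, one panel per neurogenesis rate
#' @param object A `psi_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psi_sweep <- function(object, ...) {
  g <- glance(object)
  ggplot2::ggplot(g, ggplot2::aes(.data$input_similarity, .data$mean_psi,
                                  colour = factor(.data$time_interval))) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_psi - .data$sd_psi,
      ymax = .data$mean_psi + .data$sd_psi), fatten = 1.5) +
    ggplot2::facet_wrap(~.data$neurogenesis_rate, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "input similarity", y = "PSI",
                  colour = "time interval (s)") +
    ggplot2::theme_minimal()
}

#' Synthetic block-structured reference similarity matrix
#'
#' Stand-in for a concept-feature similarity matrix derived from human
#' property norms: concepts in the same context are highly similar
#' (`within_sim`), concepts in different contexts weakly similar
#' (`across_sim`), plus truncated Gaussian noise. Symmetric with unit
#' diagonal. Labels match [make_context_set()] (`"c01.1"`, ...).
#'
#' @param n_contexts,per_context Block structure.
#' @param within_sim,across_sim Block values (`0 <= across < within <= 1`).
#' @param noise_sd SD of the added noise (entries re-truncated to `[0, 1]`).
#' @return A `similarity_matrix`.
#' @export
synth_reference_matrix <- function(n_contexts = 14, per_context = 4,
                                   within_sim = 0.6, across_sim = 0.1,
                                   noise_sd = 0) {
  if (!(across_sim >= 0 && across_sim < within_sim && within_sim <= 1)) {
    stop("need 0 <= across_sim < within_sim <= 1", call. = FALSE)
  }
  n <- n_contexts * per_context
  ctx <- rep(seq_len(n_contexts), each = per_context)
  S <- matrix(across_sim, n, n)
  S[outer(ctx, ctx, "==")] <- within_sim
  if (noise_sd > 0) {
    noise <- matrix(stats::rnorm(n * n, 0, noise_sd), n, n)
    noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
    S <- pmin(pmax(S + noise, 0), 1)
  }
  diag(S) <- 1
  labels <- sprintf("c%02d.%d", ctx, sequence(rep(per_context, n_contexts)))
  dimnames(S) <- list(labels, labels)
  structure(S, class = c("similarity_matrix", "matrix", "array"))
}

#' Multi-context concept-coding experiment
#'
#' For each repetition count: builds a fresh network, trains it on the full
#' context protocol (plasticity + neurogenesis on), then tests all concepts
#' individually with both disabled, and compares the GC similarity matrix to
#' the reference via [matrix_similarity()].
#'
#' @param repetitions Vector of context repetition counts to evaluate.
#' @param reference Reference `similarity_matrix` (labels must match the
#'   generated concept set); default [synth_reference_matrix()].
#' @param neurogenesis_rate Neurogenesis rate during training (neurons/s).
#' @param n_contexts,per_context Concept set structure.
#' @param base_seed Integer seed; each repetition count gets a derived seed.
#' @param preset Network size preset.
#' @param max_pairwise Cap on pairwise input-code similarity.
#' @return Object of class `context_experiment`: list with `summary` (tibble
#'   `repetitions`, `match_to_reference`, `ec_match_to_reference`, `n_gc`),
#'   `gc_matrices`, `ec_matrix` (from the last run) and `reference`.
#' @export
run_context_experiment <- function(repetitions = 1:5,
                                   reference = synth_reference_matrix(),
                                   neurogenesis_rate = 3, n_contexts = 14,
                                   per_context = 4, base_seed = 1,
                                   preset = "200gc", max_pairwise = 0.5) {
  gc_mats <- list()
  rows <- list()
  ec_mat <- NULL
  for (rep_i in repetitions) {
    seed <- cell_seed(base_seed, neurogenesis_rate, rep_i, 0, 1)
    set.seed(seed)
    cfg <- network_config(preset = preset,
                          neurogenesis_rate = neurogenesis_rate)
    net <- build_network(cfg)
    patterns <- make_context_set(n_contexts, per_context, cfg$n_lec,
                                 cfg$sparsity, max_pairwise)
    protocol <- context_protocol(patterns, repetitions = rep_i)
    train <- simulate_network(net, protocol, patterns, plasticity = TRUE,
                              neurogenesis = TRUE, record_spikes = FALSE)
    responses <- lapply(patterns, function(p) test_response(train$net, p))
    ids <- vapply(patterns, function(p) p$id, "")
    gc_vecs <- stats::setNames(lapply(responses, function(r) r$gc$rate), ids)
    ec_vecs <- stats::setNames(lapply(responses, function(r) r$lec$rate), ids)
    gc_m <- similarity_matrix(gc_vecs)
    ec_m <- similarity_matrix(ec_vecs)
    gc_mats[[as.character(rep_i)]] <- gc_m
    ec_mat <- ec_m
    rows[[length(rows) + 1L]] <- tibble::tibble(
      repetitions = rep_i,
      match_to_reference = matrix_similarity(gc_m, reference),
      ec_match_to_reference = matrix_similarity(ec_m, reference),
      n_gc = sum(train$net$neurons$type == "GC"),
      seed = seed
    )
  }
  structure(list(summary = dplyr::bind_rows(rows), gc_matrices = gc_mats,
                 ec_matrix = ec_mat, reference = reference),
            class = "context_experiment")
}

#' @export
print.context_experiment <- function(x, ...) {
  cat("<context_experiment>\n")
  print(x$summary)
  invisible(x)
}

#' @param x A `context_experiment`.
#' @param ... Unused.
#' @rdname run_context_experiment
#' @export
tidy.context_experiment <- function(x, ...) x$summary

#' Reference match against repetition count
#' @param object A `context_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.context_experiment <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(.data$repetitions, .data$match_to_reference)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "context repetitions",
                  y = "GC matrix similarity to reference") +
    ggplot2::theme_minimal()
}
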