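#' Random binary concept pattern over the LEC layer
#'
#' A concept is a set of active LEC neurons (binary code). Active neurons
#' fire Poisson at `rate_active` (40 Hz), the rest at the background
#' `rate_background` (0.1 Hz).
#'
#' @param n_lec Number of LEC neurons.
#' @param sparsity Fraction of active neurons, in (0, 1].
#' @param id Pattern label.
#' @param rate_active,rate_background Firing rates (Hz).
#' @return An object of class `concept_pattern`: list with `id`, `active`
#'   (sorted indices), `n_lec`, `rate_active`, `rate_background`.
#' @export
make_pattern <- function(n_lec, sparsity = 0.1, id = "A",
                         rate_active = 40, rate_background = 0.1) {
  if (sparsity <= 0 || sparsity > 1) {
    stop("sparsity must be in (0, 1]", call. = FALSE)
  }
  k <- round(sparsity * n_lec)
  new_pattern(id, sort(sample.int(n_lec, k)), n_lec, rate_active, rate_background)
}

new_pattern <- function(id, active, n_lec, rate_active = 40, rate_background = 0.1) {
  structure(list(id = id, active = as.integer(active), n_lec = as.integer(n_lec),
                 rate_active = rate_active, rate_background = rate_background),
            class = "concept_pattern")
}

#' @export
print.concept_pattern <- function(x, ...) {
  cat(sprintf("<concept_pattern '%s': %d/%d active at %g Hz>\n",
              x$id, length(x$active), x$n_lec, x$rate_active))
  invisible(x)
}

#' Per-neuron LEC rate vector of a pattern
#' @param pattern A `concept_pattern`.
#' @return Numeric vector of length `n_lec` (Hz).
#' @export
pattern_rates <- function(pattern) {
  r <- rep(pattern$rate_background, pattern$n_lec)
  r[pattern$active] <- pattern$rate_active
  r
}

#' Binary (0/1) code of a pattern
#' @param pattern A `concept_pattern`.
#' @return Integer vector of length `n_lec`.
#' @export
pattern_code <- function(pattern) {
  v <- integer(pattern$n_lec)
  v[pattern$active] <- 1L
  v
}

#' Pair of patterns with exact target similarity
#'
#' Constructs two equal-size active sets sharing exactly
#' `k = target_similarity * |active|` neurons, so the cosine similarity of
#' the binary codes equals the target exactly.
#'
#' @inheritParams make_pattern
#' @param target_similarity Desired cosine similarity, a multiple of
#'   `1 / (sparsity * n_lec)`.
#' @return List of two `concept_pattern`s (ids "A", "B").
#' @export
make_pattern_pair <- function(n_lec, sparsity = 0.1, target_similarity = 0,
                              rate_active = 40, rate_background = 0.1) {
  if (sparsity <= 0 || sparsity > 1) stop("sparsity must be in (0, 1]", call. = FALSE)
  size <- round(sparsity * n_lec)
  k_real <- target_similarity * size
  k <- round(k_real)
  if (abs(k_real - k) > 1e-9) {
    stop("target_similarity * pattern size must be an integer", call. = FALSE)
  }
  if (k < 0 || k > size || (2 * size - k) > n_lec) {
    stop("infeasible overlap for this size and similarity", call. = FALSE)
  }
  pool <- sample.int(n_lec, 2 * size - k)
  shared <- pool[seq_len(k)]
  only_a <- pool[seq_len(size - k) + k]
  only_b <- pool[seq_len(size - k) + size]
  list(
    new_pattern("A", sort(c(shared, only_a)), n_lec, rate_active, rate_background),
    new_pattern("B", sort(c(shared, only_b)), n_lec, rate_active, rate_background)
  )
}

#' Context-organised concept set with bounded pairwise similarity
#'
#' Draws `n_contexts * per_context` random patterns by rejection sampling so
#' that every pairwise binary-code cosine similarity stays strictly below
#' `max_pairwise`. Patterns are labelled `"<context>.<concept>"` and carry a
#' `context` field.
#'
#' @inheritParams make_pattern
#' @param n_contexts,per_context Number of contexts and concepts per context.
#' @param max_pairwise Upper bound (exclusive) on pairwise similarity.
#' @param max_tries Rejection budget per pattern.
#' @return List of `concept_pattern`s with `$context` set.
#' @export
make_context_set <- function(n_contexts = 14, per_context = 4, n_lec = 100,
                             sparsity = 0.1, max_pairwise = 0.5,
                             max_tries = 10000) {
  size <- round(sparsity * n_lec)
  max_overlap <- ceiling(max_pairwise * size) - 1L
  codes <- list()
  out <- list()
  total <- n_contexts * per_context
  for (i in seq_len(total)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- sort(sample.int(n_lec, size))
      if (all(vapply(codes, function(a) length(intersect(a, cand)), 1L) <= max_overlap)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop(sprintf("rejection budget exhausted at pattern %d of %d", i, total),
           call. = FALSE)
    }
    ctx <- (i - 1L) %/% per_context + 1L
    cpt <- (i - 1L) %% per_context + 1L
    p <- new_pattern(sprintf("c%02d.%d", ctx, cpt), cand, n_lec)
    p$context <- ctx
    codes[[i]] <- cand
    out[[i]] <- p
  }
  out
}

#' Two-stimulus protocol with onset-to-onset time interval
#'
#' Presents pattern A at time 0 and pattern B `time_interval` seconds after
#' A's onset (so an interval equal to the stimulus duration means immediate
#' succession).
#'
#' @param A,B `concept_pattern`s.
#' @param duration Stimulus duration (s).
#' @param time_interval Onset-to-onset interval (s), at least `duration`.
#' @return A protocol tibble with columns `pattern_id`, `onset` (s),
#'   `duration` (s).
#' @export
pair_protocol <- function(A, B, duration = 1, time_interval = 1) {
  if (time_interval < duration) {
    stop("time_interval shorter than stimulus duration: stimuli would overlap",
         call. = FALSE)
  }
  tibble::tibble(
    pattern_id = c(A$id, B$id),
    onset = c(0, time_interval),
    duration = duration
  )
}

#' Multi-context training protocol
#'
#' Presents the contexts sequentially, back-to-back; the full pass over all
#' contexts is repeated `repetitions` times. Within each context block the
#' concepts appear once, in a fresh random order per repetition.
#'
#' @param patterns List of `concept_pattern`s carrying `$context` labels.
#' @param repetitions Number of full passes.
#' @param duration Per-stimulus duration (s).
#' @param gap Inter-stimulus gap (s), default 0 (back-to-back).
#' @return A protocol tibble (`pattern_id`, `onset`, `duration`).
#' @export
context_protocol <- function(patterns, repetitions = 1, duration = 1, gap = 0) {
  stopifnot(repetitions >= 1)
  ctx <- vapply(patterns, function(p) p$context, 1)
  ids <- vapply(patterns, function(p) p$id, "")
  onset <- 0
  rows <- list()
  for (rep_i in seq_len(repetitions)) {
    for (c_i in sort(unique(ctx))) {
      members <- ids[ctx == c_i]
      members <- sample(members)
      for (id in members) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          pattern_id = id, onset = onset, duration = duration)
        onset <- onset + duration + gap
      }
    }
  }
  dplyr::bind_rows(rows)
}

check_protocol <- function(protocol) {
  stopifnot(all(c("pattern_id", "onset", "duration") %in% names(protocol)))
  o <- order(protocol$onset)
  p <- protocol[o, , drop = FALSE]
  if (nrow(p) > 1) {
    ends <- p$onset[-nrow(p)] + p$duration[-nrow(p)]
    if (any(ends > p$onset[-1] + 1e-9)) {
      stop("protocol events overlap", call. = FALSE)
    }
  }
  p
}
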