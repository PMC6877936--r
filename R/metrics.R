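#' Per-neuron firing rates of one layer over a time window
#'
#' @param spikes Spike tibble (`neuron_id`, `layer`, `time_ms`) as returned
#'   by [simulate_network()].
#' @param net The network the spikes came from (for the layer roster, so
#'   silent neurons appear with rate 0).
#' @param layer Layer label (`"LEC"`, `"GC"`, `"MC"`, `"BC"`, `"HC"`).
#' @param window `c(start_ms, end_ms)`.
#' @return Tibble with `neuron_id` and `rate` (Hz).
#' @export
rate_vector <- function(spikes, net, layer, window) {
  stopifnot(length(window) == 2, window[2] > window[1])
  ids <- net$neurons$id[net$neurons$type == layer]
  if (length(ids) == 0) stop("unknown or empty layer: ", layer, call. = FALSE)
  sel <- spikes$layer == layer &
    spikes$time_ms >= window[1] & spikes$time_ms < window[2]
  counts <- tabulate(match(spikes$neuron_id[sel], ids), nbins = length(ids))
  tibble::tibble(neuron_id = ids, rate = counts / ((window[2] - window[1]) / 1000))
}

#' Cosine similarity of two rate vectors
#'
#' Normalised dot product `A.B / (|A| |B|)`. If either vector is all-zero
#' the similarity is defined as 0 (a silent layer shares no code with
#' anything) and a diagnostic is emitted.
#'
#' @param a,b Equal-length non-negative numeric vectors (rates, or binary
#'   codes).
#' @return Similarity in `[0, 1]` for non-negative inputs.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    rlang::inform("zero-rate vector in similarity; returning 0",
                  .frequency = "once", .frequency_id = "dgsnn_zero_vec")
    return(0)
  }
  sum(a * b) / (na * nb)
}

#' Pattern separation index
#'
#' Compares input-layer (EC) and granule-cell coding similarities:
#' \deqn{PSI = (Sim_{EC} - Sim_{GC}) / Sim_{EC}} when the output is less
#' similar than the input (pattern separation, PSI > 0), and
#' \deqn{PSI = (Sim_{EC} - Sim_{GC}) / (1 - Sim_{EC})} when the output is
#' more similar (pattern integration, PSI < 0). Equal similarities give 0.
#'
#' @param sim_ec,sim_gc Similarities in `[0, 1]`.
#' @return PSI in `[-1, 1]`.
#' @export
#' @examples
#' psi(0.8, 0.4) #  0.5: separation
#' psi(0.4, 0.7) # -0.5: integration
psi <- function(sim_ec, sim_gc) {
  if (any(sim_ec < 0 | sim_ec > 1) || any(sim_gc < 0 | sim_gc > 1)) {
    stop("similarities must lie in [0, 1]", call. = FALSE)
  }
  d <- sim_ec - sim_gc
  out <- numeric(length(d))
  up <- d > 0
  dn <- d < 0
  out[up] <- d[up] / sim_ec[up]
  out[dn] <- d[dn] / (1 - sim_ec[dn])
  out
}

#' Pairwise similarity matrix over a set of rate vectors
#'
#' @param vectors Named list of equal-length numeric vectors (one per
#'   concept), or a numeric matrix with concepts as columns.
#' @return Object of class `similarity_matrix`: a symmetric unit-diagonal
#'   matrix with concept labels as dimnames.
#' @export
similarity_matrix <- function(vectors) {
  if (is.list(vectors)) {
    labels <- names(vectors)
    if (is.null(labels)) labels <- paste0("v", seq_along(vectors))
    M <- do.call(cbind, vectors)
  } else {
    M <- as.matrix(vectors)
    labels <- colnames(M)
    if (is.null(labels)) labels <- paste0("v", seq_len(ncol(M)))
  }
  norms <- sqrt(colSums(M^2))
  safe <- ifelse(norms == 0, 1, norms)
  Mn <- sweep(M, 2, safe, "/")
  S <- crossprod(Mn)
  S[norms == 0, ] <- 0
  S[, norms == 0] <- 0
  diag(S) <- 1
  dimnames(S) <- list(labels, labels)
  structure(S, class = c("similarity_matrix", "matrix", "array"))
}

#' Normalised dot product between two similarity matrices
#'
#' Cosine similarity of the flattened strict upper triangles (the unit
#' diagonal is excluded so it cannot inflate agreement).
#'
#' @param m1,m2 `similarity_matrix` objects (or plain matrices) with the
#'   same labels in the same order.
#' @return Similarity in `[0, 1]` for non-negative matrices.
#' @export
matrix_similarity <- function(m1, m2) {
  if (!all(dim(m1) == dim(m2))) stop("dimension mismatch", call. = FALSE)
  if (!is.null(dimnames(m1)[[1]]) && !is.null(dimnames(m2)[[1]]) &&
      !identical(dimnames(m1)[[1]], dimnames(m2)[[1]])) {
    stop("matrix labels differ", call. = FALSE)
  }
  ut <- upper.tri(m1, diag = FALSE)
  cosine_similarity(m1[ut], m2[ut])
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix %d x %d>\n", nrow(x), ncol(x)))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

#' Heatmap of a similarity matrix
#'
#' @param object A `similarity_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.similarity_matrix <- function(object, ...) {
  df <- tibble::as_tibble(as.table(unclass(object)), .name_repair = "minimal")
  names(df) <- c("row", "col", "similarity")
  lv <- dimnames(object)[[1]]
  df$row <- factor(df$row, levels = rev(lv))
  df$col <- factor(df$col, levels = lv)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "similarity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
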