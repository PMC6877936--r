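#' Load a network configuration from a YAML or JSON file
#'
#' Recognised top-level keys mirror the arguments of [network_config()]:
#' `preset`, `neurogenesis_rate`, `maturation_period`, `dt`, `sparsity`,
#' `rate_active`, `rate_background`, plus optional mappings `conn_prob` and
#' `gmax` keyed by pathway and an `stdp` mapping.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return A `dg_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("preset", "neurogenesis_rate", "maturation_period", "dt",
             "sparsity", "rate_active", "rate_background", "conn_prob",
             "gmax", "stdp")
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown config fields: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  args <- raw[setdiff(names(raw), c("conn_prob", "gmax", "stdp"))]
  if (!is.null(raw$conn_prob)) args$conn_prob <- unlist(raw$conn_prob)
  if (!is.null(raw$gmax)) args$gmax <- unlist(raw$gmax)
  if (!is.null(raw$stdp)) args$stdp <- do.call(stdp_params, as.list(raw$stdp))
  do.call(network_config, args)
}

#' Write a configuration back to YAML
#' @param config A `dg_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(list(
    preset = config$preset,
    neurogenesis_rate = config$neurogenesis_rate,
    maturation_period = config$schedule$stage_duration * 5,
    dt = config$dt, sparsity = config$sparsity,
    rate_active = config$rate_active,
    rate_background = config$rate_background,
    conn_prob = as.list(config$conn_prob),
    gmax = as.list(stats::setNames(config$gmax_table$gmax,
                                   config$gmax_table$pathway)),
    stdp = unclass(config$stdp)
  ), path)
  invisible(path)
}

#' Write a labelled similarity matrix as CSV
#' @param m A `similarity_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(m, path) {
  df <- as.data.frame(unclass(m))
  utils::write.csv(cbind(concept = rownames(m), df), path, row.names = FALSE)
  invisible(path)
}

#' Read a similarity matrix written by [write_similarity_matrix()]
#' @param path CSV path.
#' @return A `similarity_matrix`.
#' @export
read_similarity_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  labels <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(labels, colnames(m))
  structure(m, class = c("similarity_matrix", "matrix", "array"))
}

#' Load a user-supplied concept-by-feature table and derive its similarity
#' matrix
#'
#' For users with a real property-norm dataset: reads a CSV whose first
#' column holds concept labels and remaining columns numeric feature values,
#' and returns the pairwise cosine similarity matrix of the feature vectors.
#'
#' @param path CSV path (concepts x features).
#' @return A `similarity_matrix`.
#' @export
feature_matrix_similarity <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  labels <- as.character(df[[1]])
  M <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(M) <- labels
  similarity_matrix(M)
}

#' Write spike records as columnar text
#'
#' @param spikes Spike tibble (`neuron_id`, `layer`, `time_ms`) from
#'   [simulate_network()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(spikes, path) {
  utils::write.csv(spikes[, c("neuron_id", "layer", "time_ms")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Write experiment results with a reproducibility manifest
#'
#' Writes tidy CSV tables and labelled CSV matrices plus a JSON manifest
#' (config snapshot, seed, package version, file inventory) sufficient to
#' re-run the experiment bit-identically.
#'
#' @param x A `psi_sweep` or `context_experiment`.
#' @param out_dir Output directory (created if missing).
#' @param config Optional `dg_config` to snapshot.
#' @return The manifest (list), invisibly.
#' @export
write_results <- function(x, out_dir, config = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  if (inherits(x, "psi_sweep")) {
    f <- file.path(out_dir, "psi_records.csv")
    utils::write.csv(tidy(x), f, row.names = FALSE)
    files <- c(files, f)
    f <- file.path(out_dir, "psi_summary.csv")
    utils::write.csv(glance(x), f, row.names = FALSE)
    files <- c(files, f)
    seed <- x$base_seed
  } else if (inherits(x, "context_experiment")) {
    f <- file.path(out_dir, "context_summary.csv")
    utils::write.csv(x$summary, f, row.names = FALSE)
    files <- c(files, f)
    for (nm in names(x$gc_matrices)) {
      f <- file.path(out_dir, sprintf("gc_matrix_rep%s.csv", nm))
      write_similarity_matrix(x$gc_matrices[[nm]], f)
      files <- c(files, f)
    }
    f <- file.path(out_dir, "reference_matrix.csv")
    write_similarity_matrix(x$reference, f)
    files <- c(files, f)
    seed <- x$summary$seed[1]
  } else {
    stop("unsupported result type", call. = FALSE)
  }
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("dgsnn")),
    seed = seed,
    config = if (!is.null(config)) {
      tmp <- tempfile(fileext = ".yaml")
      on.exit(unlink(tmp), add = TRUE)
      save_config(config, tmp)
      yaml::read_yaml(tmp)
    },
    files = basename(files)
  )
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
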