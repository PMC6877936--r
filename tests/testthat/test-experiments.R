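test_that("derived cell seeds are deterministic, distinct and 32-bit safe", {
  s1 <- cell_seed(1, 3, 5, 0.3, 2)
  expect_identical(s1, cell_seed(1, 3, 5, 0.3, 2))
  expect_true(s1 != cell_seed(1, 3, 5, 0.3, 3))
  expect_true(s1 != cell_seed(2, 3, 5, 0.3, 2))
  grid <- tidyr::expand_grid(r = 0:5, ti = 1:5, s = seq(0, 0.9, 0.1), run = 1:10)
  seeds <- purrr::pmap_int(grid, function(r, ti, s, run) cell_seed(1, r, ti, s, run))
  expect_true(all(seeds > 0 & seeds < 2^31))
  expect_equal(anyDuplicated(seeds), 0)
})

test_that("a pair trial without neurogenesis keeps the granule count and recovers the input similarity", {
  cfg <- network_config("200gc", neurogenesis_rate = 0)
  rec <- run_pair_trial(cfg, time_interval = 1, input_similarity = 0.5, seed = 11)
  expect_equal(rec$n_gc, 200)
  expect_lt(abs(rec$sim_ec - 0.5), 0.1) # binary construction + Poisson noise
  expect_true(rec$psi >= -1 && rec$psi <= 1)
  expect_equal(rec$psi, psi(rec$sim_ec, rec$sim_gc))
})

test_that("the factorial sweep covers the design with derived seeds", {
  sw <- run_psi_sweep(rates = 0, intervals = 1, similarities = c(0, 0.5),
                      n_runs = 2, base_seed = 5)
  recs <- tidy(sw)
  expect_equal(nrow(recs), 4)
  expect_setequal(recs$seed, purrr::map_int(1:2, function(r)
    cell_seed(5, 0, 1, 0, r)) |> c(purrr::map_int(1:2, function(r)
    cell_seed(5, 0, 1, 0.5, r))))
  g <- glance(sw)
  expect_equal(nrow(g), 2)
  expect_equal(g$n, c(2, 2))
  expect_s3_class(autoplot(sw), "ggplot")
})

test_that("the full factorial sweep design has 3000 cells", {
  design <- tidyr::expand_grid(rate = 0:5, interval = 1:5,
                               similarity = seq(0, 0.9, 0.1), run = 1:10)
  expect_equal(nrow(design), 3000)
})

test_that("the synthetic reference matrix has the stated block structure", {
  m <- synth_reference_matrix(14, 4, within_sim = 0.6, across_sim = 0.1,
                              noise_sd = 0)
  expect_equal(dim(m), c(56, 56))
  expect_equal(unname(diag(unclass(m))), rep(1, 56))
  ctx <- rep(1:14, each = 4)
  within <- outer(ctx, ctx, "==") & upper.tri(m)
  expect_equal(sum(within), 14 * choose(4, 2))
  expect_true(all(m[within] == 0.6))
  expect_true(all(m[!outer(ctx, ctx, "==")] == 0.1))
  expect_error(synth_reference_matrix(within_sim = 0.1, across_sim = 0.6), "within")
  set.seed(20)
  noisy <- synth_reference_matrix(14, 4, noise_sd = 0.05)
  expect_true(isSymmetric(unclass(noisy)))
  expect_gt(matrix_similarity(noisy, m), 0.95)
})

test_that("a small context experiment returns matrices and comparisons", {
  ref <- synth_reference_matrix(2, 2)
  ce <- run_context_experiment(repetitions = 1, reference = ref,
                               neurogenesis_rate = 3, n_contexts = 2,
                               per_context = 2, base_seed = 3)
  expect_s3_class(ce, "context_experiment")
  expect_equal(dim(ce$gc_matrices[["1"]]), c(4, 4))
  expect_equal(nrow(ce$summary), 1)
  expect_true(ce$summary$match_to_reference >= 0 &&
                ce$summary$match_to_reference <= 1)
  expect_gt(ce$summary$n_gc, 200) # births occurred during training
  expect_true(all(ce$ec_matrix[upper.tri(ce$ec_matrix)] < 0.5 + 0.15))
  expect_s3_class(autoplot(ce), "ggplot")
  expect_s3_class(autoplot(ce$gc_matrices[["1"]]), "ggplot")
})

test_that("context training integrates within-context concepts more than across", {
  wa <- function(seed) {
    set.seed(seed)
    cfg <- network_config("200gc", neurogenesis_rate = 3)
    net <- build_network(cfg)
    pats <- make_context_set(4, 4, cfg$n_lec, cfg$sparsity)
    prot <- context_protocol(pats, repetitions = 2)
    tr <- simulate_network(net, prot, pats, record_spikes = FALSE)
    gc <- lapply(pats, function(p) test_response(tr$net, p)$gc$rate)
    ec <- lapply(pats, function(p) pattern_code(p))
    ids <- vapply(pats, function(p) p$id, "")
    S <- similarity_matrix(stats::setNames(gc, ids))
    E <- similarity_matrix(stats::setNames(ec, ids))
    ctx <- rep(1:4, each = 4)
    same <- outer(ctx, ctx, "==") & upper.tri(S)
    diff <- (!outer(ctx, ctx, "==")) & upper.tri(S)
    c(within = mean(S[same]), across = mean(S[diff]), within_ec = mean(E[same]))
  }
  m <- rowMeans(sapply(1:2, wa))
  expect_gt(m[["within"]], m[["across"]])
  # within-context GC similarity exceeds the input-code similarity:
  # shared newborn cells pull same-context concepts together
  expect_gt(m[["within"]], m[["within_ec"]])
})
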