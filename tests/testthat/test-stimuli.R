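test_that("pattern size follows the coding sparsity", {
  set.seed(1)
  p <- make_pattern(100, 0.1)
  expect_length(p$active, 10)
  expect_true(all(p$active >= 1 & p$active <= 100))
  expect_length(make_pattern(100, 1.0)$active, 100)
  expect_error(make_pattern(100, 0), "sparsity")
})

test_that("expected overlap of independent patterns is hypergeometric", {
  set.seed(2)
  ov <- replicate(400, {
    a <- make_pattern(100, 0.1)$active
    b <- make_pattern(100, 0.1)$active
    length(intersect(a, b))
  })
  expect_equal(mean(ov), 1, tolerance = 0.15) # mean 10*10/100
})

test_that("pattern pairs share exactly the requested fraction of neurons", {
  set.seed(3)
  for (s in c(0, 0.3, 0.5, 1)) {
    pr <- make_pattern_pair(100, 0.1, s)
    expect_length(pr[[1]]$active, 10)
    expect_length(pr[[2]]$active, 10)
    expect_equal(length(intersect(pr[[1]]$active, pr[[2]]$active)), round(10 * s))
    expect_equal(cosine_similarity(pattern_code(pr[[1]]), pattern_code(pr[[2]])), s,
                 tolerance = 1e-12)
  }
  expect_error(make_pattern_pair(100, 0.1, 0.25), "integer")
})

test_that("context sets respect the pairwise similarity cap", {
  set.seed(4)
  pats <- make_context_set(14, 4, 100, 0.1, 0.5)
  expect_length(pats, 56)
  codes <- vapply(pats, pattern_code, integer(100))
  S <- crossprod(codes) / 10
  expect_true(all(S[upper.tri(S)] < 0.5))
  # equivalently: overlap of any two active sets is at most 4 neurons
  expect_lte(max(S[upper.tri(S)]) * 10, 4)
  expect_equal(vapply(pats, function(p) p$context, 1), rep(1:14, each = 4))
})

test_that("pair protocols measure the interval onset-to-onset", {
  A <- new_pattern("A", 1:10, 100); B <- new_pattern("B", 11:20, 100)
  p1 <- pair_protocol(A, B, duration = 1, time_interval = 1)
  expect_equal(p1$onset, c(0, 1)) # interval 1 s = immediate succession
  p5 <- pair_protocol(A, B, duration = 1, time_interval = 5)
  expect_equal(p5$onset, c(0, 5))
  p2 <- pair_protocol(A, B, duration = 2, time_interval = 4) # scaled variant
  expect_equal(p2$onset, c(0, 4))
  expect_error(pair_protocol(A, B, duration = 1, time_interval = 0.5), "overlap")
})

test_that("context protocols present every concept once per pass", {
  set.seed(5)
  pats <- make_context_set(3, 4, 100, 0.1)
  prot <- context_protocol(pats, repetitions = 2)
  expect_equal(nrow(prot), 3 * 4 * 2)
  expect_equal(prot$onset, 0:23)
  ids <- vapply(pats, function(p) p$id, "")
  expect_equal(sort(table(prot$pattern_id)), sort(table(rep(ids, 2))))
  # each consecutive block of 4 holds the four concepts of one context
  ctx_of <- function(id) sub("\\..*", "", id)
  blocks <- split(prot$pattern_id, (seq_len(nrow(prot)) - 1) %/% 4)
  for (b in blocks) expect_length(unique(ctx_of(b)), 1)
})

test_that("simulated LEC rates realise the nominal active and background rates", {
  set.seed(6)
  cfg <- network_config("200gc")
  net <- build_network(cfg)
  p <- make_pattern(cfg$n_lec, 0.1, "A")
  res <- simulate_network(net, tibble::tibble(pattern_id = "A", onset = 0, duration = 10),
                          list(p), plasticity = FALSE, neurogenesis = FALSE)
  r <- rate_vector(res$spikes, res$net, "LEC", c(0, 10000))
  act <- mean(r$rate[p$active])
  se_act <- sqrt(40 / (10 * 10)) # Poisson SE of a 10 s mean over 10 cells
  expect_lt(abs(act - 40), 3 * se_act)
  bg <- mean(r$rate[-p$active])
  se_bg <- sqrt(0.1 / (10 * 90))
  expect_lt(abs(bg - 0.1), 3 * se_bg)
})
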