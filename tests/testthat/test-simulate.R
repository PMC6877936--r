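test_that("identical seeds give bit-identical spike records", {
  run <- function() {
    set.seed(99)
    cfg <- network_config("200gc", neurogenesis_rate = 3)
    net <- build_network(cfg)
    p <- make_pattern(cfg$n_lec, 0.1, "A")
    simulate_network(net, tibble::tibble(pattern_id = "A", onset = 0, duration = 1),
                     list(p))
  }
  a <- run(); b <- run()
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$net$synapses$weight, b$net$synapses$weight)
})

test_that("an empty protocol yields only background LEC activity", {
  set.seed(6)
  cfg <- network_config("200gc")
  net <- build_network(cfg)
  p <- make_pattern(cfg$n_lec, 0.1, "A")
  res <- simulate_network(net, tibble::tibble(pattern_id = character(0),
                                              onset = numeric(0),
                                              duration = numeric(0)),
                          list(p), t_end = 5)
  lec <- res$spikes[res$spikes$layer == "LEC", ]
  expect_lt(abs(nrow(lec) - 0.1 * 100 * 5), 4 * sqrt(0.1 * 100 * 5))
})

test_that("frozen plasticity leaves every weight untouched", {
  set.seed(7)
  cfg <- network_config("200gc")
  net <- build_network(cfg)
  p <- make_pattern(cfg$n_lec, 0.1, "A")
  w0 <- net$synapses$weight
  res <- simulate_network(net, tibble::tibble(pattern_id = "A", onset = 0, duration = 1),
                          list(p), plasticity = FALSE)
  expect_identical(res$net$synapses$weight, w0)
})

test_that("the engine integrator matches the fine-step single-neuron reference", {
  # one basket cell under constant current, no synapses: the network engine
  # (conductance-implicit, dt = 0.1 ms) against plain Euler at 1 microsecond
  p <- neuron_params("BC")
  ref <- adex_spike_times(p, I_inj = 200, t_max = 400, dt = 0.001)
  cfg <- network_config("200gc")
  neurons <- dgsnn:::make_neuron_rows("BC", 1L, 1L)
  net <- structure(list(config = cfg, neurons = neurons,
                        synapses = tibble::tibble(
                          pre = integer(0), post = integer(0),
                          pathway = character(0), receptor = character(0),
                          gmax = numeric(0), weight = numeric(0),
                          plastic = logical(0), pot_used = numeric(0),
                          dep_used = numeric(0)),
                        time_ms = 0), class = "dg_network")
  net <- reset_dynamics(net)
  res <- dgsnn:::run_engine_chunk(net, lec_rate = 0, 0, 400, FALSE,
                                  I_inj = 200, inh_atten = 1)
  eng <- res$spikes$time_ms
  expect_gt(length(eng), 0)
  expect_lt(abs(eng[1] - ref[1]), 1)
})

test_that("online perforant-path plasticity equals the replay oracle", {
  set.seed(8)
  net <- micro_net(gmax = 300, lec_rate = 20) # strong drive: most pre spikes evoke a post spike
  p <- micro_pattern(net, 20)
  res <- simulate_network(net, tibble::tibble(pattern_id = "A", onset = 0, duration = 4),
                          list(p), plasticity = TRUE, neurogenesis = FALSE)
  pre <- res$spikes$time_ms[res$spikes$layer == "LEC"]
  post <- res$spikes$time_ms[res$spikes$layer == "GC"]
  expect_gt(length(post), 3)
  w_engine <- res$net$synapses$weight[1]
  expect_equal(w_engine, apply_stdp(1, pre, post), tolerance = 1e-10)
})

test_that("granule coding stays sparse during a stimulus", {
  fr <- sapply(1:3, function(s) {
    set.seed(s)
    cfg <- network_config("200gc")
    net <- build_network(cfg)
    p <- make_pattern(cfg$n_lec, 0.1, "A")
    r <- test_response(net, p)
    mean(r$gc$rate > 0)
  })
  expect_lt(mean(fr), 0.2)
})

test_that("developing granule cells outfire mature ones during a stimulus", {
  set.seed(9)
  cfg <- network_config("200gc", neurogenesis_rate = 3)
  net <- build_network(cfg)
  p <- make_pattern(cfg$n_lec, 0.1, "A")
  res <- simulate_network(net, tibble::tibble(pattern_id = "A", onset = 0, duration = 1),
                          list(p))
  # newborns are at stages 1-2 (injected current, attenuated inhibition)
  r <- rate_vector(res$spikes, res$net, "GC", c(500, 1000))
  newborn <- !is.na(res$net$neurons$birth_time[res$net$neurons$type == "GC"])
  expect_gt(mean(r$rate[newborn]), mean(r$rate[!newborn]))
})

test_that("granule cells are only added, never removed, and births follow the rate", {
  set.seed(10)
  cfg <- network_config("200gc", neurogenesis_rate = 3)
  net <- build_network(cfg)
  pr <- make_pattern_pair(cfg$n_lec, 0.1, 0.3)
  res <- simulate_network(net, pair_protocol(pr[[1]], pr[[2]], 1, 3), pr)
  expect_equal(sum(res$net$neurons$type == "GC"), 200 + 3 + 3)
})
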