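test_that("the 200-GC preset builds the published layer sizes", {
  set.seed(1)
  net <- build_network(network_config("200gc"))
  counts <- table(net$neurons$type)
  expect_equal(unname(counts[c("LEC", "GC", "MC", "BC", "HC")]),
               c(100, 200, 50, 25, 50), ignore_attr = TRUE)
  expect_true(all(net$neurons$stage[net$neurons$type == "GC"] == 5L))
  expect_setequal(unique(net$synapses$pathway),
                  c("LEC->GC", "LEC->BC", "GC->MC", "GC->HC",
                    "MC->GC", "MC->HC", "BC->GC", "HC->GC"))
  # plasticity and receptor types follow the pathway
  expect_true(all(net$synapses$plastic == (net$synapses$pathway == "LEC->GC")))
  expect_true(all((net$synapses$receptor == "GABA") ==
                    (net$synapses$pathway %in% c("BC->GC", "HC->GC"))))
})

test_that("connection probabilities 0 and 1 give empty and full pathways", {
  set.seed(2)
  net <- build_network(network_config("200gc",
                                      conn_prob = c("MC->GC" = 1, "HC->GC" = 0)))
  mc_gc <- net$synapses[net$synapses$pathway == "MC->GC", ]
  expect_equal(nrow(mc_gc), 50 * 200)
  expect_true(all(mc_gc$gmax == 1.0)) # published mossy-to-granule conductance
  expect_equal(sum(net$synapses$pathway == "HC->GC"), 0)
})

test_that("birth times are deterministic, evenly spaced and stimulus-bound", {
  expect_length(neurogenesis_births(3, 0, 1), 3)
  expect_length(neurogenesis_births(0, 0, 1), 0)
  expect_length(neurogenesis_births(3, 0, 2), 6)
  b <- neurogenesis_births(3, 2, 1)
  expect_true(all(b > 2 & b < 3))
  expect_equal(diff(b), rep(1 / 3, 2), tolerance = 1e-12)
  set.seed(11)
  bp <- neurogenesis_births(3, 2, 1, scheme = "poisson")
  expect_true(all(bp >= 2 & bp <= 3))
  expect_false(is.unsorted(bp))
})

test_that("a newborn starts at stage 1 wired to the active input set", {
  set.seed(3)
  net <- build_network(network_config("200gc", neurogenesis_rate = 3))
  active <- 1:10
  n0 <- nrow(net$neurons)
  net2 <- add_newborn_gc(net, 0.5, active)
  expect_equal(nrow(net2$neurons), n0 + 1)
  new_id <- net2$neurons$id[nrow(net2$neurons)]
  expect_equal(net2$neurons$stage[net2$neurons$id == new_id], 1L)
  aff <- net2$synapses[net2$synapses$post == new_id &
                         net2$synapses$pathway == "LEC->GC", ]
  expect_equal(nrow(aff), ceiling(0.4 * 10)) # stage-1 wiring ratio
  expect_true(all(aff$pre %in% active))
  expect_true(all(aff$plastic) && all(aff$weight == 1))
  # stage-1 phenotype: 100 pA injected, fivefold-attenuated inhibition
  sv <- dgsnn:::stage_vectors(net2)
  i <- which(net2$neurons$id == new_id)
  expect_equal(sv$I_inj[i], 100)
  expect_equal(sv$inh_atten[i], 0.2)
  # empty active set is refused
  expect_warning(out <- add_newborn_gc(net, 0.5, integer(0)), "stimulus")
  expect_equal(nrow(out$neurons), n0)
})

test_that("maturation advances stages on schedule and is absorbing", {
  set.seed(4)
  net <- build_network(network_config("200gc", neurogenesis_rate = 3))
  net <- add_newborn_gc(net, 0, 1:10)
  id <- net$neurons$id[nrow(net$neurons)]
  stage_at <- function(t) {
    n <- advance_maturation(net, t, integer(0))
    n$neurons$stage[n$neurons$id == id]
  }
  expect_equal(stage_at(0.5), 1L)
  expect_equal(stage_at(1.001), 2L)
  expect_equal(stage_at(2.5), 3L)
  expect_equal(stage_at(4.2), 5L)
  expect_equal(stage_at(40), 5L) # never beyond the mature stage
})

test_that("stage transitions during a stimulus add non-duplicate afferents", {
  set.seed(5)
  net <- build_network(network_config("200gc", neurogenesis_rate = 3))
  active <- 1:10
  net <- add_newborn_gc(net, 0, active)
  id <- net$neurons$id[nrow(net$neurons)]
  before <- net$synapses$pre[net$synapses$post == id &
                               net$synapses$pathway == "LEC->GC"]
  net2 <- advance_maturation(net, 1.001, active)
  after <- net2$synapses$pre[net2$synapses$post == id &
                               net2$synapses$pathway == "LEC->GC"]
  expect_lte(length(after) - length(before), ceiling(0.3 * 10))
  expect_false(any(duplicated(after)))
  expect_true(all(setdiff(after, before) %in% active))
})

test_that("config validation names offending fields", {
  expect_error(network_config("999gc"), "valid presets")
  expect_error(network_config("200gc", conn_prob = c("GC->LEC" = 0.5)),
               "unknown pathway")
  expect_error(network_config("200gc", neurogenesis_rate = -1), ">= 0")
})
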