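test_that("the default full-scale network has the published structure", {
  net <- build_default_network(default_network_config("full"), seed = 7)
  nd <- net$neurons
  expect_equal(nrow(nd), 900)
  # 8 cortical subsectors (4 layers x 2), each layer 100 excitatory + 50 FS
  cort <- nd[nd$is_cortical, ]
  expect_equal(length(unique(cort$subsector)), 16) # PY and IN rows x 2 each
  for (L in c("L2/3", "L4", "L5", "L6")) {
    expect_equal(sum(cort$population == paste0(L, "_PY")), 100)
    expect_equal(sum(cort$population == paste0(L, "_IN")), 50)
    expect_true(all(cort$cell_type[cort$population == paste0(L, "_IN")] ==
                      "FS"))
  }
  for (p in c("TC_FO", "TC_HO", "NRT_FO", "NRT_HO"))
    expect_equal(sum(nd$population == p), 75)
})

test_that("connection tables satisfy the wiring invariants across seeds and radii", {
  for (seed in c(1, 12, 123)) {
    cfg <- default_network_config("desk")
    net <- build_default_network(cfg, seed = seed)
    ct <- connection_table(net)
    expect_false(any(ct$pre_id == ct$post_id))
    expect_false(anyDuplicated(paste(ct$pre_id, ct$post_id, ct$receptor)) > 0)
    expect_true(all(ct$latency_ms > 0))
    expect_true(all(ct$weight >= 0))
  }
  # topographic containment on a bare projection
  src <- data.frame(id = 1:20, position = 0:19)
  tgt <- data.frame(id = 101:120, position = 0:19)
  for (radius in c(1, 3, 5)) {
    rows <- build_projection(src, tgt, "AMPA", radius, 0.1, seed = 3)
    ctr <- round((rows$pre_id - 1) / 19 * 19)
    expect_true(all(abs((rows$post_id - 101) - ctr) <= radius))
    expect_true(all(table(rows$pre_id) <= 2 * radius + 1))
  }
})

test_that("degenerate radius connects aligned partners and never self", {
  src <- data.frame(id = 1:10, position = 0:9)
  rows <- build_projection(src, src, "AMPA", 1, 0.1, seed = 1)
  expect_false(any(rows$pre_id == rows$post_id))
  # radius wider than the row clips with a warning
  expect_warning(build_projection(src, src, "AMPA", 50, 0.1, seed = 1),
                 "clip")
})

test_that("placement is deterministic in the seed and respects counts", {
  a <- place_neurons(c(RS = 7, IB = 3), seed = 5)
  b <- place_neurons(c(RS = 7, IB = 3), seed = 5)
  d <- place_neurons(c(RS = 7, IB = 3), seed = 6)
  expect_identical(a, b)
  expect_false(identical(a$cell_type, d$cell_type))
  expect_equal(sum(a$cell_type == "RS"), 7)
  expect_equal(nrow(a), 10)
})

test_that("network construction is reproducible and hashable", {
  n1 <- build_default_network(default_network_config("desk"), seed = 3)
  n2 <- build_default_network(default_network_config("desk"), seed = 3)
  expect_identical(n1$connections, n2$connections)
  expect_identical(network_hash(n1), network_hash(n2))
  n3 <- build_default_network(default_network_config("desk"), seed = 4)
  expect_false(identical(network_hash(n1), network_hash(n3)))
})

test_that("SIB substitution follows the requested layers and fraction", {
  net <- desk_network()
  s0 <- substitute_sib(net, "L5", fraction = 0)
  expect_identical(s0$neurons, net$neurons)
  s1 <- substitute_sib(net, "L5", fraction = 1)
  expect_false(any(s1$neurons$cell_type == "IB" &
                     s1$neurons$population == "L5_PY"))
  expect_identical(s1$neurons$cell_type[net$neurons$population == "L6_PY"],
                   net$neurons$cell_type[net$neurons$population == "L6_PY"])
  expect_identical(substitute_sib(net, "L5", 0.5, seed = 9)$neurons,
                   substitute_sib(net, "L5", 0.5, seed = 9)$neurons)
  expect_error(substitute_sib(net, "L5", fraction = 1.2), "fraction")
  expect_error(substitute_sib(net, "L3"), "layers")
})

test_that("reciprocal thalamic loops and corticothalamic pathways exist", {
  net <- desk_network()
  ct <- connection_table(net)
  pop <- function(id) net$neurons$population[match(id, net$neurons$id)]
  pairs <- unique(paste(pop(ct$pre_id), pop(ct$post_id), sep = ">"))
  expect_true(all(c("TC_FO>NRT_FO", "NRT_FO>TC_FO",
                    "TC_HO>NRT_HO", "NRT_HO>TC_HO",
                    "TC_FO>L4_PY", "L6_PY>TC_FO",
                    "TC_HO>L5_PY", "L5_PY>TC_HO") %in% pairs))
})

test_that("desk scaling divides counts by five and keeps invariants", {
  desk <- build_default_network(default_network_config("desk"), seed = 2)
  expect_equal(nrow(desk$neurons), 180)
  ct <- desk$connections
  expect_false(any(ct$pre_id == ct$post_id))
  expect_false(anyDuplicated(paste(ct$pre_id, ct$post_id, ct$receptor)) > 0)
})
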