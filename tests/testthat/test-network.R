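# Population layout, in-degree rule, nearest-neighbour connectivity, weight
# normalization and the configuration axes.

# the published in-degree table for the default 75-25 layout
.table1 <- list(
  c("RS", "RS", 11), c("RS", "IB", 4), c("RS", "NRS", 4), c("RS", "LTS", 3),
  c("IB", "IB", 11), c("IB", "RS", 11), c("IB", "NRS", 11), c("IB", "LTS", 9),
  c("NRS", "NRS", 11), c("NRS", "RS", 11), c("NRS", "IB", 11),
  c("NRS", "LTS", 9), c("NRS", "TC", 16), c("NRS", "RE", 16),
  c("LTS", "RS", 11), c("LTS", "IB", 11), c("LTS", "NRS", 11),
  c("TC", "RE", 11), c("TC", "NRS", 21), c("TC", "IB", 21),
  c("TC", "RS", 21), c("TC", "LTS", 21), c("RE", "RE", 11), c("RE", "TC", 11)
)

test_that("the in-degree rule reproduces all 24 published entries exactly", {
  counts <- population_layout(75, 25)
  base_of <- function(pre, post) {
    cortical <- c("RS", "IB", "NRS", "LTS")
    if ((pre %in% cortical) == (post %in% cortical)) 11 else 21
  }
  for (row in .table1) {
    got <- in_degree(base_of(row[1], row[2]), counts[[row[1]]], counts[[row[2]]])
    expect_equal(got, as.integer(row[3]),
                 info = paste(row[1], "->", row[2]))
  }
})

test_that("non-default layouts keep in-degrees within [1, n_pre]", {
  for (nIB in c(95, 5, 50)) {
    counts <- population_layout(nIB)
    for (row in .table1) {
      k <- in_degree(if (row[2] %in% c("TC", "RE") ||
                           row[1] %in% c("TC", "RE")) 21 else 11,
                     counts[[row[1]]], counts[[row[2]]])
      expect_gte(k, 1)
      expect_lte(k, counts[[row[1]]])
    }
  }
  expect_error(population_layout(50, 40), "100")
})

test_that("connect gives every post cell exactly n_in edges, no wraparound, no self-edges", {
  em <- connect(100, 100, 11, recurrent = TRUE)
  expect_equal(nrow(em), 100 * 11)
  expect_true(all(table(em[, "post"]) == 11))
  expect_true(all(em[, "pre"] != em[, "post"]))
  # edge-of-line cells still get n_in edges, filled inward
  first <- em[em[, "post"] == 1, "pre"]
  expect_equal(length(first), 11)
  expect_true(all(first <= 13))
  # asymmetric projection
  em2 <- connect(25, 75, 4)
  expect_equal(nrow(em2), 75 * 4)
  expect_error(connect(5, 10, 6), "exceeds")
})

test_that("edge weights are g_syn/n_in and sum back to the projection conductance", {
  net <- build_network(network_config())
  ed <- net$edges
  pr <- net$projections
  # reticular recurrent: 11 edges of 0.2/11 uS each
  rere <- which(pr$pre == "RE" & pr$post == "RE")
  w <- ed$weight[ed$proj == rere]
  expect_equal(unique(w), 0.2 / 11, tolerance = 1e-12)
  # conservation for every projection: inbound weights sum to g_eff
  for (i in seq_len(nrow(pr))) {
    wsum <- sum(ed$weight[ed$proj == i & ed$post_idx == ceiling(net$counts[[pr$post[i]]] / 2)])
    expect_equal(wsum, pr$g_eff[i], tolerance = 1e-9,
                 info = paste(pr$pre[i], pr$post[i], pr$receptor[i]))
  }
})

test_that("build_network realizes the projection set of the circuit", {
  net <- build_network(network_config())
  expect_equal(sum(net$counts), 475)
  ed <- net$edges
  # LTS receives AMPA only
  expect_equal(unique(ed$receptor[ed$post_class == "LTS"]), "AMPA")
  # the only cortical input to the thalamus is from layer 6
  cortex <- c("RS", "IB", "NRS", "LTS")
  thal_in <- ed[ed$post_class %in% c("TC", "RE") & ed$pre_class %in% cortex, ]
  expect_equal(unique(thal_in$pre_class), "NRS")
  # dual-receptor projections
  expect_setequal(unique(ed$receptor[ed$pre_class == "RE" & ed$post_class == "TC"]),
                  c("GABAA", "GABAB"))
  expect_setequal(unique(ed$receptor[ed$pre_class == "LTS"]), c("GABAA", "GABAB"))
  # non-default composition keeps the total
  net50 <- build_network(network_config(50))
  expect_equal(sum(net50$counts), 475)
  expect_equal(unname(net50$counts[c("RS", "IB")]), c(50L, 50L))
})

test_that("network construction is deterministic", {
  a <- build_network(network_config(95))
  b <- build_network(network_config(95))
  expect_identical(a$edges, b$edges)
  expect_identical(a$projections, b$projections)
})

test_that("enhancement multiplies exactly the three frontocortical conductances", {
  cfg <- apply_enhancement(network_config(), 7, 5, 3)
  net <- build_network(cfg)
  pr <- net$projections
  expect_equal(pr$g_eff[pr$pre == "IB" & pr$post == "IB"], 0.3 * 7)
  expect_equal(pr$g_eff[pr$pre == "IB" & pr$post == "NRS"], 0.05 * 5)
  expect_equal(pr$g_eff[pr$pre == "NRS" & pr$post == "IB"], 0.3 * 3)
  # all other projections untouched
  base <- build_network(network_config())$projections
  same <- !(pr$pre == "IB" & pr$post %in% c("IB", "NRS")) &
    !(pr$pre == "NRS" & pr$post == "IB")
  expect_equal(pr$g_eff[same], base$g_eff[same])
  # identity factors change nothing
  expect_equal(build_network(apply_enhancement(network_config(), 1, 1, 1))$projections$g_eff,
               base$g_eff)
  expect_error(apply_enhancement(network_config(), 0.5, 1, 1), ">= 1")
})

test_that("mutation scaling reaches cortical pyramidal GABAA synapses only", {
  net <- build_network(network_config(gaba_fraction = 0.1))
  base <- build_network(network_config())
  pr <- net$projections
  pb <- base$projections
  cortical_gabaa <- pr$receptor == "GABAA" & pr$post %in% c("RS", "IB", "NRS")
  expect_equal(pr$g_eff[cortical_gabaa], 0.1 * pb$g_eff[cortical_gabaa])
  expect_equal(pr$g_eff[!cortical_gabaa], pb$g_eff[!cortical_gabaa])
})

test_that("synapse tables round-trip through the delimited format", {
  dir <- tempfile()
  write_synapse_tables(dir)
  back <- read_synapse_tables(dir)
  orig <- read_synapse_tables()
  expect_equal(back$gmax, orig$gmax)
  expect_equal(back$alpha, orig$alpha)
  expect_equal(back$beta, orig$beta)
})
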