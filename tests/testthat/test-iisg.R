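test_that("ISG is the union of per-layer exact FVSs", {
  tri1 <- tri_layer("L1")
  tri2 <- tri_layer("L2")
  net <- multilayer(list(tri1, tri2))
  r <- isg(net)
  expect_equal(r$size, sg_mfvs(tri1)$size)   # identical layers: union == one FVS
  expect_true(all(r$per_layer_valid))

  # node-disjoint cycle systems add up
  la <- layer(data.frame(from = c("a", "b"), to = c("b", "a")),
              nodes = c("a", "b", "x", "y"), layer_id = "A")
  lb <- layer(data.frame(from = c("x", "y"), to = c("y", "x")),
              nodes = c("a", "b", "x", "y"), layer_id = "B")
  expect_equal(isg(multilayer(list(la, lb)))$size, 2)
})

test_that("dominated ranking follows reference membership, loop count, then node id", {
  fx <- fig8_fixture()
  cs <- enumerate_cycles(fx$study)
  rk <- dominated_rank(fx$study$nodes, cs, F_r = c("2", "5"))
  expect_equal(sort(rk$node[1:2]), c("2", "5"))  # the worked example's picks
  expect_true(all(rk$in_reference_fvs[1:2]))

  # a single criterion: strictly more loops wins when nothing else differs
  l <- layer(data.frame(from = c("a", "b", "b", "c"),
                        to = c("b", "a", "c", "b")))
  rk2 <- dominated_rank(l$nodes, enumerate_cycles(l), F_r = character(0))
  expect_equal(rk2$node[1], "b")   # b lies on both 2-cycles

  # full tie: smaller node id first
  rk3 <- dominated_rank(c("3", "4"), residual_cycles(fx$study, c("2", "5")),
                        F_r = character(0))
  expect_equal(rk3$node[1], "3")

  # function weights break remaining ties
  w <- function_weights(c("4" = 2))
  rk4 <- dominated_rank(c("3", "4"), residual_cycles(fx$study, c("2", "5")),
                        F_r = character(0), w = w)
  expect_equal(rk4$node[1], "4")

  # nodes on no cycle are ineligible
  rk5 <- dominated_rank("6", cs, F_r = character(0))
  expect_equal(nrow(rk5), 0)
})

test_that("IISG reproduces the worked example and trivial duplexes", {
  fx <- fig8_fixture()
  r <- iisg_duplex(fx$reference, fx$study)
  expect_equal(r$size, 3)
  expect_true(all(c("2", "5") %in% r$driver_nodes))
  expect_equal(r$driver_nodes, c("2", "3", "5"))
  expect_true(all(r$per_layer_valid))
  expect_s3_class(r$trace, "tbl_df")
  expect_equal(r$trace$node, c("2", "5", "3"))  # one dominated node per step

  # two identical 3-cycles: one shared node suffices
  net <- multilayer(list(tri_layer("L1"), tri_layer("L2")))
  expect_equal(iisg(net)$size, 1)
})

test_that("IISG and ISG are sound and bounded by the exhaustive oracle", {
  n_le <- 0
  n_inst <- 40
  for (i in seq_len(n_inst)) {
    net <- withr::with_seed(33000 + i, {
      random_multilayer(n = sample(5:10, 1),
                        edge_prob = runif(1, 0.1, 0.35),
                        layer_correlation = runif(1, 0, 0.8),
                        seed = 3000 + i)
    })
    u1 <- isg(net)
    u2 <- iisg(net)
    u0 <- min_union_oracle(net)
    expect_true(all(u1$per_layer_valid))
    expect_true(all(u2$per_layer_valid))
    expect_lte(u0$size, u2$size)
    expect_lte(u0$size, u1$size)
    n_le <- n_le + (u2$size <= u1$size)
  }
  expect_gte(n_le / n_inst, 0.95)  # regression baseline: IISG at most ISG-sized
})

test_that("multilayer folding uses the running union as the reference set", {
  fx <- fig8_fixture()
  single <- multilayer(list(fx$reference))
  expect_equal(iisg(single)$driver_nodes, sg_mfvs(fx$reference)$fvs)

  duplex <- multilayer(list(fx$reference, fx$study))
  expect_equal(iisg(duplex)$driver_nodes,
               iisg_duplex(fx$reference, fx$study)$driver_nodes)

  net3 <- random_multilayer(n = 12, S = 3, edge_prob = 0.2, seed = 10)
  r3 <- iisg(net3)
  expect_true(all(r3$per_layer_valid))
  expect_lte(min_union_oracle(net3)$size, r3$size)

  # reference by layer id, and reference swap keeps validity
  r_by_id <- iisg(net3, reference = "2")
  expect_true(all(r_by_id$per_layer_valid))
})

test_that("an acyclic layer contributes no driver nodes", {
  dag <- layer(data.frame(from = c("a", "b"), to = c("b", "c")),
               nodes = letters[1:3], layer_id = "dag")
  tri <- tri_layer()
  # cyclic layer as reference: the acyclic study layer adds nothing
  r <- iisg_duplex(tri, dag)
  expect_equal(r$driver_nodes, sg_mfvs(tri)$fvs)
  # acyclic layer as reference: result is still a valid FVS of the cyclic one
  r2 <- iisg_duplex(dag, tri)
  expect_true(all(r2$per_layer_valid))
  expect_equal(r2$size, 1)
})

test_that("exact-residual mode never enlarges the greedy result", {
  for (i in 1:10) {
    net <- random_multilayer(n = 9, edge_prob = 0.25, seed = 4000 + i)
    g <- iisg(net)
    e <- iisg(net, exact_residual = TRUE)
    expect_true(all(e$per_layer_valid))
    expect_lte(e$size, g$size)
  }
})

test_that("determinism: identical inputs give identical outputs", {
  net <- random_multilayer(n = 10, edge_prob = 0.3, seed = 55)
  expect_identical(iisg(net)$driver_nodes, iisg(net)$driver_nodes)
  expect_identical(isg(net)$driver_nodes, isg(net)$driver_nodes)
})

test_that("the exhaustive union oracle is exact on structured duplexes", {
  net <- multilayer(list(tri_layer("L1"), tri_layer("L2")))
  expect_equal(min_union_oracle(net)$size, 1)

  fx <- fig8_fixture()
  expect_equal(min_union_oracle(multilayer(list(fx$reference, fx$study)))$size, 3)

  la <- layer(data.frame(from = c("a", "b"), to = c("b", "a")),
              nodes = c("a", "b", "x", "y"), layer_id = "A")
  lb <- layer(data.frame(from = c("x", "y"), to = c("y", "x")),
              nodes = c("a", "b", "x", "y"), layer_id = "B")
  expect_equal(min_union_oracle(multilayer(list(la, lb)))$size, 2)

  big <- random_multilayer(n = 16, edge_prob = 0.2, seed = 9)
  expect_error(min_union_oracle(big), "max_n")
})

test_that("compare_methods tabulates all methods with the worked example's sizes", {
  fx <- fig8_fixture()
  cmp <- compare_methods(multilayer(list(fx$reference, fx$study)))
  expect_s3_class(cmp, "multifvs_comparison")
  expect_equal(cmp$size[cmp$method == "SG" & cmp$scope == "reference"], 2)
  expect_equal(cmp$size[cmp$method == "IISG"], 3)
  expect_equal(cmp$size[cmp$method == "oracle"], 3)
  expect_true(all(cmp$valid))

  net <- multilayer(list(tri_layer("L1"), tri_layer("L2")))
  cmp2 <- compare_methods(net)
  expect_equal(cmp2$size[cmp2$method == "ISG"], cmp2$size[cmp2$method == "IISG"])

  # a 14-node duplex shaped like the cancer-immune cell network: the greedy
  # union is no larger than the blind per-layer union
  cicc <- random_multilayer(n = 14, S = 2, n_edges = c(38L, 42L), seed = 303L)
  cmp3 <- compare_methods(cicc)
  expect_lte(cmp3$size[cmp3$method == "IISG"], cmp3$size[cmp3$method == "ISG"])
  expect_true(all(cmp3$valid))

  expect_s3_class(autoplot(cmp3), "ggplot")
})

test_that("union_result tidiers and the selection trace are well formed", {
  fx <- fig8_fixture()
  r <- iisg_duplex(fx$reference, fx$study)
  td <- tidy(r)
  expect_equal(td$node, c("2", "3", "5"))
  gl <- glance(r)
  expect_equal(gl$size, 3)
  expect_true(gl$valid_all_layers)
  expect_true(all(c("node", "loop_count", "phase") %in% names(r$trace)))
})
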