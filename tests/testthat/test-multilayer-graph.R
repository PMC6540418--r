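test_that("edge lists parse, deduplicate and skip comments", {
  f <- withr::local_tempfile(lines = c("a\tb", "b\ta"))
  l <- read_edge_list(f, layer_id = "L")
  expect_s3_class(l, "fvs_layer")
  expect_equal(n_nodes(l), 2)
  expect_equal(n_edges(l), 2)

  f2 <- withr::local_tempfile(lines = c("# comment", "a b", "a b", "a c 0.7"))
  l2 <- read_edge_list(f2)
  expect_equal(n_edges(l2), 2)          # duplicate collapsed, weight ignored
  expect_setequal(layer_nodes(l2), c("a", "b", "c"))

  f3 <- withr::local_tempfile(lines = c("a b", "lonely"))
  expect_error(read_edge_list(f3), "line 2")

  f4 <- withr::local_tempfile(lines = character(0))
  expect_warning(l4 <- read_edge_list(f4), "empty")
  expect_equal(n_nodes(l4), 0)
})

test_that("the worked-example study layer round-trips through an edge-list file", {
  fx <- fig8_fixture()
  f <- withr::local_tempfile()
  write_edge_list(fx$study, f)
  back <- read_edge_list(f, layer_id = "study")
  expect_equal(n_nodes(back), 7)
  expect_equal(sort(paste(back$edges$from, back$edges$to)),
               sort(paste(fx$study$edges$from, fx$study$edges$to)))
})

test_that("multiplex extended edge lists parse into ordered shared-universe layers", {
  f <- withr::local_tempfile(lines = c("1 a b 1", "2 b a 1"))
  net <- read_multiplex(f)
  expect_s3_class(net, "multilayer_network")
  expect_equal(net$S, 2)
  expect_equal(net$node_universe, c("a", "b"))
  expect_equal(names(net$layers), c("1", "2"))
  expect_equal(layer_nodes(net$layers[[2]]), c("a", "b"))  # expanded

  fself <- withr::local_tempfile(lines = "1 a a 1")
  nself <- read_multiplex(fself)
  expect_equal(n_edges(nself$layers[[1]]), 1)
  expect_true(is_fvs(nself$layers[[1]], "a"))
  expect_false(is_fvs(nself$layers[[1]], character(0)))

  fbad <- withr::local_tempfile(lines = c("1 a b 1", "x a b 1"))
  expect_error(read_multiplex(fbad), "positive integer")
  fbad2 <- withr::local_tempfile(lines = c("1 a b"))
  expect_error(read_multiplex(fbad2), "4 tokens")
})

test_that("write-then-read is the identity for multiplex networks", {
  net <- random_multilayer(n = 20, S = 3, edge_prob = 0.15, seed = 7)
  f <- withr::local_tempfile()
  write_multiplex(net, f)
  back <- read_multiplex(f)
  expect_equal(back$S, 3)
  expect_equal(back$N, 20)
  expect_equal(back$node_universe, net$node_universe)
  for (i in 1:3) {
    expect_setequal(paste(back$layers[[i]]$edges$from, back$layers[[i]]$edges$to),
                    paste(net$layers[[i]]$edges$from, net$layers[[i]]$edges$to))
  }
  # reading twice is deterministic
  expect_identical(read_multiplex(f), back)
})

test_that("node weights parse with zero default and reject bad input", {
  f <- withr::local_tempfile(lines = c("AKT\t3", "P53\t5"))
  w <- read_node_weights(f)
  expect_equal(weight_of(w, c("AKT", "P53", "JAK")), c(3, 5, 0))

  fe <- withr::local_tempfile(lines = character(0))
  we <- read_node_weights(fe)
  expect_equal(weight_of(we, "anything"), 0)

  fneg <- withr::local_tempfile(lines = "x -1")
  expect_error(read_node_weights(fneg), "non-negative")
  fnn <- withr::local_tempfile(lines = "x high")
  expect_error(read_node_weights(fnn), "Non-numeric")
})

test_that("validate_network reports per-layer structure without raising", {
  fx <- fig8_fixture()
  rep <- validate_network(multilayer(list(fx$reference, fx$study)))
  expect_equal(nrow(rep), 2)
  expect_equal(rep$n_nodes, c(7, 7))
  expect_equal(rep$expanded_by, c(0, 0))
  expect_equal(rep$self_loops, c(0, 1))

  # disjoint raw node sets get flagged as universe expansion
  la <- layer(data.frame(from = "a", to = "b"), layer_id = "A")
  lb <- layer(data.frame(from = "x", to = "y"), layer_id = "B")
  rep2 <- validate_network(multilayer(list(la, lb)))
  expect_equal(rep2$expanded_by, c(2, 2))

  cicc <- random_multilayer(n = 14, S = 2, n_edges = c(38L, 42L), seed = 303L)
  rep3 <- validate_network(cicc)
  expect_equal(rep3$n_edges, c(38L, 42L))
  expect_equal(rep3$n_nodes, c(14L, 14L))
})

test_that("node ids are opaque strings: no case folding, hyphens preserved", {
  f <- withr::local_tempfile(lines = c("GAG-POL Tat 1", "tat GAG-POL 1"))
  l <- read_edge_list(f)
  expect_setequal(layer_nodes(l), c("GAG-POL", "Tat", "tat"))
})
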