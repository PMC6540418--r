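test_that("is_fvs matches the acyclic-after-removal definition", {
  tri <- tri_layer()
  expect_true(is_fvs(tri, "a"))
  expect_false(is_fvs(tri, character(0)))
  expect_error(is_fvs(tri, "zz"), "unknown")

  fx <- fig8_fixture()
  expect_true(is_fvs(fx$study, c("2", "5", "3")))
  expect_false(is_fvs(fx$study, c("2", "5")))  # the {3,4} cycle remains
})

test_that("simplification reduces to fixpoint with the documented guarantees", {
  # an acyclic layer collapses completely
  tr <- simplify(dag_layer())
  expect_equal(tr$forced_nodes, character(0))
  expect_equal(n_nodes(tr$residual), 0)

  # a self-loop is forced
  sl <- layer(data.frame(from = c("a", "a"), to = c("a", "b")))
  tr2 <- simplify(sl)
  expect_equal(tr2$forced_nodes, "a")

  # a chordless 4-cycle contracts to a self-loop, so one node is forced and
  # the resulting set is a valid size-1 FVS of the original
  c4 <- layer(data.frame(from = c("a", "b", "c", "d"),
                         to = c("b", "c", "d", "a")))
  tr3 <- simplify(c4)
  expect_equal(length(tr3$forced_nodes), 1)
  expect_equal(n_nodes(tr3$residual), 0)
  expect_true(is_fvs(c4, tr3$forced_nodes))
  expect_equal(brute_force_mfvs(c4)$size, 1)
})

test_that("simplification invariants hold on random graphs", {
  for (i in 1:40) {
    l <- rand_layer(n = sample(4:10, 1), p = runif(1, 0.1, 0.5),
                    seed = 400 + i, self_loop_prob = 0.15)
    tr <- simplify(l)
    expect_length(intersect(tr$forced_nodes, tr$removed_nodes), 0)
    res <- tr$residual
    if (n_nodes(res) > 0) {
      expect_true(all(res$nodes %in% res$edges$from))  # out-degree >= 1
      expect_true(all(res$nodes %in% res$edges$to))    # in-degree >= 1
      expect_false(any(res$edges$from == res$edges$to))
    }
    # size preservation against the oracle
    expect_equal(length(tr$forced_nodes) + brute_force_mfvs(res)$size,
                 brute_force_mfvs(l)$size)
  }
})

test_that("brute-force oracle handles canonical small cases and refuses big ones", {
  expect_equal(brute_force_mfvs(dag_layer())$size, 0)

  two_disjoint <- layer(data.frame(from = c("a", "b", "c", "d"),
                                   to = c("b", "a", "d", "c")))
  r <- brute_force_mfvs(two_disjoint)
  expect_equal(r$size, 2)
  expect_equal(r$method, "oracle")
  expect_true(r$is_valid)

  big <- rand_layer(n = 16, p = 0.2, seed = 11)
  expect_error(brute_force_mfvs(big, max_n = 15), "max_n")
})

test_that("exact solver is optimal: complete digraph, worked example, random graphs", {
  k4 <- layer(expand.grid(from = letters[1:4], to = letters[1:4]) |>
                subset(from != to))
  expect_equal(exact_mfvs(k4)$size, 3)
  expect_equal(brute_force_mfvs(k4)$size, 3)

  fx <- fig8_fixture()
  st <- exact_mfvs(fx$study)
  expect_equal(st$size, 3)
  expect_true(st$is_valid)

  for (i in 1:40) {
    l <- rand_layer(n = sample(4:12, 1), p = runif(1, 0.1, 0.5),
                    seed = 800 + i, self_loop_prob = 0.1)
    a <- exact_mfvs(l)
    b <- brute_force_mfvs(l)
    expect_equal(a$size, b$size)
    expect_true(a$is_valid)
  }
})

test_that("MFVS size is monotone under edge addition", {
  for (i in 1:10) {
    l <- rand_layer(n = 8, p = 0.2, seed = 900 + i)
    base <- exact_mfvs(l)$size
    absent <- setdiff(
      paste(rep(l$nodes, each = 8), rep(l$nodes, 8)),
      paste(l$edges$from, l$edges$to))
    pick <- strsplit(absent[1 + (i %% length(absent))], " ")[[1]]
    l2 <- layer(rbind(as.data.frame(l$edges),
                      data.frame(from = pick[1], to = pick[2])),
                nodes = l$nodes)
    expect_gte(exact_mfvs(l2)$size, base)
  }
})

test_that("exact solver errors when an SCC exceeds the node budget", {
  kbig <- layer(subset(expand.grid(from = as.character(1:6),
                                   to = as.character(1:6)), from != to))
  expect_error(exact_mfvs(kbig, node_budget = 3), "budget")
})

test_that("SG reproduces the worked-example reference FVS and tags results", {
  expect_equal(sg_mfvs(two_cycle())$size, 1)
  fx <- fig8_fixture()
  r <- sg_mfvs(fx$reference)
  expect_equal(r$fvs, c("2", "5"))
  expect_equal(r$method, "SG")
  l <- rand_layer(n = 12, p = 0.2, seed = 1)
  expect_equal(sg_mfvs(l)$size, brute_force_mfvs(l)$size)
})

test_that("fvs_result tidiers return tibbles in broom shape", {
  r <- sg_mfvs(tri_layer())
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  gl <- glance(r)
  expect_equal(gl$size, 1)
  expect_true(gl$is_valid)
})
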