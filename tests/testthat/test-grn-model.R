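test_that("edge lists round-trip through the TSV dialect", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "a\tb\t+", "b\ta\t-"), path)
  g <- read_edge_list(path)
  expect_equal(g$nodes, c("a", "b"))
  expect_equal(nrow(g$edges), 2L)
  expect_equal(repression_fraction(g), 0.5)

  out <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(g, out)
  expect_equal(read_edge_list(out)$edges, g$edges)
})

test_that("empty files and all sign tokens parse", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), path)
  g <- read_edge_list(path)
  expect_equal(length(g$nodes), 0L)
  expect_equal(nrow(g$edges), 0L)

  writeLines(c("a\tb\tactivation", "b\tc\trepression", "c\td\t+1",
               "d\te\t-1"), path)
  g <- read_edge_list(path)
  expect_equal(g$edges$sign, c(1L, -1L, 1L, -1L))
})

test_that("duplicate rows collapse to the last sign with a warning", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb\t+", "a\tb\t-"), path)
  expect_warning(g <- read_edge_list(path), "last sign wins")
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$sign, -1L)
})

test_that("malformed rows and unknown sign tokens raise parse errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb\t+", "broken line"), path)
  expect_error(read_edge_list(path), "line 2")
  writeLines(c("a\tb\tmaybe"), path)
  expect_error(read_edge_list(path), "sign token")
})

test_that("mean degree matches the published table arithmetic", {
  whole <- network_stats(random_signed_digraph(3236, 8366, seed = 1))
  expect_equal(floor(whole$mean_degree * 100) / 100, 5.17)
  core <- network_stats(random_signed_digraph(70, 317, seed = 1))
  expect_equal(floor(core$mean_degree * 100) / 100, 9.05)

  self <- signed_digraph("a", data.frame(from = "a", to = "a", sign = 1L))
  expect_equal(network_stats(self)$mean_degree, 2.0)
  expect_equal(network_stats(signed_digraph())$mean_degree, 0)
})

test_that("recurrent core keeps exactly the cycle-participating nodes", {
  g <- signed_digraph(c("a", "b", "c", "d"),
                      data.frame(from = c("a", "b", "c", "c"),
                                 to = c("b", "c", "a", "d"),
                                 sign = rep(1L, 4)))
  core <- extract_recurrent_core(g)
  expect_setequal(core$nodes, c("a", "b", "c"))
  expect_equal(nrow(core$edges), 3L)

  dag <- signed_digraph(c("a", "b", "c"),
                        data.frame(from = c("a", "b"), to = c("b", "c"),
                                   sign = c(1L, 1L)))
  expect_equal(length(extract_recurrent_core(dag)$nodes), 0L)
})

test_that("recurrent core agrees with brute-force cycle membership", {
  for (seed in 1:20) {
    g <- rand_test_graph(n = sample(3:10, 1), m_target = sample(3:25, 1),
                         seed = seed)
    core <- extract_recurrent_core(g)
    expect_equal(sort(core$nodes), brute_cycle_nodes(g),
                 info = paste("seed", seed))
    # idempotence
    expect_equal(extract_recurrent_core(core)$nodes, core$nodes)
  }
})

test_that("giant component selects the largest (tie: smallest node id)", {
  two <- signed_digraph(letters[1:7],
                        data.frame(from = c("a", "b", "c", "d", "e", "f", "g"),
                                   to = c("b", "c", "d", "a", "f", "g", "e"),
                                   sign = rep(1L, 7)))
  expect_setequal(giant_component(two)$nodes, c("a", "b", "c", "d"))

  tie <- signed_digraph(letters[1:6],
                        data.frame(from = c("a", "b", "c", "d", "e", "f"),
                                   to = c("b", "c", "a", "e", "f", "d"),
                                   sign = rep(1L, 6)))
  expect_setequal(giant_component(tie)$nodes, c("a", "b", "c"))

  expect_equal(giant_component(two, mode = "strong")$nodes,
               giant_component(two)$nodes)
  expect_error(giant_component(signed_digraph()), "empty")
})

test_that("constructor enforces the structural invariants", {
  expect_error(signed_digraph("a", data.frame(from = "a", to = "b", sign = 1L)),
               "endpoints")
  expect_error(signed_digraph(c("a", "b"),
                              data.frame(from = c("a", "a"), to = c("b", "b"),
                                         sign = c(1L, -1L))),
               "duplicate")
  expect_error(signed_digraph("a", data.frame(from = "a", to = "a", sign = 2L)),
               "sign")
})
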