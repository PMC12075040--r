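test_that("motif counters handle the canonical small cases", {
  loop <- signed_digraph("a", data.frame(from = "a", to = "a", sign = 1L))
  expect_equal(count_self_loops(loop), 1L)
  expect_equal(count_self_loops(delay_chain(5)), 1L)

  pair <- signed_digraph(c("a", "b"),
                         data.frame(from = c("a", "b"), to = c("b", "a"),
                                    sign = c(1L, -1L)))
  expect_equal(count_mutual_regulation(pair), 1L)

  cyc3 <- signed_digraph(c("a", "b", "c"),
                         data.frame(from = c("a", "b", "c"),
                                    to = c("b", "c", "a"),
                                    sign = rep(1L, 3)))
  expect_equal(count_mutual_regulation(cyc3), 0L)
  expect_equal(count_ffl(cyc3), 0L)

  ffl <- signed_digraph(c("x", "y", "z"),
                        data.frame(from = c("x", "y", "x"),
                                   to = c("y", "z", "z"),
                                   sign = rep(1L, 3)))
  expect_equal(count_ffl(ffl), 1L)

  # complete digraph on 3 nodes: 3 mutual pairs, 6 ordered FFL triples
  idx <- expand.grid(from = c("a", "b", "c"), to = c("a", "b", "c"))
  idx <- idx[idx$from != idx$to, ]
  full3 <- signed_digraph(c("a", "b", "c"),
                          data.frame(from = idx$from, to = idx$to,
                                     sign = rep(1L, 6)))
  expect_equal(count_mutual_regulation(full3), 3L)
  expect_equal(count_ffl(full3), 6L)
})

test_that("counters agree with exhaustive enumeration on small graphs", {
  for (seed in 1:25) {
    g <- rand_test_graph(n = sample(3:8, 1), m_target = sample(4:30, 1),
                         seed = 100 + seed)
    expect_equal(motif_census(g), brute_census(g), info = paste("seed", seed))
  }
})

test_that("the census is sign-blind", {
  g <- rand_test_graph(8, 25, seed = 7)
  for (f in c(0, 0.5, 1)) {
    expect_equal(motif_census(randomize_signs(g, f, seed = 1)),
                 motif_census(g))
  }
})

test_that("z-scores follow the caption formula exactly", {
  g <- motif_enriched_graph(20, 40, extra_self_loops = 8, seed = 3)
  n_rand <- 60
  zs <- motif_zscores(g, n_rand = n_rand, seed = 9)
  # recompute the ensemble moments independently from the same null draws
  counts <- t(vapply(seq_len(n_rand), function(i) {
    motif_census(random_signed_digraph(20, nrow(g$edges),
                                       allow_self_loops = TRUE,
                                       seed = softmem:::sub_seed(9, i, 71L)))
  }, numeric(3)))
  real <- motif_census(g)
  expect_equal(zs$null_mean, unname(colMeans(counts)))
  expect_equal(zs$null_sd, unname(apply(counts, 2, sd)))
  expect_equal(zs$zscore,
               unname((real - colMeans(counts)) / apply(counts, 2, sd)))
  # arithmetic identity: real 28, null 10 +/- 3 gives z = 6
  expect_equal((28 - 10) / 3, 6)
})

test_that("null-drawn graphs score |z| < 3 (calibration)", {
  for (i in 1:5) {
    g <- random_signed_digraph(40, 150, seed = 500 + i)
    zs <- motif_zscores(g, n_rand = 150, seed = i)
    expect_true(all(abs(zs$zscore[!zs$degenerate]) < 3),
                info = paste("draw", i))
  }
})

test_that("normalised counts divide by the null mean with analytic fallback", {
  g <- motif_enriched_graph(12, 18, extra_self_loops = 4, seed = 5)
  n_rand <- 80
  norm <- normalized_motif_counts(g, n_rand = n_rand, seed = 13)
  counts <- t(vapply(seq_len(n_rand), function(i) {
    motif_census(random_signed_digraph(12, nrow(g$edges),
                                       allow_self_loops = TRUE,
                                       seed = softmem:::sub_seed(13, i, 71L)))
  }, numeric(3)))
  real <- motif_census(g)
  mu <- colMeans(counts)
  expect_equal(unname(norm[mu > 0]), unname((real / mu)[mu > 0]))

  # zero real count normalises to zero even when the null mean is zero
  bare <- signed_digraph(c("a", "b"),
                         data.frame(from = c("a", "b"), to = c("b", "a"),
                                    sign = c(1L, 1L)))
  norm2 <- normalized_motif_counts(bare, n_rand = 3, seed = 1)
  expect_equal(unname(norm2[["ffl"]]), 0)
  expect_true(all(is.finite(norm2)))
})

test_that("analytic null expectations match the sampled ensemble", {
  n <- 25; m <- 80
  counts <- t(vapply(1:300, function(i) {
    motif_census(random_signed_digraph(n, m, seed = 3000 + i))
  }, numeric(3)))
  ana <- softmem:::analytic_null_means(n, m)
  for (j in 1:3) {
    se <- sd(counts[, j]) / sqrt(300)
    expect_lt(abs(mean(counts[, j]) - ana[j]), 3 * se + 0.05,
              label = colnames(counts)[j])
  }
})
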