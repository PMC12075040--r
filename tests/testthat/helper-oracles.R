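# Brute-force oracles, independent of the package internals.

# all nodes lying on at least one directed cycle, by DFS from every node
brute_cycle_nodes <- function(g) {
  adj <- split(g$edges$to, factor(g$edges$from, levels = g$nodes))
  on_cycle <- character(0)
  for (start in g$nodes) {
    # DFS over walks from `start`; start is on a cycle iff reachable from
    # one of its successors
    stack <- adj[[start]]
    seen <- character(0)
    while (length(stack)) {
      v <- stack[[1]]
      stack <- stack[-1]
      if (v == start) {
        on_cycle <- c(on_cycle, start)
        break
      }
      if (v %in% seen) next
      seen <- c(seen, v)
      stack <- c(stack, adj[[v]])
    }
  }
  sort(on_cycle)
}

# exhaustive motif census over all node pairs/triples
brute_census <- function(g) {
  has <- function(a, b) any(g$edges$from == a & g$edges$to == b)
  nodes <- g$nodes
  sl <- sum(vapply(nodes, function(v) has(v, v), logical(1)))
  mut <- 0L
  if (length(nodes) >= 2) {
    for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
      if (i < j && has(nodes[i], nodes[j]) && has(nodes[j], nodes[i])) {
        mut <- mut + 1L
      }
    }
  }
  ffl <- 0L
  if (length(nodes) >= 3) {
    for (x in nodes) for (y in nodes) for (z in nodes) {
      if (x != y && y != z && x != z &&
          has(x, y) && has(y, z) && has(x, z)) {
        ffl <- ffl + 1L
      }
    }
  }
  c(self_loops = sl, mutual_regulation = mut, ffl = ffl)
}

# reference NARMA-10 iteration, written independently of the package
brute_narma10 <- function(s) {
  L <- length(s)
  y <- numeric(L)
  yext <- function(t) if (t < 1) 0 else y[t]
  sext <- function(t) if (t < 1) 0 else s[t]
  y[1] <- 0.3 * 0 + 0.05 * 0 * 0 + 1.5 * sext(-9) * sext(0) + 0.1
  for (t in 1:(L - 1)) {
    acc <- 0
    for (i in 0:9) acc <- acc + yext(t - i)
    y[t + 1] <- 0.3 * y[t] + 0.05 * y[t] * acc + 1.5 * sext(t - 9) * s[t] + 0.1
  }
  y
}

# double-loop delayed AND evaluation
brute_delayed_and <- function(I1, I2, k) {
  out <- integer(length(I1))
  for (i in seq_along(I1)) {
    a <- if (i - k >= 1) I1[i - k] else 0L
    out[i] <- as.integer(a == 1L && I2[i] == 1L)
  }
  out
}

# small random signed digraph for property tests (duplicates filtered)
rand_test_graph <- function(n, m_target, seed, self_loops = TRUE) {
  set.seed(seed)
  nodes <- letters[seq_len(n)]
  from <- sample(nodes, m_target, replace = TRUE)
  to <- sample(nodes, m_target, replace = TRUE)
  if (!self_loops) {
    keep <- from != to
    from <- from[keep]; to <- to[keep]
  }
  key <- paste(from, to)
  keep <- !duplicated(key)
  signed_digraph(nodes, data.frame(
    from = from[keep], to = to[keep],
    sign = sample(c(-1L, 1L), sum(keep), replace = TRUE)))
}
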