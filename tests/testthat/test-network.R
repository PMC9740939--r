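test_that("target intersection is case-normalized, commutative, idempotent", {
  a <- target_set("c", c("A", "B", "C"))
  b <- target_set("d", c("B", "C", "D"))
  expect_equal(intersect_targets(a, b)$targets, c("B", "C"))
  expect_equal(intersect_targets(b, a)$targets, intersect_targets(a, b)$targets)
  ab <- intersect_targets(a, b)
  expect_equal(intersect_targets(ab, ab)$targets, ab$targets)

  expect_equal(intersect_targets(c("akt1"), c("AKT1"))$targets, "AKT1")
  expect_warning(dj <- intersect_targets(c("A"), c("B")),
                 class = "herbipk_disjoint_targets")
  expect_length(dj, 0)
  expect_error(intersect_targets(character(0), c("A")),
               class = "herbipk_empty_set")
})

test_that("interaction_network drops self-loops, duplicate edges, low scores", {
  ed <- data.frame(node_a = c("a", "b", "B", "c", "d"),
                   node_b = c("b", "a", "a", "c", "e"),
                   score = c(0.9, 0.8, 0.7, 0.5, 0.2))
  net <- interaction_network(ed)
  expect_equal(nrow(net$edges), 2)                 # A-B deduped, C-C loop gone
  expect_setequal(net$nodes, c("A", "B", "D", "E"))
  net2 <- interaction_network(ed, score_cutoff = 0.5)
  expect_equal(nrow(net2$edges), 1)                # D-E (0.2) filtered
})

test_that("degree and closeness follow the component-scaled convention", {
  path <- interaction_network(data.frame(a = c("A", "B"), b = c("B", "C")))
  m <- topology_metrics(path)
  expect_equal(m$degree[m$node == "B"], 2)
  expect_equal(m$closeness[m$node == "B"], 1)
  expect_equal(m$closeness[m$node == "A"], 2 / 3)

  tri <- interaction_network(data.frame(a = c("A", "B", "C"), b = c("B", "C", "A")))
  mt <- topology_metrics(tri)
  expect_equal(mt$degree, rep(2, 3))
  expect_equal(mt$closeness, rep(1, 3))

  two <- interaction_network(data.frame(a = c("A", "C"), b = c("B", "D")))
  m2 <- topology_metrics(two)
  expect_equal(m2$closeness, rep(1 / 3, 4))        # (1/1) * (1/3) each

  # harmonic variant: path ends average 1/1 and 1/2 over two others
  mh <- topology_metrics(path, closeness = "harmonic")
  expect_equal(mh$closeness[mh$node == "A"], (1 + 1 / 2) / 2)
})

test_that("isolated nodes keep others' degrees, weakly lower their closeness", {
  base <- interaction_network(data.frame(a = c("A", "B"), b = c("B", "C")))
  plus <- interaction_network(data.frame(a = c("A", "B"), b = c("B", "C")),
                              nodes = "Z")
  m0 <- topology_metrics(base); m1 <- topology_metrics(plus)
  shared <- intersect(m0$node, m1$node)
  expect_equal(m1$degree[match(shared, m1$node)], m0$degree[match(shared, m0$node)])
  expect_true(all(m1$closeness[match(shared, m1$node)] <=
                    m0$closeness[match(shared, m0$node)]))
})

test_that("key-target selection demands both metrics above the subnetwork mean", {
  m <- data.frame(node = c("X", "Y", "Z"), degree = c(1, 2, 9),
                  closeness = c(0.9, 0.9, 0.95))
  sel <- select_key_targets(m)        # mean degree 4: only Z; closeness all > mean? no
  expect_equal(sel$node, "Z")

  const <- data.frame(node = c("X", "Y"), degree = c(2, 2), closeness = c(1, 1))
  expect_warning(empty <- select_key_targets(const),
                 class = "herbipk_no_key_targets")
  expect_equal(nrow(empty), 0)

  star <- interaction_network(data.frame(a = rep("HUB", 4),
                                         b = paste0("L", 1:4)))
  sel2 <- select_key_targets(topology_metrics(star))
  expect_equal(sel2$node, "HUB")
})

test_that("hypergeometric enrichment reproduces closed-form tail probabilities", {
  # full overlap of a 5-gene pathway by a 5-gene query in a 20-gene universe
  uni <- sprintf("G%02d", 1:20)
  res <- enrich_pathways(uni[1:5], list(PW = uni[1:5]), uni)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$overlap_count, 5)

  # N=10, K=4, n=3, k>=2 -> 40/120
  uni10 <- sprintf("G%02d", 1:10)
  res2 <- enrich_pathways(c(uni10[1:2], uni10[10]), list(PW = uni10[1:4]), uni10)
  expect_equal(res2$p_value, 1 / 3, tolerance = 1e-12)

  # zero overlap -> p = 1
  res3 <- enrich_pathways(uni10[9:10], list(PW = uni10[1:4]), uni10)
  expect_equal(res3$p_value, 1)

  # EASE discount is more conservative for k >= 1
  expect_gt(enrich_pathways(uni[1:5], list(PW = uni[1:5]), uni, ease = TRUE)$p_value,
            res$p_value)

  expect_error(enrich_pathways(c("G01", "NOPE"), list(PW = uni[1:4]), uni),
               class = "herbipk_universe_violation")
})

test_that("enrichment p-values match exhaustive draw enumeration on small universes", {
  withr::with_seed(5, {
    for (rep in 1:25) {
      N <- sample(5:11, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
      uni <- sprintf("g%02d", 1:N)
      kmax <- min(K, n); kmin <- max(0, n - (N - K))
      k <- sample(seq(kmin, kmax), 1)
      query <- c(uni[seq_len(K)][seq_len(k)],
                 setdiff(uni, uni[seq_len(K)])[seq_len(n - k)])
      res <- enrich_pathways(query, list(PW = uni[seq_len(K)]), uni)
      expect_equal(res$p_value, oracle_hyper_tail(N, K, n, k), tolerance = 1e-12)
    }
  })
})

test_that("BH adjustment matches the hand step-up and its invariants", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.05, 4)), rep(0.05, 4))
  expect_error(bh_adjust(c(0.1, 0)), class = "herbipk_invalid_p")
  expect_error(bh_adjust(c(0.1, 1.2)), class = "herbipk_invalid_p")

  withr::with_seed(13, {
    for (rep in 1:50) {
      p <- runif(sample(2:40, 1))
      q <- bh_adjust(p)
      expect_equal(q, oracle_bh(p), tolerance = 1e-12)
      expect_true(all(q >= p))
      o <- order(p)
      expect_true(all(diff(q[o]) >= -1e-12))   # monotone in the p ranking
    }
  })
})
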