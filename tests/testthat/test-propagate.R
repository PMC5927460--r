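# Fusion, Consensus and chained propagation.

test_that("sigmoid has the documented midpoint, value and monotonicity", {
  expect_equal(sigmoid(0.6), 0.5)
  expect_equal(sigmoid(0.3, beta = -2, gamma = 0.3), 0.5)
  # closed form at full similarity under default parameters
  expect_equal(sigmoid(1), 1 / (1 + exp(-9 * (1 - 0.6))))
  x <- seq(0, 1, by = 0.05)
  expect_true(all(diff(sigmoid(x)) > 0))
  expect_true(all(sigmoid(x) > 0 & sigmoid(x) < 1))
})

test_that("single annotated neighbor with identical structure gives the closed-form score", {
  fam <- pool_table()
  s <- fam$smiles[1]
  other <- fam$smiles[fam$scaffold != fam$scaffold[1]][1:2]
  net <- nap_network(data.frame(node_id = c("q", "r")),
                     data.frame(node_a = "q", node_b = "r", cosine = 1))
  cand <- load_candidates(
    data.frame(node_id = "q", structure = c(s, other), fc = c(1, 0.6, 0.2))
  )
  lib <- load_library_matches(
    data.frame(node_id = "r", structure = s, match_cosine = 1)
  )
  scored <- fusion_score("q", net, cand, lib)
  top <- scored[scored$identity_key ==
                  parse_structure(s)$identity_key, ]
  # Sc = 0.3 * 1 + 0.7 * sig(1 * 1) with sig(1) = 1/(1 + e^-3.6)
  expect_equal(top$score_fusion, 0.3 + 0.7 / (1 + exp(-3.6)),
               tolerance = 1e-12)
  expect_equal(scored$identity_key[1], top$identity_key)

  # the same inputs through consensus (neighbor's rank-1 candidate = s)
  cand2 <- rbind(cand, load_candidates(
    data.frame(node_id = "r", structure = c(s, other[1]), fc = c(0.9, 0.1))
  ))
  scored2 <- consensus_score("q", net, cand2)
  top2 <- scored2[scored2$identity_key == top$identity_key, ]
  expect_equal(top2$score_consensus, top$score_fusion, tolerance = 1e-12)
})

test_that("propagation requires the right neighborhood and degrades gracefully", {
  p <- chain_problem()
  # A has no candidates; B's only annotated neighbor is A; C has none
  expect_error(fusion_score("C", p$net, p$candidates, p$matches),
               class = "nap_no_annotated_neighbor")
  lone <- nap_network(data.frame(node_id = c("B", "X")))
  expect_error(consensus_score("B", lone, p$candidates),
               class = "nap_no_neighbor_candidates")

  res <- propagate(p$net, p$candidates, p$matches,
                   scoring_params(mode = "fusion_then_consensus"))
  st <- res$node_status
  expect_true(st$fusion[st$node_id == "B"])
  expect_false(st$fusion[st$node_id == "C"])   # no annotated neighbor
  expect_true(st$consensus[st$node_id == "C"]) # but B carries candidates
})

test_that("chained mode lets consensus read fusion-re-ranked neighbors", {
  p <- chain_problem()
  res <- propagate(p$net, p$candidates, p$matches,
                   scoring_params(mode = "fusion_then_consensus",
                                  n_first = 1))
  s <- res$scores
  # B's fusion puts the family structure first despite its low base score
  b <- s[s$node_id == "B", ]
  fam_keys <- parse_structure(p$family$smiles)$identity_key
  expect_equal(b$identity_key[which.max(b$score_fusion)], fam_keys[2])
  # with n_first = 1, C's consensus sees only that re-ranked top candidate,
  # so C's family candidate wins; under plain consensus (base ranks) it
  # would compare against B's base rank-1, a decoy
  c_tab <- s[s$node_id == "C", ]
  expect_equal(c_tab$identity_key[which.max(c_tab$score_consensus)],
               fam_keys[3])
  res_plain <- propagate(p$net, p$candidates, p$matches,
                         scoring_params(mode = "consensus", n_first = 1))
  c_plain <- res_plain$scores[res_plain$scores$node_id == "C", ]
  expect_false(
    c_plain$identity_key[which.max(c_plain$score_consensus)] == fam_keys[3]
  )
})

test_that("singleton nodes pass through with base ordering", {
  pool <- pool_table()
  net <- nap_network(data.frame(node_id = "solo"))
  cand <- load_candidates(
    data.frame(node_id = "solo", structure = pool$smiles[1:4],
               fc = c(0.9, 0.7, 0.5, 0.3))
  )
  res <- propagate(net, cand, NULL, scoring_params())
  expect_true(all(is.na(res$scores$score_fusion)))
  expect_true(all(is.na(res$scores$score_consensus)))
  expect_equal(res$scores$score_final, res$scores$fc)
  expect_false(res$node_status$fusion)
  expect_false(res$node_status$consensus)
})

test_that("scores are bounded and invariant to neighbor/input permutations", {
  fx <- generate_fixture(fixture_spec(n_families = 2, seed = 77))
  res <- propagate(fx$network, fx$candidates, fx$library_matches,
                   scoring_params())
  s <- res$scores
  for (col in c("score_fusion", "score_consensus", "score_final")) {
    v <- s[[col]][!is.na(s[[col]])]
    expect_true(all(v >= 0 & v <= 1))
  }
  # permute candidate rows and edge rows: identical scores and order
  withr::with_seed(5, {
    cand_perm <- fx$candidates[sample(nrow(fx$candidates)), ]
    edge_perm <- fx$network$edges[sample(nrow(fx$network$edges)), ]
  })
  net_perm <- nap_network(fx$network$nodes, edge_perm)
  res_perm <- propagate(net_perm, napr:::order_candidates(cand_perm),
                        fx$library_matches, scoring_params())
  expect_equal(res_perm$scores, res$scores)
})

test_that("raising a neighbor similarity never lowers a candidate score", {
  # direct check on the scoring core: increase one t_cj, others fixed
  params <- scoring_params()
  withr::with_seed(3, {
    for (i in 1:20) {
      fc <- runif(1)
      cosines <- runif(3, 0.5, 1)
      t1 <- runif(3)
      j <- sample(3, 1)
      t2 <- t1
      t2[j] <- min(1, t1[j] + runif(1, 0.01, 0.3))
      s1 <- napr:::score_candidates(fc, matrix(t1, 1), cosines, params)
      s2 <- napr:::score_candidates(fc, matrix(t2, 1), cosines, params)
      expect_gte(s2, s1)
    }
  })
})
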