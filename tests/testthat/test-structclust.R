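# Dissimilarity, MDS embedding, dynamic branch cut, concordance.

test_that("dissimilarity matrix is 1 - Tanimoto, symmetric, zero-diagonal", {
  pool <- pool_table()
  sm <- c(a = "CCO", b = "OCC", c = pool$smiles[1], d = pool$smiles[100])
  d <- dissimilarity_matrix(sm)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_equal(d["a", "b"], 0)  # duplicate structures
  fps <- fingerprint_structures(sm[c("c", "d")])
  expect_equal(d["c", "d"], 1 - tanimoto(fps[1, ], fps[2, ]))
  expect_true(all(d >= 0 & d <= 1))
  expect_error(dissimilarity_matrix("CCO"), "at least 2")
})

test_that("classical MDS embedding is deterministic with bounded dimension", {
  # 3 points: at most 2 dimensions
  d3 <- matrix(1, 3, 3); diag(d3) <- 0
  rownames(d3) <- colnames(d3) <- paste0("p", 1:3)
  co <- mds_embed(d3)
  expect_lte(ncol(co), 2)
  # equilateral triangle: embedded distances all equal
  dd <- as.numeric(stats::dist(co))
  expect_equal(max(dd) - min(dd), 0, tolerance = 1e-9)

  # duplicated point embeds at the same coordinates
  d4 <- as.matrix(stats::dist(rbind(c(0, 0), c(0, 0), c(3, 4), c(6, 0))))
  co4 <- mds_embed(d4)
  expect_equal(unname(co4[1, ]), unname(co4[2, ]), tolerance = 1e-9)

  # deterministic, including the sign convention
  expect_identical(mds_embed(d4), mds_embed(d4))
  expect_error(mds_embed(matrix(c(0, 1, 2, 0), 2)), "symmetric")

  # dimension cap
  withr::with_seed(9, x <- matrix(rnorm(30 * 4), 30))
  dbig <- as.matrix(stats::dist(x))
  expect_lte(ncol(mds_embed(dbig, max_dims = 10)), 10)
})

test_that("dynamic cut finds two well-separated groups with no singletons", {
  withr::with_seed(1, {
    x <- rbind(matrix(rnorm(8, 0, 0.1), 4), matrix(rnorm(8, 10, 0.1), 4))
  })
  rownames(x) <- paste0("p", 1:8)
  cl <- cluster_candidates(x)
  expect_equal(as.integer(sort(table(cl$labels[cl$labels > 0]))), c(4L, 4L))
  expect_equal(length(unique(cl$labels[cl$labels > 0])), 2)
  # repeated runs identical
  expect_identical(cl$labels, cluster_candidates(x)$labels)
})

test_that("degenerate and minimum-size behavior of the dynamic cut", {
  y <- matrix(1, 5, 2); rownames(y) <- paste0("q", 1:5)
  expect_equal(unname(cluster_candidates(y)$labels), rep(1L, 5))
  # random clouds: labels never form singleton clusters at min size 2
  withr::with_seed(21, {
    for (i in 1:5) {
      z <- matrix(rnorm(20 * 3), 20)
      rownames(z) <- paste0("r", 1:20)
      lab <- cluster_candidates(z)$labels
      sizes <- table(lab[lab > 0])
      expect_true(all(sizes >= 2))
    }
  })
})

test_that("identical structures share a label; labels are permutation-stable", {
  pool <- pool_table()
  co <- pool$smiles[pool$scaffold == "coumarin"][1:4]
  de <- pool$smiles[pool$scaffold == "decalin"][1:4]
  sm <- stats::setNames(c(co, de, co[1]),
                        c(paste0("x", 1:8), "x1dup"))
  d <- dissimilarity_matrix(sm)
  lab <- cluster_candidates(mds_embed(d))$labels
  expect_equal(unname(lab["x1"]), unname(lab["x1dup"]))
  # permuting the input order relabels but preserves the partition
  perm <- c(5, 3, 9, 1, 8, 2, 7, 4, 6)
  d2 <- dissimilarity_matrix(sm[perm])
  lab2 <- cluster_candidates(mds_embed(d2))$labels
  for (i in seq_along(sm)) {
    for (j in seq_along(sm)) {
      same1 <- lab[names(sm)[i]] == lab[names(sm)[j]]
      same2 <- lab2[names(sm)[i]] == lab2[names(sm)[j]]
      expect_equal(unname(same1), unname(same2))
    }
  }
})

test_that("substructure concordance counts flags per node", {
  fx <- generate_fixture(fixture_spec(n_families = 2, family_size = 3,
                                      seed = 123))
  res <- propagate(fx$network, fx$candidates, fx$library_matches,
                   scoring_params())
  cl <- cluster_candidate_pool(fx$candidates, fx$truths)
  conc <- substructure_concordance(res, fx$truths, cl,
                                   score_col = "eff_fusion")
  pn <- conc$per_node
  expect_equal(nrow(pn), 6)
  expect_equal(sum(!is.na(pn$correct_substructure)),
               conc$rates$n_evaluated)
  # flags recompute from the labels
  for (r in seq_len(nrow(pn))) {
    if (is.na(pn$correct_substructure[r])) next
    expect_equal(
      pn$correct_substructure[r],
      pn$cluster_rank1[r] > 0 &&
        identical(pn$cluster_rank1[r], pn$cluster_truth[r])
    )
  }
  expect_equal(
    conc$rates$substructure_rate,
    mean(pn$correct_substructure[!is.na(pn$correct_substructure)])
  )
  # a node whose top candidate equals its truth is always concordant
  # (identical structures share a cluster label by construction)
  s <- method_scores(res)
  for (id in pn$node_id) {
    tab <- s[s$node_id == id, ]
    tab <- tab[order(-tab$eff_fusion, -tab$fc, tab$identity_key), ]
    tkey <- fx$truths$identity_key[fx$truths$node_id == id]
    if (tab$identity_key[1] == tkey &&
        !is.na(pn$correct_substructure[pn$node_id == id])) {
      expect_true(pn$correct_substructure[pn$node_id == id])
    }
  }
})

test_that("class concordance uses supplied labels", {
  fx <- generate_fixture(fixture_spec(n_families = 2, family_size = 3,
                                      seed = 123))
  res <- propagate(fx$network, fx$candidates, fx$library_matches,
                   scoring_params())
  cl <- cluster_candidate_pool(fx$candidates, fx$truths)
  # class labels from the generator's scaffold annotation
  classes <- unique(fx$candidates[, c("identity_key", "class_label")])
  conc <- substructure_concordance(res, fx$truths, cl,
                                   score_col = "eff_base",
                                   class_labels = classes)
  expect_true(any(!is.na(conc$per_node$correct_class)))
  expect_gte(conc$rates$class_rate, 0)
  expect_lte(conc$rates$class_rate, 1)
})
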