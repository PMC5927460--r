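# Network model, I/O dialects, candidate/match/truth loaders, scenarios.

test_that("GraphML round-trip reproduces nodes, edges and cosines", {
  net <- nap_network(
    data.frame(node_id = c("1", "2", "3"),
               precursor_mz = c(100.5, 114.52, 128.53)),
    data.frame(node_a = c("1", "2"), node_b = c("2", "3"),
               cosine = c(0.8123, 0.7456))
  )
  f <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, f)
  back <- load_network(f)
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$edges, net$edges)
})

test_that("edge-list TSV round-trip reproduces the edge set", {
  net <- nap_network(
    data.frame(node_id = c("10", "11", "12")),
    data.frame(node_a = c("10", "11"), node_b = c("11", "12"),
               cosine = c(0.95, 0.6))
  )
  f <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, f)
  back <- load_network(f)
  expect_equal(back$edges, net$edges)
})

test_that("validation rejects out-of-range cosines and orphan endpoints", {
  nodes <- data.frame(node_id = c("a", "b"))
  expect_error(
    nap_network(nodes, data.frame(node_a = "a", node_b = "b", cosine = 1.2)),
    "outside \\[0,1\\].*a.*b"
  )
  expect_error(
    nap_network(nodes, data.frame(node_a = "a", node_b = "c", cosine = 0.5)),
    "not in node set"
  )
  expect_error(
    nap_network(data.frame(node_id = c("a", "a"))),
    "duplicate"
  )
  expect_error(
    nap_network(data.frame(node_id = "a", precursor_mz = -5)),
    "precursor_mz"
  )
})

test_that("multi-edges collapse to the maximum cosine, order-independently", {
  nodes <- data.frame(node_id = c("a", "b", "c"))
  e1 <- data.frame(node_a = c("a", "b", "a"), node_b = c("b", "a", "c"),
                   cosine = c(0.6, 0.8, 0.5))
  net1 <- nap_network(nodes, e1)
  expect_equal(nrow(net1$edges), 2)
  expect_equal(net1$edges$cosine[net1$edges$node_a == "a" &
                                   net1$edges$node_b == "b"], 0.8)
  # permuting input rows gives the identical network
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    net2 <- nap_network(nodes, e1[perm, ])
    expect_equal(net2$edges, net1$edges)
    expect_equal(net2$nodes, net1$nodes)
  }
})

test_that("self-loops are dropped with a warning", {
  expect_warning(
    net <- nap_network(data.frame(node_id = c("a", "b")),
                       data.frame(node_a = c("a", "a"),
                                  node_b = c("a", "b"),
                                  cosine = c(0.9, 0.7))),
    "self-loop"
  )
  expect_equal(nrow(net$edges), 1)
})

test_that("candidate loader counts, dedupes by identity and isolates bad rows", {
  pool <- pool_table()
  tab <- data.frame(
    node_id = "n1",
    structure = pool$smiles[1:5],
    fc = c(0.9, 0.7, 0.5, 0.3, 0.1)
  )
  cand <- load_candidates(tab)
  expect_equal(nrow(cand), 5)
  expect_equal(cand$fc, sort(cand$fc, decreasing = TRUE))

  # two spellings of ethanol collapse to one candidate with the max fc
  dup <- data.frame(node_id = "n1", structure = c("CCO", "OCC"),
                    fc = c(0.4, 0.8))
  cand2 <- load_candidates(dup)
  expect_equal(nrow(cand2), 1)
  expect_equal(cand2$fc, 0.8)

  # a bad row is dropped with a warning; the rest survive
  mixed <- data.frame(node_id = "n1",
                      structure = c(pool$smiles[1], "not_a_smiles",
                                    pool$smiles[2]),
                      fc = c(0.9, 0.8, 0.7))
  expect_warning(cand3 <- load_candidates(mixed), "unparseable")
  expect_equal(nrow(cand3), 2)
})

test_that("fc above 1 triggers per-node min-max rescaling", {
  pool <- pool_table()
  tab <- data.frame(node_id = "n1", structure = pool$smiles[1:3],
                    fc = c(200, 150, 100))
  expect_warning(cand <- load_candidates(tab), "rescaling")
  expect_equal(range(cand$fc), c(0, 1))
  expect_equal(order(-cand$fc), 1:3)
})

test_that("components are labeled by library-match coverage", {
  # three families: 4/4 matched, 1/10 matched, 0/3 matched
  ids <- c(paste0("m", 1:4), paste0("s", 1:10), paste0("z", 1:3))
  chain <- function(x) data.frame(node_a = x[-length(x)], node_b = x[-1],
                                  cosine = 0.7)
  net <- nap_network(
    data.frame(node_id = ids),
    rbind(chain(paste0("m", 1:4)), chain(paste0("s", 1:10)),
          chain(paste0("z", 1:3)))
  )
  lib <- load_library_matches(
    data.frame(node_id = c(paste0("m", 1:4), "s1"),
               structure = "CCO", match_cosine = 0.9)
  )
  cc <- classify_components(net, lib)
  expect_setequal(cc$node_id, ids)
  expect_equal(anyDuplicated(cc$node_id), 0)
  expect_true(all(cc$scenario[grepl("^m", cc$node_id)] == "many_matches"))
  expect_true(all(cc$scenario[grepl("^s", cc$node_id)] == "sparse_matches"))
  expect_true(all(cc$scenario[grepl("^z", cc$node_id)] == "no_matches"))
  # without matches everything is no_matches
  cc0 <- classify_components(net, NULL)
  expect_true(all(cc0$scenario == "no_matches"))
})

test_that("library-match and truth loaders normalize structures", {
  lib <- load_library_matches(
    data.frame(node_id = c("a", "a", "b"),
               structure = c("CCO", "OCC", "c1ccccc1"),
               match_cosine = c(0.8, 0.9, NA))
  )
  expect_equal(nrow(lib), 2)          # one match per node, best cosine kept
  expect_equal(lib$match_cosine[lib$node_id == "a"], 0.9)
  expect_equal(nchar(lib$identity_key), c(14, 14))
  tru <- load_truths(data.frame(node_id = "a", structure = "OCC"))
  expect_equal(tru$identity_key, "LFQSCWFLJHTTHZ")
  expect_error(
    load_library_matches(data.frame(node_id = "a", structure = "CCO",
                                    match_cosine = 1.5)),
    "match_cosine"
  )
})
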