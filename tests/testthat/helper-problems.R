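# Shared builders for small test problems. All structures come from the
# packaged scaffold pool so fingerprints are cached across tests.

pool_table <- function() napr:::scaffold_pool_table()

# A random tiny propagation problem: <= 5 nodes in a random tree, <= 5
# candidates per node, a random subset of nodes carrying library matches.
tiny_problem <- function(seed) {
  pool <- pool_table()
  withr::with_seed(seed, {
    n_nodes <- sample(2:5, 1)
    ids <- paste0("N", seq_len(n_nodes))
    parents <- vapply(seq_len(n_nodes - 1), function(i) sample(i, 1),
                      integer(1))
    edges <- data.frame(
      node_a = ids[parents], node_b = ids[2:n_nodes],
      cosine = round(stats::runif(n_nodes - 1, 0.5, 1), 4),
      stringsAsFactors = FALSE
    )
    cand <- do.call(rbind, lapply(ids, function(id) {
      L <- sample(2:5, 1)
      rows <- sample(nrow(pool), L)
      data.frame(node_id = id, structure = pool$smiles[rows],
                 fc = round(stats::runif(L), 6), stringsAsFactors = FALSE)
    }))
    n_lib <- sample(0:n_nodes, 1)
    lib <- if (n_lib > 0) {
      data.frame(node_id = sample(ids, n_lib),
                 structure = pool$smiles[sample(nrow(pool), n_lib)],
                 match_cosine = round(stats::runif(n_lib, 0.6, 1), 4),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(node_id = character(0), structure = character(0),
                 match_cosine = numeric(0), stringsAsFactors = FALSE)
    }
    list(
      net = nap_network(data.frame(node_id = ids, stringsAsFactors = FALSE),
                        edges),
      candidates = load_candidates(cand),
      matches = load_library_matches(lib)
    )
  })
}

# A three-node chain A(library match) -- B -- C built from one scaffold
# family: the canonical chained-propagation scenario.
chain_problem <- function() {
  pool <- pool_table()
  fam <- pool[pool$scaffold == "coumarin", ][1:6, ]
  other <- pool[pool$scaffold == "decalin", ][1:6, ]
  ids <- c("A", "B", "C")
  net <- nap_network(
    data.frame(node_id = ids, stringsAsFactors = FALSE),
    data.frame(node_a = c("A", "B"), node_b = c("B", "C"),
               cosine = c(0.9, 0.8), stringsAsFactors = FALSE)
  )
  cand <- rbind(
    data.frame(node_id = "B",
               structure = c(fam$smiles[2], other$smiles[1:2]),
               fc = c(0.5, 0.9, 0.7), stringsAsFactors = FALSE),
    data.frame(node_id = "C",
               structure = c(fam$smiles[3], other$smiles[3:4]),
               fc = c(0.4, 0.8, 0.6), stringsAsFactors = FALSE)
  )
  lib <- data.frame(node_id = "A", structure = fam$smiles[1],
                    match_cosine = 0.95, stringsAsFactors = FALSE)
  list(net = net, candidates = load_candidates(cand),
       matches = load_library_matches(lib), family = fam, other = other)
}

# Independent brute-force reimplementation of the propagation scores:
# explicit loops, inline sigmoid and inline Tanimoto from raw bit vectors.
# Shares only the fingerprints (input data) with the package path.
brute_force_scores <- function(net, candidates, matches, params) {
  sig <- function(x) 1 / (1 + exp(params$beta * (x - params$gamma)))
  tani <- function(s1, s2) {
    f <- fingerprint_structures(c(s1, s2))
    a <- f[1, ] > 0
    b <- f[2, ] > 0
    u <- sum(a | b)
    if (u == 0) 1 else sum(a & b) / u
  }
  neighbors_of <- function(id) {
    e <- net$edges
    rbind(
      data.frame(nb = e$node_b[e$node_a == id],
                 cos = e$cosine[e$node_a == id]),
      data.frame(nb = e$node_a[e$node_b == id],
                 cos = e$cosine[e$node_b == id])
    )
  }
  out <- candidates
  out$bf_fusion <- NA_real_
  out$bf_consensus <- NA_real_

  do_fusion <- params$mode %in% c("fusion", "fusion_then_consensus")
  do_consensus <- params$mode %in% c("consensus", "fusion_then_consensus")

  if (do_fusion) {
    for (id in unique(candidates$node_id)) {
      nb <- neighbors_of(id)
      nb <- nb[nb$nb %in% matches$node_id, , drop = FALSE]
      if (nrow(nb) == 0) next
      rows <- which(out$node_id == id)
      for (r in rows) {
        terms <- numeric(0)
        for (j in seq_len(nrow(nb))) {
          lib_s <- matches$canonical_smiles[matches$node_id == nb$nb[j]]
          m_j <- if (params$use_match_cosine) {
            mc <- matches$match_cosine[matches$node_id == nb$nb[j]]
            if (is.na(mc)) nb$cos[j] else mc
          } else nb$cos[j]
          terms <- c(terms, sig(m_j * tani(out$canonical_smiles[r], lib_s)))
        }
        out$bf_fusion[r] <- params$alpha * out$fc[r] +
          (1 - params$alpha) * mean(terms)
      }
    }
  }
  if (do_consensus) {
    consensus <- rep(NA_real_, nrow(out))
    for (id in unique(candidates$node_id)) {
      nb <- neighbors_of(id)
      nb <- nb[nb$nb %in% out$node_id, , drop = FALSE]
      if (nrow(nb) == 0) next
      rows <- which(out$node_id == id)
      for (r in rows) {
        terms <- numeric(0)
        for (j in seq_len(nrow(nb))) {
          ncand <- out[out$node_id == nb$nb[j], , drop = FALSE]
          key <- if (params$mode == "fusion_then_consensus") {
            ifelse(is.na(ncand$bf_fusion), ncand$fc, ncand$bf_fusion)
          } else {
            ncand$fc
          }
          ncand <- ncand[order(-key, -ncand$fc, ncand$identity_key), ,
                         drop = FALSE]
          top <- utils::head(ncand, params$n_first)
          t_best <- max(vapply(top$canonical_smiles, function(s) {
            tani(out$canonical_smiles[r], s)
          }, numeric(1)))
          terms <- c(terms, sig(nb$cos[j] * t_best))
        }
        consensus[r] <- params$alpha * out$fc[r] +
          (1 - params$alpha) * mean(terms)
      }
    }
    out$bf_consensus <- consensus
  }
  out
}
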