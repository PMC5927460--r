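# Ranking evaluation: dense ranks with tie sharing, rank-of-true extraction,
# uniform random baseline, and the cross-method summary statistics.

#' Dense ranks of a score vector
#'
#' Ranks scores from best (highest) to worst with tied scores sharing a
#' position and the next distinct score taking the next consecutive integer:
#' scores `c(5, 4, 4, 4, 3)` rank `1, 2, 2, 2, 3` (not `1, 2, 2, 2, 5`).
#'
#' @param scores numeric vector (any order; higher is better).
#' @return integer vector of dense ranks, same length as `scores`.
#' @export
dense_rank <- function(scores) {
  stopifnot(is.numeric(scores), length(scores) >= 1)
  match(scores, sort(unique(scores), decreasing = TRUE))
}

#' Dense rank of the true structure in a scored candidate list
#'
#' @param scored data.frame for one node with columns `identity_key` and the
#'   score column named by `score_col`.
#' @param truth_key the truth's 14-character identity key.
#' @param score_col which score column to rank by.
#' @return the truth's dense rank, or `NA_integer_` when no candidate matches
#'   (the node counts as "not annotated").
#' @export
rank_of_true <- function(scored, truth_key, score_col = "fc") {
  stopifnot(is.data.frame(scored), score_col %in% names(scored))
  hit <- which(scored$identity_key == truth_key)
  if (length(hit) == 0) return(NA_integer_)
  dense_rank(scored[[score_col]])[hit[1]]
}

#' Per-node, per-method ranks of the true structures
#'
#' @param result a `nap_result` from [propagate()].
#' @param truths data.frame from [load_truths()].
#' @return data.frame with one row per node that has a truth: `node_id`,
#'   `rank_base`, `rank_fusion`, `rank_consensus` (`NA` = truth absent from
#'   the candidate list).
#' @export
truth_ranks <- function(result, truths) {
  s <- method_scores(result)
  nodes <- intersect(unique(s$node_id), truths$node_id)
  rows <- lapply(nodes, function(id) {
    tab <- s[s$node_id == id, , drop = FALSE]
    key <- truths$identity_key[match(id, truths$node_id)]
    data.frame(
      node_id = id,
      rank_base = rank_of_true(tab, key, "eff_base"),
      rank_fusion = rank_of_true(tab, key, "eff_fusion"),
      rank_consensus = rank_of_true(tab, key, "eff_consensus"),
      n_candidates = nrow(tab),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Uniform random ranking baseline
#'
#' For each node whose truth appears in its candidate list, draws the truth's
#' rank under a uniform random permutation of the candidates, `n_draws`
#' times, and summarizes. Reproducible for a fixed seed.
#'
#' @param candidates candidate table from [load_candidates()].
#' @param truths data.frame from [load_truths()].
#' @param n_draws Monte-Carlo draws per node (default 10000).
#' @param seed RNG seed (required).
#' @return list with `per_node` (node_id, n_candidates, mean_rank),
#'   `mean_rank` and `median_rank` pooled over all nodes and draws.
#' @export
random_baseline <- function(candidates, truths, n_draws = 10000, seed) {
  stopifnot(n_draws >= 1, !missing(seed))
  sizes <- table(candidates$node_id)
  nodes <- truths$node_id[truths$node_id %in% names(sizes)]
  # keep only nodes whose truth is actually in the list
  present <- vapply(nodes, function(id) {
    key <- truths$identity_key[match(id, truths$node_id)]
    key %in% candidates$identity_key[candidates$node_id == id]
  }, logical(1))
  nodes <- nodes[present]
  if (length(nodes) == 0) {
    return(list(per_node = data.frame(), mean_rank = NA_real_,
                median_rank = NA_real_))
  }
  withr::with_seed(seed, {
    draws <- lapply(nodes, function(id) {
      L <- as.integer(sizes[[id]])
      if (L == 1) rep(1L, n_draws) else sample.int(L, n_draws, replace = TRUE)
    })
  })
  per_node <- data.frame(
    node_id = nodes,
    n_candidates = as.integer(sizes[nodes]),
    mean_rank = vapply(draws, mean, numeric(1)),
    stringsAsFactors = FALSE
  )
  pooled <- unlist(draws)
  list(per_node = per_node, mean_rank = mean(pooled),
       median_rank = stats::median(pooled))
}

#' Summary statistics across methods
#'
#' Per method: mean and median rank of the truth, percentage of nodes with
#' the truth at rank 1 and within `top` positions, counts of nodes improved
#' or worsened versus the base ranking, and the unique-best count (nodes
#' where the method strictly outranks every other method; ties across
#' methods count as overlap, not as unique). Nodes whose truth is absent
#' from the candidate list are excluded from the statistics and reported in
#' `not_annotated`.
#'
#' @param ranks data.frame from [truth_ranks()] (columns `rank_base`,
#'   `rank_fusion`, `rank_consensus`; extra `rank_*` columns are included
#'   automatically).
#' @param top rank cutoff for the top-`top` percentage (default 20).
#' @return list with `methods` (one row per method) and counts
#'   `n_evaluated`, `not_annotated`.
#' @export
summarize_rankings <- function(ranks, top = 20) {
  stopifnot(is.data.frame(ranks), "rank_base" %in% names(ranks))
  rank_cols <- grep("^rank_", names(ranks), value = TRUE)
  evaluated <- stats::complete.cases(ranks[, rank_cols, drop = FALSE])
  tab <- ranks[evaluated, , drop = FALSE]
  methods <- sub("^rank_", "", rank_cols)
  rows <- lapply(seq_along(rank_cols), function(i) {
    r <- tab[[rank_cols[i]]]
    others <- tab[, setdiff(rank_cols, rank_cols[i]), drop = FALSE]
    unique_best <- if (ncol(others) == 0) 0L else {
      sum(r < apply(others, 1, min))
    }
    data.frame(
      method = methods[i],
      n = nrow(tab),
      mean_rank = mean(r),
      median_rank = stats::median(r),
      pct_rank1 = 100 * mean(r == 1),
      pct_top = 100 * mean(r <= top),
      improved_vs_base = sum(r < tab$rank_base),
      worsened_vs_base = sum(r > tab$rank_base),
      unique_best = unique_best,
      stringsAsFactors = FALSE
    )
  })
  list(methods = do.call(rbind, rows),
       n_evaluated = nrow(tab),
       not_annotated = sum(!evaluated),
       top = top)
}

#' Tabulate truth ranks per position
#'
#' Counts, per method, how many nodes place the truth at each rank up to a
#' cutoff — the per-position bars behind rank-distribution figures.
#'
#' @inheritParams summarize_rankings
#' @param cutoff highest rank tabulated (default 20).
#' @return data.frame with `rank` and one count column per method.
#' @export
rank_position_table <- function(ranks, cutoff = 20) {
  rank_cols <- grep("^rank_", names(ranks), value = TRUE)
  out <- data.frame(rank = seq_len(cutoff))
  for (col in rank_cols) {
    r <- ranks[[col]]
    out[[sub("^rank_", "", col)]] <-
      vapply(seq_len(cutoff), function(k) sum(r == k, na.rm = TRUE),
             integer(1))
  }
  out
}
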