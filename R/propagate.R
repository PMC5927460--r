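# Network Fusion and Consensus scoring.
#
# Both methods re-score each candidate c of a node as
#
#   Sc = alpha * fc + (1 - alpha) * (1/M) * sum_j sig(m_j * t_cj)
#
# where fc is the base in silico score, m_j the cosine of the edge to
# neighbor j, and t_cj the Tanimoto similarity between candidate c and the
# structural information carried by neighbor j: its spectral-library
# structure (Fusion) or the best of its top n-first candidates (Consensus).
# sig is the sigmoid 1 / (1 + exp(beta * (x - gamma))); with the default
# beta = -9 it is strictly increasing, so higher structural similarity can
# only raise the score. The neighbor sum is averaged over the M neighbors so
# that Sc stays in [0, 1] regardless of node degree; within a node this is a
# positive monotone transform and cannot change the ranking.

#' Scoring parameters
#'
#' Defaults are the MetFusion-optimized values adopted for network
#' propagation: `alpha = 0.3` (weight of the base score), sigmoid slope
#' `beta = -9` and midpoint `gamma = 0.6`, and `n_first = 10` top-ranked
#' neighbor candidates for Consensus scoring.
#'
#' @param alpha weight of the base score, in `[0, 1]`.
#' @param beta sigmoid slope (negative values give an increasing sigmoid).
#' @param gamma sigmoid midpoint, on the `m * t` product scale.
#' @param n_first number of top-ranked neighbor candidates considered in
#'   Consensus scoring (`>= 1`).
#' @param mode propagation mode: `"fusion"`, `"consensus"` or
#'   `"fusion_then_consensus"`.
#' @param use_match_cosine use the neighbor's own library-match cosine as
#'   `m_j` in Fusion scoring instead of the connecting edge cosine (falls
#'   back to the edge cosine when the match cosine is missing). Default off:
#'   `m_j` is the edge cosine.
#' @return list of class `nap_params`.
#' @export
scoring_params <- function(alpha = 0.3, beta = -9, gamma = 0.6,
                           n_first = 10,
                           mode = c("fusion_then_consensus", "fusion",
                                    "consensus"),
                           use_match_cosine = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha >= 0, alpha <= 1,
            is.numeric(beta), length(beta) == 1,
            is.numeric(gamma), length(gamma) == 1,
            is.numeric(n_first), length(n_first) == 1, n_first >= 1)
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 n_first = as.integer(n_first), mode = mode,
                 use_match_cosine = isTRUE(use_match_cosine)),
            class = "nap_params")
}

#' Sigmoid transfer function
#'
#' `1 / (1 + exp(beta * (x - gamma)))`. At `x = gamma` the value is 0.5; with
#' `beta < 0` the function increases in `x`.
#'
#' @param x numeric input (here, the product of edge cosine and Tanimoto).
#' @param beta slope; default -9.
#' @param gamma midpoint; default 0.6.
#' @return values in `(0, 1)`.
#' @export
sigmoid <- function(x, beta = -9, gamma = 0.6) {
  1 / (1 + exp(beta * (x - gamma)))
}

# Condition constructors so callers can fall back deliberately
no_annotated_neighbor <- function(node_id) {
  structure(
    class = c("nap_no_annotated_neighbor", "error", "condition"),
    list(message = paste0("node ", node_id,
                          " has no library-annotated direct neighbor"),
         call = NULL)
  )
}

no_neighbor_candidates <- function(node_id) {
  structure(
    class = c("nap_no_neighbor_candidates", "error", "condition"),
    list(message = paste0("node ", node_id,
                          " has no neighbor with candidates"),
         call = NULL)
  )
}

# Shared scoring core: given the node's candidate table (fc + fingerprints)
# and per-neighbor (cosine, fingerprint set), compute Sc per candidate.
# t_per_neighbor is a function(neighbor_index) -> numeric vector of t_cj per
# candidate.
score_candidates <- function(fc, t_matrix, cosines, params) {
  m <- length(cosines)
  stopifnot(ncol(t_matrix) == m)
  sig <- sigmoid(sweep(t_matrix, 2, cosines, `*`),
                 beta = params$beta, gamma = params$gamma)
  neighbor_term <- rowMeans(sig)
  params$alpha * fc + (1 - params$alpha) * neighbor_term
}

# Re-order a scored candidate table: score desc, then fc desc, then
# identity_key asc
order_scored <- function(tab, score_col) {
  tab[order(-tab[[score_col]], -tab$fc, tab$identity_key), , drop = FALSE]
}

#' Network Fusion scoring of one node
#'
#' Re-scores the candidates of `node_id` against the spectral-library
#' structures of its direct neighbors. Requires at least one direct neighbor
#' carrying a library match with a parseable structure; otherwise signals a
#' `nap_no_annotated_neighbor` condition (callers fall back to Consensus or
#' base scores). Neighbors whose library structure cannot be parsed are
#' skipped and do not count towards the neighbor average.
#'
#' @param node_id node to re-score.
#' @param net a [nap_network()].
#' @param candidates candidate table from [load_candidates()].
#' @param library_matches table from [load_library_matches()].
#' @param params a [scoring_params()].
#' @return the node's candidate table with a `score_fusion` column, ordered
#'   by it (ties: higher `fc`, then `identity_key`).
#' @export
fusion_score <- function(node_id, net, candidates, library_matches,
                         params = scoring_params()) {
  cand <- candidates[candidates$node_id == node_id, , drop = FALSE]
  if (nrow(cand) == 0) stop(no_annotated_neighbor(node_id))
  nb <- node_neighbors(net, node_id)
  ann <- merge(nb, library_matches, by.x = "neighbor", by.y = "node_id")
  ann <- ann[!is.na(ann$canonical_smiles), , drop = FALSE]
  if (nrow(ann) == 0) stop(no_annotated_neighbor(node_id))
  m_j <- if (params$use_match_cosine) {
    ifelse(is.na(ann$match_cosine), ann$cosine, ann$match_cosine)
  } else {
    ann$cosine
  }
  fp_c <- fingerprint_structures(cand$canonical_smiles)
  fp_n <- fingerprint_structures(ann$canonical_smiles)
  t_matrix <- tanimoto_matrix(fp_c, fp_n)
  cand$score_fusion <- score_candidates(cand$fc, t_matrix, m_j, params)
  out <- order_scored(cand, "score_fusion")
  rownames(out) <- NULL
  out
}

#' Network Consensus scoring of one node
#'
#' Re-scores the candidates of `node_id` against the candidate lists of its
#' direct neighbors: for each neighbor j, `t_cj` is the maximum Tanimoto
#' between candidate c and the top `n_first` candidates of j, ranked by
#' `neighbor_scores` (the base `fc`, or a previously computed Fusion score).
#' Signals `nap_no_neighbor_candidates` when no direct neighbor has
#' candidates.
#'
#' @inheritParams fusion_score
#' @param neighbor_scores name of the column of `candidates` used to rank
#'   each neighbor's list before taking its top `n_first` (default `"fc"`).
#' @return the node's candidate table with a `score_consensus` column,
#'   ordered by it.
#' @export
consensus_score <- function(node_id, net, candidates,
                            params = scoring_params(),
                            neighbor_scores = "fc") {
  cand <- candidates[candidates$node_id == node_id, , drop = FALSE]
  if (nrow(cand) == 0) stop(no_neighbor_candidates(node_id))
  nb <- node_neighbors(net, node_id)
  nb <- nb[nb$neighbor %in% candidates$node_id, , drop = FALSE]
  if (nrow(nb) == 0) stop(no_neighbor_candidates(node_id))
  fp_c <- fingerprint_structures(cand$canonical_smiles)
  t_matrix <- matrix(NA_real_, nrow(cand), nrow(nb))
  for (j in seq_len(nrow(nb))) {
    ncand <- candidates[candidates$node_id == nb$neighbor[j], , drop = FALSE]
    sc <- ncand[[neighbor_scores]]
    if (is.null(sc)) sc <- ncand$fc
    sc[is.na(sc)] <- ncand$fc[is.na(sc)]
    ncand <- ncand[order(-sc, -ncand$fc, ncand$identity_key), , drop = FALSE]
    top <- utils::head(ncand, params$n_first)
    fp_n <- fingerprint_structures(top$canonical_smiles)
    t_matrix[, j] <- apply(tanimoto_matrix(fp_c, fp_n), 1, max)
  }
  cand$score_consensus <- score_candidates(cand$fc, t_matrix, nb$cosine,
                                           params)
  out <- order_scored(cand, "score_consensus")
  rownames(out) <- NULL
  out
}

#' Propagate annotations over a molecular network
#'
#' Runs one propagation sweep over all nodes in the requested mode:
#' \describe{
#'   \item{fusion}{[fusion_score()] where a library-annotated direct neighbor
#'     exists; base scores elsewhere.}
#'   \item{consensus}{[consensus_score()] (neighbors ranked by base `fc`)
#'     where a candidate-bearing neighbor exists; base scores elsewhere.}
#'   \item{fusion_then_consensus}{pass 1 applies Fusion to every eligible
#'     node; pass 2 applies Consensus to every node with candidate-bearing
#'     neighbors, ranking each neighbor's list by its Fusion score when one
#'     was computed and by base `fc` otherwise. This chains the two stages so
#'     library information reaches nodes two hops from a match.}
#' }
#' There is no iteration to a fixed point: each stage runs exactly once.
#'
#' @inheritParams fusion_score
#' @return object of class `nap_result`: list with `scores` (candidate table
#'   with `score_fusion`, `score_consensus` columns, `NA` where the method
#'   did not apply), `node_status` (per node: whether fusion/consensus
#'   applied, neighbor counts) and `params`.
#' @export
propagate <- function(net, candidates, library_matches = NULL,
                      params = scoring_params()) {
  stopifnot(inherits(net, "nap_network"), inherits(params, "nap_params"))
  if (is.null(library_matches)) {
    library_matches <- load_library_matches(
      data.frame(node_id = character(0), structure = character(0))
    )
  }
  node_ids <- sort(unique(candidates$node_id))
  cand <- candidates
  cand$score_fusion <- NA_real_
  cand$score_consensus <- NA_real_
  status <- data.frame(node_id = node_ids, fusion = FALSE, consensus = FALSE,
                       n_neighbors = NA_integer_, stringsAsFactors = FALSE)

  do_fusion <- params$mode %in% c("fusion", "fusion_then_consensus")
  do_consensus <- params$mode %in% c("consensus", "fusion_then_consensus")

  if (do_fusion) {
    for (id in node_ids) {
      if (!id %in% net$nodes$node_id) next
      res <- tryCatch(
        fusion_score(id, net, candidates, library_matches, params),
        nap_no_annotated_neighbor = function(e) NULL
      )
      if (!is.null(res)) {
        idx <- match(res$identity_key,
                     cand$identity_key[cand$node_id == id])
        rows <- which(cand$node_id == id)
        cand$score_fusion[rows[idx]] <- res$score_fusion
        status$fusion[status$node_id == id] <- TRUE
      }
    }
  }
  if (do_consensus) {
    neighbor_col <- if (params$mode == "fusion_then_consensus") {
      "score_fusion"  # read each neighbor's fusion score when present
    } else {
      "fc"
    }
    consensus <- rep(NA_real_, nrow(cand))
    for (id in node_ids) {
      if (!id %in% net$nodes$node_id) next
      res <- tryCatch(
        consensus_score(id, net, cand, params,
                        neighbor_scores = neighbor_col),
        nap_no_neighbor_candidates = function(e) NULL
      )
      if (!is.null(res)) {
        rows <- which(cand$node_id == id)
        idx <- match(res$identity_key, cand$identity_key[rows])
        consensus[rows[idx]] <- res$score_consensus
        status$consensus[status$node_id == id] <- TRUE
      }
    }
    cand$score_consensus <- consensus
  }
  for (id in node_ids) {
    status$n_neighbors[status$node_id == id] <-
      if (id %in% net$nodes$node_id) nrow(node_neighbors(net, id))
      else 0L
  }
  cand <- order_scored_result(cand, params$mode)
  structure(list(scores = cand, node_status = status, params = params),
            class = "nap_result")
}

# Final per-node ordering for a propagation result: use the mode's headline
# score with fallback to base fc where the method did not apply.
order_scored_result <- function(cand, mode) {
  headline <- switch(mode,
    fusion = ifelse(is.na(cand$score_fusion), cand$fc, cand$score_fusion),
    consensus = ifelse(is.na(cand$score_consensus), cand$fc,
                       cand$score_consensus),
    fusion_then_consensus = ifelse(
      !is.na(cand$score_consensus), cand$score_consensus,
      ifelse(!is.na(cand$score_fusion), cand$score_fusion, cand$fc))
  )
  cand$score_final <- headline
  out <- cand[order(cand$node_id, -cand$score_final, -cand$fc,
                    cand$identity_key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.nap_result <- function(x, ...) {
  cat("Propagation result (", x$params$mode, "): ",
      length(unique(x$scores$node_id)), " nodes, ",
      nrow(x$scores), " candidates; fusion applied to ",
      sum(x$node_status$fusion), ", consensus to ",
      sum(x$node_status$consensus), " node(s)\n", sep = "")
  invisible(x)
}

#' Per-method effective scores of a propagation result
#'
#' For evaluation, each method's effective score falls back to the base
#' score on nodes where the method did not apply (matching how a complete
#' candidate table is reported per method).
#'
#' @param result a `nap_result`.
#' @return the `scores` table with added `eff_base`, `eff_fusion`,
#'   `eff_consensus` columns.
#' @export
method_scores <- function(result) {
  s <- result$scores
  s$eff_base <- s$fc
  s$eff_fusion <- ifelse(is.na(s$score_fusion), s$fc, s$score_fusion)
  s$eff_consensus <- ifelse(is.na(s$score_consensus), s$fc,
                            s$score_consensus)
  s
}
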