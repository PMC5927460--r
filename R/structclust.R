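# Unsupervised clustering of candidate structures and substructure-level
# concordance.
#
# Pipeline: 1 - Tanimoto dissimilarity -> classical MDS (up to 10
# dimensions) -> Ward hierarchical clustering on Euclidean distances ->
# adaptive dynamic branch cut (minimum cluster size 2, hybrid-style split
# sensitivity). The top-ranked candidate of a node is "correct at
# substructure level" when it lands in the same structural cluster as the
# known true structure.

#' Tanimoto dissimilarity matrix of candidate structures
#'
#' @param smiles character vector (length >= 2) of SMILES; names (or the
#'   SMILES themselves) label the rows.
#' @return symmetric matrix of `1 - Tanimoto` with zero diagonal.
#' @export
dissimilarity_matrix <- function(smiles) {
  if (length(smiles) < 2) {
    stop("need at least 2 structures to build a dissimilarity matrix",
         call. = FALSE)
  }
  fps <- fingerprint_structures(smiles)
  d <- 1 - tanimoto_matrix(fps, fps)
  diag(d) <- 0
  lab <- if (!is.null(names(smiles))) names(smiles) else smiles
  dimnames(d) <- list(lab, lab)
  d
}

#' Classical multidimensional scaling of a dissimilarity matrix
#'
#' Metric (eigendecomposition) MDS into at most `max_dims` dimensions,
#' capped at `n - 1`. Deterministic: no random initialization, and each
#' axis's sign is fixed by making its largest-magnitude coordinate positive.
#'
#' @param dissimilarity symmetric matrix with zero diagonal.
#' @param max_dims maximum embedding dimension (default 10).
#' @return numeric coordinate matrix (rows = objects). Axes with
#'   non-positive eigenvalues are dropped, so the column count can be lower
#'   than `max_dims`.
#' @export
mds_embed <- function(dissimilarity, max_dims = 10) {
  stopifnot(is.matrix(dissimilarity))
  if (!isTRUE(all.equal(dissimilarity, t(dissimilarity),
                        tolerance = 1e-8))) {
    stop("dissimilarity matrix must be symmetric", call. = FALSE)
  }
  n <- nrow(dissimilarity)
  k <- min(max_dims, n - 1)
  coords <- suppressWarnings(stats::cmdscale(stats::as.dist(dissimilarity),
                                             k = k))
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 1)
  # drop all-zero axes (rank-deficient configurations)
  keep <- apply(abs(coords), 2, max) > 1e-12
  if (!any(keep)) {
    coords <- coords[, 1, drop = FALSE]  # degenerate: all points coincide
  } else {
    coords <- coords[, keep, drop = FALSE]
  }
  # sign convention per axis
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(dissimilarity)
  coords
}

#' Adaptive dynamic branch cut of a dendrogram
#'
#' Extracts clusters of variable size from a hierarchical-clustering
#' dendrogram without a fixed height threshold, in the spirit of hybrid
#' dynamic tree cutting: starting at the root, a branch is split into its
#' two sub-branches when both stand out as clusters — each of size at least
#' `min_cluster_size`, internally tight (normalized core scatter below a
#' sensitivity-dependent ceiling) and separated from the merge by a
#' normalized gap above a floor. `deep_split` (0-4) controls the
#' sensitivity: higher values split more finely. A sub-branch smaller than
#' `min_cluster_size` that falls away from a qualifying sibling is left
#' unassigned (label 0). Labels are renumbered by decreasing cluster size.
#'
#' @param hc an `hclust` object (typically Ward linkage).
#' @param min_cluster_size smallest cluster size assigned a label (default 2).
#' @param deep_split split sensitivity, integer 0-4 (default 2).
#' @param cut_height reference height for normalization; default 99% of the
#'   dendrogram height.
#' @return integer vector of labels in leaf order (0 = unassigned).
#' @export
dynamic_tree_cut <- function(hc, min_cluster_size = 2, deep_split = 2,
                             cut_height = NULL) {
  stopifnot(inherits(hc, "hclust"), deep_split %in% 0:4,
            min_cluster_size >= 1)
  n <- length(hc$order)
  heights <- hc$height
  if (n < 2 || max(heights) <= .Machine$double.eps) {
    return(rep(1L, n))  # degenerate: everything identical
  }
  if (is.null(cut_height)) cut_height <- 0.99 * max(heights)
  ref_height <- stats::quantile(heights, 0.05, names = FALSE)
  scale <- max(cut_height - ref_height, .Machine$double.eps)
  max_core_scatter <- c(0.64, 0.73, 0.82, 0.91, 0.95)[deep_split + 1]
  min_gap <- (1 - max_core_scatter) * 3 / 4

  merge <- hc$merge
  # per merge: leaf members, size, top height, mean internal height
  members <- vector("list", nrow(merge))
  top_h <- numeric(nrow(merge))
  sum_h <- numeric(nrow(merge))
  n_h <- integer(nrow(merge))
  for (i in seq_len(nrow(merge))) {
    side <- function(x) if (x < 0) -x else members[[x]]
    members[[i]] <- c(side(merge[i, 1]), side(merge[i, 2]))
    child_stats <- function(x) {
      if (x < 0) c(0, 0, 0) else c(top_h[x], sum_h[x], n_h[x])
    }
    s1 <- child_stats(merge[i, 1]); s2 <- child_stats(merge[i, 2])
    top_h[i] <- heights[i]
    sum_h[i] <- s1[2] + s2[2] + heights[i]
    n_h[i] <- s1[3] + s2[3] + 1L
  }

  branch_size <- function(x) if (x < 0) 1L else length(members[[x]])
  branch_top <- function(x) if (x < 0) 0 else top_h[x]
  branch_scatter <- function(x) {
    if (x < 0 || n_h[x] == 0) return(0)
    # mean internal merge height, normalized to the [ref, cut] range
    max((sum_h[x] / n_h[x] - ref_height) / scale, 0)
  }
  qualifies <- function(x, parent_height) {
    branch_size(x) >= min_cluster_size &&
      branch_scatter(x) <= max_core_scatter &&
      (parent_height - branch_top(x)) / scale >= min_gap
  }

  labels <- integer(n)
  next_label <- 0L
  assign_cluster <- function(x) {
    next_label <<- next_label + 1L
    leaves <- if (x < 0) -x else members[[x]]
    labels[leaves] <<- next_label
  }
  recurse <- function(x) {
    if (x < 0) {
      assign_cluster(x)
      return(invisible())
    }
    h <- top_h[x]
    kids <- merge[x, ]
    q <- vapply(kids, qualifies, logical(1), parent_height = h)
    small <- vapply(kids, branch_size, integer(1)) < min_cluster_size
    if (all(q)) {
      recurse(kids[1]); recurse(kids[2])
    } else if (any(q) && small[which(!q)[1]] && sum(q) == 1) {
      # qualifying branch splits off; the small remainder is unassigned
      recurse(kids[which(q)])
      leaves <- if (kids[!q] < 0) -kids[!q] else members[[kids[!q]]]
      labels[leaves] <<- 0L
    } else {
      assign_cluster(x)
    }
  }
  recurse(nrow(merge))

  # renumber by decreasing size; ties by first leaf index
  sizes <- table(labels[labels > 0])
  if (length(sizes) > 0) {
    firsts <- vapply(names(sizes), function(l) {
      min(which(labels == as.integer(l)))
    }, integer(1))
    ord <- order(-as.integer(sizes), firsts)
    remap <- stats::setNames(seq_along(ord), names(sizes)[ord])
    labels[labels > 0] <- remap[as.character(labels[labels > 0])]
  }
  labels
}

#' Cluster candidate structures
#'
#' Full clustering pipeline on embedded coordinates: Euclidean distances,
#' Ward linkage (`ward.D2`), then [dynamic_tree_cut()] with `minClusterSize
#' = 2` and `deepSplit = 2` by default.
#'
#' @param coordinates coordinate matrix from [mds_embed()] (rows labeled by
#'   identity key or structure).
#' @param min_cluster_size,deep_split see [dynamic_tree_cut()].
#' @return object of class `nap_clusters`: list with `labels` (named integer
#'   vector, 0 = unassigned) and `params`.
#' @export
cluster_candidates <- function(coordinates, min_cluster_size = 2,
                               deep_split = 2) {
  stopifnot(is.matrix(coordinates), nrow(coordinates) >= 2)
  d <- stats::dist(coordinates)
  if (max(d) <= .Machine$double.eps) {
    labels <- stats::setNames(rep(1L, nrow(coordinates)),
                              rownames(coordinates))
  } else {
    hc <- stats::hclust(d, method = "ward.D2")
    labels <- stats::setNames(
      dynamic_tree_cut(hc, min_cluster_size, deep_split),
      rownames(coordinates)
    )
  }
  structure(list(labels = labels,
                 params = list(min_cluster_size = min_cluster_size,
                               deep_split = deep_split,
                               dims = ncol(coordinates))),
            class = "nap_clusters")
}

#' @export
print.nap_clusters <- function(x, ...) {
  k <- length(unique(x$labels[x$labels > 0]))
  cat("Structure clusters:", length(x$labels), "objects,", k,
      "cluster(s),", sum(x$labels == 0), "unassigned\n")
  invisible(x)
}

#' Cluster the candidate pool of a molecular family
#'
#' Builds the clustering pool as the union of each node's top-`top_k`
#' candidates (by the given score column) plus the truth structures, keyed
#' by identity key, then runs dissimilarity -> MDS -> Ward -> dynamic cut.
#'
#' @param candidates candidate table (one family or a whole network).
#' @param truths data.frame from [load_truths()] (optional).
#' @param score_col score used to pick each node's top candidates.
#' @param top_k candidates pooled per node (default 10).
#' @param max_dims MDS dimension cap (default 10).
#' @param min_cluster_size,deep_split see [dynamic_tree_cut()].
#' @return a `nap_clusters` whose labels are named by identity key.
#' @export
cluster_candidate_pool <- function(candidates, truths = NULL,
                                   score_col = "fc", top_k = 10,
                                   max_dims = 10, min_cluster_size = 2,
                                   deep_split = 2) {
  pool <- do.call(rbind, lapply(split(candidates, candidates$node_id),
    function(tab) {
      tab <- tab[order(-tab[[score_col]], -tab$fc, tab$identity_key), ,
                 drop = FALSE]
      utils::head(tab[, c("identity_key", "canonical_smiles")], top_k)
    }))
  if (!is.null(truths)) {
    pool <- rbind(pool,
                  truths[, c("identity_key", "canonical_smiles")])
  }
  pool <- pool[!duplicated(pool$identity_key), , drop = FALSE]
  if (nrow(pool) < 2) {
    stop("candidate pool has fewer than 2 unique structures", call. = FALSE)
  }
  d <- dissimilarity_matrix(
    stats::setNames(pool$canonical_smiles, pool$identity_key)
  )
  coords <- mds_embed(d, max_dims = max_dims)
  cluster_candidates(coords, min_cluster_size, deep_split)
}

#' Substructure and class concordance of top-ranked candidates
#'
#' For each evaluated node: `correct_substructure` is `TRUE` when the
#' top-ranked candidate and the known true structure share a cluster label
#' greater than 0; `correct_class` (only when class labels are supplied)
#' when they share a chemical-class label. Unassigned structures (label 0)
#' count as discordant. Nodes whose truth is absent from the clustered pool
#' are excluded from the rates and counted separately.
#'
#' @param result a `nap_result` from [propagate()].
#' @param truths data.frame from [load_truths()].
#' @param clusters a `nap_clusters` over the candidate pool (labels named by
#'   identity key).
#' @param score_col which effective score defines the top-ranked candidate
#'   (`"eff_base"`, `"eff_fusion"` or `"eff_consensus"`).
#' @param class_labels optional data.frame with `identity_key`,
#'   `class_label` for both candidates and truths.
#' @return list with `per_node` (flags per node) and `rates`
#'   (`substructure_rate`, `class_rate`, `n_evaluated`, `n_excluded`).
#' @export
substructure_concordance <- function(result, truths, clusters,
                                     score_col = "eff_fusion",
                                     class_labels = NULL) {
  s <- method_scores(result)
  labels <- clusters$labels
  nodes <- intersect(unique(s$node_id), truths$node_id)
  rows <- lapply(nodes, function(id) {
    tab <- s[s$node_id == id, , drop = FALSE]
    tab <- tab[order(-tab[[score_col]], -tab$fc, tab$identity_key), ,
               drop = FALSE]
    top_key <- tab$identity_key[1]
    truth_key <- truths$identity_key[match(id, truths$node_id)]
    cl_top <- unname(labels[top_key])
    cl_truth <- unname(labels[truth_key])
    excluded <- is.na(cl_truth)
    correct_sub <- if (excluded) NA else {
      !is.na(cl_top) && cl_top > 0 && identical(cl_top, cl_truth)
    }
    correct_class <- NA
    if (!is.null(class_labels)) {
      top_cls <- class_labels$class_label[
        match(top_key, class_labels$identity_key)]
      truth_cls <- class_labels$class_label[
        match(truth_key, class_labels$identity_key)]
      if (!is.na(top_cls) && !is.na(truth_cls)) {
        correct_class <- top_cls == truth_cls
      }
    }
    data.frame(node_id = id, rank1_identity_key = top_key,
               truth_identity_key = truth_key,
               cluster_rank1 = ifelse(is.na(cl_top), NA_integer_, cl_top),
               cluster_truth = ifelse(excluded, NA_integer_, cl_truth),
               correct_substructure = correct_sub,
               correct_class = correct_class,
               stringsAsFactors = FALSE)
  })
  per_node <- do.call(rbind, rows)
  rownames(per_node) <- NULL
  evaluated <- per_node[!is.na(per_node$correct_substructure), , drop = FALSE]
  class_eval <- per_node[!is.na(per_node$correct_class), , drop = FALSE]
  list(
    per_node = per_node,
    rates = list(
      substructure_rate = if (nrow(evaluated)) {
        mean(evaluated$correct_substructure)
      } else NA_real_,
      class_rate = if (nrow(class_eval)) mean(class_eval$correct_class)
                   else NA_real_,
      n_evaluated = nrow(evaluated),
      n_excluded = nrow(per_node) - nrow(evaluated)
    )
  )
}
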