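# Molecular-network data model and I/O.
#
# A molecular network is an undirected graph whose nodes are consensus MS/MS
# spectra (identified by a cluster index) and whose edges carry a spectral
# cosine similarity in [0, 1]. Networks arrive as GraphML (GNPS export
# dialect) or as an edge-list TSV (GNPS "pairs" convention).

#' Construct a molecular network
#'
#' @param nodes data.frame with columns `node_id` (unique character) and
#'   optionally `precursor_mz` (positive Da).
#' @param edges data.frame with columns `node_a`, `node_b`, `cosine`.
#'   Directed duplicates and multi-edges are collapsed to the maximum cosine;
#'   self-loops are dropped with a warning.
#' @return object of class `nap_network` with validated `nodes` and `edges`.
#' @export
nap_network <- function(nodes, edges = NULL) {
  stopifnot(is.data.frame(nodes), "node_id" %in% names(nodes))
  nodes$node_id <- as.character(nodes$node_id)
  if (anyDuplicated(nodes$node_id)) {
    stop("duplicate node_id in network", call. = FALSE)
  }
  if (!"precursor_mz" %in% names(nodes)) nodes$precursor_mz <- NA_real_
  bad_mz <- !is.na(nodes$precursor_mz) & nodes$precursor_mz <= 0
  if (any(bad_mz)) {
    stop("non-positive precursor_mz for node(s): ",
         paste(nodes$node_id[bad_mz], collapse = ", "), call. = FALSE)
  }
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(node_a = character(0), node_b = character(0),
                        cosine = numeric(0), stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("node_a", "node_b", "cosine") %in% names(edges)))
    edges$node_a <- as.character(edges$node_a)
    edges$node_b <- as.character(edges$node_b)
    edges$cosine <- as.numeric(edges$cosine)
    bad <- is.na(edges$cosine) | edges$cosine < 0 | edges$cosine > 1
    if (any(bad)) {
      i <- which(bad)[1]
      stop("edge cosine outside [0,1]: ", edges$node_a[i], " -- ",
           edges$node_b[i], " (", edges$cosine[i], ")", call. = FALSE)
    }
    loops <- edges$node_a == edges$node_b
    if (any(loops)) {
      warning("dropping ", sum(loops), " self-loop edge(s)", call. = FALSE)
      edges <- edges[!loops, , drop = FALSE]
    }
    missing <- setdiff(c(edges$node_a, edges$node_b), nodes$node_id)
    if (length(missing) > 0) {
      stop("edge endpoint(s) not in node set: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
    # canonical unordered pair; multi-edges keep the maximum cosine
    lo <- pmin(edges$node_a, edges$node_b)
    hi <- pmax(edges$node_a, edges$node_b)
    key <- paste(lo, hi, sep = "\r")
    cos <- tapply(edges$cosine, key, max)
    ord <- sort(names(cos))
    parts <- strsplit(ord, "\r", fixed = TRUE)
    edges <- data.frame(
      node_a = vapply(parts, `[[`, character(1), 1),
      node_b = vapply(parts, `[[`, character(1), 2),
      cosine = as.numeric(cos[ord]),
      stringsAsFactors = FALSE
    )
  }
  nodes <- nodes[order(nodes$node_id), c("node_id", "precursor_mz"),
                 drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "nap_network")
}

#' @export
print.nap_network <- function(x, ...) {
  cat("Molecular network:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges\n")
  invisible(x)
}

# igraph view of a network (vertex name = node_id, edge attribute cosine)
network_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("node_a", "node_b", "cosine")],
    directed = FALSE,
    vertices = net$nodes$node_id
  )
  names(igraph::edge_attr(g))[names(igraph::edge_attr(g)) == "cosine"] <-
    "cosine"
  g
}

# Direct neighbors of a node with connecting edge cosines
node_neighbors <- function(net, node_id) {
  e <- net$edges
  sel_a <- e$node_a == node_id
  sel_b <- e$node_b == node_id
  data.frame(
    neighbor = c(e$node_b[sel_a], e$node_a[sel_b]),
    cosine = c(e$cosine[sel_a], e$cosine[sel_b]),
    stringsAsFactors = FALSE
  )
}

#' Read a molecular network from GraphML or edge-list TSV
#'
#' GraphML is read through igraph. Attribute names vary across GNPS workflow
#' releases, so the reader takes an attribute-name map; the defaults match the
#' GNPS export dialect (`cluster index`, `precursor mass`, `cosine_score`).
#' Edge-list TSV uses the GNPS pairs convention: columns `CLUSTERID1`,
#' `CLUSTERID2`, `Cosine`.
#'
#' @param path file path; format chosen by extension (`.graphml` vs anything
#'   else = TSV) unless `format` is given.
#' @param format `"graphml"`, `"tsv"` or `NULL` (infer from extension).
#' @param attr_map named list mapping roles to attribute names:
#'   `node_id`, `precursor_mz`, `cosine`.
#' @return a validated [nap_network()].
#' @export
load_network <- function(path, format = NULL,
                         attr_map = list(node_id = "cluster index",
                                         precursor_mz = "precursor mass",
                                         cosine = "cosine_score")) {
  if (!file.exists(path)) stop("network file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml"
              else "tsv"
  }
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    vattrs <- igraph::vertex_attr_names(g)
    id_attr <- attr_map$node_id
    ids <- if (id_attr %in% vattrs) {
      as.character(igraph::vertex_attr(g, id_attr))
    } else if ("name" %in% vattrs) {
      igraph::V(g)$name
    } else {
      as.character(seq_len(igraph::vcount(g)))
    }
    mz <- if (attr_map$precursor_mz %in% vattrs) {
      as.numeric(igraph::vertex_attr(g, attr_map$precursor_mz))
    } else NA_real_
    if (!attr_map$cosine %in% igraph::edge_attr_names(g)) {
      stop("GraphML lacks edge cosine attribute '", attr_map$cosine, "'",
           call. = FALSE)
    }
    el <- igraph::as_edgelist(g, names = FALSE)
    edges <- data.frame(
      node_a = ids[el[, 1]],
      node_b = ids[el[, 2]],
      cosine = as.numeric(igraph::edge_attr(g, attr_map$cosine)),
      stringsAsFactors = FALSE
    )
    nap_network(data.frame(node_id = ids, precursor_mz = mz,
                           stringsAsFactors = FALSE), edges)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    req <- c("CLUSTERID1", "CLUSTERID2", "Cosine")
    if (!all(req %in% names(tab))) {
      stop("edge-list TSV must have columns ", paste(req, collapse = ", "),
           call. = FALSE)
    }
    ids <- unique(c(as.character(tab$CLUSTERID1),
                    as.character(tab$CLUSTERID2)))
    nap_network(
      data.frame(node_id = ids, stringsAsFactors = FALSE),
      data.frame(node_a = as.character(tab$CLUSTERID1),
                 node_b = as.character(tab$CLUSTERID2),
                 cosine = tab$Cosine, stringsAsFactors = FALSE)
    )
  }
}

#' Write a molecular network
#'
#' Writes GraphML (GNPS attribute dialect, readable by [load_network()]) or
#' edge-list TSV. TSV keeps only connected nodes; GraphML keeps all.
#'
#' @param net a [nap_network()].
#' @param path output path.
#' @param format `"graphml"` or `"tsv"`; inferred from extension when `NULL`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = NULL) {
  stopifnot(inherits(net, "nap_network"))
  if (is.null(format)) {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml"
              else "tsv"
  }
  if (format == "graphml") {
    g <- igraph::graph_from_data_frame(
      net$edges[, c("node_a", "node_b")],
      directed = FALSE, vertices = net$nodes$node_id
    )
    igraph::vertex_attr(g, "cluster index") <- net$nodes$node_id
    igraph::vertex_attr(g, "precursor mass") <- net$nodes$precursor_mz
    igraph::edge_attr(g, "cosine_score") <- net$edges$cosine
    igraph::write_graph(g, path, format = "graphml")
  } else {
    utils::write.table(
      data.frame(CLUSTERID1 = net$edges$node_a,
                 CLUSTERID2 = net$edges$node_b,
                 Cosine = net$edges$cosine),
      path, sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Candidate lists, library matches, ground truth

# Shared normalization: parse structures, drop unparseable rows with a
# warning, attach canonical_smiles/identity_key.
parse_structure_column <- function(tab, what) {
  parsed <- parse_structure(tab$structure)
  bad <- !parsed$ok
  if (any(bad)) {
    warning("dropping ", sum(bad), " ", what, " row(s) with unparseable ",
            "structures: ",
            paste(utils::head(tab$structure[bad], 3), collapse = ", "),
            call. = FALSE)
  }
  tab$canonical_smiles <- parsed$canonical_smiles
  tab$identity_key <- parsed$identity_key
  tab[!bad, , drop = FALSE]
}

# Deterministic candidate ordering: fc descending, ties by identity_key
order_candidates <- function(tab) {
  tab[order(tab$node_id, -tab$fc, tab$identity_key), , drop = FALSE]
}

#' Read per-node candidate lists
#'
#' Reads a TSV with columns `node_id`, `structure` (SMILES or InChI) and `fc`
#' (base in silico score in `[0, 1]`), plus optional `class_label`. Rows with
#' unparseable structures are dropped with a warning. Per node, candidates
#' are deduplicated by `identity_key` (keeping the maximal `fc`) and sorted by
#' `fc` descending with ties broken by `identity_key`.
#'
#' @param path TSV file path, or a data.frame with the same columns.
#' @return data.frame with columns `node_id`, `structure`,
#'   `canonical_smiles`, `identity_key`, `fc`, `class_label`.
#' @export
load_candidates <- function(path) {
  tab <- if (is.data.frame(path)) path else {
    if (!file.exists(path)) stop("candidates file not found: ", path,
                                 call. = FALSE)
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
  req <- c("node_id", "structure", "fc")
  if (!all(req %in% names(tab))) {
    stop("candidates table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  tab$node_id <- as.character(tab$node_id)
  tab$fc <- as.numeric(tab$fc)
  if (!"class_label" %in% names(tab)) tab$class_label <- NA_character_
  if (any(is.na(tab$fc) | tab$fc < 0)) {
    stop("fc must be numeric and >= 0", call. = FALSE)
  }
  # fc is expected in [0,1] (MetFrag convention); rescale per node otherwise
  if (any(tab$fc > 1)) {
    warning("fc values > 1 found; min-max rescaling per node", call. = FALSE)
    tab$fc <- stats::ave(tab$fc, tab$node_id, FUN = function(x) {
      if (max(x) > 1) (x - min(x)) / max(max(x) - min(x), .Machine$double.eps)
      else x
    })
  }
  tab <- parse_structure_column(tab, "candidate")
  # dedupe by (node_id, identity_key) keeping max fc
  tab <- tab[order(tab$node_id, tab$identity_key, -tab$fc), , drop = FALSE]
  tab <- tab[!duplicated(tab[, c("node_id", "identity_key")]), , drop = FALSE]
  tab <- order_candidates(tab)
  rownames(tab) <- NULL
  tab[, c("node_id", "structure", "canonical_smiles", "identity_key", "fc",
          "class_label")]
}

#' Read spectral-library matches
#'
#' TSV with columns `node_id`, `structure` and optional `match_cosine` in
#' `[0, 1]`. One match per node is kept (highest `match_cosine`, then first).
#'
#' @param path TSV file path or data.frame.
#' @return data.frame with `node_id`, `structure`, `canonical_smiles`,
#'   `identity_key`, `match_cosine`.
#' @export
load_library_matches <- function(path) {
  tab <- if (is.data.frame(path)) path else {
    if (!file.exists(path)) stop("library-matches file not found: ", path,
                                 call. = FALSE)
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
  if (nrow(tab) == 0) {
    return(data.frame(node_id = character(0), structure = character(0),
                      canonical_smiles = character(0),
                      identity_key = character(0), match_cosine = numeric(0),
                      stringsAsFactors = FALSE))
  }
  stopifnot(all(c("node_id", "structure") %in% names(tab)))
  tab$node_id <- as.character(tab$node_id)
  if (!"match_cosine" %in% names(tab)) tab$match_cosine <- NA_real_
  tab$match_cosine <- as.numeric(tab$match_cosine)
  bad <- !is.na(tab$match_cosine) &
    (tab$match_cosine < 0 | tab$match_cosine > 1)
  if (any(bad)) stop("match_cosine outside [0,1]", call. = FALSE)
  tab <- parse_structure_column(tab, "library-match")
  tab <- tab[order(tab$node_id, -ifelse(is.na(tab$match_cosine), -1,
                                        tab$match_cosine)), , drop = FALSE]
  tab <- tab[!duplicated(tab$node_id), , drop = FALSE]
  rownames(tab) <- NULL
  tab[, c("node_id", "structure", "canonical_smiles", "identity_key",
          "match_cosine")]
}

#' Read ground-truth structures
#'
#' TSV with columns `node_id` and `structure`.
#'
#' @param path TSV file path or data.frame.
#' @return data.frame with `node_id`, `structure`, `canonical_smiles`,
#'   `identity_key`.
#' @export
load_truths <- function(path) {
  tab <- if (is.data.frame(path)) path else {
    if (!file.exists(path)) stop("truths file not found: ", path,
                                 call. = FALSE)
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("node_id", "structure") %in% names(tab)))
  tab$node_id <- as.character(tab$node_id)
  tab <- parse_structure_column(tab, "truth")
  tab <- tab[!duplicated(tab$node_id), , drop = FALSE]
  rownames(tab) <- NULL
  tab[, c("node_id", "structure", "canonical_smiles", "identity_key")]
}

#' Classify connected components by library-match coverage
#'
#' Each connected component (molecular family) falls in one of the three
#' propagation scenarios: `no_matches` (no node has a spectral-library
#' match), `sparse_matches` (at least one match but fewer than half the
#' nodes matched), `many_matches` (half or more matched). The 0.5 cut is a
#' reporting convention of this package.
#'
#' @param net a [nap_network()].
#' @param library_matches data.frame from [load_library_matches()] (or NULL).
#' @return data.frame with `node_id`, `component` (integer) and `scenario`.
#' @export
classify_components <- function(net, library_matches = NULL) {
  stopifnot(inherits(net, "nap_network"))
  g <- network_igraph(net)
  comp <- igraph::components(g)
  ids <- igraph::V(g)$name
  matched <- if (is.null(library_matches) || nrow(library_matches) == 0) {
    character(0)
  } else unique(library_matches$node_id)
  out <- data.frame(node_id = ids, component = comp$membership,
                    stringsAsFactors = FALSE)
  frac <- tapply(out$node_id %in% matched, out$component, mean)
  scen <- ifelse(frac == 0, "no_matches",
                 ifelse(frac < 0.5, "sparse_matches", "many_matches"))
  out$scenario <- scen[as.character(out$component)]
  rownames(out) <- NULL
  out
}
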