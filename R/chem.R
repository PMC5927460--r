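# Structure handling: parsing/canonicalization, fingerprints, Tanimoto,
# maximum common substructure, monoisotopic masses.
#
# All structure text is normalized through OpenBabel (ChemmineOB). Results of
# parsing and fingerprinting are cached per session because molecular networks
# reuse the same candidate structures across many nodes.

.chem_cache <- new.env(parent = emptyenv())

chem_cache_get <- function(store, key) {
  env <- .chem_cache[[store]]
  if (is.null(env)) return(NULL)
  env[[key]]
}

chem_cache_set <- function(store, key, value) {
  if (is.null(.chem_cache[[store]])) {
    .chem_cache[[store]] <- new.env(parent = emptyenv())
  }
  assign(key, value, envir = .chem_cache[[store]])
  value
}

# OpenBabel conversion of a single structure line; returns NA_character_ on
# failure instead of propagating OB's empty output. OB writes parse errors to
# stderr on its own; we only interpret the result.
ob_convert1 <- function(text, from, to) {
  out <- tryCatch(
    ChemmineOB::convertFormat(from, to, paste0(text, "\n")),
    error = function(e) ""
  )
  out <- strsplit(out, "[\t\n ]")[[1]]
  out <- out[nzchar(out)]
  if (length(out) == 0) NA_character_ else out[[1]]
}

structure_input_format <- function(text) {
  ifelse(startsWith(trimws(text), "InChI="), "INCHI", "SMI")
}

#' Parse and canonicalize molecular structures
#'
#' Accepts SMILES or standard InChI text and returns, per input, the canonical
#' SMILES, the 27-character InChIKey and the `identity_key` (the first
#' InChIKey block, 14 characters). The identity key is stereo-insensitive and
#' is the unit of structure identity throughout the package: two spellings of
#' the same molecule always map to the same key.
#'
#' @param text character vector of SMILES or InChI strings.
#' @return A `data.frame` with columns `input`, `canonical_smiles`,
#'   `inchikey`, `identity_key` and logical `ok`. Unparseable inputs have
#'   `ok = FALSE` and `NA` in the derived columns.
#' @examples
#' \donttest{
#' parse_structure(c("CCO", "OCC"))  # same identity_key
#' }
#' @export
parse_structure <- function(text) {
  stopifnot(is.character(text))
  rows <- lapply(text, function(x) {
    if (is.na(x) || !nzchar(trimws(x))) {
      return(list(can = NA_character_, key = NA_character_))
    }
    hit <- chem_cache_get("parse", x)
    if (!is.null(hit)) return(hit)
    fmt <- structure_input_format(x)
    can <- ob_convert1(x, fmt, "CAN")
    key <- if (is.na(can)) NA_character_ else ob_convert1(can, "SMI", "INCHIKEY")
    chem_cache_set("parse", x, list(can = can, key = key))
  })
  can <- vapply(rows, `[[`, character(1), "can")
  key <- vapply(rows, `[[`, character(1), "key")
  ok <- !is.na(can) & !is.na(key) & nchar(key) == 27L
  data.frame(
    input = text,
    canonical_smiles = ifelse(ok, can, NA_character_),
    inchikey = ifelse(ok, key, NA_character_),
    identity_key = ifelse(ok, substr(key, 1L, 14L), NA_character_),
    ok = ok,
    stringsAsFactors = FALSE
  )
}

# Strict single-structure parse used by operations that require validity.
parse_structure1 <- function(text) {
  res <- parse_structure(text)
  if (!res$ok[1]) {
    stop("unparseable structure: '", text, "'", call. = FALSE)
  }
  res
}

#' Path-based binary fingerprints for structures
#'
#' Computes hashed linear-path fingerprints (paths of up to 7 bonds, ring
#' closures included; OpenBabel FP2) folded to a fixed length of 1024 bits.
#' The same canonical structure always yields the same bits.
#'
#' @param smiles character vector of SMILES (canonical or not; inputs are
#'   canonicalized first).
#' @return A 0/1 integer matrix with one row per input structure (rownames =
#'   input SMILES) and 1024 columns.
#' @export
fingerprint_structures <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  parsed <- parse_structure(smiles)
  if (any(!parsed$ok)) {
    stop("unparseable structure(s): ",
         paste(utils::head(smiles[!parsed$ok], 3), collapse = ", "),
         call. = FALSE)
  }
  can <- parsed$canonical_smiles
  need <- unique(can[vapply(can, function(s) is.null(chem_cache_get("fp", s)),
                            logical(1))])
  if (length(need) > 0) {
    fp_one <- function(s) {
      # single-heavy-atom molecules have no paths: empty fingerprint
      tryCatch({
        sdf <- suppressWarnings(ChemmineR::smiles2sdf(c(m = s)))
        as.integer(ChemmineR::fingerprintOB(sdf, "FP2")@fpma[1, ])
      }, error = function(e) integer(1024))
    }
    batch <- tryCatch({
      sdf <- suppressWarnings(
        ChemmineR::smiles2sdf(stats::setNames(need, seq_along(need)))
      )
      ChemmineR::fingerprintOB(sdf, "FP2")@fpma
    }, error = function(e) NULL)
    for (i in seq_along(need)) {
      bits <- if (is.null(batch)) fp_one(need[i]) else {
        as.integer(batch[i, ])
      }
      chem_cache_set("fp", need[i], bits)
    }
  }
  out <- do.call(rbind, lapply(can, chem_cache_get, store = "fp"))
  rownames(out) <- smiles
  out
}

#' Tanimoto similarity of two fingerprints
#'
#' `|A intersect B| / |A union B|` over the on-bits of two equal-length binary
#' fingerprints. When both bit sets are empty the similarity is defined as 1
#' (degenerate convention for featureless structures; a message is emitted).
#'
#' @param fp_a,fp_b binary (0/1) vectors of equal length, or vectors of on-bit
#'   indices when `indices = TRUE`.
#' @param indices interpret inputs as sets of on-bit indices.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(fp_a, fp_b, indices = FALSE) {
  if (indices) {
    a <- unique(fp_a); b <- unique(fp_b)
    inter <- length(intersect(a, b))
    uni <- length(union(a, b))
  } else {
    if (length(fp_a) != length(fp_b)) {
      stop("fingerprint length mismatch: ", length(fp_a), " vs ", length(fp_b),
           call. = FALSE)
    }
    a <- as.logical(fp_a); b <- as.logical(fp_b)
    inter <- sum(a & b)
    uni <- sum(a | b)
  }
  if (uni == 0) {
    message("tanimoto: both bit sets empty; returning 1 by convention")
    return(1)
  }
  inter / uni
}

#' Pairwise Tanimoto similarity between two fingerprint matrices
#'
#' @param fps_a,fps_b 0/1 matrices with one fingerprint per row and equal
#'   column count (as returned by [fingerprint_structures()]).
#' @return matrix of similarities, `nrow(fps_a)` by `nrow(fps_b)`. Pairs where
#'   both fingerprints are empty get 1 (see [tanimoto()]).
#' @export
tanimoto_matrix <- function(fps_a, fps_b) {
  stopifnot(is.matrix(fps_a), is.matrix(fps_b), ncol(fps_a) == ncol(fps_b))
  a <- fps_a > 0; b <- fps_b > 0
  inter <- a %*% t(b)
  uni <- outer(rowSums(a), rowSums(b), `+`) - inter
  sim <- ifelse(uni == 0, 1, inter / pmax(uni, 1))
  dimnames(sim) <- list(rownames(fps_a), rownames(fps_b))
  sim
}

# ---------------------------------------------------------------------------
# Maximum common substructure

# Heavy-atom graph of a structure: igraph with vertex attribute `element` and
# edge attribute `order`, built from the OpenBabel-generated SDF blocks.
molecular_graph <- function(smiles) {
  parsed <- parse_structure1(smiles)
  sdf <- suppressWarnings(
    ChemmineR::smiles2sdf(c(m = parsed$canonical_smiles))
  )[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  # single-atom molecules come back with a degenerate atom block; recover
  # the element symbol from the canonical SMILES
  if (nrow(ab) == 1 && !grepl("^[A-Za-z]", elements[1])) {
    elements <- regmatches(
      parsed$canonical_smiles,
      regexpr("[A-Z][a-z]?", parsed$canonical_smiles)
    )
  }
  heavy <- which(elements != "H")
  g <- igraph::make_empty_graph(n = length(heavy), directed = FALSE)
  igraph::V(g)$element <- elements[heavy]
  remap <- match(seq_along(elements), heavy)
  if (!is.null(bb) && nrow(bb) > 0 && ncol(bb) >= 3) {
    for (i in seq_len(nrow(bb))) {
      if (is.na(bb[i, 1]) || bb[i, 1] < 1 || bb[i, 2] < 1) next
      a <- remap[bb[i, 1]]; b <- remap[bb[i, 2]]
      if (!is.na(a) && !is.na(b)) {
        g <- igraph::add_edges(g, c(a, b), order = bb[i, 3])
      }
    }
  }
  g
}

# A plain SMARTS expression for a subgraph: atoms as [#Z], all bonds as "~"
# (any order). Written by depth-first traversal with ring-closure digits.
graph_to_smarts <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0) return("")
  atomic_num <- c(B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15, S = 16,
                  Cl = 17, Br = 35, I = 53, Na = 11, K = 19, Se = 34)
  el <- igraph::V(g)$element
  z <- atomic_num[el]
  z[is.na(z)] <- 6
  adj <- igraph::as_adj_list(g)
  visited <- rep(FALSE, n)
  ring_bond <- new.env(parent = emptyenv())
  ring_digit <- 0L
  tree_edge <- matrix(FALSE, n, n)
  # assign ring-closure digits to non-tree edges found during DFS
  emit <- function(v, parent) {
    visited[v] <<- TRUE
    token <- paste0("[#", z[v], "]")
    closures <- ""
    branches <- character(0)
    for (w in as.integer(adj[[v]])) {
      if (w == parent) next
      if (visited[w]) {
        key <- paste(sort(c(v, w)), collapse = "-")
        if (is.null(ring_bond[[key]])) {
          ring_digit <<- ring_digit + 1L
          ring_bond[[key]] <- ring_digit
          closures <- paste0(closures, "~%", sprintf("%02d", ring_digit))
        } else {
          closures <- paste0(closures, "~%",
                             sprintf("%02d", ring_bond[[key]]))
        }
      } else if (!tree_edge[v, w]) {
        tree_edge[v, w] <<- TRUE; tree_edge[w, v] <<- TRUE
        branches <- c(branches, paste0("~", emit(w, v)))
      }
    }
    if (length(branches) > 1) {
      branches <- c(paste0("(", branches[-length(branches)], ")"),
                    branches[length(branches)])
    }
    paste0(token, closures, paste(branches, collapse = ""))
  }
  emit(1L, 0L)
}

#' Maximum common substructure of two molecules
#'
#' Finds a connected common substructure of maximal heavy-atom count between
#' two structures, matching atoms by element and bonds by adjacency
#' (bond-order and stereo insensitive). The search reduces the problem to
#' maximum clique in the modular product of the two molecular graphs and is
#' bounded by `timeout` seconds; on timeout an empty substructure is returned
#' with `timed_out = TRUE`. The result is for annotation output only and never
#' enters scoring.
#'
#' @param structure_a,structure_b SMILES or InChI text.
#' @param timeout search budget in seconds (default 10).
#' @return list with `atom_count`, `smarts` (plain element/any-bond SMARTS)
#'   and `timed_out`.
#' @export
mcs <- function(structure_a, structure_b, timeout = 10) {
  pa <- parse_structure1(structure_a)
  pb <- parse_structure1(structure_b)
  ga <- molecular_graph(pa$canonical_smiles)
  gb <- molecular_graph(pb$canonical_smiles)
  na <- igraph::vcount(ga); nb <- igraph::vcount(gb)
  if (na == 0 || nb == 0) {
    return(list(atom_count = 0L, smarts = "", timed_out = FALSE))
  }
  # identical constitution (stereo-insensitive): the MCS is the molecule
  if (pa$identity_key == pb$identity_key) {
    return(list(atom_count = na, smarts = graph_to_smarts(ga),
                timed_out = FALSE))
  }
  ea <- igraph::V(ga)$element; eb <- igraph::V(gb)$element
  pairs <- which(outer(ea, eb, `==`), arr.ind = TRUE)
  if (nrow(pairs) == 0) {
    return(list(atom_count = 0L, smarts = "", timed_out = FALSE))
  }
  aa <- igraph::as_adjacency_matrix(ga, sparse = FALSE) > 0
  ab <- igraph::as_adjacency_matrix(gb, sparse = FALSE) > 0
  np <- nrow(pairs)
  # modular product: vertices are element-compatible atom pairs; edges where
  # adjacency agrees in both molecules
  compat <- matrix(FALSE, np, np)
  for (i in seq_len(np - 1)) {
    vi <- pairs[i, 1]; wi <- pairs[i, 2]
    j <- (i + 1):np
    ok <- pairs[j, 1] != vi & pairs[j, 2] != wi &
      (aa[vi, pairs[j, 1]] == ab[wi, pairs[j, 2]])
    compat[i, j] <- ok
    compat[j, i] <- ok
  }
  gp <- igraph::graph_from_adjacency_matrix(compat, mode = "undirected")
  timed_out <- FALSE
  cliques <- tryCatch({
    setTimeLimit(elapsed = timeout, transient = TRUE)
    on.exit(setTimeLimit(elapsed = Inf, transient = TRUE), add = TRUE)
    igraph::largest_cliques(gp)
  }, error = function(e) {
    timed_out <<- TRUE
    NULL
  })
  if (timed_out || length(cliques) == 0) {
    return(list(atom_count = 0L, smarts = "", timed_out = timed_out))
  }
  # keep the largest connected piece of the best mapping; break ties by the
  # first clique in igraph's deterministic enumeration order
  best <- NULL
  for (cl in cliques) {
    atoms_a <- pairs[as.integer(cl), 1]
    sub <- igraph::induced_subgraph(ga, atoms_a)
    comp <- igraph::components(sub)
    keep <- which(comp$membership == which.max(comp$csize))
    cand <- igraph::induced_subgraph(sub, keep)
    if (is.null(best) || igraph::vcount(cand) > igraph::vcount(best)) {
      best <- cand
    }
  }
  list(atom_count = igraph::vcount(best), smarts = graph_to_smarts(best),
       timed_out = FALSE)
}

# ---------------------------------------------------------------------------
# Monoisotopic masses

# Monoisotopic atomic masses (Da) of the most abundant isotope.
.monoisotopic_mass <- c(
  H = 1.0078250319, C = 12.0, N = 14.0030740052, O = 15.9949146221,
  P = 30.97376151, S = 31.97207069, F = 18.99840320, Cl = 34.96885271,
  Br = 78.9183376, I = 126.904468, Na = 22.98976928, K = 38.9637069,
  Si = 27.9769265327, B = 11.0093055, Se = 73.9224766
)

# Mass of a proton; adduct arithmetic uses the proton, not the hydrogen atom,
# so that protonated/deprotonated m/z values match printed 4-decimal values.
.proton_mass <- 1.007276

#' Monoisotopic m/z of an elemental formula
#'
#' Sums monoisotopic atomic masses over a molecular formula (e.g. `"C28H44O3"`)
#' and applies the adduct: `[M+H]+` adds and `[M-H]-` subtracts one proton
#' mass (1.007276 Da); `"M"` is the neutral monoisotopic mass.
#'
#' @param formula molecular formula string; element symbols followed by
#'   optional counts. The empty string has mass 0.
#' @param adduct one of `"M"`, `"[M+H]+"`, `"[M-H]-"`.
#' @return m/z in Da.
#' @examples
#' monoisotopic_mz("CH2")                 # 14.0157, a methylene difference
#' monoisotopic_mz("C28H44O3", "[M+H]+")  # 429.336
#' @export
monoisotopic_mz <- function(formula, adduct = c("M", "[M+H]+", "[M-H]-")) {
  adduct <- match.arg(adduct)
  stopifnot(is.character(formula), length(formula) == 1)
  formula <- trimws(formula)
  mass <- 0
  if (nzchar(formula)) {
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
    tokens <- regmatches(formula, list(m))[[1]]
    if (sum(nchar(tokens)) != nchar(formula)) {
      stop("cannot parse formula: '", formula, "'", call. = FALSE)
    }
    for (tok in tokens) {
      el <- gsub("[0-9]", "", tok)
      cnt <- gsub("[^0-9]", "", tok)
      cnt <- if (nzchar(cnt)) as.integer(cnt) else 1L
      if (!el %in% names(.monoisotopic_mass)) {
        stop("unknown element symbol: '", el, "'", call. = FALSE)
      }
      mass <- mass + .monoisotopic_mass[[el]] * cnt
    }
  }
  switch(adduct,
    "M" = mass,
    "[M+H]+" = mass + .proton_mass,
    "[M-H]-" = mass - .proton_mass
  )
}
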