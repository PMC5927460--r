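# Seeded synthetic-data generator.
#
# Emulates the inputs the propagation method consumes: molecular families
# built from a shared scaffold by enumerated ring decorations (methyl,
# hydroxyl, methoxy, acetoxy), so that within-family structures literally
# share a common substructure; candidate lists with the true structure
# planted at a controlled base rank among cross-scaffold decoys; sparse
# spectral-library matches; and chain edges with controlled cosines. Edge
# cosines are generated, not computed from spectra: the method consumes them
# as givens.

# Scaffold templates: drug/natural-product-like cores with four substitution
# slots ({R1}..{R4}) on ring atoms. Slots take one of the substituents in
# .decorations; the empty string leaves the position unsubstituted.
.scaffold_templates <- c(
  benzoic_acid    = "O=C(O)c1c{R1}c{R2}cc{R3}c1{R4}",
  coumarin        = "O=c1ccc2c{R1}c{R2}c{R3}c{R4}c2o1",
  indole          = "c1c{R1}c{R2}c2[nH]cc{R3}c2c1{R4}",
  naphthalene     = "c1c{R1}c{R2}c2cc{R3}c{R4}cc2c1",
  quinoline       = "c1c{R1}c{R2}c2ncc{R3}c{R4}c2c1",
  benzofuran      = "c1c{R1}c{R2}c2occ{R3}c2c1{R4}",
  benzothiophene  = "c1c{R1}c{R2}c2scc{R3}c2c1{R4}",
  chromone        = "O=c1cc{R1}oc2c{R2}c{R3}c{R4}cc12",
  cinnamate       = "COC(=O)/C=C/c1c{R1}c{R2}cc{R3}c1{R4}",
  phenylacetic    = "O=C(O)Cc1c{R1}c{R2}cc{R3}c1{R4}",
  benzamide       = "NC(=O)c1c{R1}c{R2}cc{R3}c1{R4}",
  acetophenone    = "CC(=O)c1c{R1}c{R2}cc{R3}c1{R4}",
  pyridine_amide  = "NC(=O)c1c{R1}c{R2}cnc1{R3}",
  pyrimidine      = "c1c{R1}nc{R2}nc1{R3}",
  imidazole_phenyl= "c1cnc(-c2c{R1}c{R2}cc{R3}c2{R4})[nH]1",
  piperidine_phenyl = "C1CCN(c2c{R1}c{R2}cc{R3}c2{R4})CC1",
  morpholine_phenyl = "C1COCCN1c1c{R1}c{R2}cc{R3}c1{R4}",
  decalin         = "C1C{R1}CC2CC{R2}CC{R3}C2C1{R4}",
  cyclohexanoic   = "O=C(O)C1CC{R1}CC{R2}C1{R3}",
  tetralone       = "O=C1CCCc2c1c{R1}c{R2}cc2{R3}"
)

.decorations <- c("", "(C)", "(O)", "(OC)", "(OC(C)=O)")

# Enumerate decorated variants of one scaffold in a fixed order: by total
# number of substituted slots, then lexicographically by slot choice.
enumerate_scaffold <- function(template, max_variants = 40) {
  slots <- unique(regmatches(template,
                             gregexpr("\\{R[0-9]\\}", template))[[1]])
  n_slots <- length(slots)
  grid <- expand.grid(rep(list(seq_along(.decorations)), n_slots),
                      KEEP.OUT.ATTRS = FALSE)
  n_sub <- rowSums(grid > 1)
  grid <- grid[order(n_sub, apply(grid, 1, paste, collapse = "")), ,
               drop = FALSE]
  grid <- utils::head(grid, max_variants)
  vapply(seq_len(nrow(grid)), function(i) {
    s <- template
    for (k in seq_len(n_slots)) {
      s <- sub(slots[k], .decorations[grid[i, k]], s, fixed = TRUE)
    }
    s
  }, character(1))
}

#' The packaged scaffold pool
#'
#' Twenty drug/natural-product-like scaffolds, each enumerable into
#' ring-decorated variants (methyl, hydroxyl, methoxy, acetoxy additions).
#'
#' @param max_variants decorated variants enumerated per scaffold (in a
#'   fixed order; default 40).
#' @return named list of character vectors of SMILES, one per scaffold.
#' @export
scaffold_pool <- function(max_variants = 40) {
  lapply(.scaffold_templates, enumerate_scaffold,
         max_variants = max_variants)
}

# Pool as a table with identity keys, deduplicated globally so that any two
# pool entries are distinct molecules (symmetric ring positions can make two
# decorations coincide). Cached per session.
scaffold_pool_table <- function(max_variants = 40) {
  key <- paste0("pool", max_variants)
  hit <- chem_cache_get("pool", key)
  if (!is.null(hit)) return(hit)
  pool <- scaffold_pool(max_variants)
  tab <- data.frame(
    scaffold = rep(names(pool), lengths(pool)),
    smiles = unlist(pool, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  parsed <- parse_structure(tab$smiles)
  if (any(!parsed$ok)) {
    stop("internal: unparseable scaffold variant(s): ",
         paste(utils::head(tab$smiles[!parsed$ok], 3), collapse = ", "))
  }
  tab$identity_key <- parsed$identity_key
  tab <- tab[!duplicated(tab$identity_key), , drop = FALSE]
  rownames(tab) <- NULL
  chem_cache_set("pool", key, tab)
}

#' Specification of a synthetic fixture
#'
#' Defaults describe a small benchmark network: 4 molecular families of 5
#' nodes chained by edges with cosines in `[0.6, 0.9]` (the similarity range
#' of typical molecular-network edges), 12 decoy candidates per node, the
#' true structure planted at a base rank between 3 and 8, and spectral
#' -library matches on 30% of the nodes.
#'
#' @param n_families number of molecular families (connected components).
#' @param family_size nodes per family.
#' @param decoys_per_node decoy candidates per node.
#' @param true_base_rank_range integer interval for the planted base rank of
#'   the true structure.
#' @param edge_cosine_range interval within `[0, 1]` for edge cosines.
#' @param library_match_fraction fraction of nodes given a library match
#'   (their truth revealed).
#' @param coherent when `TRUE`, each family shares one scaffold and decoys
#'   come from other scaffolds (structurally coherent neighborhoods); when
#'   `FALSE`, truths and decoys are drawn uniformly from all scaffolds
#'   (incoherent neighborhoods).
#' @param seed mandatory integer seed.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_families = 4, family_size = 5,
                         decoys_per_node = 12,
                         true_base_rank_range = c(3, 8),
                         edge_cosine_range = c(0.6, 0.9),
                         library_match_fraction = 0.3,
                         coherent = TRUE, seed) {
  if (missing(seed) || is.null(seed)) {
    stop("fixture_spec: seed is mandatory", call. = FALSE)
  }
  stopifnot(
    n_families >= 0, family_size >= 1, decoys_per_node >= 1,
    length(true_base_rank_range) == 2,
    true_base_rank_range[1] >= 1,
    true_base_rank_range[1] <= true_base_rank_range[2],
    true_base_rank_range[2] <= decoys_per_node + 1,
    length(edge_cosine_range) == 2,
    edge_cosine_range[1] >= 0, edge_cosine_range[2] <= 1,
    edge_cosine_range[1] <= edge_cosine_range[2],
    library_match_fraction >= 0, library_match_fraction <= 1
  )
  structure(list(
    n_families = as.integer(n_families),
    family_size = as.integer(family_size),
    decoys_per_node = as.integer(decoys_per_node),
    true_base_rank_range = as.integer(true_base_rank_range),
    edge_cosine_range = as.numeric(edge_cosine_range),
    library_match_fraction = library_match_fraction,
    coherent = isTRUE(coherent),
    seed = as.integer(seed)
  ), class = "fixture_spec")
}

#' Generate a synthetic molecular network with candidate lists
#'
#' Builds the fixture described by a [fixture_spec()]: one scaffold per
#' family (cycled through the pool), `family_size` decorated variants as the
#' nodes' true structures, chain edges between consecutive family members,
#' candidate lists of `decoys_per_node + 1` structures with the truth at its
#' planted base rank (base scores are sorted uniform draws, so the planted
#' rank is honored exactly), and library matches on a random subset of
#' nodes. Fully reproducible from the seed.
#'
#' @param spec a [fixture_spec()].
#' @return list with `network` ([nap_network()]), `candidates`,
#'   `library_matches`, `truths` (tables as returned by the corresponding
#'   loaders), `planted` (node_id, planted base rank of the truth) and
#'   `spec`.
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  pool <- scaffold_pool_table()
  scaffolds <- unique(pool$scaffold)
  n_scaffolds <- length(scaffolds)
  per_scaffold <- table(pool$scaffold)
  if (spec$family_size > min(per_scaffold)) {
    stop("family_size exceeds enumerable decorations per scaffold (",
         min(per_scaffold), ")", call. = FALSE)
  }
  withr::with_seed(spec$seed, {
    nodes <- list(); edges <- list(); cands <- list(); truths <- list()
    matches <- list()
    for (fam in seq_len(spec$n_families)) {
      scaf <- scaffolds[((fam - 1) %% n_scaffolds) + 1]
      fam_rows <- which(pool$scaffold == scaf)
      truth_rows <- if (spec$coherent) {
        sample(fam_rows, spec$family_size)
      } else {
        sample(nrow(pool), spec$family_size)
      }
      # decoys from other scaffolds (coherent) or any scaffold (incoherent),
      # sampled without replacement across the whole family: candidate lists
      # of distinct precursors do not repeat molecules, and each list has
      # unique identity keys by construction
      decoy_univ <- if (spec$coherent) {
        setdiff(seq_len(nrow(pool)), fam_rows)
      } else {
        setdiff(seq_len(nrow(pool)), truth_rows)
      }
      if (length(decoy_univ) < spec$decoys_per_node * spec$family_size) {
        stop("decoy pool too small for family_size * decoys_per_node",
             call. = FALSE)
      }
      fam_decoys <- matrix(
        sample(decoy_univ, spec$decoys_per_node * spec$family_size),
        nrow = spec$family_size
      )
      node_ids <- sprintf("F%02dN%02d", fam, seq_len(spec$family_size))
      for (k in seq_len(spec$family_size)) {
        id <- node_ids[k]
        truth_row <- truth_rows[k]
        decoy_rows <- fam_decoys[k, ]
        structures <- pool$smiles[c(truth_row, decoy_rows)]
        # distinct sorted base scores; truth placed at its planted rank
        L <- length(structures)
        fc_sorted <- sort(stats::runif(L), decreasing = TRUE)
        rank_choices <- seq(spec$true_base_rank_range[1],
                            spec$true_base_rank_range[2])
        rank_true <- if (length(rank_choices) == 1) rank_choices else {
          sample(rank_choices, 1)
        }
        fc <- numeric(L)
        fc[1] <- fc_sorted[rank_true]
        fc[-1] <- fc_sorted[-rank_true]
        cands[[length(cands) + 1]] <- data.frame(
          node_id = id, structure = structures, fc = fc,
          class_label = pool$scaffold[c(truth_row, decoy_rows)],
          stringsAsFactors = FALSE
        )
        truths[[length(truths) + 1]] <- data.frame(
          node_id = id, structure = pool$smiles[truth_row],
          planted_rank = rank_true,
          stringsAsFactors = FALSE
        )
        nodes[[length(nodes) + 1]] <- data.frame(
          node_id = id,
          precursor_mz = round(stats::runif(1, 150, 600), 3),
          stringsAsFactors = FALSE
        )
      }
      if (spec$family_size > 1) {
        edges[[length(edges) + 1]] <- data.frame(
          node_a = node_ids[-spec$family_size],
          node_b = node_ids[-1],
          cosine = round(stats::runif(spec$family_size - 1,
                                      spec$edge_cosine_range[1],
                                      spec$edge_cosine_range[2]), 4),
          stringsAsFactors = FALSE
        )
      }
    }
    all_nodes <- if (length(nodes)) do.call(rbind, nodes) else {
      data.frame(node_id = character(0), precursor_mz = numeric(0))
    }
    all_edges <- if (length(edges)) do.call(rbind, edges) else NULL
    all_truths <- if (length(truths)) do.call(rbind, truths) else {
      data.frame(node_id = character(0), structure = character(0),
                 planted_rank = integer(0))
    }
    n_match <- round(spec$library_match_fraction * nrow(all_nodes))
    if (n_match > 0) {
      picked <- sort(sample(all_nodes$node_id, n_match))
      matches <- data.frame(
        node_id = picked,
        structure = all_truths$structure[match(picked,
                                               all_truths$node_id)],
        match_cosine = round(stats::runif(n_match, 0.7, 1), 4),
        stringsAsFactors = FALSE
      )
    } else {
      matches <- data.frame(node_id = character(0),
                            structure = character(0),
                            match_cosine = numeric(0))
    }
    all_cands <- if (length(cands)) do.call(rbind, cands) else {
      data.frame(node_id = character(0), structure = character(0),
                 fc = numeric(0), class_label = character(0))
    }
  })
  list(
    network = nap_network(all_nodes, all_edges),
    candidates = load_candidates(all_cands),
    library_matches = load_library_matches(matches),
    truths = load_truths(all_truths[, c("node_id", "structure"),
                                    drop = FALSE]),
    planted = all_truths[, c("node_id", "planted_rank"), drop = FALSE],
    spec = spec
  )
}

#' Write a fixture bundle to disk
#'
#' Writes the exact dialects the loaders read: `network.graphml`,
#' `candidates.tsv`, `library_matches.tsv`, `truths.tsv`.
#'
#' @param fixture result of [generate_fixture()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    network = file.path(dir, "network.graphml"),
    candidates = file.path(dir, "candidates.tsv"),
    library_matches = file.path(dir, "library_matches.tsv"),
    truths = file.path(dir, "truths.tsv")
  )
  write_network(fixture$network, paths[["network"]])
  utils::write.table(
    fixture$candidates[, c("node_id", "structure", "fc", "class_label")],
    paths[["candidates"]], sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(
    fixture$library_matches[, c("node_id", "structure", "match_cosine")],
    paths[["library_matches"]], sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(
    fixture$truths[, c("node_id", "structure")],
    paths[["truths"]], sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(paths)
}
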