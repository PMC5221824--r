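#' Build an atom-mapping entry
#'
#' An atom-mapping entry aligns atoms of a substrate compound with atoms of a
#' product compound for one or more reactions, in the style of reactant-pair
#' (RPAIR) records: an injective partial mapping between the two atom sets
#' plus the reaction ids the alignment belongs to.
#'
#' @param entry_id Identifier, e.g. `"RP00587"`.
#' @param substrate_id,product_id Compound ids of the two aligned compounds.
#' @param atom_pairs Data frame with columns `sub_atom`, `prod_atom`, one row
#'   per aligned atom pair. No substrate atom may map twice and no product
#'   atom may be hit twice.
#' @param reaction_ids Nonempty character vector of reaction ids, e.g.
#'   `"R02722"`.
#' @return An object of class `atom_mapping`.
#' @export
atom_mapping <- function(entry_id, substrate_id, product_id, atom_pairs, reaction_ids) {
  stopifnot(is.character(entry_id), length(entry_id) == 1L, nzchar(entry_id))
  atom_pairs <- as_tibble(atom_pairs)
  if (nrow(atom_pairs) == 0L) {
    atom_pairs <- tibble(sub_atom = character(), prod_atom = character())
  }
  if (!all(c("sub_atom", "prod_atom") %in% names(atom_pairs))) {
    abort_domain(sprintf("mapping '%s': atom_pairs needs columns sub_atom, prod_atom.", entry_id))
  }
  atom_pairs <- atom_pairs[, c("sub_atom", "prod_atom")]
  atom_pairs[] <- lapply(atom_pairs, as.character)
  if (anyDuplicated(atom_pairs$sub_atom)) {
    abort_domain(sprintf("mapping '%s': substrate atom '%s' mapped more than once.",
                         entry_id, atom_pairs$sub_atom[duplicated(atom_pairs$sub_atom)][1]))
  }
  if (anyDuplicated(atom_pairs$prod_atom)) {
    abort_domain(sprintf("mapping '%s': product atom '%s' hit more than once.",
                         entry_id, atom_pairs$prod_atom[duplicated(atom_pairs$prod_atom)][1]))
  }
  reaction_ids <- sort(unique(as.character(reaction_ids)))
  if (!length(reaction_ids) || anyNA(reaction_ids) || any(!nzchar(reaction_ids))) {
    abort_domain(sprintf("mapping '%s': at least one reaction id is required.", entry_id))
  }
  structure(
    list(
      entry_id = entry_id,
      substrate_id = as.character(substrate_id),
      product_id = as.character(product_id),
      atom_pairs = atom_pairs,
      reaction_ids = reaction_ids
    ),
    class = "atom_mapping"
  )
}

#' @export
print.atom_mapping <- function(x, ...) {
  cat(sprintf(
    "<atom_mapping> %s: %s -> %s, %d atom pairs, reactions: %s\n",
    x$entry_id, x$substrate_id, x$product_id, nrow(x$atom_pairs),
    paste(x$reaction_ids, collapse = ", ")
  ))
  invisible(x)
}

#' Reverse an atom-mapping entry
#'
#' Swaps the substrate and product roles and inverts the atom alignment.
#' Used when a reaction is traversed in the reverse direction.
#'
#' @param m An [atom_mapping()] object.
#' @return An `atom_mapping` with roles swapped; `entry_id` is preserved.
#' @export
reverse_mapping <- function(m) {
  stopifnot(inherits(m, "atom_mapping"))
  atom_mapping(
    entry_id = m$entry_id,
    substrate_id = m$product_id,
    product_id = m$substrate_id,
    atom_pairs = tibble(sub_atom = m$atom_pairs$prod_atom,
                        prod_atom = m$atom_pairs$sub_atom),
    reaction_ids = m$reaction_ids
  )
}

#' Assemble a reaction network
#'
#' Bundles compound graphs, atom-mapping entries, a reaction energy table
#' (Gibbs free energy changes, \eqn{\Delta G'_r}) and a compound-similarity
#' table into one cross-validated object. Two compounds are adjacent when a
#' mapping entry links them as substrate and product (search may additionally
#' use the reverse direction, see [search_config()]).
#'
#' @param compounds List of [compound_graph()] objects.
#' @param mappings List of [atom_mapping()] objects.
#' @param energies Data frame with columns `reaction_id`, `dg_prime_r`.
#'   `NA` marks a reaction with unknown energy; absent reactions are equally
#'   treated as missing (never silently zero). Values are opaque signed reals
#'   on the scale of the source table.
#' @param similarities Data frame with columns `compound_a`, `compound_b`,
#'   `score` in \[0, 1\]; scores are symmetric in the pair.
#' @param default_similarity Score used for pairs absent from the table
#'   (default 0).
#' @param hydrogens `"exclude"` (default) drops hydrogen atoms, their bonds
#'   and any atom pairs touching them before anything else sees the network;
#'   `"keep"` retains them (they then count toward group sizes).
#' @return An object of class `reaction_network`.
#' @export
reaction_network <- function(compounds, mappings = list(), energies = NULL,
                             similarities = NULL, default_similarity = 0,
                             hydrogens = c("exclude", "keep")) {
  hydrogens <- match.arg(hydrogens)
  if (inherits(compounds, "compound_graph")) compounds <- list(compounds)
  if (inherits(mappings, "atom_mapping")) mappings <- list(mappings)
  stopifnot(all(vapply(compounds, inherits, TRUE, "compound_graph")),
            all(vapply(mappings, inherits, TRUE, "atom_mapping")))
  h_atoms <- list()
  if (hydrogens == "exclude") {
    for (cg in compounds) {
      h_atoms[[cg$compound_id]] <-
        cg$atoms$atom_id[!is.na(cg$atoms$element) & cg$atoms$element == "H"]
    }
    compounds <- lapply(compounds, strip_hydrogens)
  }
  ids <- vapply(compounds, `[[`, "", "compound_id")
  if (anyDuplicated(ids)) {
    abort_domain(sprintf("duplicated compound id '%s'.", ids[duplicated(ids)][1]))
  }
  names(compounds) <- ids
  compounds <- compounds[order(ids)]

  if (is.null(energies)) {
    energies <- tibble(reaction_id = character(), dg_prime_r = numeric())
  }
  energies <- as_tibble(energies)[, c("reaction_id", "dg_prime_r")]
  energies$reaction_id <- as.character(energies$reaction_id)
  energies$dg_prime_r <- as.numeric(energies$dg_prime_r)
  if (anyDuplicated(energies$reaction_id)) {
    abort_domain(sprintf("duplicated energy row for reaction '%s'.",
                         energies$reaction_id[duplicated(energies$reaction_id)][1]))
  }
  if (any(is.infinite(energies$dg_prime_r), na.rm = TRUE)) {
    abort_domain("energy table: dG'r values must be finite (use NA for missing).")
  }

  if (is.null(similarities)) {
    similarities <- tibble(compound_a = character(), compound_b = character(),
                           score = numeric())
  }
  similarities <- as_tibble(similarities)[, c("compound_a", "compound_b", "score")]
  similarities$compound_a <- as.character(similarities$compound_a)
  similarities$compound_b <- as.character(similarities$compound_b)
  similarities$score <- as.numeric(similarities$score)
  a <- pmin(similarities$compound_a, similarities$compound_b)
  b <- pmax(similarities$compound_a, similarities$compound_b)
  similarities$compound_a <- a
  similarities$compound_b <- b
  if (any(is.na(similarities$score) | similarities$score < 0 | similarities$score > 1)) {
    abort_domain("similarity scores must lie in [0, 1].")
  }
  key <- paste(a, b, sep = "~")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    conflicting <- vapply(unique(dup), function(k) {
      length(unique(similarities$score[key == k])) > 1L
    }, TRUE)
    if (any(conflicting)) {
      abort_domain(sprintf("conflicting similarity scores for pair %s.",
                           names(conflicting)[conflicting][1]))
    }
    similarities <- similarities[!duplicated(key), ]
  }
  if (!(is.numeric(default_similarity) && length(default_similarity) == 1L &&
        default_similarity >= 0 && default_similarity <= 1)) {
    abort_domain("`default_similarity` must be a single value in [0, 1].")
  }

  if (hydrogens == "exclude" && length(mappings)) {
    # atom pairs touching a (removed) hydrogen are dropped from group
    # computations; anything else referencing a vanished atom is an error
    # caught by validation below
    mappings <- lapply(mappings, function(m) {
      drop <- m$atom_pairs$sub_atom %in% (h_atoms[[m$substrate_id]] %||% character()) |
        m$atom_pairs$prod_atom %in% (h_atoms[[m$product_id]] %||% character())
      m$atom_pairs <- m$atom_pairs[!drop, ]
      m
    })
  }

  mids <- vapply(mappings, `[[`, "", "entry_id")
  if (anyDuplicated(mids)) {
    abort_domain(sprintf("duplicated mapping entry id '%s'.", mids[duplicated(mids)][1]))
  }
  names(mappings) <- mids
  mappings <- mappings[order(mids)]

  net <- structure(
    list(
      compounds = compounds,
      mappings = mappings,
      energies = energies,
      similarities = similarities,
      default_similarity = default_similarity,
      hydrogens = hydrogens
    ),
    class = "reaction_network"
  )
  validate_reaction_network(net)
  net
}

validate_reaction_network <- function(net) {
  for (m in net$mappings) {
    for (role in c("substrate_id", "product_id")) {
      cid <- m[[role]]
      if (!cid %in% names(net$compounds)) {
        abort_ref(sprintf("mapping '%s': unknown compound '%s'.", m$entry_id, cid))
      }
    }
    sub_atoms <- net$compounds[[m$substrate_id]]$atoms$atom_id
    prod_atoms <- net$compounds[[m$product_id]]$atoms$atom_id
    keep <- m$atom_pairs$sub_atom %in% sub_atoms & m$atom_pairs$prod_atom %in% prod_atoms
    if (!all(keep)) {
      bad <- m$atom_pairs[!keep, ]
      abort_ref(sprintf("mapping '%s': atom pair (%s -> %s) references an unknown atom.",
                        m$entry_id, bad$sub_atom[1], bad$prod_atom[1]))
    }
  }
  invisible(net)
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf(
    "<reaction_network> %d compounds, %d mapping entries, %d energy rows, %d similarity rows\n",
    length(x$compounds), length(x$mappings), nrow(x$energies), nrow(x$similarities)
  ))
  invisible(x)
}

#' Look up the Gibbs free energy change of a reaction
#'
#' @param net A [reaction_network()].
#' @param reaction_id Reaction identifier.
#' @return The tabulated \eqn{\Delta G'_r}, or `NA_real_` when the reaction is
#'   absent from the table or tabulated as missing. A missing energy is never
#'   coerced to a number here; substitution is a weighting policy
#'   (see [weight_params()]).
#' @export
energy_of <- function(net, reaction_id) {
  i <- match(reaction_id, net$energies$reaction_id)
  ifelse(is.na(i), NA_real_, net$energies$dg_prime_r[i])
}

#' Look up the structural similarity of two compounds
#'
#' @param net A [reaction_network()].
#' @param a,b Compound ids (order irrelevant).
#' @return Score in \[0, 1\]; pairs absent from the table get the network's
#'   `default_similarity`. `similarity_of(net, x, x)` is 1 by convention.
#' @export
similarity_of <- function(net, a, b) {
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  i <- match(paste(lo, hi, sep = "~"),
             paste(net$similarities$compound_a, net$similarities$compound_b, sep = "~"))
  out <- ifelse(is.na(i), net$default_similarity, net$similarities$score[i])
  out[a == b] <- 1
  out
}
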