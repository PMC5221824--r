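#' Read a reaction network from disk
#'
#' Reads the package's open on-disk dialect from a directory:
#' \describe{
#'   \item{`compounds.json`}{list of `{compound_id, atoms:[{atom_id, element}],
#'     bonds:[{bond_id, a1, a2}]}`}
#'   \item{`mappings.json`}{list of `{entry_id, substrate_id, product_id,
#'     atom_pairs:[[sub_atom, prod_atom]], reaction_ids:[...]}`}
#'   \item{`energies.tsv`}{two columns `reaction_id`, `dg_prime_r`; the
#'     literal string `NA` marks a reaction with unknown energy}
#'   \item{`similarity.tsv`}{three columns `compound_a`, `compound_b`, `score`}
#' }
#' The two TSV files are optional. Every structural invariant (unique ids,
#' resolving bond endpoints, injective atom alignments, similarity range and
#' symmetry) is checked at load time.
#'
#' @param path Directory containing the files above, or a named list/vector
#'   with any of `compounds`, `mappings`, `energies`, `similarities` giving
#'   explicit file paths.
#' @param default_similarity,hydrogens Passed to [reaction_network()].
#' @return A [reaction_network()].
#' @seealso [write_network()]
#' @export
read_network <- function(path, default_similarity = 0,
                         hydrogens = c("exclude", "keep")) {
  hydrogens <- match.arg(hydrogens)
  if (is.character(path) && length(path) == 1L && is.null(names(path))) {
    if (!dir.exists(path)) {
      abort_parse(sprintf("network directory '%s' does not exist.", path))
    }
    files <- list(
      compounds = file.path(path, "compounds.json"),
      mappings = file.path(path, "mappings.json"),
      energies = file.path(path, "energies.tsv"),
      similarities = file.path(path, "similarity.tsv")
    )
  } else {
    files <- as.list(path)
  }

  if (is.null(files$compounds) || !file.exists(files$compounds)) {
    abort_parse("compounds.json is required to read a network.")
  }
  compounds <- parse_compounds_json(files$compounds)

  mappings <- list()
  if (!is.null(files$mappings) && file.exists(files$mappings)) {
    mappings <- parse_mappings_json(files$mappings)
  }

  energies <- NULL
  if (!is.null(files$energies) && file.exists(files$energies)) {
    energies <- readr::read_tsv(files$energies, col_types = readr::cols(
      reaction_id = readr::col_character(), dg_prime_r = readr::col_double()
    ), na = "NA", progress = FALSE)
    if (!all(c("reaction_id", "dg_prime_r") %in% names(energies))) {
      abort_parse(sprintf("'%s': expected columns reaction_id, dg_prime_r.", files$energies))
    }
  }

  similarities <- NULL
  if (!is.null(files$similarities) && file.exists(files$similarities)) {
    similarities <- readr::read_tsv(files$similarities, col_types = readr::cols(
      compound_a = readr::col_character(), compound_b = readr::col_character(),
      score = readr::col_double()
    ), progress = FALSE)
    if (!all(c("compound_a", "compound_b", "score") %in% names(similarities))) {
      abort_parse(sprintf("'%s': expected columns compound_a, compound_b, score.",
                          files$similarities))
    }
  }

  reaction_network(compounds, mappings, energies, similarities,
                   default_similarity = default_similarity,
                   hydrogens = hydrogens)
}

parse_compounds_json <- function(file) {
  recs <- jsonlite::fromJSON(file, simplifyVector = FALSE)
  if (!is.list(recs)) abort_parse(sprintf("'%s': expected a JSON list.", file))
  lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    if (is.null(r$compound_id) || is.null(r$atoms)) {
      abort_parse(sprintf("'%s', record %d: compound_id and atoms are required.", file, i))
    }
    atoms <- dplyr::bind_rows(lapply(r$atoms, function(a) {
      tibble(atom_id = as.character(a$atom_id %||% NA_character_),
             element = as.character(a$element %||% NA_character_))
    }))
    bonds <- NULL
    if (length(r$bonds)) {
      bonds <- dplyr::bind_rows(lapply(r$bonds, function(b) {
        tibble(bond_id = as.character(b$bond_id %||% NA_character_),
               a1 = as.character(b$a1 %||% NA_character_),
               a2 = as.character(b$a2 %||% NA_character_))
      }))
    }
    tryCatch(
      compound_graph(r$compound_id, atoms, bonds),
      metapath_error = function(e) {
        abort_parse(sprintf("'%s', record %d (%s): %s", file, i,
                            as.character(r$compound_id), conditionMessage(e)))
      }
    )
  })
}

parse_mappings_json <- function(file) {
  recs <- jsonlite::fromJSON(file, simplifyVector = FALSE)
  if (!is.list(recs)) abort_parse(sprintf("'%s': expected a JSON list.", file))
  lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    need <- c("entry_id", "substrate_id", "product_id", "reaction_ids")
    if (!all(need %in% names(r))) {
      abort_parse(sprintf("'%s', record %d: fields %s are required.", file, i,
                          paste(need, collapse = ", ")))
    }
    pairs <- tibble(sub_atom = character(), prod_atom = character())
    if (length(r$atom_pairs)) {
      ok <- all(vapply(r$atom_pairs, function(p) length(p) == 2L, TRUE))
      if (!ok) {
        abort_parse(sprintf("'%s', record %d (%s): each atom pair must have 2 elements.",
                            file, i, as.character(r$entry_id)))
      }
      pairs <- tibble(
        sub_atom = vapply(r$atom_pairs, function(p) as.character(p[[1]]), ""),
        prod_atom = vapply(r$atom_pairs, function(p) as.character(p[[2]]), "")
      )
    }
    tryCatch(
      atom_mapping(r$entry_id, r$substrate_id, r$product_id, pairs,
                   unlist(r$reaction_ids)),
      metapath_error = function(e) {
        abort_parse(sprintf("'%s', record %d (%s): %s", file, i,
                            as.character(r$entry_id), conditionMessage(e)))
      }
    )
  })
}

#' Write a reaction network to disk
#'
#' Serializes a network into the dialect documented in [read_network()]; the
#' result round-trips exactly (`read_network(write_network(net, d))` restores
#' an identical network). Missing energies are written as the literal `NA`,
#' never as 0.
#'
#' @param net A [reaction_network()].
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "reaction_network"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) abort_parse(sprintf("cannot create directory '%s'.", path))

  comp_recs <- lapply(unname(net$compounds), function(cg) {
    list(
      compound_id = cg$compound_id,
      atoms = lapply(seq_len(nrow(cg$atoms)), function(i) {
        a <- list(atom_id = cg$atoms$atom_id[i])
        if (!is.na(cg$atoms$element[i])) a$element <- cg$atoms$element[i]
        a
      }),
      bonds = lapply(seq_len(nrow(cg$bonds)), function(i) {
        list(bond_id = cg$bonds$bond_id[i], a1 = cg$bonds$a1[i], a2 = cg$bonds$a2[i])
      })
    )
  })
  jsonlite::write_json(comp_recs, file.path(path, "compounds.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  map_recs <- lapply(unname(net$mappings), function(m) {
    list(
      entry_id = m$entry_id,
      substrate_id = m$substrate_id,
      product_id = m$product_id,
      atom_pairs = lapply(seq_len(nrow(m$atom_pairs)), function(i) {
        c(m$atom_pairs$sub_atom[i], m$atom_pairs$prod_atom[i])
      }),
      reaction_ids = as.list(m$reaction_ids)
    )
  })
  jsonlite::write_json(map_recs, file.path(path, "mappings.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  readr::write_tsv(net$energies, file.path(path, "energies.tsv"), na = "NA")
  readr::write_tsv(net$similarities, file.path(path, "similarity.tsv"))
  invisible(path)
}

#' Derive the bond-level mapping induced by an atom mapping
#'
#' A substrate bond `(u, v)` maps to the product bond `(f(u), f(v))` exactly
#' when both endpoints are atom-mapped and the image pair is a bond of the
#' product. The result is deterministic and each substrate bond maps to at
#' most one product bond (product graphs are simple).
#'
#' @param G,H Substrate and product [compound_graph()]s.
#' @param f An [atom_mapping()] linking `G` to `H`.
#' @return A tibble of class `edge_mapping` with columns `sub_bond`,
#'   `prod_bond`, carrying the entry/substrate/product ids as attributes.
#' @examples
#' nets <- example_networks()
#' net <- nets$serine_pair$network
#' derive_edge_mapping(net$compounds$C00065, net$compounds$C00078,
#'                     net$mappings$RP00587)
#' @export
derive_edge_mapping <- function(G, H, f) {
  stopifnot(inherits(G, "compound_graph"), inherits(H, "compound_graph"),
            inherits(f, "atom_mapping"))
  if (f$substrate_id != G$compound_id || f$product_id != H$compound_id) {
    abort_ref(sprintf("mapping '%s' links %s -> %s, not %s -> %s.",
                      f$entry_id, f$substrate_id, f$product_id,
                      G$compound_id, H$compound_id))
  }
  unknown_sub <- setdiff(f$atom_pairs$sub_atom, G$atoms$atom_id)
  unknown_prod <- setdiff(f$atom_pairs$prod_atom, H$atoms$atom_id)
  if (length(unknown_sub) || length(unknown_prod)) {
    abort_ref(sprintf("mapping '%s' references unknown atom '%s'.", f$entry_id,
                      c(unknown_sub, unknown_prod)[1]))
  }
  amap <- stats::setNames(f$atom_pairs$prod_atom, f$atom_pairs$sub_atom)
  out <- tibble(sub_bond = character(), prod_bond = character())
  if (nrow(G$bonds) && nrow(H$bonds)) {
    mu <- unname(amap[G$bonds$a1])
    mv <- unname(amap[G$bonds$a2])
    both <- !is.na(mu) & !is.na(mv)
    if (any(both)) {
      hkey <- bond_pair_key(H$bonds$a1, H$bonds$a2)
      gkey <- bond_pair_key(mu[both], mv[both])
      hit <- match(gkey, hkey)
      keep <- !is.na(hit)
      out <- tibble(sub_bond = G$bonds$bond_id[both][keep],
                    prod_bond = H$bonds$bond_id[hit[keep]])
    }
  }
  structure(out,
            entry_id = f$entry_id,
            substrate_id = G$compound_id,
            product_id = H$compound_id,
            class = c("edge_mapping", class(out)))
}
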