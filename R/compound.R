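#' Build a compound graph
#'
#' A compound is an attributed relational graph: nodes are (heavy) atoms,
#' edges are covalent bonds. Hydrogens may be present but are usually dropped
#' at network assembly (see [reaction_network()]); connectivity is all that is
#' modelled, there are no coordinates, bond orders or stereo flags.
#'
#' @param compound_id Single identifier string, e.g. a KEGG-style `"C00065"`
#'   or any synthetic id.
#' @param atoms Data frame with columns `atom_id` (unique, nonempty) and
#'   optionally `element` (symbol such as `"C"`, `"N"`; may be `NA` for
#'   abstract fixtures).
#' @param bonds Data frame with columns `bond_id` (unique), `a1`, `a2`
#'   (existing, distinct atom ids). The graph is simple and undirected: no
#'   duplicate unordered endpoint pairs.
#' @return An object of class `compound_graph`.
#' @examples
#' cg <- compound_graph(
#'   "X1",
#'   atoms = data.frame(atom_id = c("a1", "a2"), element = c("C", "O")),
#'   bonds = data.frame(bond_id = "b1", a1 = "a1", a2 = "a2")
#' )
#' cg
#' @export
compound_graph <- function(compound_id, atoms, bonds = NULL) {
  if (!is.character(compound_id) || length(compound_id) != 1L ||
      is.na(compound_id) || !nzchar(compound_id)) {
    abort_domain("`compound_id` must be a single nonempty string.")
  }
  atoms <- as_tibble(atoms)
  if (!"atom_id" %in% names(atoms)) {
    abort_domain(sprintf("compound '%s': atoms need an `atom_id` column.", compound_id))
  }
  if (!"element" %in% names(atoms)) atoms$element <- NA_character_
  atoms <- atoms[, c("atom_id", "element")]
  atoms$atom_id <- as.character(atoms$atom_id)
  atoms$element <- as.character(atoms$element)
  if (is.null(bonds) || nrow(as_tibble(bonds)) == 0L) {
    bonds <- tibble(bond_id = character(), a1 = character(), a2 = character())
  }
  bonds <- as_tibble(bonds)
  need <- c("bond_id", "a1", "a2")
  if (!all(need %in% names(bonds))) {
    abort_domain(sprintf("compound '%s': bonds need columns bond_id, a1, a2.", compound_id))
  }
  bonds <- bonds[, need]
  bonds[] <- lapply(bonds, as.character)
  out <- structure(
    list(compound_id = compound_id, atoms = atoms, bonds = bonds),
    class = "compound_graph"
  )
  validate_compound_graph(out)
  out
}

validate_compound_graph <- function(x, where = NULL) {
  ctx <- if (is.null(where)) sprintf("compound '%s'", x$compound_id) else where
  a <- x$atoms
  b <- x$bonds
  if (nrow(a) == 0L) abort_domain(sprintf("%s: at least one atom is required.", ctx))
  if (anyNA(a$atom_id) || any(!nzchar(a$atom_id))) {
    abort_domain(sprintf("%s: atom ids must be nonempty.", ctx))
  }
  if (anyDuplicated(a$atom_id)) {
    abort_domain(sprintf("%s: duplicated atom id '%s'.", ctx, a$atom_id[duplicated(a$atom_id)][1]))
  }
  bad_el <- !is.na(a$element) & !grepl("^[A-Z][a-z]?$", a$element)
  if (any(bad_el)) {
    abort_domain(sprintf("%s: invalid element symbol '%s'.", ctx, a$element[bad_el][1]))
  }
  if (nrow(b) > 0L) {
    if (anyDuplicated(b$bond_id)) {
      abort_domain(sprintf("%s: duplicated bond id '%s'.", ctx, b$bond_id[duplicated(b$bond_id)][1]))
    }
    missing_ep <- setdiff(c(b$a1, b$a2), a$atom_id)
    if (length(missing_ep)) {
      abort_ref(sprintf("%s: bond endpoint '%s' is not an atom of the compound.", ctx, missing_ep[1]))
    }
    if (any(b$a1 == b$a2)) {
      abort_domain(sprintf("%s: self-bond on atom '%s'.", ctx, b$a1[b$a1 == b$a2][1]))
    }
    key <- bond_pair_key(b$a1, b$a2)
    if (anyDuplicated(key)) {
      abort_domain(sprintf("%s: duplicate bond between the same atom pair (%s).", ctx, key[duplicated(key)][1]))
    }
  }
  invisible(x)
}

bond_pair_key <- function(a1, a2) {
  paste(pmin(a1, a2), pmax(a1, a2), sep = "~")
}

#' @export
print.compound_graph <- function(x, ...) {
  cat(sprintf(
    "<compound_graph> %s: %d atoms, %d bonds\n",
    x$compound_id, nrow(x$atoms), nrow(x$bonds)
  ))
  invisible(x)
}

# Drop hydrogens (and their bonds) from a compound graph.
strip_hydrogens <- function(cg) {
  h <- cg$atoms$atom_id[!is.na(cg$atoms$element) & cg$atoms$element == "H"]
  if (!length(h)) return(cg)
  cg$atoms <- cg$atoms[!cg$atoms$atom_id %in% h, ]
  cg$bonds <- cg$bonds[!(cg$bonds$a1 %in% h | cg$bonds$a2 %in% h), ]
  validate_compound_graph(cg)
  cg
}

# Lexicographically ordered adjacency list atom_id -> character vector.
compound_adjacency <- function(atoms, bonds) {
  adj <- stats::setNames(vector("list", length(atoms)), atoms)
  for (a in atoms) adj[[a]] <- character()
  if (nrow(bonds)) {
    for (i in seq_len(nrow(bonds))) {
      adj[[bonds$a1[i]]] <- c(adj[[bonds$a1[i]]], bonds$a2[i])
      adj[[bonds$a2[i]]] <- c(adj[[bonds$a2[i]]], bonds$a1[i])
    }
    adj <- lapply(adj, function(v) sort(unique(v)))
  }
  adj
}

# Connected components by iterative depth-first search. Atoms are visited in
# lexicographic order so the component list is deterministic; the partition
# itself does not depend on order. Returns a list of character vectors.
dfs_components <- function(atoms, bonds) {
  atoms <- sort(atoms)
  adj <- compound_adjacency(atoms, bonds)
  seen <- stats::setNames(logical(length(atoms)), atoms)
  comps <- list()
  for (root in atoms) {
    if (seen[[root]]) next
    stack <- root
    comp <- character()
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (seen[[v]]) next
      seen[[v]] <- TRUE
      comp <- c(comp, v)
      nb <- adj[[v]]
      nb <- nb[!seen[nb]]
      # push in reverse so lexicographically smallest is expanded first
      if (length(nb)) stack <- c(stack, rev(nb))
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}
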