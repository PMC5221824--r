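#' Atomic groups and conserved group sets
#'
#' An atomic group is a connected set of atoms, together with the bonds
#' between them, carried intact from a substrate to a product: none of the
#' bonds inside the group break along the way. A conserved group set collects
#' the pairwise atom-disjoint groups a compound has received from the start
#' compound of a search. A single atom with no bonds is a valid group of
#' size 1.
#'
#' @param compound_id Compound the group lives on.
#' @param atom_ids Nonempty character vector of atom ids.
#' @param bond_ids Character vector of bond ids; every bond must have both
#'   endpoints in `atom_ids`, and the induced subgraph must be connected.
#' @param compound The owning [compound_graph()], used to check connectivity.
#' @return `atomic_group()` returns an object of class `atomic_group`;
#'   `group_set()` wraps a list of groups (all on one compound, pairwise
#'   atom-disjoint) as a `group_set`.
#' @export
atomic_group <- function(compound_id, atom_ids, bond_ids = character(), compound = NULL) {
  atom_ids <- sort(unique(as.character(atom_ids)))
  bond_ids <- sort(unique(as.character(bond_ids)))
  if (!length(atom_ids)) abort_domain("an atomic group needs at least one atom.")
  g <- structure(
    list(compound_id = compound_id, atom_ids = atom_ids, bond_ids = bond_ids),
    class = "atomic_group"
  )
  if (!is.null(compound)) validate_atomic_group(g, compound)
  g
}

validate_atomic_group <- function(g, compound) {
  stopifnot(inherits(compound, "compound_graph"))
  if (g$compound_id != compound$compound_id) {
    abort_ref(sprintf("group lives on '%s', not on '%s'.", g$compound_id,
                      compound$compound_id))
  }
  if (!all(g$atom_ids %in% compound$atoms$atom_id)) {
    abort_ref(sprintf("group atom '%s' is not in compound '%s'.",
                      setdiff(g$atom_ids, compound$atoms$atom_id)[1], g$compound_id))
  }
  b <- compound$bonds[compound$bonds$bond_id %in% g$bond_ids, ]
  if (nrow(b) != length(g$bond_ids)) {
    abort_ref(sprintf("group bond '%s' is not in compound '%s'.",
                      setdiff(g$bond_ids, compound$bonds$bond_id)[1], g$compound_id))
  }
  if (nrow(b) && !all(b$a1 %in% g$atom_ids & b$a2 %in% g$atom_ids)) {
    abort_domain("every group bond must have both endpoints inside the group.")
  }
  comps <- dfs_components(g$atom_ids, b)
  if (length(comps) != 1L) {
    abort_domain(sprintf("atomic group on '%s' is not connected (%d components).",
                         g$compound_id, length(comps)))
  }
  invisible(g)
}

#' @export
print.atomic_group <- function(x, ...) {
  cat(sprintf("<atomic_group> on %s: {%s} / {%s}\n", x$compound_id,
              paste(x$atom_ids, collapse = ","),
              paste(x$bond_ids, collapse = ",")))
  invisible(x)
}

#' @rdname atomic_group
#' @param groups List of `atomic_group` objects, all on `compound_id`.
#' @export
group_set <- function(compound_id, groups = list()) {
  stopifnot(all(vapply(groups, inherits, TRUE, "atomic_group")))
  for (g in groups) {
    if (g$compound_id != compound_id) {
      abort_ref(sprintf("group on '%s' cannot join a set on '%s'.",
                        g$compound_id, compound_id))
    }
  }
  all_atoms <- unlist(lapply(groups, `[[`, "atom_ids"))
  if (anyDuplicated(all_atoms)) {
    abort_domain(sprintf("groups in a set must be atom-disjoint (atom '%s' repeats).",
                         all_atoms[duplicated(all_atoms)][1]))
  }
  # deterministic order: by smallest atom id
  if (length(groups) > 1L) {
    groups <- groups[order(vapply(groups, function(g) g$atom_ids[1], ""))]
  }
  structure(list(compound_id = compound_id, groups = groups), class = "group_set")
}

#' @export
print.group_set <- function(x, ...) {
  cat(sprintf("<group_set> on %s: %d group(s)\n", x$compound_id, length(x$groups)))
  for (g in x$groups) {
    cat(sprintf("  {%s} / {%s}\n", paste(g$atom_ids, collapse = ","),
                paste(g$bond_ids, collapse = ",")))
  }
  invisible(x)
}

#' @export
length.group_set <- function(x) length(x$groups)

group_sizes <- function(s) vapply(s$groups, function(g) length(g$atom_ids), 0L)

#' Seed the conserved group set of a start compound
#'
#' At the start of a search the whole start compound is taken as conserved:
#' one group holding all its atoms and bonds. A disconnected compound (e.g. a
#' salt written as two fragments) yields one group per connected component,
#' since groups are connected by definition.
#'
#' @param G A [compound_graph()].
#' @return A [group_set()] on `G`.
#' @export
initial_group_set <- function(G) {
  stopifnot(inherits(G, "compound_graph"))
  comps <- dfs_components(G$atoms$atom_id, G$bonds)
  groups <- lapply(comps, function(atoms) {
    b <- G$bonds[G$bonds$a1 %in% atoms & G$bonds$a2 %in% atoms, ]
    atomic_group(G$compound_id, atoms, b$bond_id)
  })
  group_set(G$compound_id, groups)
}

#' Transfer conserved atomic groups across one reaction
#'
#' Implements the conserved-atomic-group mapping step of the search. Given
#' the conserved group set `Rg` of the substrate, the bond mapping `h` of the
#' reaction and the product compound `H`, the mapped subgraph `M` of `H` is
#' assembled from the images of `Rg`'s bonds together with their endpoint
#' atoms; the connected components of `M` are discovered by depth-first
#' search, and those with at least `L` atoms form the product's conserved
#' group set `S`. `S` may be empty: the transfer then breaks every group
#' below the size threshold.
#'
#' Note that atoms enter `M` only as endpoints of mapped bonds: a mapped atom
#' whose every incident group bond breaks does not survive. Pass the images
#' of such isolated atoms via `isolated_atoms` to opt into keeping them as
#' singleton candidates.
#'
#' @param Rg [group_set()] on the substrate compound.
#' @param h An `edge_mapping` from [derive_edge_mapping()] whose substrate is
#'   `Rg`'s compound and whose product is `H`.
#' @param H Product [compound_graph()].
#' @param L Minimum group size (atoms), `L >= 1`.
#' @param isolated_atoms Optional character vector of product atom ids to
#'   seed into `M` as isolated nodes (extension; default none, which follows
#'   the bond-endpoint rule strictly).
#' @return A list with elements `groups` (the [group_set()] `S` on `H`) and
#'   `subgraph` (`M`: list of `atom_ids`, `bond_ids`, `compound_id`).
#' @examples
#' nets <- example_networks()
#' net <- nets$serine_pair$network
#' h <- derive_edge_mapping(net$compounds$C00065, net$compounds$C00078,
#'                          net$mappings$RP00587)
#' Rg <- group_set("C00065", list(
#'   atomic_group("C00065", c("O1s", "C2s", "O3s"), c("e1", "e2"))
#' ))
#' cagm(Rg, h, net$compounds$C00078, L = 2)$groups
#' @export
cagm <- function(Rg, h, H, L = 1, isolated_atoms = NULL) {
  stopifnot(inherits(Rg, "group_set"), inherits(h, "edge_mapping"),
            inherits(H, "compound_graph"))
  if (!is.numeric(L) || length(L) != 1L || L < 1) {
    abort_config("`L` must be a single integer >= 1.")
  }
  if (Rg$compound_id != attr(h, "substrate_id")) {
    abort_config(sprintf("group set lives on '%s' but the edge mapping maps from '%s'.",
                         Rg$compound_id, attr(h, "substrate_id")))
  }
  if (H$compound_id != attr(h, "product_id")) {
    abort_config(sprintf("product compound is '%s' but the edge mapping maps to '%s'.",
                         H$compound_id, attr(h, "product_id")))
  }

  rg_bonds <- unique(unlist(lapply(Rg$groups, `[[`, "bond_ids")))
  mapped <- h[h$sub_bond %in% rg_bonds, , drop = FALSE]
  unknown <- setdiff(mapped$prod_bond, H$bonds$bond_id)
  if (length(unknown)) {
    abort_ref(sprintf("edge mapping references unknown bond '%s' of '%s'.",
                      unknown[1], H$compound_id))
  }
  m_bonds <- H$bonds[H$bonds$bond_id %in% mapped$prod_bond, , drop = FALSE]
  m_atoms <- sort(unique(c(m_bonds$a1, m_bonds$a2, as.character(isolated_atoms))))
  M <- list(compound_id = H$compound_id,
            atom_ids = m_atoms,
            bond_ids = sort(m_bonds$bond_id))

  comps <- dfs_components(m_atoms, m_bonds)
  keep <- comps[vapply(comps, length, 0L) >= L]
  groups <- lapply(keep, function(atoms) {
    b <- m_bonds[m_bonds$a1 %in% atoms & m_bonds$a2 %in% atoms, ]
    atomic_group(H$compound_id, atoms, b$bond_id)
  })
  list(groups = group_set(H$compound_id, groups), subgraph = M)
}
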