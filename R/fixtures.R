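#' Built-in worked example networks
#'
#' Three small networks assembled in code, used throughout the documentation
#' and tests:
#'
#' \describe{
#'   \item{`serine_pair`}{L-serine (C00065, 7 heavy atoms, 6 bonds) and
#'     L-tryptophan (C00078, 15 heavy atoms, 16 bonds) linked by the
#'     reactant-pair entry RP00587, which aligns the six serine atoms
#'     O1s..C6s with O1t..C6t and belongs to reactions R00674 and R02722
#'     (serine + indole(-glycerol phosphate) to tryptophan). Hydrogens are
#'     omitted throughout.}
#'   \item{`serine_chain`}{Adds tryptamine (C00398) reached from tryptophan
#'     via R00685 (decarboxylation), the tabulated energies
#'     \eqn{\Delta G'_r}(R00674) = -64.5 and \eqn{\Delta G'_r}(R00685) =
#'     -19.9 (R02722 deliberately has no energy row), and the similarity
#'     scores sim(C00065, C00078) = 0.375 and sim(C00078, C00398) = 0.8.}
#'   \item{`toy_transfer`}{An abstract eight-compound network C1..C8 with
#'     reactions R1..R8 wired so that a three-atom group flows from C1 along
#'     two alternative routes to C6, while the atoms carried from C7 to C8 by
#'     R8 arrive with no preserved bond between them and therefore form no
#'     group: R8 and C8 never enter the transfer graph. Atom ids are plain
#'     numbers; elements are left unset.}
#' }
#'
#' The serine/tryptophan connectivity of the indole ring and the tryptamine
#' compound are filled in from standard structures; the aligned atoms, bond
#' labels e1..e6/f1..f16, energies and similarities are the fixture's fixed
#' points. The toy network's atom sets are fixed where stated above and
#' minimally completed elsewhere.
#'
#' @return Named list; each element has `network` (a [reaction_network()])
#'   and `expect` (a list of the quantities the fixture is built to
#'   reproduce, e.g. transferred group atoms or per-edge weights).
#' @examples
#' fx <- example_networks()
#' fx$serine_chain$network
#' @export
example_networks <- function() {
  list(
    serine_pair = fixture_serine_pair(),
    serine_chain = fixture_serine_chain(),
    toy_transfer = fixture_toy_transfer()
  )
}

compound_serine <- function() {
  compound_graph(
    "C00065",
    atoms = tibble(
      atom_id = c("O1s", "C2s", "O3s", "C4s", "N5s", "C6s", "O7s"),
      element = c("O", "C", "O", "C", "N", "C", "O")
    ),
    bonds = tibble(
      bond_id = c("e1", "e2", "e3", "e4", "e5", "e6"),
      a1 = c("O1s", "C2s", "C2s", "C4s", "C4s", "C6s"),
      a2 = c("C2s", "O3s", "C4s", "N5s", "C6s", "O7s")
    )
  )
}

compound_tryptophan <- function() {
  compound_graph(
    "C00078",
    atoms = tibble(
      atom_id = c("O1t", "C2t", "O3t", "C4t", "N5t", "C6t", "C7t", "C8t",
                  "N9t", "C10t", "C11t", "C12t", "C13t", "C14t", "C15t"),
      element = c("O", "C", "O", "C", "N", "C", "C", "C", "N", "C", "C",
                  "C", "C", "C", "C")
    ),
    bonds = tibble(
      bond_id = sprintf("f%d", 1:16),
      a1 = c("O1t", "C2t", "C2t", "C4t", "C4t", "C6t", "C7t", "C8t", "N9t",
             "C10t", "C11t", "C12t", "C13t", "C14t", "C15t", "C15t"),
      a2 = c("C2t", "O3t", "C4t", "N5t", "C6t", "C7t", "C8t", "N9t", "C10t",
             "C11t", "C12t", "C13t", "C14t", "C15t", "C10t", "C7t")
    )
  )
}

compound_tryptamine <- function() {
  # decarboxylated tryptophan: the carboxyl (O1, C2, O3) is gone
  compound_graph(
    "C00398",
    atoms = tibble(
      atom_id = c("C4u", "N5u", "C6u", "C7u", "C8u", "N9u", "C10u", "C11u",
                  "C12u", "C13u", "C14u", "C15u"),
      element = c("C", "N", "C", "C", "C", "N", "C", "C", "C", "C", "C", "C")
    ),
    bonds = tibble(
      bond_id = sprintf("g%d", 1:13),
      a1 = c("C4u", "C4u", "C6u", "C7u", "C8u", "N9u", "C10u", "C11u",
             "C12u", "C13u", "C14u", "C15u", "C15u"),
      a2 = c("N5u", "C6u", "C7u", "C8u", "N9u", "C10u", "C11u", "C12u",
             "C13u", "C14u", "C15u", "C10u", "C7u")
    )
  )
}

mapping_rp00587 <- function() {
  atom_mapping(
    "RP00587", "C00065", "C00078",
    tibble(
      sub_atom = c("O1s", "C2s", "O3s", "C4s", "N5s", "C6s"),
      prod_atom = c("O1t", "C2t", "O3t", "C4t", "N5t", "C6t")
    ),
    reaction_ids = c("R00674", "R02722")
  )
}

mapping_r00685 <- function() {
  # synthetic entry id; the alignment carries every tryptamine heavy atom
  atom_mapping(
    "RP90685", "C00078", "C00398",
    tibble(
      sub_atom = c("C4t", "N5t", "C6t", "C7t", "C8t", "N9t", "C10t", "C11t",
                   "C12t", "C13t", "C14t", "C15t"),
      prod_atom = c("C4u", "N5u", "C6u", "C7u", "C8u", "N9u", "C10u", "C11u",
                    "C12u", "C13u", "C14u", "C15u")
    ),
    reaction_ids = "R00685"
  )
}

fixture_serine_pair <- function() {
  net <- reaction_network(
    compounds = list(compound_serine(), compound_tryptophan()),
    mappings = list(mapping_rp00587())
  )
  list(
    network = net,
    expect = list(
      n_atom_pairs = 6L,
      edge_mapping = tibble(sub_bond = sprintf("e%d", 1:5),
                            prod_bond = sprintf("f%d", 1:5)),
      seed_group = list(atoms = c("O1s", "C2s", "O3s"), bonds = c("e1", "e2")),
      transferred = list(atoms = c("O1t", "C2t", "O3t"), bonds = c("f1", "f2"))
    )
  )
}

fixture_serine_chain <- function() {
  net <- reaction_network(
    compounds = list(compound_serine(), compound_tryptophan(), compound_tryptamine()),
    mappings = list(mapping_rp00587(), mapping_r00685()),
    energies = tibble(reaction_id = c("R00674", "R00685"),
                      dg_prime_r = c(-64.5, -19.9)),
    similarities = tibble(compound_a = c("C00065", "C00078"),
                          compound_b = c("C00078", "C00398"),
                          score = c(0.375, 0.8))
  )
  list(
    network = net,
    expect = list(
      energies = c(R00674 = -64.5, R00685 = -19.9),
      sims = c(0.375, 0.8),
      weights_alpha_half = c(0.469275, 0.259005),
      weights_alpha_one = c(0.625, 0.2),
      weights_alpha_zero = c(0.31355, 0.31801),
      top_path = c("C00065", "C00078", "C00398"),
      top_total_weight = 0.72828
    )
  )
}

toy_compound <- function(id, n_atoms = 4L) {
  atoms <- as.character(seq_len(n_atoms))
  compound_graph(
    id,
    atoms = tibble(atom_id = atoms, element = NA_character_),
    bonds = tibble(
      bond_id = c("b12", "b23", "b24"),
      a1 = c("1", "2", "2"),
      a2 = c("2", "3", "4")
    )
  )
}

toy_mapping <- function(entry, sub, prod, sub_atoms, prod_atoms, reaction) {
  atom_mapping(entry, sub, prod,
               tibble(sub_atom = sub_atoms, prod_atom = prod_atoms),
               reaction_ids = reaction)
}

fixture_toy_transfer <- function() {
  compounds <- lapply(sprintf("C%d", 1:8), toy_compound)
  mappings <- list(
    # C1 fans out to C2 {1,2,3}, C3 {2,3,4}, C7 {2,3,4}
    toy_mapping("M1", "C1", "C2", c("1", "2", "3"), c("1", "2", "3"), "R1"),
    toy_mapping("M2", "C1", "C3", c("2", "3", "4"), c("2", "3", "4"), "R2"),
    toy_mapping("M7", "C1", "C7", c("2", "3", "4"), c("2", "3", "4"), "R7"),
    # branch 1: C2 -> C4 {2,3} -> C6
    toy_mapping("M3", "C2", "C4", c("2", "3"), c("2", "3"), "R3"),
    toy_mapping("M5", "C4", "C6", c("2", "3"), c("2", "3"), "R5"),
    # branch 2: C3 -> C5 {2,3,4} -> C6
    toy_mapping("M4", "C3", "C5", c("2", "3", "4"), c("2", "3", "4"), "R4"),
    toy_mapping("M6", "C5", "C6", c("2", "3", "4"), c("2", "3", "4"), "R6"),
    # dead branch: the atoms reaching C8 keep no bond between them
    toy_mapping("M8", "C7", "C8", c("2", "3"), c("1", "3"), "R8")
  )
  energies <- tibble(reaction_id = sprintf("R%d", 1:8),
                     dg_prime_r = c(-10, -12, -8, -11, -9, -13, -7, -5))
  net <- reaction_network(compounds, mappings, energies)
  list(
    network = net,
    expect = list(
      gag_nodes = sprintf("C%d", 1:7),
      gag_reactions = sprintf("R%d", 1:7),
      excluded = c("C8", "R8"),
      paths = list(c("C1", "C2", "C4", "C6"), c("C1", "C3", "C5", "C6")),
      path_reactions = list(c("R1", "R3", "R5"), c("R2", "R4", "R6"))
    )
  )
}
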