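#' Configure the synthetic network generator
#'
#' The generator emulates the three external inputs a real run consumes —
#' atom-mapped reactant pairs, a reaction-energy table and a compound
#' similarity table — with a known ground truth: a planted chain of reactions
#' that carries one connected atomic group of size `group_size` intact from
#' the start to the target, surrounded by currency-metabolite decoy hubs
#' whose mappings never transfer a connected group of two or more atoms
#' (their two mapped atoms are never joined by a preserved bond), mimicking
#' the spurious shortcuts cofactors such as ATP, NAD or H2O create in
#' connectivity-only searches.
#'
#' @param seed Integer RNG seed; the same seed always yields the identical
#'   network.
#' @param n_compounds Total number of compounds (chain + hubs + dead-end
#'   branch compounds).
#' @param atoms_per_compound Length-2 integer range of heavy atoms per
#'   compound.
#' @param path_length Number of compounds on the planted chain (>= 2).
#' @param group_size Size g of the planted conserved group; must fit in the
#'   smallest compound.
#' @param n_decoy_hubs Number of hub decoys.
#' @param decoy_degree Number of chain compounds each hub connects to.
#' @param energy_range Interval the reaction energies are drawn from
#'   (uniform), on the scale of the published tables.
#' @param similarity_model `"jaccard"` scores each connected pair by shared
#'   mapped atoms over total distinct atoms; `"uniform"` draws scores from
#'   U(0, 1).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_compounds = 12L,
                         atoms_per_compound = c(6L, 10L),
                         path_length = 5L, group_size = 3L,
                         n_decoy_hubs = 2L, decoy_degree = 4L,
                         energy_range = c(-100, 50),
                         similarity_model = c("jaccard", "uniform")) {
  similarity_model <- match.arg(similarity_model)
  if (path_length < 2L) abort_config("`path_length` must be >= 2.")
  if (group_size < 1L) abort_config("`group_size` must be >= 1.")
  if (group_size > min(atoms_per_compound)) {
    abort_config("`group_size` cannot exceed the smallest compound size.")
  }
  if (n_compounds < path_length + n_decoy_hubs) {
    abort_config("`n_compounds` must cover the planted chain and the hubs.")
  }
  structure(
    list(seed = as.integer(seed), n_compounds = as.integer(n_compounds),
         atoms_per_compound = as.integer(atoms_per_compound),
         path_length = as.integer(path_length),
         group_size = as.integer(group_size),
         n_decoy_hubs = as.integer(n_decoy_hubs),
         decoy_degree = as.integer(decoy_degree),
         energy_range = as.numeric(energy_range),
         similarity_model = similarity_model),
    class = "synth_config"
  )
}

with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# One random connected compound: a g-atom core path c01-c02-...-cog shared by
# all chain/branch compounds, padded with extra atoms attached at random.
synth_compound <- function(id, n_atoms, g) {
  atom_ids <- sprintf("a%02d", seq_len(n_atoms))
  elements <- sample(c("C", "N", "O", "S"), n_atoms, replace = TRUE,
                     prob = c(0.6, 0.15, 0.2, 0.05))
  bonds <- tibble(bond_id = character(), a1 = character(), a2 = character())
  bid <- 0L
  add_bond <- function(u, v) {
    bid <<- bid + 1L
    bonds <<- dplyr::bind_rows(bonds, tibble(bond_id = sprintf("b%02d", bid),
                                             a1 = u, a2 = v))
  }
  if (g > 1L) for (i in seq_len(g - 1L)) add_bond(atom_ids[i], atom_ids[i + 1L])
  if (n_atoms > g) {
    for (i in (g + 1L):n_atoms) {
      anchor <- sample(atom_ids[seq_len(i - 1L)], 1L)
      add_bond(anchor, atom_ids[i])
    }
  }
  compound_graph(id, tibble(atom_id = atom_ids, element = elements), bonds)
}

#' Generate a synthetic atom-mapped reaction network
#'
#' See [synth_config()] for what is planted. The returned ground truth
#' records the planted chain; with group tracking at `L = group_size` the
#' planted chain is the only start-to-target route in the transfer graph, so
#' the search must rank it first and no decoy hub can appear inside a
#' returned pathway.
#'
#' @param cfg A [synth_config()].
#' @return A list with elements `network` (a [reaction_network()]) and
#'   `ground_truth` (list with `compounds`, `reactions`, `group_size`,
#'   `start`, `target`).
#' @export
generate_network <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  with_preserved_seed(cfg$seed, {
    g <- cfg$group_size
    n_chain <- cfg$path_length
    n_hub <- cfg$n_decoy_hubs
    n_branch <- cfg$n_compounds - n_chain - n_hub

    chain_ids <- sprintf("C9%04d", seq_len(n_chain))
    hub_ids <- if (n_hub) sprintf("C8%04d", seq_len(n_hub)) else character()
    branch_ids <- if (n_branch > 0) sprintf("C7%04d", seq_len(n_branch)) else character()

    sizes <- function(n) sample(seq(cfg$atoms_per_compound[1], cfg$atoms_per_compound[2]),
                                n, replace = TRUE)
    compounds <- c(
      lapply(seq_len(n_chain), function(i) synth_compound(chain_ids[i], sizes(1), g)),
      # hubs: a 4-atom path so atoms a01 and a03 are never bonded
      lapply(hub_ids, function(id) synth_compound(id, 4L, 4L)),
      lapply(branch_ids, function(id) synth_compound(id, sizes(1), g))
    )

    mappings <- list()
    rid_n <- 0L
    eid_n <- 0L
    next_ids <- function() {
      rid_n <<- rid_n + 1L
      eid_n <<- eid_n + 1L
      c(sprintf("R9%04d", rid_n), sprintf("RP9%04d", eid_n))
    }
    core <- sprintf("a%02d", seq_len(g))

    # planted chain: identity mapping on the g-atom core (bonds preserved)
    chain_rids <- character()
    for (i in seq_len(n_chain - 1L)) {
      ids <- next_ids()
      chain_rids <- c(chain_rids, ids[1])
      mappings[[ids[2]]] <- atom_mapping(
        ids[2], chain_ids[i], chain_ids[i + 1L],
        tibble(sub_atom = core, prod_atom = core), ids[1]
      )
    }

    # decoy hubs: two mapped atoms, never a preserved bond between them.
    # chain -> hub maps two bonded core atoms onto the non-adjacent hub pair
    # (a01, a03); hub -> chain maps that non-bonded pair onto (a01, a03) of
    # the chain compound. Either way no bond image exists.
    for (hi in seq_along(hub_ids)) {
      picks <- unique(c(
        1L, n_chain,  # guarantee a start->hub->target shortcut exists
        sample(seq_len(n_chain), min(cfg$decoy_degree, n_chain))
      ))[seq_len(min(cfg$decoy_degree, n_chain))]
      for (ci in picks) {
        ids <- next_ids()
        mappings[[ids[2]]] <- atom_mapping(
          ids[2], chain_ids[ci], hub_ids[hi],
          tibble(sub_atom = c("a01", "a02"), prod_atom = c("a01", "a03")),
          ids[1]
        )
        ids <- next_ids()
        mappings[[ids[2]]] <- atom_mapping(
          ids[2], hub_ids[hi], chain_ids[ci],
          tibble(sub_atom = c("a01", "a03"), prod_atom = c("a01", "a03")),
          ids[1]
        )
      }
    }

    # dead-end branches off random chain nodes, carrying a 2-atom group
    for (bi in seq_along(branch_ids)) {
      anchor <- sample(chain_ids[-n_chain], 1L)
      ids <- next_ids()
      mappings[[ids[2]]] <- atom_mapping(
        ids[2], anchor, branch_ids[bi],
        tibble(sub_atom = c("a01", "a02"), prod_atom = c("a01", "a02")),
        ids[1]
      )
    }

    all_rids <- sort(unique(unlist(lapply(mappings, `[[`, "reaction_ids"))))
    energies <- tibble(
      reaction_id = all_rids,
      dg_prime_r = round(stats::runif(length(all_rids), cfg$energy_range[1],
                                      cfg$energy_range[2]), 1)
    )

    sims <- dplyr::bind_rows(lapply(unname(mappings), function(m) {
      score <- if (cfg$similarity_model == "uniform") {
        stats::runif(1)
      } else {
        na <- nrow(compounds_by_id(compounds, m$substrate_id)$atoms)
        nb <- nrow(compounds_by_id(compounds, m$product_id)$atoms)
        shared <- nrow(m$atom_pairs)
        shared / (na + nb - shared)
      }
      tibble(compound_a = m$substrate_id, compound_b = m$product_id,
             score = round(score, 4))
    }))
    a <- pmin(sims$compound_a, sims$compound_b)
    b <- pmax(sims$compound_a, sims$compound_b)
    sims <- tibble(compound_a = a, compound_b = b, score = sims$score)
    sims <- sims[!duplicated(paste(a, b)), ]

    net <- reaction_network(compounds, mappings, energies, sims)
    list(
      network = net,
      ground_truth = list(
        compounds = chain_ids,
        reactions = chain_rids,
        group_size = g,
        start = chain_ids[1],
        target = chain_ids[n_chain]
      )
    )
  })
}

compounds_by_id <- function(compounds, id) {
  for (cg in compounds) if (cg$compound_id == id) return(cg)
  NULL
}
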