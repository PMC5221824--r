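# Independent brute-force oracles and random-instance builders used across
# the suite. Everything here deliberately avoids the package's own DFS /
# Yen code paths: components come from igraph, path enumeration from
# exhaustive simple-path listing.

random_compound <- function(id, n_atoms = 6, p_bond = 0.4) {
  atoms <- sprintf("x%02d", seq_len(n_atoms))
  pairs <- utils::combn(atoms, 2)
  pick <- stats::runif(ncol(pairs)) < p_bond
  bonds <- if (any(pick)) {
    tibble::tibble(
      bond_id = sprintf("bb%02d", seq_len(sum(pick))),
      a1 = pairs[1, pick], a2 = pairs[2, pick]
    )
  } else NULL
  compound_graph(id, tibble::tibble(atom_id = atoms, element = "C"), bonds)
}

# Random injective partial atom alignment between two compounds.
random_mapping <- function(G, H, frac = 0.7, entry_id = "RPx", reaction = "Rx") {
  na <- nrow(G$atoms); nb <- nrow(H$atoms)
  n <- max(1L, round(frac * min(na, nb)))
  atom_mapping(
    entry_id, G$compound_id, H$compound_id,
    tibble::tibble(
      sub_atom = sample(G$atoms$atom_id, n),
      prod_atom = sample(H$atoms$atom_id, n)
    ),
    reaction_ids = reaction
  )
}

# Random group set on G: connected components of a random induced subgraph.
random_group_set <- function(G, frac = 0.8) {
  atoms <- G$atoms$atom_id[stats::runif(nrow(G$atoms)) < frac]
  if (!length(atoms)) atoms <- G$atoms$atom_id[1]
  b <- G$bonds[G$bonds$a1 %in% atoms & G$bonds$a2 %in% atoms, ]
  g <- igraph::graph_from_data_frame(b[, c("a1", "a2")], directed = FALSE,
                                     vertices = data.frame(name = atoms))
  memb <- igraph::components(g)$membership
  groups <- lapply(split(names(memb), memb), function(as) {
    bi <- b[b$a1 %in% as & b$a2 %in% as, ]
    atomic_group(G$compound_id, as, bi$bond_id)
  })
  group_set(G$compound_id, unname(groups))
}

# Brute-force reference for cagm(): image bonds of the group set's bonds,
# union-find components via igraph, size filter.
oracle_cagm <- function(Rg, h, H, L) {
  rg_bonds <- unique(unlist(lapply(Rg$groups, `[[`, "bond_ids")))
  mapped <- h$prod_bond[h$sub_bond %in% rg_bonds]
  mb <- H$bonds[H$bonds$bond_id %in% mapped, ]
  if (!nrow(mb)) return(list())
  g <- igraph::graph_from_data_frame(mb[, c("a1", "a2")], directed = FALSE)
  memb <- igraph::components(g)$membership
  comps <- split(names(memb), memb)
  comps <- comps[vapply(comps, length, 0L) >= L]
  unname(lapply(comps, sort))
}

group_set_atoms <- function(S) {
  unname(lapply(S$groups, `[[`, "atom_ids"))
}

# Exhaustive reference for k_shortest(): enumerate every simple path with
# igraph, score, sort by (weight, hops, lexicographic compound sequence).
oracle_k_paths <- function(tg, k) {
  if (!nrow(tg$edges)) return(list())
  g <- igraph::graph_from_data_frame(tg$edges[, c("from", "to")], directed = TRUE,
                                     vertices = data.frame(name = tg$nodes))
  if (!tg$start %in% tg$nodes || !tg$target %in% tg$nodes) return(list())
  paths <- igraph::all_simple_paths(g, from = tg$start, to = tg$target, mode = "out")
  if (!length(paths)) return(list())
  ekey <- paste(tg$edges$from, tg$edges$to, sep = "->")
  scored <- lapply(paths, function(p) {
    seqv <- names(p)
    i <- match(paste(seqv[-length(seqv)], seqv[-1], sep = "->"), ekey)
    list(weight = sum(tg$edges$weight[i]), path = seqv)
  })
  ord <- order_paths(scored)
  scored[ord][seq_len(min(k, length(scored)))]
}

# Stable sort of (weight, path) records by the package's documented
# tie-break, implemented independently with rank vectors.
order_paths <- function(ps) {
  w <- vapply(ps, `[[`, 0, "weight")
  hops <- vapply(ps, function(p) length(p$path), 0L)
  key <- vapply(ps, function(p) paste(p$path, collapse = "\r"), "")
  order(round(w, 10), hops, key)
}

random_transfer_graph <- function(n = 8, p = 0.35, unit_weights = FALSE) {
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  pick <- stats::runif(nrow(pairs)) < p
  edges <- pairs[pick, ]
  edges$weight <- if (unit_weights) 1 else round(stats::runif(nrow(edges), 0.05, 2), 3)
  edges$reaction_id <- sprintf("R%03d", seq_len(nrow(edges)))
  transfer_graph(nodes, tibble::as_tibble(edges), start = nodes[1], target = nodes[n])
}

# Exhaustive LCS reference: all common subsequences by recursion (sequences
# must be short). Returns the maximal length and whether `items` attains it
# as an order-respecting common subsequence.
oracle_lcs_length <- function(a, b) {
  if (!length(a) || !length(b)) return(0L)
  if (a[1] == b[1]) return(1L + oracle_lcs_length(a[-1], b[-1]))
  max(oracle_lcs_length(a[-1], b), oracle_lcs_length(a, b[-1]))
}

is_common_subsequence <- function(items, a, b) {
  pos <- function(seq) {
    i <- match(items, seq)
    !anyNA(i) && !is.unsorted(i, strictly = TRUE)
  }
  pos(a) && pos(b)
}

serine_seed_groups <- function() {
  group_set("C00065", list(
    atomic_group("C00065", c("O1s", "C2s", "O3s"), c("e1", "e2"))
  ))
}
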