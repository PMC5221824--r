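test_that("the carboxyl group transfers intact from serine to tryptophan", {
  fx <- example_networks()$serine_pair
  net <- fx$network
  h <- derive_edge_mapping(net$compounds$C00065, net$compounds$C00078,
                           net$mappings$RP00587)
  res <- cagm(serine_seed_groups(), h, net$compounds$C00078, L = 2)
  expect_length(res$groups, 1L)
  g <- res$groups$groups[[1]]
  expect_setequal(g$atom_ids, c("O1t", "C2t", "O3t"))
  expect_setequal(g$bond_ids, c("f1", "f2"))
  # the same transfer dies when the size threshold exceeds the component
  expect_length(cagm(serine_seed_groups(), h, net$compounds$C00078, L = 4)$groups, 0L)
})

test_that("start compounds seed one group per connected component", {
  net <- example_networks()$serine_pair$network
  s <- initial_group_set(net$compounds$C00065)
  expect_length(s, 1L)
  expect_length(s$groups[[1]]$atom_ids, 7L)

  single <- compound_graph("S1", data.frame(atom_id = "a1"))
  expect_equal(group_sizes(initial_group_set(single)), 1L)

  two_part <- compound_graph(
    "S2", data.frame(atom_id = c("a", "b", "c")),
    data.frame(bond_id = "b1", a1 = "a", a2 = "b")
  )
  s2 <- initial_group_set(two_part)
  expect_length(s2, 2L)
  expect_setequal(unlist(group_set_atoms(s2)), c("a", "b", "c"))
})

test_that("cagm agrees with union-find component enumeration on random inputs", {
  set.seed(402)
  for (rep in 1:60) {
    G <- random_compound("G", n_atoms = sample(4:8, 1))
    H <- random_compound("H", n_atoms = sample(4:8, 1))
    f <- random_mapping(G, H)
    h <- derive_edge_mapping(G, H, f)
    Rg <- random_group_set(G)
    L <- sample(1:3, 1)
    got <- group_set_atoms(cagm(Rg, h, H, L = L)$groups)
    want <- oracle_cagm(Rg, h, H, L)
    expect_setequal(vapply(got, paste, "", collapse = ","),
                    vapply(want, paste, "", collapse = ","))
  }
})

test_that("transferred groups are connected, large enough, and shrink with L", {
  set.seed(403)
  for (rep in 1:30) {
    G <- random_compound("G", n_atoms = 7)
    H <- random_compound("H", n_atoms = 7)
    f <- random_mapping(G, H)
    h <- derive_edge_mapping(G, H, f)
    Rg <- random_group_set(G)
    prev_atoms <- NULL
    for (L in 1:4) {
      S <- cagm(Rg, h, H, L = L)$groups
      for (g in S$groups) {
        expect_gte(length(g$atom_ids), L)
        expect_no_error(metapath:::validate_atomic_group(g, H))  # connected
      }
      atoms <- vapply(group_set_atoms(S), paste, "", collapse = ",")
      if (!is.null(prev_atoms)) expect_true(all(atoms %in% prev_atoms))
      prev_atoms <- atoms
      # conservation: transferred bonds are images of group bonds of Rg
      rg_bonds <- unlist(lapply(Rg$groups, `[[`, "bond_ids"))
      s_bonds <- unlist(lapply(S$groups, `[[`, "bond_ids"))
      expect_true(all(s_bonds %in% h$prod_bond[h$sub_bond %in% rg_bonds]))
    }
  }
})

test_that("re-transferring through an identity mapping is idempotent", {
  set.seed(404)
  for (rep in 1:10) {
    G <- random_compound("G", n_atoms = 6)
    H <- random_compound("H", n_atoms = 6)
    f <- random_mapping(G, H)
    h <- derive_edge_mapping(G, H, f)
    S <- cagm(random_group_set(G), h, H, L = 1)$groups
    id <- atom_mapping("ID", H$compound_id, H$compound_id,
                       tibble::tibble(sub_atom = H$atoms$atom_id,
                                      prod_atom = H$atoms$atom_id), "Rid")
    h_id <- derive_edge_mapping(H, H, id)
    S2 <- cagm(S, h_id, H, L = 1)$groups
    expect_equal(group_set_atoms(S2), group_set_atoms(S))
  }
})

test_that("cagm validates its preconditions", {
  net <- example_networks()$serine_pair$network
  h <- derive_edge_mapping(net$compounds$C00065, net$compounds$C00078,
                           net$mappings$RP00587)
  wrong <- group_set("C00078", list(atomic_group("C00078", "O1t")))
  expect_error(cagm(wrong, h, net$compounds$C00078, L = 1),
               class = "metapath_config_error")
  expect_error(cagm(serine_seed_groups(), h, net$compounds$C00065, L = 1),
               class = "metapath_config_error")
  expect_error(cagm(serine_seed_groups(), h, net$compounds$C00078, L = 0),
               class = "metapath_config_error")
})

test_that("a mapped atom with no surviving bond does not enter the subgraph", {
  # two bonded atoms map to two atoms that are not bonded in the product:
  # the image set is empty under the bond-endpoint rule
  G <- compound_graph("G", data.frame(atom_id = c("u", "v")),
                      data.frame(bond_id = "e", a1 = "u", a2 = "v"))
  H <- compound_graph("H", data.frame(atom_id = c("m", "n", "o")),
                      data.frame(bond_id = c("f1", "f2"),
                                 a1 = c("m", "n"), a2 = c("n", "o")))
  f <- atom_mapping("M", "G", "H",
                    data.frame(sub_atom = c("u", "v"), prod_atom = c("m", "o")), "R")
  h <- derive_edge_mapping(G, H, f)
  res <- cagm(initial_group_set(G), h, H, L = 1)
  expect_length(res$groups, 0L)
  expect_length(res$subgraph$atom_ids, 0L)
  # the extension hook can seed isolated images explicitly
  res2 <- cagm(initial_group_set(G), h, H, L = 1, isolated_atoms = c("m", "o"))
  expect_equal(group_sizes(res2$groups), c(1L, 1L))
})
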