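test_that("the serine/tryptophan reactant pair loads with its full structure", {
  fx <- example_networks()$serine_pair
  net <- fx$network
  expect_length(net$compounds, 2L)
  expect_length(net$mappings, 1L)
  expect_equal(nrow(net$compounds$C00065$atoms), 7L)
  expect_equal(nrow(net$compounds$C00065$bonds), 6L)
  expect_equal(nrow(net$compounds$C00078$atoms), 15L)
  expect_equal(nrow(net$compounds$C00078$bonds), 16L)
  m <- net$mappings$RP00587
  expect_equal(nrow(m$atom_pairs), 6L)
  expect_setequal(m$reaction_ids, c("R00674", "R02722"))
})

test_that("networks round-trip through the on-disk dialect", {
  dir <- withr::local_tempdir()
  net <- example_networks()$serine_chain$network
  write_network(net, dir)
  back <- read_network(dir)
  expect_equal(back$compounds, net$compounds)
  expect_equal(back$mappings, net$mappings)
  expect_equal(back$energies, net$energies)
  expect_equal(back$similarities, net$similarities)

  # a large generated network round-trips too
  gen <- generate_network(synth_config(seed = 11, n_compounds = 100,
                                       path_length = 6, n_decoy_hubs = 3))
  dir2 <- withr::local_tempdir()
  write_network(gen$network, dir2)
  back2 <- read_network(dir2)
  expect_equal(back2$compounds, gen$network$compounds)
  expect_equal(back2$mappings, gen$network$mappings)
  expect_equal(back2$energies, gen$network$energies)
  expect_equal(back2$similarities, gen$network$similarities)
})

test_that("a network with no mappings has no adjacency", {
  net <- reaction_network(compound_graph("C1", data.frame(atom_id = "a1")))
  expect_length(net$mappings, 0L)
  expect_equal(nrow(metapath:::adjacency_candidates(net, TRUE)), 0L)
})

test_that("missing energies stay missing: NA in lookups, literal NA on disk", {
  net <- example_networks()$serine_chain$network
  expect_true(is.na(energy_of(net, "R02722")))
  expect_true(is.na(energy_of(net, "R99999")))
  expect_equal(energy_of(net, "R00674"), -64.5)

  net2 <- reaction_network(
    compound_graph("C1", data.frame(atom_id = "a1")),
    energies = data.frame(reaction_id = "R1", dg_prime_r = NA_real_)
  )
  dir <- withr::local_tempdir()
  write_network(net2, dir)
  lines <- readLines(file.path(dir, "energies.tsv"))
  expect_match(lines[2], "^R1\tNA$")
  expect_true(is.na(energy_of(read_network(dir), "R1")))
})

test_that("malformed records raise parse errors naming the file and record", {
  dir <- withr::local_tempdir()
  writeLines('[{"compound_id": "C1", "atoms": [{"atom_id": "a1"}],
    "bonds": [{"bond_id": "b1", "a1": "a1", "a2": "zz"}]}]',
    file.path(dir, "compounds.json"))
  err <- expect_error(read_network(dir), class = "metapath_parse_error")
  expect_match(conditionMessage(err), "compounds.json")
  expect_match(conditionMessage(err), "zz")

  writeLines('[{"compound_id": "C1", "atoms": [{"atom_id": "a1"}]}]',
             file.path(dir, "compounds.json"))
  writeLines('[{"entry_id": "RP1", "substrate_id": "C1", "product_id": "C9",
    "atom_pairs": [], "reaction_ids": ["R1"]}]', file.path(dir, "mappings.json"))
  expect_error(read_network(dir), class = "metapath_reference_error")
})

test_that("structural invariants are enforced at build time", {
  expect_error(
    compound_graph("C1", data.frame(atom_id = c("a", "a"))),
    class = "metapath_domain_error"
  )
  expect_error(
    compound_graph("C1", data.frame(atom_id = c("a", "b")),
                   data.frame(bond_id = c("b1", "b2"), a1 = c("a", "b"), a2 = c("b", "a"))),
    class = "metapath_domain_error"  # duplicate unordered pair
  )
  expect_error(
    atom_mapping("M", "C1", "C2",
                 data.frame(sub_atom = c("a", "a"), prod_atom = c("x", "y")), "R1"),
    class = "metapath_domain_error"  # substrate atom mapped twice
  )
  expect_error(
    reaction_network(
      compound_graph("C1", data.frame(atom_id = "a1")),
      similarities = data.frame(compound_a = "C1", compound_b = "C2", score = 1.2)
    ),
    class = "metapath_domain_error"
  )
})

test_that("similarity lookups are symmetric and default for absent pairs", {
  net <- example_networks()$serine_chain$network
  expect_equal(similarity_of(net, "C00065", "C00078"), 0.375)
  expect_equal(similarity_of(net, "C00078", "C00065"), 0.375)
  expect_equal(similarity_of(net, "C00065", "C00398"), 0)
  expect_equal(similarity_of(net, "C00065", "C00065"), 1)
})

test_that("hydrogens are dropped by default but retainable", {
  cg <- compound_graph(
    "CH", data.frame(atom_id = c("c1", "h1"), element = c("C", "H")),
    data.frame(bond_id = "b1", a1 = "c1", a2 = "h1")
  )
  other <- compound_graph("CX", data.frame(atom_id = c("c1", "h1"),
                                           element = c("C", "H")),
                          data.frame(bond_id = "b1", a1 = "c1", a2 = "h1"))
  m <- atom_mapping("M", "CH", "CX",
                    data.frame(sub_atom = c("c1", "h1"), prod_atom = c("c1", "h1")),
                    "R1")
  net <- reaction_network(list(cg, other), list(m))
  expect_equal(net$compounds$CH$atoms$atom_id, "c1")
  expect_equal(nrow(net$mappings$M$atom_pairs), 1L)
  net_keep <- reaction_network(list(cg, other), list(m), hydrogens = "keep")
  expect_equal(nrow(net_keep$compounds$CH$atoms), 2L)
  expect_equal(nrow(net_keep$mappings$M$atom_pairs), 2L)
})

test_that("derived edge mappings match the worked reactant-pair example", {
  fx <- example_networks()$serine_pair
  net <- fx$network
  h <- derive_edge_mapping(net$compounds$C00065, net$compounds$C00078,
                           net$mappings$RP00587)
  ord <- order(h$sub_bond)
  expect_equal(h$sub_bond[ord], fx$expect$edge_mapping$sub_bond)
  expect_equal(h$prod_bond[ord], fx$expect$edge_mapping$prod_bond)
})

test_that("an empty atom alignment induces an empty bond alignment", {
  G <- compound_graph("G", data.frame(atom_id = c("a", "b")),
                      data.frame(bond_id = "b1", a1 = "a", a2 = "b"))
  H <- compound_graph("H", data.frame(atom_id = c("x", "y")),
                      data.frame(bond_id = "c1", a1 = "x", a2 = "y"))
  f <- atom_mapping("M0", "G", "H",
                    data.frame(sub_atom = character(), prod_atom = character()), "R1")
  expect_equal(nrow(derive_edge_mapping(G, H, f)), 0L)
})

test_that("edge mapping equals exhaustive bond-pair matching on random inputs", {
  set.seed(401)
  for (rep in 1:25) {
    G <- random_compound("G", n_atoms = sample(3:7, 1))
    H <- random_compound("H", n_atoms = sample(3:7, 1))
    f <- random_mapping(G, H)
    h <- derive_edge_mapping(G, H, f)
    # brute force over all substrate-bond x product-bond pairs
    amap <- stats::setNames(f$atom_pairs$prod_atom, f$atom_pairs$sub_atom)
    expected <- list()
    for (i in seq_len(nrow(G$bonds))) {
      for (j in seq_len(nrow(H$bonds))) {
        u <- G$bonds$a1[i]; v <- G$bonds$a2[i]
        m <- H$bonds$a1[j]; n2 <- H$bonds$a2[j]
        fu <- amap[u]; fv <- amap[v]
        if (!is.na(fu) && !is.na(fv) &&
            setequal(c(fu, fv), c(m, n2))) {
          expected[[length(expected) + 1L]] <- c(G$bonds$bond_id[i], H$bonds$bond_id[j])
        }
      }
    }
    got <- paste(h$sub_bond, h$prod_bond)
    want <- vapply(expected, paste, "", collapse = " ")
    expect_setequal(got, want)
    expect_lte(nrow(h), min(nrow(G$bonds), nrow(H$bonds)))
  }
})

test_that("reversing a mapping inverts the alignment and swaps the roles", {
  m <- example_networks()$serine_pair$network$mappings$RP00587
  r <- reverse_mapping(m)
  expect_equal(r$substrate_id, "C00078")
  expect_equal(r$product_id, "C00065")
  expect_equal(r$atom_pairs$sub_atom, m$atom_pairs$prod_atom)
  expect_equal(reverse_mapping(r)$atom_pairs, m$atom_pairs)
})
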