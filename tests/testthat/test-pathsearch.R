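test_that("the similarity/thermodynamics switches select the documented blend", {
  expect_equal(psi_to_alpha(TRUE, TRUE), 0.5)
  expect_equal(psi_to_alpha(TRUE, FALSE), 1.0)
  expect_equal(psi_to_alpha(FALSE, TRUE), 0.0)
  expect_true(is.na(psi_to_alpha(FALSE, FALSE)))
})

test_that("edge weights reproduce the worked values at every blend", {
  expect_equal(edge_weight(0.375, -64.5, weight_params(alpha = 0.5)), 0.469275)
  expect_equal(edge_weight(0.8, -19.9, weight_params(alpha = 0.5)), 0.259005)
  expect_equal(edge_weight(0.375, -64.5, weight_params(alpha = 1)), 0.625)
  expect_equal(edge_weight(0.8, -19.9, weight_params(alpha = 1)), 0.2)
  expect_equal(edge_weight(0.375, -64.5, weight_params(alpha = 0)), 0.31355)
  expect_equal(edge_weight(0.8, -19.9, weight_params(alpha = 0)), 0.31801)
  expect_equal(edge_weight(1, -3200, weight_params(alpha = 0.7)), 0)
})

test_that("edge weighting validates, substitutes and clamps", {
  expect_error(edge_weight(1.2, 0, weight_params()), class = "metapath_domain_error")
  p_sub <- weight_params(alpha = 0, missing_energy = 0)
  expect_equal(edge_weight(0.5, NA, p_sub), 0.32)
  p_ex <- weight_params(alpha = 0, missing_energy = "exclude")
  expect_true(is.na(edge_weight(0.5, NA, p_ex)))
  expect_warning(w <- edge_weight(0.5, -5000, weight_params(alpha = 0)))
  expect_equal(w, 0)
  expect_equal(edge_weight(0.3, -999, weight_params(alpha = NA)), 1)
})

test_that("the energy normalization maps the published extremes as printed", {
  expect_equal(normalized_energy_range(-2233.7, 10194.7), c(0.09663, 1.33947))
  expect_equal(normalized_energy_range(0, 0), c(0.32, 0.32))
  expect_equal(normalized_energy_range(-3200, 6800), c(0, 1))
})

test_that("weights stay in the documented envelope and respond monotonically", {
  set.seed(405)
  for (alpha in c(0, 0.25, 0.5, 0.75, 1)) {
    p <- weight_params(alpha = alpha)
    sims <- runif(50)
    fes <- runif(50, -2233.7, 10194.7)
    w <- edge_weight(sims, fes, p)
    expect_true(all(w >= alpha * 0 + (1 - alpha) * 0.09663 - 1e-12))
    expect_true(all(w <= alpha * 1 + (1 - alpha) * 1.33947 + 1e-12))
    if (alpha > 0) {
      expect_lt(edge_weight(0.9, 0, p), edge_weight(0.1, 0, p))
    }
    if (alpha < 1) {
      expect_gt(edge_weight(0.5, 100, p), edge_weight(0.5, -100, p))
    }
  }
})

test_that("the toy transfer graph keeps both routes and drops the broken branch", {
  fx <- example_networks()$toy_transfer
  cfg <- search_config("C1", "C6", k = 2, sc = FALSE, td = FALSE)
  tg <- cagtg_build(fx$network, cfg)
  expect_setequal(tg$nodes, fx$expect$gag_nodes)
  expect_setequal(unique(tg$edges$reaction_id), fx$expect$gag_reactions)
  expect_false("C8" %in% tg$nodes)
  expect_false("R8" %in% tg$edges$reaction_id)
  expect_true(all(vapply(tg$edges$groups, length, 0L) > 0L))
})

test_that("a start with no mappings yields a single-node graph and no pathways", {
  net <- reaction_network(list(
    compound_graph("A", data.frame(atom_id = "a1")),
    compound_graph("B", data.frame(atom_id = "a1"))
  ))
  tg <- cagtg_build(net, search_config("A", "B"))
  expect_equal(tg$nodes, "A")
  expect_equal(nrow(tg$edges), 0L)
  expect_equal(nrow(k_shortest(tg)), 0L)  # unreachable: empty, not an error
})

test_that("configuration and lookup errors are explicit", {
  net <- example_networks()$serine_chain$network
  expect_error(search_config("C00065", "C00065"), class = "metapath_config_error")
  expect_error(cagtg_build(net, search_config("C00065", "NOPE")),
               class = "metapath_reference_error")
})

test_that("k_shortest matches exhaustive enumeration on random graphs", {
  set.seed(406)
  for (rep in 1:40) {
    tg <- random_transfer_graph(n = sample(5:9, 1), p = 0.35)
    k <- sample(1:5, 1)
    got <- k_shortest(tg, k = k)
    want <- oracle_k_paths(tg, k)
    expect_equal(nrow(got), length(want))
    for (i in seq_along(want)) {
      expect_equal(got$compounds[[i]], want[[i]]$path)
      expect_equal(got$total_weight[i], want[[i]]$weight, tolerance = 1e-9)
    }
  }
})

test_that("the best pathway equals Dijkstra's shortest path", {
  set.seed(407)
  for (rep in 1:10) {
    tg <- random_transfer_graph(n = 8, p = 0.4)
    got <- k_shortest(tg, k = 1)
    g <- igraph::graph_from_data_frame(tg$edges[, c("from", "to")], directed = TRUE,
                                       vertices = data.frame(name = tg$nodes))
    d <- igraph::distances(g, v = tg$start, to = tg$target, mode = "out",
                           weights = tg$edges$weight)[1, 1]
    if (is.infinite(d)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$total_weight[1], d, tolerance = 1e-9)
    }
  }
})

test_that("a single-edge graph returns one pathway however large k is", {
  tg <- transfer_graph(c("A", "B"),
                       tibble::tibble(from = "A", to = "B", weight = 0.5,
                                      reaction_id = "R1"),
                       start = "A", target = "B")
  ps <- k_shortest(tg, k = 3)
  expect_equal(nrow(ps), 1L)
  expect_equal(ps$compounds[[1]], c("A", "B"))
})

test_that("equal-weight pathways are ordered deterministically", {
  edges <- tibble::tibble(
    from = c("A", "A", "B", "C"),
    to = c("B", "C", "D", "D"),
    weight = 1,
    reaction_id = c("R1", "R2", "R3", "R4")
  )
  tg <- transfer_graph(c("A", "B", "C", "D"), edges, "A", "D")
  ps <- k_shortest(tg, k = 2)
  expect_equal(ps$compounds[[1]], c("A", "B", "D"))
  expect_equal(ps$compounds[[2]], c("A", "C", "D"))
})

test_that("the serine chain search reproduces the worked total weight", {
  fx <- example_networks()$serine_chain
  ps <- find_pathways(fx$network, search_config("C00065", "C00398", k = 1))
  expect_equal(nrow(ps), 1L)
  expect_equal(ps$compounds[[1]], fx$expect$top_path)
  expect_equal(ps$steps[[1]]$weight, fx$expect$weights_alpha_half)
  expect_equal(ps$total_weight[1], fx$expect$top_total_weight)
  # thermodynamics-only blend
  ps0 <- find_pathways(fx$network,
                       search_config("C00065", "C00398", k = 1, sc = FALSE, td = TRUE))
  expect_equal(ps0$steps[[1]]$weight, fx$expect$weights_alpha_zero)
  # similarity-only blend
  ps1 <- find_pathways(fx$network,
                       search_config("C00065", "C00398", k = 1, sc = TRUE, td = FALSE))
  expect_equal(ps1$steps[[1]]$weight, fx$expect$weights_alpha_one)
})

test_that("every returned pathway conserves a group under tracking, replayed independently", {
  set.seed(408)
  for (seed in c(21, 22, 23)) {
    gen <- generate_network(synth_config(seed = seed))
    gt <- gen$ground_truth
    cfg <- search_config(gt$start, gt$target, k = 3, min_group_size = 2)
    tg <- cagtg_build(gen$network, cfg)
    ps <- k_shortest(tg)
    expect_gte(nrow(ps), 1L)
    for (i in seq_len(nrow(ps))) {
      gs <- metapath:::replay_groups(tg, ps$compounds[[i]])
      expect_gte(length(gs), 1L)
      expect_true(all(group_sizes(gs) >= 2L))
    }
  }
})

test_that("group tracking excludes decoy hubs that untracked search walks through", {
  gen <- generate_network(synth_config(seed = 31))
  gt <- gen$ground_truth
  hubs <- grep("^C8", names(gen$network$compounds), value = TRUE)
  tracked <- find_pathways(gen$network,
                           search_config(gt$start, gt$target, k = 5,
                                         min_group_size = gt$group_size))
  internal <- unlist(lapply(tracked$compounds, function(p) p[-c(1, length(p))]))
  expect_false(any(internal %in% hubs))
  expect_equal(tracked$compounds[[1]], gt$compounds)

  untracked <- find_pathways(gen$network,
                             search_config(gt$start, gt$target, k = 5,
                                           tracking = "none"))
  internal_un <- unlist(lapply(untracked$compounds, function(p) p[-c(1, length(p))]))
  expect_true(any(internal_un %in% hubs))
})

test_that("max-group mode ranks the pathway with the largest delivered group first", {
  fx <- example_networks()$toy_transfer
  # under group mode with unit weights the C2 route wins lexicographically,
  # but the C3 route delivers a 3-atom group vs the C2 route's 2 atoms
  cfg <- search_config("C1", "C6", k = 2, sc = FALSE, td = FALSE,
                       tracking = "max-group")
  ps <- find_pathways(fx$network, cfg)
  expect_equal(ps$compounds[[1]], c("C1", "C3", "C5", "C6"))
  expect_equal(max(group_sizes(ps$conserved_groups[[1]])), 3L)
})

test_that("tidy, glance and plots summarise a pathway set", {
  fx <- example_networks()$serine_chain
  ps <- find_pathways(fx$network, search_config("C00065", "C00398", k = 1))
  td <- tidy(ps)
  expect_equal(nrow(td), 2L)
  expect_equal(td$weight, fx$expect$weights_alpha_half)
  gl <- glance(ps)
  expect_equal(gl$n_pathways, 1L)
  expect_equal(gl$best_weight, fx$expect$top_total_weight)
  expect_s3_class(autoplot(ps), "ggplot")
  tg <- cagtg_build(fx$network, search_config("C00065", "C00398"))
  expect_s3_class(autoplot(tg), "ggplot")
})
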