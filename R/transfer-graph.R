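#' Configure a pathway search
#'
#' @param start,target Compound ids (must differ).
#' @param k Number of pathways to return (`k >= 1`).
#' @param min_group_size Minimum conserved-group size `L` in atoms
#'   (`L >= 1`). Hydrogens only count when the network keeps them.
#' @param sc,td Boolean switches selecting the weighting blend, see
#'   [psi_to_alpha()].
#' @param tracking Group-tracking mode: `"group"` (default) requires every
#'   edge and every returned pathway to conserve a group of size at least
#'   `min_group_size`; `"max-group"` additionally re-ranks pathways by the
#'   size of the largest group delivered to the target (descending, then by
#'   weight); `"none"` skips group tracking entirely (pure weighted search).
#' @param reversible Consider every mapping entry in both directions, with
#'   the atom alignment inverted and the energy negated for the reverse
#'   direction (default `TRUE`; reactant-pair alignments describe reversible
#'   transformations).
#' @param max_path_length Hop cap on returned pathways (safety guard for
#'   pathological graphs; default 25).
#' @return An object of class `search_config`.
#' @export
search_config <- function(start, target, k = 10, min_group_size = 1,
                          sc = TRUE, td = TRUE,
                          tracking = c("group", "max-group", "none"),
                          reversible = TRUE, max_path_length = 25) {
  tracking <- match.arg(tracking)
  stopifnot(is.character(start), is.character(target),
            length(start) == 1L, length(target) == 1L)
  if (identical(start, target)) {
    abort_config("`start` and `target` must be different compounds.")
  }
  if (!is.numeric(k) || k < 1) abort_config("`k` must be >= 1.")
  if (!is.numeric(min_group_size) || min_group_size < 1) {
    abort_config("`min_group_size` must be >= 1.")
  }
  structure(
    list(start = start, target = target, k = as.integer(k),
         min_group_size = as.integer(min_group_size),
         sc = isTRUE(sc), td = isTRUE(td), tracking = tracking,
         reversible = isTRUE(reversible),
         max_path_length = as.integer(max_path_length)),
    class = "search_config"
  )
}

#' Construct a transfer graph directly
#'
#' Low-level constructor for a weighted, directed metabolite graph, mainly
#' useful for testing path extraction in isolation. [cagtg_build()] is the
#' normal way to obtain one.
#'
#' @param nodes Character vector of compound ids.
#' @param edges Tibble with at least `from`, `to`, `weight`; optional
#'   `reaction_id`, `entry_id`, `direction`, `sim`, `dg_prime_r`, `groups`.
#' @param start,target Endpoints of the search the graph was built for.
#' @param cfg A [search_config()]; defaults to an untracked search between
#'   the endpoints.
#' @param network The backing [reaction_network()], if any (needed to replay
#'   group transfers along paths).
#' @return An object of class `transfer_graph`.
#' @export
transfer_graph <- function(nodes, edges, start, target, cfg = NULL, network = NULL) {
  edges <- as_tibble(edges)
  stopifnot(all(c("from", "to", "weight") %in% names(edges)))
  for (col in c("reaction_id", "entry_id", "direction")) {
    if (!col %in% names(edges)) edges[[col]] <- NA_character_
  }
  for (col in c("sim", "dg_prime_r")) {
    if (!col %in% names(edges)) edges[[col]] <- NA_real_
  }
  if (!"groups" %in% names(edges)) edges$groups <- vector("list", nrow(edges))
  if (any(edges$weight < 0, na.rm = TRUE)) {
    abort_domain("transfer-graph edge weights must be nonnegative.")
  }
  bad <- setdiff(c(edges$from, edges$to), nodes)
  if (length(bad)) abort_ref(sprintf("edge endpoint '%s' is not a node.", bad[1]))
  if (is.null(cfg)) {
    cfg <- search_config(start, target, tracking = "none")
  }
  structure(
    list(nodes = sort(unique(nodes)), edges = edges, start = start,
         target = target, cfg = cfg, network = network),
    class = "transfer_graph"
  )
}

#' @export
print.transfer_graph <- function(x, ...) {
  cat(sprintf("<transfer_graph> %s -> %s: %d nodes, %d edges (tracking: %s)\n",
              x$start, x$target, length(x$nodes), nrow(x$edges), x$cfg$tracking))
  invisible(x)
}

# Directed adjacency candidates derived from the mapping entries:
# one row per (from, to, entry, direction).
adjacency_candidates <- function(net, reversible) {
  rows <- lapply(net$mappings, function(m) {
    r <- tibble(from = m$substrate_id, to = m$product_id,
                entry_id = m$entry_id, direction = "forward")
    if (reversible) {
      r <- dplyr::bind_rows(r, tibble(from = m$product_id, to = m$substrate_id,
                                      entry_id = m$entry_id, direction = "reverse"))
    }
    r
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble(from = character(), to = character(),
                  entry_id = character(), direction = character())
  }
  out[out$from != out$to, , drop = FALSE]
}

# Evaluate the best (entry, reaction) choice for an ordered compound pair,
# given the substrate's stored conserved group set. Returns NULL when no
# candidate survives (empty transfer in group mode, or all energies missing
# under the exclude policy).
best_edge <- function(net, vi, vj, groups_vi, cands, cfg, params) {
  G <- net$compounds[[vi]]
  H <- net$compounds[[vj]]
  sim <- similarity_of(net, vi, vj)
  best <- NULL
  for (ci in seq_len(nrow(cands))) {
    m <- net$mappings[[cands$entry_id[ci]]]
    if (cands$direction[ci] == "reverse") m <- reverse_mapping(m)
    S <- NULL
    if (cfg$tracking != "none") {
      h <- derive_edge_mapping(G, H, m)
      S <- cagm(groups_vi, h, H, L = cfg$min_group_size)$groups
      if (length(S) == 0L) next
    }
    for (rid in m$reaction_ids) {
      fe_raw <- energy_of(net, rid)
      fe <- if (cands$direction[ci] == "reverse") -fe_raw else fe_raw
      w <- edge_weight(sim, fe, params)
      if (is.na(w)) next  # missing energy under the exclude policy
      cand <- list(entry_id = m$entry_id, direction = cands$direction[ci],
                   reaction_id = rid, weight = w, sim = sim, fe = fe, S = S)
      if (is.null(best) ||
          cand$weight < best$weight - 1e-12 ||
          (abs(cand$weight - best$weight) <= 1e-12 &&
           (cand$entry_id < best$entry_id ||
            (cand$entry_id == best$entry_id && cand$reaction_id < best$reaction_id)))) {
        best <- cand
      }
    }
  }
  best
}

#' Build the atomic-group transfer graph between two compounds
#'
#' Breadth-first construction from the start compound: the start is seeded
#' with its full structure as conserved group set; each popped non-target
#' node expands to its adjacent compounds, the conserved groups transferred
#' across the connecting reaction are computed with [cagm()], and only
#' transfers that leave at least one group of the configured minimum size
#' produce an edge. A compound is marked visited on first encounter even when
#' the transfer breaks every group, so it is never revisited from another
#' predecessor; each node stores the group set delivered by its first
#' discoverer. Edges between already-discovered nodes are still added when
#' the transfer conserves a group, so alternative routes to the same compound
#' are kept.
#'
#' With `tracking = "none"` the group computation is skipped and every
#' adjacent pair is connected.
#'
#' @param net A [reaction_network()].
#' @param cfg A [search_config()].
#' @param params A [weight_params()]; by default derived from the config's
#'   `sc`/`td` switches via [psi_to_alpha()].
#' @return A [transfer_graph()].
#' @export
cagtg_build <- function(net, cfg, params = NULL) {
  stopifnot(inherits(net, "reaction_network"), inherits(cfg, "search_config"))
  if (is.null(params)) params <- weight_params(alpha = psi_to_alpha(cfg$sc, cfg$td))
  for (id in c(cfg$start, cfg$target)) {
    if (!id %in% names(net$compounds)) {
      abort_ref(sprintf("compound '%s' is not in the network.", id))
    }
  }

  cands_all <- adjacency_candidates(net, cfg$reversible)
  visited <- stats::setNames(logical(length(net$compounds)), names(net$compounds))
  stored <- list()
  stored[[cfg$start]] <- initial_group_set(net$compounds[[cfg$start]])
  nodes <- cfg$start
  visited[[cfg$start]] <- TRUE
  queue <- cfg$start
  edge_rows <- list()
  edge_seen <- character()

  while (length(queue)) {
    vi <- queue[[1]]
    queue <- queue[-1]
    if (identical(vi, cfg$target)) next
    nbr <- cands_all[cands_all$from == vi, , drop = FALSE]
    for (vj in sort(unique(nbr$to))) {
      ekey <- paste(vi, vj, sep = "->")
      if (!visited[[vj]]) {
        res <- best_edge(net, vi, vj, stored[[vi]], nbr[nbr$to == vj, ], cfg, params)
        visited[[vj]] <- TRUE
        if (!is.null(res)) {
          nodes <- c(nodes, vj)
          stored[[vj]] <- res$S
          queue <- c(queue, vj)
          edge_rows[[ekey]] <- res
          edge_seen <- c(edge_seen, ekey)
        }
      } else if (vj %in% nodes && !ekey %in% edge_seen) {
        # vj already in the graph through another predecessor: keep the
        # alternative route when it, too, conserves a group
        res <- best_edge(net, vi, vj, stored[[vi]], nbr[nbr$to == vj, ], cfg, params)
        if (!is.null(res)) {
          edge_rows[[ekey]] <- res
          edge_seen <- c(edge_seen, ekey)
        }
      }
    }
  }

  edges <- if (length(edge_rows)) {
    dplyr::bind_rows(lapply(names(edge_rows), function(k) {
      r <- edge_rows[[k]]
      ft <- strsplit(k, "->", fixed = TRUE)[[1]]
      tibble(from = ft[1], to = ft[2], reaction_id = r$reaction_id,
             entry_id = r$entry_id, direction = r$direction,
             weight = r$weight, sim = r$sim, dg_prime_r = r$fe,
             groups = list(r$S))
    }))
  } else {
    tibble(from = character(), to = character(), reaction_id = character(),
           entry_id = character(), direction = character(), weight = numeric(),
           sim = numeric(), dg_prime_r = numeric(), groups = list())
  }
  transfer_graph(nodes, edges, cfg$start, cfg$target, cfg = cfg, network = net)
}

# Replay the group transfer along a concrete compound path, composing cagm
# across the recorded (entry, direction) of each edge. Returns the group set
# delivered to the last compound (possibly empty).
replay_groups <- function(tg, compounds_seq) {
  net <- tg$network
  if (is.null(net)) return(NULL)
  gs <- initial_group_set(net$compounds[[compounds_seq[1]]])
  L <- tg$cfg$min_group_size
  for (i in seq_len(length(compounds_seq) - 1L)) {
    vi <- compounds_seq[i]
    vj <- compounds_seq[i + 1L]
    e <- tg$edges[tg$edges$from == vi & tg$edges$to == vj, ]
    if (!nrow(e)) return(NULL)
    m <- net$mappings[[e$entry_id[1]]]
    if (e$direction[1] == "reverse") m <- reverse_mapping(m)
    h <- derive_edge_mapping(net$compounds[[vi]], net$compounds[[vj]], m)
    gs <- cagm(gs, h, net$compounds[[vj]], L = L)$groups
    if (length(gs) == 0L) return(gs)
  }
  gs
}

#' Plot a transfer graph
#'
#' Quick diagnostic layout of the weighted transfer graph: nodes are
#' compounds, arrows are reaction edges labelled by weight, the start and
#' target are highlighted.
#'
#' @param object A [transfer_graph()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.transfer_graph <- function(object, ...) {
  g <- igraph::graph_from_data_frame(
    object$edges[, c("from", "to")], directed = TRUE,
    vertices = data.frame(name = object$nodes)
  )
  xy <- igraph::layout_with_fr(g)
  lay <- tibble(name = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
  seg <- dplyr::left_join(object$edges, lay, by = c("from" = "name"))
  seg <- dplyr::left_join(seg, lay, by = c("to" = "name"), suffix = c("", "end"))
  lay$role <- ifelse(lay$name == object$start, "start",
                     ifelse(lay$name == object$target, "target", "intermediate"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "grey50"
    ) +
    ggplot2::geom_point(data = lay,
                        ggplot2::aes(x = .data$x, y = .data$y, colour = .data$role),
                        size = 3) +
    ggplot2::geom_text(data = lay,
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$name),
                       vjust = -1, size = 3) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = NULL)
}
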