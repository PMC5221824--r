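# Path comparison used everywhere ties can arise: ascending total weight,
# then fewer hops, then lexicographic compound sequence. Returns TRUE when a
# is strictly better than b.
path_better <- function(wa, pa, wb, pb, eps = 1e-12) {
  if (wa < wb - eps) return(TRUE)
  if (wa > wb + eps) return(FALSE)
  if (length(pa) != length(pb)) return(length(pa) < length(pb))
  for (i in seq_along(pa)) {
    if (pa[i] != pb[i]) return(pa[i] < pb[i])
  }
  FALSE
}

# Deterministic Dijkstra on nonnegative weights with the tie-break above.
# adj: list keyed by node of tibbles (to, weight). Removed nodes/edges allow
# the spur computations of the k-shortest loop.
dijkstra_path <- function(nodes, adj, src, dst, removed_nodes = character(),
                          removed_edges = character()) {
  nodes <- setdiff(nodes, removed_nodes)
  if (!src %in% nodes || !dst %in% nodes) return(NULL)
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  paths <- stats::setNames(vector("list", length(nodes)), nodes)
  done <- stats::setNames(logical(length(nodes)), nodes)
  dist[[src]] <- 0
  paths[[src]] <- src
  repeat {
    u <- NA_character_
    for (v in nodes) {
      if (done[[v]] || is.infinite(dist[[v]])) next
      if (is.na(u) || path_better(dist[[v]], paths[[v]], dist[[u]], paths[[u]])) u <- v
    }
    if (is.na(u)) break
    if (u == dst) break
    done[[u]] <- TRUE
    nb <- adj[[u]]
    if (is.null(nb) || !nrow(nb)) next
    for (i in seq_len(nrow(nb))) {
      v <- nb$to[i]
      if (!v %in% nodes || done[[v]]) next
      if (paste(u, v, sep = "->") %in% removed_edges) next
      nd <- dist[[u]] + nb$weight[i]
      np <- c(paths[[u]], v)
      if (path_better(nd, np, dist[[v]], paths[[v]] %||% character())) {
        dist[[v]] <- nd
        paths[[v]] <- np
      }
    }
  }
  if (is.infinite(dist[[dst]])) return(NULL)
  list(weight = dist[[dst]], path = paths[[dst]])
}

# Yen's loopless k-shortest paths with deterministic tie-breaking.
yen_paths <- function(tg, K) {
  edges <- tg$edges
  if (!nrow(edges)) return(list())
  adj <- split(edges[, c("to", "weight")], edges$from)
  wt_of <- function(p) {
    key <- paste(p[-length(p)], p[-1], sep = "->")
    i <- match(key, paste(edges$from, edges$to, sep = "->"))
    sum(edges$weight[i])
  }
  first <- dijkstra_path(tg$nodes, adj, tg$start, tg$target)
  if (is.null(first)) return(list())
  A <- list(first)
  B <- list()
  while (length(A) < K) {
    prev <- A[[length(A)]]$path
    for (j in seq_len(length(prev) - 1L)) {
      spur <- prev[j]
      root <- prev[seq_len(j)]
      removed_edges <- character()
      for (p in A) {
        if (length(p$path) > j && identical(p$path[seq_len(j)], root)) {
          removed_edges <- c(removed_edges, paste(p$path[j], p$path[j + 1L], sep = "->"))
        }
      }
      removed_nodes <- root[-length(root)]
      sp <- dijkstra_path(tg$nodes, adj, spur, tg$target,
                          removed_nodes = removed_nodes,
                          removed_edges = unique(removed_edges))
      if (is.null(sp)) next
      cand_path <- c(root[-length(root)], sp$path)
      if (anyDuplicated(cand_path)) next
      cand <- list(weight = wt_of(cand_path), path = cand_path)
      dup <- any(vapply(c(A, B), function(x) identical(x$path, cand_path), TRUE))
      if (!dup) B[[length(B) + 1L]] <- cand
    }
    if (!length(B)) break
    best_i <- 1L
    for (i in seq_along(B)) {
      if (path_better(B[[i]]$weight, B[[i]]$path, B[[best_i]]$weight, B[[best_i]]$path)) {
        best_i <- i
      }
    }
    A[[length(A) + 1L]] <- B[[best_i]]
    B <- B[-best_i]
  }
  A
}

#' Extract the top k loop-free pathways from a transfer graph
#'
#' Yen's loopless k-shortest-paths algorithm over the nonnegative edge
#' weights, with deterministic tie-breaking (smaller total weight, then fewer
#' hops, then lexicographic compound sequence). When the graph was built with
#' group tracking, the conserved groups are replayed along every candidate
#' path with [cagm()] and pathways whose replayed target group set is empty
#' are discarded (enumeration continues until `k` conserving pathways are
#' found or the graph is exhausted). In `"max-group"` mode pathways are
#' re-ranked by the size of the largest group delivered to the target
#' (descending), then by weight.
#'
#' @param tg A [transfer_graph()].
#' @param k Number of pathways (defaults to the graph's search config).
#' @return A `pathway_set`: a tibble with one row per pathway (columns
#'   `rank`, `total_weight`, `n_steps`, `compounds`, `reactions`, `steps`,
#'   `conserved_groups`). An unreachable target yields an empty set, not an
#'   error.
#' @export
k_shortest <- function(tg, k = NULL) {
  stopifnot(inherits(tg, "transfer_graph"))
  cfg <- tg$cfg
  k <- k %||% cfg$k
  if (k < 1) abort_config("`k` must be >= 1.")

  track <- cfg$tracking != "none" && !is.null(tg$network)
  keep <- list()
  K <- as.integer(k)
  repeat {
    raw <- yen_paths(tg, K)
    raw <- raw[vapply(raw, function(p) length(p$path) - 1L <= cfg$max_path_length, TRUE)]
    keep <- list()
    for (p in raw) {
      gs <- if (track) replay_groups(tg, p$path) else NULL
      if (track && cfg$tracking == "group" && length(gs) == 0L) next
      p$groups <- gs
      keep[[length(keep) + 1L]] <- p
      if (cfg$tracking != "max-group" && length(keep) >= k) break
    }
    enough <- length(keep) >= k || length(raw) < K
    if (!track || enough) break
    K <- K * 2L
    if (K > 64L * k) break  # graph effectively exhausted
  }

  if (cfg$tracking == "max-group" && length(keep)) {
    gsz <- vapply(keep, function(p) {
      if (length(p$groups)) max(group_sizes(p$groups)) else 0L
    }, 0L)
    ord <- order(-gsz, vapply(keep, `[[`, 0, "weight"),
                 vapply(keep, function(p) length(p$path), 0L))
    keep <- keep[ord]
  }
  keep <- keep[seq_len(min(k, length(keep)))]
  new_pathway_set(keep, tg)
}

new_pathway_set <- function(paths, tg) {
  edges <- tg$edges
  ekey <- paste(edges$from, edges$to, sep = "->")
  rows <- lapply(seq_along(paths), function(r) {
    p <- paths[[r]]
    n <- length(p$path) - 1L
    i <- match(paste(p$path[-(n + 1L)], p$path[-1], sep = "->"), ekey)
    steps <- tibble(
      step = seq_len(n),
      from = p$path[-(n + 1L)],
      to = p$path[-1],
      reaction_id = edges$reaction_id[i],
      entry_id = edges$entry_id[i],
      dg_prime_r = edges$dg_prime_r[i],
      sim = edges$sim[i],
      weight = edges$weight[i]
    )
    tibble(
      rank = r,
      total_weight = p$weight,
      n_steps = n,
      compounds = list(p$path),
      reactions = list(steps$reaction_id),
      steps = list(steps),
      conserved_groups = list(p$groups)
    )
  })
  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble(rank = integer(), total_weight = numeric(), n_steps = integer(),
           compounds = list(), reactions = list(), steps = list(),
           conserved_groups = list())
  }
  structure(out, class = c("pathway_set", class(out)),
            start = tg$start, target = tg$target, cfg = tg$cfg)
}

#' Find ranked pathways between two compounds
#'
#' End-to-end search: derives the weighting blend from the config's `sc`/`td`
#' switches, builds the atomic-group transfer graph with [cagtg_build()] and
#' extracts the top k loop-free pathways with [k_shortest()]. Deterministic
#' for fixed inputs.
#'
#' @param net A [reaction_network()].
#' @param cfg A [search_config()].
#' @param params Optional [weight_params()] override.
#' @return A `pathway_set` (possibly empty when the target is unreachable).
#' @examples
#' fx <- example_networks()$serine_chain
#' find_pathways(fx$network, search_config("C00065", "C00398", k = 1))
#' @export
find_pathways <- function(net, cfg, params = NULL) {
  tg <- cagtg_build(net, cfg, params = params)
  k_shortest(tg)
}

#' @export
print.pathway_set <- function(x, ...) {
  cat(sprintf("<pathway_set> %s -> %s: %d pathway(s)\n",
              attr(x, "start"), attr(x, "target"), nrow(x)))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %d. [w = %.6g] %s\n", x$rank[i], x$total_weight[i],
                paste(x$compounds[[i]], collapse = " -> ")))
  }
  invisible(x)
}

#' Tidy a pathway set into one row per reaction step
#'
#' @param x A `pathway_set` from [find_pathways()] or [k_shortest()].
#' @param ... Unused.
#' @return A tibble with columns `rank`, `step`, `from`, `to`, `reaction_id`,
#'   `entry_id`, `dg_prime_r`, `sim`, `weight`.
#' @export
tidy.pathway_set <- function(x, ...) {
  if (!nrow(x)) {
    return(tibble(rank = integer(), step = integer(), from = character(),
                  to = character(), reaction_id = character(),
                  entry_id = character(), dg_prime_r = numeric(),
                  sim = numeric(), weight = numeric()))
  }
  dplyr::bind_rows(lapply(seq_len(nrow(x)), function(i) {
    dplyr::mutate(x$steps[[i]], rank = x$rank[i], .before = 1)
  }))
}

#' One-row summary of a pathway set
#'
#' @param x A `pathway_set`.
#' @param ... Unused.
#' @return A tibble with `n_pathways`, `best_weight`, `mean_length` and the
#'   size of the largest conserved group delivered by the best pathway.
#' @export
glance.pathway_set <- function(x, ...) {
  best_group <- NA_integer_
  if (nrow(x) && length(x$conserved_groups[[1]])) {
    best_group <- max(group_sizes(x$conserved_groups[[1]]))
  }
  tibble(
    n_pathways = nrow(x),
    best_weight = if (nrow(x)) x$total_weight[1] else NA_real_,
    mean_length = if (nrow(x)) mean(x$n_steps) else NA_real_,
    best_max_group = best_group
  )
}

#' Plot pathway weights by rank
#'
#' @param object A `pathway_set`.
#' @param ... Unused.
#' @return A ggplot object: per-step weights stacked by pathway rank.
#' @export
autoplot.pathway_set <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$rank), y = .data$weight,
                                  fill = .data$reaction_id)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "pathway rank", y = "total weight", fill = "reaction") +
    ggplot2::theme_minimal()
}
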