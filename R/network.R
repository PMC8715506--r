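#' Dynamical network analysis
#'
#' A graph over residues: nodes are residues, an edge joins two
#' non-neighbouring residues whose heavy atoms are within the contact
#' cutoff (4.5 Angstrom) in more than the occupancy fraction (75%) of
#' frames, and each edge carries the weight `w_ij = -ln|C_ij|` where `C_ij`
#' is the normalised cross-correlation of C-alpha displacement vectors.
#' Strongly correlated contacts are light (near-zero weight), so shortest
#' paths trace likely allosteric communication routes; Girvan-Newman edge
#' removal partitions the network into communities, and the
#' highest-betweenness inter-community edges mark critical nodes.
#'
#' @name network
NULL

#' Contact edges from heavy-atom proximity
#'
#' An edge `(i, j)` is retained iff the fraction of frames in which the
#' minimum heavy-atom distance between residues i and j is within `cutoff`
#' strictly exceeds `occupancy`. Sequence neighbours (`|i - j| <= 1` in
#' residue order) are excluded so trivial backbone contacts do not dominate
#' paths.
#'
#' @param ensemble An `ensemble`.
#' @param model Matching `structure_model`.
#' @param cutoff Contact cutoff, Angstrom (default 4.5).
#' @param occupancy Occupancy threshold, fraction (default 0.75, strict).
#' @return Tibble: `residue_a`, `residue_b`, `occupancy`.
#' @export
contact_edges <- function(ensemble, model, cutoff = 4.5, occupancy = 0.75) {
  pairs <- default_pairs(model, min_sep = 2)
  mind <- pair_min_heavy_dist(ensemble, model, pairs)
  occ <- colMeans(mind <= cutoff)
  keep <- occ > occupancy
  tibble(
    residue_a = pairs$residue_a[keep],
    residue_b = pairs$residue_b[keep],
    occupancy = occ[keep]
  )
}

#' C-alpha displacement cross-correlation matrix
#'
#' Frames are superposed on the core selection, then
#' `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)` over displacement
#' vectors from the time-average positions. Residues with zero fluctuation
#' get off-diagonal correlation 0 (flagged with a warning) and diagonal 1.
#'
#' @param ensemble An `ensemble` (>= 3 frames).
#' @param model Matching `structure_model`.
#' @param superpose Superpose frames on the core first (default `TRUE`).
#' @param core Core atom indices for the superposition.
#' @return residues x residues symmetric matrix with unit diagonal,
#'   dimnames = residue ids.
#' @export
correlation_matrix <- function(ensemble, model, superpose = TRUE, core = NULL) {
  if (ensemble$frame_count < 3) abort("correlation requires at least 3 frames")
  e <- if (superpose) superpose_ensemble(ensemble, model, core) else ensemble
  ca_idx <- unname(model$ca_index)
  ids <- as.integer(names(model$ca_index))
  dx <- e$coords[, ca_idx, 1]
  dy <- e$coords[, ca_idx, 2]
  dz <- e$coords[, ca_idx, 3]
  dx <- sweep(dx, 2, colMeans(dx))
  dy <- sweep(dy, 2, colMeans(dy))
  dz <- sweep(dz, 2, colMeans(dz))
  num <- crossprod(dx) + crossprod(dy) + crossprod(dz)
  msf <- diag(num)
  frozen <- msf <= 0
  if (any(frozen)) {
    warn(sprintf(
      "%d residue(s) with zero fluctuation; correlations set to 0", sum(frozen)
    ))
    msf[frozen] <- 1
  }
  cmat <- num / sqrt(outer(msf, msf))
  if (any(frozen)) {
    cmat[frozen, ] <- 0
    cmat[, frozen] <- 0
  }
  diag(cmat) <- 1
  cmat <- (cmat + t(cmat)) / 2
  dimnames(cmat) <- list(ids, ids)
  stopifnot(all(abs(cmat) <= 1 + 1e-9))
  cmat
}

#' Build a dynamic network from contacts and correlations
#'
#' Edge weight is `-ln|C_ij|`, capped at `w_max` (edges with
#' `|C| < exp(-w_max)`, including `C = 0`, are effectively
#' non-conductive). Weighted edge betweenness (weights as distances) is
#' computed on the full graph.
#'
#' @param edges Contact edge tibble from [contact_edges()].
#' @param c_matrix Correlation matrix from [correlation_matrix()].
#' @param w_max Weight cap (default 20).
#' @return A `dynamic_network`.
#' @export
build_network <- function(edges, c_matrix, w_max = 20) {
  ids <- as.integer(rownames(c_matrix))
  missing <- setdiff(unique(c(edges$residue_a, edges$residue_b)), ids)
  if (length(missing) > 0) {
    abort(paste0("no correlation available for residue(s): ", paste(missing, collapse = ", ")))
  }
  corr <- c_matrix[cbind(
    match(edges$residue_a, ids),
    match(edges$residue_b, ids)
  )]
  weight <- pmin(-log(pmax(abs(corr), exp(-w_max))), w_max)
  g <- igraph::graph_from_data_frame(
    data.frame(
      from = as.character(edges$residue_a),
      to = as.character(edges$residue_b),
      occupancy = edges$occupancy,
      correlation = corr,
      weight = weight
    ),
    directed = FALSE,
    vertices = data.frame(name = as.character(ids))
  )
  btw <- if (igraph::ecount(g) > 0) {
    # |C| = 1 edges have weight 0; betweenness needs strictly positive costs
    igraph::edge_betweenness(g,
      weights = pmax(igraph::E(g)$weight, 1e-8), directed = FALSE
    )
  } else {
    numeric(0)
  }
  structure(
    list(
      graph = g,
      edges = tibble(
        residue_a = edges$residue_a, residue_b = edges$residue_b,
        occupancy = edges$occupancy, correlation = corr,
        weight = weight, betweenness = btw
      ),
      nodes = ids,
      w_max = w_max,
      communities = NULL,
      modularity = NA_real_
    ),
    class = "dynamic_network"
  )
}

#' @export
print.dynamic_network <- function(x, ...) {
  cat(sprintf(
    "<dynamic_network> %d nodes, %d edges%s\n",
    length(x$nodes), nrow(x$edges),
    if (is.null(x$communities)) {
      ""
    } else {
      sprintf(
        ", %d communities (modularity %.3f)",
        length(unique(x$communities$community)), x$modularity
      )
    }
  ))
  invisible(x)
}

#' @rdname tidy_allokit
#' @export
tidy.dynamic_network <- function(x, ...) x$edges

#' @rdname tidy_allokit
#' @export
glance.dynamic_network <- function(x, ...) {
  tibble(
    n_nodes = length(x$nodes), n_edges = nrow(x$edges),
    n_communities = if (is.null(x$communities)) {
      NA_integer_
    } else {
      length(unique(x$communities$community))
    },
    modularity = x$modularity
  )
}

# deterministic argmax over edges: max value, ties broken by (a, b) order
pick_max_edge <- function(ends_a, ends_b, values) {
  cand <- which(values >= max(values) - 1e-12)
  cand[order(ends_a[cand], ends_b[cand])][1]
}

#' Girvan-Newman community detection
#'
#' Iteratively removes the edge of highest weighted edge betweenness
#' (weights as distances; ties broken by lexicographic edge id) and, among
#' the nested partitions produced, returns the one maximizing modularity.
#' Because the edge weights are distances, modularity is evaluated with the
#' correlation magnitudes `|C_ij|` as connection strengths.
#'
#' @param net A `dynamic_network` with >= 1 edge.
#' @return The network with `communities` (tibble `residue_id`,
#'   `community`) and `modularity` filled in, plus attributes
#'   `removal_order` (tibble of removed edges in order) available via
#'   `gn_removal_order()`.
#' @export
girvan_newman <- function(net) {
  stopifnot(inherits(net, "dynamic_network"))
  g <- net$graph
  if (igraph::ecount(g) == 0) abort("empty graph: no edges to remove")
  strengths <- abs(igraph::E(g)$correlation)
  score_partition <- function(membership) {
    igraph::modularity(g, membership, weights = strengths)
  }
  g2 <- g
  best_membership <- igraph::components(g2)$membership
  best_mod <- score_partition(best_membership)
  removed <- list()
  step <- 0
  while (igraph::ecount(g2) > 0) {
    eb <- igraph::edge_betweenness(g2,
      weights = pmax(igraph::E(g2)$weight, 1e-8), directed = FALSE
    )
    ends <- igraph::ends(g2, igraph::E(g2))
    a <- pmin(as.integer(ends[, 1]), as.integer(ends[, 2]))
    b <- pmax(as.integer(ends[, 1]), as.integer(ends[, 2]))
    pick <- pick_max_edge(a, b, eb)
    step <- step + 1
    removed[[step]] <- tibble(
      step = step, residue_a = a[pick], residue_b = b[pick], betweenness = eb[pick]
    )
    g2 <- igraph::delete_edges(g2, igraph::E(g2)[pick])
    membership <- igraph::components(g2)$membership
    mod <- score_partition(membership)
    if (mod > best_mod + 1e-12) {
      best_mod <- mod
      best_membership <- membership
    }
  }
  net$communities <- tibble(
    residue_id = as.integer(igraph::V(g)$name),
    community = as.integer(best_membership)
  )
  net$modularity <- best_mod
  attr(net, "removal_order") <- dplyr::bind_rows(removed)
  net
}

#' Edge-removal order of the last Girvan-Newman run
#'
#' @param net A `dynamic_network` returned by [girvan_newman()].
#' @return Tibble: `step`, `residue_a`, `residue_b`, `betweenness`.
#' @export
gn_removal_order <- function(net) {
  out <- attr(net, "removal_order")
  if (is.null(out)) abort("run girvan_newman() first")
  out
}

#' Critical nodes connecting neighbouring communities
#'
#' For every pair of communities joined by at least one edge, reports the
#' inter-community edge of maximum (full-graph, weighted) edge betweenness;
#' its endpoints are the critical nodes.
#'
#' @param net A `dynamic_network` with communities assigned.
#' @return Tibble: `node_a`, `node_b`, `community_a`, `community_b`,
#'   `betweenness`. Empty when there is a single community.
#' @export
critical_nodes <- function(net) {
  if (is.null(net$communities)) abort("run girvan_newman() first")
  comm <- stats::setNames(net$communities$community, net$communities$residue_id)
  e <- net$edges |>
    mutate(
      community_a = unname(comm[as.character(.data$residue_a)]),
      community_b = unname(comm[as.character(.data$residue_b)])
    ) |>
    filter(.data$community_a != .data$community_b)
  if (nrow(e) == 0) {
    return(tibble(
      node_a = integer(0), node_b = integer(0),
      community_a = integer(0), community_b = integer(0),
      betweenness = numeric(0)
    ))
  }
  lo <- pmin(e$community_a, e$community_b)
  hi <- pmax(e$community_a, e$community_b)
  e$pair <- paste(lo, hi)
  out <- lapply(split(e, e$pair), function(block) {
    pick <- pick_max_edge(block$residue_a, block$residue_b, block$betweenness)
    tibble(
      node_a = block$residue_a[pick], node_b = block$residue_b[pick],
      community_a = block$community_a[pick], community_b = block$community_b[pick],
      betweenness = block$betweenness[pick]
    )
  })
  dplyr::bind_rows(out) |> arrange(.data$community_a, .data$community_b)
}

# Floyd-Warshall all-pairs shortest paths with path reconstruction.
# Ties in total weight are broken toward fewer hops, then toward the
# smallest intermediate node index (deterministic, k ascending).
floyd_warshall <- function(net) {
  ids <- net$nodes
  n <- length(ids)
  d <- matrix(Inf, n, n)
  hops <- matrix(Inf, n, n)
  nxt <- matrix(NA_integer_, n, n)
  diag(d) <- 0
  diag(hops) <- 0
  ai <- match(net$edges$residue_a, ids)
  bi <- match(net$edges$residue_b, ids)
  for (e in seq_along(ai)) {
    if (net$edges$weight[e] < d[ai[e], bi[e]]) {
      d[ai[e], bi[e]] <- d[bi[e], ai[e]] <- net$edges$weight[e]
      hops[ai[e], bi[e]] <- hops[bi[e], ai[e]] <- 1
      nxt[ai[e], bi[e]] <- bi[e]
      nxt[bi[e], ai[e]] <- ai[e]
    }
  }
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], "+")
    hk <- outer(hops[, k], hops[k, ], "+")
    better <- (dk < d - 1e-12) | (abs(dk - d) <= 1e-12 & hk < hops)
    better[k, ] <- FALSE
    better[, k] <- FALSE
    diag(better) <- FALSE
    if (any(better)) {
      d[better] <- dk[better]
      hops[better] <- hk[better]
      nxt_k <- matrix(nxt[, k], n, n)
      nxt[better] <- nxt_k[better]
    }
  }
  list(ids = ids, dist = d, hops = hops, nxt = nxt)
}

reconstruct_path <- function(fw, si, ti) {
  if (!is.finite(fw$dist[si, ti])) {
    return(NULL)
  }
  path <- si
  u <- si
  for (guard in seq_len(length(fw$ids) + 1)) {
    if (u == ti) {
      return(path)
    }
    u <- fw$nxt[u, ti]
    path <- c(path, u)
  }
  abort("path reconstruction failed (cycle)")
}

#' Optimal allosteric path between a source and a sink
#'
#' Minimum total-weight path under `w_ij = -ln|C_ij|`, computed with the
#' Floyd-Warshall algorithm and path reconstruction. Minimizing the summed
#' weight simultaneously favours short routes and high-correlation edges.
#' Weight ties are broken toward fewer intermediate nodes, then
#' deterministically by node order.
#'
#' @param net A `dynamic_network`.
#' @param source,sink Residue ids (must differ and be in the network).
#' @return A `path_result` with the optimal `path` (residue id sequence)
#'   and `length` (summed weight).
#' @export
optimal_path <- function(net, source, sink) {
  si <- match(source, net$nodes)
  ti <- match(sink, net$nodes)
  if (is.na(si) || is.na(ti)) abort("source or sink not in the network")
  if (si == ti) abort("source and sink must differ")
  fw <- floyd_warshall(net)
  path <- reconstruct_path(fw, si, ti)
  if (is.null(path)) {
    abort(sprintf("no path between residues %s and %s (different components)", source, sink))
  }
  structure(
    list(
      source = source, sink = sink,
      path = net$nodes[path], length = fw$dist[si, ti],
      suboptimal = NULL
    ),
    class = "path_result"
  )
}

#' Optimal and suboptimal paths
#'
#' Enumerates every simple source-to-sink path whose total weight is within
#' `tolerance` of the optimal length, by depth-first search with
#' branch-and-bound pruning on the all-pairs shortest-path distances
#' (an admissible completion bound). Paths are returned sorted by length.
#'
#' @inheritParams optimal_path
#' @param tolerance Extra weight allowed above the optimal length (>= 0).
#' @param max_paths Combinatorial guard: abort if more than this many paths
#'   qualify (default 1e5).
#' @return A `path_result` whose `suboptimal` field is a tibble with
#'   list-column `path` and column `length`, sorted by length (the optimal
#'   path is its first row).
#' @export
suboptimal_paths <- function(net, source, sink, tolerance, max_paths = 1e5) {
  if (tolerance < 0) abort("tolerance must be >= 0")
  opt <- optimal_path(net, source, sink)
  fw <- floyd_warshall(net)
  si <- match(source, net$nodes)
  ti <- match(sink, net$nodes)
  bound <- opt$length + tolerance + 1e-9
  n <- length(net$nodes)
  adj <- vector("list", n)
  ai <- match(net$edges$residue_a, net$nodes)
  bi <- match(net$edges$residue_b, net$nodes)
  for (e in seq_along(ai)) {
    adj[[ai[e]]] <- rbind(adj[[ai[e]]], c(bi[e], net$edges$weight[e]))
    adj[[bi[e]]] <- rbind(adj[[bi[e]]], c(ai[e], net$edges$weight[e]))
  }
  adj <- lapply(adj, function(m) if (is.null(m)) m else m[order(m[, 1]), , drop = FALSE])
  found_paths <- list()
  found_lengths <- numeric(0)
  count <- 0
  visited <- rep(FALSE, n)
  dfs <- function(u, len, path) {
    if (len + fw$dist[u, ti] > bound) {
      return(invisible())
    }
    if (u == ti) {
      count <<- count + 1
      if (count > max_paths) {
        abort(sprintf("more than %d qualifying paths; raise max_paths or lower tolerance", max_paths))
      }
      found_paths[[count]] <<- path
      found_lengths[count] <<- len
      return(invisible())
    }
    nb <- adj[[u]]
    if (is.null(nb)) {
      return(invisible())
    }
    for (r in seq_len(nrow(nb))) {
      v <- nb[r, 1]
      if (!visited[v]) {
        visited[v] <<- TRUE
        dfs(v, len + nb[r, 2], c(path, v))
        visited[v] <<- FALSE
      }
    }
  }
  visited[si] <- TRUE
  dfs(si, 0, si)
  ord <- order(found_lengths, vapply(found_paths, length, integer(1)))
  opt$suboptimal <- tibble(
    path = lapply(found_paths[ord], function(p) net$nodes[p]),
    length = found_lengths[ord]
  )
  opt
}

#' @export
print.path_result <- function(x, ...) {
  cat(sprintf(
    "<path_result> %s -> %s: optimal length %.4f via %s%s\n",
    x$source, x$sink, x$length, paste(x$path, collapse = "-"),
    if (is.null(x$suboptimal)) "" else sprintf(" (+%d path(s) total)", nrow(x$suboptimal))
  ))
  invisible(x)
}

#' @rdname tidy_allokit
#' @export
tidy.path_result <- function(x, ...) {
  if (is.null(x$suboptimal)) {
    tibble(
      rank = 1L, length = x$length, n_nodes = length(x$path),
      path = paste(x$path, collapse = "-")
    )
  } else {
    tibble(
      rank = seq_len(nrow(x$suboptimal)),
      length = x$suboptimal$length,
      n_nodes = vapply(x$suboptimal$path, length, integer(1)),
      path = vapply(x$suboptimal$path, paste, character(1), collapse = "-")
    )
  }
}

#' Export a dynamic network as GraphML
#'
#' Writes the graph with occupancy, correlation and weight edge attributes
#' (plus community membership when present) for external viewers.
#'
#' @param net A `dynamic_network`.
#' @param path Output `.graphml` path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  g <- net$graph
  if (!is.null(net$communities)) {
    igraph::V(g)$community <- net$communities$community[
      match(igraph::V(g)$name, net$communities$residue_id)
    ]
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Plot a dynamic network
#'
#' 2-D layout (Fruchterman-Reingold on a fixed seed) with edges shaded by
#' correlation strength and nodes coloured by community when available.
#'
#' @param object A `dynamic_network`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dynamic_network <- function(object, seed = 1, ...) {
  lay <- withr::with_seed(seed, igraph::layout_with_fr(object$graph))
  nodes <- tibble(
    residue_id = as.integer(igraph::V(object$graph)$name),
    x = lay[, 1], y = lay[, 2]
  )
  if (!is.null(object$communities)) {
    nodes <- left_join(nodes, object$communities, by = "residue_id")
  } else {
    nodes$community <- 1L
  }
  seg <- object$edges |>
    left_join(nodes[, c("residue_id", "x", "y")], by = c("residue_a" = "residue_id")) |>
    left_join(nodes[, c("residue_id", "x", "y")],
      by = c("residue_b" = "residue_id"), suffix = c("", "end")
    )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(
        x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend,
        linewidth = abs(.data$correlation)
      ),
      colour = "grey60"
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(.data$x, .data$y, colour = factor(.data$community)), size = 2
    ) +
    ggplot2::scale_linewidth(range = c(0.1, 1.2), guide = "none") +
    ggplot2::labs(colour = "community") +
    ggplot2::theme_void()
}
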