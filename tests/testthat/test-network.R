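test_that("contact edges follow the strict occupancy rule and exclude neighbours", {
  # four CA-only residues on a line; residue pair (1, 3) oscillates
  model <- ca_only_model(1:4, coords = rbind(
    c(0, 0, 0), c(4, 0, 0), c(3, 2, 0), c(30, 0, 0)
  ))
  coords <- array(0, dim = c(10, 4, 3))
  for (f in 1:10) {
    coords[f, 1, ] <- c(0, 0, 0)
    coords[f, 2, ] <- c(4, 0, 0)
    coords[f, 3, ] <- if (f <= 8) c(3, 2, 0) else c(20, 0, 0) # within 4.5 in 8/10
    coords[f, 4, ] <- c(30, 0, 0)
  }
  edges <- contact_edges(array_ensemble(coords), model)
  expect_equal(nrow(edges), 1)
  expect_equal(c(edges$residue_a, edges$residue_b, edges$occupancy), c(1, 3, 0.8))
  # 7/10 frames: 0.7 > 0.75 is false -> edge absent
  coords[8, 3, ] <- c(20, 0, 0)
  expect_equal(nrow(contact_edges(array_ensemble(coords), model)), 0)
  # sequence neighbours are never edges even in permanent contact
  near <- array(rep(t(rbind(c(0, 0, 0), c(2, 0, 0), c(40, 0, 0), c(44, 0, 0))), 5),
    dim = c(3, 4, 5)
  )
  near <- aperm(near, c(3, 2, 1))
  expect_equal(nrow(contact_edges(array_ensemble(near), model)), 0)
})

test_that("correlation matrix has unit diagonal, symmetry and bounded entries", {
  gen <- quick_scenario(seed = 30, n_residues = 10, n_frames = 300)
  cmat <- correlation_matrix(gen$ensembles[[1]], gen$model, superpose = FALSE)
  expect_equal(diag(cmat), stats::setNames(rep(1, 10), 1:10))
  expect_equal(cmat, t(cmat))
  expect_true(all(abs(cmat) <= 1 + 1e-12))
  # identical displacement vectors give C = 1
  base <- gen$ensembles[[1]]$coords[1, , ]
  coords <- array(rep(base, each = 50), dim = c(50, nrow(base), 3))
  drift <- withr::with_seed(1, matrix(stats::rnorm(50 * 3), 50, 3))
  ca <- unname(gen$model$ca_index[c("2", "7")])
  for (f in 1:50) {
    coords[f, ca[1], ] <- coords[f, ca[1], ] + drift[f, ]
    coords[f, ca[2], ] <- coords[f, ca[2], ] + drift[f, ]
  }
  cm <- suppressWarnings(
    correlation_matrix(array_ensemble(coords), gen$model, superpose = FALSE)
  )
  expect_equal(cm["2", "7"], 1, tolerance = 1e-10)
})

test_that("independent displacements decorrelate at large n", {
  n <- 5000
  model <- ca_only_model(1:6)
  base <- as.matrix(model$atoms[, c("x", "y", "z")])
  coords <- array(rep(base, each = n), dim = c(n, 6, 3)) +
    withr::with_seed(2, array(stats::rnorm(n * 18, sd = 0.5), dim = c(n, 6, 3)))
  cmat <- correlation_matrix(array_ensemble(coords), model, superpose = FALSE)
  off <- cmat[row(cmat) != col(cmat)]
  expect_lt(max(abs(off)), 0.05)
})

test_that("frozen residues are flagged and zeroed", {
  model <- ca_only_model(1:3)
  base <- as.matrix(model$atoms[, c("x", "y", "z")])
  coords <- array(rep(base, each = 30), dim = c(30, 3, 3))
  coords[, 2, ] <- coords[, 2, ] + withr::with_seed(3, matrix(stats::rnorm(90), 30))
  coords[, 3, ] <- coords[, 3, ] + withr::with_seed(4, matrix(stats::rnorm(90), 30))
  expect_warning(
    cmat <- correlation_matrix(array_ensemble(coords), model, superpose = FALSE),
    "zero fluctuation"
  )
  expect_equal(cmat[1, 2], 0)
  expect_equal(cmat[1, 1], 1)
})

test_that("edge weights follow w = -ln|C| with the cap", {
  net <- manual_net(data.frame(a = c(1, 1, 2), b = c(3, 4, 4), c = c(1, exp(-1), 0)))
  expect_equal(net$edges$weight, c(0, 1, 20))
  expect_true(all(net$edges$weight >= 0))
  expect_error(
    build_network(
      tibble::tibble(residue_a = 1, residue_b = 99, occupancy = 1),
      diag(3) |> (\(m) {
        dimnames(m) <- list(1:3, 1:3)
        m
      })()
    ),
    "no correlation"
  )
})

test_that("Girvan-Newman splits two triangles joined by a bridge", {
  tri2 <- data.frame(
    a = c(1, 1, 2, 4, 4, 5, 3),
    b = c(2, 3, 3, 5, 6, 6, 4),
    c = rep(0.8, 7)
  )
  net <- girvan_newman(manual_net(tri2))
  comm <- net$communities
  expect_equal(length(unique(comm$community)), 2)
  expect_equal(length(unique(comm$community[comm$residue_id %in% 1:3])), 1)
  expect_equal(length(unique(comm$community[comm$residue_id %in% 4:6])), 1)
  # the bridge is removed first
  first <- gn_removal_order(net)[1, ]
  expect_equal(c(first$residue_a, first$residue_b), c(3, 4))
  # critical nodes are the bridge endpoints
  cn <- critical_nodes(net)
  expect_equal(nrow(cn), 1)
  expect_setequal(c(cn$node_a, cn$node_b), c(3, 4))
})

test_that("degenerate partitions behave sensibly", {
  tri <- data.frame(a = c(1, 1, 2), b = c(2, 3, 3), c = 0.8)
  net <- girvan_newman(manual_net(tri))
  expect_equal(length(unique(net$communities$community)), 1)
  expect_equal(nrow(critical_nodes(net)), 0)
  # two disconnected components are at least their own communities
  two <- data.frame(a = c(1, 1, 2, 4, 4, 5), b = c(2, 3, 3, 5, 6, 6), c = 0.8)
  net2 <- girvan_newman(manual_net(two))
  m <- stats::setNames(net2$communities$community, net2$communities$residue_id)
  expect_true(all(m[c("1", "2", "3")] == m["1"]))
  expect_true(all(m[c("4", "5", "6")] == m["4"]))
  expect_false(m["1"] == m["4"])
})

test_that("inter-community edge of maximal betweenness marks the critical nodes", {
  # two cliques joined by two parallel routes of different betweenness
  edges <- data.frame(
    a = c(1, 1, 2, 4, 4, 5, 3, 1),
    b = c(2, 3, 3, 5, 6, 6, 4, 6),
    c = c(0.9, 0.9, 0.9, 0.9, 0.9, 0.9, 0.9, 0.2)
  )
  net <- girvan_newman(manual_net(edges))
  cn <- critical_nodes(net)
  expect_equal(nrow(cn), 1)
  # the light (3, 4) edge carries the shortest paths, not the heavy (1, 6)
  expect_setequal(c(cn$node_a, cn$node_b), c(3, 4))
})

test_that("optimal path prefers low total weight over fewer hops", {
  net <- manual_net(data.frame(
    a = c(1, 1, 2),
    b = c(3, 2, 3),
    c = c(exp(-0.2), exp(-0.05), exp(-0.05))
  ))
  res <- optimal_path(net, 1, 3)
  expect_equal(res$path, c(1, 2, 3))
  expect_equal(res$length, 0.1)
  # unique minimal direct edge
  net2 <- manual_net(data.frame(a = c(1, 1, 2), b = c(3, 2, 3), c = c(0.95, 0.5, 0.5)))
  expect_equal(optimal_path(net2, 1, 3)$path, c(1, 3))
  # disconnected source/sink
  net3 <- manual_net(data.frame(a = c(1, 3), b = c(2, 4), c = 0.9))
  expect_error(optimal_path(net3, 1, 4), "no path")
  expect_error(optimal_path(net3, 1, 1), "must differ")
  expect_error(optimal_path(net3, 1, 99), "not in the network")
})

test_that("Floyd-Warshall agrees with an independent shortest-path solver", {
  for (s in 1:50) {
    net <- random_graph_net(sample(5:9, 1), seed = s)
    d_ig <- igraph::distances(net$graph, weights = igraph::E(net$graph)$weight)
    fw <- allokit:::floyd_warshall(net)
    expect_equal(unname(fw$dist), unname(d_ig), tolerance = 1e-10)
  }
})

test_that("suboptimal paths enumerate exactly the bounded path set", {
  # tolerance 0: exactly the optimal-length paths (both parallel shortest routes)
  net <- manual_net(data.frame(
    a = c(1, 2, 1, 3),
    b = c(2, 4, 3, 4),
    c = rep(exp(-0.5), 4)
  ))
  res <- suboptimal_paths(net, 1, 4, tolerance = 0)
  expect_equal(nrow(res$suboptimal), 2)
  expect_true(all(abs(res$suboptimal$length - 1.0) < 1e-12))
  # infinite tolerance on a 4-cycle: all simple paths
  res_all <- suboptimal_paths(net, 1, 4, tolerance = Inf)
  expect_equal(nrow(res_all$suboptimal), 2)
  net5 <- manual_net(data.frame(
    a = c(1, 2, 1, 3, 2),
    b = c(2, 4, 3, 4, 3),
    c = rep(exp(-0.5), 5)
  ))
  res5 <- suboptimal_paths(net5, 1, 4, tolerance = Inf)
  expect_equal(nrow(res5$suboptimal), 4) # 1-2-4, 1-3-4, 1-2-3-4, 1-3-2-4
  # combinatorial guard
  expect_error(
    suboptimal_paths(net5, 1, 4, tolerance = Inf, max_paths = 2),
    "more than 2"
  )
  # lengths are sorted non-decreasing
  expect_true(all(diff(res5$suboptimal$length) >= -1e-12))
  td <- tidy(res5)
  expect_equal(td$path[1], paste(res5$path, collapse = "-"))
})

test_that("GraphML export round-trips through igraph", {
  net <- girvan_newman(manual_net(data.frame(
    a = c(1, 1, 2, 4, 4, 5, 3), b = c(2, 3, 3, 5, 6, 6, 4), c = 0.8
  )))
  path <- tempfile(fileext = ".graphml")
  write_network_graphml(net, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::ecount(g), 7)
  expect_equal(sort(unique(igraph::V(g)$community)), 1:2)
  expect_equal(igraph::E(g)$weight, net$edges$weight)
})

test_that("network summaries and plots are well-formed", {
  gen <- quick_scenario(seed = 31, n_residues = 14, n_frames = 200)
  edges <- contact_edges(gen$ensembles[[1]], gen$model)
  cmat <- correlation_matrix(gen$ensembles[[1]], gen$model, superpose = FALSE)
  net <- girvan_newman(build_network(edges, cmat))
  expect_true(all(tidy(net)$occupancy > 0.75))
  gl <- glance(net)
  expect_equal(gl$n_nodes, 14)
  expect_gt(gl$n_edges, 0)
  expect_s3_class(autoplot(net), "ggplot")
})
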