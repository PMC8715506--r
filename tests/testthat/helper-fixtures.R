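# Shared fixtures and independent brute-force oracles.

# Hand-written PDB lines for a 3-residue peptide with hydrogens, written
# independently of the package's PDB writer.
toy_pdb_lines <- function() {
  atoms <- list(
    # serial, name, resname, resid, x, y, z, element
    list(1, "N", "ALA", 1, 0.000, 0.000, 0.000, "N"),
    list(2, "CA", "ALA", 1, 1.458, 0.000, 0.000, "C"),
    list(3, "CB", "ALA", 1, 2.000, 1.420, 0.000, "C"),
    list(4, "HB1", "ALA", 1, 1.700, 1.950, 0.900, "H"),
    list(5, "C", "ALA", 1, 2.000, -0.750, -1.200, "C"),
    list(6, "O", "ALA", 1, 1.300, -1.250, -2.080, "O"),
    list(7, "N", "GLY", 2, 3.320, -0.820, -1.250, "N"),
    list(8, "H", "GLY", 2, 3.850, -0.400, -0.510, "H"),
    list(9, "CA", "GLY", 2, 4.050, -1.500, -2.320, "C"),
    list(10, "C", "GLY", 2, 5.480, -1.050, -2.450, "C"),
    list(11, "O", "GLY", 2, 6.000, -0.300, -1.620, "O"),
    list(12, "N", "SER", 3, 6.150, -1.520, -3.500, "N"),
    list(13, "CA", "SER", 3, 7.560, -1.180, -3.740, "C"),
    list(14, "CB", "SER", 3, 8.450, -2.420, -3.640, "C"),
    list(15, "OG", "SER", 3, 8.400, -3.010, -2.350, "O"),
    list(16, "HG", "SER", 3, 8.950, -3.790, -2.330, "H")
  )
  vapply(atoms, function(a) {
    name_field <- if (nchar(a[[2]]) >= 4) a[[2]] else sprintf(" %-3s", a[[2]])
    sprintf(
      "ATOM  %5d %s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      a[[1]], name_field, a[[3]], a[[4]], a[[5]], a[[6]], a[[7]], a[[8]]
    )
  }, character(1))
}

write_toy_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(toy_pdb_lines(), "END"), path)
  path
}

# The same system as a GRO file (nm units), written from the same
# coordinate table by hand.
write_toy_gro <- function(path = tempfile(fileext = ".gro")) {
  pdb <- toy_pdb_lines()
  resid <- as.integer(substr(pdb, 23, 26))
  resname <- trimws(substr(pdb, 18, 20))
  name <- trimws(substr(pdb, 13, 16))
  xyz <- cbind(
    as.numeric(substr(pdb, 31, 38)),
    as.numeric(substr(pdb, 39, 46)),
    as.numeric(substr(pdb, 47, 54))
  ) / 10
  lines <- c("toy peptide", sprintf("%5d", length(resid)))
  for (i in seq_along(resid)) {
    lines <- c(lines, sprintf(
      "%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
      resid[i], resname[i], name[i], i, xyz[i, 1], xyz[i, 2], xyz[i, 3]
    ))
  }
  writeLines(c(lines, sprintf("%10.5f%10.5f%10.5f", 10, 10, 10)), path)
  path
}

# A CA-only model with arbitrary residue numbering, built in code.
ca_only_model <- function(residue_ids, coords = NULL) {
  n <- length(residue_ids)
  if (is.null(coords)) coords <- cbind(seq_len(n) * 4, 0, 0)
  new_structure_model(tibble::tibble(
    residue_id = residue_ids, resname = "ALA", chain = "A",
    atom_name = "CA", element = "C",
    x = coords[, 1], y = coords[, 2], z = coords[, 3]
  ))
}

# Ensemble from an explicit frames x atoms x 3 array.
array_ensemble <- function(coords, label = "toy") new_ensemble(coords, label)

# --- brute-force graph oracles (independent of the package internals) ----

# All simple paths between two nodes of an undirected weighted edge list.
bf_all_simple_paths <- function(edges, source, sink) {
  nodes <- sort(unique(c(edges$residue_a, edges$residue_b)))
  adj <- lapply(nodes, function(u) {
    rows <- edges$residue_a == u | edges$residue_b == u
    other <- ifelse(edges$residue_a[rows] == u, edges$residue_b[rows], edges$residue_a[rows])
    data.frame(to = other, w = edges$weight[rows])
  })
  names(adj) <- nodes
  paths <- list()
  lens <- numeric(0)
  recurse <- function(u, visited, len, path) {
    if (u == sink) {
      paths[[length(paths) + 1]] <<- path
      lens[length(lens) + 1] <<- len
      return(invisible())
    }
    nb <- adj[[as.character(u)]]
    for (r in seq_len(nrow(nb))) {
      v <- nb$to[r]
      if (!v %in% visited) {
        recurse(v, c(visited, v), len + nb$w[r], c(path, v))
      }
    }
  }
  recurse(source, source, 0, source)
  list(paths = paths, lengths = lens)
}

# Weighted edge betweenness by shortest-path counting over enumerated
# simple paths (Brandes-style fractional credit), for small graphs only.
bf_edge_betweenness <- function(edges, tol = 1e-9) {
  nodes <- sort(unique(c(edges$residue_a, edges$residue_b)))
  score <- numeric(nrow(edges))
  edge_key <- paste(
    pmin(edges$residue_a, edges$residue_b),
    pmax(edges$residue_a, edges$residue_b)
  )
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (i >= j) next
      res <- bf_all_simple_paths(edges, nodes[i], nodes[j])
      if (length(res$lengths) == 0) next
      best <- min(res$lengths)
      hit <- which(res$lengths <= best + tol)
      for (h in hit) {
        p <- res$paths[[h]]
        for (s in seq_len(length(p) - 1)) {
          key <- paste(min(p[s], p[s + 1]), max(p[s], p[s + 1]))
          score[edge_key == key] <- score[edge_key == key] + 1 / length(hit)
        }
      }
    }
  }
  score
}

# Random weighted graph as an edge tibble plus a consistent correlation
# matrix (|C| = exp(-w)) so build_network() reproduces the weights.
random_graph_net <- function(n_nodes, p_edge = 0.45, seed = 1) {
  withr::with_seed(seed, {
    pairs <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
    keep <- stats::runif(nrow(pairs)) < p_edge
    # guarantee a connected spine so paths exist
    spine <- cbind(seq_len(n_nodes - 1), 2:n_nodes)
    sel <- unique(rbind(pairs[keep, , drop = FALSE], spine))
    w <- stats::runif(nrow(sel), 0.1, 2)
    edges <- tibble::tibble(
      residue_a = as.integer(sel[, 1]), residue_b = as.integer(sel[, 2]),
      occupancy = 1, weight = w
    )
  })
  cmat <- diag(n_nodes)
  dimnames(cmat) <- list(seq_len(n_nodes), seq_len(n_nodes))
  for (e in seq_len(nrow(edges))) {
    cval <- exp(-edges$weight[e])
    cmat[edges$residue_a[e], edges$residue_b[e]] <- cval
    cmat[edges$residue_b[e], edges$residue_a[e]] <- cval
  }
  build_network(edges[, c("residue_a", "residue_b", "occupancy")], cmat)
}

# Hand-built network from explicit edges with chosen |C| values.
manual_net <- function(edges_df, n_nodes = max(c(edges_df$a, edges_df$b))) {
  cmat <- diag(n_nodes)
  dimnames(cmat) <- list(seq_len(n_nodes), seq_len(n_nodes))
  for (e in seq_len(nrow(edges_df))) {
    cmat[edges_df$a[e], edges_df$b[e]] <- edges_df$c[e]
    cmat[edges_df$b[e], edges_df$a[e]] <- edges_df$c[e]
  }
  build_network(
    tibble::tibble(
      residue_a = edges_df$a, residue_b = edges_df$b,
      occupancy = rep(1, nrow(edges_df))
    ),
    cmat
  )
}

# Small synthetic scenario shared by several tests.
quick_scenario <- function(seed = 1, n_residues = 20, n_frames = 200, ...) {
  planted <- n_residues %/% 2 + c(0L, 3L)
  planted <- planted[planted <= n_residues]
  truth <- planted_truth(n_residues, 2,
    discriminative_residues = planted, shift = 3, seed = seed
  )
  gen <- generate_two_state_ensembles(n_residues, max(n_frames, 50), truth, ...)
  if (n_frames < 50) {
    gen$ensembles <- lapply(gen$ensembles, function(e) {
      new_ensemble(e$coords[seq_len(n_frames), , , drop = FALSE], e$class_label)
    })
  }
  gen
}
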