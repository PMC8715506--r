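test_that("inverse closest-heavy distance is 1/min over heavy-atom pairs", {
  # residue 1: one atom at origin; residue 2: three atoms at x = 5, 4, 6
  model <- new_structure_model(tibble::tibble(
    residue_id = c(1L, 2L, 2L, 2L),
    resname = "ALA", chain = "A",
    atom_name = c("CA", "CA", "CB", "CG"),
    element = "C",
    x = c(0, 5, 4, 6), y = 0, z = 0
  ))
  coords <- array(0, dim = c(1, 4, 3))
  coords[1, , 1] <- c(0, 5, 4, 6)
  ens <- array_ensemble(coords)
  fm <- featurize(ens, model, pairs = data.frame(residue_a = 1, residue_b = 2))
  expect_equal(as.numeric(fm$values), 1 / 4)

  # translating the pair apart x2 halves the feature
  coords2 <- coords
  coords2[1, 2:4, 1] <- 2 * coords[1, 2:4, 1]
  fm2 <- featurize(array_ensemble(coords2), model,
    pairs = data.frame(residue_a = 1, residue_b = 2)
  )
  expect_equal(as.numeric(fm2$values), as.numeric(fm$values) / 2)
})

test_that("featurization matches a brute-force double loop over heavy atoms", {
  gen <- quick_scenario(seed = 2, n_residues = 8, n_frames = 5)
  ens <- gen$ensembles[[1]]
  model <- gen$model
  fm <- featurize(ens, model, min_sep = 3)
  for (f in seq_len(ncol(fm$values))) {
    ra <- fm$descriptors$residue_a[f]
    rb <- fm$descriptors$residue_b[f]
    ia <- model$atoms$atom[model$atoms$residue_id == ra & model$atoms$is_heavy]
    ib <- model$atoms$atom[model$atoms$residue_id == rb & model$atoms$is_heavy]
    for (fr in seq_len(ens$frame_count)) {
      best <- Inf
      for (a in ia) {
        for (b in ib) {
          best <- min(best, sqrt(sum((ens$coords[fr, a, ] - ens$coords[fr, b, ])^2)))
        }
      }
      expect_equal(fm$values[fr, f], 1 / best)
    }
  }
})

test_that("CA distances follow the Euclidean norm", {
  model <- ca_only_model(1:2, coords = rbind(c(0, 0, 0), c(3, 4, 0)))
  coords <- array(0, dim = c(2, 2, 3))
  coords[1, 2, ] <- c(3, 4, 0)
  ens <- array_ensemble(coords)
  d <- ca_distance(ens, model, 1, 2)
  expect_equal(d, c(5, 0))
  gen <- quick_scenario(seed = 3, n_residues = 8, n_frames = 4)
  oracle <- vapply(seq_len(4), function(f) {
    a <- gen$model$ca_index[["2"]]
    b <- gen$model$ca_index[["7"]]
    sqrt(sum((gen$ensembles[[1]]$coords[f, a, ] - gen$ensembles[[1]]$coords[f, b, ])^2))
  }, numeric(1))
  expect_equal(ca_distance(gen$ensembles[[1]], gen$model, 2, 7), oracle)
})

test_that("inverse closest-heavy equals 1/CA distance for CA-only residues", {
  set.seed(4)
  model <- ca_only_model(1:6, coords = matrix(rnorm(18, sd = 8), 6))
  coords <- array(rnorm(5 * 6 * 3, sd = 8), dim = c(5, 6, 3))
  ens <- array_ensemble(coords)
  inv <- featurize(ens, model, transform = "inverse_closest_heavy")
  cad <- featurize(ens, model, transform = "ca_distance")
  expect_equal(inv$values, 1 / cad$values)
})

test_that("Kabsch superposition removes rigid motion exactly", {
  set.seed(5)
  a <- matrix(rnorm(30, sd = 4), 10)
  expect_equal(kabsch_rmsd(a, a)$rmsd, 0)
  expect_equal(kabsch_rmsd(a, a)$rotation, diag(3))
  th <- pi / 2
  rot_z <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  b <- a %*% rot_z + matrix(c(5, -2, 1), 10, 3, byrow = TRUE)
  res <- kabsch_rmsd(a, b)
  expect_lt(res$rmsd, 1e-10)
  expect_equal(det(res$rotation), 1, tolerance = 1e-10)
  # degenerate fit sets are rejected
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_rmsd(line, line), "degenerate")
})

test_that("Kabsch RMSD matches a brute-force rotation-sampling oracle", {
  set.seed(6)
  a <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(0, 0, 3))
  b <- a
  b[2, ] <- b[2, ] + c(1, 0, 0) # 1 A displacement on one of 4 points
  fast <- kabsch_rmsd(a, b)$rmsd
  # oracle: numeric minimisation over Euler angles from multiple starts
  rmsd_at <- function(par) {
    cx <- cos(par[1:3])
    sx <- sin(par[1:3])
    rx <- matrix(c(1, 0, 0, 0, cx[1], sx[1], 0, -sx[1], cx[1]), 3)
    ry <- matrix(c(cx[2], 0, -sx[2], 0, 1, 0, sx[2], 0, cx[2]), 3)
    rz <- matrix(c(cx[3], sx[3], 0, -sx[3], cx[3], 0, 0, 0, 1), 3)
    bc <- sweep(b, 2, colMeans(b))
    ac <- sweep(a, 2, colMeans(a))
    sqrt(mean(rowSums((bc %*% (rx %*% ry %*% rz) - ac)^2)))
  }
  best <- Inf
  for (s in 1:12) {
    start <- withr::with_seed(s, stats::runif(3, -pi, pi))
    best <- min(best, stats::optim(start, rmsd_at)$value)
  }
  expect_equal(fast, best, tolerance = 1e-3)
  expect_lte(fast, best + 1e-8) # never worse than the sampled minimum
})

test_that("RMSF is zero for static and rigidly moved trajectories", {
  gen <- quick_scenario(seed = 7, n_residues = 8, n_frames = 60)
  base <- gen$ensembles[[1]]$coords[1, , ]
  static <- array(rep(base, each = 10), dim = c(10, nrow(base), 3))
  expect_true(all(rmsf(array_ensemble(static), gen$model)$rmsf < 1e-10))
  # rigid-body translated copies align back to zero fluctuation
  moved <- static
  for (f in 1:10) moved[f, , ] <- sweep(static[f, , ], 2, c(f, -f, 2 * f), "+")
  expect_true(all(rmsf(array_ensemble(moved), gen$model)$rmsf < 1e-10))
  expect_error(rmsf(array_ensemble(static[1, , , drop = FALSE]), gen$model), "at least 2")
})

test_that("RMSF of a jittered residue matches the direct formula", {
  model <- ca_only_model(1:6, coords = rbind(
    c(0, 0, 0), c(4, 0, 0), c(4, 4, 0), c(0, 4, 0), c(0, 0, 4), c(8, 8, 8)
  ))
  n_frames <- 400
  coords <- array(rep(t(as.matrix(model$atoms[, c("x", "y", "z")])), n_frames),
    dim = c(3, 6, n_frames)
  )
  coords <- aperm(coords, c(3, 2, 1))
  jit <- withr::with_seed(8, matrix(stats::rnorm(n_frames * 3), n_frames, 3))
  coords[, 6, ] <- coords[, 6, ] + jit
  ens <- array_ensemble(coords)
  # fit on the five static residues: superposition is then exact identity
  out <- rmsf(ens, model, core = 1:5)
  direct <- sqrt(mean(rowSums(sweep(jit, 2, colMeans(jit))^2)))
  expect_equal(out$rmsf[6], direct, tolerance = 1e-8)
  expect_true(all(out$rmsf[1:5] < 1e-10))
})

test_that("distance features are invariant to per-frame rigid motion", {
  gen <- quick_scenario(seed = 9, n_residues = 8, n_frames = 12)
  ens <- gen$ensembles[[1]]
  moved <- ens$coords
  for (f in seq_len(dim(moved)[1])) {
    ang <- withr::with_seed(f, stats::runif(3, -pi, pi))
    rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), sin(ang[1]), 0, -sin(ang[1]), cos(ang[1])), 3)
    rz <- matrix(c(cos(ang[3]), sin(ang[3]), 0, -sin(ang[3]), cos(ang[3]), 0, 0, 0, 1), 3)
    moved[f, , ] <- sweep(ens$coords[f, , ] %*% (rx %*% rz), 2, ang * 7, "+")
  }
  ens_moved <- array_ensemble(moved)
  fm <- featurize(ens, gen$model)
  fm_moved <- featurize(ens_moved, gen$model)
  expect_equal(fm_moved$values, fm$values, tolerance = 1e-9)
  r1 <- rmsf(ens, gen$model)
  r2 <- rmsf(ens_moved, gen$model)
  expect_equal(r2$rmsf, r1$rmsf, tolerance = 1e-6)
})

test_that("microswitch report resolves generic labels and references", {
  gen <- quick_scenario(seed = 10, n_residues = 20, n_frames = 30)
  model <- set_label_map(gen$model, c(
    "3.50" = 5, "6.34" = 12, "5.58" = 8, "7.49" = 14, "7.50" = 15,
    "7.51" = 16, "7.52" = 17, "7.53" = 18
  ))
  ens <- gen$ensembles[[1]]
  ms <- microswitches(ens, model)
  expect_equal(nrow(ms), 30)
  expect_true(all(ms$tm6_tm3 >= 0 & ms$yy >= 0 & ms$npxxy_rmsd >= 0))
  # frame 1 is the default reference: zero NPxxY RMSD there
  expect_equal(ms$npxxy_rmsd[1], 0, tolerance = 1e-10)
  expect_equal(ms$tm6_tm3, ca_distance(ens, model, 5, 12))
  # yy on a constructed frame with known closest heavy pair at 3.2 A
  c2 <- ens$coords
  a8 <- model$atoms$atom[model$atoms$residue_id == 8]
  a18 <- model$atoms$atom[model$atoms$residue_id == 18]
  c2[2, a18, ] <- c2[2, a18, ] + 50 # move the partner residue far away
  c2[2, a8[2], ] <- c2[2, a8[1], ] - c(1, 0, 0) # park the other heavy atoms
  c2[2, a8[3], ] <- c2[2, a8[1], ] - c(2, 0, 0) # behind the anchor
  c2[2, a18[1], ] <- c2[2, a8[1], ] + c(3.2, 0, 0)
  ms2 <- microswitches(array_ensemble(c2), model, npxxy_reference = ens$coords[1, , ])
  expect_equal(ms2$yy[2], 3.2)
  model_nolabel <- gen$model
  expect_error(microswitches(ens, model_nolabel), "no label map")

  # the CV-set wrapper evaluates the same microswitches per frame
  cvs <- make_microswitch_cvs(model, npxxy_reference = ens$coords[1, , ])
  v <- cvs(ens$coords[3, , ])
  expect_equal(unname(v), unname(unlist(ms[3, c("tm6_tm3", "yy", "npxxy_rmsd")])),
    tolerance = 1e-10
  )
})
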