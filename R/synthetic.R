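#' Synthetic two-state ensembles with planted ground truth
#'
#' The generator emulates the analysis surface of a two-condition receptor
#' simulation study (e.g. nanobody-bound vs unbound) as a coarse toy: a
#' helical pseudo-protein whose per-frame displacements carry (i)
#' block-structured residue-residue correlations (planted communities),
#' (ii) class-dependent mean shifts on chosen residues (planted
#' discriminative features), and (iii) a chain of extra-correlated contacts
#' linking two sites (planted allosteric path). Every downstream stage of
#' the package can be validated against this known truth.
#'
#' @name synthetic_data
NULL

#' Describe a planted ground truth
#'
#' Residues are split into `n_communities` contiguous blocks; the planted
#' allosteric chain must follow the i -> i+3 contact lattice of the toy
#' helix (steps of exactly 3 in residue id).
#'
#' @param n_residues Number of residues (>= 6).
#' @param n_communities Number of contiguous correlation blocks.
#' @param discriminative_residues Residue ids receiving a class-dependent
#'   mean shift.
#' @param shift Shift magnitude in Angstrom.
#' @param path_residues Ordered residue ids forming the planted
#'   high-correlation chain (possibly empty); consecutive entries must
#'   differ by 3.
#' @param seed Integer seed owning all randomness of the generator.
#' @return A `planted_truth` object.
#' @export
planted_truth <- function(n_residues, n_communities = 2,
                          discriminative_residues = integer(0), shift = 3,
                          path_residues = integer(0), seed = 1) {
  if (n_residues < 6) abort("need at least 6 residues")
  ids <- seq_len(n_residues)
  if (!all(discriminative_residues %in% ids)) {
    abort("discriminative_residues outside residue range")
  }
  if (length(path_residues) > 0) {
    if (!all(path_residues %in% ids)) abort("path_residues outside residue range")
    if (length(path_residues) > 1 && !all(diff(path_residues) == 3)) {
      abort("path_residues must step by 3 to stay on the toy contact lattice")
    }
  }
  community <- stats::setNames(
    as.integer(cut(ids, breaks = n_communities, labels = FALSE)), ids
  )
  structure(
    list(
      community_assignment = community,
      discriminative_residues = as.integer(discriminative_residues),
      shift = shift,
      path_residues = as.integer(path_residues),
      seed = as.integer(seed)
    ),
    class = "planted_truth"
  )
}

# Coarse helical pseudo-protein: CA on a helix, CB pointing radially
# outward, CG bridging toward the i+3 CA so that (i, i+3) heavy-atom
# contacts exist at the 4.5 A cutoff.
helix_geometry <- function(n_residues, radius = 2.3, rise = 1.5, turn_deg = 100) {
  i <- seq_len(n_residues) - 1
  theta <- i * turn_deg * pi / 180
  ca <- cbind(radius * cos(theta), radius * sin(theta), rise * i)
  cb <- cbind((radius + 1.5) * cos(theta), (radius + 1.5) * sin(theta), rise * i)
  cg <- matrix(NA_real_, n_residues, 3)
  for (r in seq_len(n_residues)) {
    partner <- if (r + 3 <= n_residues) r + 3 else r - 3
    cg[r, ] <- (ca[r, ] + ca[partner, ]) / 2
  }
  list(ca = ca, cb = cb, cg = cg, radial = cbind(cos(theta), sin(theta), 0))
}

synthetic_model <- function(n_residues) {
  geo <- helix_geometry(n_residues)
  atoms <- tibble(
    residue_id = rep(seq_len(n_residues), each = 3),
    resname = "ALA",
    chain = "A",
    atom_name = rep(c("CA", "CB", "CG"), n_residues),
    element = "C",
    x = as.numeric(t(cbind(geo$ca[, 1], geo$cb[, 1], geo$cg[, 1]))),
    y = as.numeric(t(cbind(geo$ca[, 2], geo$cb[, 2], geo$cg[, 2]))),
    z = as.numeric(t(cbind(geo$ca[, 3], geo$cb[, 3], geo$cg[, 3])))
  )
  list(model = new_structure_model(atoms), geometry = geo)
}

planted_correlation <- function(truth, rho_in, rho_out, rho_path) {
  n <- length(truth$community_assignment)
  comm <- truth$community_assignment
  sigma <- matrix(rho_out, n, n)
  for (k in unique(comm)) {
    members <- which(comm == k)
    sigma[members, members] <- rho_in
  }
  diag(sigma) <- 1
  if (length(truth$path_residues) > 1) {
    # shared path factor: loading q^2 solved so cross-community path pairs
    # reach rho_path after renormalisation by cov2cor
    q2 <- (rho_path - rho_out) / (1 - rho_path)
    p <- truth$path_residues
    sigma[p, p] <- sigma[p, p] + q2
  }
  stats::cov2cor(sigma)
}

#' Generate two labelled synthetic ensembles
#'
#' Frame coordinates are the helix base geometry plus correlated Gaussian
#' residue displacements (i.i.d. across frames) drawn from a block
#' correlation structure: `rho_in` within a planted community, `rho_out`
#' between, and `rho_path` along the planted chain. Side-chain pseudo-atoms
#' inherit their residue's displacement plus independent jitter, so
#' closest-heavy-atom and C-alpha features are correlated but not
#' identical. Class B additionally shifts the mean position of the planted
#' discriminative residues radially outward by `truth$shift` Angstrom.
#'
#' @param n_residues Number of residues (>= 6).
#' @param n_frames Frames per class (>= 50).
#' @param truth A [planted_truth()].
#' @param rho_in,rho_out Within/between-community displacement correlation;
#'   both in (-1, 1) with `rho_in > rho_out`.
#' @param rho_path Target correlation between planted-path residues.
#' @param sigma Displacement standard deviation per axis, Angstrom.
#' @param jitter_sd Independent side-chain jitter, Angstrom.
#' @param labels Class labels for the two ensembles.
#' @return List with `model`, `ensembles` (list of two `ensemble`s) and
#'   `truth`.
#' @export
generate_two_state_ensembles <- function(n_residues, n_frames, truth,
                                         rho_in = 0.5, rho_out = 0.05,
                                         rho_path = 0.9, sigma = 0.4,
                                         jitter_sd = 0.2,
                                         labels = c("unbound", "bound")) {
  if (n_residues < 6) abort("need at least 6 residues")
  if (n_frames < 50) abort("need at least 50 frames per class")
  if (length(truth$community_assignment) != n_residues) {
    abort("truth was built for a different number of residues")
  }
  for (rho in c(rho_in, rho_out, rho_path)) {
    if (rho <= -1 || rho >= 1) abort("correlation parameters must lie in (-1, 1)")
  }
  if (rho_in <= rho_out) abort("rho_in must exceed rho_out")
  if (rho_out < 0) abort("rho_out must be non-negative (block factor model)")

  sm <- synthetic_model(n_residues)
  corr <- planted_correlation(truth, rho_in, rho_out, rho_path)
  cf <- chol(corr)
  base <- matrix(NA_real_, n_residues * 3, 3)
  base[seq(1, by = 3, length.out = n_residues), ] <- sm$geometry$ca
  base[seq(2, by = 3, length.out = n_residues), ] <- sm$geometry$cb
  base[seq(3, by = 3, length.out = n_residues), ] <- sm$geometry$cg

  draw_class <- function(shifted) {
    b <- base
    if (shifted && length(truth$discriminative_residues) > 0) {
      for (r in truth$discriminative_residues) {
        rows <- (r - 1) * 3 + 1:3
        b[rows, ] <- b[rows, ] +
          matrix(truth$shift * sm$geometry$radial[r, ], 3, 3, byrow = TRUE)
      }
    }
    coords <- array(NA_real_, dim = c(n_frames, n_residues * 3, 3))
    for (axis in 1:3) {
      disp <- sigma * (matrix(stats::rnorm(n_frames * n_residues), n_frames) %*% cf)
      per_atom <- disp[, rep(seq_len(n_residues), each = 3)]
      side <- rep(c(0, 1, 1), n_residues) # CB/CG get jitter, CA does not
      jit <- matrix(stats::rnorm(n_frames * n_residues * 3, sd = jitter_sd),
        n_frames, n_residues * 3
      ) * matrix(side, n_frames, n_residues * 3, byrow = TRUE)
      coords[, , axis] <- matrix(b[, axis], n_frames, n_residues * 3, byrow = TRUE) +
        per_atom + jit
    }
    coords
  }

  ensembles <- withr::with_seed(truth$seed, {
    list(
      new_ensemble(draw_class(FALSE), labels[1], model = sm$model),
      new_ensemble(draw_class(TRUE), labels[2], model = sm$model)
    )
  })
  list(model = sm$model, ensembles = ensembles, truth = truth)
}

#' Write a planted truth table as TSV
#'
#' @param truth A `planted_truth`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  ids <- as.integer(names(truth$community_assignment))
  tab <- tibble(
    residue_id = ids,
    community = unname(truth$community_assignment),
    discriminative = ids %in% truth$discriminative_residues,
    path_order = match(ids, truth$path_residues)
  )
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Specify a two-well toy potential
#'
#' A double-well surface standing in for a molecular system with two
#' metastable states: quartic along the axis joining the two minima
#' (barrier of `barrier_height` kT at the midpoint), harmonic transverse to
#' it. All units are reduced (kT = 1 at `temperature = 1`).
#'
#' @param minima List of exactly two 2-D points.
#' @param barrier_height Barrier at the saddle, in kT units (> 0).
#' @param friction,timestep,temperature Langevin parameters, reduced units.
#' @return A `toy_potential` object.
#' @export
double_well_spec <- function(minima = list(c(-1, 0), c(1, 0)),
                             barrier_height = 6, friction = 1,
                             timestep = 0.01, temperature = 1) {
  if (length(minima) < 2) abort("need at least 2 minima")
  if (length(minima) != 2) abort("only two-minima potentials are supported")
  if (!all(vapply(minima, function(m) length(m) == 2 && all(is.finite(m)), logical(1)))) {
    abort("minima must be finite 2-D points")
  }
  if (!is.finite(barrier_height) || barrier_height <= 0) abort("barrier_height must be > 0")
  if (!all(is.finite(c(friction, timestep, temperature))) ||
    friction <= 0 || timestep <= 0 || temperature < 0) {
    abort("friction and timestep must be positive, temperature non-negative")
  }
  m1 <- as.numeric(minima[[1]])
  m2 <- as.numeric(minima[[2]])
  center <- (m1 + m2) / 2
  axis <- (m2 - m1) / 2
  half_sep <- vec_norm(axis)
  if (half_sep == 0) abort("the two minima coincide")
  structure(
    list(
      minima = list(m1, m2), barrier_height = barrier_height,
      friction = friction, timestep = timestep, temperature = temperature,
      center = center, axis_unit = axis / half_sep, half_sep = half_sep,
      transverse_k = 2 * barrier_height / half_sep^2
    ),
    class = "toy_potential"
  )
}

#' Potential energy of a toy double well
#'
#' @param spec A [double_well_spec()].
#' @param point 2-D point.
#' @return Potential energy in kT units.
#' @export
double_well_energy <- function(spec, point) {
  rel <- as.numeric(point) - spec$center
  s <- sum(rel * spec$axis_unit) / spec$half_sep
  perp <- rel - sum(rel * spec$axis_unit) * spec$axis_unit
  spec$barrier_height * (s^2 - 1)^2 + 0.5 * spec$transverse_k * sum(perp^2)
}

double_well_gradient <- function(spec, point) {
  rel <- as.numeric(point) - spec$center
  s <- sum(rel * spec$axis_unit) / spec$half_sep
  perp <- rel - sum(rel * spec$axis_unit) * spec$axis_unit
  grad_s <- 4 * spec$barrier_height * s * (s^2 - 1) / spec$half_sep
  grad_s * spec$axis_unit + spec$transverse_k * perp
}

#' Simulate overdamped Langevin dynamics on the toy double well
#'
#' Euler-Maruyama integration of `dx = -grad U dt / gamma +
#' sqrt(2 kT dt / gamma) dW`. At zero temperature this reduces to plain
#' gradient descent.
#'
#' @param spec A [double_well_spec()].
#' @param start 2-D starting point.
#' @param n_steps Number of integration steps (>= 1).
#' @param seed Integer seed.
#' @return `(n_steps + 1) x 2` matrix of points, first row = `start`.
#' @export
simulate_double_well <- function(spec, start, n_steps, seed = 1) {
  stopifnot(inherits(spec, "toy_potential"))
  if (n_steps < 1) abort("n_steps must be >= 1")
  start <- as.numeric(start)
  if (length(start) != 2 || !all(is.finite(start))) abort("start must be a finite 2-D point")
  dt <- spec$timestep
  gamma <- spec$friction
  amp <- sqrt(2 * spec$temperature * dt / gamma)
  traj <- matrix(NA_real_, n_steps + 1, 2)
  traj[1, ] <- start
  noise <- withr::with_seed(seed, matrix(stats::rnorm(2 * n_steps), n_steps, 2))
  x <- start
  for (t in seq_len(n_steps)) {
    x <- x - double_well_gradient(spec, x) * dt / gamma + amp * noise[t, ]
    traj[t + 1, ] <- x
  }
  traj
}

#' Langevin backend for the sampling controller
#'
#' Wraps [simulate_double_well()] as a `function(start, n_steps, seed)`
#' returning a trajectory matrix, the backend interface
#' [run_controller()] expects.
#'
#' @param spec A [double_well_spec()].
#' @return A backend function.
#' @export
make_langevin_backend <- function(spec) {
  force(spec)
  function(start, n_steps, seed) simulate_double_well(spec, start, n_steps, seed)
}
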