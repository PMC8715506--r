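#' Distance-based features and microswitch collective variables
#'
#' Per-frame features follow the conventions of data-driven MD analysis:
#' inverse closest-heavy-atom distances between residue pairs (the machine
#' learning input), C-alpha distances, and the class A GPCR activation
#' microswitches (TM6-TM3 C-alpha distance, Y-Y motif closest-heavy
#' distance, NPxxY-motif RMSD after Kabsch superposition).
#'
#' @name features
NULL

#' Minimum heavy-atom distance per frame for residue pairs
#'
#' @param ensemble An `ensemble`.
#' @param model Matching `structure_model`.
#' @param pairs Two-column data frame (`residue_a`, `residue_b`).
#' @return frames x pairs matrix of minimum heavy-atom distances (Angstrom).
#' @keywords internal
pair_min_heavy_dist <- function(ensemble, model, pairs) {
  coords <- ensemble$coords
  heavy <- split(
    model$atoms$atom[model$atoms$is_heavy],
    model$atoms$residue_id[model$atoms$is_heavy]
  )
  n_frames <- dim(coords)[1]
  out <- matrix(NA_real_, n_frames, nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    ia <- heavy[[as.character(pairs$residue_a[p])]]
    ib <- heavy[[as.character(pairs$residue_b[p])]]
    if (is.null(ia) || is.null(ib)) {
      abort(sprintf(
        "residue %s or %s has no heavy atoms",
        pairs$residue_a[p], pairs$residue_b[p]
      ))
    }
    best <- rep(Inf, n_frames)
    for (a in ia) {
      for (b in ib) {
        d2 <- (coords[, a, 1] - coords[, b, 1])^2 +
          (coords[, a, 2] - coords[, b, 2])^2 +
          (coords[, a, 3] - coords[, b, 3])^2
        best <- pmin(best, d2)
      }
    }
    out[, p] <- sqrt(best)
  }
  out
}

default_pairs <- function(model, min_sep = 3) {
  ids <- model$residue_ids
  pos <- seq_along(ids)
  idx <- which(outer(pos, pos, function(i, j) j - i) >= min_sep, arr.ind = TRUE)
  tibble(residue_a = ids[idx[, 1]], residue_b = ids[idx[, 2]])
}

#' Construct a feature matrix
#'
#' @param values frames x features numeric matrix.
#' @param descriptors Tibble with one row per feature: `residue_a`,
#'   `residue_b`, `transform`.
#' @param labels Character vector of per-frame class labels.
#' @return A `feature_matrix`.
#' @export
new_feature_matrix <- function(values, descriptors, labels) {
  values <- as.matrix(values)
  descriptors <- as_tibble(descriptors)
  stopifnot(
    nrow(values) == length(labels),
    ncol(values) == nrow(descriptors),
    all(c("residue_a", "residue_b", "transform") %in% names(descriptors))
  )
  if (!all(is.finite(values))) abort("feature values must be finite")
  if (any(descriptors$residue_a >= descriptors$residue_b)) {
    abort("descriptors must have residue_a < residue_b")
  }
  key <- paste(descriptors$residue_a, descriptors$residue_b, descriptors$transform)
  if (anyDuplicated(key)) abort("duplicate feature descriptors")
  inv <- descriptors$transform == "inverse_closest_heavy"
  if (any(inv) && any(values[, inv, drop = FALSE] <= 0)) {
    abort("inverse closest-heavy features must be strictly positive")
  }
  descriptors$feature <- seq_len(nrow(descriptors))
  structure(
    list(values = values, descriptors = descriptors, labels = as.character(labels)),
    class = "feature_matrix"
  )
}

#' Featurize one or more ensembles
#'
#' Computes per-frame residue-pair features and stacks all ensembles into a
#' single labelled feature matrix suitable for classification and
#' dimensionality reduction. The default feature set is all residue pairs
#' with sequence separation of at least `min_sep` (to skip trivially
#' constant neighbours), transformed as inverse closest-heavy-atom
#' distances (1/Angstrom); `"ca_distance"` gives plain C-alpha distances.
#' Both are internal coordinates, so no frame alignment is needed.
#'
#' @param ensembles An `ensemble` or list of ensembles (their class labels
#'   become the frame labels).
#' @param model Matching `structure_model`.
#' @param transform `"inverse_closest_heavy"` or `"ca_distance"`.
#' @param pairs Optional two-column data frame (`residue_a`, `residue_b`)
#'   overriding the default pair set.
#' @param min_sep Minimum sequence separation for the default pair set.
#' @return A `feature_matrix`.
#' @export
featurize <- function(ensembles, model,
                      transform = c("inverse_closest_heavy", "ca_distance"),
                      pairs = NULL, min_sep = 3) {
  transform <- match.arg(transform)
  if (inherits(ensembles, "ensemble")) ensembles <- list(ensembles)
  if (is.null(pairs)) pairs <- default_pairs(model, min_sep)
  pairs <- as_tibble(pairs)
  flip <- pairs$residue_a > pairs$residue_b
  tmp <- pairs$residue_a[flip]
  pairs$residue_a[flip] <- pairs$residue_b[flip]
  pairs$residue_b[flip] <- tmp
  bad <- setdiff(c(pairs$residue_a, pairs$residue_b), model$residue_ids)
  if (length(bad) > 0) {
    abort(paste0("pairs refer to unknown residue id(s): ", paste(bad, collapse = ", ")))
  }
  blocks <- lapply(ensembles, function(e) {
    if (transform == "inverse_closest_heavy") {
      1 / pair_min_heavy_dist(e, model, pairs)
    } else {
      ca <- vapply(seq_len(nrow(pairs)), function(p) {
        ca_distance(e, model, pairs$residue_a[p], pairs$residue_b[p])
      }, numeric(e$frame_count))
      matrix(ca, nrow = e$frame_count)
    }
  })
  labels <- unlist(lapply(ensembles, function(e) rep(e$class_label, e$frame_count)))
  descriptors <- tibble(
    residue_a = pairs$residue_a, residue_b = pairs$residue_b,
    transform = transform
  )
  new_feature_matrix(do.call(rbind, blocks), descriptors, labels)
}

#' Per-frame C-alpha distance between two residues
#'
#' @param ensemble An `ensemble`.
#' @param model Matching `structure_model`.
#' @param res_a,res_b Residue ids.
#' @return Numeric vector, one distance (Angstrom) per frame.
#' @export
ca_distance <- function(ensemble, model, res_a, res_b) {
  a <- ca_of(model, res_a)
  b <- ca_of(model, res_b)
  sqrt(
    (ensemble$coords[, a, 1] - ensemble$coords[, b, 1])^2 +
      (ensemble$coords[, a, 2] - ensemble$coords[, b, 2])^2 +
      (ensemble$coords[, a, 3] - ensemble$coords[, b, 3])^2
  )
}

#' Optimal rigid-body superposition (Kabsch) and RMSD
#'
#' Superposes `coords_b` onto `coords_a` by the least-squares optimal proper
#' rotation (determinant +1) computed on `fit_indices`, then reports the RMSD
#' over `rmsd_indices`. The returned transform maps mobile coordinates as
#' `aligned = sweep(coords_b, 2, -translation) %*% rotation` is *not* the
#' convention used; instead `aligned = (coords_b - centroid_b) %*% rotation +
#' centroid_a`, both centroids over the fit set.
#'
#' @param coords_a Reference coordinates, n x 3.
#' @param coords_b Mobile coordinates, n x 3.
#' @param fit_indices Rows used for the superposition (default all).
#' @param rmsd_indices Rows the RMSD is computed over (default all).
#' @return List with `rotation` (3 x 3), `translation` (length 3), `rmsd`
#'   (Angstrom) and `aligned` (the transformed mobile coordinates).
#' @export
kabsch_rmsd <- function(coords_a, coords_b, fit_indices = NULL, rmsd_indices = NULL) {
  coords_a <- as.matrix(coords_a)
  coords_b <- as.matrix(coords_b)
  stopifnot(ncol(coords_a) == 3, all(dim(coords_a) == dim(coords_b)))
  if (is.null(fit_indices)) fit_indices <- seq_len(nrow(coords_a))
  if (is.null(rmsd_indices)) rmsd_indices <- seq_len(nrow(coords_a))
  if (length(fit_indices) < 3) abort("need at least 3 fit points")
  pa <- coords_a[fit_indices, , drop = FALSE]
  pb <- coords_b[fit_indices, , drop = FALSE]
  ca_c <- colMeans(pa)
  cb_c <- colMeans(pb)
  pa <- sweep(pa, 2, ca_c)
  pb <- sweep(pb, 2, cb_c)
  # degenerate (collinear/coincident) fit sets have rank < 2
  if (svd(pa)$d[2] < 1e-8 || svd(pb)$d[2] < 1e-8) {
    abort("degenerate fit set: fit points are collinear or coincident")
  }
  m <- crossprod(pb, pa) # maximize tr(R' t(pb) pa) over proper rotations R
  sv <- svd(m)
  d <- sign(det(sv$u %*% t(sv$v)))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  aligned <- sweep(coords_b, 2, cb_c) %*% rot
  aligned <- sweep(aligned, 2, ca_c, "+")
  dev <- coords_a[rmsd_indices, , drop = FALSE] - aligned[rmsd_indices, , drop = FALSE]
  list(
    rotation = rot,
    translation = as.numeric(ca_c - cb_c %*% rot),
    rmsd = sqrt(mean(rowSums(dev^2))),
    aligned = aligned
  )
}

core_atoms <- function(model, core = NULL) {
  if (is.null(core)) unname(model$ca_index) else core
}

#' Superpose every frame of an ensemble on a core selection
#'
#' Frames are first aligned to the initial frame on the core atoms (all
#' C-alpha by default), then re-aligned to the resulting frame-average
#' structure, removing global rigid-body motion.
#'
#' @param ensemble An `ensemble`.
#' @param model Matching `structure_model`.
#' @param core Atom indices used for the fit (default: all C-alpha atoms).
#' @return A superposed `ensemble`.
#' @export
superpose_ensemble <- function(ensemble, model, core = NULL) {
  core <- core_atoms(model, core)
  coords <- ensemble$coords
  ref <- coords[1, , ]
  pass <- function(target) {
    out <- coords
    for (f in seq_len(dim(coords)[1])) {
      out[f, , ] <- kabsch_rmsd(target, coords[f, , ], fit_indices = core)$aligned
    }
    out
  }
  coords <- pass(ref)
  avg <- apply(coords, c(2, 3), mean)
  coords0 <- coords
  for (f in seq_len(dim(coords)[1])) {
    coords[f, , ] <- kabsch_rmsd(avg, coords0[f, , ], fit_indices = core)$aligned
  }
  new_ensemble(coords, ensemble$class_label)
}

#' Root-mean-square fluctuation per residue
#'
#' RMSF of each residue's C-alpha around its time-average position, after
#' superposing every frame on the core selection.
#'
#' @inheritParams superpose_ensemble
#' @return Tibble with `residue_id` and `rmsf` (Angstrom).
#' @export
rmsf <- function(ensemble, model, core = NULL) {
  if (ensemble$frame_count < 2) abort("RMSF requires at least 2 frames")
  sup <- superpose_ensemble(ensemble, model, core)
  ca_idx <- model$ca_index
  vals <- vapply(seq_along(ca_idx), function(i) {
    xyz <- sup$coords[, unname(ca_idx[i]), ]
    mu <- colMeans(xyz)
    sqrt(mean(rowSums(sweep(xyz, 2, mu)^2)))
  }, numeric(1))
  tibble(residue_id = as.integer(names(ca_idx)), rmsf = vals)
}

#' GPCR activation microswitches per frame
#'
#' Computes the three activation reporters used for class A GPCRs: the
#' TM6-TM3 separation (C-alpha distance between generic positions 3.50 and
#' 6.34), the Y-Y motif (closest heavy-atom distance between 5.58 and 7.53)
#' and the RMSD of the NPxxY motif (generic positions 7.49-7.53, heavy
#' atoms) against a reference structure after superposing each frame on the
#' core selection.
#'
#' @param ensemble An `ensemble`.
#' @param model `structure_model` with a label map resolving 3.50, 6.34,
#'   5.58 and 7.49-7.53.
#' @param npxxy_reference Optional atoms x 3 reference coordinate matrix
#'   (e.g. the starting active structure); defaults to frame 1.
#' @param core Atom indices for the superposition (default: all C-alpha).
#' @return Tibble with `frame`, `label`, `tm6_tm3`, `yy`, `npxxy_rmsd`
#'   (all Angstrom).
#' @export
microswitches <- function(ensemble, model, npxxy_reference = NULL, core = NULL) {
  r350 <- resolve_label(model, "3.50")
  r634 <- resolve_label(model, "6.34")
  r558 <- resolve_label(model, "5.58")
  r753 <- resolve_label(model, "7.53")
  npxxy_ids <- vapply(
    c("7.49", "7.50", "7.51", "7.52", "7.53"),
    function(l) resolve_label(model, l), integer(1)
  )
  tm6_tm3 <- ca_distance(ensemble, model, r350, r634)
  yy <- as.numeric(pair_min_heavy_dist(
    ensemble, model,
    tibble(residue_a = min(r558, r753), residue_b = max(r558, r753))
  ))
  core <- core_atoms(model, core)
  npxxy_atoms <- unlist(lapply(npxxy_ids, function(r) heavy_atoms_of(model, r)))
  ref <- if (is.null(npxxy_reference)) ensemble$coords[1, , ] else as.matrix(npxxy_reference)
  if (nrow(ref) != dim(ensemble$coords)[2]) {
    abort("npxxy_reference must have one row per atom in the model")
  }
  npxxy_rmsd <- vapply(seq_len(ensemble$frame_count), function(f) {
    kabsch_rmsd(ref, ensemble$coords[f, , ],
      fit_indices = core, rmsd_indices = npxxy_atoms
    )$rmsd
  }, numeric(1))
  tibble(
    frame = seq_len(ensemble$frame_count),
    label = ensemble$class_label,
    tm6_tm3 = tm6_tm3, yy = yy, npxxy_rmsd = npxxy_rmsd
  )
}

#' Microswitch collective-variable set for the sampling controller
#'
#' Wraps [microswitches()] as a per-frame CV function: given one frame's
#' atoms x 3 coordinate matrix it returns the named vector (tm6_tm3, yy,
#' npxxy_rmsd) in Angstrom — the default CV set for driving
#' [run_controller()] on receptor-like systems.
#'
#' @inheritParams microswitches
#' @return `function(coords)` returning a named length-3 numeric vector.
#' @export
make_microswitch_cvs <- function(model, npxxy_reference = NULL, core = NULL) {
  force(model)
  force(npxxy_reference)
  force(core)
  function(coords) {
    coords <- as.matrix(coords)
    frame <- array(coords, dim = c(1, nrow(coords), 3))
    ms <- microswitches(new_ensemble(frame, "cv"), model,
      npxxy_reference = npxxy_reference %||% coords, core = core
    )
    c(tm6_tm3 = ms$tm6_tm3, yy = ms$yy, npxxy_rmsd = ms$npxxy_rmsd)
  }
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix> %d frames x %d features (%s); classes: %s\n",
    nrow(x$values), ncol(x$values),
    paste(unique(x$descriptors$transform), collapse = ", "),
    paste(unique(x$labels), collapse = ", ")
  ))
  invisible(x)
}

#' @rdname tidy_allokit
#' @export
tidy.feature_matrix <- function(x, ...) {
  vals <- as_tibble(x$values, .name_repair = function(nm) {
    paste0("f", seq_len(ncol(x$values)))
  })
  out <- dplyr::bind_cols(
    tibble(frame = seq_len(nrow(x$values)), label = x$labels), vals
  )
  tidyr::pivot_longer(out, -c("frame", "label"),
    names_to = "feature", values_to = "value"
  ) |>
    mutate(feature = as.integer(sub("^f", "", .data$feature))) |>
    left_join(x$descriptors, by = "feature")
}

#' @rdname tidy_allokit
#' @export
glance.feature_matrix <- function(x, ...) {
  tibble(
    n_frames = nrow(x$values), n_features = ncol(x$values),
    transform = paste(unique(x$descriptors$transform), collapse = ","),
    classes = paste(unique(x$labels), collapse = ",")
  )
}

#' Export a feature matrix to CSV
#'
#' Writes the values (one row per frame, with label) and a descriptor
#' sidecar mapping columns to residue pairs.
#'
#' @param fm A `feature_matrix`.
#' @param values_path,descriptors_path Output CSV paths.
#' @return `values_path`, invisibly.
#' @export
write_feature_csv <- function(fm, values_path, descriptors_path) {
  vals <- as.data.frame(fm$values)
  names(vals) <- paste0("f", seq_len(ncol(vals)))
  readr::write_csv(dplyr::bind_cols(tibble(label = fm$labels), vals), values_path)
  readr::write_csv(fm$descriptors, descriptors_path)
  invisible(values_path)
}
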