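#' Dimensionality reduction of feature matrices
#'
#' PCA (eigendecomposition of the data covariance) and metric MDS
#' (SMACOF stress majorization on pairwise Euclidean distances), plus the
#' unsupervised per-feature importance obtained by multiplying principal
#' components with their eigenvalues and projecting back onto the input
#' features. The pipeline default of four components matches the practice
#' of inspecting conformational landscapes as (PC1, PC2) and (PC3, PC4)
#' panels.
#'
#' @name dimred
NULL

fm_values <- function(x) {
  if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
}

fm_labels <- function(x) {
  if (inherits(x, "feature_matrix")) x$labels else rep(NA_character_, nrow(as.matrix(x)))
}

#' Principal component analysis
#'
#' Mean-centred covariance eigendecomposition. Component signs are fixed so
#' that each component's largest-magnitude loading is positive, making the
#' decomposition fully deterministic.
#'
#' @param x A `feature_matrix` or a frames x features matrix.
#' @param n_components Number of components to keep (<= min(frames - 1,
#'   features)).
#' @return A `projection` object with `embedding`, `components` (rows are
#'   components), `eigenvalues`, and the full eigenvalue spectrum in
#'   `all_eigenvalues`.
#' @export
fit_pca <- function(x, n_components = 4) {
  values <- fm_values(x)
  n <- nrow(values)
  p <- ncol(values)
  if (n < 2) abort("PCA requires at least 2 frames")
  if (n_components > min(n - 1, p)) {
    abort(sprintf("n_components must be <= min(frames - 1, features) = %d", min(n - 1, p)))
  }
  pr <- stats::prcomp(values, center = TRUE, scale. = FALSE)
  k <- n_components
  comps <- t(pr$rotation[, seq_len(k), drop = FALSE])
  emb <- pr$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    lead <- which.max(abs(comps[j, ]))
    if (comps[j, lead] < 0) {
      comps[j, ] <- -comps[j, ]
      emb[, j] <- -emb[, j]
    }
  }
  dimnames(emb) <- list(NULL, paste0("comp", seq_len(k)))
  eig <- pr$sdev^2
  structure(
    list(
      method = "pca",
      embedding = emb,
      components = comps,
      eigenvalues = eig[seq_len(k)],
      all_eigenvalues = eig,
      center = pr$center,
      stress = NULL,
      n_components = k,
      labels = fm_labels(x)
    ),
    class = "projection"
  )
}

mds_stress <- function(embedding, delta) {
  d <- as.matrix(stats::dist(embedding))
  sum(((d - delta)[upper.tri(delta)])^2)
}

#' Metric multidimensional scaling (SMACOF)
#'
#' Finds a low-dimensional embedding minimizing the raw stress
#' `sum((d_ij - delta_ij)^2)` over all pairs, where `delta` are the
#' pairwise Euclidean distances of the input (or a user-supplied distance
#' matrix). Initialization is the deterministic classical (Torgerson)
#' scaling solution unless `init = "random"`, in which case `seed` controls
#' it; SMACOF majorization then decreases stress monotonically.
#'
#' @param x A `feature_matrix`, a frames x features matrix, or a distance
#'   matrix (`dist` objects, or square symmetric zero-diagonal matrices,
#'   or any matrix with `distance = TRUE`).
#' @param n_components Embedding dimension.
#' @param max_iter,tol Majorization iteration controls (relative stress
#'   change).
#' @param init `"torgerson"` (default, deterministic) or `"random"`.
#' @param seed Seed used for random initializations.
#' @param n_starts Number of starts: the first uses `init`, the rest are
#'   random restarts (majorization only finds local optima; restarts are
#'   the standard guard). The lowest-stress solution is returned;
#'   deterministic given `seed`.
#' @param distance Force interpreting `x` as a distance matrix.
#' @return A `projection` with `embedding` and final `stress`.
#' @export
fit_mds <- function(x, n_components = 2, max_iter = 500, tol = 1e-10,
                    init = c("torgerson", "random"), seed = 1,
                    n_starts = 1, distance = NULL) {
  init <- match.arg(init)
  labels <- fm_labels(x)
  if (inherits(x, "dist")) {
    delta <- as.matrix(x)
  } else {
    values <- fm_values(x)
    looks_dist <- nrow(values) == ncol(values) &&
      isSymmetric(unname(values), tol = 1e-12) &&
      all(abs(diag(values)) < 1e-12)
    if (isTRUE(distance) || (is.null(distance) && looks_dist)) {
      if (!isSymmetric(unname(values), tol = 1e-8)) {
        abort("distance matrix must be symmetric")
      }
      delta <- values
    } else {
      delta <- as.matrix(stats::dist(values))
    }
  }
  n <- nrow(delta)
  if (n < n_components + 1) abort("need at least n_components + 1 points")
  torgerson_start <- function() {
    cm <- stats::cmdscale(delta, k = n_components)
    if (ncol(cm) < n_components) { # degenerate spectrum: pad with zeros
      cm <- cbind(cm, matrix(0, n, n_components - ncol(cm)))
    }
    cm
  }
  random_start <- function(s) {
    withr::with_seed(s, matrix(stats::rnorm(n * n_components, sd = mean(delta) / 2), n))
  }
  smacof_run <- function(emb) {
    stress <- mds_stress(emb, delta)
    for (it in seq_len(max_iter)) {
      d <- as.matrix(stats::dist(emb))
      ratio <- ifelse(d > 1e-12, delta / d, 0)
      b <- -ratio
      diag(b) <- 0
      diag(b) <- -rowSums(b)
      emb_new <- (b %*% emb) / n # Guttman transform
      stress_new <- mds_stress(emb_new, delta)
      done <- stress - stress_new <= tol * max(stress, .Machine$double.eps)
      emb <- emb_new
      stress <- stress_new
      if (done) break
    }
    list(emb = emb, stress = stress)
  }
  best <- smacof_run(if (init == "torgerson") torgerson_start() else random_start(seed))
  for (s in seq_len(n_starts - 1)) {
    cand <- smacof_run(random_start(derive_seed(seed, "mds", s)))
    if (cand$stress < best$stress) best <- cand
  }
  emb <- best$emb
  stress <- best$stress
  dimnames(emb) <- list(NULL, paste0("comp", seq_len(n_components)))
  structure(
    list(
      method = "mds",
      embedding = emb,
      components = NULL,
      eigenvalues = NULL,
      all_eigenvalues = NULL,
      center = NULL,
      stress = stress,
      n_components = n_components,
      labels = if (length(labels) == n) labels else rep(NA_character_, n)
    ),
    class = "projection"
  )
}

#' Unsupervised per-feature importance from PCA loadings
#'
#' Back-projects the principal components onto the input features:
#' `importance_f = sum_k eigenvalue_k * |loading_kf|`, then min-max
#' normalised to `[0, 1]`.
#'
#' @param proj A PCA `projection` from [fit_pca()].
#' @return Numeric vector of per-feature importances in `[0, 1]`.
#' @export
pca_importance <- function(proj) {
  stopifnot(inherits(proj, "projection"))
  if (proj$method != "pca") abort("pca_importance requires a PCA projection")
  raw <- as.numeric(proj$eigenvalues %*% abs(proj$components))
  minmax(raw)
}

#' @export
print.projection <- function(x, ...) {
  cat(sprintf(
    "<projection> %s, %d points x %d components%s\n",
    toupper(x$method), nrow(x$embedding), x$n_components,
    if (x$method == "mds") sprintf(", stress %.4g", x$stress) else ""
  ))
  invisible(x)
}

#' @rdname tidy_allokit
#' @export
tidy.projection <- function(x, ...) {
  dplyr::bind_cols(
    tibble(frame = seq_len(nrow(x$embedding)), label = x$labels),
    as_tibble(x$embedding)
  )
}

#' @rdname tidy_allokit
#' @export
glance.projection <- function(x, ...) {
  tibble(
    method = x$method,
    n_components = x$n_components,
    explained_variance = if (x$method == "pca") {
      sum(x$eigenvalues) / sum(x$all_eigenvalues)
    } else {
      NA_real_
    },
    stress = if (x$method == "mds") x$stress else NA_real_
  )
}

#' Scatter plot of a projection
#'
#' @param object A `projection`.
#' @param dims Which two components to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.projection <- function(object, dims = c(1, 2), ...) {
  df <- tidy(object)
  xn <- paste0("comp", dims[1])
  yn <- paste0("comp", dims[2])
  ggplot2::ggplot(df, ggplot2::aes(.data[[xn]], .data[[yn]], colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::labs(
      x = xn, y = yn, colour = "class",
      title = sprintf("%s projection", toupper(object$method))
    ) +
    ggplot2::theme_minimal()
}
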