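#' Per-residue importance profiling
#'
#' Three routes to a per-residue importance profile for discriminating two
#' conformational ensembles: (i) symmetrised Kullback-Leibler divergence of
#' the per-feature class distributions (the distribution-overlap control),
#' (ii) a multilayer perceptron classifier whose decision is decomposed
#' onto input features by epsilon-rule layerwise relevance propagation, and
#' (iii) unsupervised PCA loading back-projection ([pca_importance()]).
#' Pairwise-feature scores are aggregated to residues by the maximum over a
#' residue's features and min-max normalised, so the top residue scores 1.
#'
#' @name importance
NULL

fd_bins <- function(x, cap = 50) {
  iqr <- stats::IQR(x)
  if (iqr == 0) {
    return(10)
  }
  h <- 2 * iqr / length(x)^(1 / 3)
  max(2, min(cap, ceiling(diff(range(x)) / h)))
}

#' Symmetrised KL divergence per feature
#'
#' Both classes are histogrammed on shared bin edges spanning the pooled
#' range (Freedman-Diaconis bin count, capped at 50, unless `n_bins` is
#' given), a pseudo-count of 1 is added to every bin, and the symmetrised
#' divergence `0.5 * (KL(P||Q) + KL(Q||P))` (natural log) is returned.
#' High divergence marks features whose class distributions do not
#' overlap. Constant features get divergence 0 by convention.
#'
#' @param fm A `feature_matrix` with exactly two classes.
#' @param n_bins Optional fixed bin count.
#' @return Tibble: descriptors plus `score` and `method = "kl"`.
#' @export
kl_importance <- function(fm, n_bins = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  classes <- unique(fm$labels)
  if (length(classes) != 2) abort("kl_importance requires exactly 2 classes")
  ia <- fm$labels == classes[1]
  ib <- fm$labels == classes[2]
  if (sum(ia) < 2 || sum(ib) < 2) abort("each class needs at least 2 frames")
  scores <- vapply(seq_len(ncol(fm$values)), function(f) {
    x <- fm$values[, f]
    rng <- range(x)
    if (diff(rng) == 0) {
      return(0)
    }
    nb <- if (is.null(n_bins)) fd_bins(x) else n_bins
    edges <- seq(rng[1], rng[2], length.out = nb + 1)
    bin <- pmin(pmax(findInterval(x, edges, all.inside = TRUE), 1), nb)
    p <- tabulate(bin[ia], nb) + 1
    q <- tabulate(bin[ib], nb) + 1
    p <- p / sum(p)
    q <- q / sum(q)
    0.5 * (sum(p * log(p / q)) + sum(q * log(q / p)))
  }, numeric(1))
  mutate(fm$descriptors, score = scores, method = "kl")
}

relu <- function(x) pmax(x, 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Train a multilayer perceptron classifier
#'
#' A softmax-output feed-forward network with one hidden ReLU layer,
#' trained by mini-batch gradient descent (Adam) on z-scored features until
#' the training loss plateaus. The network carries no bias terms so that
#' epsilon-rule relevance propagation conserves relevance exactly (inputs
#' are standardized, so biases contribute little here). A stratified
#' held-out split is always evaluated to flag overfitting, although
#' relevance is interpreted on the training distribution.
#'
#' @param fm A `feature_matrix` with >= 2 classes, each with >= 2 frames.
#' @param hidden Hidden layer width (default 64).
#' @param max_epochs,batch_size,learning_rate,l2 Optimiser controls.
#' @param val_fraction Held-out fraction for the reported accuracy.
#' @param tol Relative loss-improvement threshold for the plateau stop.
#' @param seed Integer seed (initialisation, shuffling, split).
#' @return An `mlp_model`.
#' @export
train_mlp <- function(fm, hidden = 64, max_epochs = 150, batch_size = 256,
                      learning_rate = 0.01, l2 = 1e-4, val_fraction = 0.2,
                      tol = 1e-4, seed = 1) {
  stopifnot(inherits(fm, "feature_matrix"))
  y_f <- factor(fm$labels)
  classes <- levels(y_f)
  if (length(classes) < 2) abort("need at least 2 classes")
  if (any(table(y_f) < 2)) abort("every class needs at least 2 frames")
  x <- fm$values
  mu <- colMeans(x)
  sd_ <- apply(x, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sd_, "/")
  y <- as.integer(y_f)
  n <- nrow(xs)
  p <- ncol(xs)
  k <- length(classes)

  withr::with_seed(seed, {
    val_idx <- unlist(lapply(seq_len(k), function(cl) {
      members <- which(y == cl)
      sample(members, max(1, floor(length(members) * val_fraction)))
    }))
    train_idx <- setdiff(seq_len(n), val_idx)
    w1 <- matrix(stats::rnorm(p * hidden, sd = sqrt(2 / p)), p, hidden)
    w2 <- matrix(stats::rnorm(hidden * k, sd = sqrt(2 / hidden)), hidden, k)
    m1 <- v1 <- matrix(0, p, hidden)
    m2 <- v2 <- matrix(0, hidden, k)
    b1 <- 0.9
    b2_ <- 0.999
    eps <- 1e-8
    step <- 0
    prev_loss <- Inf
    epochs_run <- 0
    onehot <- diag(k)[y, , drop = FALSE]
    for (epoch in seq_len(max_epochs)) {
      idx <- sample(train_idx)
      batches <- split(idx, ceiling(seq_along(idx) / batch_size))
      total_loss <- 0
      for (batch in batches) {
        xb <- xs[batch, , drop = FALSE]
        yb <- onehot[batch, , drop = FALSE]
        a1 <- relu(xb %*% w1)
        z2 <- a1 %*% w2
        prob <- softmax_rows(z2)
        total_loss <- total_loss - sum(log(pmax(prob[yb == 1], 1e-12)))
        dz2 <- (prob - yb) / length(batch)
        g2 <- crossprod(a1, dz2) + l2 * w2
        da1 <- dz2 %*% t(w2)
        da1[a1 <= 0] <- 0
        g1 <- crossprod(xb, da1) + l2 * w1
        step <- step + 1
        m1 <- b1 * m1 + (1 - b1) * g1
        v1 <- b2_ * v1 + (1 - b2_) * g1^2
        m2 <- b1 * m2 + (1 - b1) * g2
        v2 <- b2_ * v2 + (1 - b2_) * g2^2
        lr_t <- learning_rate * sqrt(1 - b2_^step) / (1 - b1^step)
        w1 <- w1 - lr_t * m1 / (sqrt(v1) + eps)
        w2 <- w2 - lr_t * m2 / (sqrt(v2) + eps)
      }
      epochs_run <- epoch
      loss <- total_loss / length(train_idx)
      if (is.finite(prev_loss) &&
        prev_loss - loss < tol * max(abs(prev_loss), 1e-8)) {
        break
      }
      prev_loss <- loss
    }
  })

  predict_class <- function(rows) {
    a1 <- relu(xs[rows, , drop = FALSE] %*% w1)
    max.col(a1 %*% w2, ties.method = "first")
  }
  train_acc <- mean(predict_class(train_idx) == y[train_idx])
  val_acc <- mean(predict_class(val_idx) == y[val_idx])

  structure(
    list(
      w1 = w1, w2 = w2, mu = mu, sd = sd_, classes = classes,
      hidden = hidden, seed = seed, epochs = epochs_run,
      train_accuracy = train_acc, val_accuracy = val_acc,
      n_features = p
    ),
    class = "mlp_model"
  )
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf(
    "<mlp_model> %d -> %d -> %d, %d epoch(s); train acc %.3f, held-out acc %.3f\n",
    x$n_features, x$hidden, length(x$classes), x$epochs,
    x$train_accuracy, x$val_accuracy
  ))
  invisible(x)
}

#' @rdname tidy_allokit
#' @export
glance.mlp_model <- function(x, ...) {
  tibble(
    n_features = x$n_features, hidden = x$hidden,
    n_classes = length(x$classes), epochs = x$epochs,
    train_accuracy = x$train_accuracy, val_accuracy = x$val_accuracy
  )
}

#' Layerwise relevance propagation (epsilon rule)
#'
#' Propagates the pre-softmax score of each frame's true-class output unit
#' back to the input features with the epsilon-stabilised rule
#' (`epsilon = 1e-9`). Per sample, the input relevances sum to the output
#' score up to the epsilon-induced tolerance. Relevances are averaged over
#' frames within each class and then across classes.
#'
#' @param model An `mlp_model` trained on the same feature space.
#' @param fm The `feature_matrix` to explain.
#' @param samplewise If `TRUE`, also return the per-sample relevance matrix
#'   and output scores (used to verify relevance conservation).
#' @return Tibble of descriptors plus `score` (mean relevance) and
#'   `method = "mlp_lrp"`; with `samplewise = TRUE`, a list with elements
#'   `relevance` (frames x features), `output_score` and `per_feature`.
#' @export
lrp_relevance <- function(model, fm, samplewise = FALSE) {
  stopifnot(inherits(model, "mlp_model"), inherits(fm, "feature_matrix"))
  if (ncol(fm$values) != model$n_features) {
    abort("feature-count mismatch between model and feature matrix")
  }
  eps <- 1e-9
  xs <- sweep(sweep(fm$values, 2, model$mu), 2, model$sd, "/")
  cls <- match(fm$labels, model$classes)
  if (anyNA(cls)) abort("feature matrix contains labels unseen at training")
  z1 <- xs %*% model$w1
  a1 <- relu(z1)
  z2 <- a1 %*% model$w2
  n <- nrow(xs)
  out_score <- z2[cbind(seq_len(n), cls)]
  # hidden relevance: R1_ij = a1_ij * w2[j, c_i] * R_out / (z2_c + eps*sign)
  w2c <- t(model$w2)[cls, , drop = FALSE] # n x hidden
  denom2 <- out_score + eps * sign(out_score)
  r1 <- a1 * w2c * (out_score / ifelse(denom2 == 0, eps, denom2))
  # input relevance: R0_if = xs_if * sum_j w1[f, j] * r1_ij / (z1_ij + eps*sign)
  denom1 <- z1 + eps * sign(z1)
  denom1[denom1 == 0] <- eps
  g <- r1 / denom1
  r0 <- xs * (g %*% t(model$w1))
  per_class <- lapply(unique(cls), function(cl) colMeans(r0[cls == cl, , drop = FALSE]))
  per_feature <- Reduce(`+`, per_class) / length(per_class)
  tab <- mutate(fm$descriptors, score = per_feature, method = "mlp_lrp")
  if (samplewise) {
    list(relevance = r0, output_score = out_score, per_feature = tab)
  } else {
    tab
  }
}

#' Aggregate per-feature scores to a residue importance profile
#'
#' Residue score = the maximum absolute score over all pair-features the
#' residue participates in (so one sharp contact change is not diluted;
#' `agg = "mean"` averages instead), min-max normalised to `[0, 1]`.
#' Residues with no features score 0, with a warning.
#'
#' @param per_feature Either the tibble returned by [kl_importance()] /
#'   [lrp_relevance()] (with `score` column) or a numeric vector, in which
#'   case `descriptors` must be supplied.
#' @param model The `structure_model` (fixes the residue set of the
#'   profile).
#' @param descriptors Feature descriptors when `per_feature` is a bare
#'   vector.
#' @param method Method tag recorded in the profile.
#' @param agg `"max"` (default) or `"mean"`.
#' @return Tibble: `residue_id`, `importance` in `[0, 1]`, `method`.
#' @export
residue_importance <- function(per_feature, model, descriptors = NULL,
                               method = NULL, agg = c("max", "mean")) {
  agg <- match.arg(agg)
  if (is.data.frame(per_feature)) {
    descriptors <- per_feature
    scores <- per_feature$score
    if (is.null(method) && "method" %in% names(per_feature)) {
      method <- per_feature$method[1]
    }
  } else {
    if (is.null(descriptors)) abort("descriptors required for a bare score vector")
    scores <- as.numeric(per_feature)
  }
  if (is.null(method)) method <- "custom"
  stopifnot(length(scores) == nrow(descriptors))
  ids <- model$residue_ids
  long <- tibble(
    residue_id = c(descriptors$residue_a, descriptors$residue_b),
    s = rep(abs(scores), 2)
  )
  per_res <- long |>
    group_by(.data$residue_id) |>
    summarise(raw = if (agg == "max") max(.data$s) else mean(.data$s)) |>
    ungroup()
  missing <- setdiff(ids, per_res$residue_id)
  if (length(missing) > 0) {
    warn(sprintf("%d residue(s) participate in no feature; importance set to 0", length(missing)))
  }
  out <- tibble(residue_id = ids) |>
    left_join(per_res, by = "residue_id") |>
    mutate(raw = ifelse(is.na(.data$raw), 0, .data$raw))
  tibble(
    residue_id = out$residue_id,
    importance = minmax(out$raw),
    method = method
  )
}

#' Compute all residue importance profiles
#'
#' Runs the supervised (KL, MLP+LRP) and unsupervised (PCA back-projection)
#' importance methods and stacks the per-residue profiles. When given raw
#' ensembles, each method uses its field convention: KL and the MLP run on
#' inverse closest-heavy-atom distances, while PCA importance runs on plain
#' C-alpha distances (inverse distances have heavy-tailed variance near
#' contact, which dominates an unsupervised covariance eigendecomposition;
#' C-alpha distances keep feature noise commensurate). MLP relevance is
#' averaged over `n_models` independently initialised networks, the
#' standard way to stabilise relevance against initialisation noise.
#'
#' @param x A list of `ensemble`s (two classes; recommended) or a single
#'   two-class `feature_matrix` used for every method.
#' @param model Matching `structure_model`.
#' @param methods Subset of `c("kl", "mlp_lrp", "pca")`.
#' @param n_components Components used by the PCA route.
#' @param n_models MLP ensemble size for relevance averaging.
#' @param seed Seed for MLP training (per-model seeds are derived).
#' @param min_sep Sequence-separation cutoff for the default feature pairs.
#' @param ... Passed on to [train_mlp()].
#' @return Tibble: `residue_id`, `importance`, `method` (stacked profiles).
#' @export
importance_profiles <- function(x, model, methods = c("kl", "mlp_lrp", "pca"),
                                n_components = 4, n_models = 3, seed = 1,
                                min_sep = 3, ...) {
  if (inherits(x, "feature_matrix")) {
    fm <- x
    fm_ca <- x
  } else {
    fm <- featurize(x, model, transform = "inverse_closest_heavy", min_sep = min_sep)
    fm_ca <- if ("pca" %in% methods) {
      featurize(x, model, transform = "ca_distance", min_sep = min_sep)
    } else {
      NULL
    }
  }
  out <- list()
  if ("kl" %in% methods) {
    out$kl <- residue_importance(kl_importance(fm), model)
  }
  if ("mlp_lrp" %in% methods) {
    rel <- 0
    for (j in seq_len(n_models)) {
      mlp <- train_mlp(fm, seed = derive_seed(seed, "mlp", j), ...)
      rel <- rel + abs(lrp_relevance(mlp, fm)$score)
    }
    out$mlp <- residue_importance(rel / n_models, model,
      descriptors = fm$descriptors, method = "mlp_lrp"
    )
  }
  if ("pca" %in% methods) {
    proj <- fit_pca(fm_ca, n_components = min(n_components, nrow(fm_ca$values) - 1, ncol(fm_ca$values)))
    out$pca <- residue_importance(pca_importance(proj), model,
      descriptors = fm_ca$descriptors, method = "pca"
    )
  }
  dplyr::bind_rows(out)
}

#' Write a structure PDB coloured by residue importance
#'
#' Stamps the per-residue importance into the B-factor column of the
#' model's reference coordinates, for structure viewers.
#'
#' @param model A `structure_model`.
#' @param profile Importance profile tibble (`residue_id`, `importance`).
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_importance_pdb <- function(model, profile, path) {
  b <- profile$importance[match(model$atoms$residue_id, profile$residue_id)]
  b[is.na(b)] <- 0
  coords <- array(NA_real_, dim = c(1, nrow(model$atoms), 3))
  coords[1, , ] <- as.matrix(model$atoms[, c("x", "y", "z")])
  write_ensemble_pdb(new_ensemble(coords, "reference"), model, path, bfactor = b * 99.99)
}

#' Plot residue importance profiles
#'
#' @param profiles Tibble from [importance_profiles()] or
#'   [residue_importance()].
#' @return A ggplot (importance vs residue, one panel per method).
#' @export
plot_importance <- function(profiles) {
  ggplot2::ggplot(profiles, ggplot2::aes(.data$residue_id, .data$importance)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::facet_wrap(~method, ncol = 1) +
    ggplot2::labs(x = "residue", y = "normalised importance") +
    ggplot2::theme_minimal()
}
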