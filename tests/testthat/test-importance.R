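make_fm <- function(values, labels, transform = "ca_distance") {
  n <- ncol(values)
  new_feature_matrix(
    values,
    tibble::tibble(
      residue_a = seq_len(n), residue_b = seq_len(n) + n,
      transform = transform
    ),
    labels
  )
}

test_that("symmetrised KL is zero for identical class distributions", {
  x <- withr::with_seed(1, matrix(rnorm(400), 200, 2))
  fm <- make_fm(rbind(x, x), rep(c("a", "b"), each = 200))
  kl <- kl_importance(fm)
  expect_true(all(kl$score < 1e-12))
  # non-negative always
  fm2 <- make_fm(withr::with_seed(2, matrix(rnorm(200), 100)), rep(c("a", "b"), 50))
  expect_true(all(kl_importance(fm2)$score >= 0))
})

test_that("two-bin fully separated KL matches the hand-evaluated formula", {
  # class a occupies bin 1 (counts 10, 0), class b bin 2 (0, 10)
  vals <- cbind(c(seq(0, 0.4, length.out = 10), seq(0.6, 1, length.out = 10)))
  fm <- make_fm(vals, rep(c("a", "b"), each = 10))
  kl <- kl_importance(fm, n_bins = 2)
  # pseudo-count 1: P = (11, 1)/12, Q = (1, 11)/12; by symmetry
  # sKL = sum((p - q) * log(p / q)) / 2 = (10/12) * log(11)
  expect_equal(kl$score, (10 / 12) * log(11))
  # permutation-symmetric in the two classes
  fm_swap <- make_fm(vals, rep(c("b", "a"), each = 10))
  expect_equal(kl_importance(fm_swap, n_bins = 2)$score, kl$score)
})

test_that("constant features get divergence zero by convention", {
  vals <- cbind(rep(1, 40), c(rnorm(20), rnorm(20, 5)))
  fm <- make_fm(vals, rep(c("a", "b"), each = 20))
  kl <- kl_importance(fm)
  expect_equal(kl$score[1], 0)
  expect_gt(kl$score[2], 1)
  expect_error(kl_importance(make_fm(vals, rep("a", 40))), "exactly 2 classes")
})

test_that("MLP training is deterministic in the seed and learns planted signal", {
  gen <- quick_scenario(seed = 20, n_residues = 12, n_frames = 300)
  fm <- featurize(gen$ensembles, gen$model)
  m1 <- train_mlp(fm, seed = 5)
  m2 <- train_mlp(fm, seed = 5)
  expect_identical(m1$w1, m2$w1)
  expect_identical(m1$w2, m2$w2)
  m3 <- train_mlp(fm, seed = 6)
  expect_false(identical(m1$w1, m3$w1))
  expect_gt(m1$train_accuracy, 0.95)
  expect_gt(m1$val_accuracy, 0.95)
})

test_that("shuffled labels give chance held-out accuracy", {
  gen <- quick_scenario(seed = 21, n_residues = 12, n_frames = 2000)
  fm <- featurize(gen$ensembles, gen$model)
  fm$labels <- withr::with_seed(1, sample(fm$labels))
  m <- train_mlp(fm, seed = 2)
  expect_lt(abs(m$val_accuracy - 0.5), 0.05)
})

test_that("epsilon-rule relevance reduces to w*x through a linear network", {
  # hidden layer [relu(x); relu(-x)] with output weights [w; -w] computes
  # exactly w.x, so input relevance must be proportional to w_f * x_f
  p <- 4
  w <- c(0.8, -0.5, 0.3, 1.2)
  model <- structure(
    list(
      w1 = cbind(diag(p), -diag(p)),
      w2 = rbind(matrix(c(w, -w), p, 2), matrix(c(-w, w), p, 2)),
      mu = rep(0, p), sd = rep(1, p), classes = c("a", "b"),
      hidden = 2L * p, seed = 1L, epochs = 0L,
      train_accuracy = NA_real_, val_accuracy = NA_real_, n_features = p
    ),
    class = "mlp_model"
  )
  x <- withr::with_seed(3, matrix(rnorm(12 * p), 12, p))
  labels <- ifelse(x %*% w > 0, "a", "b") # true class = sign of w.x
  fm <- make_fm(x, labels)
  out <- lrp_relevance(model, fm, samplewise = TRUE)
  expected <- sweep(x, 2, w, "*") * ifelse(c(x %*% w) > 0, 1, -1)
  expect_equal(out$relevance, unname(expected), tolerance = 1e-6)
})

test_that("relevance is conserved from output score to inputs", {
  gen <- quick_scenario(seed = 22, n_residues = 10, n_frames = 150)
  fm <- featurize(gen$ensembles, gen$model)
  m <- train_mlp(fm, seed = 3)
  out <- lrp_relevance(m, fm, samplewise = TRUE)
  total_in <- rowSums(out$relevance)
  rel_err <- abs(total_in - out$output_score) / pmax(abs(out$output_score), 1e-8)
  expect_lt(max(rel_err), 1e-4)
  expect_error(lrp_relevance(m, make_fm(matrix(0, 4, 2), rep(c("a", "b"), 2))), "mismatch")
})

test_that("residue aggregation takes the max feature and normalises to [0, 1]", {
  model <- ca_only_model(1:5)
  desc <- tibble::tibble(
    residue_a = c(1, 1, 2), residue_b = c(3, 4, 4),
    transform = "ca_distance"
  )
  # residue 5 has no features throughout: warnings checked once below
  prof <- suppressWarnings(
    residue_importance(c(0, 2, 0), model, descriptors = desc, method = "toy")
  )
  expect_equal(prof$importance, c(1, 0, 0, 1, 0))
  # scaling all features x10 leaves the profile unchanged
  prof10 <- suppressWarnings(
    residue_importance(c(0, 20, 0), model, descriptors = desc, method = "toy")
  )
  expect_equal(prof10$importance, prof$importance)
  # residue 5 participates in no feature: zero with a warning
  expect_warning(
    residue_importance(c(1, 1, 1), model, descriptors = desc, method = "toy"),
    "no feature"
  )
  # mean aggregation is available
  prof_mean <- suppressWarnings(
    residue_importance(c(1, 3, 0), model,
      descriptors = desc, method = "toy", agg = "mean"
    )
  )
  expect_equal(prof_mean$importance[1], 1) # residue 1: mean(1, 3) = 2, the max
})

test_that("supervised and unsupervised profiles agree on a strong planted signal", {
  gen <- quick_scenario(seed = 23, n_residues = 16, n_frames = 400, sigma = 1.0, rho_in = 0.1)
  profs <- importance_profiles(gen$ensembles, gen$model, n_models = 2, seed = 1)
  expect_setequal(unique(profs$method), c("kl", "mlp_lrp", "pca"))
  expect_equal(nrow(profs), 3 * 16)
  expect_true(all(profs$importance >= 0 & profs$importance <= 1))
  wide <- tidyr::pivot_wider(profs, names_from = "method", values_from = "importance")
  expect_gt(stats::cor(wide$kl, wide$mlp_lrp, method = "spearman"), 0.3)
  expect_s3_class(plot_importance(profs), "ggplot")
})

test_that("importance PDB stamps the profile into B-factors", {
  gen <- quick_scenario(seed = 24, n_residues = 8, n_frames = 60)
  prof <- tibble::tibble(
    residue_id = 1:8, importance = seq(0, 1, length.out = 8), method = "kl"
  )
  path <- tempfile(fileext = ".pdb")
  write_importance_pdb(gen$model, prof, path)
  lines <- readLines(path)
  b <- as.numeric(substr(grep("^ATOM", lines, value = TRUE), 61, 66))
  expect_equal(sort(unique(b)), sort(unique(round(prof$importance * 99.99, 2))), tolerance = 0.01)
})
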