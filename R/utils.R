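#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows across
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' Derive a reproducible child seed
#'
#' Hashes a parent seed together with any number of integer or character
#' tags into a new seed in `[1, 2^31 - 2]`. Used so that pipeline stages,
#' controller iterations and replicas each get an independent, reproducible
#' RNG stream from one top-level seed.
#'
#' @param seed Integer parent seed.
#' @param ... Integer or character tags (stage name, iteration, replica index).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.numeric(seed) %% m
  for (tag in list(...)) {
    codes <- if (is.character(tag)) utf8ToInt(paste(tag, collapse = "|")) else as.numeric(tag)
    for (x in codes) {
      h <- (h * 48271 + x + 1) %% m
    }
  }
  as.integer(h %% (m - 2) + 1)
}

#' Min-max normalise a numeric vector to [0, 1]
#'
#' All-equal input maps to zeros (no signal convention).
#' @param x Numeric vector.
#' @return Numeric vector in `[0, 1]`.
#' @keywords internal
minmax <- function(x) {
  rng <- range(x, finite = TRUE)
  if (!all(is.finite(rng)) || diff(rng) == 0) {
    return(rep(0, length(x)))
  }
  (x - rng[1]) / diff(rng)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 means identical partitions (up to label permutation), 0 is the
#' expectation under independence.
#'
#' @param a,b Vectors of cluster labels, same length.
#' @return Scalar adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) {
    return(1)
  }
  (sum_ij - expected) / (maxi - expected)
}

vec_norm <- function(x) sqrt(sum(x^2))
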