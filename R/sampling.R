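#' Adaptive single-state sampling controller
#'
#' Iterative replica resampling toward the closest kinetically stable
#' state: a fixed count of replicas (24 by default) is launched, the swarm
#' center `c` in collective-variable space is computed, each replica is
#' weighted by its distance to the center, and replicas are cloned with
#' copy counts proportional to weight, keeping the total constant. The
#' controller stops when the center-to-center displacement between
#' subsequent iterations falls below the standard error of the replica
#' distances.
#'
#' @name sampling
NULL

#' Swarm center in CV space
#'
#' @param endpoints n x k matrix of replica endpoints in CV space.
#' @return Length-k arithmetic mean.
#' @export
compute_center <- function(endpoints) {
  endpoints <- rbind(endpoints) # promote a single vector to a 1 x k matrix
  if (nrow(endpoints) < 1) abort("empty endpoint set")
  colMeans(endpoints)
}

#' Replica distances and weights
#'
#' Distances are Euclidean distances `x_i` to the center, `d` their mean.
#' The default weight law `w_i = exp(-x_i / d)` is scale-free in `d`,
#' maximal at the center and strictly decreasing in distance, so
#' center-proximal replicas multiply under resampling. If `d = 0`
#' (all replicas at the center) every weight is 1. The law is pluggable:
#' `"rational"` uses `w_i = 1 / (1 + x_i / d)`.
#'
#' @param endpoints n x k matrix of replica endpoints.
#' @param center Length-k center.
#' @param law Weight law, `"exp"` (default) or `"rational"`.
#' @return List with `distances`, `mean_distance` and `weights`.
#' @export
assign_weights <- function(endpoints, center, law = c("exp", "rational")) {
  law <- match.arg(law)
  endpoints <- rbind(endpoints)
  if (length(center) != ncol(endpoints)) abort("center dimension mismatch")
  x <- sqrt(rowSums(sweep(endpoints, 2, center)^2))
  d <- mean(x)
  w <- if (d == 0) {
    rep(1, length(x))
  } else if (law == "exp") {
    exp(-x / d)
  } else {
    1 / (1 + x / d)
  }
  list(distances = x, mean_distance = d, weights = w)
}

#' Weight-proportional integer resampling (largest remainder)
#'
#' Apportions `total` copies across replicas proportionally to their
#' weights with the largest-remainder (Hamilton) method; remainder ties are
#' broken by replica index, so the result is deterministic. The copy total
#' is exactly `total` for any weight vector; replicas may receive 0 copies
#' (terminated).
#'
#' @param weights Non-negative weights, not all zero.
#' @param total Total copy count to distribute (default 24).
#' @return Integer vector of copy counts summing to `total`.
#' @export
resample_replicas <- function(weights, total = 24) {
  if (total < 1) abort("total must be >= 1")
  if (any(weights < 0) || any(!is.finite(weights))) abort("weights must be finite and non-negative")
  s <- sum(weights)
  if (s == 0) abort("all weights are zero")
  quota <- total * weights / s
  copies <- floor(quota)
  leftover <- total - sum(copies)
  if (leftover > 0) {
    pick <- order(-(quota - copies), seq_along(quota))[seq_len(leftover)]
    copies[pick] <- copies[pick] + 1
  }
  as.integer(copies)
}

#' Center-drift convergence test
#'
#' Converged when the distance between subsequent center points is strictly
#' smaller than the standard error of the replica distances,
#' `sd(x_i) / sqrt(n)`, computed on the current iteration. A center that
#' did not move at all (exactly zero drift, as a deterministic
#' zero-temperature backend produces once it reaches a fixed point) counts
#' as converged even when the standard error is zero.
#'
#' @param center_prev,center_curr Centers of two subsequent iterations.
#' @param distances Replica distances `x_i` of the current iteration
#'   (length >= 2).
#' @return Logical.
#' @export
check_convergence <- function(center_prev, center_curr, distances) {
  if (length(center_prev) != length(center_curr)) abort("center dimension mismatch")
  if (length(distances) < 2) abort("standard error undefined for fewer than 2 replicas")
  se <- stats::sd(distances) / sqrt(length(distances))
  drift <- vec_norm(center_curr - center_prev)
  drift < se || drift == 0
}

#' Run the single-state sampling controller
#'
#' Each iteration launches every replica from its parent's endpoint through
#' `backend(start, n_steps, seed)` (a matrix of CV-space points; the last
#' row is the endpoint), recomputes the center, weights and copy counts,
#' and stops at convergence or `max_iter`. Replica RNG streams are derived
#' from `(seed, iteration, replica index)`, so runs are fully reproducible.
#'
#' @param backend Frame source, `function(start, n_steps, seed)`; see
#'   [make_langevin_backend()] for the toy double-well backend.
#' @param start Starting point in CV space (all replicas start here).
#' @param n_replicas Replica count, held fixed (default 24).
#' @param n_steps Steps per replica per iteration.
#' @param max_iter Maximum iterations (default 8).
#' @param seed Integer seed.
#' @param law Weight law passed to [assign_weights()].
#' @return A `controller_trace` object; see [tidy.controller_trace()].
#' @export
run_controller <- function(backend, start, n_replicas = 24, n_steps = 200,
                           max_iter = 8, seed = 1, law = "exp") {
  if (max_iter < 1) abort("max_iter must be >= 1")
  if (n_replicas < 2) abort("need at least 2 replicas")
  start <- as.numeric(start)
  k <- length(start)
  starts <- matrix(start, n_replicas, k, byrow = TRUE)
  rows <- vector("list", max_iter)
  center_prev <- NULL
  converged <- FALSE
  endpoints <- NULL
  center <- NULL
  for (iter in seq_len(max_iter)) {
    endpoints <- matrix(NA_real_, n_replicas, k)
    for (i in seq_len(n_replicas)) {
      traj <- tryCatch(
        backend(starts[i, ], n_steps, derive_seed(seed, iter, i)),
        error = function(e) {
          abort(sprintf("backend failed at iteration %d, replica %d: %s", iter, i, conditionMessage(e)))
        }
      )
      endpoints[i, ] <- traj[nrow(traj), ]
    }
    center <- compute_center(endpoints)
    wts <- assign_weights(endpoints, center, law = law)
    se <- stats::sd(wts$distances) / sqrt(n_replicas)
    shift <- if (is.null(center_prev)) NA_real_ else vec_norm(center - center_prev)
    converged <- !is.null(center_prev) &&
      check_convergence(center_prev, center, wts$distances)
    rows[[iter]] <- tibble(
      iteration = iter,
      center = list(center),
      mean_distance = wts$mean_distance,
      se = se,
      center_shift = shift,
      converged = converged
    )
    if (converged) break
    copies <- resample_replicas(wts$weights, total = n_replicas)
    stopifnot(sum(copies) == n_replicas)
    starts <- endpoints[rep(seq_len(n_replicas), copies), , drop = FALSE]
    center_prev <- center
  }
  structure(
    list(
      trace = dplyr::bind_rows(rows),
      final_center = center,
      final_endpoints = endpoints,
      converged = converged,
      n_replicas = n_replicas,
      seed = seed
    ),
    class = "controller_trace"
  )
}

#' Total sampling budget of the adaptive protocol
#'
#' @param n_replicas Replicas per iteration (default 24).
#' @param replica_length_ns Length of each replica segment in ns
#'   (default 7.5).
#' @param n_iterations Number of iterations (default 8).
#' @return Tibble with the per-system totals in ns and microseconds.
#' @export
sampling_budget <- function(n_replicas = 24, replica_length_ns = 7.5,
                            n_iterations = 8) {
  total_ns <- n_replicas * replica_length_ns * n_iterations
  tibble(
    n_replicas = n_replicas,
    replica_length_ns = replica_length_ns,
    n_iterations = n_iterations,
    total_ns = total_ns,
    total_us = total_ns / 1000
  )
}

#' @export
print.controller_trace <- function(x, ...) {
  cat(sprintf(
    "<controller_trace> %d iteration(s), %d replicas, converged: %s\n",
    nrow(x$trace), x$n_replicas, x$converged
  ))
  invisible(x)
}

#' Tidiers for allokit result objects
#'
#' `tidy()` returns the per-unit table of a result (trace rows, embedding
#' rows, edges, paths); `glance()` returns a one-row summary.
#'
#' @param x An allokit result object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy_allokit
NULL

#' @rdname tidy_allokit
#' @export
tidy.controller_trace <- function(x, ...) {
  k <- length(x$final_center)
  centers <- do.call(rbind, x$trace$center)
  colnames(centers) <- paste0("cv", seq_len(k))
  dplyr::bind_cols(
    x$trace[, c("iteration", "mean_distance", "se", "center_shift", "converged")],
    as_tibble(centers)
  )
}

#' @rdname tidy_allokit
#' @export
glance.controller_trace <- function(x, ...) {
  tibble(
    iterations = nrow(x$trace),
    n_replicas = x$n_replicas,
    converged = x$converged,
    final_mean_distance = x$trace$mean_distance[nrow(x$trace)]
  )
}
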