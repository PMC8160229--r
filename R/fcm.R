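#' Fuzzy C-means configuration
#'
#' Settings for the per-position fuzzy clustering of phase 1.  `K = 2` pairs
#' each cell position with one "lesion-associated" and one "normal-tissue"
#' descriptor cluster; the fuzzifier controls how soft the memberships are
#' (2 is the standard choice; values near 1 approach hard k-means).
#'
#' @param K number of clusters (>= 2, default 2).
#' @param fuzzifier exponent m > 1 (default 2).
#' @param tol convergence threshold on the maximum absolute membership
#'   change (default 1e-5).
#' @param max_iter iteration cap (default 300).
#' @param n_init seeded random restarts; the run with the lowest objective
#'   is kept (default 3).
#' @param seed RNG seed.
#' @param scope `"per_position"` (one clustering per cell position across
#'   subjects, the default) or `"global"` (one clustering over all
#'   positions pooled).
#' @return An object of class `fcm_config`.
#' @export
fcm_config <- function(K = 2, fuzzifier = 2, tol = 1e-5, max_iter = 300,
                       n_init = 3, seed = 1L,
                       scope = c("per_position", "global")) {
  scope <- match.arg(scope)
  if (K < 2) stop("`K` must be >= 2")
  if (fuzzifier <= 1) stop("`fuzzifier` must be > 1")
  if (tol <= 0) stop("`tol` must be positive")
  structure(list(K = as.integer(K), fuzzifier = fuzzifier, tol = tol,
                 max_iter = as.integer(max_iter), n_init = as.integer(n_init),
                 seed = as.integer(seed), scope = scope),
            class = "fcm_config")
}

# Membership update from squared distances (n x K): u_ik proportional to
# d2_ik^(-1/(m-1)), rows normalized.  A point at zero distance from one or
# more centroids splits full membership equally among the coincident ones.
fcm_memberships <- function(d2, fuzzifier) {
  inv <- d2^(-1 / (fuzzifier - 1))
  u <- inv / rowSums(inv)
  z <- d2 == 0
  hit <- rowSums(z) > 0
  if (any(hit)) u[hit, ] <- z[hit, , drop = FALSE] / rowSums(z)[hit]
  u
}

# Core FCM engine, batched over positions.  Xa is a list of N (n x Pa)
# matrices (one per descriptor dimension), U a list of K (n x Pa) membership
# matrices.  Every position iterates independently and is removed from the
# working set once its maximum membership change drops below tol, so each
# column's trajectory is identical to a standalone single-position run.
# Returned centroids are the ones the final memberships were computed from.
# Traces (per-iteration objective and memberships) are recorded for the
# positions still active at each iteration; they are intended for
# single-position use via fcm_fit().
fcm_batch <- function(Xa, U, fuzzifier, tol, max_iter, trace = FALSE) {
  n <- nrow(Xa[[1]]); Pa <- ncol(Xa[[1]])
  K <- length(U); N <- length(Xa)
  Ufin <- U
  Cfin <- array(NA_real_, c(Pa, K, N))
  objfin <- rep(NA_real_, Pa)
  iters <- integer(Pa)
  expo <- -1 / (fuzzifier - 1)
  cur <- seq_len(Pa)
  Xc <- Xa; Uc <- U
  J_trace <- if (trace) list() else NULL
  U_trace <- if (trace) list() else NULL
  for (it in seq_len(max_iter)) {
    w <- length(cur)
    # centroid update from current memberships
    C <- array(0, c(w, K, N))
    for (k in seq_len(K)) {
      umk <- Uc[[k]]^fuzzifier
      sk <- .colSums(umk, n, w)
      for (j in seq_len(N)) C[, k, j] <- .colSums(umk * Xc[[j]], n, w) / sk
    }
    # squared Euclidean distances to each centroid
    D2 <- vector("list", K)
    for (k in seq_len(K)) {
      d2 <- matrix(0, n, w)
      for (j in seq_len(N)) {
        dif <- Xc[[j]] - rep(C[, k, j], each = n)
        d2 <- d2 + dif * dif
      }
      D2[[k]] <- d2
    }
    # membership update (coincident points get full membership, split on ties)
    inv <- lapply(D2, function(d) d^expo)
    den <- Reduce(`+`, inv)
    Unew <- lapply(inv, function(iv) iv / den)
    zs <- lapply(D2, function(d) d == 0)
    nz <- Reduce(`+`, zs)
    hit <- nz > 0
    if (any(hit)) for (k in seq_len(K))
      Unew[[k]][hit] <- zs[[k]][hit] / nz[hit]
    # objective; a position converges when no membership moved by >= tol
    J <- 0
    moved <- 0
    for (k in seq_len(K)) {
      J <- J + .colSums(Unew[[k]]^fuzzifier * D2[[k]], n, w)
      moved <- moved + .colSums(abs(Unew[[k]] - Uc[[k]]) >= tol, n, w)
    }
    if (trace) {
      J_trace[[it]] <- J
      U_trace[[it]] <- Unew
    }
    conv <- moved == 0 | it == max_iter
    if (any(conv)) {
      gi <- cur[conv]
      for (k in seq_len(K)) Ufin[[k]][, gi] <- Unew[[k]][, conv, drop = FALSE]
      Cfin[gi, , ] <- C[conv, , , drop = FALSE]
      objfin[gi] <- J[conv]
      iters[gi] <- it
      keep <- !conv
      cur <- cur[keep]
      if (length(cur) == 0) break
      Xc <- lapply(Xc, function(M) M[, keep, drop = FALSE])
      Uc <- lapply(Unew, function(M) M[, keep, drop = FALSE])
    } else {
      Uc <- Unew
    }
  }
  list(U = Ufin, C = Cfin, objective = objfin, iterations = iters,
       J_trace = J_trace, U_trace = U_trace)
}

fcm_init_memberships <- function(n, K, seed) {
  u <- with_seed(seed, matrix(stats::runif(n * K), n, K))
  u / rowSums(u)
}

#' Fit fuzzy C-means
#'
#' Standard FCM on a point set: memberships are initialized from a seeded
#' uniform random matrix normalized row-wise, then centroid updates
#' `v_k = sum(u^m x) / sum(u^m)` alternate with membership updates
#' `u_ik = 1 / sum_j (d_ik / d_jk)^(2/(m-1))` (Euclidean distances) until
#' the maximum membership change falls below `tol` or `max_iter` is hit.
#' Among `n_init` restarts the run with the lowest objective
#' `J = sum_ik u_ik^m d_ik^2` is returned.  A point coinciding with a
#' centroid receives membership 1 there (split equally on coincidence with
#' several).
#'
#' @param x numeric matrix, one point per row (`nrow(x) >= K`).
#' @param config an [fcm_config()].
#' @param trace keep per-iteration objectives and membership matrices (for
#'   auditing the monotone-objective and row-stochasticity properties).
#' @return List with `centroids` (K x d), `memberships` (n x K),
#'   `objective`, `iterations`, `objective_trace`, optional
#'   `membership_trace`, and `degenerate` (TRUE when all points are
#'   identical, in which case memberships are uniform).
#' @examples
#' x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 6), 20))
#' f <- fcm_fit(x, fcm_config(seed = 1))
#' f$objective
#' @export
fcm_fit <- function(x, config = fcm_config(), trace = FALSE) {
  x <- as.matrix(x)
  n <- nrow(x); K <- config$K; d <- ncol(x)
  if (n < K) stop("need at least K points to fit K clusters")
  if (all(x == rep(x[1, ], each = n))) {
    return(list(centroids = matrix(x[1, ], K, d, byrow = TRUE),
                memberships = matrix(1 / K, n, K), objective = 0,
                iterations = 0L, objective_trace = numeric(0),
                membership_trace = NULL, degenerate = TRUE))
  }
  Xa <- lapply(seq_len(d), function(j) matrix(x[, j], n, 1))
  best <- NULL
  for (i in seq_len(config$n_init)) {
    u0 <- fcm_init_memberships(n, K, derive_seed(config$seed, i))
    U0 <- lapply(seq_len(K), function(k) matrix(u0[, k], n, 1))
    r <- fcm_batch(Xa, U0, config$fuzzifier, config$tol, config$max_iter,
                   trace = trace)
    if (is.null(best) || r$objective[1] < best$objective[1]) best <- r
  }
  list(centroids = matrix(best$C[1, , ], K, d),
       memberships = vapply(best$U, function(m) m[, 1], numeric(n)),
       objective = best$objective[1],
       iterations = best$iterations[1],
       objective_trace = if (is.null(best$J_trace)) numeric(0)
         else vapply(best$J_trace, `[`, 0, 1),
       membership_trace = if (is.null(best$U_trace)) NULL
         else lapply(best$U_trace, function(Ul)
           vapply(Ul, function(m) m[, 1], numeric(n))),
       degenerate = FALSE)
}
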