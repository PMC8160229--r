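#' Fit phase 1: per-position fuzzy clustering of HOG descriptors
#'
#' For every cell position of the (shared) descriptor grid, clusters the
#' training subjects' descriptors at that position with fuzzy C-means (one
#' point per subject), exploiting the spatial alignment of the cohort.  Each
#' position's clusters are ordered deterministically (descending centroid
#' Euclidean norm, ties keeping the fit order) and the membership of the
#' first cluster becomes that position's scalar feature, so one subject is
#' summarized by P numbers instead of P x n_bins.  Positions whose
#' descriptors are identical across all training subjects (typically
#' background cells) are flagged degenerate and emit the uninformative
#' constant 0.5, as are positions whose fitted centroids coincide.
#'
#' With `config$scope = "global"` a single clustering over all positions'
#' descriptors pooled is fitted instead, and every position is scored
#' against the shared centroids.
#'
#' The per-position path runs all positions' FCM iterations jointly
#' (convergence tracked per position) and is exactly equivalent to calling
#' [fcm_fit()] position by position with seeds derived from `config$seed`
#' and the position index.
#'
#' @param train list of `hog_set` objects from [extract_hog()], all with
#'   identical grids and configs.
#' @param config an [fcm_config()].
#' @return An object of class `fuzzy_phase`: centroids, degenerate flags,
#'   grid and positions, configs, and the training subjects' membership
#'   matrix (`train_memberships`, n x P).
#' @export
fit_phase1 <- function(train, config = fcm_config()) {
  stopifnot(length(train) >= 1, all(vapply(train, inherits, TRUE, "hog_set")))
  n <- length(train)
  if (n < config$K) stop("need at least K training subjects")
  hash <- train[[1]]$config_hash
  grid <- train[[1]]$grid
  for (s in train) {
    if (!identical(s$config_hash, hash)) stop("HOG config mismatch across subjects")
    if (!identical(unname(s$grid), unname(grid))) stop("grid mismatch across subjects")
  }
  P <- nrow(train[[1]]$descriptors)
  N <- ncol(train[[1]]$descriptors)
  K <- config$K

  if (config$scope == "global") {
    pool <- do.call(rbind, lapply(train, `[[`, "descriptors"))
    f <- fcm_fit(pool, config)
    ord <- order(-sqrt(rowSums(f$centroids^2)))
    cent <- f$centroids[ord, , drop = FALSE]
    u1 <- if (f$degenerate) rep(0.5, n * P) else f$memberships[, ord[1]]
    train_u <- matrix(u1, n, P, byrow = TRUE)
    model <- list(scope = "global", centroids = cent,
                  degenerate = rep(f$degenerate, P))
  } else {
    fitted <- fcm_fit_positions(train, config, P, N)
    model <- list(scope = "per_position", centroids = fitted$centroids,
                  degenerate = fitted$degenerate)
    train_u <- fitted$train_memberships
  }
  structure(c(model,
              list(grid = grid, positions = train[[1]]$positions,
                   fcm = config, hog_config = train[[1]]$config,
                   hog_hash = hash, train_memberships = train_u,
                   subject_ids = vapply(train, `[[`, "", "subject_id"),
                   n_train = n)),
            class = "fuzzy_phase")
}

# Per-position FCM via the batched engine; every position's run is
# identical to a standalone fcm_fit with seed derive_seed(config$seed, p).
fcm_fit_positions <- function(train, config, P, N) {
  n <- length(train)
  K <- config$K; mf <- config$fuzzifier
  # Xj[[j]]: n x P matrix of bin-j descriptor values
  Xj <- lapply(seq_len(N), function(j)
    do.call(rbind, lapply(train, function(s) s$descriptors[, j])))

  # positions with identical descriptors across all subjects are degenerate
  rng0 <- Reduce(`+`, lapply(Xj, function(M)
    colSums(abs(M - rep(M[1, ], each = n)))))
  degenerate <- rng0 == 0
  act_idx <- which(!degenerate)
  Pa <- length(act_idx)
  centroids <- array(NA_real_, c(P, K, N))
  train_u <- matrix(0.5, n, P)
  if (Pa > 0) {
    Xa <- lapply(Xj, function(M) M[, act_idx, drop = FALSE])
    best <- NULL
    for (init in seq_len(config$n_init)) {
      U0 <- lapply(seq_len(K), function(k) matrix(0, n, Pa))
      for (a in seq_len(Pa)) {
        u0 <- fcm_init_memberships(
          n, K, derive_seed(derive_seed(config$seed, act_idx[a]), init))
        for (k in seq_len(K)) U0[[k]][, a] <- u0[, k]
      }
      r <- fcm_batch(Xa, U0, mf, config$tol, config$max_iter)
      if (is.null(best)) best <- r
      else {
        sel <- r$objective < best$objective
        if (any(sel)) {
          for (k in seq_len(K)) best$U[[k]][, sel] <- r$U[[k]][, sel]
          best$C[sel, , ] <- r$C[sel, , ]
          best$objective[sel] <- r$objective[sel]
        }
      }
    }
    # deterministic cluster ordering: descending centroid norm, stable ties
    nrm <- vapply(seq_len(K), function(k)
      sqrt(rowSums(matrix(best$C[, k, ], Pa, N)^2)), numeric(Pa))
    ords <- if (K == 2) {
      swap <- nrm[, 2] > nrm[, 1]
      cbind(ifelse(swap, 2L, 1L), ifelse(swap, 1L, 2L))
    } else {
      t(apply(nrm, 1, function(v) order(-v)))
    }
    for (a in seq_len(Pa)) {
      p <- act_idx[a]
      o <- ords[a, ]
      centroids[p, , ] <- best$C[a, o, ]
      train_u[, p] <- best$U[[o[1]]][, a]
    }
    # coincident centroids carry no information: flag degenerate
    if (K == 2) {
      co <- rowSums((matrix(best$C[, 1, ], Pa, N) -
                     matrix(best$C[, 2, ], Pa, N))^2) == 0
    } else {
      co <- vapply(seq_len(Pa), function(a) {
        cm <- matrix(best$C[a, , ], K, N)
        min(stats::dist(cm)) == 0
      }, logical(1))
    }
    if (any(co)) {
      degenerate[act_idx[co]] <- TRUE
      train_u[, act_idx[co]] <- 0.5
    }
  }
  list(centroids = centroids, degenerate = degenerate,
       train_memberships = train_u)
}


#' Transform a subject into its membership vector
#'
#' Scores one subject's descriptors against a fitted [fit_phase1()] model:
#' at each position the descriptor is compared with the stored centroids and
#' the membership of the designated first cluster is emitted, in canonical
#' position order.  `mode = "soft"` (default) evaluates the FCM membership
#' formula with frozen centroids, giving a continuous value in \[0, 1\];
#' `mode = "hard"` applies the literal nearest-centroid rule (1 when the
#' first cluster's centroid is nearest, 0 otherwise; ties go to the first
#' cluster).  Degenerate positions emit 0.5.
#'
#' @param model a `fuzzy_phase` model.
#' @param subject a `hog_set` with matching grid and HOG configuration.
#' @param mode `"soft"` or `"hard"`.
#' @return Numeric vector of length P.
#' @export
fcm_transform <- function(model, subject, mode = c("soft", "hard")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "fuzzy_phase"), inherits(subject, "hog_set"))
  if (!identical(subject$config_hash, model$hog_hash))
    stop("HOG configuration of subject does not match the phase-1 model")
  if (!identical(unname(subject$grid), unname(model$grid)))
    stop("descriptor grid of subject does not match the phase-1 model")
  D <- subject$descriptors
  P <- nrow(D); N <- ncol(D); K <- model$fcm$K
  d2 <- matrix(0, P, K)
  for (k in seq_len(K)) {
    ck <- if (model$scope == "global")
      matrix(model$centroids[k, ], P, N, byrow = TRUE)
    else matrix(model$centroids[, k, ], P, N)
    d2[, k] <- rowSums((D - ck)^2)
  }
  deg <- model$degenerate
  u <- if (mode == "soft") {
    d2ok <- d2; d2ok[deg, ] <- 1   # placeholder, overwritten below
    fcm_memberships(d2ok, model$fcm$fuzzifier)[, 1]
  } else {
    as.numeric(max.col(-d2, ties.method = "first") == 1)
  }
  u[deg] <- 0.5
  u
}
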