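#' SVM configuration for phase 2
#'
#' @param kernel `"linear"` (default; yields an explicit weight vector for
#'   discriminant mapping) or `"rbf"`.
#' @param C regularization constant (> 0).
#' @param gamma RBF kernel width; the default `"scale"` uses
#'   `1 / (n_features * var(x))`.
#' @param class_weight `"balanced"` (inverse class frequencies, default —
#'   appropriate for imbalanced cohorts) or `"none"`.
#' @param seed RNG seed (the fit itself is deterministic; the seed covers
#'   any randomized extensions).
#' @return An object of class `svm_config`.
#' @export
svm_config <- function(kernel = c("linear", "rbf"), C = 1, gamma = "scale",
                       class_weight = c("balanced", "none"), seed = 1L) {
  kernel <- match.arg(kernel)
  class_weight <- match.arg(class_weight)
  if (C <= 0) stop("`C` must be positive")
  structure(list(kernel = kernel, C = C, gamma = gamma,
                 class_weight = class_weight, seed = as.integer(seed)),
            class = "svm_config")
}

# Fit a binary SVM on a feature matrix with 0/1 labels.  Decision scores are
# oriented so positive values favor class 1; for the linear kernel the
# primal weight vector (same orientation) is materialized.
fit_svm_binary <- function(X, y, config) {
  if (length(unique(y)) < 2) stop("both classes must be present in training data")
  if (min(table(y)) < 2) stop("need at least 2 subjects per class")
  yf <- factor(y, levels = c(0, 1))
  cw <- NULL
  if (config$class_weight == "balanced") {
    tb <- table(yf)
    cw <- as.numeric(sum(tb) / (2 * tb))
    names(cw) <- names(tb)
  }
  gamma <- if (identical(config$gamma, "scale"))
    1 / (ncol(X) * max(stats::var(as.vector(X)), .Machine$double.eps))
  else config$gamma
  fit <- with_seed(config$seed,
                   e1071::svm(x = X, y = yf,
                              kernel = if (config$kernel == "rbf") "radial"
                                       else "linear",
                              cost = config$C, gamma = gamma,
                              class.weights = cw, scale = FALSE))
  # e1071's binary decision value is positive for the first class named in
  # the "a/b" column label; orient scores toward class "1"
  dv <- attr(stats::predict(fit, X[1, , drop = FALSE], decision.values = TRUE),
             "decision.values")
  sgn <- if (strsplit(colnames(dv), "/")[[1]][1] == "1") 1 else -1
  w <- NULL; b <- NULL
  if (config$kernel == "linear") {
    w <- sgn * drop(crossprod(fit$coefs, fit$SV))
    b <- sgn * (-fit$rho)
  }
  list(fit = fit, sign = sgn, w = w, b = b, config = config, gamma = gamma)
}

svm_scores <- function(sf, X) {
  pr <- stats::predict(sf$fit, X, decision.values = TRUE)
  sf$sign * drop(attr(pr, "decision.values"))
}

#' Fit the two-phase MRI classifier
#'
#' The main fitting function.  Given an aligned cohort (one binary label per
#' subject), it extracts slice-wise R-HOG descriptors, converts each
#' subject's descriptors into a compact vector of per-position fuzzy-cluster
#' membership probabilities ([fit_phase1()]), and trains a support vector
#' machine on those vectors.  `method = "baseline"` skips the membership
#' transformation and trains the SVM on the directly concatenated
#' descriptors (the conventional HOG representation, P x n_bins long instead
#' of P) — the comparison method the two-phase framework is designed to
#' beat in small-cohort, high-dimensional regimes.
#'
#' @param x list of [mri_volume()]s (normalized automatically with
#'   [zscore_normalize()] unless already normalized) or of `hog_set`
#'   objects from [extract_hog()].
#' @param labels binary vector (0/1), one label per subject.
#' @param hog a [hog_config()].
#' @param fcm an [fcm_config()].
#' @param svm an [svm_config()].
#' @param method `"twophase"` (default) or `"baseline"`.
#' @param transform_mode how test subjects are scored against phase-1
#'   centroids: `"soft"` (continuous FCM memberships, default — matches the
#'   distribution of the training features) or `"hard"` (literal
#'   nearest-centroid 0/1 labels).
#' @return An object of class `twophase_model` with `print`, `summary`,
#'   `coef` and `predict` methods; see also [discriminant_map()].
#' @examples
#' \donttest{
#' co <- generate_cohort(5, "detection", seed = 3)
#' fit <- twophase(co$volumes, co$labels$label, hog = hog_config(cell_size = 20))
#' predict(fit, co$volumes[1:2])
#' }
#' @export
twophase <- function(x, labels, hog = hog_config(), fcm = fcm_config(),
                     svm = svm_config(), method = c("twophase", "baseline"),
                     transform_mode = c("soft", "hard")) {
  method <- match.arg(method)
  transform_mode <- match.arg(transform_mode)
  sets <- as_hog_sets(x, hog)
  labels <- as.integer(labels)
  if (length(labels) != length(sets))
    stop("`labels` must have one entry per subject")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")

  if (method == "twophase") {
    phase1 <- fit_phase1(sets, fcm)
    V <- phase1$train_memberships
    svm_fit <- fit_svm_binary(V, labels, svm)
  } else {
    phase1 <- NULL
    V <- t(vapply(sets, baseline_features,
                  numeric(nrow(sets[[1]]$descriptors) *
                          ncol(sets[[1]]$descriptors))))
    svm_fit <- fit_svm_binary(V, labels, svm)
  }
  train_scores <- svm_scores(svm_fit, V)
  structure(list(phase1 = phase1, svm = svm_fit, method = method,
                 train_scores = train_scores,
                 transform_mode = transform_mode, hog = sets[[1]]$config,
                 fcm = fcm, grid = sets[[1]]$grid,
                 positions = sets[[1]]$positions,
                 hog_hash = sets[[1]]$config_hash,
                 vol_shape = sets[[1]]$vol_shape, affine = sets[[1]]$affine,
                 labels = labels, n_features = ncol(V),
                 subject_ids = vapply(sets, `[[`, "", "subject_id"),
                 call = match.call()),
            class = "twophase_model")
}

# Coerce volumes (normalizing on the way) or ready-made hog_sets to a
# descriptor-set list with a common configuration.
as_hog_sets <- function(x, hog) {
  stopifnot(is.list(x), length(x) >= 1)
  if (inherits(x[[1]], "hog_set")) {
    hashes <- vapply(x, `[[`, "", "config_hash")
    if (length(unique(hashes)) != 1)
      stop("HOG configurations differ across subjects")
    return(x)
  }
  if (!all(vapply(x, inherits, TRUE, "mri_volume")))
    stop("`x` must be a list of mri_volume or hog_set objects")
  shapes <- vapply(x, function(v) paste(dim(v$data), collapse = "x"), "")
  if (length(unique(shapes)) != 1)
    stop("all volumes of a cohort must share the same shape")
  lapply(x, function(v) {
    if (!inherits(v, "normalized_volume")) v <- zscore_normalize(v)
    extract_hog(v, hog)
  })
}

#' Predict from a fitted two-phase model
#'
#' Applies the frozen phase-1 transformation (if any) and the fitted SVM to
#' new subjects.  The decision score is the signed distance to the
#' separating hyperplane oriented toward class 1; a score of exactly 0 is
#' assigned to class 1 by convention.
#'
#' @param object a `twophase_model`.
#' @param newdata list of [mri_volume()]s or `hog_set`s (their HOG
#'   configuration must match the model's).
#' @param type `"class"` (0/1 labels), `"score"` (decision values) or
#'   `"features"` (the feature matrix fed to the SVM).
#' @param ... unused.
#' @return Vector of labels or scores, or the feature matrix.
#' @export
predict.twophase_model <- function(object, newdata,
                                   type = c("class", "score", "features"),
                                   ...) {
  type <- match.arg(type)
  sets <- as_hog_sets(newdata, object$hog)
  for (s in sets)
    if (!identical(s$config_hash, object$hog_hash))
      stop("HOG configuration of new data does not match the model")
  V <- if (object$method == "twophase") {
    t(vapply(sets, function(s)
      fcm_transform(object$phase1, s, object$transform_mode),
      numeric(object$n_features)))
  } else {
    t(vapply(sets, baseline_features, numeric(object$n_features)))
  }
  if (type == "features") return(V)
  score <- svm_scores(object$svm, V)
  names(score) <- vapply(sets, `[[`, "", "subject_id")
  if (type == "score") score else as.integer(score >= 0)
}

#' Extract the linear decision rule
#'
#' @param object a `twophase_model` fitted with the linear kernel.
#' @param ... unused.
#' @return Named vector: `bias` followed by one weight per feature
#'   (per cell position for the two-phase method, per position x bin for the
#'   baseline).
#' @export
coef.twophase_model <- function(object, ...) {
  if (is.null(object$svm$w))
    stop("weights are only available for the linear kernel")
  w <- object$svm$w
  names(w) <- if (object$method == "twophase")
    sprintf("s%d_r%d_c%d", object$positions[, 1], object$positions[, 2],
            object$positions[, 3])
  else paste0("f", seq_along(w))
  c(bias = object$svm$b, w)
}

#' @export
print.twophase_model <- function(x, ...) {
  cat(sprintf("Two-phase MRI classifier (%s features, %s kernel)\n",
              x$method, x$svm$config$kernel))
  cat(sprintf("  subjects: %d (%d positive)  features: %d  grid: %dx%dx%d\n",
              length(x$labels), sum(x$labels), x$n_features,
              x$grid[1], x$grid[2], x$grid[3]))
  invisible(x)
}

#' @export
summary.twophase_model <- function(object, ...) {
  acc <- mean(as.integer(object$train_scores >= 0) == object$labels)
  out <- list(model = object, train_accuracy = acc,
              n_support = nrow(object$svm$fit$SV))
  class(out) <- "summary.twophase_model"
  out
}

#' @export
print.summary.twophase_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("  support vectors: %d  training accuracy: %.3f\n",
              x$n_support, x$train_accuracy))
  invisible(x)
}

#' Plot per-slice discriminant weight profiles
#'
#' For a linear two-phase fit, plots the maximum absolute SVM weight per
#' slice (which slices carry discriminative signal) and an image of the
#' weight magnitudes of the most discriminant slice.
#'
#' @param x a `twophase_model` (linear kernel, two-phase features).
#' @param ... passed to [graphics::image()].
#' @export
plot.twophase_model <- function(x, ...) {
  if (is.null(x$svm$w) || x$method != "twophase")
    stop("plotting requires a linear-kernel two-phase fit")
  w <- abs(x$svm$w)
  m <- x$grid[1]; R <- x$grid[2]; Q <- x$grid[3]
  per_slice <- vapply(seq_len(m), function(s)
    max(w[x$positions[, 1] == s]), 0)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(seq_len(m), per_slice, type = "h", lwd = 3,
                 xlab = "slice", ylab = "max |w|",
                 main = "Discriminant weight by slice")
  s_best <- which.max(per_slice)
  W <- matrix(0, R, Q)
  sel <- x$positions[, 1] == s_best
  W[cbind(x$positions[sel, 2], x$positions[sel, 3])] <- w[sel]
  graphics::image(seq_len(Q), seq_len(R), t(W)[, R:1, drop = FALSE],
                  xlab = "cell column", ylab = "cell row",
                  main = sprintf("|w|, slice %d", s_best), ...)
  invisible(x)
}
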