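#' Cross-validation configuration
#'
#' @param n_folds folds per run (default 10).
#' @param n_runs random runs; each reshuffles subjects before dealing folds
#'   (default 10).
#' @param cell_sizes HOG cell sizes to sweep (default 10:20).
#' @param seed master seed; every nested seed (fold shuffles, phase-1
#'   restarts, SVM) is derived deterministically from it.
#' @param method `"twophase"` or `"baseline"`.
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(n_folds = 10, n_runs = 10, cell_sizes = 10:20,
                      seed = 1L, method = c("twophase", "baseline")) {
  method <- match.arg(method)
  if (n_folds < 2) stop("`n_folds` must be >= 2")
  if (n_runs < 1) stop("`n_runs` must be >= 1")
  structure(list(n_folds = as.integer(n_folds), n_runs = as.integer(n_runs),
                 cell_sizes = as.integer(cell_sizes), seed = as.integer(seed),
                 method = method),
            class = "cv_config")
}

#' Stratified fold assignment
#'
#' Shuffles the subjects of each class with the given seed and deals them
#' round-robin into folds, so fold sizes within a class differ by at most
#' one and every fold preserves the cohort's class proportions.  Assignment
#' is by whole subject.
#'
#' @param labels binary label vector.
#' @param n_folds number of folds; every class must have at least
#'   `n_folds` members.
#' @param seed shuffle seed.
#' @return Integer vector of fold indices (1..n_folds) per subject.
#' @examples
#' table(stratified_folds(rep(c(1, 0), c(62, 37)), 10, seed = 1),
#'       rep(c(1, 0), c(62, 37)))
#' @export
stratified_folds <- function(labels, n_folds, seed = 1L) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      if (length(idx) < n_folds)
        stop(sprintf("class %s has %d members, fewer than n_folds = %d",
                     cl, length(idx), n_folds))
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

confusion_counts <- function(truth, pred) {
  c(TP = sum(truth == 1 & pred == 1), FN = sum(truth == 1 & pred == 0),
    FP = sum(truth == 0 & pred == 1), TN = sum(truth == 0 & pred == 0))
}

auc_score <- function(truth, score) {
  if (length(unique(truth)) < 2) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(response = factor(truth, levels = c(0, 1)),
                                 predictor = score, levels = c("0", "1"),
                                 direction = "<", quiet = TRUE)))
}

#' Repeated stratified cross-validation of the two-phase classifier
#'
#' The evaluation harness: for every cell size in the sweep and every
#' random run, subjects are dealt into stratified folds; within each fold
#' the phase-1 clustering (for the two-phase method) and the SVM are fitted
#' strictly on the training subjects, test subjects are scored with frozen
#' centroids, and confusion counts are recorded.  Per run, ACC/SEN/SPE are
#' computed from the counts summed over folds and AUC from the pooled
#' out-of-fold decision scores; per cell size, means and SDs are taken
#' across runs.  All seeds derive from `cv$seed`, so a result is exactly
#' reproducible.
#'
#' @param x list of [mri_volume()]s (raw; normalized internally).
#' @param labels binary labels, one per subject.
#' @param cv a [cv_config()].
#' @param fcm an [fcm_config()] (its seed field is overridden by derived
#'   seeds).
#' @param svm an [svm_config()].
#' @param hog a [hog_config()] supplying all settings except `cell_size`.
#' @param transform_mode passed to [twophase()].
#' @return An object of class `cv_result`: `records` (per cell size / run /
#'   fold counts and metrics), `runs` (per-run aggregates), `summary` (per
#'   cell size mean/SD of ACC, SEN, SPE, AUC), `best` (best cell size per
#'   metric) and the configurations.
#' @export
run_cv <- function(x, labels, cv = cv_config(), fcm = fcm_config(),
                   svm = svm_config(), hog = hog_config(),
                   transform_mode = "soft") {
  stopifnot(inherits(cv, "cv_config"))
  labels <- as.integer(labels)
  vols <- lapply(x, function(v)
    if (inherits(v, "normalized_volume")) v else zscore_normalize(v))
  records <- list()
  runs <- list()
  for (ci in seq_along(cv$cell_sizes)) {
    cs <- cv$cell_sizes[ci]
    hog_cs <- hog; hog_cs$cell_size <- as.integer(cs)
    sets <- lapply(vols, extract_hog, config = hog_cs)
    for (run in seq_len(cv$n_runs)) {
      fold <- stratified_folds(labels, cv$n_folds,
                               seed = derive_seed(cv$seed, "fold", cs, run))
      scores <- numeric(length(labels))
      counts_run <- c(TP = 0, FN = 0, FP = 0, TN = 0)
      for (f in seq_len(cv$n_folds)) {
        tr <- which(fold != f); te <- which(fold == f)
        fcm_f <- fcm; fcm_f$seed <- derive_seed(cv$seed, "fcm", cs, run, f)
        svm_f <- svm; svm_f$seed <- derive_seed(cv$seed, "svm", cs, run, f)
        fit <- twophase(sets[tr], labels[tr], hog = hog_cs, fcm = fcm_f,
                        svm = svm_f, method = cv$method,
                        transform_mode = transform_mode)
        sc <- predict(fit, sets[te], type = "score")
        pred <- as.integer(sc >= 0)
        scores[te] <- sc
        cnt <- confusion_counts(labels[te], pred)
        counts_run <- counts_run + cnt
        records[[length(records) + 1]] <- data.frame(
          cell_size = cs, run = run, fold = f,
          TP = cnt["TP"], FN = cnt["FN"], FP = cnt["FP"], TN = cnt["TN"],
          ACC = (cnt["TP"] + cnt["TN"]) / length(te),
          row.names = NULL)
      }
      runs[[length(runs) + 1]] <- data.frame(
        cell_size = cs, run = run,
        TP = counts_run["TP"], FN = counts_run["FN"],
        FP = counts_run["FP"], TN = counts_run["TN"],
        ACC = (counts_run["TP"] + counts_run["TN"]) / length(labels),
        SEN = counts_run["TP"] / (counts_run["TP"] + counts_run["FN"]),
        SPE = counts_run["TN"] / (counts_run["TN"] + counts_run["FP"]),
        AUC = auc_score(labels, scores), row.names = NULL)
    }
  }
  records <- do.call(rbind, records)
  runs <- do.call(rbind, runs)
  summ <- do.call(rbind, lapply(split(runs, runs$cell_size), function(g)
    data.frame(cell_size = g$cell_size[1],
               ACC_mean = mean(g$ACC), ACC_sd = stats::sd(g$ACC),
               SEN_mean = mean(g$SEN), SEN_sd = stats::sd(g$SEN),
               SPE_mean = mean(g$SPE), SPE_sd = stats::sd(g$SPE),
               AUC_mean = mean(g$AUC), AUC_sd = stats::sd(g$AUC),
               row.names = NULL)))
  summ <- summ[order(summ$cell_size), , drop = FALSE]
  rownames(summ) <- NULL
  best <- vapply(c("ACC_mean", "SEN_mean", "SPE_mean", "AUC_mean"),
                 function(mcol) summ$cell_size[which.max(summ[[mcol]])],
                 integer(1))
  names(best) <- c("ACC", "SEN", "SPE", "AUC")
  structure(list(records = records, runs = runs, summary = summ, best = best,
                 n_subjects = length(labels), n_positive = sum(labels),
                 config = list(cv = unclass(cv), fcm = unclass(fcm),
                               svm = unclass(svm), hog = unclass(hog),
                               transform_mode = transform_mode)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Cross-validation: %s method, %d subjects (%d positive), %d x %d-fold\n",
              x$config$cv$method, x$n_subjects, x$n_positive,
              x$config$cv$n_runs, x$config$cv$n_folds))
  print(x$summary, digits = 3)
  invisible(x)
}

# Aggregate confusion matrix: element-wise median across runs of the
# per-run (fold-summed) counts, rounded.  Because TP+FN and FP+TN are
# constant across runs, the aggregate still sums to the subject count.
aggregate_confusion <- function(runs, cell_size) {
  g <- runs[runs$cell_size == cell_size, , drop = FALSE]
  round(c(TP = stats::median(g$TP), FN = stats::median(g$FN),
          FP = stats::median(g$FP), TN = stats::median(g$TN)))
}

#' Write cross-validation reports
#'
#' Writes `summary.csv` (cell-size sweep with mean (SD) metrics),
#' `runs.csv` and `records.csv` (per-run and per-fold detail),
#' `confusion_<cellsize>.csv` (aggregate confusion matrix at the best-ACC
#' cell size: element-wise median across runs of fold-summed counts,
#' rounded), `manifest.json` (all configurations and seeds) and
#' `metrics_by_cell_size.pdf`.  Output is a pure function of the
#' `cv_result`, so regenerating a report yields identical tables.
#'
#' @param result a `cv_result` from [run_cv()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
cv_report <- function(result, out_dir) {
  stopifnot(inherits(result, "cv_result"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  summ <- result$summary
  pretty <- data.frame(
    cell_size = summ$cell_size,
    ACC = sprintf("%.1f%% (%.1f)", 100 * summ$ACC_mean, 100 * summ$ACC_sd),
    SEN = sprintf("%.1f%% (%.1f)", 100 * summ$SEN_mean, 100 * summ$SEN_sd),
    SPE = sprintf("%.1f%% (%.1f)", 100 * summ$SPE_mean, 100 * summ$SPE_sd),
    AUC = sprintf("%.3f (%.3f)", summ$AUC_mean, summ$AUC_sd))
  utils::write.csv(pretty, file.path(out_dir, "summary.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(result$runs, file.path(out_dir, "runs.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(result$records, file.path(out_dir, "records.csv"),
                   row.names = FALSE, quote = FALSE)
  cs_best <- result$best[["ACC"]]
  cm <- aggregate_confusion(result$runs, cs_best)
  cm_tab <- data.frame(actual = c("positive", "negative"),
                       predicted_positive = c(cm["TP"], cm["FP"]),
                       predicted_negative = c(cm["FN"], cm["TN"]))
  utils::write.csv(cm_tab, file.path(out_dir,
                                     sprintf("confusion_%d.csv", cs_best)),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    c(result$config, list(best_cell_size = as.list(result$best),
                          n_subjects = result$n_subjects,
                          n_positive = result$n_positive)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  grDevices::pdf(file.path(out_dir, "metrics_by_cell_size.pdf"),
                 width = 7, height = 5)
  on.exit(grDevices::dev.off())
  graphics::matplot(summ$cell_size,
                    cbind(summ$ACC_mean, summ$SEN_mean, summ$SPE_mean,
                          summ$AUC_mean),
                    type = "b", pch = 1:4, lty = 1, xlab = "cell size",
                    ylab = "metric", ylim = c(0, 1),
                    main = sprintf("%s method", result$config$cv$method))
  graphics::legend("bottomright", c("ACC", "SEN", "SPE", "AUC"),
                   pch = 1:4, col = 1:4, lty = 1)
  invisible(out_dir)
}
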