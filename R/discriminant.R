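#' Back-project SVM weights into a discriminant map
#'
#' For a linear-kernel fit, localizes the class-separating signal: each cell
#' position's absolute weight `|w_p|` (for the baseline method, the
#' Euclidean norm of its n_bins weights) is painted over the cell's
#' `cell_size` x `cell_size` pixel footprint on its slice, producing a
#' volume in the cohort's geometry.  Cells are kept either by an absolute
#' threshold on `|w_p|` or as the top-k; all other voxels are zero.
#'
#' @param model a `twophase_model` fitted with the linear kernel.
#' @param top_k keep the k cells with the largest `|w|` (ties resolved by
#'   canonical position order).
#' @param threshold alternatively, keep cells with `|w| >= threshold`
#'   (ignored when `top_k` is given).
#' @param file optional path; the map is written there as NIfTI-1 with the
#'   cohort affine.
#' @return A list of class `discriminant_map`: `data` (3D array of painted
#'   weight magnitudes), `affine`, `kept` (data.frame of retained positions
#'   and weights), and the selection rule used.
#' @export
discriminant_map <- function(model, top_k = NULL, threshold = NULL,
                             file = NULL) {
  stopifnot(inherits(model, "twophase_model"))
  if (is.null(model$svm$w))
    stop("discriminant maps require the linear kernel (no primal weights ",
         "exist for the rbf kernel)")
  P <- nrow(model$positions)
  wp <- if (model$method == "twophase") abs(model$svm$w)
  else sqrt(rowSums(matrix(model$svm$w, P, byrow = TRUE)^2))
  keep <- if (!is.null(top_k)) {
    if (top_k < 1) stop("`top_k` must be >= 1")
    order(-wp)[seq_len(min(top_k, P))]
  } else if (!is.null(threshold)) {
    which(wp >= threshold)
  } else stop("supply `top_k` or `threshold`")

  arr <- array(0, model$vol_shape)
  cs <- model$hog$cell_size
  axis <- model$hog$slice_axis
  for (p in keep) {
    s <- model$positions[p, 1]
    rows <- ((model$positions[p, 2] - 1) * cs + 1):(model$positions[p, 2] * cs)
    cols <- ((model$positions[p, 3] - 1) * cs + 1):(model$positions[p, 3] * cs)
    if (axis == 1) arr[s, rows, cols] <- wp[p]
    else if (axis == 2) arr[rows, s, cols] <- wp[p]
    else arr[rows, cols, s] <- wp[p]
  }
  out <- structure(list(data = arr, affine = model$affine,
                        kept = data.frame(position = keep,
                                          slice = model$positions[keep, 1],
                                          row = model$positions[keep, 2],
                                          col = model$positions[keep, 3],
                                          weight = wp[keep]),
                        top_k = top_k, threshold = threshold,
                        cell_size = cs, slice_axis = axis),
                   class = "discriminant_map")
  if (!is.null(file)) RNifti::writeNifti(RNifti::asNifti(arr), file)
  out
}

#' @export
print.discriminant_map <- function(x, ...) {
  cat(sprintf("<discriminant_map> %d cell(s) kept (%s), footprint %dx%d\n",
              nrow(x$kept),
              if (!is.null(x$top_k)) sprintf("top-%d", x$top_k)
              else sprintf("|w| >= %g", x$threshold),
              x$cell_size, x$cell_size))
  invisible(x)
}
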