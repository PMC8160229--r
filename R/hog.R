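#' HOG extraction configuration
#'
#' Settings for slice-wise rectangular-cell (R-HOG) descriptor extraction:
#' square cells of `cell_size` pixels, `n_bins` orientation channels evenly
#' spread over 0–360 degrees when `signed` (0–180 otherwise), with channel k
#' centered at `k * period / n_bins`.  Votes are gradient-magnitude weighted;
#' `"hard"` voting gives the whole magnitude to the nearest channel center
#' (angular ties to the lower channel index), `"bilinear"` splits it between
#' the two nearest centers proportionally to angular distance, wrapping
#' across 360/0.
#'
#' @param cell_size pixels per cell side (>= 2).
#' @param n_bins orientation channel count (>= 2, default 8).
#' @param signed use the full 0–360 degree circle (default) or fold to
#'   0–180.
#' @param normalize per-cell contrast normalization: `"l2"` (unit Euclidean
#'   norm; all-zero cells stay zero), `"none"`, or `"l2hys"` (L2, clip at
#'   0.2, renormalize).
#' @param vote_interp `"bilinear"` (default) or `"hard"`.
#' @param slice_axis volume axis sliced into 2D images (default 3, axial for
#'   conventionally ordered acquisitions).
#' @return An object of class `hog_config`.
#' @export
hog_config <- function(cell_size = 10, n_bins = 8, signed = TRUE,
                       normalize = c("l2", "none", "l2hys"),
                       vote_interp = c("bilinear", "hard"),
                       slice_axis = 3) {
  normalize <- match.arg(normalize)
  vote_interp <- match.arg(vote_interp)
  if (cell_size < 2) stop("`cell_size` must be >= 2")
  if (n_bins < 2) stop("`n_bins` must be >= 2")
  if (!slice_axis %in% 1:3) stop("`slice_axis` must be 1, 2 or 3")
  structure(list(cell_size = as.integer(cell_size),
                 n_bins = as.integer(n_bins), signed = isTRUE(signed),
                 normalize = normalize, vote_interp = vote_interp,
                 slice_axis = as.integer(slice_axis)),
            class = "hog_config")
}

# Canonical serialization; stored with models so train/predict configurations
# cannot silently diverge.
hog_hash <- function(config) {
  paste("hog", config$cell_size, config$n_bins, config$signed,
        config$normalize, config$vote_interp, config$slice_axis, sep = "|")
}

#' Per-pixel image gradients
#'
#' Gradient estimates by centered differences, `(f(t+1) - f(t-1)) / 2` in the
#' interior and one-sided differences at the borders, applied along each
#' image axis.  Magnitude is the Euclidean norm of the two components and
#' direction is `atan2(gy, gx)` mapped to \[0, 360) degrees, where `gx` runs
#' along columns and `gy` along rows; zero-magnitude pixels get direction 0
#' by convention.
#'
#' @param slice2d numeric matrix with at least 2 rows and 2 columns.
#' @return A list with matrices `magnitude` and `direction` (degrees).
#' @export
pixel_gradients <- function(slice2d) {
  slice2d <- as.matrix(slice2d)
  H <- nrow(slice2d); W <- ncol(slice2d)
  if (H < 2 || W < 2) stop("slice must have at least 2 rows and 2 columns")
  gy <- matrix(0, H, W)
  if (H > 2) gy[2:(H - 1), ] <- (slice2d[3:H, ] - slice2d[1:(H - 2), ]) / 2
  gy[1, ] <- slice2d[2, ] - slice2d[1, ]
  gy[H, ] <- slice2d[H, ] - slice2d[H - 1, ]
  gx <- matrix(0, H, W)
  if (W > 2) gx[, 2:(W - 1)] <- (slice2d[, 3:W] - slice2d[, 1:(W - 2)]) / 2
  gx[, 1] <- slice2d[, 2] - slice2d[, 1]
  gx[, W] <- slice2d[, W] - slice2d[, W - 1]
  magnitude <- sqrt(gx^2 + gy^2)
  direction <- (atan2(gy, gx) * 180 / pi) %% 360
  direction[magnitude == 0] <- 0
  list(magnitude = magnitude, direction = direction)
}

# Channel neighbors and interpolation fraction for each direction value.
# k1 is the channel whose center lies at or below the direction, k2 the next
# channel (wrapping); frac in [0,1) is the angular position between the two
# centers in channel-width units.
vote_bins <- function(direction, config) {
  period <- if (config$signed) 360 else 180
  width <- period / config$n_bins
  t <- (direction %% period) / width
  k1 <- floor(t)
  frac <- t - k1
  k1 <- k1 %% config$n_bins
  k2 <- (k1 + 1) %% config$n_bins
  list(k1 = k1, k2 = k2, frac = frac)
}

# Accumulate weighted votes into a (n_cells x n_bins) table.
acc_votes <- function(cell, bin, w, n_cells, n_bins) {
  out <- numeric(n_cells * n_bins)
  s <- rowsum(w, cell + n_cells * bin)
  out[as.integer(rownames(s))] <- s
  matrix(out, n_cells, n_bins)
}

vote_table <- function(cell, magnitude, vb, n_cells, config) {
  if (config$vote_interp == "hard") {
    b <- ifelse(vb$frac < 0.5, vb$k1,
                ifelse(vb$frac > 0.5, vb$k2, pmin(vb$k1, vb$k2)))
    acc_votes(cell, b, magnitude, n_cells, config$n_bins)
  } else {
    acc_votes(cell, vb$k1, magnitude * (1 - vb$frac), n_cells, config$n_bins) +
      acc_votes(cell, vb$k2, magnitude * vb$frac, n_cells, config$n_bins)
  }
}

normalize_rows <- function(H, mode) {
  if (mode == "none") return(H)
  nrm <- sqrt(rowSums(H^2))
  nz <- nrm > 0
  H[nz, ] <- H[nz, , drop = FALSE] / nrm[nz]
  if (mode == "l2hys") {
    H[H > 0.2] <- 0.2
    nrm <- sqrt(rowSums(H^2))
    nz <- nrm > 0
    H[nz, ] <- H[nz, , drop = FALSE] / nrm[nz]
  }
  H
}

#' Orientation histogram of one rectangular cell
#'
#' Bins the gradient directions of the pixels in `rows` x `cols` into the
#' configured orientation channels, each pixel voting with its gradient
#' magnitude, then applies the configured contrast normalization.  A cell
#' with no nonzero gradient yields the all-zero histogram.
#'
#' @param magnitude,direction matrices from [pixel_gradients()].
#' @param rows,cols integer index vectors delimiting the cell within the
#'   slice.
#' @param config a [hog_config()].
#' @return Numeric vector of length `config$n_bins`.
#' @export
cell_histogram <- function(magnitude, direction, rows, cols,
                           config = hog_config()) {
  if (min(rows) < 1 || max(rows) > nrow(magnitude) ||
      min(cols) < 1 || max(cols) > ncol(magnitude))
    stop("cell bounds lie outside the slice")
  m <- as.vector(magnitude[rows, cols])
  d <- as.vector(direction[rows, cols])
  vb <- vote_bins(d, config)
  h <- vote_table(rep(1L, length(m)), m, vb, 1L, config)
  drop(normalize_rows(h, config$normalize))
}

slice_matrix <- function(data, axis, s) {
  switch(axis, data[s, , ], data[, s, ], data[, , s])
}

#' Slice-wise R-HOG descriptors of one subject
#'
#' Slices the volume along `config$slice_axis`, partitions every slice into
#' the dense origin-anchored grid of non-overlapping `cell_size` x
#' `cell_size` cells (trailing partial rows/columns discarded), and computes
#' one orientation histogram per cell.  Descriptors are emitted in the
#' canonical order: slice-major, then row-major within each slice, so all
#' subjects of an aligned cohort produce position-comparable descriptor
#' sets.
#'
#' @param vol an [mri_volume()] (typically a [zscore_normalize()]d one).
#' @param config a [hog_config()].
#' @return An object of class `hog_set`: list with `descriptors` (P x n_bins
#'   matrix), `positions` (P x 3 matrix of slice/row/col), `grid`
#'   (slices, rows, cols), the config, its hash, and the source geometry.
#' @examples
#' v <- zscore_normalize(generate_phantom(phantom_spec(seed = 2)))
#' hs <- extract_hog(v, hog_config(cell_size = 20))
#' hs$grid
#' @export
extract_hog <- function(vol, config = hog_config()) {
  stopifnot(inherits(vol, "mri_volume"))
  dims <- dim(vol$data)
  axis <- config$slice_axis
  m <- dims[axis]
  sdims <- dims[-axis]
  cs <- config$cell_size
  if (cs > sdims[1] || cs > sdims[2])
    stop("`cell_size` exceeds a slice dimension")
  R <- sdims[1] %/% cs
  Q <- sdims[2] %/% cs
  n_cells <- R * Q
  N <- config$n_bins
  D <- matrix(0, m * n_cells, N)
  rsel <- seq_len(R * cs); csel <- seq_len(Q * cs)
  cell_of <- (rep(seq_len(R * cs) - 1L, Q * cs) %/% cs) * Q +
    (rep(seq_len(Q * cs) - 1L, each = R * cs) %/% cs) + 1L
  for (s in seq_len(m)) {
    g <- pixel_gradients(slice_matrix(vol$data, axis, s))
    mag <- g$magnitude[rsel, csel]
    vb <- vote_bins(g$direction[rsel, csel], config)
    Hs <- vote_table(cell_of, as.vector(mag),
                     lapply(vb, as.vector), n_cells, config)
    D[((s - 1L) * n_cells + 1L):(s * n_cells), ] <-
      normalize_rows(Hs, config$normalize)
  }
  positions <- cbind(slice = rep(seq_len(m), each = n_cells),
                     row = rep(rep(seq_len(R), each = Q), m),
                     col = rep(rep(seq_len(Q), R), m))
  structure(list(descriptors = D, positions = positions,
                 grid = c(slices = m, rows = R, cols = Q),
                 config = config, config_hash = hog_hash(config),
                 subject_id = vol$subject_id, label = vol$label,
                 vol_shape = dims, affine = vol$affine),
            class = "hog_set")
}

#' @export
print.hog_set <- function(x, ...) {
  cat(sprintf("<hog_set> %s  grid %dx%dx%d (%d cells x %d bins)\n",
              x$subject_id, x$grid[1], x$grid[2], x$grid[3],
              nrow(x$descriptors), ncol(x$descriptors)))
  invisible(x)
}

#' Baseline concatenated-HOG feature vector
#'
#' The comparison method: all cell histograms concatenated in canonical
#' order into one flat vector of length `P * n_bins`, so the elements
#' `[(p-1)*N + 1 .. p*N]` are cell p's histogram.
#'
#' @param subject a `hog_set` from [extract_hog()].
#' @return Numeric vector of length `P * n_bins`.
#' @export
baseline_features <- function(subject) {
  stopifnot(inherits(subject, "hog_set"))
  as.vector(t(subject$descriptors))
}

#' Write a descriptor table
#'
#' Dumps one subject's descriptors as a flat CSV with columns
#' `slice,row,col,bin_0..bin_{N-1}`, rows in canonical (slice-major,
#' row-major) order.
#'
#' @param subject a `hog_set`.
#' @param file output CSV path.
#' @export
write_descriptors <- function(subject, file) {
  stopifnot(inherits(subject, "hog_set"))
  tab <- data.frame(subject$positions, subject$descriptors)
  names(tab) <- c("slice", "row", "col",
                  paste0("bin_", seq_len(ncol(subject$descriptors)) - 1L))
  utils::write.csv(tab, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
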