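# Independent brute-force oracles and small fixture builders shared by the
# unit and acceptance tests.  These deliberately use naive per-pixel loops,
# not the package's vectorized paths.

with_seed_test <- function(seed, expr) {
  set.seed(seed)
  expr
}

# gradients of one pixel by explicit centered / one-sided differences
naive_gradient_at <- function(M, i, j) {
  H <- nrow(M); W <- ncol(M)
  gy <- if (i == 1) M[2, j] - M[1, j]
        else if (i == H) M[H, j] - M[H - 1, j]
        else (M[i + 1, j] - M[i - 1, j]) / 2
  gx <- if (j == 1) M[i, 2] - M[i, 1]
        else if (j == W) M[i, W] - M[i, W - 1]
        else (M[i, j + 1] - M[i, j - 1]) / 2
  mag <- sqrt(gx^2 + gy^2)
  dir <- (atan2(gy, gx) * 180 / pi) %% 360
  if (mag == 0) dir <- 0
  c(mag = mag, dir = dir)
}

# hard-voting histogram of one cell: classify every pixel's direction to the
# nearest channel center (ties to the lower channel index) and sum magnitudes
naive_cell_histogram <- function(M, rows, cols, n_bins) {
  width <- 360 / n_bins
  centers <- (seq_len(n_bins) - 1) * width
  h <- numeric(n_bins)
  for (i in rows) for (j in cols) {
    g <- naive_gradient_at(M, i, j)
    if (g["mag"] == 0 && g["dir"] == 0) {
      # zero-gradient pixels vote 0 magnitude into channel 0; no-op
      next
    }
    dist <- abs(g["dir"] - centers)
    dist <- pmin(dist, 360 - dist)
    h[which.min(dist)] <- h[which.min(dist)] + g["mag"]
  }
  h
}

# full naive descriptor set of one slice (no normalization, hard votes)
naive_slice_descriptors <- function(M, cell_size, n_bins) {
  R <- nrow(M) %/% cell_size
  Q <- ncol(M) %/% cell_size
  out <- matrix(0, R * Q, n_bins)
  for (r in seq_len(R)) for (q in seq_len(Q)) {
    rows <- ((r - 1) * cell_size + 1):(r * cell_size)
    cols <- ((q - 1) * cell_size + 1):(q * cell_size)
    out[(r - 1) * Q + q, ] <- naive_cell_histogram(M, rows, cols, n_bins)
  }
  out
}

# small aligned cohort of descriptor sets built straight from arrays
hog_sets_from_arrays <- function(arrs, config) {
  lapply(seq_along(arrs), function(i)
    extract_hog(mri_volume(arrs[[i]], subject_id = sprintf("a%02d", i)),
                config))
}

# independent gradient-magnitude oracle over the lesion interior (3D finite
# differences, no use of the package's gradient code)
mean_lesion_gradient <- function(spec) {
  vol <- generate_phantom(spec)
  mask <- lesion_mask(spec)
  g2 <- array(0, dim(vol$data))
  for (ax in 1:3) {
    d <- apply(vol$data, setdiff(1:3, ax), function(v) {
      n <- length(v)
      c(v[2] - v[1], (v[3:n] - v[1:(n - 2)]) / 2, v[n] - v[n - 1])
    })
    g2 <- g2 + aperm(d, order(c(ax, setdiff(1:3, ax))))^2
  }
  mean(sqrt(g2)[mask])
}

# compact detection cohort for the mid-weight pipeline tests
small_detection_cohort <- function(n_per_class = 6, seed = 42,
                                   jitter = TRUE,
                                   shape = c(40, 40, 8)) {
  generate_cohort(n_per_class, "detection",
                  base_spec = phantom_spec(shape = shape, lesion_present = TRUE,
                                           lesion_radius = 6),
                  seed = seed, jitter = jitter)
}
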