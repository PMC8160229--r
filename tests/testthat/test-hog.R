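# Slice-wise R-HOG extraction

test_that("gradients of constant and ramp slices are analytic", {
  g0 <- pixel_gradients(matrix(7, 6, 6))
  expect_true(all(g0$magnitude == 0))
  expect_true(all(g0$direction == 0))

  # f(x, y) = x: unit gradient along columns everywhere (one-sided borders
  # also step by exactly 1)
  ramp <- matrix(rep(1:8, each = 8), 8, 8)  # M[i, j] = j
  g <- pixel_gradients(ramp)
  expect_equal(g$magnitude, matrix(1, 8, 8))
  expect_equal(g$direction, matrix(0, 8, 8))

  expect_error(pixel_gradients(matrix(1, 1, 5)), "at least 2")
})

test_that("gradients match the per-pixel loop oracle on random slices", {
  for (s in 1:3) {
    M <- with_seed_test(s, matrix(rnorm(25), 5, 5))
    g <- pixel_gradients(M)
    for (i in 1:5) for (j in 1:5) {
      ref <- naive_gradient_at(M, i, j)
      expect_equal(g$magnitude[i, j], unname(ref["mag"]), tolerance = 1e-12)
      expect_equal(g$direction[i, j], unname(ref["dir"]), tolerance = 1e-12)
    }
  }
})

test_that("concentrated and split votes behave as the binning rules say", {
  cfg_hard <- hog_config(cell_size = 2, n_bins = 8, normalize = "none",
                         vote_interp = "hard")
  # all gradients point at channel 0's center: everything lands in bin 1
  mag <- matrix(c(1, 2, 3, 4), 2, 2)
  dir <- matrix(0, 2, 2)
  h <- cell_histogram(mag, dir, 1:2, 1:2, cfg_hard)
  expect_equal(h, c(10, rep(0, 7)))

  # one pixel exactly midway between channel centers 0 and 1, magnitude 2:
  # bilinear splits evenly, hard voting breaks the tie to the lower channel
  cfg_bil <- hog_config(cell_size = 2, n_bins = 8, normalize = "none",
                        vote_interp = "bilinear")
  mag1 <- matrix(c(2, 0, 0, 0), 2, 2)
  dir1 <- matrix(c(22.5, 0, 0, 0), 2, 2)
  expect_equal(cell_histogram(mag1, dir1, 1:2, 1:2, cfg_bil),
               c(1, 1, rep(0, 6)))
  expect_equal(cell_histogram(mag1, dir1, 1:2, 1:2, cfg_hard),
               c(2, rep(0, 7)))

  # the wrap midpoint between the last channel and channel 0 also goes to
  # the lower index, which on the circle is channel 0
  dirw <- matrix(c(337.5, 0, 0, 0), 2, 2)
  expect_equal(cell_histogram(mag1, dirw, 1:2, 1:2, cfg_hard),
               c(2, rep(0, 7)))
})

test_that("hard-voting histograms match the naive loop on random cells", {
  cfg <- hog_config(cell_size = 10, n_bins = 8, normalize = "none",
                    vote_interp = "hard")
  for (s in 1:5) {
    M <- with_seed_test(100 + s, matrix(rnorm(100), 10, 10))
    g <- pixel_gradients(M)
    h <- cell_histogram(g$magnitude, g$direction, 1:10, 1:10, cfg)
    expect_equal(h, naive_cell_histogram(M, 1:10, 1:10, 8), tolerance = 1e-12)
  }
})

test_that("the descriptor grid follows the truncation rule", {
  v1 <- mri_volume(array(with_seed_test(1, rnorm(60 * 60 * 12)),
                         c(60, 60, 12)), subject_id = "g1")
  s1 <- extract_hog(v1, hog_config(cell_size = 20))
  expect_equal(unname(s1$grid), c(12, 3, 3))
  expect_equal(nrow(s1$descriptors), 108)

  v2 <- mri_volume(array(with_seed_test(2, rnorm(64 * 60 * 12)),
                         c(64, 60, 12)), subject_id = "g2")
  s2 <- extract_hog(v2, hog_config(cell_size = 20))
  expect_equal(unname(s2$grid), c(12, 3, 3))

  expect_error(extract_hog(mri_volume(array(0, c(8, 8, 4)), subject_id = "t"),
                           hog_config(cell_size = 10)),
               "cell_size")
})

test_that("descriptor ordering is slice-major then row-major", {
  v <- mri_volume(array(with_seed_test(3, rnorm(40 * 40 * 4)), c(40, 40, 4)),
                  subject_id = "ord")
  s <- extract_hog(v, hog_config(cell_size = 10, normalize = "none",
                                 vote_interp = "hard"))
  expect_equal(unname(s$grid), c(4, 4, 4))
  # cross-check a handful of positions against per-cell recomputation
  for (p in c(1, 5, 17, 40, 64)) {
    pos <- s$positions[p, ]
    g <- pixel_gradients(v$data[, , pos["slice"]])
    rows <- ((pos["row"] - 1) * 10 + 1):(pos["row"] * 10)
    cols <- ((pos["col"] - 1) * 10 + 1):(pos["col"] * 10)
    expect_equal(s$descriptors[p, ],
                 cell_histogram(g$magnitude, g$direction, rows, cols,
                                s$config),
                 tolerance = 1e-12)
  }
  # canonical index arithmetic: position p = ((s-1)*R + (r-1))*Q + q... as
  # slice-major, row-major
  expect_equal(s$positions[1, ], c(slice = 1, row = 1, col = 1))
  expect_equal(s$positions[5, ], c(slice = 1, row = 2, col = 1))
  expect_equal(s$positions[17, ], c(slice = 2, row = 1, col = 1))
})

test_that("vote mass is conserved and shift invariance holds", {
  cfg <- hog_config(cell_size = 10, normalize = "none", vote_interp = "hard")
  v <- mri_volume(array(with_seed_test(4, rnorm(30 * 30 * 3)), c(30, 30, 3)),
                  subject_id = "c")
  s <- extract_hog(v, cfg)
  for (sl in 1:3) {
    g <- pixel_gradients(v$data[, , sl])
    expect_equal(sum(s$descriptors[s$positions[, 1] == sl, ]),
                 sum(g$magnitude), tolerance = 1e-9)
  }
  # bilinear voting conserves mass too (each pixel's magnitude is split)
  cfg_b <- hog_config(cell_size = 10, normalize = "none")
  s_b <- extract_hog(v, cfg_b)
  g_all <- sum(sapply(1:3, function(sl)
    sum(pixel_gradients(v$data[, , sl])$magnitude)))
  expect_equal(sum(s_b$descriptors), g_all, tolerance = 1e-9)

  v_shift <- v; v_shift$data <- v$data + 11.5
  expect_equal(extract_hog(v_shift, cfg)$descriptors, s$descriptors,
               tolerance = 1e-12)
})

test_that("l2 normalization yields unit rows except for zero cells", {
  arr <- array(0, c(30, 30, 2))
  arr[, , 1] <- with_seed_test(5, matrix(rnorm(900), 30, 30))
  # slice 2 stays constant: all its cells must give all-zero histograms
  v <- mri_volume(arr, subject_id = "n")
  s <- extract_hog(v, hog_config(cell_size = 10, normalize = "l2"))
  nrm <- sqrt(rowSums(s$descriptors^2))
  sl <- s$positions[, 1]
  expect_equal(nrm[sl == 1], rep(1, 9), tolerance = 1e-9)
  expect_equal(nrm[sl == 2], rep(0, 9))
})

test_that("halving the cell size quadruples the per-slice descriptor count", {
  v <- mri_volume(array(with_seed_test(6, rnorm(40 * 40 * 2)), c(40, 40, 2)),
                  subject_id = "h")
  n20 <- nrow(extract_hog(v, hog_config(cell_size = 20))$descriptors)
  n10 <- nrow(extract_hog(v, hog_config(cell_size = 10))$descriptors)
  expect_equal(n10, 4 * n20)
})

test_that("rotating a periodic slice by 90 degrees shifts signed bins by 2", {
  # periodic texture so the cell contents are identical up to rotation;
  # rotate counterclockwise: M2[i, j] = M[j, H - i + 1]
  n <- 40; cs <- 10
  xs <- matrix(rep(1:n, n), n, n, byrow = TRUE)
  ys <- matrix(rep(1:n, n), n, n, byrow = FALSE)
  M <- sin(2 * pi * xs / 10) + cos(2 * pi * ys / 5)
  M2 <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) M2[i, j] <- M[j, n - i + 1]
  cfg <- hog_config(cell_size = cs, n_bins = 8, normalize = "none",
                    vote_interp = "bilinear")
  s1 <- extract_hog(mri_volume(array(M, c(n, n, 1)), subject_id = "o"), cfg)
  s2 <- extract_hog(mri_volume(array(M2, c(n, n, 1)), subject_id = "r"), cfg)
  # compare interior cells only (border gradients are one-sided)
  interior <- s1$positions[, 2] %in% 2:3 & s1$positions[, 3] %in% 2:3
  # gradients rotate by -90 degrees ((gx, gy) -> (gy, -gx)), so channel c's
  # mass moves to channel c - 2 (cyclically)
  shift2 <- function(h) h[c(3:8, 1, 2)]
  for (p in which(interior)) {
    # the cell at (r, q) maps to (R - q + 1, r) under this rotation
    r <- s1$positions[p, 2]; q <- s1$positions[p, 3]
    p2 <- which(s2$positions[, 2] == 4 - q + 1 & s2$positions[, 3] == r)
    expect_equal(s2$descriptors[p2, ], shift2(s1$descriptors[p, ]),
                 tolerance = 1e-9)
  }
})

test_that("descriptor dumps round-trip through CSV", {
  v <- mri_volume(array(with_seed_test(8, rnorm(20 * 20 * 2)), c(20, 20, 2)),
                  subject_id = "d")
  s <- extract_hog(v, hog_config(cell_size = 10, normalize = "none"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_descriptors(s, f)
  tab <- read.csv(f)
  expect_identical(names(tab)[1:3], c("slice", "row", "col"))
  expect_equal(as.matrix(tab[, -(1:3)]), s$descriptors,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(as.matrix(tab[, 1:3]), s$positions, ignore_attr = TRUE)
})

test_that("baseline features concatenate histograms in canonical order", {
  v <- mri_volume(array(with_seed_test(7, rnorm(20 * 20 * 3)), c(20, 20, 3)),
                  subject_id = "b")
  s <- extract_hog(v, hog_config(cell_size = 10, normalize = "none"))
  f <- baseline_features(s)
  P <- nrow(s$descriptors); N <- ncol(s$descriptors)
  expect_length(f, P * N)
  for (p in c(1, 4, P))
    expect_equal(f[((p - 1) * N + 1):(p * N)], s$descriptors[p, ])
  expect_identical(f, baseline_features(s))
})
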