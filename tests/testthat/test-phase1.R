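# Phase 1: per-position clustering and the membership transform

make_sets <- function(n_subj = 8, shape = c(20, 20, 2), seed = 50,
                      config = hog_config(cell_size = 10)) {
  arrs <- lapply(seq_len(n_subj), function(i)
    with_seed_test(seed + i, array(rnorm(prod(shape)), shape)))
  hog_sets_from_arrays(arrs, config)
}

test_that("model bookkeeping: one centroid set per position", {
  sets <- make_sets()
  ph <- fit_phase1(sets, fcm_config(seed = 1))
  P <- nrow(sets[[1]]$descriptors)
  expect_equal(dim(ph$centroids), c(P, 2, 8))
  expect_length(ph$degenerate, P)
  expect_equal(dim(ph$train_memberships), c(8, P))
  expect_true(all(ph$train_memberships >= 0 & ph$train_memberships <= 1))
})

test_that("positions identical across subjects are degenerate with 0.5", {
  # constant slice 2 in every subject: zero descriptors at its positions
  arrs <- lapply(1:6, function(i) {
    a <- with_seed_test(60 + i, array(rnorm(20 * 20 * 2), c(20, 20, 2)))
    a[, , 2] <- 3
    a
  })
  sets <- hog_sets_from_arrays(arrs, hog_config(cell_size = 10))
  ph <- fit_phase1(sets, fcm_config(seed = 1))
  sl <- ph$positions[, 1]
  expect_true(all(ph$degenerate[sl == 2]))
  expect_false(any(ph$degenerate[sl == 1]))
  expect_true(all(ph$train_memberships[, sl == 2] == 0.5))
  # and transform emits 0.5 there too
  u <- fcm_transform(ph, sets[[1]])
  expect_true(all(u[sl == 2] == 0.5))
})

test_that("batched per-position fitting equals position-by-position fcm_fit", {
  sets <- make_sets(n_subj = 7, seed = 70)
  cfg <- fcm_config(seed = 13)
  ph <- fit_phase1(sets, cfg)
  P <- nrow(sets[[1]]$descriptors)
  for (p in seq_len(P)) {
    x <- t(vapply(sets, function(s) s$descriptors[p, ], numeric(8)))
    cfg_p <- cfg; cfg_p$seed <- fuzzyhog:::derive_seed(cfg$seed, p)
    f <- fcm_fit(x, cfg_p)
    ord <- order(-sqrt(rowSums(f$centroids^2)))
    expect_identical(unname(ph$centroids[p, , ]),
                     unname(f$centroids[ord, ]))
    expect_identical(unname(ph$train_memberships[, p]),
                     unname(f$memberships[, ord[1]]))
  }
})

test_that("transform is exact for coincident descriptors and soft for others", {
  sets <- make_sets(n_subj = 6, seed = 90)
  ph <- fit_phase1(sets, fcm_config(seed = 2))
  # build a synthetic subject whose descriptor at every position equals the
  # first-cluster centroid: soft membership must be exactly 1
  probe <- sets[[1]]
  probe$descriptors <- matrix(ph$centroids[, 1, ],
                              nrow(probe$descriptors),
                              ncol(probe$descriptors))
  expect_true(all(fcm_transform(ph, probe, "soft") == 1))
  expect_true(all(fcm_transform(ph, probe, "hard") == 1))
  # equidistant descriptor: soft 0.5, hard ties to the first cluster
  mid <- sets[[1]]
  mid$descriptors <- matrix((ph$centroids[, 1, ] + ph$centroids[, 2, ]) / 2,
                            nrow(mid$descriptors), ncol(mid$descriptors))
  expect_equal(fcm_transform(ph, mid, "soft"),
               rep(0.5, nrow(mid$descriptors)), tolerance = 1e-6)
  # exact ties (mirror-image centroids, zero descriptor) go to the first
  # cluster under hard assignment
  tie <- ph
  v <- seq(0.1, 0.8, by = 0.1)
  P <- nrow(mid$descriptors)
  tie$centroids[, 1, ] <- matrix(v, P, 8, byrow = TRUE)
  tie$centroids[, 2, ] <- matrix(-v, P, 8, byrow = TRUE)
  tie$degenerate[] <- FALSE
  zero <- sets[[1]]
  zero$descriptors <- matrix(0, P, 8)
  expect_true(all(fcm_transform(tie, zero, "hard") == 1))
  expect_equal(fcm_transform(tie, zero, "soft"), rep(0.5, P))
})

test_that("soft transform reproduces the training memberships", {
  sets <- make_sets(n_subj = 9, seed = 110)
  ph <- fit_phase1(sets, fcm_config(seed = 3))
  for (i in c(1, 5, 9))
    expect_equal(fcm_transform(ph, sets[[i]], "soft"),
                 ph$train_memberships[i, ], tolerance = 1e-6)
})

test_that("grid or config mismatches are refused", {
  sets <- make_sets(n_subj = 5, seed = 130)
  ph <- fit_phase1(sets, fcm_config(seed = 1))
  other_cfg <- make_sets(n_subj = 1, seed = 131,
                         config = hog_config(cell_size = 10, n_bins = 6))
  expect_error(fcm_transform(ph, other_cfg[[1]]), "configuration")
  other_grid <- hog_sets_from_arrays(
    list(with_seed_test(1, array(rnorm(20 * 20 * 3), c(20, 20, 3)))),
    hog_config(cell_size = 10))
  expect_error(fcm_transform(ph, other_grid[[1]]), "grid")
  mixed <- c(sets[1:3], other_grid)
  expect_error(fit_phase1(mixed, fcm_config()), "grid")
})

test_that("a position inside every lesion separates the classes", {
  # fixed lesion position so one cell is lesioned in every class-1 subject
  co <- generate_cohort(8, "detection",
                        base_spec = phantom_spec(shape = c(40, 40, 8),
                                                 lesion_present = TRUE,
                                                 lesion_radius = 6),
                        seed = 140, jitter = FALSE)
  sets <- lapply(lapply(co$volumes, zscore_normalize), extract_hog,
                 config = hog_config(cell_size = 10))
  ph <- fit_phase1(sets, fcm_config(seed = 4))
  # cell containing the lesion center: center voxel 20.5 -> row 2, col 2,
  # slice 4 (grid 8 x 4 x 4)
  p <- which(ph$positions[, 1] == 4 & ph$positions[, 2] == 2 &
             ph$positions[, 3] == 2)
  hard <- ph$train_memberships[, p] > 0.5
  labs <- co$labels$label == 1
  agree <- max(mean(hard == labs), mean(hard == !labs))
  expect_gte(agree, 0.9)
})

test_that("global scope shares one centroid set across positions", {
  sets <- make_sets(n_subj = 6, seed = 150)
  ph <- fit_phase1(sets, fcm_config(seed = 5, scope = "global"))
  expect_equal(dim(ph$centroids), c(2, 8))
  u <- fcm_transform(ph, sets[[1]])
  expect_length(u, nrow(sets[[1]]$descriptors))
  expect_equal(u, ph$train_memberships[1, ], tolerance = 1e-6)
})

test_that("membership vectors are N times shorter than concatenated HOG", {
  sets <- make_sets(n_subj = 5, seed = 160)
  ph <- fit_phase1(sets, fcm_config(seed = 1))
  u <- fcm_transform(ph, sets[[1]])
  expect_equal(length(baseline_features(sets[[1]])),
               length(u) * ncol(sets[[1]]$descriptors))
})
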