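#' Specification of a synthetic brain phantom
#'
#' Describes one synthetic "brain": an ellipsoid of tissue-level intensity on
#' a zero background with additive Gaussian noise, optionally carrying a
#' bright spherical lesion.  Two lesion textures are available:
#' `"smooth_bright"` is a constant hyperintense plateau (edge gradients only,
#' emulating a homogeneous low-grade lesion) and `"rough_bright"` modulates
#' the plateau with seeded high-frequency multiplicative texture (strong
#' heterogeneous internal gradients, emulating a high-grade lesion).
#'
#' @param shape integer vector of length 3, voxel dimensions (X, Y, Z).
#' @param background_level mean intensity of brain tissue (arbitrary units).
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param lesion_present logical; add a spherical lesion?
#' @param lesion_center voxel coordinates of the lesion center (defaults to
#'   the grid center).
#' @param lesion_radius lesion radius in voxels.
#' @param lesion_texture `"smooth_bright"` or `"rough_bright"`.
#' @param lesion_contrast intensity added to `background_level` inside the
#'   lesion.
#' @param texture_amplitude relative amplitude of the multiplicative texture
#'   used by `"rough_bright"` (uniform on \[-amplitude, amplitude\]).
#' @param seed RNG seed; identical specs (including seed) yield bit-identical
#'   volumes.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()], [generate_cohort()]
#' @export
phantom_spec <- function(shape = c(60, 60, 12),
                         background_level = 100,
                         noise_sd = 5,
                         lesion_present = FALSE,
                         lesion_center = NULL,
                         lesion_radius = 8,
                         lesion_texture = c("smooth_bright", "rough_bright"),
                         lesion_contrast = 40,
                         texture_amplitude = 0.3,
                         seed = 1L) {
  lesion_texture <- match.arg(lesion_texture)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 4L))
    stop("`shape` must be three dimensions, each >= 4 voxels")
  if (is.null(lesion_center)) lesion_center <- (shape + 1) / 2
  if (length(lesion_center) != 3L)
    stop("`lesion_center` must have three coordinates")
  if (lesion_present) {
    if (lesion_radius <= 0)
      stop("`lesion_radius` must be positive when a lesion is present")
    check_lesion_inside(shape, lesion_center, lesion_radius)
  }
  structure(list(shape = shape, background_level = background_level,
                 noise_sd = noise_sd, lesion_present = lesion_present,
                 lesion_center = lesion_center, lesion_radius = lesion_radius,
                 lesion_texture = lesion_texture,
                 lesion_contrast = lesion_contrast,
                 texture_amplitude = texture_amplitude,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# The volume models a thick-slab axial acquisition through the middle of the
# brain: in-plane the ellipsoid covers 90% of the field of view, while its
# through-plane semi-axis equals the full slab thickness, so the slab samples
# the brain around its equator (each slice shows a large ellipse) and a
# realistically sized spherical lesion fits inside the ellipsoid even though
# the slab itself is thin.
brain_geometry <- function(shape) {
  list(center = (shape + 1) / 2, semi = c(0.45 * shape[1:2], shape[3]))
}

# Conservative containment check: the lesion sphere must lie entirely inside
# the brain ellipsoid.  Sufficient condition: the center lies inside the
# ellipsoid with all semi-axes shrunk by the radius.
check_lesion_inside <- function(shape, center, radius) {
  g <- brain_geometry(shape)
  margin <- g$semi - radius
  if (any(margin <= 0) ||
      sqrt(sum(((center - g$center) / margin)^2)) > 1)
    stop("lesion sphere does not fit inside the brain ellipsoid")
  invisible(TRUE)
}

#' Construct an MRI volume object
#'
#' Bundles a 3D intensity array with its voxel-to-world affine, a subject
#' identifier and an optional binary class label.  All volumes of one cohort
#' must share shape and affine (the aligned-to-template precondition of the
#' downstream position-wise analysis).
#'
#' @param data 3D numeric array of intensities (all finite).
#' @param affine 4x4 voxel-to-world transform (default identity).
#' @param subject_id subject identifier string.
#' @param label binary class label (0/1) or `NA` if unknown.
#' @return An object of class `mri_volume`.
#' @export
mri_volume <- function(data, affine = diag(4), subject_id = "subject",
                       label = NA_integer_) {
  if (length(dim(data)) != 3L) stop("`data` must have exactly 3 axes")
  if (!all(is.finite(data))) stop("`data` must be all finite")
  structure(list(data = data, affine = affine,
                 subject_id = as.character(subject_id),
                 label = label),
            class = "mri_volume")
}

#' @export
print.mri_volume <- function(x, ...) {
  cat(sprintf("<mri_volume> %s  %s  label=%s  range=[%.3g, %.3g]\n",
              x$subject_id, paste(dim(x$data), collapse = "x"),
              ifelse(is.na(x$label), "?", x$label),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Generate one synthetic brain phantom
#'
#' Renders the phantom described by a [phantom_spec()]: an ellipsoid (semi-axes
#' 0.45 of each dimension) at `background_level` on a zero background, the
#' optional lesion sphere, then additive Gaussian noise.  The texture and
#' noise draws use seeds derived from `spec$seed`, so the result is fully
#' reproducible.
#'
#' @param spec a [phantom_spec()].
#' @param subject_id identifier stored in the returned volume.
#' @param label binary label stored in the returned volume.
#' @return An [mri_volume()] with identity affine.
#' @examples
#' vol <- generate_phantom(phantom_spec(lesion_present = TRUE, seed = 7))
#' range(vol$data)
#' @export
generate_phantom <- function(spec, subject_id = "phantom", label = NA_integer_) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  g <- brain_geometry(shape)
  ax <- (seq_len(shape[1]) - g$center[1]) / g$semi[1]
  ay <- (seq_len(shape[2]) - g$center[2]) / g$semi[2]
  az <- (seq_len(shape[3]) - g$center[3]) / g$semi[3]
  e2 <- outer(outer(ax^2, ay^2, "+"), az^2, "+")
  data <- ifelse(e2 <= 1, spec$background_level, 0)

  if (spec$lesion_present) {
    check_lesion_inside(shape, spec$lesion_center, spec$lesion_radius)
    dx <- seq_len(shape[1]) - spec$lesion_center[1]
    dy <- seq_len(shape[2]) - spec$lesion_center[2]
    dz <- seq_len(shape[3]) - spec$lesion_center[3]
    d2 <- outer(outer(dx^2, dy^2, "+"), dz^2, "+")
    mask <- d2 <= spec$lesion_radius^2
    level <- spec$background_level + spec$lesion_contrast
    if (spec$lesion_texture == "smooth_bright") {
      data[mask] <- level
    } else {
      tex <- with_seed(derive_seed(spec$seed, "texture"),
                       stats::runif(sum(mask), -1, 1))
      data[mask] <- level * (1 + spec$texture_amplitude * tex)
    }
  }
  if (spec$noise_sd > 0) {
    data <- data + with_seed(derive_seed(spec$seed, "noise"),
                             stats::rnorm(length(data), sd = spec$noise_sd))
  }
  dim(data) <- shape
  mri_volume(data, diag(4), subject_id, label)
}

#' Voxel mask of a spec's lesion sphere
#'
#' Logical array marking the lesion voxels of a [phantom_spec()]; used as
#' ground truth when assessing discriminant-weight localization.
#'
#' @param spec a [phantom_spec()] with `lesion_present = TRUE`.
#' @return Logical 3D array of the spec's shape.
#' @export
lesion_mask <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"), spec$lesion_present)
  dx <- seq_len(spec$shape[1]) - spec$lesion_center[1]
  dy <- seq_len(spec$shape[2]) - spec$lesion_center[2]
  dz <- seq_len(spec$shape[3]) - spec$lesion_center[3]
  outer(outer(dx^2, dy^2, "+"), dz^2, "+") <= spec$lesion_radius^2
}

#' Generate an aligned synthetic cohort
#'
#' Builds `2 * n_per_class` phantoms for one of two tasks.  `"detection"`
#' contrasts lesioned brains (label 1) with lesion-free brains (label 0);
#' `"grading"` contrasts rough-textured lesions (label 1, high-grade
#' analogue) with smooth lesions (label 0, low-grade analogue).  Across
#' subjects the lesion center is jittered by up to +/-10% of each dimension
#' and the radius by up to +/-20%, so boundary cell positions see both
#' lesioned and normal tissue — the regime the soft cluster assignment is
#' designed for.  Per-subject seeds are derived deterministically from
#' `seed`.
#'
#' @param n_per_class subjects per class (>= 2).
#' @param task `"detection"` or `"grading"`.
#' @param base_spec template [phantom_spec()]; its lesion geometry is the
#'   jitter center.
#' @param seed cohort master seed.
#' @param dir if non-`NULL`, write `<subject_id>.nii.gz` files, a
#'   `labels.csv` (`subject_id,label`) and a `manifest.json` there.
#' @param jitter logical; disable to place every lesion at the exact
#'   `base_spec` geometry (used for localization ground truth).
#' @return A list with `volumes` (list of [mri_volume()]), `labels`
#'   (data.frame `subject_id`, `label` in generation order) and `specs`
#'   (per-subject [phantom_spec()]s).
#' @export
generate_cohort <- function(n_per_class, task = c("detection", "grading"),
                            base_spec = phantom_spec(lesion_present = TRUE),
                            seed = 1L, dir = NULL, jitter = TRUE) {
  task <- match.arg(task)
  if (n_per_class < 2) stop("`n_per_class` must be >= 2")
  if (!base_spec$lesion_present)
    stop("`base_spec` must describe a lesion (lesion_present = TRUE)")
  n <- 2L * n_per_class
  labels <- rep(c(1L, 0L), each = n_per_class)
  shape <- base_spec$shape

  specs <- vector("list", n)
  volumes <- vector("list", n)
  ids <- sprintf("sub%03d", seq_len(n))
  for (i in seq_len(n)) {
    si <- derive_seed(seed, i)
    sp <- base_spec
    sp$seed <- si
    lesioned <- task == "grading" || labels[i] == 1L
    sp$lesion_present <- lesioned
    if (lesioned) {
      if (jitter) {
        jit <- with_seed(derive_seed(si, "jitter"), list(
          center = stats::runif(3, -0.10, 0.10) * shape,
          radius = stats::runif(1, 0.8, 1.2)))
        sp$lesion_center <- base_spec$lesion_center + jit$center
        sp$lesion_radius <- base_spec$lesion_radius * jit$radius
      }
      sp$lesion_texture <- if (task == "grading") {
        if (labels[i] == 1L) "rough_bright" else "smooth_bright"
      } else base_spec$lesion_texture
      check_lesion_inside(shape, sp$lesion_center, sp$lesion_radius)
    }
    specs[[i]] <- sp
    volumes[[i]] <- generate_phantom(sp, subject_id = ids[i], label = labels[i])
  }
  out <- list(volumes = volumes,
              labels = data.frame(subject_id = ids, label = labels,
                                  stringsAsFactors = FALSE),
              specs = specs)
  if (!is.null(dir)) write_cohort(out, dir)
  invisible(out)
}

write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (v in cohort$volumes) {
    img <- RNifti::asNifti(v$data)
    RNifti::writeNifti(img, file.path(dir, paste0(v$subject_id, ".nii.gz")))
  }
  utils::write.csv(cohort$labels, file.path(dir, "labels.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest <- lapply(cohort$specs, function(s) unclass(s))
  names(manifest) <- cohort$labels$subject_id
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
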