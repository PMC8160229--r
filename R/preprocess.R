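#' Z-score intensity standardization
#'
#' Standardizes a volume to zero mean and unit variance over the whole data
#' array, clips the z-scores at \[-4, 4\], and rescales linearly to \[0, 1\]
#' (so z = -4 maps to 0, z = 0 to 0.5, z = +4 to 1).  The standard deviation
#' uses the population convention (divide by N) for bit-reproducibility.
#' By default the statistics include every voxel, background air included;
#' `mask = TRUE` restricts them to nonzero voxels.
#'
#' @param vol an [mri_volume()].
#' @param mask logical; compute mean/SD over nonzero voxels only.
#' @return An `mri_volume` additionally classed `normalized_volume`, with the
#'   removed mean and SD recorded in attribute `params_used`.
#' @examples
#' v <- generate_phantom(phantom_spec(seed = 1))
#' nv <- zscore_normalize(v)
#' range(nv$data)
#' @export
zscore_normalize <- function(vol, mask = FALSE) {
  stopifnot(inherits(vol, "mri_volume"))
  x <- vol$data
  sel <- if (mask) x != 0 else rep(TRUE, length(x))
  mu <- mean(x[sel])
  sd_pop <- sqrt(mean((x[sel] - mu)^2))
  if (sd_pop == 0)
    stop(sprintf("constant volume (zero variance) for subject '%s'",
                 vol$subject_id))
  z <- pmin(pmax((x - mu) / sd_pop, -4), 4)
  out <- vol
  out$data <- (z + 4) / 8
  dim(out$data) <- dim(x)
  attr(out, "params_used") <- list(mean = mu, sd = sd_pop, mask = mask)
  class(out) <- c("normalized_volume", "mri_volume")
  out
}

#' Load an aligned NIfTI cohort with labels
#'
#' Reads every subject listed in a labels CSV (`subject_id,label`, header
#' required) from `<nifti_dir>/<subject_id>.nii.gz` (or `.nii`), in CSV row
#' order.  All volumes must share the same shape (the aligned-cohort
#' contract) and labels must be 0/1.
#'
#' @param nifti_dir directory holding the NIfTI files.
#' @param labels_csv path to the labels CSV.
#' @return A list with `volumes` (list of [mri_volume()], labels attached)
#'   and `labels` (the parsed data.frame).
#' @export
load_cohort <- function(nifti_dir, labels_csv) {
  tab <- utils::read.csv(labels_csv, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "label") %in% names(tab)))
    stop("labels CSV must have columns subject_id,label")
  vols <- vector("list", nrow(tab))
  ref_shape <- NULL
  for (i in seq_len(nrow(tab))) {
    id <- tab$subject_id[i]
    lab <- tab$label[i]
    if (!lab %in% c(0, 1))
      stop(sprintf("non-binary label '%s' for subject '%s'", lab, id))
    path <- file.path(nifti_dir, paste0(id, c(".nii.gz", ".nii")))
    path <- path[file.exists(path)]
    if (length(path) == 0)
      stop(sprintf("no NIfTI file found for subject '%s'", id))
    img <- RNifti::readNifti(path[1])
    arr <- as.array(img)
    if (length(dim(arr)) != 3L)
      stop(sprintf("volume for subject '%s' is not 3D", id))
    if (is.null(ref_shape)) ref_shape <- dim(arr)
    else if (!identical(dim(arr), ref_shape))
      stop(sprintf("shape mismatch for subject '%s' (%s vs %s)", id,
                   paste(dim(arr), collapse = "x"),
                   paste(ref_shape, collapse = "x")))
    vols[[i]] <- mri_volume(arr, structure(RNifti::xform(img), dim = c(4, 4)),
                            id, as.integer(lab))
  }
  list(volumes = vols, labels = tab)
}
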