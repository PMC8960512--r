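#' Lesion phantom: 3-D intensity volume with a lesion mask
#'
#' Container for the lesion-filling operator: a 3-D intensity array, a binary
#' lesion mask of the same shape, the voxel size in mm, and (optionally) the
#' ground-truth tissue labels and a segmentation-style filling mask that may
#' overshoot the true lesion at tissue interfaces.
#'
#' @param intensity 3-D numeric array.
#' @param lesion_mask 3-D logical array, same shape (the true lesion).
#' @param voxel_size length-3 positive numeric, mm.
#' @param tissue_truth optional 3-D character array of tissue labels.
#' @param fill_mask optional 3-D logical array actually used for filling
#'   (e.g. a binarised lesion probability map); defaults to `lesion_mask`.
#' @return An object of class `scn_phantom`.
#' @export
lesion_phantom <- function(intensity, lesion_mask, voxel_size = c(1, 1, 1),
                           tissue_truth = NULL, fill_mask = NULL) {
  if (length(dim(intensity)) != 3) stopf("intensity must be a 3-D array")
  if (!identical(dim(intensity), dim(lesion_mask)))
    stopf("intensity and lesion_mask shapes differ")
  if (!is.null(tissue_truth) && !identical(dim(intensity), dim(tissue_truth)))
    stopf("tissue_truth shape differs")
  if (!is.null(fill_mask) && !identical(dim(intensity), dim(fill_mask)))
    stopf("fill_mask shape differs")
  if (length(voxel_size) != 3 || any(voxel_size <= 0))
    stopf("voxel_size must be 3 positive values (mm)")
  structure(
    list(intensity = intensity, lesion_mask = lesion_mask != 0,
         voxel_size = as.numeric(voxel_size), tissue_truth = tissue_truth,
         fill_mask = if (is.null(fill_mask)) NULL else fill_mask != 0),
    class = "scn_phantom")
}

#' @export
print.scn_phantom <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("Lesion phantom: %d x %d x %d voxels (%.1f x %.1f x %.1f mm)\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3]))
  cat(sprintf("  lesion voxels: %d (%.2f ml)\n", sum(x$lesion_mask),
              lesion_volume_ml(x)))
  if (!is.null(x$fill_mask))
    cat(sprintf("  filling mask: %d voxels\n", sum(x$fill_mask)))
  invisible(x)
}

#' Total lesion volume of a phantom in ml
#'
#' @param phantom an `scn_phantom`.
#' @return Lesion volume in ml (mask voxel count times voxel volume).
#' @export
lesion_volume_ml <- function(phantom) {
  sum(phantom$lesion_mask) * prod(phantom$voxel_size) / 1000
}

#' Fill lesions with the intensity of adjacent voxels
#'
#' Iterative inward filling: at each pass, every unfilled lesion voxel with
#' at least one filled or non-lesion 6-neighbour receives the mean intensity
#' of those neighbours; passes repeat (synchronously) until the mask is
#' exhausted, so intensities propagate from the lesion rim towards its core.
#' Non-lesion voxels are untouched and the output mask is empty.
#'
#' @param phantom an `scn_phantom` with at least one non-lesion voxel.
#' @param use_fill_mask fill over the phantom's `fill_mask` when present
#'   (default) rather than the true `lesion_mask`.
#' @return The filled `scn_phantom` (empty masks); attribute `n_passes`
#'   records the number of inward sweeps.
#' @examples
#' v <- array(5, c(4, 4, 4)); m <- array(FALSE, c(4, 4, 4)); m[2, 2, 2] <- TRUE
#' filled <- fill_lesions(lesion_phantom(v, m))
#' all(filled$intensity == 5)
#' @export
fill_lesions <- function(phantom, use_fill_mask = TRUE) {
  stopifnot(inherits(phantom, "scn_phantom"))
  mask <- if (use_fill_mask && !is.null(phantom$fill_mask))
    phantom$fill_mask else phantom$lesion_mask
  if (all(mask)) stopf("lesion mask covers the entire volume; no source intensities")
  if (!any(mask)) {
    out <- phantom
    attr(out, "n_passes") <- 0L
    return(out)
  }
  filled <- .cpp_fill_lesions(as.numeric(phantom$intensity),
                              as.integer(mask), dim(phantom$intensity))
  n_passes <- attr(filled, "n_passes")
  out <- lesion_phantom(array(filled, dim(phantom$intensity)),
                        array(FALSE, dim(phantom$intensity)),
                        voxel_size = phantom$voxel_size,
                        tissue_truth = phantom$tissue_truth)
  attr(out, "n_passes") <- n_passes
  out
}

#' Generate a deterministic brain-like lesion phantom
#'
#' Builds a concentric three-shell "brain": a white-matter core, a
#' grey-matter shell, a CSF rim and background, with per-class mean
#' intensities from `tissue_spec` plus optional Gaussian noise. Lesions are
#' spheres (voxel-centre test against `center`/`radius`), given a
#' hypointense intensity; placing them near the WM/GM boundary reproduces
#' the interface situation where filling artefacts arise. When
#' `mask_dilate > 0` the phantom also carries a `fill_mask` dilated by that
#' many 6-neighbourhood steps, emulating a binarised lesion probability map
#' that overshoots the true lesion.
#'
#' @param shape length-3 integer volume dimensions.
#' @param lesion_spec data.frame with columns `x`, `y`, `z`, `radius`
#'   (voxel units); every sphere must lie inside the volume.
#' @param tissue_spec named numeric of class mean intensities, in
#'   classification tie-break order; default
#'   `c(background = 0, CSF = 25, GM = 60, WM = 90)`.
#' @param seed integer seed (noise reproducibility).
#' @param noise_sd Gaussian intensity noise SD.
#' @param lesion_intensity intensity assigned inside lesions before filling;
#'   the default 55 is a WM hypointensity close to the GM mean, the
#'   segmentation hazard that motivates filling.
#' @param mask_dilate 6-neighbourhood dilation steps for the `fill_mask`.
#' @param voxel_size length-3 voxel size in mm.
#' @return An `scn_phantom` with `tissue_truth` labels.
#' @export
generate_phantom <- function(shape = c(32, 32, 32), lesion_spec = NULL,
                             tissue_spec = c(background = 0, CSF = 25,
                                             GM = 60, WM = 90),
                             seed = 1L, noise_sd = 2,
                             lesion_intensity = 55, mask_dilate = 0,
                             voxel_size = c(1, 1, 1)) {
  stopifnot(length(shape) == 3, all(shape >= 4))
  cx <- (shape + 1) / 2
  r_brain <- 0.45 * min(shape)
  ax <- seq_len(shape[1]); ay <- seq_len(shape[2]); az <- seq_len(shape[3])
  R <- sqrt(outer(outer((ax - cx[1])^2, (ay - cx[2])^2, "+"),
                  (az - cx[3])^2, "+"))
  truth <- array("background", shape)
  truth[R <= r_brain] <- "CSF"
  truth[R <= 0.85 * r_brain] <- "GM"
  truth[R <= 0.55 * r_brain] <- "WM"
  intensity <- array(tissue_spec[truth], shape)
  if (noise_sd > 0) {
    set.seed(child_seed(seed, 21L))
    intensity <- intensity + array(stats::rnorm(prod(shape), 0, noise_sd),
                                   shape)
  }
  mask <- array(FALSE, shape)
  if (!is.null(lesion_spec) && nrow(lesion_spec) > 0) {
    for (i in seq_len(nrow(lesion_spec))) {
      ls <- lesion_spec[i, ]
      if (any(c(ls$x - ls$radius, ls$y - ls$radius, ls$z - ls$radius) < 1) ||
          ls$x + ls$radius > shape[1] || ls$y + ls$radius > shape[2] ||
          ls$z + ls$radius > shape[3])
        stopf("lesion sphere %d extends outside the volume", i)
      d2 <- outer(outer((ax - ls$x)^2, (ay - ls$y)^2, "+"), (az - ls$z)^2, "+")
      mask <- mask | (d2 <= ls$radius^2)
    }
    intensity[mask] <- lesion_intensity
    if (noise_sd > 0) {
      set.seed(child_seed(seed, 22L))
      intensity[mask] <- intensity[mask] +
        stats::rnorm(sum(mask), 0, noise_sd)
    }
  }
  fill_mask <- NULL
  if (mask_dilate > 0 && any(mask)) {
    fill_mask <- mask
    for (i in seq_len(mask_dilate)) fill_mask <- dilate6(fill_mask)
  }
  lesion_phantom(intensity, mask, voxel_size = voxel_size,
                 tissue_truth = truth, fill_mask = fill_mask)
}

# One 6-neighbourhood binary dilation step.
#' @keywords internal
#' @noRd
dilate6 <- function(m) {
  d <- dim(m)
  out <- m
  out[-1, , ] <- out[-1, , ] | m[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
  out[, -1, ] <- out[, -1, ] | m[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
  out[, , -1] <- out[, , -1] | m[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
  out
}

#' Nearest-mean tissue classification
#'
#' Assigns each voxel the tissue class whose mean intensity (from
#' `tissue_spec`) is closest; ties go to the earlier class in the vector
#' (deterministic).
#'
#' @param intensity 3-D numeric array.
#' @param tissue_spec named numeric of class mean intensities.
#' @return 3-D character array of class labels.
#' @export
classify_tissue <- function(intensity, tissue_spec = c(background = 0,
                                                       CSF = 25, GM = 60,
                                                       WM = 90)) {
  v <- as.numeric(intensity)
  d <- abs(outer(v, tissue_spec, "-"))
  idx <- max.col(-d, ties.method = "first")
  array(names(tissue_spec)[idx], dim(intensity))
}

#' Count filling-induced tissue-class changes
#'
#' Compares tissue labels before and after filling and counts changed voxels
#' inside and outside the true lesion mask. Changes inside the mask are the
#' intended effect of filling; changes outside are artefacts — the
#' quantitative surrogate for a visual artefact census on filled images.
#'
#' @param before,after 3-D character (or integer) label arrays, same shape.
#' @param lesion_mask 3-D logical array partitioning the counts.
#' @return List with `changed_voxels_inside_mask` and
#'   `changed_voxels_outside_mask`.
#' @export
tissue_change_score <- function(before, after, lesion_mask) {
  if (!identical(dim(before), dim(after)) ||
      !identical(dim(before), dim(lesion_mask)))
    stopf("label arrays and mask must share one shape")
  changed <- before != after
  m <- lesion_mask != 0
  list(changed_voxels_inside_mask = sum(changed & m),
       changed_voxels_outside_mask = sum(changed & !m))
}

#' Binarise a lesion probability map
#'
#' @param prob 3-D numeric array of lesion probabilities in \[0, 1\].
#' @param threshold binarisation threshold (default 0.5).
#' @return 3-D logical array.
#' @export
binarize_probability_mask <- function(prob, threshold = 0.5) {
  if (any(prob < 0 | prob > 1)) stopf("probabilities must lie in [0, 1]")
  prob >= threshold
}

#' Read or write phantoms as NIfTI-1
#'
#' Thin wrappers over RNifti for interoperating with imaging pipelines.
#' RNifti is only required when these are called.
#'
#' @param image_path,mask_path NIfTI file paths (intensity and binary mask).
#' @param phantom an `scn_phantom`.
#' @param path output NIfTI path for the intensity volume.
#' @return `read_phantom()` returns an `scn_phantom`; `write_phantom()`
#'   returns `path` invisibly.
#' @export
read_phantom <- function(image_path, mask_path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stopf("RNifti is required for NIfTI input")
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  lesion_phantom(array(as.numeric(img), dim(img)),
                 array(as.numeric(msk) > 0.5, dim(msk)),
                 voxel_size = RNifti::pixdim(img)[1:3])
}

#' @rdname read_phantom
#' @export
write_phantom <- function(phantom, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stopf("RNifti is required for NIfTI output")
  img <- RNifti::asNifti(phantom$intensity)
  RNifti::pixdim(img) <- phantom$voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}
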