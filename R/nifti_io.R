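#' In-memory set of aligned subject brain volumes
#'
#' Holds `n` subjects' 3-D volumes in one array (subject index first), the
#' shared voxel-to-world affine, and an analysis mask. All volumes must be
#' in the same space: one shape, one affine.
#'
#' @param data numeric array of dimension `c(n, X, Y, Z)`.
#' @param affine 4 x 4 voxel-to-world matrix (0-based voxel indices, as in
#'   the NIfTI convention).
#' @param mask logical `X x Y x Z` array of analysis voxels; defaults to all.
#' @param subject_id optional subject identifiers (length `n`).
#' @return object of class `brain_image_set`.
#' @export
brain_image_set <- function(data, affine = diag(4), mask = NULL,
                            subject_id = NULL) {
  if (length(dim(data)) != 4L) {
    stop("data must be a 4-D array: subjects x X x Y x Z")
  }
  dims <- dim(data)[2:4]
  if (!identical(dim(affine), c(4L, 4L))) stop("affine must be 4 x 4")
  if (is.null(mask)) mask <- array(TRUE, dims)
  mask <- array(as.logical(mask), dim(mask))
  if (!identical(dim(mask), as.integer(dims))) {
    stop("mask dimensions do not match the volumes")
  }
  if (is.null(subject_id)) subject_id <- as.character(seq_len(dim(data)[1]))
  if (length(subject_id) != dim(data)[1]) {
    stop("subject_id must have one entry per volume")
  }
  structure(list(data = data, affine = affine, mask = mask,
                 subject_id = as.character(subject_id)),
            class = "brain_image_set")
}

#' @export
print.brain_image_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<brain_image_set> %d subjects, %d x %d x %d voxels (%d in mask)\n",
              d[1], d[2], d[3], d[4], sum(x$mask)))
  invisible(x)
}

#' Read aligned subject volumes from NIfTI files
#'
#' Accepts either one 4-D NIfTI (4th dimension = subjects) or a vector of
#' 3-D files, plus an optional mask image. All images must share shape and
#' affine (tolerance `1e-4` on affine entries).
#'
#' @param paths one 4-D NIfTI path or a character vector of 3-D paths.
#' @param mask_path optional NIfTI mask (non-zero = in mask).
#' @param subject_id optional subject identifiers.
#' @return a [brain_image_set()].
#' @export
read_brain_images <- function(paths, mask_path = NULL, subject_id = NULL) {
  imgs <- lapply(paths, RNifti::readNifti)
  first <- imgs[[1L]]
  affine <- unclass(RNifti::xform(first))
  if (length(paths) == 1L && length(dim(first)) == 4L) {
    dat <- aperm(array(as.numeric(first), dim(first)), c(4, 1, 2, 3))
  } else {
    for (k in seq_along(imgs)) {
      if (length(dim(imgs[[k]])) != 3L) {
        stop("expected 3-D volumes, got ", length(dim(imgs[[k]])),
             "-D in ", paths[k])
      }
      if (!identical(dim(imgs[[k]]), dim(first))) {
        stop("volume shape mismatch: ", paths[k])
      }
      a <- unclass(RNifti::xform(imgs[[k]]))
      if (max(abs(a - affine)) > 1e-4) {
        stop("affine mismatch (beyond 1e-4): ", paths[k],
             "; volumes must be spatially aligned")
      }
    }
    dims <- dim(first)
    dat <- array(0, c(length(imgs), dims))
    for (k in seq_along(imgs)) dat[k, , , ] <- as.numeric(imgs[[k]])
  }
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- RNifti::readNifti(mask_path)
    if (!identical(as.integer(dim(m)), as.integer(dim(dat)[2:4]))) {
      stop("mask dimensions do not match the volumes")
    }
    a <- unclass(RNifti::xform(m))
    if (max(abs(a - affine)) > 1e-4) {
      stop("mask affine does not match the volumes (beyond 1e-4)")
    }
    mask <- array(as.numeric(m) != 0, dim(m))
  }
  brain_image_set(dat, affine, mask, subject_id)
}

#' Write a brain image set (and optionally its mask) to NIfTI
#'
#' @param images a [brain_image_set()].
#' @param path output path for the 4-D volume (subjects along dimension 4).
#' @param mask_path optional output path for the mask volume.
#' @return invisible `path`.
#' @export
write_brain_images <- function(images, path, mask_path = NULL) {
  stopifnot(inherits(images, "brain_image_set"))
  vol <- aperm(images$data, c(2, 3, 4, 1))
  RNifti::writeNifti(set_affine(RNifti::asNifti(vol), images$affine), path)
  if (!is.null(mask_path)) {
    m <- RNifti::asNifti(array(as.numeric(images$mask), dim(images$mask)))
    RNifti::writeNifti(set_affine(m, images$affine), mask_path)
  }
  invisible(path)
}

# Stamp a 4x4 affine onto a NIfTI image as both qform and sform.  The voxel
# sizes must be written to pixdim before the quaternion assignment, otherwise
# the scale component of the transform is silently dropped.
set_affine <- function(nii, affine) {
  pd <- RNifti::pixdim(nii)
  pd[1:3] <- sqrt(colSums(affine[1:3, 1:3]^2))
  RNifti::pixdim(nii) <- pd
  RNifti::qform(nii) <- structure(affine, code = 2L)
  RNifti::sform(nii) <- structure(affine, code = 2L)
  nii
}

#' Write statistic maps from a voxelwise analysis to NIfTI
#'
#' One 3-D image per requested statistic; voxels outside the analysis mask
#' (and voxels that failed to fit) are written as 0.
#'
#' @param result a `voxel_map_result` from [run_voxelwise()].
#' @param dir output directory.
#' @param what statistics to write, subset of
#'   `c("estimate", "se", "z", "p")`.
#' @return invisible named vector of file paths.
#' @export
write_voxel_maps <- function(result, dir,
                             what = c("estimate", "se", "z", "p")) {
  stopifnot(inherits(result, "voxel_map_result"))
  what <- match.arg(what, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  for (w in what) {
    vol <- result[[w]]
    vol[is.na(vol)] <- 0
    nii <- set_affine(RNifti::asNifti(vol), result$affine)
    p <- file.path(dir, paste0(w, "_map.nii.gz"))
    RNifti::writeNifti(nii, p)
    out[w] <- p
  }
  invisible(out)
}
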