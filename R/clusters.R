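#' Label connected components of a 3-D binary volume
#'
#' Breadth-first 3-D connected-component labeling under 6-, 18- or
#' 26-neighbour connectivity. Labels are assigned in raster order of each
#' component's first voxel and start at 1; background is 0.
#'
#' @param vol logical (or 0/1 numeric) 3-D array.
#' @param connectivity 6 (faces), 18 (faces + edges) or 26 (faces + edges +
#'   corners).
#' @return integer array of the same shape holding component labels.
#' @export
label_components <- function(vol, connectivity = 26) {
  if (!connectivity %in% c(6, 18, 26)) {
    stop("connectivity must be 6, 18 or 26")
  }
  dims <- dim(vol)
  if (length(dims) != 3L) stop("vol must be a 3-D array")
  lab <- cpp_label_components(as.logical(vol), as.integer(dims),
                              as.integer(connectivity))
  array(lab, dims)
}

#' Voxel-to-world coordinate transform
#'
#' Applies a 4 x 4 voxel-to-world affine to voxel coordinates given in the
#' affine's own convention (NIfTI affines address 0-based voxel indices, so
#' R array index `[i, j, k]` is voxel `(i-1, j-1, k-1)`).
#'
#' @param ijk matrix (or vector) of voxel coordinates, one row per voxel.
#' @param affine 4 x 4 affine matrix; must be invertible.
#' @return matrix of world coordinates, one row per voxel.
#' @export
world_coordinates <- function(ijk, affine) {
  if (!identical(dim(affine), c(4L, 4L))) stop("affine must be 4 x 4")
  if (abs(det(affine)) < 1e-12) stop("affine is singular")
  ijk <- matrix(ijk, ncol = 3)
  out <- cbind(ijk, 1) %*% t(affine)
  out[, 1:3, drop = FALSE]
}

#' Cluster-extent thresholding of a voxelwise statistic map
#'
#' Implements the conventional two-stage mass-univariate correction: voxels
#' are first screened at an uncorrected per-voxel p threshold, then the
#' surviving voxels are grouped into connected components and only
#' components with strictly more than `k_min` voxels are kept. Positive and
#' negative effects are clustered separately so a cluster never mixes
#' signs. Defaults follow common practice for this design: p < 0.001
#' two-sided with an extent of more than 100 voxels under 26-neighbour
#' connectivity.
#'
#' @param result a `voxel_map_result` from [run_voxelwise()], or a list with
#'   3-D arrays `z` and `p` plus `affine` (and optionally `estimate`).
#' @param p_threshold uncorrected per-voxel threshold; a voxel survives when
#'   `p < p_threshold` (strict).
#' @param k_min extent threshold; a cluster is reported when its size is
#'   strictly greater than `k_min` voxels.
#' @param connectivity neighbourhood definition: 6, 18 or 26.
#' @return object of class `cluster_table`: a data frame with one row per
#'   cluster (`cluster`, `sign`, `n_voxels`, peak voxel indices
#'   `peak_i/j/k`, world-space `peak_x/y/z`, `peak_z_stat`, `peak_p`),
#'   sorted by decreasing size, with the label array, the thresholds and
#'   the connectivity attached as attributes.
#' @export
threshold_clusters <- function(result, p_threshold = 0.001, k_min = 100,
                               connectivity = 26) {
  z <- result$z; p <- result$p; affine <- result$affine
  if (is.null(z) || is.null(p)) stop("result must carry z and p maps")
  if (is.null(affine)) affine <- diag(4)
  dims <- dim(z)
  rows <- list()
  labels <- array(0L, dims)
  n_found <- 0L
  for (sgn in c(1, -1)) {
    supra <- !is.na(p) & p < p_threshold & sign(z) == sgn
    if (!any(supra)) next
    lab <- label_components(supra, connectivity)
    sizes <- tabulate(lab)
    for (l in which(sizes > k_min)) {
      vox <- which(lab == l)
      peak <- vox[which.max(abs(z[vox]))]
      pk <- arrayInd(peak, dims)
      xyz <- world_coordinates(pk - 1, affine)  # NIfTI voxels are 0-based
      n_found <- n_found + 1L
      labels[vox] <- n_found
      rows[[n_found]] <- data.frame(
        sign = if (sgn > 0) "positive" else "negative",
        n_voxels = sizes[l],
        peak_i = pk[1], peak_j = pk[2], peak_k = pk[3],
        peak_x = xyz[1], peak_y = xyz[2], peak_z = xyz[3],
        peak_z_stat = z[peak], peak_p = p[peak])
    }
  }
  if (n_found == 0L) {
    tab <- data.frame(cluster = integer(0), sign = character(0),
                      n_voxels = integer(0),
                      peak_i = integer(0), peak_j = integer(0),
                      peak_k = integer(0),
                      peak_x = numeric(0), peak_y = numeric(0),
                      peak_z = numeric(0),
                      peak_z_stat = numeric(0), peak_p = numeric(0))
  } else {
    tab <- do.call(rbind, rows)
    ord <- order(-tab$n_voxels, -abs(tab$peak_z_stat))
    relabel <- array(0L, dim(labels))
    for (new in seq_along(ord)) relabel[labels == ord[new]] <- new
    labels <- relabel
    tab <- tab[ord, , drop = FALSE]
    tab <- cbind(cluster = seq_len(nrow(tab)), tab)
    rownames(tab) <- NULL
  }
  structure(tab, class = c("cluster_table", "data.frame"),
            labels = labels, p_threshold = p_threshold, k_min = k_min,
            connectivity = connectivity)
}

#' @export
print.cluster_table <- function(x, ...) {
  cat(sprintf("<cluster_table> %d cluster(s) at p < %g, k > %d, %d-connectivity\n",
              nrow(x), attr(x, "p_threshold"), attr(x, "k_min"),
              attr(x, "connectivity")))
  if (nrow(x)) print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Write a cluster table as CSV
#'
#' Fixed column order and `NA` coding so identical analyses produce
#' byte-identical files.
#'
#' @param clusters a `cluster_table` from [threshold_clusters()].
#' @param path output file.
#' @return invisible `path`.
#' @export
write_cluster_table <- function(clusters, path) {
  df <- as.data.frame(clusters)
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  for (cn in names(df)[num]) df[[cn]] <- sprintf("%.10g", df[[cn]])
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Dice overlap between a cluster and a reference mask
#'
#' @param labels integer label array (e.g. `attr(clusters, "labels")`).
#' @param which_label label value of the cluster of interest.
#' @param reference logical array of the reference region.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(labels, which_label, reference) {
  a <- labels == which_label
  b <- as.logical(reference)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(NA_real_)
  2 * sum(a & b) / denom
}
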