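#' Centroid of a mask in physical coordinates
#'
#' Unweighted mean of the foreground voxel centres, in mm.
#'
#' @param mask a non-empty `mask_volume`.
#' @return numeric length-3 (mm).
#' @export
mask_centroid <- function(mask) {
  idx <- which(mask$data != 0L, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("cannot take the centroid of an empty mask")
  unname(colMeans(voxel_coords(idx, mask$spacing, mask$origin)))
}

#' Principal axes of a mask
#'
#' Directions are the eigenvectors of the covariance of the foreground voxel
#' centres (physical mm); the length of each axis is the extent
#' (max - min) of the foreground projected onto that direction. Axes are
#' ordered major >= intermediate >= minor by extent.
#'
#' @param mask a `mask_volume` with at least 3 non-collinear foreground
#'   voxels.
#' @return An `axis_set`: `lengths` (named, mm), `directions` (3x3, columns
#'   are unit vectors), `aspect_major_minor`, `aspect_major_intermediate`.
#' @export
principal_axes <- function(mask) {
  idx <- which(mask$data != 0L, arr.ind = TRUE)
  if (nrow(idx) < 3) stop("principal axes need at least 3 foreground voxels")
  xyz <- voxel_coords(idx, mask$spacing, mask$origin)
  cen <- sweep(xyz, 2, colMeans(xyz))
  if (qr(cen)$rank < 2) stop("degenerate (collinear) mask")
  eg <- eigen(stats::cov(cen), symmetric = TRUE)
  proj <- cen %*% eg$vectors
  len <- apply(proj, 2, function(p) diff(range(p)))
  ord <- order(len, decreasing = TRUE)
  len <- len[ord]
  dirs <- eg$vectors[, ord, drop = FALSE]
  names(len) <- c("major", "intermediate", "minor")
  structure(list(lengths = len, directions = dirs,
                 aspect_major_minor = len[["major"]] / len[["minor"]],
                 aspect_major_intermediate = len[["major"]] / len[["intermediate"]]),
            class = "axis_set")
}

#' Partition a mask into equal-thickness axial slabs
#'
#' The axial slices containing foreground are split into `n` consecutive
#' runs of near-equal count; when the count is not divisible, the extra
#' slices go to the *lower* slabs (e.g., 10 slices -> 3,3,2,2 bottom to
#' top). Label 1 (PQ1) is the lowermost slab, label `n` (PQ4) the uppermost.
#'
#' @param mask a non-empty `mask_volume`.
#' @param n number of slabs.
#' @return A `mask_volume` labelled 1..n on the foreground (scheme attribute
#'   `"slab"`).
#' @export
partition_axial_slabs <- function(mask, n = 4) {
  fg_any <- apply(mask$data != 0L, 3, any)
  slices <- which(fg_any)
  s <- length(slices)
  if (s == 0) stop("cannot partition an empty mask")
  if (s < n) stop(sprintf("only %d foreground slices for %d slabs", s, n))
  base <- s %/% n; extra <- s %% n
  sizes <- base + as.integer(seq_len(n) <= extra)
  slab_of <- rep(seq_len(n), times = sizes)  # slices sorted bottom-up
  lab_by_slice <- integer(dim(mask$data)[3])
  lab_by_slice[slices] <- slab_of
  lab <- array(0L, dim(mask$data))
  fg <- which(mask$data != 0L, arr.ind = TRUE)
  lab[mask$data != 0L] <- lab_by_slice[fg[, 3]]
  out <- mask_volume(lab, mask$spacing, mask$origin)
  attr(out, "scheme") <- "slab"
  attr(out, "slab_sizes") <- sizes
  out
}

#' Euclidean distance to the mask exterior
#'
#' For every foreground voxel, the anisotropy-aware Euclidean distance (mm)
#' to the nearest background voxel centre; 0 on the background.
#'
#' @param mask a `mask_volume`.
#' @return numeric array of distances (mm), same shape as the mask.
#' @export
exterior_distance <- function(mask) {
  d <- dim(mask$data)
  .edt_anisotropic(array(as.integer(mask$data != 0L), d), as.integer(d),
                   mask$spacing)
}

#' Partition the sac into equidistant shells
#'
#' Computes the distance `d` of every sac voxel to the sac exterior and, with
#' `D = max(d)`, assigns shell `k` to voxels with
#' `d` in `((k-1) D/n, k D/n]`; a voxel exactly on a band edge goes to the
#' outer shell of the pair. Label 1 (SH1) is the outermost ribbon, label `n`
#' (SH4) the innermost core.
#'
#' @param sac a non-empty `mask_volume`.
#' @param n number of shells.
#' @return A `mask_volume` labelled 1..n (scheme attribute `"shell"`).
#' @export
partition_shells <- function(sac, n = 4) {
  if (!any(sac$data != 0L)) stop("cannot partition an empty sac")
  d <- exterior_distance(sac)
  fg <- sac$data != 0L
  D <- max(d[fg])
  width <- D / n
  lab <- array(0L, dim(sac$data))
  k <- ceiling(d[fg] / width)
  k[k < 1L] <- 1L; k[k > n] <- as.integer(n)
  lab[fg] <- as.integer(k)
  out <- mask_volume(lab, sac$spacing, sac$origin)
  attr(out, "scheme") <- "shell"
  attr(out, "max_depth_mm") <- D
  out
}

# binary sub-mask of one label of a region map, intersected with a parent
# mask (e.g., EAT within slab PQ2)
region_submask <- function(labels, label, parent = NULL) {
  sel <- labels$data == as.integer(label)
  if (!is.null(parent)) sel <- sel & (parent$data != 0L)
  mask_volume(array(as.integer(sel), dim(labels$data)),
              labels$spacing, labels$origin)
}
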