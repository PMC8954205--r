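#' Crop box (half-open, 0-based voxel indices)
#'
#' @param start,stop integer length-3; `start < stop` per axis.
#' @return a `crop_box` list.
#' @export
crop_box <- function(start, stop) {
  start <- as.integer(start); stop <- as.integer(stop)
  stopifnot(length(start) == 3, length(stop) == 3,
            all(start >= 0), all(start < stop))
  structure(list(start = start, stop = stop), class = "crop_box")
}

#' Axial slab covering the limbic system
#'
#' Computes the tightest axial slab (full in-plane extent) containing every
#' voxel of the listed atlas regions, optionally widened by `margin` slices
#' and clipped to the volume — mirroring slab-of-slices cropping around the
#' limbic area.
#'
#' @param atlas a `limbic_atlas`.
#' @param regions region names; defaults to the four limbic structures.
#' @param margin extra axial slices on each side (>= 0).
#' @return a [crop_box()].
#' @export
limbic_crop_box <- function(atlas,
                            regions = c("hippocampus", "amygdala",
                                        "thalamus", "putamen"),
                            margin = 0L) {
  stopifnot(margin >= 0)
  labs <- match_regions(atlas, regions)
  sel <- array(atlas$labels %in% labs, atlas$dims)
  zhit <- which(apply(sel, 3, any))
  if (!length(zhit)) {
    empty <- regions[vapply(regions, function(r)
      !any(atlas$labels %in% match_regions(atlas, r)), logical(1))]
    stop(sprintf("region '%s' has no voxels in the atlas", empty[1]))
  }
  z0 <- max(0L, min(zhit) - 1L - as.integer(margin))
  z1 <- min(atlas$dims[3], max(zhit) + as.integer(margin))
  crop_box(c(0L, 0L, z0), c(atlas$dims[1], atlas$dims[2], z1))
}

#' Crop a volume to a box
#'
#' @param vol 3-D volume.
#' @param box a [crop_box()] within the volume.
#' @return list with `volume` (the sub-volume) and `box` (echoed for
#'   coordinate back-mapping).
#' @export
crop_volume <- function(vol, box) {
  stop_if_not_volume(vol)
  d <- dim(vol)
  if (any(box$stop > d)) stop("crop box exceeds volume dimensions")
  out <- vol[(box$start[1] + 1):box$stop[1],
             (box$start[2] + 1):box$stop[2],
             (box$start[3] + 1):box$stop[3], drop = FALSE]
  attr(out, "voxel_size") <- attr(vol, "voxel_size")
  list(volume = out, box = box)
}

#' Embed a cropped volume back into a full grid
#'
#' Places `vol` at `box$start` inside a zero volume of dimension `dims`;
#' the exact inverse of [crop_volume()] inside the box.
#'
#' @param vol cropped volume whose dims equal `box$stop - box$start`.
#' @param box the [crop_box()] it was cut with.
#' @param dims full-volume dimensions.
#' @export
embed_volume <- function(vol, box, dims) {
  stop_if_not_volume(vol)
  stopifnot(all(dim(vol) == box$stop - box$start), all(box$stop <= dims))
  out <- array(0, dims)
  out[(box$start[1] + 1):box$stop[1],
      (box$start[2] + 1):box$stop[2],
      (box$start[3] + 1):box$stop[3]] <- vol
  out
}

#' Trilinear resampling to a network input shape
#'
#' @param vol 3-D volume.
#' @param newdims target dimensions.
#' @return resampled volume.
#' @export
resample_volume <- function(vol, newdims) {
  stop_if_not_volume(vol)
  newdims <- as.integer(newdims)
  if (all(dim(vol) == newdims)) return(vol)
  array(cpp_resample3d(as.numeric(vol), dim(vol), newdims), newdims)
}
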