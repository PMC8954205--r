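#' Synthetic anatomical atlas
#'
#' Builds a geometric stand-in for an anatomical labelling atlas: an
#' ellipsoidal brain shell ("cortex") containing disjoint ellipsoidal
#' subregions for the cortical and limbic structures implicated in
#' Alzheimer-type hypometabolism. Lateralised structures get `_left` /
#' `_right` labels placed mirror-symmetrically about the mid-sagittal plane.
#'
#' The limbic structures (hippocampus, amygdala, thalamus, putamen) sit in a
#' mid-axial band so that an axial slab crop around them is a proper
#' sub-volume; the middle frontal gyri sit in higher slices.
#'
#' @param dims integer length-3, volume dimensions (x = left-right,
#'   y = posterior-anterior, z = inferior-superior). Each must be >= 16.
#' @return An object of class `limbic_atlas`: a list with `labels` (3-D
#'   integer array, 0 = background), `region_names` (named character vector
#'   keyed by label) and `dims`.
#' @examples
#' atl <- build_atlas(c(32, 32, 20))
#' table(atl$labels)[1:3]
#' @export
build_atlas <- function(dims = c(64, 64, 40)) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3)
  if (any(dims[1:2] < 16) || dims[3] < 12)
    stop("atlas dims too small: need >= 16 in-plane voxels and >= 12 slices")

  spec <- atlas_region_spec()
  labels <- array(0L, dims)

  fx <- (seq_len(dims[1]) - 0.5) / dims[1]
  fy <- (seq_len(dims[2]) - 0.5) / dims[2]
  fz <- (seq_len(dims[3]) - 0.5) / dims[3]
  X <- array(fx, dims)
  Y <- array(rep(fy, each = dims[1]), dims)
  Z <- array(rep(fz, each = dims[1] * dims[2]), dims)

  inside <- function(cx, cy, cz, rx, ry, rz)
    ((X - cx) / rx)^2 + ((Y - cy) / ry)^2 + ((Z - cz) / rz)^2 <= 1

  brain <- inside(0.5, 0.5, 0.5, 0.42, 0.46, 0.40)
  labels[brain] <- 1L
  region_names <- c("1" = "cortex")

  next_label <- 2L
  for (i in seq_len(nrow(spec))) {
    r <- spec[i, ]
    sides <- if (r$lateral) c(left = 0.5 - r$dx, right = 0.5 + r$dx) else c(bilateral = 0.5)
    for (s in seq_along(sides)) {
      nm <- if (r$lateral) paste0(r$name, "_", names(sides)[s]) else r$name
      vox <- inside(sides[[s]], r$cy, r$cz, r$rx, r$ry, r$rz) & labels == 1L
      grow <- 1
      while (sum(vox) < 8 && grow < 4) {
        # at coarse grids the nominal ellipsoid can cover < 8 voxels; grow it
        # (claiming unassigned cortex only, so regions stay disjoint)
        grow <- grow * 1.25
        vox <- inside(sides[[s]], r$cy, r$cz,
                      r$rx * grow, r$ry * grow, r$rz * grow) & labels == 1L
      }
      if (sum(vox) < 8)
        stop(sprintf("atlas dims too small: region '%s' has fewer than 8 voxels", nm))
      labels[vox] <- next_label
      region_names[as.character(next_label)] <- nm
      next_label <- next_label + 1L
    }
  }

  structure(list(labels = labels, region_names = region_names, dims = dims),
            class = "limbic_atlas")
}

# Fractional centres/radii of the ellipsoidal subregions (units of volume
# extent). Chosen so that ellipsoids are pairwise disjoint at dims >= 16 and
# the four limbic structures share a mid-axial band.
atlas_region_spec <- function() {
  data.frame(
    name = c("middle_frontal", "middle_temporal", "insula", "hippocampus",
             "amygdala", "thalamus", "putamen", "caudate"),
    lateral = TRUE,
    dx = c(0.20, 0.31, 0.165, 0.13, 0.115, 0.085, 0.24, 0.10),
    cy = c(0.72, 0.42, 0.56, 0.33, 0.62, 0.42, 0.57, 0.64),
    cz = c(0.70, 0.38, 0.51, 0.45, 0.38, 0.55, 0.52, 0.60),
    rx = c(0.085, 0.065, 0.045, 0.055, 0.040, 0.050, 0.045, 0.040),
    ry = c(0.090, 0.110, 0.060, 0.080, 0.045, 0.065, 0.060, 0.055),
    rz = c(0.100, 0.080, 0.065, 0.055, 0.045, 0.060, 0.060, 0.055)
  )
}

#' @export
print.limbic_atlas <- function(x, ...) {
  cat("limbic_atlas:", paste(x$dims, collapse = " x "), "voxels,",
      length(x$region_names), "labelled regions\n")
  invisible(x)
}

#' Resolve region names to atlas labels
#'
#' A base name such as `"hippocampus"` matches both `hippocampus_left` and
#' `hippocampus_right`; fully qualified names match themselves.
#'
#' @param atlas a `limbic_atlas`.
#' @param regions character vector of region names (base or lateralised).
#' @return integer vector of atlas labels.
#' @export
match_regions <- function(atlas, regions) {
  out <- integer(0)
  for (r in regions) {
    hit <- which(atlas$region_names == r |
                 atlas$region_names == paste0(r, "_left") |
                 atlas$region_names == paste0(r, "_right"))
    if (length(hit) == 0)
      stop(sprintf("region '%s' not found in atlas", r))
    out <- c(out, as.integer(names(atlas$region_names)[hit]))
  }
  sort(unique(out))
}

#' Write / read an atlas (NIfTI labels + tab-separated label table)
#'
#' @param atlas a `limbic_atlas`.
#' @param path path of the label volume (`.nii.gz`); the side-car table is
#'   written next to it with suffix `_labels.tsv`.
#' @export
write_atlas <- function(atlas, path) {
  write_volume(array(as.numeric(atlas$labels), atlas$dims), path)
  tab <- data.frame(label = as.integer(names(atlas$region_names)),
                    name = unname(atlas$region_names))
  write.table(tab, sidecar_path(path), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  vol <- read_volume(path)
  tab <- read.delim(sidecar_path(path), stringsAsFactors = FALSE)
  rn <- stats::setNames(as.character(tab$name), as.character(tab$label))
  structure(list(labels = array(as.integer(round(vol)), dim(vol)),
                 region_names = rn, dims = dim(vol)),
            class = "limbic_atlas")
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", "_labels.tsv", path)
}

#' Brain mask of an atlas
#' @param atlas a `limbic_atlas`.
#' @return logical 3-D array, `TRUE` inside the brain (any nonzero label).
#' @export
brain_mask <- function(atlas) atlas$labels > 0L
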