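#' Scanner profile for synthetic degradation
#'
#' Captures the inter-scanner variability that matters for the degradation
#' model: in-plane blur width, relative noise level and axial slice count.
#'
#' @param name profile name.
#' @param blur_sigma Gaussian PSF width in voxels (>= 0).
#' @param noise_sd additive-noise standard deviation as a fraction of the
#'   mean in-brain intensity (>= 0).
#' @param n_slices axial slice count the scanner delivers.
#' @return a `scanner_profile` list.
#' @export
scanner_profile <- function(name, blur_sigma, noise_sd, n_slices) {
  stopifnot(blur_sigma >= 0, noise_sd >= 0, n_slices >= 1)
  structure(list(name = name, blur_sigma = blur_sigma,
                 noise_sd = noise_sd, n_slices = as.integer(n_slices)),
            class = "scanner_profile")
}

# Three profiles spanning the range of axial sampling and noise seen across
# clinical PET scanner generations (high-resolution research tomograph down
# to older BGO block scanners), rescaled to the phantom grid.
default_scanner_profiles <- function(dim3 = 40L) {
  list(
    scanner_profile("hires",  blur_sigma = 1.0, noise_sd = 0.05, n_slices = dim3),
    scanner_profile("mid",    blur_sigma = 1.5, noise_sd = 0.08, n_slices = as.integer(round(dim3 * 0.8))),
    scanner_profile("legacy", blur_sigma = 2.0, noise_sd = 0.12, n_slices = as.integer(round(dim3 * 0.6)))
  )
}

#' Cohort specification for the phantom generator
#'
#' @param n_control,n_ad class sizes.
#' @param effect_map named numeric vector: fractional intensity reduction in
#'   `[0, 1)` applied to each region for the AD class (base names such as
#'   `"hippocampus"` address both hemispheres).
#' @param scanner_profiles list of [scanner_profile()] objects.
#' @param scanner_weights sampling weights, one per profile.
#' @param dims phantom dimensions.
#' @param seed master seed; everything the generator draws flows from it.
#' @param noise_model `"gaussian"` (additive, intensity-scaled; default) or
#'   `"poisson"` (scale to expected counts, draw, rescale).
#' @param counts_scale expected counts per intensity unit for the Poisson
#'   model.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_control, n_ad,
                        effect_map = c(hippocampus = 0.25, middle_temporal = 0.25),
                        scanner_profiles = default_scanner_profiles(dims[3]),
                        scanner_weights = rep(1, length(scanner_profiles)),
                        dims = c(64, 64, 40),
                        seed = 1L,
                        noise_model = c("gaussian", "poisson"),
                        counts_scale = 100) {
  stopifnot(n_control >= 1, n_ad >= 1,
            all(effect_map >= 0), all(effect_map < 1),
            length(scanner_weights) == length(scanner_profiles))
  structure(list(n_control = as.integer(n_control), n_ad = as.integer(n_ad),
                 effect_map = effect_map,
                 scanner_profiles = scanner_profiles,
                 scanner_weights = scanner_weights,
                 dims = as.integer(dims), seed = as.integer(seed),
                 noise_model = match.arg(noise_model),
                 counts_scale = counts_scale),
            class = "cohort_spec")
}

#' Benchmark cohort: the study conditions used throughout the package
#'
#' Sixty subjects (30 per class), 64 x 64 x 40 voxels, 25% hypometabolism in
#' hippocampus and middle temporal gyrus for the AD class, one scanner with
#' a sigma = 2 voxel PSF and 10% additive noise at full axial sampling.
#'
#' @param seed master seed.
#' @param n_control,n_ad class sizes.
#' @return a `cohort_spec`.
#' @export
benchmark_cohort_spec <- function(seed = 1L, n_control = 30L, n_ad = 30L) {
  cohort_spec(
    n_control = n_control, n_ad = n_ad,
    effect_map = c(hippocampus = 0.25, middle_temporal = 0.25),
    scanner_profiles = list(scanner_profile("bench", blur_sigma = 2,
                                            noise_sd = 0.10, n_slices = 40L)),
    dims = c(64, 64, 40), seed = seed)
}

# Mean activity per region in arbitrary units. Cortical/subcortical grey is
# hot relative to the (zero) background; subcortical nuclei slightly hotter
# than the cortical shell, as in FDG uptake patterns.
default_region_means <- function() {
  c(cortex = 1.0, middle_frontal = 1.10, middle_temporal = 1.10,
    insula = 1.15, hippocampus = 1.20, amygdala = 1.15,
    thalamus = 1.25, putamen = 1.30, caudate = 1.25)
}

#' Generate one clean phantom volume
#'
#' Each atlas region receives its baseline mean intensity times a per-subject
#' log-normal factor (5% coefficient of variation per region), and, for the
#' AD class, regions named in `effect_map` are scaled by `1 - effect`.
#' Background stays at zero. Uses the current RNG state.
#'
#' @param atlas a `limbic_atlas`.
#' @param label `"control"` or `"ad"`.
#' @param effect_map named fractional reductions (see [cohort_spec()]).
#' @param region_means named baseline means keyed by base region name.
#' @param subject_cv per-region per-subject coefficient of variation.
#' @return 3-D intensity array with a `voxel_size` attribute.
#' @export
make_phantom <- function(atlas, label = c("control", "ad"),
                         effect_map = numeric(0),
                         region_means = default_region_means(),
                         subject_cv = 0.05) {
  label <- match.arg(label)
  if (length(effect_map)) {
    bad <- setdiff(names(effect_map), names(region_means))
    for (b in bad) match_regions(atlas, b)  # errors if truly unknown
  }
  vol <- array(0, atlas$dims)
  sdlog <- sqrt(log(1 + subject_cv^2))
  for (lab in as.integer(names(atlas$region_names))) {
    nm <- atlas$region_names[[as.character(lab)]]
    base <- sub("_(left|right)$", "", nm)
    mu <- region_means[[base]] %||% 1.0
    if (label == "ad" && length(effect_map)) {
      eff <- if (base %in% names(effect_map)) effect_map[[base]]
             else if (nm %in% names(effect_map)) effect_map[[nm]] else 0
      mu <- mu * (1 - eff)
    }
    vol[atlas$labels == lab] <- mu * rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  attr(vol, "voxel_size") <- c(2, 2, 2)
  vol
}

#' Degrade a clean volume through a scanner profile
#'
#' The degradation model is slice-wise 2-D Gaussian blurring followed by
#' additive zero-mean Gaussian noise whose standard deviation is
#' `noise_sd` times the mean in-brain (nonzero) intensity of the clean
#' volume; negative intensities are clipped to zero, and the axial extent is
#' decimated to the profile's slice count by nearest-slice selection. A
#' Poisson alternative (scale to counts, draw, rescale) is available.
#'
#' @param clean 3-D clean volume.
#' @param profile a [scanner_profile()].
#' @param noise_model `"gaussian"` or `"poisson"`.
#' @param counts_scale expected counts per intensity unit (Poisson model).
#' @return degraded 3-D array, `profile$n_slices` axial slices.
#' @export
degrade_volume <- function(clean, profile, noise_model = "gaussian",
                           counts_scale = 100) {
  stop_if_not_volume(clean)
  d <- dim(clean)
  stopifnot(profile$n_slices <= d[3])
  out <- clean
  if (profile$blur_sigma > 0) {
    psf <- make_psf(profile$blur_sigma)
    for (z in seq_len(d[3]))
      out[, , z] <- cpp_conv2d_sym(out[, , z], psf$kernel)
  }
  if (profile$noise_sd > 0) {
    if (identical(noise_model, "poisson")) {
      lam <- pmax(out, 0) * counts_scale / profile$noise_sd^2
      out <- array(stats::rpois(length(lam), lam), d) * profile$noise_sd^2 / counts_scale
    } else {
      sdv <- profile$noise_sd * mean(clean[clean > 0])
      out <- out + array(rnorm(length(out), 0, sdv), d)
    }
  }
  out[out < 0] <- 0
  if (profile$n_slices < d[3]) {
    keep <- slice_decimation_index(d[3], profile$n_slices)
    out <- out[, , keep, drop = FALSE]
  }
  attr(out, "voxel_size") <- attr(clean, "voxel_size")
  out
}

# Evenly spaced nearest-slice decimation indices (invertible by nearest
# re-expansion in expand_slices()).
slice_decimation_index <- function(d3, n_slices) {
  round(seq(1, d3, length.out = n_slices))
}

#' Re-expand a slice-decimated volume to a target axial extent
#'
#' Nearest-slice inverse of the decimation in [degrade_volume()]; restores
#' voxel alignment with the atlas grid.
#'
#' @param vol degraded volume.
#' @param d3 target axial extent.
#' @return volume with `d3` axial slices.
#' @export
expand_slices <- function(vol, d3) {
  n <- dim(vol)[3]
  if (n == d3) return(vol)
  kept <- slice_decimation_index(d3, n)
  nearest <- vapply(seq_len(d3), function(z) which.min(abs(kept - z)), integer(1))
  out <- vol[, , nearest, drop = FALSE]
  attr(out, "voxel_size") <- attr(vol, "voxel_size")
  out
}

#' Generate a full cohort on disk
#'
#' Draws every subject of a [cohort_spec()] (clean phantom, scanner
#' assignment, degradation), writes one NIfTI volume per subject plus the
#' atlas, and a tab-separated manifest `manifest.tsv` with columns
#' `id`, `label`, `volume`, `scanner`. Fully reproducible from `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir output directory (created if needed).
#' @param atlas optional pre-built atlas; defaults to `build_atlas(spec$dims)`.
#' @return the manifest as a data.frame (invisibly also written to disk).
#' @export
generate_cohort <- function(spec, out_dir, atlas = build_atlas(spec$dims)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- spec$n_control + spec$n_ad
  labels <- rep(c("control", "ad"), c(spec$n_control, spec$n_ad))
  rows <- with_seed(spec$seed, {
    prof_idx <- sample.int(length(spec$scanner_profiles), n, replace = TRUE,
                           prob = spec$scanner_weights)
    lapply(seq_len(n), function(i) {
      prof <- spec$scanner_profiles[[prof_idx[i]]]
      clean <- make_phantom(atlas, labels[i], spec$effect_map)
      deg <- degrade_volume(clean, prof, spec$noise_model, spec$counts_scale)
      id <- sprintf("sub%03d", i)
      path <- file.path(out_dir, paste0(id, ".nii.gz"))
      write_volume(deg, path)
      data.frame(id = id, label = labels[i], volume = path,
                 scanner = prof$name, stringsAsFactors = FALSE)
    })
  })
  manifest <- do.call(rbind, rows)
  write.table(manifest, file.path(out_dir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_atlas(atlas, file.path(out_dir, "atlas.nii.gz"))
  manifest
}

#' Read a cohort manifest
#' @param path directory containing `manifest.tsv` or the file itself.
#' @return data.frame with columns id, label, volume, scanner.
#' @export
read_manifest <- function(path) {
  f <- if (dir.exists(path)) file.path(path, "manifest.tsv") else path
  read.delim(f, stringsAsFactors = FALSE)
}
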