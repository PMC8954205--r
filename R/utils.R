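#' @useDynLib limbicnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rlnorm median sd var fft
#' @importFrom utils write.table read.delim modifyList
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a stream seed from a master seed; keeps results < 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + offset * 7919) %% 2147483629)
}

#' Peak signal-to-noise ratio against a reference image
#'
#' @param x image (matrix or array) to score.
#' @param ref reference of the same shape.
#' @param peak dynamic range; defaults to the reference maximum.
#' @return PSNR in dB (`Inf` when `x == ref`).
#' @export
psnr <- function(x, ref, peak = max(ref)) {
  stopifnot(length(x) == length(ref))
  mse <- mean((as.numeric(x) - as.numeric(ref))^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

stop_if_not_volume <- function(x, what = "volume") {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop(sprintf("`%s` must be a 3-D array", what), call. = FALSE)
}

#' Read / write volumes as NIfTI-1
#'
#' Thin wrappers over RNifti that carry the voxel size (mm) in the header.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param vol 3-D array of intensities.
#' @param voxel_size numeric length-3, voxel edge lengths in mm.
#' @return `read_volume` returns a plain 3-D array with a `voxel_size`
#'   attribute; `write_volume` returns `path` invisibly.
#' @export
write_volume <- function(vol, path, voxel_size = attr(vol, "voxel_size") %||% c(2, 2, 2)) {
  stop_if_not_volume(vol)
  img <- RNifti::asNifti(array(as.numeric(vol), dim(vol)))
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim(img)[1:3])
  attr(out, "voxel_size") <- RNifti::pixdim(img)[1:3]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
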