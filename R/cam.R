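#' Class activation map for one volume
#'
#' Collapses the two fully connected layers after global average pooling
#' into an effective per-channel weight vector for the requested class (the
#' head is affine, so the collapse `W_fc128 %*% W_fc2` is exact), takes the
#' weighted sum of the final convolutional feature maps, and trilinearly
#' upsamples to the network input grid. Because the post-GAP head is linear,
#' gradient weighting (`method = "gradcam"`) yields the same channel weights
#' up to the constant GAP factor; both are exposed.
#'
#' @param trained a `limbicnet_trained` model.
#' @param volume 3-D array conforming to the model input shape.
#' @param class_index 1 = control, 2 = AD (default).
#' @param crop_box optional [crop_box()] recording where the input sits in
#'   the whole-volume grid.
#' @param method `"cam"` or `"gradcam"`.
#' @return an `activation_map`: list with `weights` (3-D array at input
#'   dims), `class_index`, `crop_box`.
#' @export
cam <- function(trained, volume, class_index = 2L, crop_box = NULL,
                method = c("cam", "gradcam")) {
  method <- match.arg(method)
  model <- trained$model
  if (!all(dim(volume) == model$config$input_shape))
    stop("volume does not conform to the model input shape")
  fw <- nn_forward(model, list(volume), training = FALSE)
  feat <- fw$features[[1]]                     # [nvox, C]
  w_eff <- (model$params$fc1_W %*% model$params$fc2_W)[, class_index]
  if (method == "gradcam") w_eff <- w_eff / prod(fw$feature_dims)
  map <- array(as.numeric(feat %*% w_eff), fw$feature_dims)
  up <- array(cpp_resample3d(as.numeric(map), fw$feature_dims,
                             model$config$input_shape),
              model$config$input_shape)
  structure(list(weights = up, class_index = as.integer(class_index),
                 crop_box = crop_box),
            class = "activation_map")
}

#' Voxel-wise average of activation maps
#'
#' @param maps list of `activation_map` objects with identical dims and
#'   crop boxes.
#' @return an `activation_map`.
#' @export
average_maps <- function(maps) {
  stopifnot(length(maps) >= 1)
  d <- dim(maps[[1]]$weights)
  for (m in maps) {
    if (!all(dim(m$weights) == d)) stop("activation maps have mixed dims")
    if (!identical(m$crop_box, maps[[1]]$crop_box))
      stop("activation maps have mixed crop boxes")
  }
  acc <- Reduce(`+`, lapply(maps, `[[`, "weights")) / length(maps)
  structure(list(weights = acc, class_index = maps[[1]]$class_index,
                 crop_box = maps[[1]]$crop_box),
            class = "activation_map")
}

# Map an activation map to the whole-volume grid: embed at the crop offset
# (zero elsewhere) and resample to the atlas dims if needed.
map_to_grid <- function(map, dims) {
  w <- map$weights
  if (!is.null(map$crop_box)) {
    box <- map$crop_box
    span <- box$stop - box$start
    if (!all(dim(w) == span))
      w <- array(cpp_resample3d(as.numeric(w), dim(w), span), span)
    w <- embed_volume(w, box, dims)
  } else if (!all(dim(w) == dims)) {
    w <- array(cpp_resample3d(as.numeric(w), dim(w), dims), dims)
  }
  w
}

#' Per-region importance summary of an activation map
#'
#' Embeds the map into the atlas grid through its crop box, keeps the
#' positive part (evidence for the mapped class), and reports the mean
#' positive weight per region (descending ranking) plus the fraction of
#' total positive weight lying outside the brain mask. An all-zero map
#' yields an empty ranking and a non-brain fraction of 0.
#'
#' @param map an `activation_map`.
#' @param atlas a `limbic_atlas` on the whole-volume grid.
#' @param mask optional logical brain mask; defaults to [brain_mask()].
#' @return a `region_importance`: list with `table` (region, mean_weight,
#'   rank), `non_brain_fraction`, `ranking`.
#' @export
region_importance <- function(map, atlas, mask = brain_mask(atlas)) {
  w <- map_to_grid(map, atlas$dims)
  pos <- pmax(w, 0)
  tot <- sum(pos)
  nbf <- if (tot == 0) 0 else sum(pos[!mask]) / tot
  rows <- lapply(names(atlas$region_names), function(lab) {
    sel <- atlas$labels == as.integer(lab)
    n <- sum(sel)
    data.frame(region = atlas$region_names[[lab]],
               mean_weight = if (n == 0) NA_real_ else mean(pos[sel]),
               n_voxels = n, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[!is.na(tab$mean_weight), , drop = FALSE]
  if (tot == 0) tab <- tab[tab$mean_weight > 0, , drop = FALSE]
  tab <- tab[order(-tab$mean_weight), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(table = tab, non_brain_fraction = nbf,
                 ranking = tab$region),
            class = "region_importance")
}

#' Write an activation map as NIfTI on the whole-volume grid
#' @param map an `activation_map`.
#' @param atlas atlas defining the whole grid.
#' @param path output path.
#' @export
write_activation_map <- function(map, atlas, path) {
  write_volume(map_to_grid(map, atlas$dims), path)
}
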