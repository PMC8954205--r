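#' Model configuration for the 3D residual CNN
#'
#' Architecture: 7x7x7 stride-2 conv (pad 3) + BN + ReLU; 3x3x3 stride-2
#' max pool (pad 1); residual stage 1 (3x3x3 conv + BN, identity skip);
#' residual stage 2 (3x3x3 stride-2 conv + BN, 1x1x1 stride-2 projection
#' branch with BN); global average pooling; fully connected 128; fully
#' connected 2; softmax. Trained with cross-entropy and Adam.
#'
#' @param input_shape spatial input dimensions (3 integers).
#' @param base_channels channels of the stem convolution (64 in the
#'   reference architecture).
#' @param stage_channels channels of the two residual stages (64, 128).
#' @param fc_width width of the penultimate fully connected layer.
#' @param lr initial Adam learning rate.
#' @param batch_size mini-batch size.
#' @param epochs training epochs.
#' @param seed seed controlling weight init and shuffling.
#' @return a `model_config` list.
#' @export
model_config <- function(input_shape = c(128, 128, 79),
                         base_channels = 64L,
                         stage_channels = c(64L, 128L),
                         fc_width = 128L,
                         lr = 1e-4, batch_size = 4L, epochs = 20L,
                         seed = 1L) {
  stopifnot(length(input_shape) == 3, all(input_shape >= 1),
            base_channels >= 1, length(stage_channels) == 2,
            lr >= 0, batch_size >= 1, epochs >= 1)
  structure(list(input_shape = as.integer(input_shape),
                 base_channels = as.integer(base_channels),
                 stage_channels = as.integer(stage_channels),
                 fc_width = as.integer(fc_width),
                 lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 loss = "cross_entropy", optimizer = "adam"),
            class = "model_config")
}

conv_out <- function(d, k, s, p) (d + 2L * p - k) %/% s + 1L

#' Symbolic layer-shape trace
#'
#' Computes the output dimensions of every layer from the convolution
#' arithmetic `floor((d + 2 pad - k) / stride) + 1`, erroring on the first
#' layer that would produce a non-positive dimension.
#'
#' @param cfg a [model_config()].
#' @return data.frame with columns `layer`, `d1`, `d2`, `d3`, `channels`.
#' @examples
#' layer_shapes(model_config(input_shape = c(128, 128, 79)))
#' @export
layer_shapes <- function(cfg) {
  d <- cfg$input_shape
  rows <- list(list("input", d, 1L))
  step <- function(nm, k, s, p, ch) {
    d <<- vapply(d, conv_out, integer(1), k = k, s = s, p = p)
    if (any(d < 1)) stop(sprintf("layer '%s' produces a non-positive dimension", nm))
    rows[[length(rows) + 1L]] <<- list(nm, d, ch)
  }
  step("conv1", 7L, 2L, 3L, cfg$base_channels)
  step("maxpool", 3L, 2L, 1L, cfg$base_channels)
  step("res_stage1", 3L, 1L, 1L, cfg$stage_channels[1])
  step("res_stage2", 3L, 2L, 1L, cfg$stage_channels[2])
  rows[[length(rows) + 1L]] <- list("gap", c(1L, 1L, 1L), cfg$stage_channels[2])
  rows[[length(rows) + 1L]] <- list("fc128", c(1L, 1L, 1L), cfg$fc_width)
  rows[[length(rows) + 1L]] <- list("fc2", c(1L, 1L, 1L), 2L)
  rows[[length(rows) + 1L]] <- list("softmax", c(1L, 1L, 1L), 2L)
  data.frame(layer = vapply(rows, `[[`, "", 1),
             d1 = vapply(rows, function(r) r[[2]][1], integer(1)),
             d2 = vapply(rows, function(r) r[[2]][2], integer(1)),
             d3 = vapply(rows, function(r) r[[2]][3], integer(1)),
             channels = vapply(rows, function(r) as.integer(r[[3]]), integer(1)))
}

he_init <- function(nr, nc, fan_in) matrix(rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)

#' Build an untrained model
#'
#' Weight initialisation is fan-in-scaled normal, drawn from `cfg$seed`;
#' identical seeds give identical initial weights.
#'
#' @param cfg a [model_config()].
#' @return a `limbicnet_model` (parameters, BN running statistics, config).
#' @export
build_model <- function(cfg) {
  shapes <- layer_shapes(cfg)  # validates dims
  c1 <- cfg$base_channels; s1 <- cfg$stage_channels[1]; s2 <- cfg$stage_channels[2]
  if (s1 != c1) stop("stage 1 uses an identity skip; stage_channels[1] must equal base_channels")
  fw <- cfg$fc_width
  params <- with_seed(cfg$seed, list(
    conv1_W = he_init(343L, c1, 343),
    bn1_gamma = rep(1, c1), bn1_beta = rep(0, c1),
    res1_W = he_init(27L * c1, s1, 27 * c1),
    res1_gamma = rep(1, s1), res1_beta = rep(0, s1),
    res2_W = he_init(27L * s1, s2, 27 * s1),
    res2_gamma = rep(1, s2), res2_beta = rep(0, s2),
    proj_W = he_init(s1, s2, s1),
    proj_gamma = rep(1, s2), proj_beta = rep(0, s2),
    fc1_W = matrix(rnorm(s2 * fw, 0, sqrt(1 / s2)), s2, fw), fc1_b = rep(0, fw),
    fc2_W = matrix(rnorm(fw * 2, 0, sqrt(1 / fw)), fw, 2L), fc2_b = rep(0, 2)
  ))
  running <- list(
    bn1 = list(mean = rep(0, c1), var = rep(1, c1)),
    res1 = list(mean = rep(0, s1), var = rep(1, s1)),
    res2 = list(mean = rep(0, s2), var = rep(1, s2)),
    proj = list(mean = rep(0, s2), var = rep(1, s2)))
  structure(list(params = params, running = running, config = cfg,
                 shapes = shapes),
            class = "limbicnet_model")
}

# ---- batch-norm primitives (activations stacked as [rows, channels]) ----

bn_forward <- function(A, gamma, beta, run, training, momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- colMeans(A)
    v <- colMeans(A * A) - mu^2
    v[v < 0] <- 0
    run$mean <- (1 - momentum) * run$mean + momentum * mu
    run$var <- (1 - momentum) * run$var + momentum * v
  } else {
    mu <- run$mean; v <- run$var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- cpp_center_scale(A, mu, invstd)
  out <- cpp_scale_shift(xhat, gamma, beta)
  list(out = out, cache = list(xhat = xhat, invstd = invstd, gamma = gamma),
       run = run)
}

bn_backward <- function(dout, cache) {
  N <- nrow(dout)
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- cpp_scale_shift(dout, cache$gamma, numeric(length(cache$gamma)))
  t1 <- colSums(dxhat)
  t2 <- colSums(dxhat * cache$xhat)
  dx <- cpp_bn_dx(dxhat, cache$xhat, t1, t2, cache$invstd / N)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

stack_rows <- function(lst) do.call(rbind, lst)
unstack_rows <- function(M, n, i) M[((i - 1) * n + 1):(i * n), , drop = FALSE]

# Forward pass over a list of 3-D input arrays. Returns class probabilities,
# the per-sample final feature matrices (for CAM) and, when `training`,
# every cache needed by nn_backward.
nn_forward <- function(model, xs, training = FALSE, stem_cols = NULL) {
  p <- model$params; cfg <- model$config
  B <- length(xs)
  din <- c(cfg$input_shape, 1L)
  ca <- list(B = B)

  # stem conv 7^3 /2 pad 3 (the unfolded input depends only on the volume,
  # so callers may pass it precomputed via `stem_cols`)
  cols1 <- if (is.null(stem_cols))
    lapply(xs, function(x) cpp_vol2col(as.numeric(x), din, 7L, 2L, 3L))
  else stem_cols
  d1 <- vapply(cfg$input_shape, conv_out, integer(1), k = 7L, s = 2L, p = 3L)
  z1 <- stack_rows(lapply(cols1, function(cc) cc %*% p$conv1_W))
  bn1 <- bn_forward(z1, p$bn1_gamma, p$bn1_beta, model$running$bn1, training)
  a1 <- bn1$out; a1[a1 < 0] <- 0

  # max pool 3^3 /2 pad 1
  n1 <- prod(d1)
  pool <- lapply(seq_len(B), function(i)
    cpp_maxpool3d(as.numeric(unstack_rows(a1, n1, i)), c(d1, cfg$base_channels),
                  3L, 2L, 1L))
  dp <- vapply(d1, conv_out, integer(1), k = 3L, s = 2L, p = 1L)
  np <- prod(dp)
  ap <- lapply(pool, function(pl) matrix(pl$y, np, cfg$base_channels))

  # residual stage 1: identity skip
  cols2 <- lapply(ap, function(a)
    cpp_vol2col(as.numeric(a), c(dp, cfg$base_channels), 3L, 1L, 1L))
  z2 <- stack_rows(lapply(cols2, function(cc) cc %*% p$res1_W))
  bn2 <- bn_forward(z2, p$res1_gamma, p$res1_beta, model$running$res1, training)
  skip <- stack_rows(ap)
  a2 <- bn2$out + skip; a2[a2 < 0] <- 0

  # residual stage 2: stride-2 conv main path + 1x1 stride-2 projection
  cols3 <- lapply(seq_len(B), function(i)
    cpp_vol2col(as.numeric(unstack_rows(a2, np, i)),
                c(dp, cfg$stage_channels[1]), 3L, 2L, 1L))
  z3 <- stack_rows(lapply(cols3, function(cc) cc %*% p$res2_W))
  bn3 <- bn_forward(z3, p$res2_gamma, p$res2_beta, model$running$res2, training)
  colsp <- lapply(seq_len(B), function(i)
    cpp_vol2col(as.numeric(unstack_rows(a2, np, i)),
                c(dp, cfg$stage_channels[1]), 1L, 2L, 0L))
  zp <- stack_rows(lapply(colsp, function(cc) cc %*% p$proj_W))
  bnp <- bn_forward(zp, p$proj_gamma, p$proj_beta, model$running$proj, training)
  a3 <- bn3$out + bnp$out; a3[a3 < 0] <- 0
  d3 <- vapply(dp, conv_out, integer(1), k = 3L, s = 2L, p = 1L)
  n3 <- prod(d3)

  # global average pooling + FC head (FC-128 is linear; the whole head after
  # the final feature maps is affine, which makes CAM collapse exact)
  G <- t(vapply(seq_len(B), function(i)
    colMeans(unstack_rows(a3, n3, i)), numeric(cfg$stage_channels[2])))
  h1 <- sweep(G %*% p$fc1_W, 2, p$fc1_b, "+")
  logits <- sweep(h1 %*% p$fc2_W, 2, p$fc2_b, "+")
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)

  if (training) {
    ca <- list(B = B, din = din, d1 = d1, dp = dp, d3 = d3,
               cols1 = cols1, bn1 = bn1$cache, a1 = a1,
               pool = pool, ap = ap, cols2 = cols2, bn2 = bn2$cache, a2 = a2,
               cols3 = cols3, bn3 = bn3$cache, colsp = colsp, bnp = bnp$cache,
               a3 = a3, G = G, h1 = h1, probs = probs)
    running <- list(bn1 = bn1$run, res1 = bn2$run, res2 = bn3$run, proj = bnp$run)
    list(probs = probs, cache = ca, running = running,
         features = lapply(seq_len(B), function(i) unstack_rows(a3, n3, i)),
         feature_dims = d3)
  } else {
    list(probs = probs,
         features = lapply(seq_len(B), function(i) unstack_rows(a3, n3, i)),
         feature_dims = d3)
  }
}

# Backward pass: gradients of mean cross-entropy w.r.t. every parameter.
nn_backward <- function(model, ca, y_onehot) {
  p <- model$params; cfg <- model$config
  B <- ca$B
  g <- list()

  dlogits <- (ca$probs - y_onehot) / B
  g$fc2_W <- crossprod(ca$h1, dlogits)
  g$fc2_b <- colSums(dlogits)
  dh1 <- tcrossprod(dlogits, p$fc2_W)
  g$fc1_W <- crossprod(ca$G, dh1)
  g$fc1_b <- colSums(dh1)
  dG <- tcrossprod(dh1, p$fc1_W)

  n3 <- prod(ca$d3)
  da3 <- (dG / n3)[rep(seq_len(B), each = n3), , drop = FALSE]
  da3 <- da3 * (ca$a3 > 0)

  bb3 <- bn_backward(da3, ca$bn3)
  g$res2_gamma <- bb3$dgamma; g$res2_beta <- bb3$dbeta
  bbp <- bn_backward(da3, ca$bnp)
  g$proj_gamma <- bbp$dgamma; g$proj_beta <- bbp$dbeta

  np <- prod(ca$dp)
  g$res2_W <- matrix(0, nrow(p$res2_W), ncol(p$res2_W))
  g$proj_W <- matrix(0, nrow(p$proj_W), ncol(p$proj_W))
  da2 <- matrix(0, np * B, cfg$stage_channels[1])
  for (i in seq_len(B)) {
    dz3 <- unstack_rows(bb3$dx, n3, i)
    g$res2_W <- g$res2_W + crossprod(ca$cols3[[i]], dz3)
    dcols <- tcrossprod(dz3, p$res2_W)
    dx_main <- cpp_col2vol(dcols, c(ca$dp, cfg$stage_channels[1]), 3L, 2L, 1L)
    dzp <- unstack_rows(bbp$dx, n3, i)
    g$proj_W <- g$proj_W + crossprod(ca$colsp[[i]], dzp)
    dcolsp <- tcrossprod(dzp, p$proj_W)
    dx_proj <- cpp_col2vol(dcolsp, c(ca$dp, cfg$stage_channels[1]), 1L, 2L, 0L)
    da2[((i - 1) * np + 1):(i * np), ] <-
      matrix(dx_main + dx_proj, np, cfg$stage_channels[1])
  }
  da2 <- da2 * (ca$a2 > 0)

  bb2 <- bn_backward(da2, ca$bn2)
  g$res1_gamma <- bb2$dgamma; g$res1_beta <- bb2$dbeta
  g$res1_W <- matrix(0, nrow(p$res1_W), ncol(p$res1_W))
  dap <- vector("list", B)
  for (i in seq_len(B)) {
    dz2 <- unstack_rows(bb2$dx, np, i)
    g$res1_W <- g$res1_W + crossprod(ca$cols2[[i]], dz2)
    dcols <- tcrossprod(dz2, p$res1_W)
    dskip <- unstack_rows(da2, np, i)  # identity branch
    dap[[i]] <- matrix(cpp_col2vol(dcols, c(ca$dp, cfg$base_channels), 3L, 1L, 1L),
                       np, cfg$base_channels) + dskip
  }

  n1 <- prod(ca$d1)
  da1 <- matrix(0, n1 * B, cfg$base_channels)
  for (i in seq_len(B)) {
    dx <- cpp_maxpool3d_bwd(as.numeric(dap[[i]]), ca$pool[[i]]$argmax,
                            as.integer(n1 * cfg$base_channels))
    da1[((i - 1) * n1 + 1):(i * n1), ] <- matrix(dx, n1, cfg$base_channels)
  }
  da1 <- da1 * (ca$a1 > 0)
  bb1 <- bn_backward(da1, ca$bn1)
  g$bn1_gamma <- bb1$dgamma; g$bn1_beta <- bb1$dbeta
  g$conv1_W <- matrix(0, nrow(p$conv1_W), ncol(p$conv1_W))
  for (i in seq_len(B)) {
    dz1 <- unstack_rows(bb1$dx, n1, i)
    g$conv1_W <- g$conv1_W + crossprod(ca$cols1[[i]], dz1)
  }
  g
}

adam_init <- function(params)
  list(t = 0L,
       m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0))

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

label_to_onehot <- function(labels) {
  y <- matrix(0, length(labels), 2)
  y[cbind(seq_along(labels), ifelse(labels == "ad", 2L, 1L))] <- 1
  y
}

batch_loss <- function(probs, y) -mean(log(pmax(rowSums(probs * y), 1e-12)))

#' Train the network
#'
#' Runs exactly `cfg$epochs` epochs of mini-batch cross-entropy/Adam updates
#' with a seeded shuffling stream, recording mean training loss and
#' evaluation-mode test loss per epoch. Deterministic given the config seed.
#'
#' @param model an untrained [build_model()] output.
#' @param train_x,test_x lists of 3-D arrays conforming to the input shape.
#' @param train_y,test_y character labels (`"control"` / `"ad"`).
#' @return a `limbicnet_trained`: list with `model` (trained weights and BN
#'   running statistics), `train_loss`, `test_loss`, `config`.
#' @export
train_model <- function(model, train_x, train_y, test_x = list(),
                        test_y = character(0)) {
  cfg <- model$config
  stopifnot(length(train_x) == length(train_y))
  if (length(unique(train_y)) < 2)
    stop("training set contains a single class; cross-entropy is degenerate")
  adam <- adam_init(model$params)
  train_curve <- test_curve <- numeric(0)
  n <- length(train_x)
  din <- c(cfg$input_shape, 1L)
  stem <- lapply(train_x, function(x) cpp_vol2col(as.numeric(x), din, 7L, 2L, 3L))
  stem_test <- lapply(test_x, function(x) cpp_vol2col(as.numeric(x), din, 7L, 2L, 3L))
  with_seed(derive_seed(cfg$seed, 101L), {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0); wts <- numeric(0)
      for (b0 in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[b0:min(b0 + cfg$batch_size - 1, n)]
        fw <- nn_forward(model, train_x[idx], training = TRUE,
                         stem_cols = stem[idx])
        model$running <- fw$running
        y <- label_to_onehot(train_y[idx])
        losses <- c(losses, batch_loss(fw$probs, y))
        wts <- c(wts, length(idx))
        if (cfg$lr > 0) {
          grads <- nn_backward(model, fw$cache, y)
          upd <- adam_step(model$params, grads, adam, cfg$lr)
          model$params <- upd$params
          adam <- upd$state
        }
      }
      train_curve <- c(train_curve, sum(losses * wts) / sum(wts))
      test_curve <- c(test_curve,
        if (length(test_x)) eval_loss(model, test_x, test_y, stem_test)
        else NA_real_)
    }
  })
  structure(list(model = model, train_loss = train_curve,
                 test_loss = test_curve, config = cfg),
            class = "limbicnet_trained")
}

eval_loss <- function(model, xs, ys, stem_cols = NULL) {
  bs <- model$config$batch_size
  tot <- 0
  for (b0 in seq(1, length(xs), by = bs)) {
    idx <- b0:min(b0 + bs - 1, length(xs))
    fw <- nn_forward(model, xs[idx], training = FALSE,
                     stem_cols = if (is.null(stem_cols)) NULL else stem_cols[idx])
    tot <- tot + batch_loss(fw$probs, label_to_onehot(ys[idx])) * length(idx)
  }
  tot / length(xs)
}

#' Predict class probabilities and hard labels
#'
#' Evaluation-mode forward pass (BN running statistics), so predictions are
#' invariant to how subjects are batched. Hard labels take the argmax
#' probability; exact ties go to `"control"`.
#'
#' @param object a trained model (`limbicnet_trained`).
#' @param volumes list of 3-D arrays conforming to the input shape.
#' @param ... unused.
#' @return data.frame with `prob_control`, `prob_ad`, `label`.
#' @export
predict.limbicnet_trained <- function(object, volumes, ...) {
  model <- object$model
  d <- model$config$input_shape
  for (v in volumes)
    if (!all(dim(v) == d))
      stop("volume does not conform to the model input shape")
  bs <- model$config$batch_size
  out <- NULL
  for (b0 in seq(1, length(volumes), by = bs)) {
    idx <- b0:min(b0 + bs - 1, length(volumes))
    fw <- nn_forward(model, volumes[idx], training = FALSE)
    out <- rbind(out, fw$probs)
  }
  data.frame(prob_control = out[, 1], prob_ad = out[, 2],
             label = ifelse(out[, 2] > out[, 1], "ad", "control"),
             stringsAsFactors = FALSE)
}

#' Normalise a volume by its in-brain mean
#'
#' Network inputs are arbitrary-unit activity images; dividing by the mean
#' over voxels above a small positive floor makes training scale-free.
#'
#' @param vol 3-D volume.
#' @param floor voxels strictly above this value count as in-brain.
#' @export
normalize_volume <- function(vol, floor = 1e-6) {
  m <- mean(vol[vol > floor])
  if (!is.finite(m) || m <= 0) return(vol)
  out <- vol / m
  attr(out, "voxel_size") <- attr(vol, "voxel_size")
  out
}
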