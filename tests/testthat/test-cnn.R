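test_that("layer-shape trace reproduces the reference architecture for whole volumes", {
  tr <- layer_shapes(model_config(input_shape = c(128, 128, 79)))
  g <- function(layer) unlist(tr[tr$layer == layer, c("d1", "d2", "d3", "channels")],
                              use.names = FALSE)
  expect_equal(g("conv1"), c(64, 64, 40, 64))
  expect_equal(g("maxpool"), c(32, 32, 20, 64))
  expect_equal(g("res_stage1"), c(32, 32, 20, 64))
  expect_equal(g("res_stage2"), c(16, 16, 10, 128))
  expect_equal(g("gap"), c(1, 1, 1, 128))
  expect_equal(g("fc128"), c(1, 1, 1, 128))
  expect_equal(g("fc2"), c(1, 1, 1, 2))
})

test_that("layer-shape trace reproduces the reference architecture for cropped volumes", {
  tr <- layer_shapes(model_config(input_shape = c(128, 128, 10)))
  g <- function(layer) unlist(tr[tr$layer == layer, c("d1", "d2", "d3", "channels")],
                              use.names = FALSE)
  expect_equal(g("conv1"), c(64, 64, 5, 64))
  expect_equal(g("maxpool"), c(32, 32, 3, 64))
  expect_equal(g("res_stage1"), c(32, 32, 3, 64))
  expect_equal(g("res_stage2"), c(16, 16, 2, 128))
  expect_equal(g("gap"), c(1, 1, 1, 128))
  # padding keeps every dimension >= 1 even for degenerate inputs
  tiny <- layer_shapes(model_config(input_shape = c(2, 2, 1)))
  expect_true(all(tiny$d1 >= 1 & tiny$d2 >= 1 & tiny$d3 >= 1))
})

test_that("forward pass yields softmax probabilities, deterministic in the seed", {
  cfg <- tiny_model_config(seed = 3)
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  set.seed(1)
  xs <- list(random_volume(cfg$input_shape), random_volume(cfg$input_shape))
  p1 <- limbicnet:::nn_forward(m1, xs)$probs
  p2 <- limbicnet:::nn_forward(m2, xs)$probs
  expect_equal(dim(p1), c(2L, 2L))
  expect_equal(rowSums(p1), c(1, 1), tolerance = 1e-6)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_identical(p1, p2)
  m3 <- build_model(model_config(input_shape = cfg$input_shape,
                                 base_channels = 3L, stage_channels = c(3L, 4L),
                                 fc_width = 5L, seed = 4))
  expect_false(identical(limbicnet:::nn_forward(m3, xs)$probs, p1))
})

test_that("analytic gradients match central finite differences", {
  cfg <- tiny_model_config(seed = 7)
  m <- build_model(cfg)
  set.seed(1)
  xs <- list(random_volume(cfg$input_shape), random_volume(cfg$input_shape))
  y <- limbicnet:::label_to_onehot(c("control", "ad"))
  fw <- limbicnet:::nn_forward(m, xs, training = TRUE)
  gr <- limbicnet:::nn_backward(m, fw$cache, y)
  lossfn <- function(model) {
    f <- limbicnet:::nn_forward(model, xs, training = TRUE)
    limbicnet:::batch_loss(f$probs, y)
  }
  eps <- 1e-5
  set.seed(2)
  for (nm in names(gr)) {
    for (i in sample(length(m$params[[nm]]), min(3, length(m$params[[nm]])))) {
      mp <- mm <- m
      mp$params[[nm]][i] <- m$params[[nm]][i] + eps
      mm$params[[nm]][i] <- m$params[[nm]][i] - eps
      num <- (lossfn(mp) - lossfn(mm)) / (2 * eps)
      expect_lt(abs(num - gr[[nm]][i]), 1e-6 + 1e-4 * (abs(num) + abs(gr[[nm]][i])),
                label = sprintf("gradient of %s[%d]", nm, i))
    }
  }
})

test_that("training descends on a separable cohort and is seed-reproducible", {
  cfg <- tiny_model_config(seed = 5)
  cfg$epochs <- 6L
  cfg$batch_size <- 4L
  cfg$lr <- 3e-3  # step size matched to the tiny problem
  set.seed(10)
  n <- 12
  # class signal is a spatial pattern (left vs right bright half), which
  # survives batch normalisation; a pure global mean shift would not
  pA <- array(0, cfg$input_shape); pA[1:4, , ] <- 1
  pB <- array(0, cfg$input_shape); pB[5:8, , ] <- 1
  xs <- lapply(1:n, function(i)
    array(rnorm(prod(cfg$input_shape), 0, 0.5), cfg$input_shape) +
      3 * (if (i %% 2 == 1) pA else pB))
  ys <- ifelse(1:n %% 2 == 1, "ad", "control")
  tr1 <- train_model(build_model(cfg), xs, ys, xs[1:4], ys[1:4])
  expect_length(tr1$train_loss, 6)
  expect_length(tr1$test_loss, 6)
  expect_lt(tr1$train_loss[6], tr1$train_loss[1])
  tr2 <- train_model(build_model(cfg), xs, ys, xs[1:4], ys[1:4])
  expect_identical(tr1$train_loss, tr2$train_loss)
  expect_identical(tr1$test_loss, tr2$test_loss)
  expect_error(train_model(build_model(cfg), xs[c(1, 3)], ys[c(1, 3)]),
               "single class")
})

test_that("zero learning rate freezes the weights", {
  cfg <- tiny_model_config(seed = 6)
  cfg$lr <- 0
  cfg$epochs <- 3L
  set.seed(3)
  xs <- lapply(1:6, function(i) random_volume(cfg$input_shape))
  ys <- rep(c("control", "ad"), 3)
  m <- build_model(cfg)
  tr <- train_model(m, xs, ys)
  expect_identical(tr$model$params, m$params)
})

test_that("predictions are batching-invariant with a control tie rule", {
  cfg <- tiny_model_config(seed = 8)
  cfg$epochs <- 1L
  set.seed(4)
  xs <- lapply(1:7, function(i) random_volume(cfg$input_shape))
  ys <- c(rep("control", 4), rep("ad", 3))
  tr <- train_model(build_model(cfg), xs, ys)
  p_all <- predict(tr, xs)
  cfg1 <- cfg; cfg1$batch_size <- 1L
  tr1 <- tr; tr1$model$config <- cfg1
  p_one <- predict(tr1, xs)
  expect_equal(p_all$prob_ad, p_one$prob_ad, tolerance = 1e-12)
  expect_true(all(p_all$label == ifelse(p_all$prob_ad > p_all$prob_control,
                                        "ad", "control")))
  expect_error(predict(tr, list(array(0, c(2, 2, 2)))), "input shape")
})
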