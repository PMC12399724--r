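# Backpropagation engine: every layer's reverse-mode gradient is checked
# against central finite differences, for inputs and for parameters.

check_layer_grads <- function(make_layer, in_shape, n = 3L, seed = 1L,
                              tol = 1e-6) {
  ns <- asNamespace("harclust")
  set.seed(seed)
  layer <- make_layer()
  ns$layer_init(layer, in_shape)
  x <- array(stats::rnorm(prod(c(n, in_shape))), c(n, in_shape))
  fw0 <- ns$layer_forward(layer, x, training = FALSE)
  set.seed(seed + 100)
  ct <- array(stats::rnorm(length(fw0$out)), dim(fw0$out) %||% length(fw0$out))

  fw <- ns$layer_forward(layer, x, training = FALSE)
  dx <- ns$layer_backward(layer, fw$cache, ct)
  gx <- num_grad(function(xx) {
    sum(ns$layer_forward(layer, array(xx, dim(x)), training = FALSE)$out * ct)
  }, x)
  expect_lt(max(abs(dx - gx)) / max(1, max(abs(gx))), tol)

  for (pl in ns$collect_param_layers(list(layer))) {
    fw <- ns$layer_forward(layer, x, training = FALSE)
    ns$layer_backward(layer, fw$cache, ct)
    grads <- pl$grads
    for (nm in names(pl$params)) {
      p0 <- pl$params[[nm]]
      gn <- num_grad(function(pp) {
        pl$params[[nm]] <- if (is.null(dim(p0))) as.numeric(pp)
                           else array(pp, dim(p0))
        out <- sum(ns$layer_forward(layer, x, training = FALSE)$out * ct)
        pl$params[[nm]] <- p0
        out
      }, p0)
      expect_lt(max(abs(grads[[nm]] - gn)) / max(1, max(abs(gn))), tol)
    }
  }
}

test_that("dense, conv and pooling gradients match finite differences", {
  ns <- asNamespace("harclust")
  check_layer_grads(function() ns$nn_dense(4, "relu"), c(5))
  check_layer_grads(function() ns$nn_dense(4, "tanh"), c(6, 3))  # per-step
  check_layer_grads(function() ns$nn_conv1d(3, 5, "relu", "same"), c(8, 2))
  check_layer_grads(function() ns$nn_conv1d(3, 3, "sigmoid", "valid"), c(8, 2))
  check_layer_grads(function() ns$nn_conv2d(2, c(3, 3), "relu", "same"), c(6, 3, 3))
  check_layer_grads(function() ns$nn_maxpool1d(2), c(8, 2))
  check_layer_grads(function() ns$nn_maxpool2d(c(2, 1)), c(6, 3, 2))
  check_layer_grads(function() ns$nn_upsample1d(3), c(4, 2))
  check_layer_grads(function() ns$nn_flatten(), c(4, 3))
  check_layer_grads(function() ns$nn_repeat(4), c(3))
})

test_that("recurrent and normalization gradients match finite differences", {
  ns <- asNamespace("harclust")
  check_layer_grads(function() ns$nn_lstm(3, return_sequences = TRUE), c(6, 2))
  check_layer_grads(function() ns$nn_lstm(3, return_sequences = FALSE), c(6, 2))
  check_layer_grads(function() ns$nn_bilstm(3, return_sequences = TRUE), c(5, 2))
  check_layer_grads(function() ns$nn_bilstm(3, return_sequences = FALSE), c(5, 2))
  check_layer_grads(function() ns$nn_batchnorm(), c(5))
  check_layer_grads(function() ns$nn_multihead(list(
    list(ns$nn_conv1d(2, 3, "relu"), ns$nn_maxpool1d(2)),
    list(ns$nn_conv1d(3, 5, "relu"), ns$nn_maxpool1d(2))
  )), c(8, 2))

  # batchnorm in training mode (batch statistics on the backward path)
  set.seed(2)
  l <- ns$nn_batchnorm()
  ns$layer_init(l, c(3))
  x <- matrix(stats::rnorm(15), 5, 3)
  ct <- matrix(stats::rnorm(15), 5, 3)
  fw <- ns$layer_forward(l, x, training = TRUE)
  dx <- ns$layer_backward(l, fw$cache, ct)
  gx <- num_grad(function(xx) {
    sum(ns$layer_forward(l, matrix(xx, 5, 3), training = TRUE)$out * ct)
  }, x)
  expect_lt(max(abs(dx - gx)), 1e-6)
})

test_that("forward passes preserve batch size and stay finite", {
  ns <- asNamespace("harclust")
  set.seed(4)
  layers <- list(
    ns$nn_conv1d(4, 5, "relu"), ns$nn_maxpool1d(2),
    ns$nn_lstm(6, return_sequences = TRUE), ns$nn_bilstm(3),
    ns$nn_dense(5, "tanh"), ns$nn_batchnorm(), ns$nn_dense(2)
  )
  model <- ns$nn_build(layers, c(12, 3), seed = 1)
  for (n in c(1L, 4L, 9L)) {
    x <- array(stats::rnorm(n * 12 * 3), c(n, 12, 3))
    out <- ns$nn_forward(model, x, training = FALSE)$out
    expect_equal(nrow(out), n)
    expect_true(all(is.finite(out)))
  }
})

test_that("Adam drives a small regression loss down", {
  ns <- asNamespace("harclust")
  set.seed(5)
  x <- matrix(stats::rnorm(80), 20, 4)
  yt <- x %*% matrix(c(1, -2, 0.5, 3), 4, 1)
  model <- ns$nn_build(list(ns$nn_dense(8, "tanh"), ns$nn_dense(1)), c(4), seed = 2)
  plist <- ns$collect_param_layers(model$layers)
  opt <- ns$adam_new(lr = 0.01)
  losses <- numeric(200)
  for (i in 1:200) {
    fw <- ns$nn_forward(model, x, training = TRUE)
    lg <- ns$mse_loss_grad(fw$out, yt)
    ns$nn_backward(model, fw$caches, lg$grad)
    ns$adam_step(opt, plist)
    losses[i] <- lg$loss
  }
  expect_lt(losses[200], losses[1] / 20)
})
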