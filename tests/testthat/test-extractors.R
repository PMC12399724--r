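# Feature-extractor family.

test_that("build_spec resolves the documented architectures", {
  th <- build_spec("tri_head_te", c(200L, 9L), 6L)
  expect_equal(th$hyperparams$head_kernels, c(5L, 7L, 11L))
  layers <- harclust:::assemble_layers(th)
  expect_length(layers$encoder[[1]]$heads, 3)

  la <- build_spec("lstm_ae", c(200L, 9L), 6L)
  expect_equal(la$hyperparams$lstm_units, c(128L, 64L))
  dec <- harclust:::assemble_layers(la)$decoder
  rec_units <- vapply(Filter(function(l) l$type == "lstm", dec),
                      function(l) l$units, integer(1))
  expect_equal(rec_units, c(64L, 128L))  # mirrored encoder

  expect_equal(build_spec("mlp_ae", c(200L, 9L), 6L)$latent_dim, 32L)

  expect_error(build_spec("cnn2d", c(201L, 9L), 6L), "pad")
  expect_error(build_spec("hybrid_conv_lstm", c(201L, 9L), 6L), "pad")
  expect_error(build_spec("mlp_ae", c(32L, 9L), 6L,
                          overrides = list(nonsense = 1)), "nonsense")
})

test_that("supervised training enforces preconditions and records history", {
  ws <- make_separable_windows(n_per = 10, w = 32, seed = 2)
  spec <- build_spec("mlp_ae", c(32L, 9L), 2L)
  expect_error(train_supervised(spec, ws, epochs = 0), "epochs")
  single <- window_set(ws$tensor, rep(0L, 20), window_len = 32L, step = 32L)
  expect_error(train_supervised(spec, single, epochs = 1), "single class")
  m <- train_supervised(spec, ws, ws, epochs = 3, seed = 1)
  expect_equal(nrow(m$training_history), 3)
  expect_true(all(c("loss", "accuracy", "val_loss", "val_accuracy") %in%
                  names(m$training_history)))
})

test_that("every family separates a two-class fixture (3-seed majority)", {
  ws <- make_separable_windows(n_per = 30, w = 32, seed = 1)
  for (fam in c("cnn2d", "mlp_ae", "lstm_ae", "hybrid_conv_lstm",
                "timedist_te", "tri_head_te")) {
    spec <- build_spec(fam, c(32L, 9L), 2L)
    passes <- vapply(1:3, function(s) {
      m <- train_supervised(spec, ws, ws, epochs = 10, seed = s)
      tail(m$training_history$val_accuracy, 1) > 0.9
    }, logical(1))
    expect_gte(sum(passes), 2)
  }
})

test_that("autoencoders reconstruct with non-increasing smoothed loss", {
  ws <- make_separable_windows(n_per = 15, w = 32, seed = 3)
  spec <- build_spec("mlp_ae", c(32L, 9L), 2L)
  m <- train_autoencoder(spec, ws, epochs = 30, seed = 1)
  loss <- m$training_history$loss
  ma <- stats::filter(loss, rep(1 / 10, 10), sides = 1)
  ma <- ma[!is.na(ma)]
  expect_true(all(diff(ma) <= 1e-6))

  # zero-input tensor: reconstruction loss converges toward 0
  zero <- window_set(array(0, c(8, 32, 9)), rep(0L, 8), 32L, 32L)
  spec_fast <- build_spec("mlp_ae", c(32L, 9L), 2L,
                          overrides = list(lr = 0.05))
  mz <- train_autoencoder(spec_fast, zero, epochs = 200, seed = 1)
  expect_lt(tail(mz$training_history$loss, 1), 0.01)
  expect_lt(tail(mz$training_history$loss, 1), mz$training_history$loss[1])

  # decode(encode(x)) preserves the window shape
  ns <- asNamespace("harclust")
  fw <- ns$nn_forward(m$model, ws$tensor[1:3, , , drop = FALSE])
  expect_equal(dim(fw$out), c(3L, 32L, 9L))

  # out-of-range inputs are rejected with rescaling advice
  bad <- window_set(ws$tensor * 4 - 1, ws$window_labels, 32L, 32L)
  expect_error(train_autoencoder(spec, bad, epochs = 1), "rescale")
})

test_that("encode is deterministic, shape-true and per-window independent", {
  ws <- make_separable_windows(n_per = 10, w = 32, seed = 4)
  spec <- build_spec("hybrid_conv_lstm", c(32L, 9L), 2L, latent_dim = 16L)
  m <- train_supervised(spec, ws, epochs = 2, seed = 1)
  sub <- harclust:::subset_windows(ws, 1:7)
  z1 <- encode(m, sub)
  expect_equal(dim(z1$matrix), c(7L, 16L))
  z2 <- encode(m, sub)
  expect_identical(z1$matrix, z2$matrix)
  perm <- c(3L, 1L, 7L, 2L, 6L, 4L, 5L)
  zp <- encode(m, harclust:::subset_windows(ws, perm))
  expect_equal(zp$matrix, z1$matrix[perm, ])
})

test_that("classify takes the argmax with sane accuracy bounds", {
  ws <- make_separable_windows(n_per = 25, w = 32, seed = 5)
  spec <- build_spec("hybrid_conv_lstm", c(32L, 9L), 2L)
  m <- train_supervised(spec, ws, epochs = 10, seed = 1)
  cl <- classify(m, ws)
  expect_equal(cl$accuracy, 1.0)
  expect_true(all(cl$labels %in% 0:1))
  empty <- window_set(array(0, c(0, 32, 9)), integer(0), 32L, 32L)
  expect_error(classify(m, empty), "empty")
})

test_that("tri-head with equal kernels and tied weights gives identical heads", {
  ns <- asNamespace("harclust")
  spec <- build_spec("tri_head_te", c(32L, 9L), 2L,
                     overrides = list(head_kernels = c(5L, 5L, 5L)))
  parts <- harclust:::assemble_layers(spec)
  model <- ns$nn_build(list(parts$encoder[[1]]), c(32L, 9L), seed = 1)
  mh <- model$layers[[1]]
  # tie every head to the first head's convolution weights
  for (h in 2:3) {
    mh$heads[[h]][[1]]$params <- mh$heads[[1]][[1]]$params
  }
  set.seed(9)
  x <- array(stats::rnorm(2 * 32 * 9), c(2, 32, 9))
  out <- ns$nn_forward(model, x, training = FALSE)$out
  w <- dim(out)[3] / 3
  expect_equal(out[, , 1:w], out[, , w + 1:w])
  expect_equal(out[, , 1:w], out[, , 2 * w + 1:w])
})

test_that("checkpoints round-trip through the JSON container", {
  ws <- make_separable_windows(n_per = 8, w = 32, seed = 6)
  spec <- build_spec("mlp_ae", c(32L, 9L), 2L, latent_dim = 8L)
  m <- train_supervised(spec, ws, epochs = 2, seed = 3)
  path <- tempfile(fileext = ".json")
  save_extractor(m, path)
  m2 <- load_extractor(path)
  expect_equal(m2$spec$family, "mlp_ae")
  expect_equal(encode(m2, ws)$matrix, encode(m, ws)$matrix, tolerance = 1e-12)
  expect_equal(classify(m2, ws)$labels, classify(m, ws)$labels)
})
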