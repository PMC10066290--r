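test_that("conv_forward matches hand examples", {
  # identity 1x1 kernel
  x <- array(runif(5 * 5 * 1), dim = c(5, 5, 1))
  id <- conv_layer_spec(array(1, dim = c(1, 1, 1, 1)), 0)
  expect_equal(conv_forward(x, id), x, tolerance = 1e-12)
  # bias-only with ReLU: constant maps at max(b, 0)
  zk <- conv_layer_spec(array(0, dim = c(2, 2, 1, 2)), c(0.7, -0.3), "relu")
  out <- conv_forward(x, zk)
  expect_true(all(out[, , 1] == 0.7))
  expect_true(all(out[, , 2] == 0))
  # 3x3 ones input, 2x2 ones kernel -> 2x2 output of 4s
  ones <- array(1, dim = c(3, 3, 1))
  k <- conv_layer_spec(array(1, dim = c(2, 2, 1, 1)), 0)
  expect_equal(conv_forward(ones, k), array(4, dim = c(2, 2, 1)))
  # contract errors
  big <- conv_layer_spec(array(1, dim = c(7, 7, 1, 1)), 0)
  expect_error(conv_forward(x, big), class = "fangmark_conv")
  two <- conv_layer_spec(array(1, dim = c(2, 2, 2, 1)), 0)
  expect_error(conv_forward(x, two), class = "fangmark_conv")
})

test_that("conv_forward agrees with the brute-force loop oracle", {
  for (case in 1:20) {
    set.seed(case)
    x <- array(rnorm(5 * 5 * 2), dim = c(5, 5, 2))
    k <- array(rnorm(3 * 3 * 2 * 3), dim = c(3, 3, 2, 3))
    b <- rnorm(3)
    act <- if (case %% 2 == 0) fangmark:::relu else identity
    spec <- conv_layer_spec(k, b, if (case %% 2 == 0) "relu" else "linear")
    expect_equal(conv_forward(x, spec), oracle_conv(x, k, b, act),
                 tolerance = 1e-5)
  }
})

test_that("pool_output_shape follows the pooling arithmetic", {
  expect_identical(pool_output_shape(c(3, 224, 224), 2, 2), c(3L, 112L, 112L))
  expect_identical(pool_output_shape(c(5, 7, 9), 1, 1), c(5L, 7L, 9L))
  expect_identical(pool_output_shape(c(1, 4, 4), 4, 1), c(1L, 1L, 1L))
  expect_error(pool_output_shape(c(1, 3, 3), 4, 1), class = "fangmark_pool")
})

test_that("max_pool matches its oracle and its declared shape", {
  expect_equal(max_pool(matrix(c(1, 3, 2, 4), 2, 2), 2, 2), matrix(4))
  cst <- matrix(2.5, 6, 6)
  expect_equal(max_pool(cst, 2, 2), matrix(2.5, 3, 3))
  m <- matrix(rnorm(49), 7, 7)
  expect_identical(max_pool(m, 1, 1), m)
  for (F in 1:3) for (S in 1:3) {
    for (n in c(4, 7, 9)) {
      set.seed(F * 100 + S * 10 + n)
      m <- matrix(rnorm(n * n), n, n)
      got <- max_pool(m, F, S)
      expect_equal(got, oracle_pool(m, F, S), tolerance = 1e-12)
      expect_identical(pool_output_shape(c(1, n, n), F, S)[2:3], dim(got))
    }
  }
})

test_that("build_model honours the backbone contract", {
  cfg <- train_config(seed = 5, input_side = 64)
  m <- build_model(cfg)
  img <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  z <- fangmark:::model_forward(m, img)
  expect_length(z, 2)
  # seeded determinism of the initial parameters
  expect_identical(m$params, build_model(cfg)$params)
  expect_error(build_model(train_config(backbone = "vgg19")),
               class = "fangmark_weights")
  expect_error(build_model(train_config(backbone = "alexnet")),
               class = "fangmark_backbone")
})

test_that("training defaults echo the tuned protocol", {
  cfg <- train_config()
  expect_identical(cfg$epochs, 100L)
  expect_identical(cfg$batch, 64L)
  expect_equal(cfg$lr, 0.001)
  expect_equal(cfg$epsilon, 1e-10)
})

test_that("the training harness logs, errors and stays consistent", {
  ds <- fixture_dataset(30, seed = 0)   # 60 images at 64 px
  cfg <- train_config(epochs = 5, batch = 16, seed = 0, input_side = 64)
  m <- train_classifier(build_model(cfg), ds, cfg)
  expect_identical(nrow(m$history), 5L)
  expect_named(m$history, c("epoch", "train_loss", "train_acc", "val_acc"))
  expect_true(m$trained)
  # predictions on the training images reproduce the logged final accuracy
  tr <- m$splits$train
  pred <- predict(m, ds[tr])
  truth <- vapply(ds[tr], function(d) d$label, character(1))
  expect_equal(mean(pred$label == truth), tail(m$history$train_acc, 1),
               tolerance = 1e-6)
  expect_true(all(pred$score >= 0 & pred$score <= 1))
  # seeded determinism of the whole training run
  m2 <- train_classifier(build_model(cfg), ds, cfg)
  expect_identical(m$history, m2$history)
  # error contracts
  expect_error(train_classifier(build_model(cfg), list(), cfg),
               class = "fangmark_train")
  onecls <- ds[vapply(ds, function(d) d$label, character(1)) == "cobra"]
  expect_error(train_classifier(build_model(cfg), onecls, cfg),
               class = "fangmark_train")
})

test_that("predict handles empty input and rejects shape mismatches", {
  cfg <- train_config(epochs = 1, batch = 8, seed = 1, input_side = 64)
  m <- train_classifier(build_model(cfg), fixture_dataset(10, seed = 2), cfg)
  expect_identical(nrow(predict(m, list())), 0L)
  bad <- array(0.5, dim = c(32, 32, 3))
  expect_error(predict(m, list(bad)), class = "fangmark_predict")
})

test_that("the tiny backbone learns the synthetic classes", {
  # seeded run asserted as a floor: 200 images, 15 epochs, lr 0.001
  ds <- fixture_dataset(100, seed = 0)
  cfg <- train_config(epochs = 15, lr = 0.001, batch = 64, seed = 0,
                      input_side = 64)
  m <- train_classifier(build_model(cfg), ds, cfg)
  expect_gte(tail(m$history$train_acc, 1), 0.90)
})
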