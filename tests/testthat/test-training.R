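test_that("100 pairs split 80/20, deterministically", {
  pairs <- lapply(1:100, function(i) list(image = matrix(i), mask = matrix(0L)))
  cfg <- train_config(split = 0.8, seed = 3)
  sp <- split_dataset(pairs, cfg)
  expect_length(sp$train, 80)
  expect_length(sp$test, 20)
  sp2 <- split_dataset(pairs, cfg)
  expect_identical(sp, sp2)
  # exhaustive and disjoint
  ids <- c(vapply(sp$train, function(p) p$image[1], 0),
           vapply(sp$test, function(p) p$image[1], 0))
  expect_identical(sort(ids), as.numeric(1:100))
})

test_that("augmented variants always land on the same side as their source", {
  src <- lapply(1:10, function(i)
    list(image = matrix(rnorm(64), 8, 8), mask = random_mask(8, 8)))
  expanded <- expand_dataset(src)                  # 40 pairs, 10 sources
  sp <- split_dataset(expanded, train_config(split = 0.8, seed = 5))
  expect_length(sp$train, 32)
  expect_length(sp$test, 8)
  train_src <- unique(vapply(sp$train, `[[`, 0L, "source"))
  test_src <- unique(vapply(sp$test, `[[`, 0L, "source"))
  expect_length(intersect(train_src, test_src), 0)
  # each retained source contributes all 4 variants
  expect_identical(length(sp$train) / length(train_src), 4)
})

test_that("degenerate splits are rejected", {
  pairs <- lapply(1:2, function(i) list(image = matrix(0), mask = matrix(0L)))
  expect_error(split_dataset(pairs[1], train_config()),
               class = "msunet_config_error")
  expect_error(split_dataset(pairs, train_config(split = 0.01)),
               class = "msunet_config_error")
})

test_that("a zero learning rate leaves the loss history flat", {
  p <- tiny_pair(32, seed = 21)
  model <- build_network(small_net_config(), seed = 1)
  fit <- train(model, list(p), train_config(learning_rate = 0,
                                            batch_size = 1, epochs = 3,
                                            seed = 1))
  expect_equal(diff(range(fit$history$loss)), 0, tolerance = 1e-12)
})

test_that("training is bit-identical under identical config and seed", {
  pairs <- lapply(1:2, function(i) tiny_pair(32, seed = 30 + i))
  run <- function() {
    model <- build_network(small_net_config(), seed = 2)
    fit <- train(model, pairs, train_config(learning_rate = 0.003,
                                            batch_size = 2, epochs = 2,
                                            seed = 9))
    list(history = fit$history,
         pred = predict_prob(fit$model, pairs[[1]]$image))
  }
  a <- run(); b <- run()
  expect_identical(a$history, b$history)
  expect_identical(a$pred, b$pred)
})

test_that("loss decreases over a short overfitting run", {
  p <- tiny_pair(32, seed = 40, contrast = 1, noise = 0)
  model <- build_network(small_net_config(), seed = 3)
  fit <- train(model, list(p), train_config(learning_rate = 0.01,
                                            batch_size = 1, epochs = 40,
                                            seed = 1))
  h <- fit$history$loss
  n <- length(h)
  first <- h[1:max(1, floor(n / 10))]
  last <- h[(n - max(1, floor(n / 10)) + 1):n]
  expect_lt(median(last), median(first))
  expect_identical(fit$best_epoch, which.min(h))
})

test_that("online augmentation during training keeps losses finite", {
  p <- tiny_pair(32, seed = 50)
  aug <- augmentation_spec(methods = c("vertical_flip", "random_rotation"),
                           rotation_range = 10)
  model <- build_network(small_net_config(), seed = 4)
  fit <- train(model, list(p), train_config(learning_rate = 0.003,
                                            batch_size = 1, epochs = 2,
                                            seed = 1, augmentation = aug))
  expect_true(all(is.finite(fit$history$loss)))
})
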