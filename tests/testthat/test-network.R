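test_that("the default configuration reproduces the printed contraction and channel plan", {
  tab <- audit_network(network_config())
  bottleneck <- tab[tab$stage == "bottleneck", ]
  expect_identical(bottleneck$size, 8L)
  expect_identical(bottleneck$channels, 1024L)
  expect_identical(tab$size[tab$stage == "input"], 128L)
  expect_identical(tab$channels[tab$stage == "conv_block_1"], 64L)
  expect_identical(tab$size[tab$stage == "classifier"], 128L)
  expect_identical(tab$channels[tab$stage == "classifier"], 1L)
  # contracting widths are base_width * 2^stage, halving on expansion
  expect_identical(tab$channels[grepl("^conv_block", tab$stage)],
                   c(64L, 128L, 256L, 512L))
  expect_identical(tab$channels[grepl("^deconv_block", tab$stage)],
                   c(512L, 256L, 128L))
})

test_that("forward passes conserve shape and emit probabilities", {
  cfg <- small_net_config()
  model <- build_network(cfg, seed = 1)
  img <- matrix(rnorm(32 * 32), 32, 32)
  p <- predict_prob(model, img)
  expect_identical(dim(p), c(32L, 32L))
  expect_gte(min(p), 0); expect_lte(max(p), 1)
  # shape conservation at another 16-divisible size
  cfg48 <- network_config(input_size = 48, base_width = 8,
                          n_down_stages = 4, stem_branch_width = 4)
  m48 <- build_network(cfg48, seed = 2)
  p48 <- predict_prob(m48, matrix(rnorm(48 * 48), 48, 48))
  expect_identical(dim(p48), c(48L, 48L))
})

test_that("evaluation-mode inference is bit-identical across calls", {
  model <- build_network(small_net_config(), seed = 3)
  img <- matrix(rnorm(32 * 32), 32, 32)
  expect_identical(predict_prob(model, img), predict_prob(model, img))
})

test_that("the static shape audit matches the instantiated model end to end", {
  cfg <- small_net_config()
  tab <- audit_network(cfg)
  expect_identical(tab$size[nrow(tab)], cfg$input_size)
  model <- build_network(cfg, seed = 4)
  p <- predict_prob(model, matrix(rnorm(32 * 32), 32, 32))
  expect_identical(dim(p)[1], tab$size[tab$stage == "classifier"])
  # bottleneck channels follow base_width * 2^n_down_stages
  expect_identical(tab$channels[tab$stage == "bottleneck"],
                   as.integer(cfg$base_width * 2^cfg$n_down_stages))
})

test_that("glorot initialization is seeded and reproducible", {
  a <- build_network(small_net_config(), seed = 7)
  b <- build_network(small_net_config(), seed = 7)
  expect_identical(collect_params(a), collect_params(b))
  c <- build_network(small_net_config(), seed = 8)
  expect_false(identical(collect_params(a), collect_params(c)))
})

test_that("probability thresholding follows the >= convention", {
  expect_identical(predict_mask(matrix(0.9, 2, 2), 0.5),
                   matrix(1L, 2, 2))
  expect_identical(predict_mask(matrix(0.1, 2, 2), 0.5),
                   matrix(0L, 2, 2))
  expect_identical(as.integer(predict_mask(c(0.4, 0.5, 0.6), 0.5)),
                   c(0L, 1L, 1L))
  expect_error(predict_mask(matrix(0.5), 0), class = "msunet_config_error")
  expect_error(predict_mask(matrix(0.5), 1), class = "msunet_config_error")
})

test_that("configuration invariants are enforced", {
  expect_error(network_config(input_size = 100), # not divisible by 16
               class = "msunet_config_error")
  expect_error(network_config(n_unet_up_blocks = 4),
               class = "msunet_config_error")
  model <- build_network(small_net_config(), seed = 1)
  expect_error(predict_prob(model, matrix(0, 16, 16)),
               class = "msunet_geometry_error")
})

test_that("checkpoints round-trip weights and configuration", {
  model <- build_network(small_net_config(), seed = 5)
  img <- matrix(rnorm(32 * 32), 32, 32)
  p0 <- predict_prob(model, img)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  restored <- load_checkpoint(path)
  expect_identical(predict_prob(restored, img), p0)
  unlink(path)
})

test_that("the two-channel softmax classifier also emits valid probabilities", {
  cfg <- network_config(input_size = 32, base_width = 8, n_down_stages = 3,
                        stem_branch_width = 4, classifier = "softmax_2ch")
  model <- build_network(cfg, seed = 6)
  p <- predict_prob(model, matrix(rnorm(32 * 32), 32, 32))
  expect_identical(dim(p), c(32L, 32L))
  expect_gte(min(p), 0); expect_lte(max(p), 1)
})

test_that("the model parameter count equals the sum of its block counts", {
  model <- build_network(small_net_config(), seed = 9)
  blocks <- msunet:::model_blocks(model)
  expect_identical(count_parameters(model),
                   sum(vapply(blocks, count_parameters, 0L)))
  layers <- msunet:::model_layers(model)
  expect_identical(count_parameters(model),
                   as.integer(sum(vapply(layers, count_parameters, 0L))))
})
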