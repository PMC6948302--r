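test_that("the output-size formula matches the zero-padding contract", {
  expect_identical(conv_output_size(128, kernel = 3, stride = 1,
                                    padding = 1), 128L)
  expect_identical(conv_output_size(8, kernel = 1, stride = 1, padding = 0),
                   8L)
  expect_identical(conv_output_size(128, kernel = 2, stride = 2,
                                    padding = 0), 64L)   # (128-2)/2 + 1
  # dilation enlarges the effective kernel
  expect_identical(conv_output_size(64, kernel = 3, stride = 1, padding = 2,
                                    dilation = 2), 64L)
  expect_error(conv_output_size(2, kernel = 5, stride = 1, padding = 0),
               class = "msunet_geometry_error")
})

test_that("stacked dilated receptive fields follow the 3/7/15 progression", {
  p1 <- conv_plan(3, dilation = 1)
  p2 <- conv_plan(3, dilation = 2)
  p4 <- conv_plan(3, dilation = 4)
  expect_identical(stacked_receptive_field(list(p1)), 3L)
  expect_identical(stacked_receptive_field(list(p1, p2)), 7L)
  expect_identical(stacked_receptive_field(list(p1, p2, p4)), 15L)
  expect_identical(stacked_receptive_field(list(conv_plan(1))), 1L)
  expect_error(stacked_receptive_field(list()),
               class = "msunet_config_error")
  expect_error(stacked_receptive_field(list(conv_plan(3, stride = 2))),
               class = "msunet_config_error")
})

test_that("parameter counts match hand arithmetic", {
  expect_identical(count_parameters(conv_plan(1, in_channels = 1,
                                              out_channels = 16,
                                              has_bn = FALSE)), 32L)
  expect_identical(count_parameters(conv_plan(3, in_channels = 16,
                                              out_channels = 16,
                                              has_bn = FALSE)), 2320L)
  asym <- list(conv_plan(c(1, 3), in_channels = 1, out_channels = 16,
                         has_bn = FALSE),
               conv_plan(c(3, 1), in_channels = 16, out_channels = 16,
                         has_bn = FALSE))
  expect_identical(sum(vapply(asym, count_parameters, 0L)), 848L)
})

test_that("plan parameter counts equal the engine's allocated trainable counts", {
  cases <- list(list(k = c(3, 3), d = 1, i = 4, o = 8),
                list(k = c(1, 5), d = 1, i = 1, o = 16),
                list(k = c(3, 3), d = 4, i = 2, o = 2),
                list(k = c(2, 2), d = 1, i = 8, o = 8))
  for (cs in cases) {
    plan <- conv_plan(cs$k, dilation = cs$d, in_channels = cs$i,
                      out_channels = cs$o, has_bn = TRUE)
    layer <- msunet:::layer_conv(cs$i, cs$o, cs$k, dilation = cs$d)
    bn <- msunet:::layer_bn(cs$o)
    expect_identical(count_parameters(plan),
                     count_parameters(layer) + count_parameters(bn))
  }
})

test_that("the stem concatenates five equal-size branches and keeps spatial size", {
  set.seed(1)
  stem <- build_stem(branch_width = 4, post_conv_width = 8)
  x <- array(rnorm(32 * 32), dim = c(32, 32, 1))
  branch_outs <- lapply(stem$branches, function(b)
    msunet:::forward_seq(b, x)$out)
  for (bo in branch_outs) expect_identical(dim(bo), c(32L, 32L, 4L))
  cat_out <- do.call(msunet:::concat_channels, branch_outs)
  expect_identical(dim(cat_out), c(32L, 32L, 20L))   # 5 x branch_width
  r <- msunet:::forward_stem(stem, x)
  expect_identical(dim(r$out), c(32L, 32L, 8L))      # post_conv_width
})

test_that("conv, deconv and decoder-head blocks follow the channel plan", {
  set.seed(2)
  cb <- build_conv_block(8, 16)
  x <- array(rnorm(16 * 16 * 8), dim = c(16, 16, 8))
  expect_identical(dim(msunet:::forward_seq(cb, x)$out), c(16L, 16L, 16L))

  db <- build_deconv_block(64, 32, 32)
  bottom <- array(rnorm(8 * 8 * 64), dim = c(8, 8, 64))
  skip <- array(rnorm(16 * 16 * 32), dim = c(16, 16, 32))
  r <- msunet:::forward_deconv_block(db, bottom, skip)
  expect_identical(dim(r$out), c(16L, 16L, 32L))   # spatial x2, channels /2

  head <- build_decoder_head(32)
  h <- array(rnorm(8 * 8 * 32), dim = c(8, 8, 32))
  expect_identical(dim(msunet:::forward_seq(head, h)$out), c(16L, 16L, 16L))

  expect_error(build_deconv_block(64, 16, 32), class = "msunet_config_error")
})

test_that("formula receptive fields equal empirically measured support widths", {
  stacks <- list(
    list(conv_plan(3, dilation = 1)),
    list(conv_plan(3, dilation = 2)),
    list(conv_plan(3, dilation = 4)),
    list(conv_plan(c(1, 3)), conv_plan(c(3, 1))),
    list(conv_plan(3, dilation = 1), conv_plan(3, dilation = 2)),
    list(conv_plan(3, dilation = 1), conv_plan(3, dilation = 2),
         conv_plan(3, dilation = 4)))
  for (plans in stacks) {
    expect_identical(measure_receptive_field(plans, input_size = 48),
                     stacked_receptive_field(plans))
  }
})

test_that("layer-by-layer size predictions match instantiated block shapes", {
  set.seed(3)
  plans <- list(conv_plan(3),                       # same-padded 3x3
                conv_plan(3, dilation = 2),         # same-padded dilated
                conv_plan(c(2, 2), stride = 2, padding = 0))
  size <- 32L
  x <- array(rnorm(32 * 32), dim = c(32, 32, 1))
  for (p in plans) {
    l <- msunet:::layer_conv(1, 1, p$kernel, p$stride, p$padding, p$dilation)
    out <- msunet:::layer_forward(l, x)$out
    size <- conv_output_size(size, p)
    expect_identical(dim(out)[1], size)
    x <- out
  }
})
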