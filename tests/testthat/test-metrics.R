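test_that("soft Dice loss matches hand-evaluated cases", {
  truth <- matrix(c(1L, 0L), 1, 2)
  expect_equal(dice_loss(truth, truth), 0, tolerance = 1e-6)
  disjoint <- matrix(c(0L, 1L), 1, 2)
  expect_equal(dice_loss(disjoint, truth), 1, tolerance = 1e-6)
  # worked two-pixel example: 1 - (2*0.5) / (0.25 + 0.25 + 1 + 0)
  pred <- matrix(c(0.5, 0.5), 1, 2)
  expect_equal(dice_loss(pred, truth), 1 - 1 / 1.5, tolerance = 1e-6)
})

test_that("Dice loss is permutation invariant and bounded", {
  set.seed(10)
  truth <- random_mask(8, 8)
  pred <- matrix(runif(64), 8, 8)
  l0 <- dice_loss(pred, truth)
  perm <- sample(64)
  expect_equal(dice_loss(matrix(pred[perm], 8, 8),
                         matrix(truth[perm], 8, 8)), l0)
  expect_gte(l0, 0); expect_lte(l0, 1)
  # empty-vs-empty is well defined
  z <- matrix(0L, 4, 4)
  expect_equal(dice_loss(z, z), 0)
})

test_that("the analytic Dice-loss gradient matches finite differences", {
  set.seed(11)
  truth <- random_mask(6, 6)
  pred <- matrix(runif(36, 0.05, 0.95), 6, 6)
  g <- msunet:::dice_loss_grad(pred, truth)
  for (idx in sample(36, 5)) {
    e <- 1e-6
    pp <- pred; pp[idx] <- pp[idx] + e
    pm <- pred; pm[idx] <- pm[idx] - e
    expect_equal(g[idx], (dice_loss(pp, truth) - dice_loss(pm, truth)) /
                   (2 * e), tolerance = 1e-5)
  }
})

test_that("overlap counts match a hand-enumerated grid", {
  # 4x4 grid: prediction covers 6 pixels, truth 4, overlapping on 3
  pred <- matrix(0L, 4, 4); truth <- matrix(0L, 4, 4)
  pred[1, 1:3] <- 1L; pred[2, 1:3] <- 1L         # 6 predicted
  truth[1, 3:4] <- 1L; truth[2, 2:3] <- 1L       # 4 true, overlap {13,22,23}
  oc <- overlap_counts(pred, truth)
  expect_identical(oc$tp, 3L); expect_identical(oc$fp, 3L)
  expect_identical(oc$fn, 1L); expect_identical(oc$tn, 9L)
  m <- compute_metrics(oc)
  expect_equal(m$dsc, 0.6)
  expect_equal(m$sen, 0.75)
  expect_equal(m$ppv, 0.5)
  expect_equal(m$iou, 3 / 7)
})

test_that("perfect and disjoint predictions hit the metric extremes", {
  set.seed(12)
  truth <- random_mask(8, 8, 0.4)
  perfect <- compute_metrics(truth, truth)
  expect_equal(c(perfect$dsc, perfect$sen, perfect$ppv, perfect$iou),
               c(1, 1, 1, 1))
  dis <- 1L - truth
  disjoint <- compute_metrics(dis, truth)
  expect_equal(c(disjoint$dsc, disjoint$sen, disjoint$ppv, disjoint$iou),
               c(0, 0, 0, 0))
})

test_that("empty-mask conventions are bounded and symmetric", {
  empty <- matrix(0L, 4, 4)
  some <- matrix(c(1L, rep(0L, 15)), 4, 4)
  both <- compute_metrics(empty, empty)
  expect_equal(c(both$dsc, both$sen, both$ppv, both$iou), c(1, 1, 1, 1))
  m1 <- compute_metrics(some, empty)    # empty truth, non-empty prediction
  expect_equal(m1$sen, 0); expect_equal(m1$dsc, 0)
  m2 <- compute_metrics(empty, some)    # empty prediction, non-empty truth
  expect_equal(m2$ppv, 0); expect_equal(m2$dsc, 0)
})

test_that("DSC identities hold over 1000 seeded random mask pairs", {
  set.seed(99)
  for (i in 1:1000) {
    pred <- random_mask(8, 8, runif(1, 0.1, 0.9))
    truth <- random_mask(8, 8, runif(1, 0.1, 0.9))
    m <- compute_metrics(pred, truth)
    expect_equal(m$dsc, 2 * m$iou / (1 + m$iou), tolerance = 1e-12)
    if (m$counts$tp > 0)
      expect_equal(m$dsc, 2 / (1 / m$sen + 1 / m$ppv), tolerance = 1e-12)
    # hard-prediction loss agrees with 1 - DSC up to the smoothing epsilon
    expect_equal(dice_loss(pred, truth), 1 - m$dsc, tolerance = 1e-5)
  }
})

test_that("incongruent or non-binary inputs are rejected", {
  expect_error(overlap_counts(matrix(0L, 2, 2), matrix(0L, 2, 3)),
               class = "msunet_congruence_error")
  expect_error(dice_loss(matrix(0.5, 2, 2), matrix(2L, 2, 2)),
               class = "msunet_label_error")
  expect_error(dice_loss(matrix(1.5, 2, 2), matrix(1L, 2, 2)),
               class = "msunet_label_error")
})

test_that("evaluate_pairs reports per-case rows plus a mean aggregate", {
  set.seed(13)
  truths <- lapply(1:3, function(i) random_mask(8, 8))
  preds <- truths
  preds[[2]] <- random_mask(8, 8)
  tab <- evaluate_pairs(preds, truths)
  expect_identical(nrow(tab), 4L)
  expect_identical(tab$case[4], "mean")
  expect_equal(tab$dsc[1], 1)
  expect_equal(tab$dsc[4], mean(tab$dsc[1:3]))
})
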