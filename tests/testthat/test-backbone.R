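test_that("removability is exactly stride-1 with equal widths", {
  expect_true(uib_spec(32L, 32L, 2, 1L)$removable)
  expect_false(uib_spec(32L, 32L, 2, 2L)$removable)
  expect_false(uib_spec(32L, 64L, 2, 1L)$removable)
})

test_that("parameter counts follow the closed form and hit the pinned budgets", {
  # one conv layer contributes k^2*cin*cout + cout (bias) + 2*cout (affine)
  s1 <- backbone_spec(8L, list(uib_spec(8L, 8L, 2, 1L)), 16L, 32L)
  s2 <- backbone_spec(9L, list(uib_spec(9L, 9L, 2, 1L)), 16L, 32L)
  stem_diff <- (27 * 9 + 3 * 9) - (27 * 8 + 3 * 8)
  uib8 <- 8 * 16 + 3 * 16 + 12 * 16 + 16 * 8 + 3 * 8   # expand+mid+project
  uib9 <- 9 * 18 + 3 * 18 + 12 * 18 + 18 * 9 + 3 * 9
  head_diff <- (9 - 8) * 16                             # head input widens
  expect_equal(count_params(s2) - count_params(s1),
               stem_diff + uib9 - uib8 + head_diff)
  head16 <- 8 * 16 + 16 + 2 * 16
  expect_equal(count_params(s1), 30 * 8 + uib8 + head16)

  expect_equal(count_params(reference_backbone_spec("original")), 340992L)
  expect_equal(count_params(reference_backbone_spec("reduced")), 68880L)
})

test_that("exactly ten removable blocks are eliminated from the reference spec", {
  orig <- reference_backbone_spec("original")
  removable <- vapply(orig$blocks, function(b) b$removable, logical(1))
  expect_equal(sum(removable), 10L)
  red <- remove_uibs(orig, 10L)
  expect_equal(length(red$blocks), length(orig$blocks) - 10L)
  expect_false(any(vapply(red$blocks, function(b) b$removable, logical(1))))
  expect_identical(remove_uibs(orig, 0L), orig)
  expect_error(remove_uibs(red, 1L), "removable")
  # removing removable blocks never changes the head input width
  expect_equal(red$head$in_channels, orig$head$in_channels)
})

test_that("APoZ equals brute-force zero counting", {
  expect_equal(apoz(matrix(c(0, 0, 1, 2), 4, 1))$per_channel_apoz, 0.5)
  expect_equal(apoz(matrix(1, 5, 2))$per_channel_apoz, c(0, 0))
  expect_equal(apoz(matrix(0, 5, 2))$per_channel_apoz, c(1, 1))
  expect_error(apoz(matrix(0, 0, 2)), "empty")

  set.seed(2)
  a <- array(pmax(rnorm(4 * 6 * 10), 0), c(4, 6, 10))
  rep_ <- apoz(a)
  brute <- vapply(1:6, function(ch) mean(a[, ch, ] <= 0), numeric(1))
  expect_identical(rep_$per_channel_apoz, brute)
  expect_equal(rep_$calibration_count, 40L)
})

test_that("pruning keeps lowest-APoZ channels and shrinks parameters monotonically", {
  spec <- tiny_backbone_spec(8L, 64L)
  mk_rep <- function(v) structure(
    list(layer_id = "head", per_channel_apoz = v, calibration_count = 1L),
    class = "apoz_report")
  r <- mk_rep(c(0.9, 0.1, 0.5, 0.2, 0.3, 0.8, 0.05, 0.6))
  pruned <- prune_channels(spec, r, 2L)
  expect_equal(pruned$head$kept_channels, c(2L, 7L))
  expect_equal(pruned$feature_dim, 2L)
  keep_all <- prune_channels(spec, mk_rep(rep(0.1, 8)), 8L)
  expect_equal(keep_all$head$out_channels, 8L)
  # ties broken by ascending channel index
  t2 <- prune_channels(spec, mk_rep(rep(0.5, 8)), 3L)
  expect_equal(t2$head$kept_channels, 1:3)

  p2 <- count_params(prune_channels(spec, r, 2L))
  p5 <- count_params(prune_channels(spec, r, 5L))
  expect_lt(p2, p5)
  expect_lt(p5, count_params(spec))
  expect_error(prune_channels(spec, r, 0L), "positive")
})

test_that("feature extraction is a pure per-patch map", {
  bb <- build_backbone(tiny_backbone_spec(8L, 32L), seed = 3L)
  set.seed(4)
  x <- array(runif(5 * 32 * 32 * 3), c(5, 32, 32, 3))
  f <- extract_features(bb, x)
  expect_equal(dim(f), c(5L, 8L))

  xdup <- x[c(1, 1, 2, 3, 4), , , , drop = FALSE]
  fdup <- extract_features(bb, xdup)
  expect_equal(fdup[1, ], fdup[2, ], tolerance = 1e-12)

  perm <- c(3L, 5L, 1L, 2L, 4L)
  expect_equal(extract_features(bb, x[perm, , , , drop = FALSE]),
               f[perm, ], tolerance = 1e-10)

  expect_error(extract_features(bb, array(0, c(2, 16, 16, 3))), "input size")
  expect_error(extract_features(bb, array(0, c(2, 32, 32, 1))), "array")
})

test_that("APoZ calibration and pruning preserve outputs for dead channels", {
  bb <- build_backbone(tiny_backbone_spec(8L, 32L), seed = 6L)
  # kill two head channels: zero kernels and biases, so post-ReLU is zero
  dead <- c(2L, 5L)
  bb$params$head$w$value[, , , dead] <- 0
  bb$params$head$b$value[dead] <- 0
  bb$params$head$g$value[dead] <- 0
  bb$params$head$bt$value[dead] <- 0
  set.seed(7)
  calib <- array(runif(6 * 32 * 32 * 3), c(6, 32, 32, 3))
  rep_ <- apoz_calibrate(bb, calib)
  expect_equal(rep_$per_channel_apoz[dead], c(1, 1))
  pruned_spec <- prune_channels(bb$spec, rep_, 6L)
  expect_false(any(dead %in% pruned_spec$head$kept_channels))
  # removing exactly-dead channels leaves surviving feature columns intact
  feats <- extract_features(bb, calib)
  expect_true(all(abs(feats[, dead]) < 1e-12))
})
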