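test_that("the four reference configurations reproduce the published totals", {
  expect_identical(
    count_learnable_parameters(build_model(model_spec("two_view_2d", 18))),
    11475330L)
  expect_identical(
    count_learnable_parameters(build_model(model_spec("two_view_2d", 34))),
    21583490L)
  expect_identical(
    count_learnable_parameters(build_model(model_spec("resnet3d", 18))),
    33161986L)
  expect_identical(
    count_learnable_parameters(build_model(model_spec("resnet3d", 34))),
    63471618L)
})

test_that("the two-view model is lighter than the 3D baseline at equal depth", {
  for (d in c(18L, 34L)) {
    expect_lt(
      count_learnable_parameters(build_model(model_spec("two_view_2d", d))),
      count_learnable_parameters(build_model(model_spec("resnet3d", d))))
  }
})

test_that("the ConvSpec counting formula holds for the compression convolution", {
  expect_identical(conv_param_count(98L, 32L, 7L, ndim = 2L, bias = FALSE),
                   153664L)
  expect_identical(conv_param_count(98L, 32L, 7L, ndim = 2L, bias = TRUE),
                   153696L)
  expect_identical(conv_param_count(1L, 64L, 7L, ndim = 3L, bias = TRUE),
                   21952L + 64L)
  # agreement with an actually built layer
  conv <- ns$nn_conv(2L, 98L, 32L, 7L, 3L, 0L, bias = FALSE)
  expect_identical(length(conv$params$W), 153664L)
})

test_that("compress_view obeys the strided-convolution shape law", {
  cfg <- compression_config(per_view_in_channels = 4L)
  for (S in c(16L, 33L, 64L, 100L, 128L)) {
    x <- array(rnorm(4 * S * S), c(4, S, S))
    y <- compress_view(x, "h", cfg, seed = 1)
    expect_equal(dim(y), c(32L, conv_out_extent(S), conv_out_extent(S)))
  }
  expect_equal(conv_out_extent(100L), 32L)
  # the full-size default: a (98, 100, 100) folded view maps to (32, 32, 32)
  xfull <- array(rnorm(98 * 100 * 100), c(98, 100, 100))
  expect_equal(dim(compress_view(xfull, "h", compression_config(), seed = 3)),
               c(32L, 32L, 32L))
  # folded-axis mismatch is a shape error
  expect_error(compress_view(array(0, c(5, 20, 20)), "h", cfg),
               class = "wmh_shape_error")
})

test_that("compress_view output is non-negative and zero for zero weights", {
  cfg <- compression_config(per_view_in_channels = 10L)
  set.seed(7)
  x <- array(rnorm(30 * 10 * 30), c(30, 10, 30))  # fold w: extent 10
  y <- compress_view(x, "w", cfg, seed = 2)
  expect_gte(min(y), 0)
  zero_state <- list(W = array(0, c(7, 7, 10, 32)))
  y0 <- compress_view(x, "w", cfg, state = zero_state)
  expect_true(all(y0 == 0))
})

test_that("compress_view equals a direct-convolution oracle on tiny folded inputs", {
  # stride-1 config on a 3 x 8 x 8 volume folded along h
  cfg <- compression_config(kernel = 3L, stride = 1L, out_channels = 2L,
                            per_view_in_channels = 3L)
  set.seed(8)
  x <- array(rnorm(3 * 8 * 8), c(3, 8, 8))
  W <- array(rnorm(3 * 3 * 3 * 2), c(3, 3, 3, 2))
  st <- list(W = W)
  y <- compress_view(x, "h", cfg, state = st)
  xin <- array(aperm(x, c(2, 3, 1)), c(8, 8, 3, 1))
  ref <- brute_conv2d(xin, W, NULL, 1L, 0L)
  ref <- pmax(ref / sqrt(1 + 1e-5), 0)   # default BN stats, then ReLU
  expect_equal(y, aperm(ref[, , , 1], c(3, 1, 2)), tolerance = 1e-10)

  # flipping both spatial axes of the input flips the outputs (stride 1)
  xf <- x[, rev(seq_len(8)), rev(seq_len(8))]
  Wf <- W[rev(1:3), rev(1:3), , , drop = FALSE]
  yf <- compress_view(xf, "h", cfg, state = list(W = Wf))
  expect_equal(yf, y[, rev(seq_len(dim(y)[2])), rev(seq_len(dim(y)[3]))],
               tolerance = 1e-10)
})

test_that("fuse_views concatenates channels with view 1 first", {
  set.seed(9)
  y1 <- array(rnorm(32 * 5 * 5), c(32, 5, 5))
  y2 <- array(rnorm(32 * 5, 5), c(32, 5, 5))
  f <- fuse_views(y1, y2)
  expect_equal(dim(f), c(64, 5, 5))
  expect_identical(f[1:32, , ], y1)
  expect_identical(f[33:64, , ], y2)
  expect_false(identical(fuse_views(y1, y2), fuse_views(y2, y1)))
  expect_error(fuse_views(y1, array(0, c(32, 4, 5))),
               class = "wmh_shape_error")
})

test_that("both families emit two finite logits on cube inputs", {
  spec2 <- small_two_view_spec()
  m2 <- build_model(spec2, seed = 4)
  s <- generate_phantom(phantom_params(side = 24, easy = TRUE), "MS", 3)
  batch <- ns$make_batch(m2, list(s$mask$data))
  logits <- ns$model_forward(m2, batch, training = FALSE)
  expect_equal(dim(logits), c(2L, 1L))
  expect_true(all(is.finite(logits)))

  m3 <- build_model(model_spec("resnet3d", 18), seed = 4)
  s3 <- generate_phantom(phantom_params(side = 40, easy = TRUE), "NMOSD", 5)
  logits3 <- ns$model_forward(m3, ns$make_batch(m3, list(s3$mask$data)),
                              training = FALSE)
  expect_equal(dim(logits3), c(2L, 1L))
  expect_true(all(is.finite(logits3)))
})

test_that("forward_classify returns a normalized, deterministic probability pair", {
  m <- build_model(small_two_view_spec(), seed = 6)
  s <- generate_phantom(phantom_params(side = 24, easy = TRUE), "MS", 11)
  p1 <- forward_classify(m, s)
  p2 <- forward_classify(m, s)
  expect_equal(sum(p1), 1, tolerance = 1e-6)
  expect_identical(p1, p2)      # inference mode: no dropout
  expect_length(p1, 2)
  for (mode in c("flair", "masked_flair")) {
    pm <- forward_classify(m, s, input_mode = mode)
    expect_equal(sum(pm), 1, tolerance = 1e-6)
  }
})

test_that("model builds are deterministic in the seed", {
  a <- build_model(small_two_view_spec(), seed = 10)
  b <- build_model(small_two_view_spec(), seed = 10)
  expect_identical(ns$layer_state(a$net), ns$layer_state(b$net))
  c <- build_model(small_two_view_spec(), seed = 11)
  expect_false(identical(ns$layer_state(a$net), ns$layer_state(c$net)))
})

test_that("pretrained backbone loading copies stages and nothing else", {
  target <- build_model(small_two_view_spec(), seed = 1)
  donor <- build_model(small_two_view_spec(), seed = 2)
  src <- backbone_weights(donor)
  before_branch <- target$net$children$branch_h$children$conv$params$W
  before_fc <- target$net$children$fc$params$W
  target <- load_pretrained_backbone(target, src)
  after <- backbone_weights(target)
  # stage weights equal the source bit-for-bit
  expect_identical(after, src)
  # compression branches and head untouched
  expect_identical(target$net$children$branch_h$children$conv$params$W,
                   before_branch)
  expect_identical(target$net$children$fc$params$W, before_fc)
})

test_that("depth-mismatched or malformed weight sources are rejected", {
  m18 <- build_model(small_two_view_spec(18), seed = 1)
  donor34 <- build_model(small_two_view_spec(34), seed = 2)
  expect_error(load_pretrained_backbone(m18, backbone_weights(donor34)),
               class = "wmh_transfer_error")
  # shape conflict on one array
  src <- backbone_weights(build_model(small_two_view_spec(18), seed = 3))
  src[["layer1.0.conv1.W"]] <- array(0, c(3, 3, 64, 32))
  expect_error(load_pretrained_backbone(m18, src),
               class = "wmh_transfer_error")
  expect_error(load_pretrained_backbone(m18, "/no/such/file.rds"),
               class = "wmh_io_error")
  m3d <- build_model(model_spec("resnet3d", 18), seed = 1)
  expect_error(load_pretrained_backbone(m3d, src),
               class = "wmh_validation_error")
})

test_that("checkpoints round-trip through save_model/load_model", {
  dir <- withr::local_tempdir()
  m <- build_model(small_two_view_spec(), seed = 13)
  m$classes <- c("MS", "NMOSD")
  path <- file.path(dir, "model.rds")
  save_model(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  m2 <- load_model(path)
  expect_identical(ns$layer_state(m2$net), ns$layer_state(m$net))
  expect_identical(m2$classes, c("MS", "NMOSD"))
  s <- generate_phantom(phantom_params(side = 24, easy = TRUE), "MS", 3)
  expect_identical(forward_classify(m, s), forward_classify(m2, s))
})
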