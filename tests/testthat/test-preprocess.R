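test_that("crop kernel is the tightest box over foreground voxels", {
  # forced case: block of ones on [10,20) x [5,15) x [0,8)
  a <- array(0, c(30, 25, 20))
  a[11:20, 6:15, 1:8] <- 1
  v <- volume(a, modality = "flair")
  k <- compute_crop_kernel(v, 0)
  expect_equal(k$lo, c(10L, 5L, 0L))
  expect_equal(k$hi, c(20L, 15L, 8L))

  # noise below threshold plus a bright block; oracle = exhaustive scan
  set.seed(4)
  b <- array(runif(30 * 25 * 20, 0, 0.05), c(30, 25, 20))
  b[13:18, 3:9, 5:11] <- b[13:18, 3:9, 5:11] + 1
  vb <- volume(b, modality = "flair")
  kb <- compute_crop_kernel(vb, 0.1)
  idx <- which(b > 0.1, arr.ind = TRUE)
  expect_equal(kb$lo, as.integer(apply(idx, 2, min)) - 1L)
  expect_equal(kb$hi, as.integer(apply(idx, 2, max)))

  expect_error(compute_crop_kernel(volume(array(0, c(4, 4, 4))), 0),
               class = "wmh_no_foreground")
})

test_that("apply_crop copies the selected box and reuses across modalities", {
  v <- tiny_flair(c(30, 25, 20), lo = c(10, 5, 0), hi = c(20, 15, 8))
  k <- crop_kernel(c(10, 5, 0), c(20, 15, 8))
  out <- apply_crop(v, k)
  expect_equal(dim(out), c(10, 10, 8))
  expect_true(all(out$data == 5))
  expect_equal(out$spacing, v$spacing)

  # full-volume kernel is the identity
  kfull <- crop_kernel(c(0, 0, 0), dim(v))
  expect_identical(apply_crop(v, kfull)$data, v$data)

  # same kernel on flair and mask gives equal shapes
  m <- tiny_mask(c(30, 25, 20), voxels = rbind(c(12, 7, 3)))
  expect_equal(dim(apply_crop(m, k)), dim(out))

  expect_error(apply_crop(tiny_flair(c(5, 5, 5), c(0, 0, 0), c(5, 5, 5)), k),
               class = "wmh_validation_error")
})

test_that("crop kernel computation is idempotent after cropping", {
  set.seed(11)
  a <- array(runif(20^3), c(20, 20, 20)) * (array(runif(20^3), c(20, 20, 20)) > 0.7)
  v <- volume(a, modality = "flair")
  k1 <- compute_crop_kernel(v, 0)
  cropped <- apply_crop(v, k1)
  k2 <- compute_crop_kernel(cropped, 0)
  expect_equal(k2$lo, c(0L, 0L, 0L))
  expect_equal(k2$hi, dim(cropped))
})

test_that("resize_to_cube hits the target shape for arbitrary inputs", {
  shapes <- list(c(224, 224, 160), c(37, 61, 101), c(16, 100, 40))
  for (sh in shapes) {
    v <- volume(array(2.5, sh), modality = "flair")
    out <- resize_to_cube(v, 20)
    expect_equal(dim(out), c(20, 20, 20))
    expect_true(all(abs(out$data - 2.5) < 1e-12))  # constant stays constant
  }
})

test_that("resize preserves identity at equal size and binarity for masks", {
  set.seed(2)
  a <- array(runif(10^3), c(10, 10, 10))
  v <- volume(a, modality = "flair")
  expect_identical(resize_to_cube(v, 10)$data, a)

  m <- tiny_mask(c(15, 11, 9),
                 voxels = which(array(runif(15 * 11 * 9) < 0.2,
                                      c(15, 11, 9)), arr.ind = TRUE))
  out <- resize_to_cube(m, 12)
  expect_true(all(out$data %in% c(0, 1)))
  expect_equal(out$modality, "wmh_mask")
  expect_error(resize_to_cube(m, 0), class = "wmh_validation_error")
})

test_that("normalize_intensity maps to [0,1] with the min-max formula", {
  a <- array(seq(10, 110, length.out = 4^3), c(4, 4, 4))
  v <- normalize_intensity(volume(a, modality = "flair"))
  expect_equal(v$data, (a - 10) / 100, tolerance = 1e-12)
  expect_equal(range(v$data), c(0, 1))
  cv <- normalize_intensity(volume(array(7, c(3, 3, 3)), modality = "flair"))
  expect_true(all(cv$data == 0))
})

test_that("augmentation transforms are paired, invertible and seeded", {
  s <- tiny_subject("aug1", "MS", side = 10)
  spec <- augment_spec(max_shift = 2, flip_axes = c("h", "w"),
                       n_per_subject = 5, seed = 3)
  out1 <- augment(s, spec)
  out2 <- augment(s, spec)
  expect_length(out1, 5)
  # determinism under the same seed
  for (i in seq_along(out1))
    expect_identical(out1[[i]]$flair$data, out2[[i]]$flair$data)
  # labels preserved; flair and mask get the same transform
  for (r in out1) {
    expect_equal(r$label, "MS")
    sh <- r$meta$shift
    # lesions are never created: every lesion voxel maps back to one
    expect_equal(sum(r$mask$data >= 0), length(r$mask$data))
    expect_lte(sum(r$mask$data), sum(s$mask$data))
  }
  expect_error(augment(s, augment_spec(max_shift = 10)),
               class = "wmh_validation_error")
})

test_that("flip is an involution and opposite shifts cancel on the interior", {
  s <- tiny_subject("alg", "NMOSD", side = 8)
  a <- s$flair$data
  flip_array <- ns$flip_array; shift_array <- ns$shift_array
  expect_identical(flip_array(flip_array(a, 1L), 1L), a)
  roundtrip <- shift_array(shift_array(a, c(1, 0, 0)), c(-1, 0, 0))
  expect_identical(roundtrip[1:7, , ], a[1:7, , ])   # interior restored
  expect_true(all(roundtrip[8, , ] == 0))            # boundary slab zeroed
})

test_that("augmented masks never gain lesion voxels under pure flips", {
  s <- tiny_subject("flp", "MS", side = 9)
  spec <- augment_spec(max_shift = 0, flip_axes = c("h", "w", "l"),
                       n_per_subject = 6, seed = 8)
  for (r in augment(s, spec)) {
    expect_equal(sum(r$mask$data), sum(s$mask$data))
    expect_true(all(r$mask$data %in% c(0, 1)))
  }
})

test_that("preprocess_subject runs crop-resize-normalize end to end", {
  set.seed(9)
  dims <- c(40, 36, 30)
  fl <- array(0, dims)
  fl[6:35, 4:33, 3:28] <- runif(30 * 30 * 26, 0.2, 1)
  mk <- array(0, dims); mk[15:18, 15:18, 10:12] <- 1
  s <- subject_record("pp", volume(fl, modality = "flair"),
                      volume(mk, modality = "wmh_mask"), "MS")
  out <- preprocess_subject(s, side = 20)
  expect_equal(dim(out$flair), c(20, 20, 20))
  expect_equal(dim(out$mask), c(20, 20, 20))
  expect_equal(range(out$flair$data), c(0, 1))
  expect_true(all(out$mask$data %in% c(0, 1)))
  expect_gt(sum(out$mask$data), 0)  # the lesion survived the pipeline
})
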