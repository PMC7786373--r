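# Shared fixtures: everything is generated in code at test time.

ns <- asNamespace("wmh2view")

# A small deterministic FLAIR-like volume with zero padding around a
# brighter interior block.
tiny_flair <- function(dims = c(12, 10, 8), lo = c(3, 2, 1), hi = c(9, 8, 6),
                       value = 5, id = "t1") {
  a <- array(0, dims)
  a[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2], (lo[3] + 1):hi[3]] <- value
  volume(a, spacing = c(1, 1, 2), subject_id = id, modality = "flair")
}

tiny_mask <- function(dims = c(12, 10, 8), voxels = rbind(c(5, 5, 4))) {
  a <- array(0, dims)
  a[voxels] <- 1
  volume(a, spacing = c(1, 1, 2), subject_id = "t1", modality = "wmh_mask")
}

tiny_subject <- function(id = "s1", label = "MS", side = 10) {
  set.seed(utf8ToInt(id)[1] + side)
  fl <- array(runif(side^3, 0.1, 1), rep(side, 3))
  mk <- array(as.numeric(runif(side^3) < 0.05), rep(side, 3))
  subject_record(id,
                 volume(fl, subject_id = id, modality = "flair"),
                 volume(mk, subject_id = id, modality = "wmh_mask"),
                 label)
}

# Direct (non-im2col) convolution oracle used to cross-check the GEMM path.
brute_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L) {
  d <- dim(x); k <- dim(w)[1]; Cin <- dim(w)[3]; Cout <- dim(w)[4]
  H <- d[1]; W <- d[2]; N <- d[4]
  xp <- array(0, c(H + 2 * pad, W + 2 * pad, Cin, N))
  xp[pad + 1:H, pad + 1:W, , ] <- x
  oH <- (H + 2 * pad - k) %/% stride + 1
  oW <- (W + 2 * pad - k) %/% stride + 1
  y <- array(0, c(oH, oW, Cout, N))
  for (n in 1:N) for (co in 1:Cout) for (ow in 1:oW) for (oh in 1:oH) {
    patch <- array(xp[(oh - 1) * stride + 1:k, (ow - 1) * stride + 1:k, , n],
                   c(k, k, Cin))
    y[oh, ow, co, n] <- sum(patch * array(w[, , , co], c(k, k, Cin))) +
      if (!is.null(b)) b[co] else 0
  }
  y
}

brute_conv3d <- function(x, w, b = NULL, stride = 1L, pad = 0L) {
  d <- dim(x); k <- dim(w)[1]; Cin <- dim(w)[4]; Cout <- dim(w)[5]
  H <- d[1]; W <- d[2]; L <- d[3]; N <- d[5]
  xp <- array(0, c(H + 2 * pad, W + 2 * pad, L + 2 * pad, Cin, N))
  xp[pad + 1:H, pad + 1:W, pad + 1:L, , ] <- x
  oH <- (H + 2 * pad - k) %/% stride + 1
  oW <- (W + 2 * pad - k) %/% stride + 1
  oL <- (L + 2 * pad - k) %/% stride + 1
  y <- array(0, c(oH, oW, oL, Cout, N))
  for (n in 1:N) for (co in 1:Cout) for (ol in 1:oL) for (ow in 1:oW)
    for (oh in 1:oH) {
      patch <- array(xp[(oh - 1) * stride + 1:k, (ow - 1) * stride + 1:k,
                        (ol - 1) * stride + 1:k, , n], c(k, k, k, Cin))
      y[oh, ow, ol, co, n] <- sum(patch * array(w[, , , , co],
                                                c(k, k, k, Cin))) +
        if (!is.null(b)) b[co] else 0
    }
  y
}

# Compact model used wherever a real (but cheap) two-view classifier is
# needed: phantoms of side 24, folded axes cropped to 22 channels.
small_two_view_spec <- function(depth = 18L) {
  model_spec("two_view_2d", depth,
             compression = compression_config(per_view_in_channels = 22L))
}

small_phantom_cohort <- function(n_per_class = 4, side = 24, seed = 99,
                                 easy = TRUE) {
  generate_cohort(phantom_params(side = side, easy = easy),
                  n_ms = n_per_class, n_nmosd = n_per_class, seed = seed)
}
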