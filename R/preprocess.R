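#' Foreground crop kernel
#'
#' Computes the tightest axis-aligned bounding box containing every voxel
#' strictly above `background_threshold`. The kernel is always computed on
#' the FLAIR volume and then reused, unchanged, on the paired lesion mask so
#' that both volumes are cropped identically. Indices are 0-based and
#' half-open: axis `a` keeps voxels `lo[a] <= i < hi[a]`.
#'
#' @param v a [volume] (normally the FLAIR volume).
#' @param background_threshold voxels with value strictly greater than this
#'   count as foreground. The default 0 treats exact-zero padding as
#'   background, which matches skull-stripped/registered exports.
#' @return A list of class `crop_kernel` with fields `lo` and `hi`
#'   (integer 3-vectors).
#' @export
compute_crop_kernel <- function(v, background_threshold = 0) {
  stopifnot(inherits(v, "volume"))
  fg <- which(v$data > background_threshold, arr.ind = TRUE)
  if (nrow(fg) == 0L)
    stop_wmh("wmh_no_foreground",
             "no voxel above threshold %g", background_threshold)
  lo <- as.integer(apply(fg, 2, min)) - 1L   # to 0-based
  hi <- as.integer(apply(fg, 2, max))        # half-open
  crop_kernel(lo, hi)
}

#' @rdname compute_crop_kernel
#' @param lo,hi integer 3-vectors, 0-based half-open bounds with
#'   `lo < hi` per axis.
#' @export
crop_kernel <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (length(lo) != 3L || length(hi) != 3L || any(lo < 0L) || any(lo >= hi))
    stop_wmh("wmh_validation_error", "invalid crop kernel bounds")
  structure(list(lo = lo, hi = hi), class = "crop_kernel")
}

#' Apply a crop kernel
#'
#' @param v a [volume].
#' @param k a `crop_kernel` valid for `dim(v)`.
#' @return The cropped [volume]; spacing and modality are unchanged and the
#'   output dimensions are `k$hi - k$lo`.
#' @export
apply_crop <- function(v, k) {
  stopifnot(inherits(v, "volume"), inherits(k, "crop_kernel"))
  d <- dim(v$data)
  if (any(k$hi > d))
    stop_wmh("wmh_validation_error",
             "crop kernel (hi=%s) out of bounds for volume %s",
             paste(k$hi, collapse = ","), paste(d, collapse = "x"))
  out <- v$data[(k$lo[1] + 1L):k$hi[1],
                (k$lo[2] + 1L):k$hi[2],
                (k$lo[3] + 1L):k$hi[3], drop = FALSE]
  volume(out, v$spacing, v$subject_id, v$modality)
}

# Linear or nearest resampling of one axis to n_out samples, with
# corner-aligned coordinates so that n_out == n_in is the identity.
resample_axis <- function(arr, axis, n_out, method = c("linear", "nearest")) {
  method <- match.arg(method)
  d <- dim(arr)
  n_in <- d[axis]
  if (n_out == n_in) return(arr)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = n_in)
  pos <- if (n_out > 1L) seq(0, n_in - 1, length.out = n_out) else (n_in - 1) / 2
  if (method == "nearest") {
    out <- m[round(pos) + 1L, , drop = FALSE]
  } else {
    i0 <- pmin(floor(pos), n_in - 1)
    t <- pos - i0
    i1 <- pmin(i0 + 1, n_in - 1)
    out <- m[i0 + 1L, , drop = FALSE] * (1 - t) +
      m[i1 + 1L, , drop = FALSE] * t
  }
  dn <- d; dn[axis] <- n_out
  aperm(array(out, dn[perm]), order(perm))
}

#' Resize a volume to an isotropic cube
#'
#' Mirrors the two-stage protocol of the preprocessing pipeline: every
#' `(w, l)` section is first resized in-plane, then the stack of sections is
#' resampled along `h`. Intensity volumes are interpolated linearly
#' (separable, i.e. bilinear in-plane); mask volumes use nearest-neighbour
#' sampling throughout and therefore remain strictly binary. Voxel spacing
#' is rescaled to preserve physical extent.
#'
#' @param v a [volume].
#' @param side target edge length in voxels (default 100).
#' @return A [volume] of dimensions `(side, side, side)`.
#' @export
resize_to_cube <- function(v, side = 100L) {
  stopifnot(inherits(v, "volume"))
  side <- as.integer(side)
  if (side < 1L)
    stop_wmh("wmh_validation_error", "side must be >= 1")
  method <- if (v$modality == "wmh_mask") "nearest" else "linear"
  d0 <- dim(v$data)
  out <- v$data
  out <- resample_axis(out, 2L, side, method)  # in-plane: w
  out <- resample_axis(out, 3L, side, method)  # in-plane: l
  out <- resample_axis(out, 1L, side, method)  # across sections: h
  volume(out, v$spacing * d0 / side, v$subject_id, v$modality)
}

#' Min-max intensity normalization
#'
#' Per-volume scaling of a FLAIR volume to `[0, 1]`; constant volumes map to
#' all zeros.
#'
#' @param v a [volume] with modality `"flair"`.
#' @return The rescaled [volume].
#' @export
normalize_intensity <- function(v) {
  stopifnot(inherits(v, "volume"))
  rng <- range(v$data)
  out <- if (rng[2] > rng[1]) (v$data - rng[1]) / (rng[2] - rng[1])
         else array(0, dim(v$data))
  volume(out, v$spacing, v$subject_id, v$modality)
}

#' Augmentation specification
#'
#' @param max_shift non-negative integer, maximum voxel shift per axis.
#' @param flip_axes character subset of `c("h","w","l")`; each listed axis
#'   is flipped independently with probability 1/2. The default flips only
#'   `w`, exploiting approximate left-right anatomical symmetry.
#' @param n_per_subject number of augmented copies per subject.
#' @param seed integer RNG seed.
#' @return A list of class `augment_spec`.
#' @export
augment_spec <- function(max_shift = 2L, flip_axes = "w",
                         n_per_subject = 4L, seed = 1L) {
  stopifnot(max_shift >= 0, n_per_subject >= 1,
            all(flip_axes %in% c("h", "w", "l")))
  structure(list(max_shift = as.integer(max_shift),
                 flip_axes = flip_axes,
                 n_per_subject = as.integer(n_per_subject),
                 seed = as.integer(seed)),
            class = "augment_spec")
}

shift_array <- function(a, sh) {
  # integer shift with zero fill; sh[i] > 0 moves content toward higher index
  d <- dim(a)
  out <- array(0, d)
  src <- dst <- vector("list", 3)
  for (i in 1:3) {
    if (abs(sh[i]) >= d[i]) return(out)
    if (sh[i] >= 0) {
      src[[i]] <- 1:(d[i] - sh[i]); dst[[i]] <- (1 + sh[i]):d[i]
    } else {
      src[[i]] <- (1 - sh[i]):d[i]; dst[[i]] <- 1:(d[i] + sh[i])
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

flip_array <- function(a, axes) {
  idx <- lapply(1:3, function(i) if (i %in% axes) rev(seq_len(dim(a)[i]))
                                 else seq_len(dim(a)[i]))
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Shift/flip augmentation of a subject
#'
#' Produces `n_per_subject` new records. Each applies one uniformly drawn
#' integer shift per axis in `[-max_shift, max_shift]` (vacated voxels are
#' zero-filled) and an independent coin-flip reflection on each axis in
#' `flip_axes`. FLAIR and mask receive exactly the same transform, so no
#' lesion voxel is ever created that was not present in the source mask.
#' Deterministic given `spec$seed`.
#'
#' @param s a [subject_record], already preprocessed to the cube shape.
#' @param spec an [augment_spec].
#' @return List of `n_per_subject` new [subject_record]s with ids
#'   `<id>_aug<k>`.
#' @export
augment <- function(s, spec) {
  stopifnot(inherits(s, "subject_record"), inherits(spec, "augment_spec"))
  d <- dim(s$flair$data)
  if (spec$max_shift >= min(d))
    stop_wmh("wmh_validation_error",
             "max_shift %d >= smallest volume dimension %d",
             spec$max_shift, min(d))
  axis_num <- c(h = 1L, w = 2L, l = 3L)
  set.seed(derive_seed(spec$seed, utf8ToInt(s$subject_id)))
  lapply(seq_len(spec$n_per_subject), function(k) {
    sh <- sample.int(2L * spec$max_shift + 1L, 3L, replace = TRUE) -
      spec$max_shift - 1L
    fl <- axis_num[spec$flip_axes][runif(length(spec$flip_axes)) < 0.5]
    tf <- function(a) shift_array(flip_array(a, fl), sh)
    subject_record(
      paste0(s$subject_id, "_aug", k),
      volume(tf(s$flair$data), s$flair$spacing, s$subject_id, "flair"),
      volume(tf(s$mask$data), s$mask$spacing, s$subject_id, "wmh_mask"),
      s$label,
      meta = c(s$meta, list(augmented_from = s$subject_id,
                            shift = sh, flipped_axes = unname(fl))))
  })
}

#' Full preprocessing of one subject
#'
#' Runs the standard pipeline: compute the foreground crop kernel on the
#' FLAIR volume, crop FLAIR and mask with that same kernel, resize both to a
#' `side`-voxel cube, and min-max normalize the FLAIR intensities.
#'
#' @param s a [subject_record] with raw volumes.
#' @param side cube edge length (default 100).
#' @param background_threshold passed to [compute_crop_kernel].
#' @return The preprocessed [subject_record].
#' @export
preprocess_subject <- function(s, side = 100L, background_threshold = 0) {
  stopifnot(inherits(s, "subject_record"))
  k <- compute_crop_kernel(s$flair, background_threshold)
  flair <- normalize_intensity(resize_to_cube(apply_crop(s$flair, k), side))
  mask <- resize_to_cube(apply_crop(s$mask, k), side)
  subject_record(s$subject_id, flair, mask, s$label,
                 meta = c(s$meta, list(crop_lo = k$lo, crop_hi = k$hi)))
}
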