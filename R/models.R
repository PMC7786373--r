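#' Compression block configuration
#'
#' The compression block folds one spatial axis of a 3D volume into the
#' channel axis of a single strided 2D convolution, followed by batch
#' normalization and ReLU. The published operating point uses a 7x7 kernel,
#' stride 3 and 32 output channels; with 100-voxel spatial extents this
#' yields `floor((100 - 7) / 3) + 1 = 32` output positions per axis. The
#' folded axis is center-cropped from 100 to 98 voxels before folding, so
#' the convolution sees 98 input channels; together with a bias-free
#' convolution and non-affine normalization this is the configuration whose
#' learnable-parameter totals match the published complexity table.
#'
#' @param kernel convolution kernel size (default 7).
#' @param stride convolution stride (default 3).
#' @param out_channels output channels per view (default 32).
#' @param per_view_in_channels extent of the folded axis, i.e. input
#'   channels of the per-view convolution (default 98).
#' @param conv_bias logical, add a bias to the per-view convolution
#'   (default `FALSE`).
#' @param norm_affine logical, learnable scale/shift in the per-view batch
#'   normalization (default `FALSE`).
#' @return A list of class `compression_config`.
#' @export
compression_config <- function(kernel = 7L, stride = 3L, out_channels = 32L,
                               per_view_in_channels = 98L,
                               conv_bias = FALSE, norm_affine = FALSE) {
  structure(list(kernel = as.integer(kernel), stride = as.integer(stride),
                 out_channels = as.integer(out_channels),
                 per_view_in_channels = as.integer(per_view_in_channels),
                 conv_bias = conv_bias, norm_affine = norm_affine),
            class = "compression_config")
}

#' Output extent of a strided valid convolution
#'
#' @param extent input spatial extent.
#' @param kernel,stride convolution geometry.
#' @return `floor((extent - kernel) / stride) + 1`.
#' @export
conv_out_extent <- function(extent, kernel = 7L, stride = 3L) {
  (extent - kernel) %/% stride + 1L
}

#' Learnable parameters of one convolution
#'
#' `kernel^d * in_channels * out_channels`, plus `out_channels` when the
#' convolution carries a bias.
#'
#' @param in_channels,out_channels channel counts.
#' @param kernel kernel size per spatial axis.
#' @param ndim 2 or 3 spatial dimensions.
#' @param bias logical.
#' @return Integer parameter count.
#' @export
conv_param_count <- function(in_channels, out_channels, kernel,
                             ndim = 2L, bias = FALSE) {
  as.integer(kernel^ndim * in_channels * out_channels +
               if (bias) out_channels else 0L)
}

#' Model specification
#'
#' @param family `"two_view_2d"` (compressed two-view 2D classifier) or
#'   `"resnet3d"` (conventional 3D residual baseline).
#' @param depth backbone depth, 18 or 34 layers.
#' @param num_classes number of output classes (default 2).
#' @param dropout_rate dropout before the final affine layer (default 0.15).
#' @param pretrained logical flag recorded with the spec; weights are
#'   loaded separately with [load_pretrained_backbone].
#' @param compression a [compression_config] (two-view family only).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(family = c("two_view_2d", "resnet3d"),
                       depth = 18L, num_classes = 2L, dropout_rate = 0.15,
                       pretrained = FALSE,
                       compression = compression_config()) {
  family <- match.arg(family)
  depth <- as.integer(depth)
  if (!depth %in% c(18L, 34L))
    stop_wmh("wmh_validation_error", "depth must be 18 or 34, got %d", depth)
  structure(list(family = family, depth = depth,
                 num_classes = as.integer(num_classes),
                 dropout_rate = dropout_rate, pretrained = pretrained,
                 compression = compression),
            class = "model_spec")
}

resnet_blocks_per_stage <- function(depth) {
  if (depth == 18L) c(2L, 2L, 2L, 2L) else c(3L, 4L, 6L, 3L)
}

build_backbone <- function(ndim, depth, conv_bias = FALSE,
                           down_bias = FALSE) {
  nb <- resnet_blocks_per_stage(depth)
  widths <- c(64L, 128L, 256L, 512L)
  stages <- list()
  in_ch <- 64L
  for (s in 1:4) {
    blocks <- list()
    for (b in seq_len(nb[s])) {
      stride <- if (s > 1L && b == 1L) 2L else 1L
      blocks[[sprintf("%d", b - 1L)]] <-
        nn_basic_block(ndim, in_ch, widths[s], stride,
                       conv_bias = conv_bias, down_bias = down_bias)
      in_ch <- widths[s]
    }
    stages[[paste0("layer", s)]] <- nn_sequential(blocks)
  }
  stages
}

#' Build a classifier model
#'
#' `two_view_2d`: two compression branches fold axes `h` and `w`
#' respectively (axis `l` is never folded); their 32-channel outputs are
#' concatenated into a 64-channel map that enters a standard 18/34-layer 2D
#' residual backbone at its first pooling stage -- the usual 7x7 stem
#' convolution and its normalization are omitted, which is exactly what
#' makes the fused map shape-compatible with the backbone's first residual
#' stage (and with pretrained backbone weights). Backbone convolutions are
#' bias-free with affine normalization; global average pooling, dropout and
#' a 2-unit affine output head follow.
#'
#' `resnet3d`: conventional 18/34-layer 3D residual network -- 7x7x7
#' single-channel stem convolution with bias, 3x3x3 bias-free block
#' convolutions, 1x1x1 downsample projections with bias, affine
#' normalization throughout, then pooling, dropout and the 2-unit head.
#'
#' Convolution weights are He-uniform initialized, biases zero; the build is
#' deterministic given `seed`.
#'
#' @param spec a [model_spec].
#' @param seed integer seed for weight initialization.
#' @return An object of class `wmh_model`.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  set.seed(as.integer(seed))
  cfg <- spec$compression
  if (spec$family == "two_view_2d") {
    branches <- lapply(c("branch_h", "branch_w"), function(nm)
      nn_sequential(list(
        conv = nn_conv(2L, cfg$per_view_in_channels, cfg$out_channels,
                       cfg$kernel, cfg$stride, 0L, bias = cfg$conv_bias),
        bn = nn_batchnorm(cfg$out_channels, affine = cfg$norm_affine),
        relu = nn_relu())))
    names(branches) <- c("branch_h", "branch_w")
    for (br in branches) br$children$conv$is_input <- TRUE
    root <- new_layer("two_view_net")
    root$children <- c(
      branches,
      list(maxpool = nn_maxpool(2L)),
      build_backbone(2L, spec$depth),
      list(gap = nn_gap(),
           dropout = nn_dropout(spec$dropout_rate),
           fc = nn_linear(512L, spec$num_classes, bias = TRUE)))
  } else {
    root <- new_layer("resnet3d_net")
    root$children <- c(
      list(stem = nn_conv(3L, 1L, 64L, 7L, 2L, 3L, bias = TRUE),
           bn1 = nn_batchnorm(64L, affine = TRUE),
           relu = nn_relu(),
           maxpool = nn_maxpool(3L)),
      build_backbone(3L, spec$depth, conv_bias = FALSE, down_bias = TRUE),
      list(gap = nn_gap(),
           dropout = nn_dropout(spec$dropout_rate),
           fc = nn_linear(512L, spec$num_classes, bias = TRUE)))
    root$children$stem$is_input <- TRUE
  }
  structure(list(spec = spec, net = root, seed = as.integer(seed),
                 classes = NULL), class = "wmh_model")
}

#' @export
print.wmh_model <- function(x, ...) {
  cat(sprintf("<wmh_model> %s depth %d, %s parameters\n", x$spec$family,
              x$spec$depth,
              format(count_learnable_parameters(x), big.mark = ",")))
  invisible(x)
}

# Forward through the trunk shared by both families (everything after the
# 64-channel map for two_view, or after input for resnet3d).
trunk_forward <- function(net, x, training) {
  for (nm in names(net$children)) {
    if (nm %in% c("branch_h", "branch_w")) next
    x <- ly_forward(net$children[[nm]], x, training)
  }
  x
}

trunk_backward <- function(net, dy) {
  for (nm in rev(names(net$children))) {
    if (nm %in% c("branch_h", "branch_w")) next
    dy <- ly_backward(net$children[[nm]], dy)
  }
  dy
}

# batch: for two_view, list(x1, x2) each (S, S, C, N); for resnet3d an
# array (H, W, L, 1, N). Returns logits (K, N).
model_forward <- function(model, batch, training = FALSE) {
  net <- model$net
  if (model$spec$family == "two_view_2d") {
    y1 <- ly_forward(net$children$branch_h, batch$x1, training)
    y2 <- ly_forward(net$children$branch_w, batch$x2, training)
    fused <- fuse_feature_maps(y1, y2)
    trunk_forward(net, fused, training)
  } else {
    trunk_forward(net, batch, training)
  }
}

model_backward <- function(model, dlogits) {
  net <- model$net
  dfused <- trunk_backward(net, dlogits)
  if (model$spec$family == "two_view_2d") {
    C1 <- dim(dfused)[3] / 2L
    ly_backward(net$children$branch_h,
                dfused[, , seq_len(C1), , drop = FALSE])
    ly_backward(net$children$branch_w,
                dfused[, , C1 + seq_len(C1), , drop = FALSE])
  }
  invisible(NULL)
}

# Channel concatenation of two (S1, S2, C, N) maps.
fuse_feature_maps <- function(y1, y2) {
  d1 <- dim(y1); d2 <- dim(y2)
  if (!all(d1[c(1, 2, 4)] == d2[c(1, 2, 4)]))
    stop_wmh("wmh_shape_error", "fused views must share spatial extents")
  out <- array(0, c(d1[1], d1[2], d1[3] + d2[3], d1[4]))
  out[, , seq_len(d1[3]), ] <- y1
  out[, , d1[3] + seq_len(d2[3]), ] <- y2
  out
}

#' Compress one view of a volume
#'
#' Folds `folded_axis` of a rank-3 array into the channel axis (so the
#' folded extent must equal `cfg$per_view_in_channels`), then applies the
#' compression block: one strided 2D convolution, batch normalization in
#' inference mode (stored statistics) and ReLU.
#'
#' @param x rank-3 numeric array indexed `(h, w, l)`.
#' @param folded_axis `"h"` or `"w"`.
#' @param cfg a [compression_config].
#' @param state optional named list with `W` (and `b`, `running_mean`,
#'   `running_var`, `gamma`, `beta`); defaults to a fresh He-uniform
#'   initialization with identity normalization, deterministic under `seed`.
#' @param seed seed for the default initialization.
#' @return Rank-3 array `(out_channels, h', w')`, channels first.
#' @export
compress_view <- function(x, folded_axis = c("h", "w"), cfg =
                            compression_config(), state = NULL, seed = 1L) {
  folded_axis <- match.arg(folded_axis)
  stopifnot(is.array(x), length(dim(x)) == 3L)
  d <- dim(x)
  ax <- if (folded_axis == "h") 1L else 2L
  if (d[ax] != cfg$per_view_in_channels)
    stop_wmh("wmh_shape_error",
             "folded axis extent %d != per_view_in_channels %d",
             d[ax], cfg$per_view_in_channels)
  sp <- d[-ax]
  if (any(sp < cfg$kernel))
    stop_wmh("wmh_shape_error", "spatial extents smaller than the kernel")
  xin <- if (ax == 1L) aperm(x, c(2, 3, 1)) else aperm(x, c(1, 3, 2))
  xin <- array(xin, c(dim(xin), 1L))
  branch <- nn_sequential(list(
    conv = nn_conv(2L, cfg$per_view_in_channels, cfg$out_channels,
                   cfg$kernel, cfg$stride, 0L, bias = cfg$conv_bias),
    bn = nn_batchnorm(cfg$out_channels, affine = cfg$norm_affine),
    relu = nn_relu()))
  set.seed(as.integer(seed))
  branch$children$conv$params$W <-
    he_uniform(dim(branch$children$conv$params$W),
               cfg$kernel^2 * cfg$per_view_in_channels)
  if (!is.null(state)) {
    if (!is.null(state$W)) branch$children$conv$params$W <- state$W
    if (!is.null(state$b)) branch$children$conv$params$b <- state$b
    if (!is.null(state$running_mean))
      branch$children$bn$buffers$running_mean <- state$running_mean
    if (!is.null(state$running_var))
      branch$children$bn$buffers$running_var <- state$running_var
    if (cfg$norm_affine && !is.null(state$gamma)) {
      branch$children$bn$params$gamma <- state$gamma
      branch$children$bn$params$beta <- state$beta
    }
  }
  y <- ly_forward(branch, xin, training = FALSE)
  aperm(array(y, dim(y)[1:3]), c(3, 1, 2))
}

#' Fuse two compressed views
#'
#' Channel-axis concatenation of two channels-first feature maps, view 1
#' first; values are copied unchanged, so order is significant.
#'
#' @param y1,y2 rank-3 arrays `(channels, h', w')` with equal spatial
#'   extents.
#' @return Rank-3 array with `channels(y1) + channels(y2)` channels.
#' @export
fuse_views <- function(y1, y2) {
  d1 <- dim(y1); d2 <- dim(y2)
  if (!all(d1[2:3] == d2[2:3]))
    stop_wmh("wmh_shape_error", "spatial extents differ: %s vs %s",
             paste(d1[2:3], collapse = "x"), paste(d2[2:3], collapse = "x"))
  out <- array(0, c(d1[1] + d2[1], d1[2], d1[3]))
  out[seq_len(d1[1]), , ] <- y1
  out[d1[1] + seq_len(d2[1]), , ] <- y2
  out
}

#' Count learnable parameters
#'
#' Sums the element counts of every trainable array in the model. Batch
#' normalization contributes its scale and shift only when affine; running
#' statistics are buffers and never counted.
#'
#' @param model a `wmh_model`.
#' @return Integer total.
#' @export
count_learnable_parameters <- function(model) {
  st <- layer_state(model$net, buffers = FALSE)
  sum(vapply(st, length, 0L))
}

#' Extract backbone weights for transfer
#'
#' Returns the named residual-stage arrays (`layer1..layer4`, parameters
#' and normalization running statistics) of a model, in the form accepted
#' by [load_pretrained_backbone]. A practitioner would fill such a list
#' from e.g. ImageNet-pretrained 2D weights exported from another
#' framework.
#'
#' @param model a `wmh_model`.
#' @return Named list of arrays.
#' @export
backbone_weights <- function(model) {
  st <- layer_state(model$net, buffers = TRUE)
  st[grepl("^layer[1-4]\\.", names(st))]
}

#' Load pretrained backbone weights
#'
#' Copies residual-stage weights (convolutions, normalization parameters
#' and running statistics) by name and shape into a two-view model's
#' backbone. Because the stem is omitted and the fused map natively carries
#' 64 channels, a standard 18/34-layer 2D residual network's stage weights
#' drop in without any adapter. Compression branches and the output head
#' are left untouched. The source must describe exactly the model's
#' backbone: missing arrays, extra stage arrays (e.g. a depth-34 source for
#' a depth-18 model) or any shape mismatch raise a transfer error naming
#' the offending array.
#'
#' @param model a `wmh_model` of family `two_view_2d`.
#' @param weight_source named list of arrays, or path to an RDS file
#'   containing one (names as in [backbone_weights]).
#' @return The model, with backbone weights replaced.
#' @export
load_pretrained_backbone <- function(model, weight_source) {
  stopifnot(inherits(model, "wmh_model"))
  if (model$spec$family != "two_view_2d")
    stop_wmh("wmh_validation_error",
             "pretrained loading applies to the two_view_2d family only")
  if (is.character(weight_source)) {
    if (!file.exists(weight_source))
      stop_wmh("wmh_io_error", "weight source not found: %s", weight_source)
    weight_source <- readRDS(weight_source)
  }
  src <- weight_source[grepl("^layer[1-4]\\.", names(weight_source))]
  leaves <- walk_layers(model$net)
  want <- names(layer_state(model$net, buffers = TRUE))
  want <- want[grepl("^layer[1-4]\\.", want)]
  missing <- setdiff(want, names(src))
  if (length(missing))
    stop_wmh("wmh_transfer_error", "weight source lacks: %s",
             paste(missing[seq_len(min(3, length(missing)))], collapse = ", "))
  extra <- setdiff(names(src), want)
  if (length(extra))
    stop_wmh("wmh_transfer_error",
             "weight source has arrays absent from this backbone (%s); depth mismatch?",
             paste(extra[seq_len(min(3, length(extra)))], collapse = ", "))
  for (nm in want) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    leaf_nm <- paste(parts[-length(parts)], collapse = ".")
    field <- parts[length(parts)]
    tgt <- leaves[[leaf_nm]]
    slot <- if (field %in% names(tgt$params)) "params" else "buffers"
    cur <- tgt[[slot]][[field]]
    new <- src[[nm]]
    if (!identical(dim(cur) %||% length(cur), dim(new) %||% length(new)))
      stop_wmh("wmh_transfer_error", "shape mismatch for %s", nm)
    # force a copy: the optimizer updates arrays in place and must never
    # touch the caller's weight source
    tgt[[slot]][[field]] <- new + 0
  }
  model
}

# Build per-family network input from a preprocessed subject cube.
subject_input_array <- function(s, input_mode = c("mask", "flair",
                                                  "masked_flair")) {
  input_mode <- match.arg(input_mode)
  switch(input_mode,
         mask = s$mask$data,
         flair = s$flair$data,
         masked_flair = s$flair$data * s$mask$data)
}

# Center-crop axis `ax` of cube x to n voxels.
center_crop_axis <- function(x, ax, n) {
  d <- dim(x)
  if (d[ax] < n)
    stop_wmh("wmh_shape_error", "axis %d extent %d < %d", ax, d[ax], n)
  start <- (d[ax] - n) %/% 2L
  idx <- lapply(seq_along(d), function(a)
    if (a == ax) start + seq_len(n) else seq_len(d[a]))
  x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# Assemble the two-view batch (list x1, x2) or 3D batch from cubes.
make_batch <- function(model, cubes) {
  N <- length(cubes)
  d <- dim(cubes[[1]])
  if (model$spec$family == "two_view_2d") {
    pv <- model$spec$compression$per_view_in_channels
    x1 <- array(0, c(d[2], d[3], pv, N))
    x2 <- array(0, c(d[1], d[3], pv, N))
    for (i in seq_len(N)) {
      x1[, , , i] <- aperm(center_crop_axis(cubes[[i]], 1L, pv), c(2, 3, 1))
      x2[, , , i] <- aperm(center_crop_axis(cubes[[i]], 2L, pv), c(1, 3, 2))
    }
    list(x1 = x1, x2 = x2)
  } else {
    x <- array(0, c(d, 1L, N))
    for (i in seq_len(N)) x[, , , 1L, i] <- cubes[[i]]
    x
  }
}

#' Classify one subject
#'
#' Runs the model in inference mode (dropout off, stored normalization
#' statistics) on a preprocessed subject and returns the softmax class
#' probabilities. For the two-view family, the two folded axes are
#' center-cropped to `per_view_in_channels` voxels first.
#'
#' @param model a `wmh_model`.
#' @param s a preprocessed [subject_record].
#' @param input_mode which volume feeds the network: the binary lesion mask
#'   (default), the raw FLAIR intensities, or the mask-restricted FLAIR.
#' @return Named numeric probability vector over the model's classes
#'   (names default to `class1`/`class2` for an untrained model), summing
#'   to 1.
#' @export
forward_classify <- function(model, s,
                             input_mode = c("mask", "flair",
                                            "masked_flair")) {
  stopifnot(inherits(model, "wmh_model"), inherits(s, "subject_record"))
  cube <- subject_input_array(s, input_mode)
  logits <- model_forward(model, make_batch(model, list(cube)),
                          training = FALSE)
  p <- as.numeric(softmax_ce(logits, 1L)$probs)
  names(p) <- model$classes %||%
    paste0("class", seq_len(model$spec$num_classes))
  p
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a named-array archive (RDS) holding every parameter
#' and buffer, with a JSON sidecar recording the model specification.
#'
#' @param model a `wmh_model`.
#' @param path output path for the archive; the sidecar gets `.json`
#'   appended.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  st <- layer_state(model$net, buffers = TRUE)
  saveRDS(list(state = st, classes = model$classes, seed = model$seed,
               spec = model$spec), path)
  side <- model$spec
  side$compression <- unclass(side$compression)
  jsonlite::write_json(unclass(side), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$spec, seed = ck$seed)
  leaves <- walk_layers(model$net)
  for (nm in names(ck$state)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    leaf_nm <- paste(parts[-length(parts)], collapse = ".")
    field <- parts[length(parts)]
    slot <- if (field %in% names(leaves[[leaf_nm]]$params)) "params"
            else "buffers"
    leaves[[leaf_nm]][[slot]][[field]] <- ck$state[[nm]]
  }
  model$classes <- ck$classes
  model
}
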