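# -- minimal convolutional network engine ------------------------------------
# 3x3 convolutions via im2col matrix products; residual blocks y = F(x) + x
# with zero-padded subsampled identity shortcuts at dimension changes;
# global average pooling -> feature standardization -> fully-connected ->
# softmax head. The pooled feature vector is standardized per channel with
# exponentially averaged running statistics (treated as constants in the
# backward pass), which conditions the head well enough to train from
# scratch without any batch-coupled normalization an image could leak
# through. Pure R: problem sizes here are desk scale (tens of filters,
# <= 224 px inputs). All gradients are verified against numerical
# differentiation in the test suite.

FEAT_EPS <- 1e-5

# patch matrix of x (H,W,C) for a 3x3 kernel, pad 1: rows = output pixels,
# columns in the flattening order of a (3,3,C,F) weight array
im2col3 <- function(x, stride) {
  h <- dim(x)[1]; w <- dim(x)[2]; cc <- dim(x)[3]
  xp <- array(0, c(h + 2, w + 2, cc))
  xp[2:(h + 1), 2:(w + 1), ] <- x
  i0 <- seq(1, h + 2 - 3 + 1, by = stride)
  j0 <- seq(1, w + 2 - 3 + 1, by = stride)
  ho <- length(i0); wo <- length(j0)
  p <- matrix(0, ho * wo, 9 * cc)
  t <- 0
  for (c_ in seq_len(cc)) for (kj in 1:3) for (ki in 1:3) {
    t <- t + 1
    p[, t] <- xp[i0 + ki - 1, j0 + kj - 1, c_]
  }
  list(p = p, ho = ho, wo = wo, i0 = i0, j0 = j0, in_dim = dim(x))
}

conv_fwd <- function(x, wt, b, stride) {
  ic <- im2col3(x, stride)
  f <- dim(wt)[4]
  out <- sweep(ic$p %*% matrix(wt, ncol = f), 2, b, "+")
  list(out = array(out, c(ic$ho, ic$wo, f)), cache = ic)
}

conv_bwd <- function(dout, wt, cache) {
  f <- dim(wt)[4]
  dmat <- matrix(dout, ncol = f)
  dw <- array(crossprod(cache$p, dmat), dim = dim(wt))
  db <- colSums(dmat)
  dp <- dmat %*% t(matrix(wt, ncol = f))
  h <- cache$in_dim[1]; w <- cache$in_dim[2]; cc <- cache$in_dim[3]
  dxp <- array(0, c(h + 2, w + 2, cc))
  t <- 0
  for (c_ in seq_len(cc)) for (kj in 1:3) for (ki in 1:3) {
    t <- t + 1
    dxp[cache$i0 + ki - 1, cache$j0 + kj - 1, c_] <-
      dxp[cache$i0 + ki - 1, cache$j0 + kj - 1, c_] +
      matrix(dp[, t], cache$ho, cache$wo)
  }
  list(dx = dxp[2:(h + 1), 2:(w + 1), , drop = FALSE], dw = dw, db = db)
}

# identity shortcut across a downsampling block: spatial subsampling plus
# zero padding of the new channels
shortcut_fwd <- function(x, stride, out_ch) {
  xs <- x[seq(1, dim(x)[1], by = stride), seq(1, dim(x)[2], by = stride), ,
          drop = FALSE]
  if (dim(xs)[3] < out_ch) {
    z <- array(0, c(dim(xs)[1], dim(xs)[2], out_ch))
    z[, , seq_len(dim(xs)[3])] <- xs
    xs <- z
  }
  xs
}

shortcut_bwd <- function(dout, in_dim, stride) {
  dx <- array(0, in_dim)
  dx[seq(1, in_dim[1], by = stride), seq(1, in_dim[2], by = stride), ] <-
    dout[, , seq_len(in_dim[3]), drop = FALSE]
  dx
}

he_init <- function(fan_in, dims) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dim = dims)
}

new_block <- function(in_ch, out_ch, stride) {
  list(w1 = he_init(9 * in_ch, c(3, 3, in_ch, out_ch)), b1 = rep(0, out_ch),
       w2 = he_init(9 * out_ch, c(3, 3, out_ch, out_ch)), b2 = rep(0, out_ch),
       stride = as.integer(stride), in_ch = in_ch, out_ch = out_ch)
}

#' Build a small residual network
#'
#' A compact residual backbone honoring the block identity y = F(x) + x:
#' a 3x3 stem convolution, stages of two-convolution residual blocks,
#' stride-2 downsampling blocks with filter doubling and zero-padded
#' identity shortcuts at the dimension changes, then global average
#' pooling, per-channel feature standardization (running statistics), a
#' fully-connected layer and a softmax over the classes. Depth and width
#' are configurable; the default is far shallower than an 18-layer network
#' so it trains from scratch on a single CPU.
#'
#' @param input_size spatial input `c(rows, cols)`.
#' @param widths filter counts per stage; each later stage halves the
#'   spatial resolution.
#' @param blocks_per_stage identity residual blocks per stage.
#' @param n_classes output classes (softmax width).
#' @param stem_stride stride of the stem convolution (2 halves resolution at
#'   the input; 1 keeps it, useful for small images).
#' @param in_channels input channels (3 for replicated grayscale).
#' @return object of class `resnet_small`.
#' @export
build_backbone <- function(input_size = c(224L, 224L), widths = c(8L, 16L),
                           blocks_per_stage = 1L, n_classes = 2L,
                           stem_stride = 2L, in_channels = 3L) {
  if (length(widths) < 1 || any(widths < 1) || blocks_per_stage < 1)
    stop("construction error: invalid width/depth configuration")
  final <- min(input_size) / (stem_stride * 2^(length(widths) - 1))
  if (final < 2)
    stop("construction error: input too small for the configured depth")
  blocks <- list()
  in_ch <- widths[1]
  for (s in seq_along(widths)) {
    if (s > 1) {
      blocks[[length(blocks) + 1]] <- new_block(in_ch, widths[s], 2L)
      in_ch <- widths[s]
    }
    for (b in seq_len(blocks_per_stage))
      blocks[[length(blocks) + 1]] <- new_block(in_ch, in_ch, 1L)
  }
  nf <- widths[length(widths)]
  structure(list(
    stem = list(w = he_init(9 * in_channels, c(3, 3, in_channels, widths[1])),
                b = rep(0, widths[1]), stride = as.integer(stem_stride)),
    blocks = blocks,
    head = list(m = rep(0, nf), v = rep(1, nf)),   # running feature stats
    # zero-initialized classifier: every fully-connected weight is learned
    # evidence, so class-activation maps carry no initialization noise
    fc = list(w = matrix(0, nf, n_classes), b = rep(0, n_classes)),
    input_size = as.integer(input_size), widths = as.integer(widths),
    n_classes = as.integer(n_classes)), class = "resnet_small")
}

# parameter names updated by the optimizer, per model part; the head's
# running statistics are state, not parameters
cnn_param_names <- function(part) {
  switch(part, stem = c("w", "b"), fc = c("w", "b"),
         block = c("w1", "b1", "w2", "b2"))
}

#' Number of trainable parameters
#' @param model a `resnet_small`.
#' @export
n_parameters <- function(model) {
  np <- sum(lengths(model$stem[cnn_param_names("stem")])) +
    sum(lengths(model$fc[cnn_param_names("fc")]))
  for (bl in model$blocks)
    np <- np + sum(lengths(bl[cnn_param_names("block")]))
  np
}

#' Forward pass
#'
#' @param model a `resnet_small`.
#' @param x input array `input_size x channels`.
#' @param keep_cache retain intermediates for the backward pass.
#' @return list with `probs` (softmax vector), `logits`, `gap` (pooled
#'   features before standardization), `features` (final convolutional
#'   maps), and `cache` when requested.
#' @export
forward_cnn <- function(model, x, keep_cache = FALSE) {
  caches <- if (keep_cache) list() else NULL
  st <- conv_fwd(x, model$stem$w, model$stem$b, model$stem$stride)
  z <- pmax(st$out, 0)
  if (keep_cache) caches$stem <- list(conv = st$cache, pre = st$out)
  for (i in seq_along(model$blocks)) {
    bl <- model$blocks[[i]]
    c1 <- conv_fwd(z, bl$w1, bl$b1, bl$stride)
    r1 <- pmax(c1$out, 0)
    c2 <- conv_fwd(r1, bl$w2, bl$b2, 1L)
    sc <- if (bl$stride == 1L && bl$in_ch == bl$out_ch) z
          else shortcut_fwd(z, bl$stride, bl$out_ch)
    pre <- c2$out + sc
    if (keep_cache)
      caches[[paste0("block", i)]] <- list(c1 = c1$cache, pre1 = c1$out,
                                           c2 = c2$cache, pre = pre,
                                           in_dim = dim(z))
    z <- pmax(pre, 0)
  }
  g <- apply(z, 3, mean)
  inv <- 1 / sqrt(model$head$v + FEAT_EPS)
  ghat <- (g - model$head$m) * inv
  logits <- as.vector(ghat %*% model$fc$w + model$fc$b)
  p <- exp(logits - max(logits))
  p <- p / sum(p)
  list(probs = p, logits = logits, gap = g, features = z,
       cache = if (keep_cache) c(caches, list(final = z, ghat = ghat,
                                              inv = inv)) else NULL)
}

# gradients of the cross-entropy loss w.r.t. all parameters for one image;
# y is the 1-based true class index. The head's running statistics are
# constants here by construction.
backward_cnn <- function(model, fw, y) {
  dlogit <- fw$probs
  dlogit[y] <- dlogit[y] - 1
  grads <- list(fc = list(w = outer(fw$cache$ghat, dlogit), b = dlogit))
  dg <- as.vector(model$fc$w %*% dlogit) * fw$cache$inv
  z <- fw$cache$final
  dz <- array(rep(dg, each = prod(dim(z)[1:2])) / prod(dim(z)[1:2]),
              dim = dim(z))
  for (i in rev(seq_along(model$blocks))) {
    bl <- model$blocks[[i]]
    ca <- fw$cache[[paste0("block", i)]]
    dpre <- dz * (ca$pre > 0)
    b2 <- conv_bwd(dpre, bl$w2, ca$c2)
    dr1 <- b2$dx * (ca$pre1 > 0)
    b1 <- conv_bwd(dr1, bl$w1, ca$c1)
    dsc <- if (bl$stride == 1L && bl$in_ch == bl$out_ch) dpre
           else shortcut_bwd(dpre, ca$in_dim, bl$stride)
    dz <- b1$dx + dsc
    grads[[paste0("block", i)]] <- list(w1 = b1$dw, b1 = b1$db,
                                        w2 = b2$dw, b2 = b2$db)
  }
  dstem <- dz * (fw$cache$stem$pre > 0)
  bs <- conv_bwd(dstem, model$stem$w, fw$cache$stem$conv)
  grads$stem <- list(w = bs$dw, b = bs$db)
  grads
}

#' Calibrate the head's feature standardization
#'
#' Computes the per-channel mean and variance of the pooled (GAP) feature
#' vector over a set of images and stores them in the model head. Done once
#' on the training images before optimization: the statistics are fixed
#' constants thereafter, so training has no moving normalization target and
#' inference is identical to training. Channels whose variance is dominated
#' by a between-class difference get amplified by the standardization, which
#' is what makes the head trainable from scratch.
#'
#' @param model a `resnet_small`.
#' @param xs list of input arrays (typically the training images).
#' @return the model with `head$m`, `head$v` set and `head$calibrated = TRUE`.
#' @export
calibrate_head <- function(model, xs) {
  gaps <- lapply(xs, function(xi) forward_cnn(model, xi)$gap)
  model$head$m <- Reduce(`+`, gaps) / length(gaps)
  model$head$v <- Reduce(`+`, lapply(gaps, function(g)
    (g - model$head$m)^2)) / length(gaps)
  model$head$calibrated <- TRUE
  model
}

# exponential tracking of the head statistics from one minibatch's pooled
# features, so the standardization follows slow feature drift during
# training; the update happens after the batch's forward/backward, so an
# image's own prediction never depends on its batch
FEAT_MOMENTUM <- 0.1

update_feature_stats <- function(model, gaps) {
  gm <- Reduce(`+`, gaps) / length(gaps)
  gv <- Reduce(`+`, lapply(gaps, function(g) (g - gm)^2)) / length(gaps)
  model$head$m <- (1 - FEAT_MOMENTUM) * model$head$m + FEAT_MOMENTUM * gm
  model$head$v <- (1 - FEAT_MOMENTUM) * model$head$v + FEAT_MOMENTUM * gv
  model
}

#' Class activation map
#'
#' Weighted sum of the final convolutional feature maps by the predicted
#' class's fully-connected weights — the standard localization readout of a
#' global-average-pooling head. The head's per-channel feature
#' standardization is a fixed affine map, so its scale factors are absorbed
#' into the channel weights (its shifts only offset the whole map, which
#' the final min-max scaling removes). Upsampled bilinearly to the input
#' spatial size and min-max scaled to \[0, 1\].
#'
#' @param model a `resnet_small` (must carry the GAP + FC head).
#' @param image preprocessed input array.
#' @param class optional 1-based class index; default = predicted class.
#' @param baseline optional reference feature maps (from
#'   [feature_map_baseline()]) subtracted from the image's feature maps
#'   before weighting. A deep pretrained backbone yields sparse high-level
#'   features for which the raw CAM is already image-specific; the compact
#'   from-scratch backbone's maps carry class-independent spatial structure,
#'   and subtracting the cohort-mean map localizes the image's own evidence.
#' @return matrix of the input spatial size, values in \[0, 1\]. A spatially
#'   constant map is returned as zeros with attribute `constant = TRUE`.
#' @export
class_activation_map <- function(model, image, class = NULL,
                                 baseline = NULL) {
  if (!inherits(model, "resnet_small") || is.null(model$fc))
    stop("unsupported-model error: needs a global-average-pooling head")
  fw <- forward_cnn(model, image)
  if (is.null(class)) class <- which.max(fw$probs)
  w <- model$fc$w[, class] / sqrt(model$head$v + FEAT_EPS)
  feats <- fw$features
  if (!is.null(baseline)) feats <- feats - baseline
  cam <- matrix(0, dim(feats)[1], dim(feats)[2])
  for (c_ in seq_len(dim(feats)[3])) cam <- cam + w[c_] * feats[, , c_]
  cam <- as.matrix(EBImage::resize(cam, w = dim(image)[1], h = dim(image)[2]))
  rng <- range(cam)
  if (rng[1] == rng[2])
    return(structure(matrix(0, nrow(cam), ncol(cam)), constant = TRUE))
  (cam - rng[1]) / (rng[2] - rng[1])
}

#' Cohort-mean feature maps for CAM baseline correction
#'
#' @param model a `resnet_small`.
#' @param xs list of input arrays (typically the training images).
#' @return array of the final convolutional map dimensions: the mean
#'   feature maps over `xs`.
#' @export
feature_map_baseline <- function(model, xs) {
  Reduce(`+`, lapply(xs, function(xi) forward_cnn(model, xi)$features)) /
    length(xs)
}
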