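#' Preprocess a slice for the network
#'
#' Min-max normalizes the intensity grid to \[0, 1\], resizes it (bilinear)
#' to the target spatial size, replicates it to 3 identical channels, and
#' re-anchors the range so the output spans exactly \[0, 1\].
#'
#' @param x 2D intensity matrix with `max(x) > min(x)`.
#' @param size integer `c(rows, cols)`, default 224 x 224.
#' @return array `size[1] x size[2] x 3` in \[0, 1\], channels identical.
#' @export
preprocess_slice <- function(x, size = c(224L, 224L)) {
  x <- as.matrix(x)
  rng <- range(x)
  if (rng[1] == rng[2])
    stop("degenerate-input error: constant image cannot be min-max scaled")
  x <- (x - rng[1]) / (rng[2] - rng[1])
  if (!all(dim(x) == size))
    x <- as.matrix(EBImage::resize(x, w = size[1], h = size[2]))
  rng <- range(x)
  x <- (x - rng[1]) / (rng[2] - rng[1])
  array(rep(x, 3), dim = c(dim(x), 3))
}

# reflect an index vector into [1, n] (mirror boundary)
reflect_index <- function(i, n) {
  if (n == 1) return(rep(1, length(i)))
  p <- 2 * (n - 1)
  i <- (i - 1) %% p
  i <- ifelse(i < 0, i + p, i)
  ifelse(i >= n, p - i, i) + 1
}

# bilinear sampling of `img` at the inverse affine map of the output grid:
# source = A %*% (out - center) + center + shift; reflection at borders
warp_bilinear <- function(img, A, shift = c(0, 0)) {
  h <- nrow(img); w <- ncol(img)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  oy <- matrix(seq_len(h), h, w) - cy
  ox <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  sy <- A[1, 1] * oy + A[1, 2] * ox + cy + shift[1]
  sx <- A[2, 1] * oy + A[2, 2] * ox + cx + shift[2]
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  g <- function(yy, xx) img[cbind(reflect_index(as.vector(yy), h),
                                  reflect_index(as.vector(xx), w))]
  v <- (1 - fy) * (1 - fx) * g(y0, x0) + (1 - fy) * fx * g(y0, x0 + 1) +
       fy * (1 - fx) * g(y0 + 1, x0) + fy * fx * g(y0 + 1, x0 + 1)
  matrix(v, h, w)
}

rotate_reflect <- function(img, angle_deg) {
  th <- angle_deg * pi / 180
  warp_bilinear(img, matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2))
}

zoom_reflect <- function(img, scale) {
  warp_bilinear(img, diag(2) / scale)
}

translate_reflect <- function(img, shift) {
  warp_bilinear(img, diag(2), shift = -shift)
}

#' Augmentation parameter ranges
#'
#' Defaults mirror the training protocol: rotation by a uniform angle in
#' \[-30, 30\] degrees, vertical flip with probability 0.5, zoom by a uniform
#' scale in \[0.9, 1.1\], and horizontal/vertical translation by a uniform
#' distance in \[-30, 30\] pixels.
#'
#' @param rotation,zoom,translation numeric `c(lo, hi)` ranges.
#' @param flip_prob vertical-flip probability.
#' @export
augment_ranges <- function(rotation = c(-30, 30), flip_prob = 0.5,
                           zoom = c(0.9, 1.1), translation = c(-30, 30)) {
  stopifnot(rotation[1] <= rotation[2], zoom[1] <= zoom[2], zoom[1] > 0,
            translation[1] <= translation[2],
            flip_prob >= 0, flip_prob <= 1)
  list(rotation = rotation, flip_prob = flip_prob, zoom = zoom,
       translation = translation)
}

#' Draw one set of augmentation parameters
#'
#' @param ranges an [augment_ranges()] list.
#' @return list with `angle` (degrees), `flip` (logical), `zoom` (scale),
#'   `shift` (`c(dy, dx)` pixels), drawn uniformly from the ranges using the
#'   session RNG.
#' @export
draw_augmentation <- function(ranges = augment_ranges()) {
  list(angle = stats::runif(1, ranges$rotation[1], ranges$rotation[2]),
       flip = stats::runif(1) < ranges$flip_prob,
       zoom = stats::runif(1, ranges$zoom[1], ranges$zoom[2]),
       shift = stats::runif(2, ranges$translation[1], ranges$translation[2]))
}

#' Randomly augment a preprocessed image
#'
#' One random draw of each transform, applied in the fixed order
#' rotation -> vertical flip -> zoom -> translation, with reflection padding
#' at the borders. All channels receive the identical transform; the label
#' is untouched. Parameters left `NULL` are drawn from `ranges` via
#' [draw_augmentation()] using the session RNG; passing explicit values
#' makes the call deterministic.
#'
#' @param img matrix or H x W x C array (channels transformed identically).
#' @param ranges an [augment_ranges()] list.
#' @param angle,flip,zoom,shift optional fixed draws (degrees; logical;
#'   scale; `c(dy, dx)` pixels).
#' @return augmented image, same shape as the input.
#' @export
augment_image <- function(img, ranges = augment_ranges(), angle = NULL,
                          flip = NULL, zoom = NULL, shift = NULL) {
  draw <- draw_augmentation(ranges)
  if (is.null(angle)) angle <- draw$angle
  if (is.null(flip)) flip <- draw$flip
  if (is.null(zoom)) zoom <- draw$zoom
  if (is.null(shift)) shift <- draw$shift
  one <- function(m) {
    if (angle != 0) m <- rotate_reflect(m, angle)
    if (flip) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
    if (zoom != 1) m <- zoom_reflect(m, zoom)
    if (any(shift != 0)) m <- translate_reflect(m, shift)
    m
  }
  if (length(dim(img)) == 3) {
    out <- img
    for (c in seq_len(dim(img)[3])) out[, , c] <- one(img[, , c])
    out
  } else one(img)
}
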