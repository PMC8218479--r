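test_that("preprocessing scales to [0,1], resizes, and replicates channels", {
  set.seed(1)
  x <- matrix(runif(48 * 48, 10, 200), 48)
  out <- preprocess_slice(x, c(32L, 32L))
  expect_equal(dim(out), c(32, 32, 3))
  expect_equal(min(out), 0)
  expect_equal(max(out), 1)
  expect_identical(out[, , 1], out[, , 2])
  expect_identical(out[, , 1], out[, , 3])
  up <- preprocess_slice(x, c(224L, 224L))
  expect_equal(dim(up), c(224, 224, 3))
  expect_error(preprocess_slice(matrix(5, 10, 10)), "degenerate-input")
})

test_that("augmentation draws stay inside the configured ranges", {
  set.seed(6)
  draws <- replicate(10000, unlist(draw_augmentation()), simplify = TRUE)
  expect_equal(mean(draws["flip", ]), 0.5, tolerance = 0.02)
  expect_true(all(draws["angle", ] >= -30 & draws["angle", ] <= 30))
  expect_true(all(draws["zoom", ] >= 0.9 & draws["zoom", ] <= 1.1))
  expect_true(all(abs(draws[c("shift1", "shift2"), ]) <= 30))
  # the angle draw actually explores the range
  expect_lt(min(draws["angle", ]), -25)
  expect_gt(max(draws["angle", ]), 25)
})

test_that("augmentation is deterministic under a fixed seed and identity at null draws", {
  set.seed(2)
  img <- preprocess_slice(matrix(runif(64 * 64), 64), c(32L, 32L))
  expect_identical(augment_image(img, angle = 0, flip = FALSE, zoom = 1,
                                 shift = c(0, 0)), img)
  set.seed(33); a <- augment_image(img)
  set.seed(33); b <- augment_image(img)
  expect_identical(a, b)
  expect_equal(dim(a), dim(img))
  # vertical flip alone reverses rows exactly
  flipped <- augment_image(img, angle = 0, flip = TRUE, zoom = 1,
                           shift = c(0, 0))
  expect_identical(flipped[, , 1], img[rev(seq_len(32)), , 1])
})

test_that("splits are stratified, leakage-free and reproducible", {
  y <- rep(c("ABE", "non-ABE"), each = 95)
  set.seed(12)
  sp <- make_splits(y, split_ratio = 0.8, folds = 5, split_unit = "slice")
  expect_length(sp$train, 152)
  expect_length(sp$test, 38)
  expect_equal(sort(unique(sp$fold)), 1:5)
  # subject-unit split keeps subjects on one side
  subj <- rep(sprintf("P%02d", 1:20), each = 2)
  ys <- rep(rep(c("ABE", "non-ABE"), each = 10), each = 2)
  set.seed(12)
  sps <- make_splits(ys, subj, split_unit = "subject")
  expect_length(intersect(subj[sps$train], subj[sps$test]), 0)
  set.seed(12)
  again <- make_splits(ys, subj, split_unit = "subject")
  expect_identical(sps, again)
  expect_error(make_splits(rep(c("ABE", "non-ABE"), c(3, 20)),
                           split_unit = "slice"), "split error")
})

test_that("backbone forward pass is a softmax over two classes", {
  set.seed(3)
  m <- build_backbone(c(32L, 32L), widths = c(4L, 8L))
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  fw <- forward_cnn(m, x)
  expect_length(fw$probs, 2)
  expect_equal(sum(fw$probs), 1)
  expect_true(all(fw$probs > 0))
  deeper <- build_backbone(c(32L, 32L), widths = c(4L, 8L),
                           blocks_per_stage = 2L)
  expect_gt(n_parameters(deeper), n_parameters(m))
  wider <- build_backbone(c(32L, 32L), widths = c(4L, 8L, 16L))
  expect_gt(n_parameters(wider), n_parameters(m))
  expect_error(build_backbone(c(8L, 8L), widths = c(4L, 8L, 16L, 32L)),
               "construction error")
})

test_that("a zeroed residual branch makes each identity block a no-op", {
  set.seed(4)
  m <- build_backbone(c(16L, 16L), widths = c(4L), stem_stride = 1L)
  for (i in seq_along(m$blocks)) {
    m$blocks[[i]]$w2[] <- 0
    m$blocks[[i]]$b2[] <- 0
  }
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  fw <- forward_cnn(m, x)
  # with F == 0 the final features equal the stem output exactly
  stem_out <- pmax(abeT1:::conv_fwd(x, m$stem$w, m$stem$b,
                                    m$stem$stride)$out, 0)
  expect_identical(fw$features, stem_out)
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(5)
  m <- build_backbone(c(8L, 8L), widths = c(2L, 3L), stem_stride = 1L,
                      in_channels = 1L)
  # non-trivial classifier and standardization state, so gradients reach
  # every layer
  m$fc$w[] <- rnorm(length(m$fc$w), 0, 0.5)
  m$head$m <- runif(3, -0.2, 0.2)
  m$head$v <- runif(3, 0.5, 2)
  x <- array(runif(64), c(8, 8, 1))
  fw <- forward_cnn(m, x, keep_cache = TRUE)
  gr <- abeT1:::backward_cnn(m, fw, 1L)
  loss_at <- function(mod) -log(forward_cnn(mod, x)$probs[1])
  eps <- 1e-6
  num_grad <- function(mutate) {
    (loss_at(mutate(eps)) - loss_at(mutate(-eps))) / (2 * eps)
  }
  # a few coordinates in every parameter family
  expect_equal(num_grad(function(d) { mm <- m; mm$fc$w[1, 1] <- mm$fc$w[1, 1] + d; mm }),
               gr$fc$w[1, 1], tolerance = 1e-5)
  expect_equal(num_grad(function(d) { mm <- m; mm$fc$b[2] <- mm$fc$b[2] + d; mm }),
               gr$fc$b[2], tolerance = 1e-5)
  expect_equal(num_grad(function(d) { mm <- m; mm$stem$w[2, 2, 1, 1] <- mm$stem$w[2, 2, 1, 1] + d; mm }),
               gr$stem$w[2, 2, 1, 1], tolerance = 1e-5)
  expect_equal(num_grad(function(d) { mm <- m; mm$stem$b[2] <- mm$stem$b[2] + d; mm }),
               gr$stem$b[2], tolerance = 1e-5)
  expect_equal(num_grad(function(d) { mm <- m; mm$blocks[[1]]$w1[1, 3, 1, 2] <- mm$blocks[[1]]$w1[1, 3, 1, 2] + d; mm }),
               gr$block1$w1[1, 3, 1, 2], tolerance = 1e-5)
  expect_equal(num_grad(function(d) { mm <- m; mm$blocks[[2]]$w2[3, 1, 2, 1] <- mm$blocks[[2]]$w2[3, 1, 2, 1] + d; mm }),
               gr$block2$w2[3, 1, 2, 1], tolerance = 1e-5)
  expect_equal(num_grad(function(d) { mm <- m; mm$blocks[[2]]$b1[3] <- mm$blocks[[2]]$b1[3] + d; mm }),
               gr$block2$b1[3], tolerance = 1e-5)
})

test_that("class activation maps obey the output contract", {
  set.seed(6)
  m <- build_backbone(c(32L, 32L), widths = c(4L, 8L))
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  # untrained classifier weights are zero: the map is a flagged constant
  cam0 <- class_activation_map(m, x)
  expect_true(attr(cam0, "constant"))
  expect_true(all(cam0 == 0))
  # with non-degenerate weights the map spans [0, 1] at image size
  m$fc$w[] <- rnorm(length(m$fc$w))
  cam <- class_activation_map(m, x)
  expect_equal(dim(cam), c(32, 32))
  expect_gte(min(cam), 0)
  expect_equal(min(cam), 0)
  expect_equal(max(cam), 1)
  expect_error(class_activation_map(list(), x), "unsupported-model")
})

test_that("cross-validated training returns one metric set per fold", {
  set.seed(30)
  cfg <- phantom_config(n_pos = 8, n_neg = 8,
                        slice_shape = c(64L, 64L), n_slices = 3L, seed = 30)
  ds <- generate_phantom_dataset(cfg)
  sl <- cnn_slice_dataset(ds$stacks, ds$records, input_size = c(32L, 32L),
                          slices_per_subject = 2L)
  expect_equal(length(sl$x), length(sl$y))
  expect_lte(max(table(sl$subject)), 2)
  res <- train_eval(sl, tiny_train_config(folds = 5L))
  expect_length(res$fold_metrics, 5)
  expect_s3_class(res$fold_metrics[[1]], "metric_set")
  expect_true("accuracy" %in% res$aggregate$metric)
  expect_true(all(is.finite(res$histories[[1]]$loss)))
  expect_s3_class(res$test_metrics, "metric_set")
})
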