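#' Training configuration for the residual-network protocol
#'
#' Defaults follow the study protocol: learning rate 0.0003, 6 epochs,
#' minibatch 10, SGD with momentum, 80/20 train/test split, fivefold
#' cross-validation, and the augmentation ranges of [augment_ranges()].
#' `split_unit = "subject"` keeps all slices of one subject on the same side
#' of every split (the slice-level mode mirrors a per-slice split and risks
#' leakage across slices of one patient).
#'
#' @param input_size spatial size images are preprocessed to.
#' @param learning_rate,max_epochs,minibatch,momentum optimizer settings.
#' @param weight_decay L2 penalty applied to convolution and fully-connected
#'   weights (not to bias parameters); the conventional SGDM solver
#'   default. Decay removes loss-flat weight directions, which keeps
#'   class-activation maps focused on discriminative evidence.
#' @param normalize_updates if `TRUE`, each parameter tensor's gradient is
#'   scaled to unit root-mean-square before the momentum update (layer-wise
#'   adaptive SGDM). Off by default (plain SGDM, the study protocol).
#' @param conv_lr_scale multiplier on the learning rate of the
#'   convolutional body relative to the classifier head (discriminative
#'   learning rates). The head's feature standardization amplifies
#'   gradients flowing into the convolutions by the inverse feature scale,
#'   so desk-scale from-scratch training uses a small body rate; 1 trains
#'   all layers at the same rate, 0 freezes the body (random convolutional
#'   features, trained head).
#' @param folds,split_ratio cross-validation folds and train fraction.
#' @param augment an [augment_ranges()] list, or `NULL` to disable
#'   augmentation.
#' @param widths,blocks_per_stage,stem_stride backbone shape
#'   (see [build_backbone()]).
#' @param split_unit `"subject"` or `"slice"`.
#' @param seed integer seed for split, initialization and training order.
#' @export
train_config <- function(input_size = c(224L, 224L), learning_rate = 3e-4,
                         max_epochs = 6L, minibatch = 10L, momentum = 0.9,
                         weight_decay = 1e-4, normalize_updates = FALSE,
                         conv_lr_scale = 1,
                         folds = 5L, split_ratio = 0.8,
                         augment = augment_ranges(),
                         widths = c(8L, 16L), blocks_per_stage = 1L,
                         stem_stride = 2L,
                         split_unit = c("subject", "slice"), seed = 1L) {
  split_unit <- match.arg(split_unit)
  if (folds < 2) stop("folds must be >= 2")
  if (split_ratio <= 0 || split_ratio >= 1) stop("split_ratio in (0,1)")
  structure(list(input_size = as.integer(input_size),
                 learning_rate = learning_rate, max_epochs = max_epochs,
                 minibatch = minibatch, momentum = momentum,
                 weight_decay = weight_decay,
                 normalize_updates = normalize_updates,
                 conv_lr_scale = conv_lr_scale, folds = folds,
                 split_ratio = split_ratio, augment = augment,
                 widths = widths, blocks_per_stage = blocks_per_stage,
                 stem_stride = stem_stride, split_unit = split_unit,
                 seed = seed), class = "train_config")
}

#' Stratified train/test split with cross-validation folds
#'
#' Splits at the configured unit (subject keeps all of a subject's slices
#' together), stratified by class, then partitions the training side into
#' folds, again stratified.
#'
#' @param labels per-item class labels.
#' @param subjects per-item subject ids (required for subject-unit splits).
#' @param split_ratio train fraction.
#' @param folds number of folds over the training set.
#' @param split_unit `"subject"` or `"slice"`.
#' @return list with integer item indices `train`, `test`, and `fold`
#'   (fold id per training item, parallel to `train`).
#' @export
make_splits <- function(labels, subjects = NULL, split_ratio = 0.8,
                        folds = 5L, split_unit = c("subject", "slice")) {
  split_unit <- match.arg(split_unit)
  labels <- as.character(labels)
  if (split_unit == "subject") {
    if (is.null(subjects)) stop("subject-unit split needs subject ids")
    units <- unique(subjects)
    ucls <- labels[match(units, subjects)]
  } else {
    units <- seq_along(labels)
    ucls <- labels
  }
  if (any(table(ucls) < folds))
    stop("split error: a class has fewer units than folds")
  train_units <- unlist(lapply(unique(ucls), function(k) {
    u <- units[ucls == k]
    sample(u, round(split_ratio * length(u)))
  }))
  if (split_unit == "subject") {
    train <- which(subjects %in% train_units)
    test <- which(!subjects %in% train_units)
    tr_units <- subjects[train]
  } else {
    train <- sort(as.integer(train_units))
    test <- setdiff(seq_along(labels), train)
    tr_units <- train
  }
  # fold ids assigned at the unit level, stratified by class
  uu <- unique(tr_units)
  uc <- labels[match(uu, if (split_unit == "subject") subjects
                         else seq_along(labels))]
  fold_of_unit <- integer(length(uu))
  for (k in unique(uc)) {
    idx <- sample(which(uc == k))
    fold_of_unit[idx] <- rep_len(seq_len(folds), length(idx))
  }
  names(fold_of_unit) <- uu
  list(train = train, test = test,
       fold = unname(fold_of_unit[as.character(tr_units)]))
}

#' Slice dataset for the network from a phantom cohort
#'
#' Selects the GP-covering central slices of each subject (two or three
#' contiguous slices, as in the clinical selection), preprocesses each to
#' the configured input size.
#'
#' @param stacks,records as returned by [generate_phantom_dataset()].
#' @param input_size passed to [preprocess_slice()].
#' @param slices_per_subject at most this many GP-covering slices per
#'   subject (centered on the largest cross-section).
#' @return list with `x` (list of arrays), `y` (labels), `subject` ids, and
#'   `slice_index` (0-based index of each slice in its subject's stack).
#' @export
cnn_slice_dataset <- function(stacks, records, input_size = c(64L, 64L),
                              slices_per_subject = 3L) {
  x <- list(); y <- character(); subject <- character()
  slice_index <- integer()
  for (id in records$subject_id) {
    st <- stacks[[id]]
    has_gp <- which(vapply(st, function(s) any(s$mask == 2L), TRUE))
    if (!length(has_gp)) next
    area <- vapply(st[has_gp], function(s) sum(s$mask == 2L), 0)
    keep <- has_gp[order(-area)][seq_len(min(slices_per_subject,
                                             length(has_gp)))]
    for (k in sort(keep)) {
      x[[length(x) + 1]] <- preprocess_slice(st[[k]]$intensity, input_size)
      y <- c(y, records$group[records$subject_id == id])
      subject <- c(subject, id)
      slice_index <- c(slice_index, st[[k]]$slice_index)
    }
  }
  list(x = x, y = y, subject = subject, slice_index = slice_index)
}

#' CAM localization experiment on GP-discriminative phantoms
#'
#' Generates a phantom cohort in which, after per-slice min-max
#' preprocessing, the two groups differ only inside the globus pallidus
#' (the STN ratio is fixed at the global intensity maximum in both groups so
#' the normalization anchor is class-independent), trains the network, and
#' scores class-activation-map localization: the fraction of correctly
#' classified positive (ABE) test slices whose baseline-corrected CAM
#' maximum falls inside that slice's GP mask. Non-ABE slices are excluded
#' from the localization score: the classes differ only by the presence of
#' the bright GP blob, and convolutional evidence for its absence is not
#' spatially localizable.
#'
#' The default configuration is the desk-scale setting selected for spatial
#' fidelity: full-resolution 128 x 128 slices, a single-stage stride-1
#' backbone (small receptive field, feature maps at image resolution), the
#' classifier head trained on standardized pooled features with the
#' convolutional body frozen, and the analysis slice with the largest GP
#' cross-section per subject.
#'
#' @param n_per_group subjects per group.
#' @param gp_ratios `c(positive, negative)` true GP ratios.
#' @param anchor_ratio STN ratio (both groups), the intensity maximum.
#' @param noise_cv voxel noise level.
#' @param config a [train_config()]; `NULL` uses the default above.
#' @param seed integer seed for phantom generation and training.
#' @return list with `test_accuracy`, `cam_hit_rate` (on correct positive
#'   test slices), `n_scored`, the trained `model`, and the `dataset`.
#' @export
cam_localization_experiment <- function(n_per_group = 30,
                                        gp_ratios = c(1.5, 1.0),
                                        anchor_ratio = 1.8,
                                        noise_cv = 0.01,
                                        config = NULL, seed = 42) {
  if (is.null(config))
    config <- train_config(input_size = c(128L, 128L), learning_rate = 0.2,
                           max_epochs = 6L, minibatch = 10L,
                           weight_decay = 0.01, conv_lr_scale = 0,
                           widths = c(16L), stem_stride = 1L,
                           augment = NULL, seed = seed)
  cfg <- phantom_config(
    n_pos = n_per_group, n_neg = n_per_group,
    ratio_params = list(
      ABE    = list(gp = c(mean = gp_ratios[1], sd = 0.03),
                    stn = c(mean = anchor_ratio, sd = 0.01)),
      nonABE = list(gp = c(mean = gp_ratios[2], sd = 0.03),
                    stn = c(mean = anchor_ratio, sd = 0.01))),
    noise_cv = noise_cv, slice_shape = config$input_size, n_slices = 7L,
    seed = seed)
  ds <- generate_phantom_dataset(cfg)
  sl <- cnn_slice_dataset(ds$stacks, ds$records,
                          input_size = config$input_size,
                          slices_per_subject = 1L)
  set.seed(config$seed)
  sp <- make_splits(sl$y, sl$subject, config$split_ratio, config$folds,
                    config$split_unit)
  fit <- train_cnn(sl$x[sp$train], sl$y[sp$train], config)
  pred <- predict_cnn(fit$model, sl$x[sp$test], fit$classes)
  base <- feature_map_baseline(fit$model, sl$x[sp$train])
  correct_pos <- sp$test[pred == sl$y[sp$test] & sl$y[sp$test] == "ABE"]
  hits <- vapply(correct_pos, function(i) {
    cam <- class_activation_map(fit$model, sl$x[[i]], baseline = base)
    mx <- which(cam == max(cam), arr.ind = TRUE)[1, ]
    msk <- ds$stacks[[sl$subject[i]]][[sl$slice_index[i] + 1]]$mask
    msk[mx[1], mx[2]] == 2L
  }, logical(1))
  list(test_accuracy = mean(pred == sl$y[sp$test]),
       cam_hit_rate = if (length(hits)) mean(hits) else NA_real_,
       n_scored = length(hits), model = fit$model, dataset = sl)
}

#' Train a small residual network by SGD with momentum
#'
#' Minibatch stochastic gradient descent with momentum on the cross-entropy
#' loss, with optional on-the-fly augmentation of each training image.
#'
#' @param x list of preprocessed input arrays.
#' @param y class labels (character or factor; 2 levels typical).
#' @param config a [train_config()].
#' @param model optional prebuilt `resnet_small` (otherwise built from the
#'   config).
#' @param classes optional fixed class-level ordering.
#' @return list with the trained `model`, `classes`, and `history` (data
#'   frame: iteration, epoch, loss, batch accuracy). A non-finite loss stops
#'   training with a divergence error carrying the history so far.
#' @export
train_cnn <- function(x, y, config = train_config(), model = NULL,
                      classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(as.character(y)))
  yi <- match(as.character(y), classes)
  if (anyNA(yi)) stop("labels outside the class set")
  if (is.null(model))
    model <- build_backbone(dim(x[[1]])[1:2], widths = config$widths,
                            blocks_per_stage = config$blocks_per_stage,
                            n_classes = length(classes),
                            stem_stride = config$stem_stride,
                            in_channels = dim(x[[1]])[3])
  if (is.null(model$head$calibrated)) model <- calibrate_head(model, x)
  vel <- rapply(model[c("stem", "blocks", "fc")],
                function(p) p * 0, how = "replace")
  head_only <- config$conv_lr_scale == 0
  hist <- list()
  iter <- 0
  for (ep in seq_len(config$max_epochs)) {
    ord <- sample(length(x))
    for (start in seq(1, length(ord), by = config$minibatch)) {
      batch <- ord[start:min(start + config$minibatch - 1, length(ord))]
      grads_sum <- NULL
      gaps <- list()
      loss <- 0; correct <- 0
      for (i in batch) {
        xi <- x[[i]]
        if (!is.null(config$augment)) xi <- augment_image(xi, config$augment)
        fw <- forward_cnn(model, xi, keep_cache = !head_only)
        loss <- loss - log(max(fw$probs[yi[i]], 1e-12))
        correct <- correct + (which.max(fw$probs) == yi[i])
        gaps[[length(gaps) + 1]] <- fw$gap
        g <- if (head_only) {
          # frozen body: only the classifier head receives gradients
          dlogit <- fw$probs
          dlogit[yi[i]] <- dlogit[yi[i]] - 1
          ghat <- (fw$gap - model$head$m) / sqrt(model$head$v + FEAT_EPS)
          list(fc = list(w = outer(ghat, dlogit), b = dlogit))
        } else backward_cnn(model, fw, yi[i])
        grads_sum <- if (is.null(grads_sum)) g else
          mapply(function(a, b) mapply(`+`, a, b, SIMPLIFY = FALSE),
                 grads_sum, g, SIMPLIFY = FALSE)
      }
      model <- update_feature_stats(model, gaps)
      iter <- iter + 1
      loss <- loss / length(batch)
      if (!is.finite(loss)) {
        cond <- simpleError("divergence error: non-finite training loss")
        cond$history <- do.call(rbind, hist)
        stop(cond)
      }
      hist[[iter]] <- data.frame(iteration = iter, epoch = ep, loss = loss,
                                 accuracy = correct / length(batch))
      # SGD momentum update, gradients averaged over the minibatch; L2
      # decay on weight tensors only (names starting with "w")
      step <- function(p, v, g, decay, lr) {
        if (lr == 0) return(list(p = p, v = v))
        g <- g / length(batch)
        if (isTRUE(config$normalize_updates))
          g <- g / (sqrt(mean(g^2)) + 1e-8)
        if (decay) g <- g + config$weight_decay * p
        v <- config$momentum * v - lr * g
        list(p = p + v, v = v)
      }
      body_lr <- config$learning_rate * config$conv_lr_scale
      for (part in c("stem", "fc")) {
        lr_part <- if (part == "fc") config$learning_rate else body_lr
        for (nm in cnn_param_names(part)) {
          s <- step(model[[part]][[nm]], vel[[part]][[nm]],
                    grads_sum[[part]][[nm]], startsWith(nm, "w"), lr_part)
          model[[part]][[nm]] <- s$p
          vel[[part]][[nm]] <- s$v
        }
      }
      for (bi in seq_along(model$blocks)) {
        gb <- grads_sum[[paste0("block", bi)]]
        for (nm in cnn_param_names("block")) {
          s <- step(model$blocks[[bi]][[nm]], vel$blocks[[bi]][[nm]],
                    gb[[nm]], startsWith(nm, "w"), body_lr)
          model$blocks[[bi]][[nm]] <- s$p
          vel$blocks[[bi]][[nm]] <- s$v
        }
      }
    }
  }
  list(model = model, classes = classes, history = do.call(rbind, hist))
}

predict_cnn <- function(model, x, classes) {
  vapply(x, function(xi) classes[which.max(forward_cnn(model, xi)$probs)],
         character(1))
}

#' Cross-validated training and evaluation
#'
#' Runs the full protocol on a slice dataset: stratified 80/20 train/test
#' split at the configured unit, k-fold cross-validation inside the training
#' set (train on k-1 folds, evaluate on the held-out fold), per-fold
#' diagnostic metrics, and their aggregate.
#'
#' @param dataset list with `x`, `y`, `subject` (see [cnn_slice_dataset()]).
#' @param config a [train_config()].
#' @param positive positive-class label for the metrics.
#' @return list with `fold_metrics` (list of `metric_set`), `aggregate`
#'   (mean +/- SD data frame), `histories`, `splits`, and `test_metrics`
#'   (a model trained on the full training set, evaluated on the held-out
#'   test set).
#' @export
train_eval <- function(dataset, config = train_config(), positive = "ABE") {
  set.seed(config$seed)
  sp <- make_splits(dataset$y, dataset$subject, config$split_ratio,
                    config$folds, config$split_unit)
  classes <- sort(unique(dataset$y))
  negative <- setdiff(classes, positive)
  fold_metrics <- list(); histories <- list()
  for (k in seq_len(config$folds)) {
    tr <- sp$train[sp$fold != k]
    va <- sp$train[sp$fold == k]
    fit <- train_cnn(dataset$x[tr], dataset$y[tr], config, classes = classes)
    pred <- predict_cnn(fit$model, dataset$x[va], fit$classes)
    cm <- confusion(pred, dataset$y[va], positive = positive,
                    negative = negative)
    fold_metrics[[k]] <- classification_metrics(cm)
    histories[[k]] <- fit$history
  }
  fit_all <- train_cnn(dataset$x[sp$train], dataset$y[sp$train], config,
                       classes = classes)
  pred_test <- predict_cnn(fit_all$model, dataset$x[sp$test], fit_all$classes)
  cm_test <- confusion(pred_test, dataset$y[sp$test], positive = positive,
                       negative = negative)
  # aggregate over the metrics defined in every fold (a degenerate fold can
  # leave e.g. precision undefined)
  common <- Reduce(intersect, lapply(fold_metrics, function(s)
    names(s$fractions)[!is.na(s$fractions)]))
  list(fold_metrics = fold_metrics,
       aggregate = aggregate_metrics(lapply(fold_metrics, function(s)
         s$fractions[common])),
       histories = histories, splits = sp, model = fit_all$model,
       classes = fit_all$classes,
       test_metrics = classification_metrics(cm_test))
}
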