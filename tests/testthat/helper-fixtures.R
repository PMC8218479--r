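# in-code fixtures shared across test files

# labeled slice with explicit grids
make_slice <- function(intensity, mask, id = "S001", idx = 0L) {
  structure(list(subject_id = id, slice_index = idx,
                 intensity = intensity,
                 mask = matrix(as.integer(mask), nrow(intensity))),
            class = "labeled_slice")
}

# slice whose three ROIs have known means: WM pixels = wm, GP = gp, STN = stn
make_roi_slice <- function(wm = 100, gp = 139, stn = 147, n_each = 25,
                           id = "S001", idx = 0L) {
  side <- ceiling(sqrt(3 * n_each + 1))
  intensity <- matrix(0, side, side)
  mask <- matrix(0L, side, side)
  cells <- seq_len(3 * n_each)
  mask[cells] <- rep(1:3, each = n_each)
  intensity[cells] <- rep(c(wm, gp, stn), each = n_each)
  make_slice(intensity, mask, id, idx)
}

# small, fast phantom configuration
tiny_config <- function(...) {
  phantom_config(n_pos = 3, n_neg = 2, slice_shape = c(64L, 64L),
                 n_slices = 5L, ...)
}

# fast training configuration for protocol tests (head-only, stable)
tiny_train_config <- function(...) {
  train_config(input_size = c(32L, 32L), learning_rate = 0.2,
               max_epochs = 1L, minibatch = 8L, weight_decay = 0.01,
               conv_lr_scale = 0, widths = c(4L),
               stem_stride = 2L, augment = NULL, seed = 1L, ...)
}
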