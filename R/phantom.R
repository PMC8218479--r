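#' Configuration for a synthetic phantom cohort
#'
#' Defaults reproduce the clinical study design this package emulates: 47 ABE
#' and 32 non-ABE hyperbilirubinemia neonates; subject-level true normalized
#' intensities GP 1.39 +/- 0.06 (ABE) vs 1.33 +/- 0.06 (non-ABE) and STN
#' 1.47 +/- 0.09 vs 1.42 +/- 0.07; clinical covariates matching the cohort
#' table; 18-slice axial stacks. Subject-level (biological) variation lives
#' in the cohort sampler; voxelwise measurement noise lives in the renderer.
#'
#' @param n_pos,n_neg subjects per group (ABE / non-ABE), both >= 1.
#' @param ratio_params nested list `group -> region -> c(mean, sd)` of the
#'   true normalized-intensity distributions, groups `ABE`/`nonABE`, regions
#'   `gp`/`stn`.
#' @param wm_mean baseline white-matter intensity, arbitrary units, > 0.
#' @param noise_cv voxel noise SD as a fraction of the local clean intensity.
#' @param n_slices slices per axial stack.
#' @param slice_shape integer `c(rows, cols)` of each slice.
#' @param covariate_params nested list `group -> covariate -> c(mean, sd)`
#'   plus `male_prop`; covariates: `age_days`, `weight_kg`,
#'   `gestational_age_weeks`, `tsb_umol_per_l`, `albumin_g_per_l`.
#' @param seed integer seed consumed by [generate_phantom_dataset()].
#' @return list of class `phantom_config`.
#' @export
phantom_config <- function(n_pos = 47, n_neg = 32,
                           ratio_params = list(
                             ABE    = list(gp = c(mean = 1.39, sd = 0.06),
                                           stn = c(mean = 1.47, sd = 0.09)),
                             nonABE = list(gp = c(mean = 1.33, sd = 0.06),
                                           stn = c(mean = 1.42, sd = 0.07))),
                           wm_mean = 100, noise_cv = 0.02,
                           n_slices = 18, slice_shape = c(128L, 128L),
                           covariate_params = list(
                             ABE = list(male_prop = 29 / 47,
                                        age_days = c(9.83, 3.05),
                                        weight_kg = c(3.21, 0.48),
                                        gestational_age_weeks = c(38.47, 1.58),
                                        tsb_umol_per_l = c(369.11, 114.78),
                                        albumin_g_per_l = c(38.34, 2.98)),
                             nonABE = list(male_prop = 23 / 32,
                                           age_days = c(12.15, 5.28),
                                           weight_kg = c(3.36, 0.43),
                                           gestational_age_weeks = c(38.38, 1.47),
                                           tsb_umol_per_l = c(326.13, 79.20),
                                           albumin_g_per_l = c(38.45, 3.21))),
                           seed = NULL) {
  cfg <- list(n_pos = n_pos, n_neg = n_neg, ratio_params = ratio_params,
              wm_mean = wm_mean, noise_cv = noise_cv, n_slices = n_slices,
              slice_shape = as.integer(slice_shape),
              covariate_params = covariate_params, seed = seed)
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  if (cfg$n_pos < 1 || cfg$n_neg < 1)
    stop("configuration error: both groups need at least one subject")
  sds <- c(vapply(cfg$ratio_params, function(g)
    c(g$gp[["sd"]], g$stn[["sd"]]), numeric(2)))
  means <- c(vapply(cfg$ratio_params, function(g)
    c(g$gp[["mean"]], g$stn[["mean"]]), numeric(2)))
  if (any(!is.finite(c(sds, means))) || any(sds < 0))
    stop("configuration error: ratio parameters must be finite with SD >= 0")
  if (!is.finite(cfg$noise_cv) || cfg$noise_cv < 0)
    stop("configuration error: noise_cv must be >= 0")
  if (!is.finite(cfg$wm_mean) || cfg$wm_mean <= 0)
    stop("configuration error: wm_mean must be > 0")
  if (cfg$n_slices < 1 || length(cfg$slice_shape) != 2)
    stop("configuration error: invalid stack geometry")
  invisible(cfg)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Sample a synthetic subject cohort
#'
#' Draws one record per subject: group label, sex, clinical covariates
#' (truncated to physiologic ranges; chronological age clamped to 1-18 days),
#' a BIND severity score carried as metadata only, and the true per-subject
#' normalized-intensity ratios that the renderer will paint into the phantom.
#' Uses the session RNG; seed via `set.seed()` or
#' [generate_phantom_dataset()].
#'
#' @param config a [phantom_config()].
#' @return data frame with `n_pos + n_neg` rows: `subject_id`, `group`
#'   (`"ABE"`/`"non-ABE"`), `sex`, covariates, `pma_weeks` (postmenstrual
#'   age = gestational age + chronological age), `bind_score`,
#'   `true_gp_ratio`, `true_stn_ratio`.
#' @export
sample_cohort <- function(config) {
  validate_phantom_config(config)
  one_group <- function(n, group_key, label, id0) {
    rp <- config$ratio_params[[group_key]]
    cp <- config$covariate_params[[group_key]]
    draw <- function(par, lo, hi) clamp(stats::rnorm(n, par[1], par[2]), lo, hi)
    age <- draw(cp$age_days, 1, 18)
    ga <- draw(cp$gestational_age_weeks, 34, 42)
    data.frame(
      subject_id = sprintf("S%03d", id0 + seq_len(n)),
      group = label,
      sex = ifelse(stats::runif(n) < cp$male_prop, "M", "F"),
      age_days = age,
      weight_kg = draw(cp$weight_kg, 1.5, 6),
      gestational_age_weeks = ga,
      tsb_umol_per_l = draw(cp$tsb_umol_per_l, 50, 700),
      albumin_g_per_l = draw(cp$albumin_g_per_l, 20, 55),
      pma_weeks = ga + age / 7,
      bind_score = if (label == "ABE") sample(1:9, n, replace = TRUE,
                                              prob = 9:1)
                   else 0L,
      true_gp_ratio = pmax(stats::rnorm(n, rp$gp[["mean"]], rp$gp[["sd"]]),
                           0.1),
      true_stn_ratio = pmax(stats::rnorm(n, rp$stn[["mean"]], rp$stn[["sd"]]),
                            0.1),
      stringsAsFactors = FALSE)
  }
  rbind(one_group(config$n_pos, "ABE", "ABE", 0),
        one_group(config$n_neg, "nonABE", "non-ABE", config$n_pos))
}

# logical ellipse on a grid; center/axes as fractions of the grid dims
ellipse_mask <- function(shape, center, axes) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c_ <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  ((r - center[1] * shape[1]) / (axes[1] * shape[1]))^2 +
    ((c_ - center[2] * shape[2]) / (axes[2] * shape[2]))^2 <= 1
}

# ROI layout, loosely mimicking an axial slice through the basal ganglia:
# anterior (low-row) white-matter reference, bilateral GP, bilateral STN
# slightly posterior and medial. `scale` shrinks ROIs off the central slice.
# Geometry depends only on (shape, scale), so it is memoized.
.roi_cache <- new.env(parent = emptyenv())

phantom_rois <- function(shape, scale = 1) {
  key <- paste(shape[1], shape[2], scale, sep = "x")
  hit <- .roi_cache[[key]]
  if (!is.null(hit)) return(hit)
  ax <- function(a) a * scale
  val <- list(
    brain = ellipse_mask(shape, c(0.5, 0.5), c(0.42, 0.36)),
    wm    = ellipse_mask(shape, c(0.27, 0.5), c(ax(0.07), ax(0.11))),
    gp    = ellipse_mask(shape, c(0.50, 0.36), c(ax(0.065), ax(0.05))) |
            ellipse_mask(shape, c(0.50, 0.64), c(ax(0.065), ax(0.05))),
    stn   = ellipse_mask(shape, c(0.64, 0.40), c(ax(0.045), ax(0.035))) |
            ellipse_mask(shape, c(0.64, 0.60), c(ax(0.045), ax(0.035))))
  .roi_cache[[key]] <- val
  val
}

#' Render the axial phantom stack for one subject
#'
#' Draws an elliptical brain of white-matter-level tissue on every slice;
#' the central three slices additionally carry the anterior white-matter
#' reference ROI (mask code 1) and bilateral globus pallidus (code 2) and
#' subthalamic nucleus (code 3) ellipses, the middle slice with the largest
#' ROI cross-sections. Clean regional intensities are `wm_mean` for tissue
#' and `wm_mean * true ratio` inside GP/STN; independent zero-mean Gaussian
#' noise with SD `noise_cv x` the local clean intensity is then added and
#' the result clipped at 0.
#'
#' @param record one-row data frame (or list) as produced by
#'   [sample_cohort()].
#' @param config a [phantom_config()].
#' @return list of `n_slices` objects of class `labeled_slice`, each with
#'   `subject_id`, 0-based `slice_index`, `intensity` matrix, integer `mask`
#'   matrix (codes 0 background / 1 WM / 2 GP / 3 STN).
#' @export
render_subject <- function(record, config) {
  validate_phantom_config(config)
  shape <- config$slice_shape
  mid <- floor((config$n_slices - 1) / 2)
  central <- intersect(mid + (-1:1), 0:(config$n_slices - 1))

  lapply(0:(config$n_slices - 1), function(k) {
    mask <- matrix(0L, shape[1], shape[2])
    rois <- phantom_rois(shape, scale = if (k == mid) 1 else 0.85)
    clean <- matrix(0, shape[1], shape[2])
    clean[rois$brain] <- config$wm_mean
    if (k %in% central) {
      if (any((rois$wm & rois$gp) | (rois$wm & rois$stn) |
              (rois$gp & rois$stn)))
        stop("rendering error: ROI ellipses overlap at this slice shape")
      if (any(c(sum(rois$wm), sum(rois$gp), sum(rois$stn)) < 20))
        stop("rendering error: slice_shape too small for the ROI geometry")
      if (any((rois$wm | rois$gp | rois$stn) & !rois$brain))
        stop("rendering error: ROIs fall outside the brain ellipse")
      mask[rois$wm] <- 1L
      mask[rois$gp] <- 2L
      mask[rois$stn] <- 3L
      clean[rois$gp] <- config$wm_mean * record$true_gp_ratio
      clean[rois$stn] <- config$wm_mean * record$true_stn_ratio
    }
    intensity <- clean
    if (config$noise_cv > 0) {
      intensity <- clean + stats::rnorm(length(clean),
                                        sd = config$noise_cv * clean)
      intensity <- pmax(intensity, 0)
      dim(intensity) <- dim(clean)
    }
    structure(list(subject_id = record$subject_id, slice_index = k,
                   intensity = intensity, mask = mask),
              class = "labeled_slice")
  })
}

#' Generate a complete phantom dataset
#'
#' Seeds the RNG from the config (if a seed is set), samples the cohort,
#' renders every subject, and optionally writes the dataset to disk.
#'
#' @param config a [phantom_config()].
#' @param dir optional output directory passed to [write_phantom_dataset()].
#' @return list with `records` (cohort data frame), `stacks` (named list of
#'   slice lists), `config`, and `dir` (or `NULL`).
#' @export
generate_phantom_dataset <- function(config, dir = NULL) {
  validate_phantom_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  records <- sample_cohort(config)
  stacks <- lapply(seq_len(nrow(records)), function(i)
    render_subject(records[i, ], config))
  names(stacks) <- records$subject_id
  if (!is.null(dir)) write_phantom_dataset(stacks, records, dir,
                                           config = config)
  list(records = records, stacks = stacks, config = config, dir = dir)
}

#' Write a phantom dataset to disk
#'
#' One NIfTI image volume and one NIfTI mask volume per subject, the cohort
#' table as CSV, and a JSON manifest recording files, seed and a config echo.
#'
#' @param stacks named list (by subject_id) of `labeled_slice` lists.
#' @param records cohort data frame from [sample_cohort()].
#' @param dir output directory (created if missing).
#' @param config optional [phantom_config()] echoed in the manifest.
#' @return invisibly, the manifest list.
#' @export
write_phantom_dataset <- function(stacks, records, dir, config = NULL) {
  if (!setequal(names(stacks), records$subject_id))
    stop("integrity error: subject ids of stacks and records differ")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("unwritable directory: ", dir)
  files <- lapply(records$subject_id, function(id) {
    st <- stacks[[id]]
    img <- vapply(st, function(s) s$intensity,
                  matrix(0, nrow(st[[1]]$intensity), ncol(st[[1]]$intensity)))
    msk <- vapply(st, function(s) s$mask + 0,
                  matrix(0, nrow(st[[1]]$mask), ncol(st[[1]]$mask)))
    fi <- file.path(dir, paste0(id, "_img.nii.gz"))
    fm <- file.path(dir, paste0(id, "_mask.nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(img, datatype = "double"), fi)
    RNifti::writeNifti(RNifti::asNifti(msk, datatype = "int16"), fm)
    list(subject_id = id, image = basename(fi), mask = basename(fm))
  })
  utils::write.csv(records, file.path(dir, "cohort.csv"), row.names = FALSE)
  manifest <- list(n_subjects = nrow(records),
                   cohort_table = "cohort.csv",
                   seed = if (!is.null(config)) config$seed,
                   config = if (!is.null(config))
                     config[setdiff(names(config), "seed")],
                   files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a phantom dataset written by [write_phantom_dataset()]
#'
#' @param dir dataset directory containing `cohort.csv`, per-subject NIfTI
#'   volumes and `manifest.json`.
#' @return list with `records` and `stacks` in the same form as
#'   [generate_phantom_dataset()].
#' @export
read_phantom_dataset <- function(dir) {
  ct <- file.path(dir, "cohort.csv")
  if (!file.exists(ct)) stop("integrity error: missing cohort table")
  records <- utils::read.csv(ct, stringsAsFactors = FALSE)
  stacks <- lapply(records$subject_id, function(id) {
    fi <- file.path(dir, paste0(id, "_img.nii.gz"))
    fm <- file.path(dir, paste0(id, "_mask.nii.gz"))
    if (!file.exists(fi) || !file.exists(fm))
      stop("integrity error: missing volume for subject ", id)
    img <- as.array(RNifti::readNifti(fi))
    msk <- as.array(RNifti::readNifti(fm))
    lapply(seq_len(dim(img)[3]), function(k)
      structure(list(subject_id = id, slice_index = k - 1L,
                     intensity = img[, , k],
                     mask = matrix(as.integer(msk[, , k]), dim(msk)[1])),
                class = "labeled_slice"))
  })
  names(stacks) <- records$subject_id
  list(records = records, stacks = stacks)
}
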