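#' Mean intensity over a labeled region
#'
#' @param slice a `labeled_slice`.
#' @param region_code 1 (WM), 2 (GP) or 3 (STN).
#' @return arithmetic mean of the intensities at pixels whose mask equals
#'   `region_code`. An absent region is a hard error, never a silent zero.
#' @export
roi_mean <- function(slice, region_code) {
  stopifnot(inherits(slice, "labeled_slice"))
  if (!region_code %in% 1:3) stop("region_code must be 1, 2 or 3")
  sel <- slice$mask == region_code
  if (!any(sel))
    stop("empty-region error: code ", region_code, " absent from mask")
  mean(slice$intensity[sel])
}

#' Select the analysis slice from a stack
#'
#' Returns the slice with the largest combined GP + STN cross-section
#' (pixel count), mirroring the clinical choice of the slice covering the
#' largest area of both nuclei; ties break to the lowest slice index.
#'
#' @param stack non-empty list of `labeled_slice` objects.
#' @return the selected `labeled_slice`.
#' @export
select_slice <- function(stack) {
  if (!length(stack)) stop("stack is empty")
  area <- vapply(stack, function(s) sum(s$mask == 2L | s$mask == 3L), 0)
  if (all(area == 0))
    stop("selection error: no slice contains GP or STN")
  idx <- vapply(stack, function(s) as.numeric(s$slice_index), 0)
  best <- which(area == max(area))
  stack[[best[which.min(idx[best])]]]
}

#' Normalized GP and STN intensities of one slice
#'
#' The package's semi-quantitative scores: mean GP (resp. STN) intensity
#' divided by mean anterior subcortical white-matter intensity. Invariant
#' under any positive rescaling of the whole intensity grid.
#'
#' @param slice a `labeled_slice` carrying mask codes 1-3.
#' @return named numeric `c(gp_norm, stn_norm)`.
#' @export
normalized_intensities <- function(slice) {
  wm <- roi_mean(slice, 1)
  if (wm == 0) stop("division error: white-matter reference mean is zero")
  c(gp_norm = roi_mean(slice, 2) / wm,
    stn_norm = roi_mean(slice, 3) / wm)
}

#' Per-subject feature table from phantom stacks
#'
#' For every subject: pick the analysis slice with [select_slice()], score it
#' with [normalized_intensities()]. Row order follows the cohort table.
#'
#' @param stacks named list (by subject id) of `labeled_slice` lists.
#' @param records cohort data frame with `subject_id` and `group`.
#' @return data frame: `subject_id`, `gp_norm`, `stn_norm`, `label`,
#'   `selected_slice_index`.
#' @export
feature_table <- function(stacks, records) {
  if (!all(records$subject_id %in% names(stacks)))
    stop("integrity error: missing stack for some subject(s)")
  if (is.null(records$group)) stop("integrity error: missing group label")
  rows <- lapply(records$subject_id, function(id) {
    sl <- select_slice(stacks[[id]])
    ni <- normalized_intensities(sl)
    data.frame(subject_id = id, gp_norm = ni[["gp_norm"]],
               stn_norm = ni[["stn_norm"]],
               selected_slice_index = sl$slice_index)
  })
  out <- do.call(rbind, rows)
  out$label <- records$group[match(out$subject_id, records$subject_id)]
  out[c("subject_id", "gp_norm", "stn_norm", "label",
        "selected_slice_index")]
}

#' Feature table straight from a phantom configuration
#'
#' Samples a cohort, renders each subject and scores it immediately,
#' discarding the image stack — memory stays flat in the cohort size, which
#' matters for parameter-recovery simulations with hundreds of subjects per
#' group.
#'
#' @param config a [phantom_config()]; its `seed` (if set) seeds the run.
#' @return feature table data frame (see [feature_table()]) with the true
#'   ratios appended as `true_gp_ratio` / `true_stn_ratio`.
#' @export
phantom_feature_table <- function(config) {
  validate_phantom_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  records <- sample_cohort(config)
  rows <- lapply(seq_len(nrow(records)), function(i) {
    sl <- select_slice(render_subject(records[i, ], config))
    ni <- normalized_intensities(sl)
    data.frame(subject_id = records$subject_id[i],
               gp_norm = ni[["gp_norm"]], stn_norm = ni[["stn_norm"]],
               label = records$group[i],
               selected_slice_index = sl$slice_index,
               true_gp_ratio = records$true_gp_ratio[i],
               true_stn_ratio = records$true_stn_ratio[i])
  })
  do.call(rbind, rows)
}

#' Feature table from a dataset directory
#'
#' Reads a phantom dataset (or any conformant NIfTI + mask + cohort-table
#' set) from disk and builds the per-subject feature table.
#'
#' @param dir dataset directory written by [write_phantom_dataset()].
#' @param out optional path to also write the table as CSV.
#' @return the feature table data frame (see [feature_table()]).
#' @export
build_feature_table <- function(dir, out = NULL) {
  ds <- read_phantom_dataset(dir)
  ft <- feature_table(ds$stacks, ds$records)
  if (!is.null(out)) utils::write.csv(ft, out, row.names = FALSE)
  ft
}
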