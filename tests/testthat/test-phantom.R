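test_that("default cohort matches the study design", {
  set.seed(1)
  rec <- sample_cohort(phantom_config())
  expect_equal(nrow(rec), 79)
  expect_equal(sum(rec$group == "ABE"), 47)
  expect_equal(sum(rec$group == "non-ABE"), 32)
  expect_true(all(rec$age_days >= 1 & rec$age_days <= 18))
  expect_true(all(rec$true_gp_ratio > 0))
  expect_true(all(rec$bind_score[rec$group == "ABE"] >= 1))
  cfg <- phantom_config()
  expect_equal(cfg$n_slices, 18)
  expect_equal(cfg$ratio_params$ABE$gp, c(mean = 1.39, sd = 0.06))
  expect_equal(cfg$ratio_params$nonABE$stn, c(mean = 1.42, sd = 0.07))
})

test_that("invalid configurations are rejected", {
  expect_error(phantom_config(n_pos = 0), "configuration error")
  expect_error(phantom_config(noise_cv = -0.1), "configuration error")
  expect_error(phantom_config(wm_mean = 0), "configuration error")
  expect_error(phantom_config(ratio_params = list(
    ABE = list(gp = c(mean = 1.39, sd = -1), stn = c(mean = 1.47, sd = 0.09)),
    nonABE = list(gp = c(mean = 1.33, sd = 0.06), stn = c(mean = 1.42, sd = 0.07)))),
    "configuration error")
})

test_that("cohort sampling is reproducible and unbiased", {
  cfg <- phantom_config(seed = 5)
  set.seed(5); a <- sample_cohort(cfg)
  set.seed(5); b <- sample_cohort(cfg)
  expect_identical(a, b)
  # grand mean of ABE true GP ratios over many replicate cohorts
  set.seed(99)
  grand <- replicate(500, mean(sample_cohort(cfg)$true_gp_ratio[1:47]))
  expect_equal(mean(grand), 1.39, tolerance = 0.005)
})

test_that("swapping group ratio parameters relabels the distributions", {
  swapped <- phantom_config(n_pos = 32, n_neg = 47, ratio_params = list(
    ABE    = list(gp = c(mean = 1.33, sd = 0.06), stn = c(mean = 1.42, sd = 0.07)),
    nonABE = list(gp = c(mean = 1.39, sd = 0.06), stn = c(mean = 1.47, sd = 0.09))))
  set.seed(23)
  m <- replicate(200, {
    r <- sample_cohort(swapped)
    c(mean(r$true_gp_ratio[r$group == "non-ABE"]),
      sd(r$true_gp_ratio[r$group == "non-ABE"]))
  })
  # the relabeled negative group now carries the ABE distribution
  expect_equal(mean(m[1, ]), 1.39, tolerance = 0.003)
  expect_equal(mean(m[2, ]), 0.06, tolerance = 0.005)
})

test_that("rendering honors the intensity contract", {
  cfg <- tiny_config(noise_cv = 0)
  rec <- data.frame(subject_id = "S900", true_gp_ratio = 1.39,
                    true_stn_ratio = 1.47)
  st <- render_subject(rec, cfg)
  expect_length(st, 5)
  expect_equal(vapply(st, function(s) s$slice_index, 0L), 0:4)
  central <- st[[3]]
  expect_setequal(unique(as.vector(central$mask)), 0:3)
  expect_equal(roi_mean(central, 2) / roi_mean(central, 1), 1.39)
  expect_equal(roi_mean(central, 3) / roi_mean(central, 1), 1.47)
  expect_equal(roi_mean(central, 1), cfg$wm_mean)
  # each labeled region occupies at least 20 pixels
  for (code in 1:3) expect_gte(sum(central$mask == code), 20)
  # default stacks carry 18 slices
  expect_length(render_subject(rec, phantom_config()), 18)
  expect_error(render_subject(rec, phantom_config(slice_shape = c(12L, 12L))),
               "rendering error")
})

test_that("rendered noise leaves the extracted ratio nearly unbiased", {
  cfg <- phantom_config(n_pos = 200, n_neg = 1, noise_cv = 0.02,
                        slice_shape = c(64L, 64L), n_slices = 3L,
                        ratio_params = list(
                          ABE = list(gp = c(mean = 1.39, sd = 0),
                                     stn = c(mean = 1.47, sd = 0)),
                          nonABE = list(gp = c(mean = 1.33, sd = 0),
                                        stn = c(mean = 1.42, sd = 0))),
                        seed = 31)
  ft <- phantom_feature_table(cfg)
  ratios <- ft$gp_norm[ft$label == "ABE"]
  expect_equal(mean(ratios), 1.39, tolerance = 0.01)
  # voxel noise is small relative to the between-subject SD of 0.06
  expect_lt(sd(ratios), 0.02)
})

test_that("datasets round-trip through disk bit-identically", {
  cfg <- tiny_config(seed = 77)
  dir <- withr::local_tempdir()
  ds <- generate_phantom_dataset(cfg, dir = dir)
  expect_length(list.files(dir, pattern = "_img\\.nii\\.gz$"), 5)
  expect_length(list.files(dir, pattern = "_mask\\.nii\\.gz$"), 5)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_phantom_dataset(dir)
  id <- ds$records$subject_id[1]
  expect_identical(back$stacks[[id]][[3]]$intensity,
                   ds$stacks[[id]][[3]]$intensity)
  expect_identical(back$stacks[[id]][[3]]$mask, ds$stacks[[id]][[3]]$mask)
  # manifest seed replay regenerates an identical cohort table
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  cfg2 <- tiny_config(seed = manifest$seed)
  dir2 <- withr::local_tempdir()
  generate_phantom_dataset(cfg2, dir = dir2)
  expect_identical(readLines(file.path(dir, "cohort.csv")),
                   readLines(file.path(dir2, "cohort.csv")))
})

test_that("mismatched ids are an integrity error", {
  cfg <- tiny_config(seed = 3)
  ds <- generate_phantom_dataset(cfg)
  names(ds$stacks)[1] <- "WRONG"
  expect_error(write_phantom_dataset(ds$stacks, ds$records, tempfile()),
               "integrity error")
})
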