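test_that("confusion counts with ABE as the positive class", {
  truth <- rep(c("ABE", "non-ABE"), c(47, 32))
  cm <- confusion(truth, truth)
  expect_equal(c(cm$tp, cm$fp, cm$fn, cm$tn), c(47, 0, 0, 32))
  all_pos <- confusion(rep("ABE", 79), truth)
  expect_equal(c(all_pos$tp, all_pos$fp, all_pos$fn, all_pos$tn),
               c(47, 32, 0, 0))
  expect_error(confusion(c("ABE", "maybe"), c("ABE", "ABE")), "unknown label")
  expect_error(confusion("ABE", c("ABE", "ABE")), "equal length")
})

test_that("a prediction with 32 hits and 25 correct rejections gives the clinical matrix", {
  truth <- rep(c("ABE", "non-ABE"), c(47, 32))
  pred <- c(rep("ABE", 32), rep("non-ABE", 15),   # 32 of 47 detected
            rep("ABE", 7), rep("non-ABE", 25))    # 25 of 32 rejected
  cm <- confusion(pred, truth)
  expect_equal(c(cm$tp, cm$fp, cm$fn, cm$tn), c(32, 7, 15, 25))
})

test_that("metric fractions and display percentages follow the table convention", {
  ms <- classification_metrics(confusion_from_counts(32, 7, 15, 25))
  expect_equal(unname(ms$fractions["sensitivity"]), 32 / 47)
  expect_equal(unname(ms$fractions["accuracy"]), 57 / 79)
  expect_equal(unname(ms$display),
               c("68.10%", "78.10%", "82.05%", "74.42%", "72.15%"))
  # accuracy identity, pre-rounding: accuracy * total = tp + tn
  expect_equal(ms$fractions[["accuracy"]] * 79, 32 + 25)
  perfect <- classification_metrics(confusion_from_counts(47, 0, 0, 32))
  expect_true(all(perfect$fractions == 1))
  expect_true(all(perfect$display == "100.00%"))
})

test_that("zero-denominator metrics are flagged undefined, not zeroed", {
  degenerate <- classification_metrics(confusion_from_counts(0, 0, 47, 32))
  expect_equal(unname(degenerate$fractions["sensitivity"]), 0)
  expect_true(is.na(degenerate$fractions["precision"]))
  expect_true("precision" %in% degenerate$undefined)
  expect_true("f1" %in% degenerate$undefined)
})

test_that("aggregation returns mean and sample SD per metric", {
  two <- list(c(m = 0.5), c(m = 0.6))
  ag <- aggregate_metrics(two)
  expect_equal(ag$mean, 0.55)
  expect_equal(ag$sd, sqrt(sum((c(0.5, 0.6) - 0.55)^2)))  # 0.0707...
  same <- aggregate_metrics(list(c(a = 0.7, b = 0.2), c(a = 0.7, b = 0.2)))
  expect_true(all(same$sd == 0))
  # permutation invariance
  sets <- lapply(1:5, function(i) c(acc = i / 10, f1 = 1 - i / 10))
  expect_equal(aggregate_metrics(sets), aggregate_metrics(rev(sets)))
  expect_error(aggregate_metrics(sets[1]), "at least two")
  expect_error(aggregate_metrics(list(c(a = 1), c(b = 1))), "mismatched")
})

test_that("Fleiss' kappa matches hand-computed cases", {
  # unanimity on every subject, both categories present
  unanimous <- rbind(rep("ABE", 3), rep("non-ABE", 3), rep("ABE", 3))
  expect_equal(fleiss_kappa(unanimous), 1)
  # 2 subjects, 3 raters, votes (2,1) and (1,2): Pbar = 1/3, Pe = 1/2
  split_votes <- rbind(c("ABE", "ABE", "non-ABE"), c("ABE", "non-ABE", "non-ABE"))
  expect_equal(fleiss_kappa(split_votes), -1 / 3)
  # single category everywhere: chance agreement is 1, kappa undefined
  flat <- fleiss_kappa(matrix("ABE", 4, 3))
  expect_true(is.na(flat))
  expect_true(attr(flat, "undefined"))
  expect_error(fleiss_kappa(matrix("ABE", 4, 1)), "2 raters")
})

test_that("Fleiss' kappa is invariant to rater and subject order", {
  set.seed(13)
  r <- matrix(sample(c("ABE", "non-ABE"), 60, replace = TRUE), 15, 4)
  expect_equal(fleiss_kappa(r), fleiss_kappa(r[, c(3, 1, 4, 2)]))
  expect_equal(fleiss_kappa(r), fleiss_kappa(r[sample(15), ]))
})

test_that("accuracy comparison chi-squared reproduces hand-computed 2x2 tests", {
  same <- compare_accuracy_chi2(30, 60, 30, 60)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  # hand-check against the textbook formula n(ad-bc)^2 / (row/col margins)
  a <- 57; b <- 22; c <- 42; d <- 37; n <- a + b + c + d
  stat_hand <- n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  got <- compare_accuracy_chi2(57, 79, 42, 79)
  expect_equal(got$statistic, stat_hand)
  expect_equal(got$p, pchisq(stat_hand, 1, lower.tail = FALSE))
  # symmetry in the two methods
  swapped <- compare_accuracy_chi2(42, 79, 57, 79)
  expect_equal(got$statistic, swapped$statistic)
  expect_equal(got$p, swapped$p)
  # degenerate margin
  und <- compare_accuracy_chi2(60, 60, 60, 60)
  expect_true(is.na(und$p))
  expect_error(compare_accuracy_chi2(5, 3, 1, 3), "\\[0, n\\]")
})
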