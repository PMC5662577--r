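test_that("welch test from summaries matches the closed-form oracle", {
  ben <- group_summary(84, 11.9, 15.1)
  mal <- group_summary(27, 21.7, 19.6)
  r <- two_sample_t(mal, ben, "welch")
  # frozen from an independent summary-statistics t implementation
  expect_equal(r$t, 2.380875304820775, tolerance = 1e-12)
  expect_equal(r$df, 36.4511185334, tolerance = 1e-10)
  expect_equal(r$p, 0.022614743094547, tolerance = 1e-12)
  expect_lt(r$p, 0.05)
  rp <- two_sample_t(mal, ben, "pooled")
  expect_equal(rp$t, 2.719899501145993, tolerance = 1e-12)
  expect_equal(rp$p, 0.007601475577214, tolerance = 1e-12)
})

test_that("summary-based tests agree with stats::t.test on raw data", {
  a <- vector_with_stats(30, 14.2, 6.1, seed = 2)
  b <- vector_with_stats(45, 11.0, 9.7, seed = 3)
  sa <- group_summary(30, mean(a), stats::sd(a))
  sb <- group_summary(45, mean(b), stats::sd(b))
  for (variant in c("welch", "pooled")) {
    mine <- two_sample_t(sa, sb, variant)
    ref <- stats::t.test(a, b, var.equal = variant == "pooled")
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-9)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("degenerate and invalid summaries are handled by convention", {
  s <- group_summary(10, 5, 2)
  r <- two_sample_t(s, s)
  expect_equal(r$t, 0); expect_equal(r$p, 1)
  z <- group_summary(10, 5, 0)
  expect_equal(two_sample_t(z, z)$p, 1)
  expect_equal(two_sample_t(z, group_summary(10, 7, 0))$p, 0)
  expect_vicad_error(group_summary(1, 5, 2), "vicad_validation_error")
  expect_vicad_error(group_summary(10, 5, -1), "vicad_validation_error")
})

test_that("study summaries select 22% as the unique optimum offset", {
  res <- optimum_offset(study_vi_summaries(), alpha = 0.05, "welch")
  expect_equal(res$optimum, 22)
  expect_equal(res$qualifying, 22)
  # the rule is conjunctive: 25% peripheral alone is significant, yet the
  # offset does not qualify
  t25 <- res$table[res$table$offset == 25, ]
  expect_lt(t25$p_peripheral, 0.05)
  expect_gt(t25$p_central, 0.05)
})

test_that("identical groups qualify at no offset", {
  s <- study_vi_summaries()
  s$mean <- 15; s$sd <- 10
  res <- optimum_offset(s)
  expect_true(is.na(res$optimum))
  expect_length(res$qualifying, 0)
})

test_that("two-stage search mirrors the coarse-then-refine schedule", {
  co <- generate_cohort(cohort_spec(seed = 7))
  full <- optimum_offset(summarize_cohort(co))
  staged <- search_optimum_offset(co)
  # the staged search tests a subset of levels but must agree wherever the
  # full scan qualified within that subset
  expect_true(all(staged$qualifying %in% full$qualifying))
  expect_true(all(staged$table$offset %in% c(5, 10, 15, 20:25)))
})

test_that("roc_cutoff equals exhaustive brute force", {
  sep <- roc_cutoff(c(1, 2, 3, 10, 11), c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(sep$cutoff, 10)
  expect_equal(sep$sensitivity, 1)
  expect_equal(sep$specificity, 1)
  expect_equal(sep$auc, 1)
  flat <- roc_cutoff(rep(4, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(flat$youden, 0)
  set.seed(77)
  for (n in c(20, 57, 200)) {
    scores <- round(runif(n, 0, 40), 1)        # force ties
    labels <- runif(n) < 0.3
    if (!any(labels) || all(labels)) labels[1:2] <- c(TRUE, FALSE)
    mine <- roc_cutoff(scores, labels)
    ref <- brute_roc(scores, labels)
    expect_equal(mine$cutoff, ref$cutoff)
    expect_equal(mine$youden, ref$j, tolerance = 1e-12)
  }
  expect_vicad_error(roc_cutoff(1:5, rep(TRUE, 5)), "vicad_validation_error")
})

test_that("roc AUC agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(5)
  scores <- c(rnorm(40, 16, 6), rnorm(15, 24, 7))
  labels <- rep(c(FALSE, TRUE), c(40, 15))
  mine <- roc_cutoff(scores, labels)
  ref <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("diagnostic metrics and their inverse close over printed rows", {
  m <- diagnostic_metrics(confusion_counts(tp = 26, fp = 45, tn = 39, fn = 1))
  expect_equal(round_half_up(m, 1),
               c(sensitivity = 96.3, specificity = 46.4, ppv = 36.6,
                 npv = 97.5, accuracy = 58.6))
  m2 <- diagnostic_metrics(confusion_counts(tp = 19, fp = 24, tn = 60, fn = 8))
  expect_equal(round_half_up(m2[["accuracy"]], 1), 71.2)
  edge <- diagnostic_metrics(confusion_counts(tp = 0, fp = 0, tn = 1, fn = 1))
  expect_equal(edge[["sensitivity"]], 0)
  expect_equal(edge[["specificity"]], 100)
  expect_equal(edge[["accuracy"]], 50)
  expect_true(is.na(edge[["ppv"]]))

  cc <- counts_from_rates(96.3, 46.4, 27, 84)
  expect_equal(unlist(cc[c("tp", "fp", "tn", "fn")]),
               c(tp = 26, fp = 45, tn = 39, fn = 1))
  expect_equal(unlist(counts_from_rates(100, 100, 5, 5)),
               c(tp = 5, fp = 0, tn = 5, fn = 0))
  expect_equal(unlist(counts_from_rates(0, 0, 3, 3)),
               c(tp = 0, fp = 3, tn = 0, fn = 3))
})

test_that("GSU chi-square matches hand-computed 2x2 results", {
  co <- data.frame(malignant = rep(c(TRUE, FALSE), c(27, 84)),
                   gsu_microcalc = c(rep(c(TRUE, FALSE), c(21, 6)),
                                     rep(c(TRUE, FALSE), c(6, 78))))
  r <- gsu_feature_test(co, "gsu_microcalc")
  expect_equal(unname(r$prevalence["malignant"]), 100 * 21 / 27,
               tolerance = 1e-9)
  expect_equal(unname(r$prevalence["benign"]), 100 * 6 / 84, tolerance = 1e-9)
  expect_equal(r$chi_square, 55.3811413454, tolerance = 1e-9)
  expect_lt(r$p, 0.05)

  same <- data.frame(malignant = rep(c(TRUE, FALSE), each = 10),
                     gsu_tall = rep(c(TRUE, FALSE), 10))
  r2 <- gsu_feature_test(same, "gsu_tall")
  expect_equal(r2$chi_square, 0, tolerance = 1e-12)
  expect_equal(r2$p, 1, tolerance = 1e-12)

  diag <- data.frame(malignant = rep(c(TRUE, FALSE), each = 10),
                     gsu_irregular = rep(c(TRUE, FALSE), each = 10))
  r3 <- gsu_feature_test(diag, "gsu_irregular")
  expect_equal(r3$chi_square, 20, tolerance = 1e-9)    # n * 1 for a perfect 2x2
  expect_lt(r3$p, 0.001)
})

test_that("cohort summaries aggregate per offset, region and group", {
  co <- data.frame(malignant = c(FALSE, FALSE, FALSE, TRUE, TRUE),
                   peripheral_vi_10 = c(10, 20, 30, 40, 50),
                   central_vi_10 = c(5, 5, 5, 9, NA))
  s <- summarize_cohort(co, 10)
  ben_p <- s[s$group == "benign" & s$region == "peripheral", ]
  expect_equal(ben_p$mean, 20); expect_equal(ben_p$sd, 10)
  mal_c <- s[s$group == "malignant" & s$region == "central", ]
  expect_equal(mal_c$n, 1)       # missing central VI dropped, not zeroed
  expect_equal(mal_c$mean, 9)
})
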