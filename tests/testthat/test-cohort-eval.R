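test_that("reference-standard labeling follows both arms and the occlusion rule", {
  rec <- tibble::tibble(stenosis_band = "25-49", ctffr = 0.88, occluded = FALSE)
  expect_identical(label_cad(rec, 1)$cad_label, "negative")
  rec$ctffr <- 0.74
  expect_identical(label_cad(rec, 1)$cad_label, "positive")

  occ <- tibble::tibble(stenosis_band = "100", ctffr = NA_real_, occluded = TRUE)
  for (s in 1:4) expect_identical(label_cad(occ, s)$cad_label, "positive")

  # monotone: lowering CT-FFR or raising stenosis never flips to negative
  grid <- tidyr::expand_grid(stenosis_band = STENOSIS_BANDS,
                             ctffr = seq(0.05, 1, by = 0.05))
  grid$occluded <- FALSE
  lab <- label_cad(grid, 1)
  for (b in STENOSIS_BANDS) {
    v <- lab$cad_label[lab$stenosis_band == b][order(grid$ctffr[grid$stenosis_band == b])]
    expect_true(all(diff(v == "positive") <= 0))  # positive only at low ctffr
  }
  expect_error(label_cad(tibble::tibble(stenosis_band = "55", ctffr = 0.9), 1),
               "unknown stenosis band")
})

test_that("the ischemia reading applies the printed criteria", {
  base <- tibble::tibble(
    lead = LEADS_12, st_dev_mv = 0, st_slope = "horizontal",
    t_amp_mv = 0.3, r_amp_mv = 1, s_amp_mv = -0.3
  )
  expect_identical(ecg_ischemia_call(base, "male")$call, "negative")

  elev <- base
  elev$st_dev_mv[elev$lead %in% c("V2", "V3")] <- 0.20
  expect_identical(ecg_ischemia_call(elev, "male")$call, "positive")

  elev$st_dev_mv[elev$lead %in% c("V2", "V3")] <- 0.16
  expect_identical(ecg_ischemia_call(elev, "female")$call, "positive")
  expect_identical(ecg_ischemia_call(elev, "male")$call, "negative")

  dep <- base
  dep$st_dev_mv[dep$lead %in% c("II", "III")] <- -0.06
  dep$st_slope[dep$lead %in% c("II", "III")] <- "downsloping"
  expect_identical(ecg_ischemia_call(dep, "male")$call, "positive")
  dep$st_slope[dep$lead %in% c("II", "III")] <- "upsloping"
  expect_identical(ecg_ischemia_call(dep, "male")$call, "negative")

  tinv <- base
  tinv$t_amp_mv[tinv$lead %in% c("V4", "V5")] <- -0.15
  expect_identical(ecg_ischemia_call(tinv, "male")$call, "positive")
  tinv$r_amp_mv <- 0.2
  tinv$s_amp_mv <- -0.5  # no prominent R, R/S < 1
  expect_identical(ecg_ischemia_call(tinv, "male")$call, "negative")

  bad <- base
  bad$lead[1] <- "X9"
  expect_error(ecg_ischemia_call(bad, "male"), "unknown lead")
})

test_that("confusion counts partition the cohort", {
  cc <- confusion_counts(c("positive", "negative"), c("positive", "negative"))
  expect_equal(unlist(cc), c(tp = 1, tn = 1, fp = 0, fn = 0))
  cc2 <- confusion_counts(rep("positive", 4),
                          c("positive", "positive", "negative", "negative"))
  expect_equal(cc2$tp, 2)
  expect_equal(cc2$fp, 2)
  expect_error(confusion_counts("positive", character(0)), "equal length")
})

test_that("diagnostic metrics reproduce the frozen-table rows at 2 decimals", {
  m <- diagnostic_metrics(127, 161, 33, 41)
  expect_equal(m$sensitivity, 75.60)
  expect_equal(m$specificity, 82.99)
  expect_equal(m$ppv, 79.38)
  expect_equal(m$npv, 79.70)
  expect_equal(m$accuracy, 79.56)

  e <- diagnostic_metrics(64, 119, 75, 104)
  expect_equal(e$sensitivity, 38.10)
  expect_equal(e$specificity, 61.34)
  expect_equal(e$accuracy, 50.55)

  perfect <- diagnostic_metrics(1, 1, 0, 0)
  expect_true(all(unlist(perfect[c("sensitivity", "specificity", "ppv",
                                   "npv", "accuracy")]) == 100))

  # zero denominators are reported missing, never zero
  none_pos <- diagnostic_metrics(0, 5, 0, 0)
  expect_true(is.na(none_pos$sensitivity))
  expect_true(is.na(none_pos$ppv))
  expect_equal(none_pos$accuracy, 100)
})

test_that("AUC equals the normalized Mann-Whitney statistic", {
  sep <- roc_auc(c(1, 2, 3, 10, 11, 12),
                 c(rep("negative", 3), rep("positive", 3)))
  expect_equal(sep$auc, 1.0)
  flat <- roc_auc(rep(1, 10), rep(c("negative", "positive"), 5))
  expect_equal(flat$auc, 0.5)

  withr::with_seed(21, {
    scores <- c(rnorm(8, 1), rnorm(12, 0))
    scores[3] <- scores[15]  # inject a cross-class tie
    truths <- c(rep("positive", 8), rep("negative", 12))
  })
  expect_equal(roc_auc(scores, truths)$auc,
               mann_whitney_auc(scores, truths), tolerance = 1e-12)
  expect_error(roc_auc(1:5, rep("positive", 5)),
               class = "cardiodyn_single_class_error")
})

test_that("Spearman correlation matches the average-rank formula", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_corr(x, -x)$rho, -1)

  withr::with_seed(5, {
    a <- rnorm(1000)
    b <- rnorm(1000)
  })
  expect_lt(abs(spearman_corr(a, b)$rho), 0.08)

  withr::with_seed(6, {
    xt <- sample(1:4, 60, replace = TRUE)  # tie-heavy
    yt <- xt + sample(0:2, 60, replace = TRUE)
  })
  expect_equal(spearman_corr(xt, yt)$rho, brute_force_spearman(xt, yt),
               tolerance = 1e-12)

  expect_warning(res <- spearman_corr(rep(1, 10), rnorm(10)), "constant")
  expect_true(is.na(res$rho))
})
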