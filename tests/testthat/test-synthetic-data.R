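test_that("the generator is seed-deterministic and zero dispersion clones beats", {
  a <- simulate_ecg(dispersion = dispersion_spec(noise_mv = 0.05, seed = 12),
                    duration_s = 5)
  b <- simulate_ecg(dispersion = dispersion_spec(noise_mv = 0.05, seed = 12),
                    duration_s = 5)
  expect_identical(as.data.frame(a$record), as.data.frame(b$record))
  expect_identical(a$truth, b$truth)

  clean <- simulate_ecg(dispersion = dispersion_spec(seed = 1), duration_s = 20)
  sig <- as.matrix(as.data.frame(clean$record))
  beat1 <- sig[1:1000, ]
  for (k in 1:15) {
    expect_lt(max(abs(sig[(k * 1000 + 1):((k + 1) * 1000), ] - beat1)), 1e-12)
  }
})

test_that("generator truth matches its documented beat anatomy", {
  sim <- simulate_ecg(duration_s = 10)
  tr <- sim$truth
  expect_true(all(tr$j_point - tr$r_peak == 40))   # J at R + 40 ms
  expect_true(all(tr$t_end - tr$r_peak == 360))    # tangent-rule T end
  expect_true(all(tr$r_peak < tr$j_point & tr$j_point < tr$t_apex &
                    tr$t_apex < tr$t_end))
  expect_error(simulate_ecg(duration_s = 0.5), "duration")
})

test_that("cohort prevalence stays within its binomial envelope", {
  sc <- simulate_cohort(n = 362, prevalence = 0.4641, seed = 11)
  expect_equal(nrow(sc), 362)
  n_pos <- sum(label_cad(sc, 1)$cad_label == "positive")
  expect_lt(abs(n_pos - 168), 2 * sqrt(362 * 0.4641 * (1 - 0.4641)))
  # standard-1 labeling recovers the latent class by construction
  expect_true(all(sc$ctffr[label_cad(sc, 1)$cad_label == "negative"] > 0.8))
})

test_that("null and strong effects bracket the AUC as designed", {
  aucs <- vapply(1:20, function(s) {
    run_cohort(simulate_cohort(effect = 0, seed = s), standard = 1)$auc$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)

  strong <- run_cohort(simulate_cohort(effect = 4.5, seed = 7), standard = 1)
  expect_gt(strong$auc$auc, 0.95)
})

test_that("infeasible association targets warn and fall back", {
  expect_warning(simulate_cohort(rho_target = -0.95, seed = 1), "best effort")
  expect_warning(simulate_cohort(rho_target = 0.2, seed = 1), "negative")
  expect_error(simulate_cohort(n = 5), "n must be")
  expect_error(simulate_cohort(prevalence = 1.2), "prevalence")
})

test_that("frozen reference tables are internally consistent", {
  t2 <- table2_counts()
  expect_equal(sum(t2), 362)
  expect_equal(sum(t2["cdg_negative", ]), 202)
  expect_equal(sum(t2["cdg_positive", ]), 160)

  fc <- fixture_cohort()
  expect_equal(nrow(fc), 362)
  expect_equal(sum(fc$cdg_value < 0), 202)
  # the fixture reproduces the cross-tabulation cell by cell
  lt50 <- stenosis_lower_edge(fc$stenosis_band) < 50
  ffr <- ifelse(fc$occluded, 0.5, fc$ctffr)
  cells <- c(sum(fc$cdg_value < 0 & lt50 & ffr > 0.8),
             sum(fc$cdg_value < 0 & lt50 & ffr <= 0.8),
             sum(fc$cdg_value < 0 & !lt50 & ffr > 0.8),
             sum(fc$cdg_value < 0 & !lt50 & ffr <= 0.8))
  expect_equal(cells, unname(t2["cdg_negative", ]))

  # standard-1 confusion from the fixture equals the frozen counts
  lab <- label_cad(fc, 1)
  cc <- confusion_counts(ifelse(fc$cdg_value >= 0, "positive", "negative"),
                         lab$cad_label)
  expect_equal(unlist(cc), c(tp = 127, tn = 161, fp = 33, fn = 41))
})

test_that("cohort tables round trip through CSV", {
  sc <- simulate_cohort(n = 40, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(sc, path)
  back <- read_cohort(path)
  expect_equal(back$cdg_value, sc$cdg_value)
  expect_equal(back$stenosis_band, sc$stenosis_band)
})
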