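clean_pipeline <- function(sim) {
  kors_transform(denoise(sim$record))
}

test_that("R peaks are recovered exactly on clean records and robustly in noise", {
  sim <- simulate_ecg(dispersion = dispersion_spec(seed = 1), duration_s = 20)
  vcg <- clean_pipeline(sim)
  r <- detect_r_peaks(vcg)
  expect_equal(length(r), nrow(sim$truth))
  expect_true(all(abs(r - sim$truth$r_peak) <= 10))  # within 10 ms at 1 kHz

  sim2 <- simulate_ecg(beat_template(heart_rate = 100),
                       dispersion_spec(noise_mv = 0.05, seed = 2), 20)
  r2 <- detect_r_peaks(clean_pipeline(sim2))
  hits <- vapply(sim2$truth$r_peak, function(rp) min(abs(r2 - rp)), numeric(1))
  expect_gte(mean(hits <= 10), 0.95)
  expect_lte(length(r2), nrow(sim2$truth))  # no extra detections
})

test_that("flat records raise a no-beats error", {
  flat <- vcg_record(numeric(4000), numeric(4000), numeric(4000), fs = 1000)
  expect_error(detect_r_peaks(flat), class = "cardiodyn_no_beats_error")
})

test_that("J point and T end land within tolerance of generator truth", {
  sim <- simulate_ecg(dispersion = dispersion_spec(seed = 1), duration_s = 20)
  vcg <- clean_pipeline(sim)
  fids <- locate_fiducials(vcg, detect_r_peaks(vcg))
  truth <- sim$truth[vapply(fids$r_peak,
                            function(r) which.min(abs(sim$truth$r_peak - r)),
                            integer(1)), ]
  expect_true(all(abs(fids$j_point - truth$j_point) <= 15))
  expect_true(all(abs(fids$t_end - truth$t_end) <= 25))
  # per-beat ordering invariant
  expect_true(all(fids$r_peak < fids$j_point &
                    fids$j_point < fids$t_apex &
                    fids$t_apex < fids$t_end))
})

test_that("a final beat truncated before its T end is dropped", {
  sim <- simulate_ecg(dispersion = dispersion_spec(seed = 1), duration_s = 19.5)
  expect_true(any(sim$truth$truncated))
  vcg <- clean_pipeline(sim)
  r <- detect_r_peaks(vcg)
  fids <- locate_fiducials(vcg, r)
  expect_equal(nrow(fids), length(r) - 1L)
})

test_that("fiducials are time-shift equivariant and amplitude-scale invariant", {
  sim <- simulate_ecg(dispersion = dispersion_spec(seed = 3), duration_s = 12)
  vcg <- clean_pipeline(sim)
  fids <- locate_fiducials(vcg, detect_r_peaks(vcg))

  k <- 50  # the record opens with baseline, so beats are unaffected
  shifted <- vcg_record(vcg$x[-(1:k)], vcg$y[-(1:k)], vcg$z[-(1:k)], fs = 1000)
  fids_s <- locate_fiducials(shifted, detect_r_peaks(shifted))
  expect_equal(fids_s$r_peak, fids$r_peak - k)
  expect_equal(fids_s$j_point, fids$j_point - k)
  expect_equal(fids_s$t_end, fids$t_end - k)

  scaled <- vcg_record(2.5 * vcg$x, 2.5 * vcg$y, 2.5 * vcg$z, fs = 1000)
  fids_c <- locate_fiducials(scaled, detect_r_peaks(scaled))
  expect_identical(fids_c$r_peak, fids$r_peak)
  expect_identical(fids_c$j_point, fids$j_point)
  expect_identical(fids_c$t_end, fids$t_end)
})

test_that("ST-T loops resample exactly and reproduce identical beats", {
  sim <- simulate_ecg(dispersion = dispersion_spec(seed = 1), duration_s = 20)
  vcg <- kors_transform(sim$record)  # no filtering: beats are exact clones
  truth_ok <- sim$truth[!sim$truth$truncated, ]
  fids <- as_fiducial_set(truth_ok, fs = 1000)

  loops <- extract_stt_loops(vcg, fids, n_points = 100)
  P <- cbind(loops$x, loops$y, loops$z)
  l1 <- P[loops$beat == 1, ]
  for (b in unique(loops$beat)[-1]) {
    expect_lt(max(abs(P[loops$beat == b, ] - l1)), 1e-6)
  }

  # identity resampling: n_points equal to the raw segment length
  raw_len <- fids$t_end[1] - fids$j_point[1] + 1L
  one <- as_fiducial_set(truth_ok[1, ], fs = 1000)
  loop1 <- extract_stt_loops(vcg, one, n_points = raw_len)
  seg <- fids$j_point[1]:fids$t_end[1]
  expect_lt(max(abs(loop1$x - vcg$x[seg])), 1e-9)
  expect_lt(max(abs(loop1$z - vcg$z[seg])), 1e-9)

  expect_error(extract_stt_loops(vcg, fids, n_points = 8), "n_points")
  expect_warning(extract_stt_loops(vcg, one, n_points = 2 * raw_len),
                 "interpolating")
})

test_that("alternans produces two loop clusters tighter than their separation", {
  sim <- simulate_ecg(dispersion = dispersion_spec(alternans = TRUE, seed = 5),
                      duration_s = 20)
  vcg <- clean_pipeline(sim)
  fids <- locate_fiducials(vcg, detect_r_peaks(vcg))
  loops <- extract_stt_loops(vcg, fids, n_points = 100)
  P <- cbind(loops$x, loops$y, loops$z)
  flat <- t(vapply(unique(loops$beat),
                   function(b) as.vector(P[loops$beat == b, ]),
                   numeric(300)))
  parity <- unique(loops$beat) %% 2
  centr <- function(g) colMeans(flat[parity == g, , drop = FALSE])
  spread <- function(g) mean(sqrt(rowSums(
    (flat[parity == g, , drop = FALSE] -
       matrix(centr(g), sum(parity == g), 300, byrow = TRUE))^2)))
  between <- sqrt(sum((centr(0) - centr(1))^2))
  expect_lt(max(spread(0), spread(1)), between)
})
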