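test_that("SHI is zero on exactly periodic trajectories", {
  cycle <- cbind(cos(seq(0, 2 * pi, length.out = 11)[-11]),
                 sin(seq(0, 2 * pi, length.out = 11)[-11]),
                 rep(0, 10))
  P <- do.call(rbind, replicate(5, cycle, simplify = FALSE))
  expect_equal(compute_shi(P, step_k = 10, theiler = 0), 0)
})

test_that("SHI is invariant to uniform scaling and translation", {
  P <- diverging_fixture()
  ref <- compute_shi(P, step_k = 10, theiler = 2)
  expect_equal(compute_shi(3.7 * P, step_k = 10, theiler = 2), ref)
  shift <- matrix(c(5, -2, 11), nrow(P), 3, byrow = TRUE)
  expect_equal(compute_shi(P + shift, step_k = 10, theiler = 2), ref,
               tolerance = 1e-10)
})

test_that("SHI matches the brute-force oracle on the diverging-cycles fixture", {
  P <- diverging_fixture(seed = 7)
  expect_equal(compute_shi(P, step_k = 10, theiler = 2),
               brute_force_shi(P, step_k = 10, theiler = 2),
               tolerance = 1e-12)
})

test_that("SHI equals exhaustive search on many random small trajectories", {
  for (i in 1:50) {
    n <- 30 + (i * 7) %% 171  # sizes spread over 30..200
    P <- random_trajectory(n, seed = 1000 + i)
    k <- c(5, 10)[1 + i %% 2]
    w <- c(0, 3, 10)[1 + i %% 3]
    expect_equal(compute_shi(P, step_k = k, theiler = w),
                 brute_force_shi(P, step_k = k, theiler = w),
                 tolerance = 1e-12)
  }
})

test_that("degenerate and undersized trajectories raise errors", {
  expect_error(compute_shi(matrix(0, 5, 3), step_k = 10),
               class = "cardiodyn_size_error")
  expect_error(compute_shi(matrix(1, 50, 3), step_k = 10, theiler = 0),
               class = "cardiodyn_degenerate_error")
})

test_that("THI selects the damped-spectrum minimiser with smallest-lambda ties", {
  # norm series with every low bin populated except bin 3
  n <- 64
  t <- seq_len(n) - 1
  s <- numeric(n)
  for (k in c(1, 2, 4, 5, 6)) s <- s + cos(2 * pi * k * t / n)
  P <- cbind(10 + s, rep(0, n), rep(0, n))
  expect_equal(compute_thi(P, lambda_grid = 1:6), 3)

  # constant norm: every bin is exactly zero, tie breaks to the smallest
  Pc <- matrix(1, 32, 3)
  expect_equal(compute_thi(Pc, lambda_grid = c(2, 5)), 2)

  expect_error(compute_thi(P, lambda_grid = integer(0)), "empty")
  expect_error(compute_thi(P, lambda_grid = c(5, 2)), "ascending")
})

test_that("THI equals the brute-force grid scan and is bit-deterministic", {
  P <- diverging_fixture(seed = 7)
  grid <- 1:20
  expect_identical(compute_thi(P, lambda_grid = grid),
                   brute_force_thi(P, grid))
  expect_identical(compute_thi(P, lambda_grid = grid),
                   compute_thi(P, lambda_grid = grid))
  expect_identical(compute_thi(P, lambda_grid = grid, spectrum_mode = "per_axis"),
                   brute_force_thi(P, grid, mode = "per_axis"))
  for (i in 1:10) {
    Q <- random_trajectory(80, seed = 300 + i)
    expect_identical(compute_thi(Q, lambda_grid = 1:40),
                     brute_force_thi(Q, 1:40))
  }
})

test_that("heterogeneity_indices bundles SHI and THI with metadata", {
  sim <- simulate_ecg(dispersion = dispersion_spec(stt_jitter = 0.1, seed = 2),
                      duration_s = 20)
  out <- run_subject(sim$record)
  idx <- heterogeneity_indices(out$trajectory)
  expect_named(idx, c("subject_id", "shi", "thi", "n_points", "step_k"))
  expect_equal(idx$n_points, nrow(out$trajectory))
  expect_equal(idx$shi, out$result$shi)
  expect_equal(idx$thi, out$result$thi)
})
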