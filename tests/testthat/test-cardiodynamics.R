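test_that("lattice construction covers the loop bounding box", {
  # loops spanning exactly the unit cube, spacing 0.5: 5 centers per axis
  P <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1)))
  P <- P[rep(1:8, length.out = 32), ]
  net <- rbf_lattice(as_loops(P, L = 32), spacing = 0.5)
  expect_equal(nrow(net$centers), 125)
  expect_equal(range(net$centers[, 1]), c(-0.5, 1.5))
  expect_true(all(net$weights == 0))

  # degenerate cover: spacing larger than the bounding box
  small <- matrix(runif(48, 0, 0.1), 16, 3)
  net2 <- rbf_lattice(as_loops(small, L = 16), spacing = 1)
  expect_gte(nrow(net2$centers), 8)
  for (k in 1:3) expect_gte(length(unique(net2$centers[, k])), 2)

  expect_error(rbf_lattice(as_loops(P, L = 32), spacing = 0.01),
               class = "cardiodyn_size_error")
})

test_that("no adaptation means zero weights; training is deterministic", {
  loops <- circle_loops(n_beats = 3, L = 50)
  net <- rbf_lattice(loops)
  frozen <- learn_dynamics(loops, net, gamma = 0)
  expect_true(all(frozen$weights == 0))
  expect_true(all(frozen$wbar == 0))

  n1 <- learn_dynamics(loops, net)
  n2 <- learn_dynamics(loops, net)
  expect_identical(n1$weights, n2$weights)
  expect_identical(n1$wbar, n2$wbar)
})

test_that("deterministic learning reproduces limit-cycle dynamics to < 5%", {
  loops <- circle_loops(n_beats = 15, L = 100)
  net <- learn_dynamics(loops, rbf_lattice(loops))
  pe <- prediction_error(net, loops)
  expect_lt(pe$relative, 0.05)
})

test_that("plain-gradient adaptation at high gain reports instability", {
  sim <- simulate_ecg(dispersion = dispersion_spec(seed = 1), duration_s = 20)
  vcg <- kors_transform(denoise(sim$record))
  loops <- extract_stt_loops(vcg, locate_fiducials(vcg, detect_r_peaks(vcg)))
  expect_error(
    learn_dynamics(loops, rbf_lattice(loops), normalized = FALSE),
    class = "cardiodyn_instability_error")
})

test_that("kernels are exactly local beyond three widths", {
  loops <- circle_loops(n_beats = 5, L = 60)
  net <- learn_dynamics(loops, rbf_lattice(loops))
  far <- matrix(100, 4, 3)  # far outside the lattice
  expect_true(all(rbf_activations(net, far) == 0))
  expect_true(all(rbf_activations(net, far) %*% net$wbar == 0))
})

test_that("dynamics of a true RBF system are recovered along the orbit", {
  # truth: an RBF expansion on the lattice, fitted to circle increments, then
  # iterated to produce the training orbit; learned map must match the true
  # map to <= 10% along the visited region
  base <- circle_loops(n_beats = 1, L = 100)
  net0 <- rbf_lattice(base)
  P0 <- cbind(base$x, base$y, base$z)
  S0 <- rbf_activations(net0, P0)
  target <- rbind(diff(P0), P0[1, ] - P0[100, ])  # closed-cycle increments
  sv <- svd(S0)
  keep <- sv$d > 1e-10 * sv$d[1]
  W_true <- sv$v[, keep] %*% ((t(sv$u[, keep]) %*% target) / sv$d[keep])
  f_true <- function(X) rbf_activations(net0, X) %*% W_true

  x <- P0[1, ]
  orbit <- matrix(NA_real_, 1200, 3)
  for (k in 1:1200) {
    orbit[k, ] <- x
    x <- x + drop(f_true(rbind(x)))
  }
  loops <- as_loops(orbit, L = 100)
  net <- learn_dynamics(loops, net0)
  pred <- rbf_activations(net, orbit) %*% net$wbar
  truth <- f_true(orbit)
  rel <- sqrt(mean(rowSums((pred - truth)^2))) /
    mean(sqrt(rowSums(truth^2)))
  expect_lte(rel, 0.10)
})

test_that("zero-weight networks emit a zero trajectory of the right length", {
  loops <- circle_loops(n_beats = 4, L = 40)
  net <- rbf_lattice(loops)
  expect_warning(traj <- generate_cdg(net, loops), "zero")
  expect_equal(nrow(traj), 160)
  expect_true(all(traj$x == 0 & traj$y == 0 & traj$z == 0))
})

test_that("identical beats give identical CDG segments; dispersion separates them", {
  seg_distance <- function(jitter, seed) {
    sim <- simulate_ecg(dispersion = dispersion_spec(stt_jitter = jitter,
                                                     seed = seed),
                        duration_s = 20)
    vcg <- kors_transform(sim$record)
    fids <- as_fiducial_set(sim$truth[!sim$truth$truncated, ], fs = 1000)
    loops <- extract_stt_loops(vcg, fids, n_points = 100)
    traj <- generate_cdg(learn_dynamics(loops, rbf_lattice(loops)), loops)
    P <- cbind(traj$x, traj$y, traj$z)
    beats <- unique(traj$beat)
    segs <- lapply(beats, function(b) P[traj$beat == b, ])
    d <- c()
    for (i in seq_along(segs)[-1]) {
      d <- c(d, mean(sqrt(rowSums((segs[[i]] - segs[[1]])^2))))
    }
    d
  }
  d0 <- seg_distance(0, seed = 11)
  expect_lt(max(d0), 1e-6)
  d3 <- seg_distance(0.3, seed = 11)
  expect_gt(mean(d3), mean(d0))
})

test_that("trained networks serialise to JSON and back", {
  loops <- circle_loops(n_beats = 3, L = 40)
  net <- learn_dynamics(loops, rbf_lattice(loops))
  path <- withr::local_tempfile(fileext = ".json")
  write_rbf_network(net, path)
  back <- read_rbf_network(path)
  expect_equal(back$weights, unname(net$weights))
  expect_equal(back$centers, unname(net$centers))
  expect_equal(back$width, net$width)
})
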