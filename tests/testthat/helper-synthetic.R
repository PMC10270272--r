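# shared fixture builders and independent oracles

# 8-lead record with the same series on every independent lead
make_flat_record <- function(v, fs = 1000) {
  d <- as.data.frame(matrix(rep(v, 8), ncol = 8))
  names(d) <- LEADS_INDEPENDENT
  ecg_record(d, fs = fs)
}

# package a matrix of 3-D points into an stt_loops container
as_loops <- function(P, L, subject_id = "fixture") {
  n_beats <- nrow(P) / L
  stopifnot(n_beats == round(n_beats))
  loops <- tibble::tibble(
    beat = rep(seq_len(n_beats), each = L),
    point = rep(seq_len(L), n_beats),
    x = P[, 1], y = P[, 2], z = P[, 3]
  )
  attr(loops, "L") <- as.integer(L)
  attr(loops, "n_beats") <- as.integer(n_beats)
  attr(loops, "subject_id") <- subject_id
  class(loops) <- c("stt_loops", class(loops))
  loops
}

# closed non-self-intersecting 3-D limit cycle, repeated n_beats times
circle_loops <- function(n_beats = 15, L = 100, radius = 1) {
  th <- seq(0, 2 * pi, length.out = L + 1)[-(L + 1)]
  pts <- cbind(radius * cos(th), radius * sin(th), 0.2 * radius * cos(2 * th))
  as_loops(do.call(rbind, replicate(n_beats, pts, simplify = FALSE)), L)
}

# independent brute-force SHI: exhaustive neighbour search, direct formula
brute_force_shi <- function(P, step_k = 10, theiler = 0) {
  N <- nrow(P)
  vals <- c()
  for (n in seq_len(N)) {
    if (n + step_k > N) next
    best_j <- NA
    best_d <- Inf
    for (j in seq_len(N)) {
      if (abs(j - n) <= theiler || j + step_k > N) next
      d <- sqrt(sum((P[n, ] - P[j, ])^2))
      if (d > 0 && d < best_d) {
        best_d <- d
        best_j <- j
      }
    }
    if (is.na(best_j)) next
    d2 <- sqrt(sum((P[n + step_k, ] - P[best_j + step_k, ])^2))
    v <- log(d2 / best_d)
    if (is.finite(v)) vals <- c(vals, v)
  }
  mean(vals)
}

# independent brute-force THI: direct grid scan of the damped-spectrum
# objective with first-minimum tie-break
brute_force_thi <- function(P, grid, mode = "norm") {
  N <- nrow(P)
  spec <- if (mode == "norm") {
    s <- sqrt(rowSums(P^2))
    Mod(fft(s - mean(s)))
  } else {
    rowMeans(vapply(1:3, function(k) Mod(fft(P[, k] - mean(P[, k]))),
                    numeric(N)))
  }
  best <- Inf
  best_l <- NA
  for (l in grid) {
    obj <- spec[l + 1] * exp(-0.1 * l)
    if (obj < best) {
      best <- obj
      best_l <- l
    }
  }
  best_l
}

# two slowly diverging noisy cycles, 40 points, fixed seed
diverging_fixture <- function(seed = 7) {
  withr::with_seed(seed, {
    th <- seq(0, 2 * pi, length.out = 21)[-21]
    c1 <- cbind(cos(th), sin(th), 0.1 * sin(2 * th))
    c2 <- 1.05 * c1
    P <- rbind(c1, c2) + matrix(rnorm(120, sd = 0.01), 40, 3)
    P
  })
}

# random small trajectory for oracle-equivalence sweeps
random_trajectory <- function(n, seed) {
  withr::with_seed(seed, {
    t <- seq_len(n)
    cbind(
      sin(0.3 * t) + cumsum(rnorm(n, sd = 0.05)),
      cos(0.2 * t) + rnorm(n, sd = 0.1),
      0.5 * sin(0.15 * t + 1) + rnorm(n, sd = 0.1)
    )
  })
}

# Mann-Whitney statistic / (n1 * n0): rank-based AUC oracle with tie halving
mann_whitney_auc <- function(scores, truths) {
  pos <- scores[truths == "positive"]
  neg <- scores[truths == "negative"]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Spearman rho by the direct average-rank formula
brute_force_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
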