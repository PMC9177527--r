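test_that("the kinetic pulse-chase curve is continuous with the right limits", {
  kp <- kinetic_params(M = 0.62, tau1 = 1.25, m = 0.10, tau2 = 5, t_pulse = 2)
  expect_equal(brdu_level(0, kp), 0)
  expect_equal(brdu_level(-3, kp), 0)
  as_end <- kp$M * (1 - exp(-kp$t_pulse / kp$tau1))
  expect_equal(brdu_level(kp$t_pulse, kp), as_end, tolerance = 1e-12)
  expect_equal(brdu_level(kp$t_pulse + 1e-9, kp), as_end, tolerance = 1e-6)
  expect_equal(brdu_level(1e9, kp), kp$m, tolerance = 1e-9)
  # monotone rise during the pulse, monotone relaxation during the chase
  tt <- seq(0, kp$t_pulse, length.out = 200)
  expect_true(all(diff(brdu_level(tt, kp)) > 0))
  tc <- seq(kp$t_pulse, 60, length.out = 200)
  expect_true(all(diff(brdu_level(tc, kp)) < 0))
})

test_that("kinetic parameter constraints are enforced", {
  expect_error(kinetic_params(M = 0.5, m = 0.6), "0 < m < M")
  expect_error(kinetic_params(M = 1.2), "0 < m < M")
  expect_error(kinetic_params(tau1 = -1), "> 0")
})

test_that("single-fork geometry encodes speed times pulse duration", {
  sim <- simulate_single_forks(20, speeds = rep(2000, 20), noise = NULL,
                               kinetics_cv = 0, seed = 3)
  expect_equal(abs(sim$truth$X1_true - sim$truth$X0_true), rep(4000, 20))
  # the noise-free profile starts decreasing at X1
  i <- 1
  sig <- sim$traces$signal[[i]]
  s <- if (sim$truth$direction[i] == "right") 1 else -1
  at <- function(p) sig$prob[match(p, sig$position)]
  expect_gt(at(sim$truth$X1_true[i]), at(sim$truth$X1_true[i] + s * 500))
  expect_gt(at(sim$truth$X1_true[i]), at(sim$truth$X0_true[i]))
})

test_that("emitted probabilities obey the noise model contract", {
  np <- noise_params()
  sim <- simulate_single_forks(30, noise = np, seed = 9)
  for (i in 1:5) {
    sig <- sim$traces$signal[[i]]
    expect_true(all(sig$prob >= 0 & sig$prob <= 1))
    L <- sim$traces$end[i] - sim$traces$start[i]
    frac <- nrow(sig) / L
    expect_lt(abs(frac - np$p_t), 4 * sqrt(np$p_t * (1 - np$p_t) / L))
    # binomial quantisation: every value is a multiple of 1, 1/2 or 1/3
    q <- sig$prob * 6
    expect_true(all(abs(q - round(q)) < 1e-9))
  }
})

test_that("a pure-offset read emits values averaging the offset level", {
  np <- noise_params()
  set.seed(21)
  off <- replifork:::draw_offsets(5000, np)
  expect_true(all(off >= np$offset_min & off <= np$offset_max))
  # shape/location/scale convention: the untruncated median is loc + scale
  expect_lt(abs(median(off) - (np$offset_loc + np$offset_scale)), 3e-4)
  # underlying level o emitted through B(n, o)/n keeps mean o: use a noise
  # model whose own offset is negligibly small so only o remains
  np0 <- noise_params(offset_scale = 2e-7, offset_max = 1e-3)
  o <- 0.05
  set.seed(22)
  em <- replifork:::emit_signal(rep(o, 6e5), np0)
  se <- sd(em$prob) / sqrt(length(em$prob))
  expect_lt(abs(mean(em$prob) - o), 3 * se + 1e-3)
})

test_that("seeded simulations are bit-reproducible", {
  a <- simulate_single_forks(5, noise = noise_params(), seed = 42)
  b <- simulate_single_forks(5, noise = noise_params(), seed = 42)
  expect_identical(a$truth, b$truth)
  expect_identical(a$traces$signal, b$traces$signal)
  g1 <- simulate_genome(30, noise = noise_params(), seed = 43)
  g2 <- simulate_genome(30, noise = noise_params(), seed = 43)
  expect_identical(g1$truth, g2$truth)
  expect_identical(g1$fork_truth, g2$fork_truth)
  expect_identical(g1$traces$signal, g2$traces$signal)
})

test_that("multi-fork segments carry six active origins and twelve forks", {
  g <- simulate_genome(60, noise = NULL, seed = 7)
  per_seg <- table(g$fork_truth$segment_id)
  expect_true(all(per_seg == 12))
  expect_equal(length(unique(g$fork_truth$origin)), 6)
  # all sliced read lengths within the truncation bounds
  lens <- g$traces$end - g$traces$start
  expect_true(all(lens <= 300000))
  # every read's speed matches its segment's single speed
  expect_equal(length(unique(g$truth$v_true[g$truth$segment_id == 1])), 1)
})

test_that("fork truth regions tile each segment and orient correctly", {
  g <- simulate_genome(40, noise = NULL, seed = 19)
  ft <- g$fork_truth[g$fork_truth$segment_id == 1, ]
  ft <- ft[order(ft$region_start, ft$region_end), ]
  expect_equal(ft$region_start[1], 0)
  expect_equal(ft$region_end[nrow(ft)], 300000)
  expect_equal(ft$region_start[-1], ft$region_end[-nrow(ft)])
  # leftward forks own the region left of their origin
  left <- g$fork_truth[g$fork_truth$direction == "left", ]
  expect_true(all(left$X1_true <= left$X0_true))
})

test_that("noise-free detection loses forks but never invents them", {
  g <- simulate_genome(40, noise = NULL, seed = 23)
  fc <- call_forks(g$traces)
  n_complete <- sum(g$fork_truth$complete)
  expect_lte(glance(fc)$n_forks, nrow(g$fork_truth))
  # detected forks match a true fork's direction at their centre
  if (nrow(fc$forks)) {
    ok <- vapply(seq_len(nrow(fc$forks)), function(i) {
      f <- fc$forks[i, ]
      ft <- g$fork_truth[g$fork_truth$chrom == f$chrom, ]
      ctr <- (f$X0 + f$X1) / 2
      hit <- ft[ft$region_start <= ctr & ctr < ft$region_end, ]
      nrow(hit) == 1 && hit$direction == f$direction
    }, logical(1))
    expect_true(all(ok))
  }
})

test_that("white-noise traces have near-zero autocorrelation at positive lags", {
  set.seed(33)
  n <- 40
  L <- 12000
  sig <- lapply(seq_len(n), function(i) {
    tibble::tibble(position = 0:(L - 1), prob = runif(L))
  })
  tr <- trace_tbl(sprintf("w%02d", seq_len(n)), "sim", 0, L, "+", sig)
  ac <- noise_autocorrelation(tr, lag_max = 1500)
  expect_equal(ac$acf[1], 1, tolerance = 1e-9)
  # the 100 bp box smoothing induces correlation below ~100 bp lags;
  # beyond 1100 bp (past both smoothing windows) it must vanish
  far <- ac$acf[ac$lag > 1100]
  expect_lt(max(abs(far)), 3 / sqrt(n * (L - 2 * 1500)) * 50)
})

test_that("averaging a repeated trace equals the single-trace curve", {
  set.seed(34)
  L <- 12000
  s <- tibble::tibble(position = 0:(L - 1), prob = runif(L))
  one <- trace_tbl("a", "sim", 0, L, "+", list(s))
  three <- trace_tbl(c("a", "b", "c"), "sim", 0, L, "+", list(s, s, s))
  expect_equal(noise_autocorrelation(one, 800), noise_autocorrelation(three, 800))
})
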