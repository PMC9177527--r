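toy_forks <- function(n, chrom = "chrI", span = c(0, 1e6), speed = NULL,
                      seed = 1) {
  set.seed(seed)
  ctr <- runif(n, span[1] + 3000, span[2] - 3000)
  dir <- sample(c("left", "right"), n, replace = TRUE)
  len <- runif(n, 2000, 6000)
  tibble::tibble(
    chrom = chrom,
    X0 = ifelse(dir == "right", ctr - len / 2, ctr + len / 2),
    X1 = ifelse(dir == "right", ctr + len / 2, ctr - len / 2),
    direction = dir,
    speed = if (is.null(speed)) rnorm(n, 2200, 400) else speed
  )
}

test_that("RFD takes its hand-computed values on toy coverage", {
  # 10 rightward forks covering one bin -> RFD = 1
  fk <- tibble::tibble(chrom = "c", X0 = rep(0, 10), X1 = rep(100, 10),
                       direction = "right")
  expect_equal(compute_rfd(fk, 100)$rfd, 1)
  # 5 right + 5 left -> 0; 3 right + 1 left -> 0.5
  fk <- tibble::tibble(chrom = "c", X0 = c(rep(0, 5), rep(100, 5)),
                       X1 = c(rep(100, 5), rep(0, 5)),
                       direction = rep(c("right", "left"), each = 5))
  expect_equal(compute_rfd(fk, 100)$rfd, 0)
  fk <- tibble::tibble(chrom = "c", X0 = c(0, 0, 0, 100), X1 = c(100, 100, 100, 0),
                       direction = c("right", "right", "right", "left"))
  expect_equal(compute_rfd(fk, 100)$rfd, 0.5)
})

test_that("RFD is bounded, missing where uncovered, and counts add up", {
  fk <- toy_forks(300, seed = 11)
  rfd <- compute_rfd(fk, 1000)
  defined <- !is.na(rfd$rfd)
  expect_true(all(abs(rfd$rfd[defined]) <= 1))
  expect_true(all(rfd$total == rfd$n_left + rfd$n_right))
  expect_true(all(rfd$total[!defined] == 0))
  expect_equal(rfd$rfd[defined],
               (rfd$n_right[defined] - rfd$n_left[defined]) / rfd$total[defined])
})

test_that("speed map flags a planted slow window and tags empty windows na", {
  fk <- toy_forks(20000, seed = 21)
  # plant: divide speeds by 5 inside a 2 kb window (~40 forks)
  sel <- (fk$X0 + fk$X1) / 2 >= 500000 & (fk$X0 + fk$X1) / 2 < 502000
  fk$speed[sel] <- fk$speed[sel] / 5
  sm <- speed_map(fk, widths = c(2000, 5000, 10000))
  hit <- sm[sm$width == 2000 & sm$start == 500000, ]
  expect_equal(hit$status, "slower")
  # wider windows containing it are flagged too (at 40 planted forks the
  # signal survives dilution up to ~10 kb)
  for (w in c(5000, 10000)) {
    hw <- sm[sm$width == w & sm$start == floor(500000 / w) * w, ]
    expect_equal(hw$status, "slower")
  }
  # na handling
  expect_true(all(sm$status[sm$n_forks == 0] == "na"))
  expect_true(all(is.na(sm$median_speed[sm$n_forks == 0])))
  # CI brackets the median
  ok <- sm$n_forks > 1
  expect_true(all(sm$ci_lo[ok] <= sm$median_speed[ok] + 1e-9))
  expect_true(all(sm$ci_hi[ok] >= sm$median_speed[ok] - 1e-9))
})

test_that("the speed map is invariant to fork ordering", {
  fk <- toy_forks(600, seed = 31)
  sm1 <- speed_map(fk, widths = c(10000, 20000))
  set.seed(32)
  sm2 <- speed_map(fk[sample(nrow(fk)), ], widths = c(10000, 20000))
  expect_equal(as.data.frame(sm1), as.data.frame(sm2))
})

test_that("Holm correction keeps the family-wise error at bay under the null", {
  # homogeneous speeds with no spatial structure: no window of any width
  # should reach significance
  fk <- toy_forks(6000, span = c(0, 5e5), seed = 41)
  sm <- speed_map(fk, widths = c(1, 2, 5, 10, 20) * 1000)
  expect_equal(sum(sm$status %in% c("slower", "faster")), 0)
})

test_that("the exact binomial median CI matches its nominal construction", {
  set.seed(51)
  x <- rnorm(201, 2000, 300)
  ci <- replifork:::median_ci(x, 0.98)
  s <- sort(x)
  l <- qbinom(0.01, 201, 0.5)
  expect_equal(ci, c(s[l], s[201 - l + 1]))
  expect_lte(ci[1], median(x))
  expect_gte(ci[2], median(x))
})

test_that("shuffle envelopes degenerate for constant speeds and cover medians", {
  fk <- toy_forks(400, span = c(0, 2e5), speed = 1800, seed = 61)
  env <- shuffle_envelope(fk, n_shuffles = 50, width = 20000, seed = 62)
  expect_true(all(env$shuffled_median == 1800))
  expect_true(all(env$lower == 1800 & env$upper == 1800))
  # homogeneous speeds: observed per-bin medians almost always inside the band
  fk <- toy_forks(4000, span = c(0, 4e5), seed = 63)
  env <- shuffle_envelope(fk, n_shuffles = 400, width = 20000, seed = 64)
  ctr <- (fk$X0 + fk$X1) / 2
  obs <- tapply(fk$speed, paste(fk$chrom, floor(ctr / 20000)), median)
  obs <- obs[match(paste(env$chrom, env$start / 20000), names(obs))]
  inside <- obs >= env$lower & obs <= env$upper
  expect_gte(mean(inside), 0.9)
})

test_that("feature overlap applies the one-nucleotide and exclusivity rules", {
  fk <- tibble::tibble(
    chrom = "chrI",
    X0 = c(10000, 30000, 50000), X1 = c(14000, 34000, 54000),
    direction = "right", speed = c(2000, 2100, 2200),
    sample = "s1"
  )
  feats <- tibble::tibble(
    chrom = "chrI",
    start = c(13999, 30500, 33900, 80000),
    end = c(14050, 31000, 34200, 81000),
    name = c("tRNA_1", "CEN_1", "tRNA_2", "tRNA_3"),
    strand = c("+", "+", "-", "+")
  )
  res <- feature_overlap_speeds(fk, feats)
  # 1 nt overlap counts (fork 1 ends at 14000 half-open; feature starts 13999)
  expect_equal(res$forks$feature[1], "tRNA_1")
  # fork 2 overlaps two features -> excluded from summaries
  expect_true(res$forks$multi_feature[2])
  expect_false("s1" %in% res$summary$sample[res$summary$feature == "CEN_1"])
  # fork 3 overlaps nothing
  expect_true(is.na(res$forks$feature[3]))
  expect_equal(res$summary$feature, "tRNA_1")
  expect_equal(res$summary$n, 1L)
})

test_that("stranded features are oriented CD/HO by the mean RFD sign", {
  fk <- tibble::tibble(chrom = "chrI", X0 = rep(0, 8), X1 = rep(20000, 8),
                       direction = "right", speed = 2000, sample = "s1")
  rfd <- compute_rfd(fk, 1000)
  feats <- tibble::tibble(chrom = "chrI", start = c(5000, 9000),
                          end = c(5200, 9100), name = c("plus", "minus"),
                          strand = c("+", "-"))
  res <- feature_overlap_speeds(fk[1, ], rfd = rfd, features = feats[1, ])
  expect_equal(unique(res$forks$orientation_class), "CD")
  res2 <- feature_overlap_speeds(fk[1, ], rfd = rfd, features = feats[2, ])
  expect_equal(unique(res2$forks$orientation_class), "HO")
})

test_that("speed versus timing recovers monotone and degenerate cases", {
  n <- 60
  fk <- tibble::tibble(
    chrom = "chrI", X0 = seq(0, by = 10000, length.out = n),
    X1 = seq(0, by = 10000, length.out = n) + 4000,
    direction = "right", speed = seq(1000, 3000, length.out = n)
  )
  timing <- tibble::tibble(chrom = "chrI",
                           start = seq(0, by = 10000, length.out = n),
                           end = seq(0, by = 10000, length.out = n) + 10000,
                           value = seq(0, 1, length.out = n))
  res <- speed_vs_timing(fk, timing)
  expect_equal(res$rho, 1)
  expect_equal(res$n, n)
  # constant speeds: correlation undefined
  fk$speed <- 2000
  expect_error(speed_vs_timing(fk, timing), "variance")
  # no overlap at all
  t2 <- timing; t2$chrom <- "chrX"
  fk$speed <- seq(1000, 3000, length.out = n)
  expect_error(speed_vs_timing(fk, t2), "intersect")
})

test_that("wiggle timing tracks are parsed and usable", {
  path <- withr::local_tempfile(fileext = ".wig")
  writeLines(c(
    "track type=wiggle_0",
    "fixedStep chrom=chrI start=1 step=10000 span=10000",
    sprintf("%.3f", seq(0, 1, length.out = 40))
  ), path)
  n <- 40
  fk <- tibble::tibble(
    chrom = "chrI", X0 = seq(0, by = 10000, length.out = n),
    X1 = seq(0, by = 10000, length.out = n) + 4000,
    direction = "right", speed = seq(1000, 3000, length.out = n)
  )
  res <- speed_vs_timing(fk, path)
  expect_gt(res$rho, 0.99)
})

test_that("sample summaries match the half-eye quantities", {
  s <- summarize_sample(tibble::tibble(speed = c(2000, 2100, 2200)))
  expect_equal(s$mean, 2100)
  expect_equal(s$median, 2100)
  one <- summarize_sample(tibble::tibble(speed = 1234))
  expect_true(all(one[, c("mean", "median", "q25", "q75", "q2.5", "q97.5")] == 1234))
  x <- rnorm(50, 2000, 100)
  a <- summarize_sample(tibble::tibble(speed = x))
  b <- summarize_sample(tibble::tibble(speed = c(x, x)))
  expect_equal(a$mean, b$mean)
  expect_equal(a$median, b$median)
})
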