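test_that("fork pattern truth table behaves as specified", {
  # B,P,N truncated by the read end: one rightward fork at the junctions
  f <- detect_forks(segments_from_labels(c("B", "P", "N")))
  expect_equal(nrow(f), 1)
  expect_equal(f$direction, "right")
  expect_equal(f$X0, 1000)  # B/P junction
  expect_equal(f$X1, 2000)  # P/N junction
  expect_gt(f$d_y, 0)

  # symmetric leftward pattern at the read start
  f <- detect_forks(segments_from_labels(c("P", "N", "B")))
  expect_equal(nrow(f), 1)
  expect_equal(f$direction, "left")
  expect_equal(f$X0, 2000)  # N/B junction
  expect_equal(f$X1, 1000)  # end of the leading P run

  # B,P,N,B: both candidates touch a bounding B and are rejected
  expect_equal(nrow(detect_forks(segments_from_labels(c("B", "P", "N", "B")))), 0)

  # P,N,B,P,N: a leftward and a rightward fork share the central B;
  # the rightward X0 is the B/P junction (x = 3000), its X1 the P/N
  # junction (x = 4000)
  f <- detect_forks(segments_from_labels(c("P", "N", "B", "P", "N")))
  expect_equal(f$direction, c("left", "right"))
  expect_equal(f$X0, c(2000, 3000))
  expect_equal(f$X1, c(1000, 4000))

  # A segments interrupt the pulse but not the pattern
  f <- detect_forks(segments_from_labels(c("B", "P", "A", "P", "N")))
  expect_equal(f$direction, "right")
  expect_equal(f$X0, 1000)
  expect_equal(f$X1, 4000)  # start of the first N

  # multiple N segments: X1 stays at the start of the first N
  f <- detect_forks(segments_from_labels(c("B", "P", "N", "N", "A")))
  expect_equal(f$X1, 2000)
})

test_that("fork matching agrees with a two-pass regex oracle on random strings", {
  set.seed(202)
  for (rep in 1:300) {
    labels <- sample(c("B", "A", "P", "N"), sample(3:12, 1), replace = TRUE)
    seg <- segments_from_labels(labels)
    got <- detect_forks(seg)
    ref <- regex_forks(labels)
    expect_equal(nrow(got), nrow(ref),
                 info = paste(labels, collapse = ""))
    if (nrow(got) && nrow(got) == nrow(ref)) {
      o <- order(got$seg_first)
      expect_equal(got$direction[o], ref$direction,
                   info = paste(labels, collapse = ""))
      expect_equal(got$seg_first[o], ref$first,
                   info = paste(labels, collapse = ""))
      expect_equal(got$seg_last[o], ref$last,
                   info = paste(labels, collapse = ""))
      # no overlap except a shared boundary B
      if (nrow(got) > 1) {
        expect_true(all(got$seg_first[o][-1] >= got$seg_last[o][-nrow(got)]))
      }
    }
  }
})

test_that("speed is track length over pulse time, symmetric in direction", {
  expect_equal(measure_speed(10000, 14200, 2), 2100)
  expect_equal(measure_speed(14200, 10000, 2), 2100)
  expect_error(measure_speed(5000, 5000, 2), "degenerate")
  expect_error(measure_speed(0, 100, 0), "t_pulse")
})

test_that("initiation and termination events sit at facing-landmark midpoints", {
  forks <- tibble::tibble(
    direction = c("left", "right"),
    X0 = c(50000, 60000), X1 = c(46000, 64000)
  )
  ev <- call_events(forks)
  expect_equal(ev$kind, "initiation")
  expect_equal(ev$position, 55000)

  forks <- tibble::tibble(
    direction = c("right", "left"),
    X0 = c(16000, 30000), X1 = c(20000, 26000)
  )
  ev <- call_events(forks)
  expect_equal(ev$kind, "termination")
  expect_equal(ev$position, 23000)

  expect_equal(nrow(call_events(forks[1, ])), 0)

  # diverging then converging on one read: one of each
  forks <- tibble::tibble(
    direction = c("left", "right", "left"),
    X0 = c(20000, 30000, 60000), X1 = c(15000, 38000, 52000)
  )
  ev <- call_events(forks)
  expect_equal(ev$kind, c("initiation", "termination"))
  expect_equal(ev$position, c(25000, 45000))
})

test_that("forks overlapping recorded gaps are filtered out", {
  forks <- tibble::tibble(direction = "right", X0 = 10000, X1 = 14000,
                          speed = 2000, d_y = 0.4)
  gap_in <- tibble::tibble(gap_start = 12000, gap_end = 12200)
  gap_out <- tibble::tibble(gap_start = 20000, gap_end = 21000)
  expect_equal(nrow(filter_gap_forks(forks, gap_in)), 0)
  expect_equal(nrow(filter_gap_forks(forks, gap_out)), 1)
  expect_equal(nrow(filter_gap_forks(forks, NULL)), 1)
})

test_that("leading/lagging classification follows the nascent-strand convention", {
  expect_equal(classify_strand("right", "+"), "leading")
  expect_equal(classify_strand("right", "-"), "lagging")
  expect_equal(classify_strand("left", "-"), "leading")
  expect_equal(classify_strand("left", "+"), "lagging")
  expect_equal(classify_strand("right", "+", convention = "template"),
               "lagging")
})

test_that("no fork is emitted from short, sparse or all-background reads", {
  p <- fork_params()
  # short read
  sim <- simulate_single_forks(1, speeds = 2000, noise = NULL, seed = 1,
                               pre_range = c(100, 200),
                               post_range = c(100, 200))
  sg <- sim$traces$signal[[1]]
  d <- replifork:::detect_one_read(sg$position, sg$prob, 0,
                                   sim$traces$end[1], "+", NULL, p)
  expect_null(d$forks)
  # all-background read
  pos <- seq(0, 19999, by = 4)
  d <- replifork:::detect_one_read(pos, rep(0.005, length(pos)), 0, 20000,
                                   "+", NULL, p)
  expect_null(d$forks)
})
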