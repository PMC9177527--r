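test_that("tabular traces round-trip losslessly and errors carry line numbers", {
  tr <- trace_tbl(
    read_id = c("a", "b"), chrom = c("chrI", "chrII"),
    start = c(0, 100), end = c(6000, 9000), strand = c("+", "-"),
    signal = list(
      data.frame(position = c(5, 50, 900, 1500, 2000), prob = c(0, 0.5, 1, 0.2, 0.8)),
      data.frame(position = c(150, 151), prob = c(0.25, 0.75))
    )
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_traces(tr, path)
  back <- read_traces(path)
  expect_equal(back$read_id, tr$read_id)
  expect_equal(back$start, tr$start)
  expect_equal(back$signal[[1]]$prob, tr$signal[[1]]$prob)
  expect_equal(back$signal[[2]]$position, tr$signal[[2]]$position)

  one <- read_traces(path)
  expect_s3_class(one, "trace_tbl")
  expect_equal(nrow(one$signal[[1]]), 5)
  expect_equal(nrow(one$signal[[2]]), 2)

  # probability outside [0,1]: error names the file line (header = line 1)
  bad <- readLines(path)
  bad[7] <- sub("\t[0-9.]+$", "\t1.2", bad[7])
  bad_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(bad, bad_path)
  expect_error(read_traces(bad_path), "line 7")

  # unsorted positions within a read
  swapped <- readLines(path)
  tmp <- swapped[2]; swapped[2] <- swapped[3]; swapped[3] <- tmp
  sw_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(swapped, sw_path)
  expect_error(read_traces(sw_path), "increasing")
})

test_that("trace invariants are enforced at construction", {
  expect_error(
    trace_tbl("r", "c", 0, 100, "+",
              list(data.frame(position = c(5, 5), prob = c(0.1, 0.2)))),
    "strictly increasing"
  )
  expect_error(
    trace_tbl("r", "c", 0, 100, "+",
              list(data.frame(position = 200, prob = 0.1))),
    "outside"
  )
  expect_error(
    trace_tbl("r", "c", 0, 100, "+",
              list(data.frame(position = 5, prob = 1.5))),
    "probabilities"
  )
})

make_test_bam <- function(records, dir) {
  sam <- file.path(dir, "t.sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chrT\tLN:100000",
    records
  ), sam)
  Rsamtools::asBam(sam, file.path(dir, "t"), overwrite = TRUE,
                   indexDestination = TRUE)
}

test_that("modified-base BAM parsing decodes MM/ML and projects through CIGAR", {
  dir <- withr::local_tempdir()
  # forward read at 1-based pos 1001, 10 bases, T at query offsets 1,4,7,10;
  # MM marks T ranks 1,2,3 -> query positions 1,4,7 -> 0-based refs
  # 1000, 1003, 1006; ML scores 0,128,255 -> (s+0.5)/256
  rec1 <- paste("r1", 0, "chrT", 1001, 60, "10M", "*", 0, 0,
                "TAATAATAAT", "*", "MM:Z:T+b,0,0,0;", "ML:B:C,0,128,255",
                sep = "\t")
  bam <- make_test_bam(rec1, dir)
  tr <- read_traces_bam(bam)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$start, 1000)
  expect_equal(tr$end, 1010)
  expect_equal(tr$signal[[1]]$position, c(1000, 1003, 1006))
  expect_equal(tr$signal[[1]]$prob, (c(0, 128, 255) + 0.5) / 256,
               tolerance = 1e-12)
})

test_that("deletions over the gap threshold are recorded, shorter ones not", {
  dir <- withr::local_tempdir()
  # 10M 150D 10M 60D 10M: only the 150 bp deletion is a gap; the T in the
  # second block (query 11 -> ref0 1000 + 10 + 150 = 1160) checks projection
  seq2 <- paste0("AAAAAAAAAA", "TAAAAAAAAA", "AAAAAAAAAA")
  rec <- paste("r2", 0, "chrT", 1001, 60, "10M150D10M60D10M", "*", 0, 0,
               seq2, "*", "MM:Z:T+b,0;", "ML:B:C,255", sep = "\t")
  bam <- make_test_bam(rec, dir)
  tr <- read_traces_bam(bam, min_gap_len = 100)
  gaps <- tr$gaps[[1]]
  expect_equal(nrow(gaps), 1)
  expect_equal(gaps$gap_end - gaps$gap_start, 150)
  expect_equal(gaps$gap_start, 1010)
  expect_equal(tr$signal[[1]]$position, 1160)
  expect_equal(tr$end - tr$start, 10 + 150 + 10 + 60 + 10)
})

test_that("reverse-strand reads count thymidines from the original read end", {
  dir <- withr::local_tempdir()
  # SEQ (forward genome orientation) AACCGGTTAA at 1-based 2001; original
  # read is its reverse complement TTAACCGGTT with T ranks 1,3 marked
  # (deltas 0,1): original positions 1 and 9 -> SEQ positions 10 and 2 ->
  # 0-based refs 2009 and 2001
  rec <- paste("r3", 16, "chrT", 2001, 60, "10M", "*", 0, 0,
               "AACCGGTTAA", "*", "MM:Z:T+b,0,1;", "ML:B:C,255,128",
               sep = "\t")
  bam <- make_test_bam(rec, dir)
  tr <- read_traces_bam(bam)
  expect_equal(tr$strand, "-")
  expect_equal(tr$signal[[1]]$position, c(2001, 2009))
  expect_equal(tr$signal[[1]]$prob, (c(128, 255) + 0.5) / 256,
               tolerance = 1e-12)
})

test_that("records without modification tags are skipped with a warning", {
  dir <- withr::local_tempdir()
  recs <- c(
    paste("good", 0, "chrT", 1001, 60, "4M", "*", 0, 0, "TTTT", "*",
          "MM:Z:T+b,0;", "ML:B:C,200", sep = "\t"),
    paste("bare", 0, "chrT", 3001, 60, "4M", "*", 0, 0, "TTTT", "*",
          sep = "\t")
  )
  bam <- make_test_bam(recs, dir)
  expect_warning(tr <- read_traces_bam(bam), "bare")
  expect_equal(tr$read_id, "good")
})

test_that("an empty BAM yields an empty trace table", {
  dir <- withr::local_tempdir()
  bam <- make_test_bam(character(0), dir)
  tr <- read_traces_bam(bam)
  expect_equal(nrow(tr), 0)
})

test_that("strand does not alter reference coordinates of a trace", {
  sig <- list(data.frame(position = seq(10, 5990, by = 7), prob = 0.3))
  fwd <- trace_tbl("r", "c", 0, 6000, "+", sig)
  rev <- trace_tbl("r", "c", 0, 6000, "-", sig)
  expect_equal(fwd$signal[[1]], rev$signal[[1]])
  p <- fork_params()
  s_f <- smooth_trace(fwd$signal[[1]]$position, fwd$signal[[1]]$prob, 0, 6000, p)
  s_r <- smooth_trace(rev$signal[[1]]$position, rev$signal[[1]]$prob, 0, 6000, p)
  expect_equal(s_f, s_r)
})
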