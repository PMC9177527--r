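#' Measurement-error experiment on single-fork reads
#'
#' Simulates reads each carrying one fork of known speed, runs the full
#' smoothing/segmentation/pattern pipeline on them and pairs every read's
#' detected fork with its ground truth. The detected fork retained for a read
#' is the one whose span overlaps the true track most. Work proceeds in
#' chunks so that arbitrarily large experiments run in constant memory.
#'
#' @param n_reads Number of simulated reads.
#' @param speeds True speeds (length `n_reads`) or `NULL` for the
#'   [sample_true_speeds()] stand-in distribution.
#' @param noise A [noise_params()] list or `NULL` (noise-free).
#' @param params A [fork_params()] list.
#' @param seed RNG seed.
#' @param chunk_size Reads simulated and detected per chunk.
#' @param ... Passed to [simulate_single_forks()] (kinetics etc.).
#' @return A tibble with one row per simulated read: `v_true`,
#'   `direction_true`, `detected`, `speed` (measured; `NA` when undetected),
#'   `direction`, `direction_ok`, `error` (= `speed - v_true`).
#' @examples
#' ev <- evaluate_single_forks(20, noise = NULL, seed = 1)
#' median(ev$error, na.rm = TRUE)
#' @export
evaluate_single_forks <- function(n_reads, speeds = NULL,
                                  noise = noise_params(),
                                  params = fork_params(), seed = NULL,
                                  chunk_size = 250L, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(speeds)) speeds <- sample_true_speeds(n_reads)
  stopifnot(length(speeds) == n_reads)
  starts <- seq(1L, n_reads, by = chunk_size)
  out <- vector("list", length(starts))
  for (ci in seq_along(starts)) {
    idx <- starts[ci]:min(starts[ci] + chunk_size - 1L, n_reads)
    sim <- simulate_single_forks(length(idx), speeds = speeds[idx],
                                 noise = noise, seed = NULL, ...)
    out[[ci]] <- match_single_truth(sim, params)
  }
  res <- dplyr::bind_rows(out)
  res$error <- res$speed - res$v_true
  res
}

match_single_truth <- function(sim, params) {
  tr <- sim$traces
  th <- sim$truth
  n <- nrow(tr)
  speed <- rep(NA_real_, n)
  direction <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    sig <- tr$signal[[i]]
    d <- detect_one_read(sig$position, sig$prob, tr$start[i], tr$end[i],
                         tr$strand[i], tr$gaps[[i]], params)
    fk <- d$forks
    if (is.null(fk) || !nrow(fk)) next
    lo_t <- min(th$X0_true[i], th$X1_true[i])
    hi_t <- max(th$X0_true[i], th$X1_true[i])
    ov <- pmin(pmax(fk$X0, fk$X1), hi_t) - pmax(pmin(fk$X0, fk$X1), lo_t)
    j <- which.max(ov)
    if (ov[j] <= 0) next
    speed[i] <- fk$speed[j]
    direction[i] <- fk$direction[j]
  }
  tibble::tibble(
    read_id = th$read_id, v_true = th$v_true,
    direction_true = th$direction,
    detected = !is.na(speed), speed = speed, direction = direction,
    direction_ok = direction == th$direction
  )
}

#' Measurement-error experiment on multi-fork genome reads
#'
#' Simulates replicating 300 kb segments sliced into reads
#' ([simulate_genome()]), detects forks on every read and compares each
#' measured speed with the segment's true speed (all forks of a segment
#' travel at the same speed). Orientation is checked against the ground-truth
#' fork owning the position of the detected fork's centre.
#'
#' @inheritParams evaluate_single_forks
#' @param chunk_reads Approximate number of reads simulated per chunk.
#' @param ... Passed to [simulate_genome()].
#' @return A tibble with one row per detected fork: `read_id`, `v_true`,
#'   `speed`, `error`, `direction`, `direction_ok`.
#' @export
evaluate_genome_forks <- function(n_reads, noise = noise_params(),
                                  params = fork_params(), seed = NULL,
                                  chunk_reads = 200L, ...) {
  if (!is.null(seed)) set.seed(seed)
  done <- 0L
  out <- list()
  while (done < n_reads) {
    nb <- min(chunk_reads, n_reads - done)
    sim <- simulate_genome(nb, noise = noise, seed = NULL, ...)
    out[[length(out) + 1L]] <- match_genome_truth(sim, params)
    done <- done + nrow(sim$traces)
  }
  dplyr::bind_rows(out)
}

match_genome_truth <- function(sim, params) {
  tr <- sim$traces
  th <- sim$truth
  ft <- sim$fork_truth
  rows <- list()
  for (i in seq_len(nrow(tr))) {
    sig <- tr$signal[[i]]
    d <- detect_one_read(sig$position, sig$prob, tr$start[i], tr$end[i],
                         tr$strand[i], tr$gaps[[i]], params)
    fk <- d$forks
    if (is.null(fk) || !nrow(fk)) next
    ftc <- ft[ft$chrom == tr$chrom[i], ]
    v_true <- th$v_true[i]
    ctr <- (fk$X0 + fk$X1) / 2
    dir_true <- vapply(ctr, function(p) {
      hit <- which(ftc$region_start <= p & p < ftc$region_end)
      if (length(hit)) ftc$direction[hit[1]] else NA_character_
    }, character(1))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      read_id = tr$read_id[i], v_true = v_true, speed = fk$speed,
      error = fk$speed - v_true, direction = fk$direction,
      direction_ok = fk$direction == dir_true
    )
  }
  dplyr::bind_rows(rows)
}

#' Median relative speed error per true-speed bin
#'
#' Groups paired (true, measured) speeds into bins of `bin` bp/min of true
#' speed and reports, per bin, the median signed error and the median
#' relative error in percent of the bin centre.
#'
#' @param pairs A tibble with `v_true` and `error` columns (from
#'   [evaluate_single_forks()] or [evaluate_genome_forks()]).
#' @param bin Bin width (bp/min).
#' @return A tibble with `bin_center`, `n`, `median_error`,
#'   `median_rel_error_pct`.
#' @export
speed_error_profile <- function(pairs, bin = 100) {
  ok <- pairs[!is.na(pairs$error), ]
  ctr <- (floor(ok$v_true / bin) + 0.5) * bin
  dplyr::summarise(
    dplyr::group_by(tibble::tibble(bin_center = ctr, error = ok$error),
                    .data$bin_center),
    n = dplyr::n(),
    median_error = stats::median(.data$error),
    median_rel_error_pct = 100 * stats::median(.data$error) / .data$bin_center[1],
    .groups = "drop"
  )
}
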