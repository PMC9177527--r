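#' Run the full fork-detection pipeline on a trace table
#'
#' For every read: smooth the per-thymidine probabilities ([smooth_trace()]),
#' simplify the smoothed signal into classified linear segments
#' ([segment_trace()]), search the label string for oriented fork patterns
#' ([detect_forks()]), drop forks overlapping mapping gaps
#' ([filter_gap_forks()]), classify leading/lagging synthesis
#' ([classify_strand()]) and call initiation/termination events
#' ([call_events()]). Reads shorter than `params$min_read_len` or producing
#' fewer than three segments cannot contain a complete fork and are skipped.
#'
#' @param traces A [trace_tbl] tibble.
#' @param params A [fork_params()] list.
#' @param sample Optional sample label attached to every fork.
#' @return An object of class `fork_calls`: a list with elements
#'   * `forks`: tibble of detected forks (`read_id`, `chrom`, `read_start`,
#'     `read_end`, `strand`, `X0`, `X1`, `direction`, `speed`, `d_y`, `type`,
#'     `sample`),
#'   * `events`: tibble of initiation/termination events,
#'   * `summary`: one-row tibble of pipeline counters,
#'   * `params`: the parameter list used.
#'   Use [tidy()][generics::tidy] to extract the fork table and
#'   [glance()][generics::glance] for the summary.
#' @examples
#' sim <- simulate_single_forks(4, noise = NULL, seed = 1)
#' fc <- call_forks(sim$traces)
#' glance(fc)
#' @export
call_forks <- function(traces, params = fork_params(), sample = NA_character_) {
  res <- purrr::pmap(
    list(traces$signal, traces$read_id, traces$chrom, traces$start,
         traces$end, traces$strand, traces$gaps),
    function(sig, id, ch, st, en, sd, gp) {
      detect_one_read(sig$position, sig$prob, st, en, sd, gp, params,
                      read_id = id, chrom = ch)
    }
  )
  forks <- dplyr::bind_rows(purrr::map(res, "forks"))
  events <- dplyr::bind_rows(purrr::map(res, "events"))
  if (nrow(forks)) forks$sample <- sample
  n_seg <- purrr::map_int(res, "n_segments")
  long_enough <- purrr::map_lgl(res, "long_enough")
  reads_with_forks <- purrr::map_lgl(res, function(r) !is.null(r$forks) && nrow(r$forks) > 0)
  med_len <- if (any(reads_with_forks)) {
    stats::median(traces$end[reads_with_forks] - traces$start[reads_with_forks])
  } else NA_real_
  summary <- tibble::tibble(
    n_reads = nrow(traces),
    n_long_enough = sum(long_enough),
    n_with_3_segments = sum(n_seg >= 3L),
    n_reads_with_forks = sum(reads_with_forks),
    n_forks = nrow(forks),
    n_events = nrow(events),
    median_read_len_with_forks = med_len
  )
  structure(
    list(forks = forks, events = events, summary = summary, params = params),
    class = "fork_calls"
  )
}

# Per-read pipeline on plain vectors; the hot path used by call_forks() and
# the simulation-evaluation drivers.
detect_one_read <- function(positions, probs, start, end, strand, gaps,
                            params, read_id = NA_character_,
                            chrom = NA_character_) {
  nothing <- list(forks = NULL, events = NULL, n_segments = 0L,
                  long_enough = FALSE)
  if ((end - start) < max(params$min_read_len, 2L * params$w2)) return(nothing)
  nothing$long_enough <- TRUE
  sm <- smooth_core(positions, probs, start, end,
                    w1 = params$w1, w2 = params$w2,
                    gauss_sd = params$gauss_sd, grid = params$grid)
  if (is.null(sm)) return(nothing)
  fin <- is.finite(sm$val)
  if (sum(fin) < 2L) return(nothing)
  y <- sm$val
  if (!all(fin)) y <- stats::approx(sm$pos[fin], y[fin], xout = sm$pos, rule = 2)$y
  br <- rdp_simplify(sm$pos, y, epsilon = params$epsilon)
  n_segments <- length(br) - 1L
  nothing$n_segments <- n_segments
  if (n_segments < 3L) return(nothing)
  seg <- classify_segments(br, sm$pos, y,
                           b2a_thr = params$b2a_thr, a_min = params$a_min)
  fk <- detect_forks(seg, t_pulse = params$t_pulse)
  fk <- fk[fk$d_y > params$min_d_y, , drop = FALSE]
  fk <- filter_gap_forks(fk, gaps)
  if (!nrow(fk)) return(nothing)
  ev <- call_events(fk)
  nf <- nrow(fk)
  fk <- tibble::new_tibble(
    list(
      read_id = rep(read_id, nf), chrom = rep(chrom, nf),
      read_start = rep(start, nf), read_end = rep(end, nf),
      strand = rep(strand, nf), X0 = fk$X0, X1 = fk$X1,
      direction = fk$direction, speed = fk$speed, d_y = fk$d_y,
      type = classify_strand(fk$direction, strand,
                             convention = params$leading_convention)
    ),
    nrow = nf
  )
  if (nrow(ev)) ev <- tibble::tibble(read_id = read_id, chrom = chrom,
                                     kind = ev$kind, position = ev$position)
  list(forks = fk, events = if (nrow(ev)) ev else NULL,
       n_segments = n_segments, long_enough = TRUE)
}

#' @export
print.fork_calls <- function(x, ...) {
  s <- x$summary
  cat("<fork_calls> ", s$n_forks, " forks on ", s$n_reads_with_forks,
      " of ", s$n_reads, " reads (", s$n_events, " events)\n", sep = "")
  if (nrow(x$forks)) {
    cat("  median speed: ", round(stats::median(x$forks$speed)), " bp/min\n",
        sep = "")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname call_forks
#' @param x A `fork_calls` object.
#' @param ... Unused.
#' @export
tidy.fork_calls <- function(x, ...) x$forks

#' @rdname call_forks
#' @export
glance.fork_calls <- function(x, ...) x$summary
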