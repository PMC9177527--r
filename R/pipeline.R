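#' Sample metadata attached to fork tables
#'
#' The experimental descriptors carried alongside each fork measurement:
#' experiment name, BrdU pulse concentration, pulse duration, thymidine
#' chase concentration, growth temperature, strain, mutant and hydroxyurea
#' dose.
#'
#' @param exp Experiment / run name.
#' @param b_pulse BrdU concentration during the pulse (uM).
#' @param t_pulse Pulse duration (min).
#' @param t_chase Thymidine concentration during the chase (uM).
#' @param temp Growth temperature (degrees C).
#' @param strain Strain name.
#' @param mutant `"WT"` or the inactivated gene.
#' @param hu Hydroxyurea concentration (mM).
#' @return A one-row tibble.
#' @export
sample_info <- function(exp = NA_character_, b_pulse = 100, t_pulse = 2,
                        t_chase = 1000, temp = 30, strain = NA_character_,
                        mutant = "WT", hu = 0) {
  tibble::tibble(Exp = exp, B_pulse = b_pulse, t_pulse = t_pulse,
                 T_chase = t_chase, temp = temp, strain = strain,
                 mutant = mutant, HU = hu)
}

#' Run the detection pipeline end to end and write its outputs
#'
#' Loads traces (tabular or modified-base BAM, decided by extension or
#' `format`), runs [call_forks()], and writes three files into `out_dir`:
#' `forks.tsv` (the fork table with sample metadata columns), `events.bed`
#' (initiation/termination events) and `summary.tsv` (pipeline counters).
#'
#' @param input Path to a trace TSV or BAM file, or a [trace_tbl] tibble.
#' @param out_dir Output directory (created if missing).
#' @param params A [fork_params()] list.
#' @param sample A [sample_info()] row.
#' @param format `"auto"`, `"tsv"` or `"bam"`.
#' @return The [call_forks()] result, invisibly.
#' @export
run_detect <- function(input, out_dir, params = fork_params(),
                       sample = sample_info(), format = "auto") {
  traces <- if (inherits(input, "trace_tbl")) {
    input
  } else {
    fmt <- if (format != "auto") format else
      if (grepl("\\.bam$", input, ignore.case = TRUE)) "bam" else "tsv"
    if (fmt == "bam") read_traces_bam(input, min_gap_len = params$min_gap_len)
    else read_traces(input)
  }
  fc <- call_forks(traces, params = params, sample = sample$Exp[1])
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  forks <- fc$forks
  if (nrow(forks)) {
    forks <- dplyr::bind_cols(forks,
                              sample[rep(1, nrow(forks)),
                                     setdiff(names(sample), character(0))])
  }
  readr::write_tsv(forks, file.path(out_dir, "forks.tsv"), progress = FALSE)
  write_events_bed(fc$events, file.path(out_dir, "events.bed"))
  readr::write_tsv(fc$summary, file.path(out_dir, "summary.tsv"),
                   progress = FALSE)
  invisible(fc)
}

write_events_bed <- function(events, path) {
  if (is.null(events) || !nrow(events)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  bed <- data.frame(
    chrom = events$chrom,
    start = format(pmax(round(events$position) - 1, 0), scientific = FALSE,
                   trim = TRUE),
    end = format(round(events$position), scientific = FALSE, trim = TRUE),
    name = events$kind
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a binned track as bedGraph
#'
#' @param track Tibble with `chrom`, `start`, `end` and the value column.
#' @param path Output path.
#' @param value Name of the value column.
#' @param na_rm Drop bins with missing values (default) rather than writing
#'   them.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, value = "rfd", na_rm = TRUE) {
  v <- track[[value]]
  keep <- if (na_rm) !is.na(v) else rep(TRUE, length(v))
  df <- data.frame(
    chrom = track$chrom[keep],
    start = format(track$start[keep], scientific = FALSE, trim = TRUE),
    end = format(track$end[keep], scientific = FALSE, trim = TRUE),
    value = v[keep]
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Simulate reads and write them in the interchange formats
#'
#' @param out_dir Output directory.
#' @param n_reads Number of reads.
#' @param mode `"single"` (one fork per read) or `"genome"` (multi-fork
#'   segments sliced into reads).
#' @param noise A [noise_params()] list or `NULL`.
#' @param seed RNG seed (required: simulation output must be reproducible).
#' @param ... Passed to [simulate_single_forks()] or [simulate_genome()].
#' @return The simulation result, invisibly; writes `traces.tsv` and
#'   `truth.tsv` (plus `fork_truth.tsv` in genome mode).
#' @export
run_simulate <- function(out_dir, n_reads, mode = c("single", "genome"),
                         noise = noise_params(), seed, ...) {
  mode <- match.arg(mode)
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  sim <- if (mode == "single") {
    simulate_single_forks(n_reads, noise = noise, seed = seed, ...)
  } else {
    simulate_genome(n_reads, noise = noise, seed = seed, ...)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_traces(sim$traces, file.path(out_dir, "traces.tsv"))
  readr::write_tsv(sim$truth, file.path(out_dir, "truth.tsv"),
                   progress = FALSE)
  if (!is.null(sim$fork_truth)) {
    readr::write_tsv(sim$fork_truth, file.path(out_dir, "fork_truth.tsv"),
                     progress = FALSE)
  }
  invisible(sim)
}

#' Aggregate a fork table into genome-wide maps and write them
#'
#' Computes the RFD track ([compute_rfd()]) and the multi-scale speed map
#' ([speed_map()]) and writes `rfd.bedgraph`, `coverage.bedgraph`,
#' `coverage_left.bedgraph`, `coverage_right.bedgraph` and `speed_map.tsv`.
#'
#' @param forks Fork tibble or path to a `forks.tsv` written by
#'   [run_detect()].
#' @param out_dir Output directory.
#' @param bin_size RFD bin width (bp).
#' @param widths Speed-map window widths (bp).
#' @return A list with `rfd` and `speed_map`, invisibly.
#' @export
run_map <- function(forks, out_dir, bin_size = 100,
                    widths = c(1:10, 15, 20) * 1000) {
  if (is.character(forks)) {
    forks <- readr::read_tsv(forks, show_col_types = FALSE, progress = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!nrow(forks)) {
    rfd <- NULL; sm <- NULL
    writeLines(character(0), file.path(out_dir, "rfd.bedgraph"))
    readr::write_tsv(tibble::tibble(), file.path(out_dir, "speed_map.tsv"),
                     progress = FALSE)
  } else {
    rfd <- compute_rfd(forks, bin_size = bin_size)
    write_bedgraph(rfd, file.path(out_dir, "rfd.bedgraph"), "rfd")
    write_bedgraph(rfd, file.path(out_dir, "coverage.bedgraph"), "total")
    write_bedgraph(rfd, file.path(out_dir, "coverage_left.bedgraph"), "n_left")
    write_bedgraph(rfd, file.path(out_dir, "coverage_right.bedgraph"), "n_right")
    sm <- speed_map(forks, widths = widths)
    readr::write_tsv(sm, file.path(out_dir, "speed_map.tsv"), progress = FALSE)
  }
  invisible(list(rfd = rfd, speed_map = sm))
}

#' Deconvolve a measured speed distribution and write the estimate
#'
#' Builds `n_repeats` independent response libraries, deconvolves the
#' observed speeds ([deconvolve_speeds()]) and writes `weights.tsv` (class
#' centre, weight) and `mixture.tsv` (continuous-fit parameters).
#'
#' @param observed_speeds Measured speeds, or a fork tibble / `forks.tsv`
#'   path whose `speed` column is used.
#' @param out_dir Output directory.
#' @param seed RNG seed (required).
#' @param n_repeats Number of independent response libraries.
#' @param library_reads Simulated reads per library.
#' @param noise,params As in [build_response_library()].
#' @return The `speed_deconv` object, invisibly.
#' @export
run_deconvolve <- function(observed_speeds, out_dir, seed,
                           n_repeats = 5, library_reads = 100000,
                           noise = noise_params(), params = fork_params()) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  if (is.character(observed_speeds)) {
    observed_speeds <- readr::read_tsv(observed_speeds,
                                       show_col_types = FALSE,
                                       progress = FALSE)
  }
  if (is.data.frame(observed_speeds)) observed_speeds <- observed_speeds$speed
  libs <- lapply(seq_len(n_repeats), function(r) {
    build_response_library(library_reads, seed = seed + r, noise = noise,
                           params = params)
  })
  est <- deconvolve_speeds(observed_speeds, libs, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(est$weights, file.path(out_dir, "weights.tsv"),
                   progress = FALSE)
  readr::write_tsv(est$mixture, file.path(out_dir, "mixture.tsv"),
                   progress = FALSE)
  invisible(est)
}
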