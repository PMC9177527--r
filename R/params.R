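#' Detection pipeline parameters
#'
#' Bundles every tunable of the trace-to-fork pipeline. Defaults reproduce the
#' standard analysis settings: a 2 min BrdU pulse, a two-stage smoothing
#' (100 bp rolling mean then 2.5 kb Gaussian-weighted rolling mean with the
#' first and last 2.5 kb of each read dropped), piecewise-linear
#' simplification at vertical tolerance 0.1, a background threshold of 0.02
#' separating B from A segments, and a minimum amplitude change of 0.05
#' separating sloped (P/N) from flat (B/A) segments.
#'
#' @param t_pulse BrdU pulse duration in minutes. Fork speed is the pulse-track
#'   length divided by `t_pulse`.
#' @param w1 Width (bp) of the first-stage centered rolling mean.
#' @param w2 Width (bp) of the Gaussian-weighted rolling mean; also the margin
#'   trimmed from both read ends, so reads shorter than `2 * w2` are excluded.
#' @param gauss_sd Standard deviation (bp) of the Gaussian kernel, truncated at
#'   `w2 / 2`. Defaults to `w2 / 6`.
#' @param epsilon Vertical (signal-axis) tolerance of the Ramer-Douglas-Peucker
#'   simplification, in signal units.
#' @param b2a_thr Background threshold (signal units): flat segments with mean
#'   signal below it are B, at or above it A. See
#'   [estimate_background_threshold()] for a data-driven estimate.
#' @param a_min Minimum total amplitude change (signal units) for a segment to
#'   be called sloped (P or N) rather than flat (B or A).
#' @param grid Lattice step (bp) at which the smoothed signal is evaluated for
#'   segmentation. 10 bp trades a <10 bp breakpoint quantisation for a large
#'   speed-up; set to 1 for dense evaluation.
#' @param min_read_len Minimum mapped read length (bp); shorter reads carry no
#'   analysable interior after trimming and are skipped.
#' @param min_gap_len Mapping gaps (reference deletions/skips) longer than this
#'   many bp are recorded and forks overlapping them are discarded.
#' @param min_d_y Optional minimum BrdU amplitude (signal at X1 minus at X0)
#'   for a fork to be kept; 0 disables the filter.
#' @param leading_convention Either `"nascent"` (nanopore reads the nascent,
#'   BrdU-substituted strand: a rightward fork on a forward-mapped read is
#'   leading-strand synthesis) or `"template"` for the opposite mapping.
#'
#' @return A list of class `fork_params`.
#' @examples
#' p <- fork_params(t_pulse = 2)
#' p$epsilon
#' @export
fork_params <- function(t_pulse = 2,
                        w1 = 100,
                        w2 = 2500,
                        gauss_sd = w2 / 6,
                        epsilon = 0.1,
                        b2a_thr = 0.02,
                        a_min = 0.05,
                        grid = 10L,
                        min_read_len = 2 * w2,
                        min_gap_len = 100,
                        min_d_y = 0,
                        leading_convention = c("nascent", "template")) {
  leading_convention <- match.arg(leading_convention)
  stopifnot(t_pulse > 0, w1 > 0, w2 > 0, epsilon > 0, a_min > 0, grid >= 1)
  structure(
    list(
      t_pulse = t_pulse, w1 = as.integer(w1), w2 = as.integer(w2),
      gauss_sd = gauss_sd, epsilon = epsilon, b2a_thr = b2a_thr,
      a_min = a_min, grid = as.integer(grid),
      min_read_len = as.integer(min_read_len),
      min_gap_len = as.integer(min_gap_len),
      min_d_y = min_d_y,
      leading_convention = leading_convention
    ),
    class = "fork_params"
  )
}

#' @export
print.fork_params <- function(x, ...) {
  cat("<fork_params>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
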