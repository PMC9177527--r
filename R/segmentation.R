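#' Ramer-Douglas-Peucker polyline simplification
#'
#' Recursively simplifies a signal into a piecewise-linear approximation:
#' starting from the chord joining the endpoints, the point of maximal
#' vertical (signal-axis) deviation is retained and the two halves are
#' simplified in turn, until every point lies within `epsilon` of the
#' interpolant. Deviation is measured on the signal axis only: abscissae are
#' in bp (1e3-1e5) while ordinates live in `[0, 1]`, so a Euclidean
#' point-to-chord distance would be degenerate. Ties at the maximal deviation
#' are broken towards the leftmost index for determinism.
#'
#' @param x Abscissae (bp), strictly increasing.
#' @param y Signal values; must be finite.
#' @param epsilon Vertical tolerance in signal units.
#' @return Sorted integer indices of the retained breakpoints, always
#'   including `1` and `length(y)`.
#' @examples
#' x <- 1:100
#' rdp_simplify(x, 0.001 * x, epsilon = 0.1)   # perfectly linear: endpoints
#' @export
rdp_simplify <- function(x, y, epsilon = 0.1) {
  n <- length(y)
  stopifnot(length(x) == n, n >= 2)
  if (any(!is.finite(y))) stop("non-finite values in signal; resolve missing values first")
  keep <- logical(n)
  keep[c(1L, n)] <- TRUE
  stack <- list(c(1L, n))
  while (length(stack)) {
    rg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i1 <- rg[1]; i2 <- rg[2]
    if (i2 - i1 < 2L) next
    ii <- i1:i2
    chord <- y[i1] + (y[i2] - y[i1]) * (x[ii] - x[i1]) / (x[i2] - x[i1])
    dev <- abs(y[ii] - chord)
    dev[c(1L, length(dev))] <- 0
    im <- which.max(dev)           # leftmost maximum
    if (dev[im] > epsilon) {
      j <- i1 + im - 1L
      keep[j] <- TRUE
      stack <- c(stack, list(c(i1, j), c(j, i2)))
    }
  }
  which(keep)
}

#' Classify piecewise-linear segments into B/A/P/N categories
#'
#' Each inter-breakpoint piece is labelled from its total amplitude change and
#' mean signal: `P` if it rises by at least `a_min`, `N` if it falls by at
#' least `a_min`, otherwise flat - `B` (background) when the mean signal is
#' below `b2a_thr`, `A` (above background) when it is not. The labels form the
#' alphabet of the fork-pattern search in [detect_forks()].
#'
#' @param breaks Breakpoint indices into `x`/`y` (from [rdp_simplify()]).
#' @param x Abscissae (bp) of the signal points.
#' @param y Signal values.
#' @param b2a_thr Background threshold (signal units).
#' @param a_min Minimum amplitude change for a sloped call (signal units).
#' @return A tibble with one row per segment: `x_start`, `x_end`, `y_start`,
#'   `y_end`, `mean_signal`, `label`.
#' @export
classify_segments <- function(breaks, x, y, b2a_thr = 0.02, a_min = 0.05) {
  stopifnot(length(breaks) >= 2)
  cs <- c(0, cumsum(y))
  s <- breaks[-length(breaks)]
  e <- breaks[-1]
  # mean over the half-open index range [s, e); the final segment includes
  # its right endpoint so every point contributes to exactly one segment
  e_idx <- e - 1L
  e_idx[length(e_idx)] <- e[length(e)]
  mean_sig <- (cs[e_idx + 1L] - cs[s]) / (e_idx - s + 1L)
  dy <- y[e] - y[s]
  label <- ifelse(dy >= a_min, "P",
           ifelse(-dy >= a_min, "N",
           ifelse(mean_sig < b2a_thr, "B", "A")))
  tibble::tibble(
    x_start = x[s], x_end = x[e],
    y_start = y[s], y_end = y[e],
    mean_signal = mean_sig, label = label
  )
}

#' Segment a smoothed trace
#'
#' Convenience wrapper: fills interior missing values of the smoothed signal
#' by linear interpolation, runs [rdp_simplify()] at `params$epsilon` and
#' classifies the pieces with [classify_segments()].
#'
#' @param smoothed A tibble with columns `position`, `value` (see
#'   [smooth_trace()]).
#' @param params A [fork_params()] list.
#' @return A segment tibble (see [classify_segments()]); zero rows when fewer
#'   than two finite signal points are available.
#' @export
segment_trace <- function(smoothed, params = fork_params()) {
  x <- smoothed$position
  y <- smoothed$value
  fin <- is.finite(y)
  if (sum(fin) < 2L) {
    return(tibble::tibble(
      x_start = numeric(0), x_end = numeric(0), y_start = numeric(0),
      y_end = numeric(0), mean_signal = numeric(0), label = character(0)
    ))
  }
  if (!all(fin)) {
    y <- stats::approx(x[fin], y[fin], xout = x, rule = 2)$y
  }
  br <- rdp_simplify(x, y, epsilon = params$epsilon)
  classify_segments(br, x, y, b2a_thr = params$b2a_thr, a_min = params$a_min)
}

#' Estimate the background threshold from a set of reads
#'
#' DNA replicated before the BrdU pulse carries a near-zero signal, while
#' labelled DNA sits well above it; the density of per-1-kb-window mean BrdU
#' values is therefore bimodal and its valley separates background from
#' labelled DNA. This function computes window means over reads that produce
#' at least three segments, locates the background mode (the density maximum
#' nearest zero) and the labelled mode (the strongest maximum above it), and
#' returns the position of the lowest-valued density minimum between them.
#' When fewer than `min_reads` qualify or no interior minimum exists, the
#' default threshold is returned with a warning.
#'
#' @param traces A [trace_tbl] tibble.
#' @param params A [fork_params()] list (smoothing/segmentation settings and
#'   the fallback `b2a_thr`).
#' @param window Window width (bp) for the per-read mean BrdU values.
#' @param min_reads Minimum number of qualifying reads.
#' @return The background threshold, in signal units.
#' @export
estimate_background_threshold <- function(traces, params = fork_params(),
                                          window = 1000, min_reads = 100) {
  n_seg <- vapply(seq_len(nrow(traces)), function(i) {
    sig <- traces$signal[[i]]
    sm <- smooth_core(sig$position, sig$prob, traces$start[i], traces$end[i],
                      w1 = params$w1, w2 = params$w2,
                      gauss_sd = params$gauss_sd, grid = params$grid)
    if (is.null(sm)) return(0L)
    fin <- is.finite(sm$val)
    if (sum(fin) < 2L) return(0L)
    y <- sm$val
    if (!all(fin)) y <- stats::approx(sm$pos[fin], y[fin], xout = sm$pos, rule = 2)$y
    length(rdp_simplify(sm$pos, y, params$epsilon)) - 1L
  }, integer(1))
  qual <- which(n_seg >= 3L)
  if (length(qual) < min_reads) {
    warning("only ", length(qual), " reads with >= 3 segments; ",
            "falling back to default threshold ", params$b2a_thr)
    return(params$b2a_thr)
  }
  wm <- unlist(lapply(qual, function(i) {
    sig <- traces$signal[[i]]
    win <- floor((sig$position - traces$start[i]) / window)
    tapply(sig$prob, win, mean, na.rm = TRUE)
  }), use.names = FALSE)
  wm <- wm[is.finite(wm)]
  density_valley(wm, fallback = params$b2a_thr)
}

# Valley of a bimodal density: lowest local minimum between the mode nearest
# zero and the strongest mode above it. The background mode is far sharper
# than the labelled one, so the global bandwidth is halved to keep the
# valley from being smeared towards the labelled mode.
density_valley <- function(x, fallback = 0.02, n = 512, adjust = 0.5) {
  d <- stats::density(x, n = n, from = min(x), to = max(x), adjust = adjust)
  y <- d$y
  dy <- diff(y)
  locmax <- which(diff(sign(dy)) < 0) + 1L
  locmin <- which(diff(sign(dy)) > 0) + 1L
  # ignore micro-bumps: candidate modes carry at least 5% of the peak density
  cand <- locmax[y[locmax] >= 0.05 * max(y)]
  if (length(cand) < 2 || !length(locmin)) return(fallback_warn(fallback))
  bg <- cand[1]
  above <- cand[cand > bg]
  lab <- above[which.max(y[above])]
  mid <- locmin[locmin > bg & locmin < lab]
  if (!length(mid)) return(fallback_warn(fallback))
  valley <- mid[which.min(y[mid])]
  # a genuine dip separates the modes; otherwise the data are unimodal
  if (y[valley] >= 0.5 * min(y[bg], y[lab])) return(fallback_warn(fallback))
  d$x[valley]
}

fallback_warn <- function(fallback) {
  warning("no interior density minimum found; using default threshold ", fallback)
  fallback
}
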