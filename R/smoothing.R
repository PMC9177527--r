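#' Smooth a BrdU trace
#'
#' Two-stage smoothing of the sparse per-thymidine probabilities into a dense
#' signal defined at every position (or every `grid`-th position) of the read
#' interior: a centered rolling mean of width `w1` over the available
#' probabilities, followed by a Gaussian-weighted rolling mean of window `w2`
#' (kernel truncated at `w2 / 2`, standard deviation `gauss_sd`). Both stages
#' renormalise their weights over non-missing values, so non-thymidine
#' positions carry a value wherever any thymidine falls inside the window.
#' The first and last `w2` of the read are dropped; reads shorter than
#' `2 * w2` yield an empty result.
#'
#' @param positions Sorted reference positions of thymidine calls (0-based).
#' @param probs BrdU probabilities at `positions`, in `[0, 1]`.
#' @param start,end Reference span of the read (0-based half-open).
#' @param params A [fork_params()] list (uses `w1`, `w2`, `gauss_sd`).
#' @param grid Evaluation lattice step in bp (1 = dense).
#' @return A tibble with columns `position`, `value`, covering
#'   `[start + w2, end - w2)`; zero rows when the read is too short.
#' @examples
#' tr <- tibble::tibble(position = seq(0, 9999, by = 4), prob = 0.5)
#' sm <- smooth_trace(tr$position, tr$prob, 0, 10000)
#' range(sm$value)
#' @export
smooth_trace <- function(positions, probs, start, end,
                         params = fork_params(), grid = 1L) {
  out <- smooth_core(positions, probs, start, end,
                     w1 = params$w1, w2 = params$w2,
                     gauss_sd = params$gauss_sd, grid = grid)
  if (is.null(out)) {
    return(tibble::tibble(position = numeric(0), value = numeric(0)))
  }
  tibble::tibble(position = out$pos, value = out$val)
}

#' Add smoothed signals to a trace table
#'
#' @param traces A [trace_tbl] tibble.
#' @inheritParams smooth_trace
#' @return `traces` with a `smoothed` list-column of tibbles
#'   (`position`, `value`) and a logical `excluded` column flagging reads
#'   shorter than `2 * w2`.
#' @export
smooth_traces <- function(traces, params = fork_params(), grid = 1L) {
  sm <- purrr::pmap(
    list(traces$signal, traces$start, traces$end),
    function(sig, st, en) {
      smooth_trace(sig$position, sig$prob, st, en, params = params, grid = grid)
    }
  )
  traces$smoothed <- sm
  traces$excluded <- vapply(sm, nrow, integer(1)) == 0L
  traces
}

# Core smoother on plain vectors; returns NULL for short reads.
smooth_core <- function(positions, probs, start, end,
                        w1 = 100L, w2 = 2500L, gauss_sd = w2 / 6,
                        grid = 1L) {
  L <- as.integer(round(end - start))
  if (L < 2L * w2 || length(positions) < 1L) return(NULL)
  grid <- as.integer(grid)
  ok <- !is.na(probs)
  idx <- as.integer(round(positions[ok] - start)) + 1L
  v <- numeric(L)
  a <- numeric(L)
  v[idx] <- probs[ok]
  a[idx] <- 1
  # stage 1: centered box mean, weights renormalised over available values
  h <- as.integer(w1) %/% 2L
  cv <- c(0, cumsum(v))
  ca <- c(0, cumsum(a))
  g <- seq(1L, L, by = grid)
  lo <- pmax(g - h, 1L)
  hi <- pmin(g + h, L)
  den <- ca[hi + 1L] - ca[lo]
  s1 <- (cv[hi + 1L] - cv[lo]) / den
  s1[den == 0] <- NA_real_
  # stage 2: truncated Gaussian weighted mean on the evaluation lattice
  avail <- !is.na(s1)
  halfk <- (w2 %/% 2L) %/% grid
  kx <- (-halfk:halfk) * grid
  kern <- exp(-0.5 * (kx / gauss_sd)^2)
  num <- conv_same(ifelse(avail, s1, 0), kern)
  dn <- conv_same(as.numeric(avail), kern)
  s2 <- ifelse(dn > 1e-12, num / dn, NA_real_)
  s2 <- pmin(pmax(s2, 0), 1)
  keep <- g >= (w2 + 1L) & g <= (L - w2)
  if (!any(keep)) return(NULL)
  list(pos = start + g[keep] - 1L, val = s2[keep])
}

# FFT-based "same"-size convolution with a centered odd-length kernel.
conv_same <- function(x, k) {
  n <- length(x)
  m <- length(k)
  h <- (m - 1L) %/% 2L
  N <- stats::nextn(n + m - 1L, 2)
  fx <- stats::fft(c(x, numeric(N - n)))
  fk <- stats::fft(c(k, numeric(N - m)))
  full <- Re(stats::fft(fx * fk, inverse = TRUE)) / N
  full[(h + 1L):(h + n)]
}
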