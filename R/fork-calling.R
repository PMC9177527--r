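#' Detect and orient replication forks in a segmented read
#'
#' Scans the B/A/P/N label string of one read left-to-right for the two fork
#' patterns. A rightward fork is `B P (P|A)* N+`: a background segment
#' replicated before the pulse, a rising pulse track (possibly interrupted by
#' flat above-background segments due to noise) and at least one falling
#' chase segment; the match is rejected when the segment immediately after
#' the final N is a B, since DNA replicated during the chase retains an
#' above-background BrdU level. A leftward fork is the mirror pattern
#' `P+ (N|A)* N B`, rejected when the segment before its first P is a B.
#' Matches never overlap, except that one B segment may serve as both the
#' right boundary of a leftward fork and the left boundary of the adjacent
#' rightward fork. Matches truncated by a read end are kept as long as both
#' landmark junctions exist.
#'
#' Landmarks: for a rightward fork, `X0` (start of BrdU incorporation) is the
#' B/P junction and `X1` (start of the chase) the junction between the last
#' P-or-A segment and the first N; for a leftward fork, `X0` is the N/B
#' junction and `X1` the end of the leading run of P segments. Speed is
#' `|X1 - X0| / t_pulse` and `d_y` the fitted signal at `X1` minus at `X0`.
#'
#' @param segments Segment tibble for one read (see [classify_segments()]),
#'   in genomic order.
#' @param t_pulse Pulse duration in minutes.
#' @return A tibble with one row per fork: `direction` (`"left"`/`"right"`),
#'   `X0`, `X1`, `speed` (bp/min), `d_y`, and the first/last segment indices
#'   of the match (`seg_first`, `seg_last`).
#' @examples
#' seg <- tibble::tibble(
#'   x_start = c(0, 4000, 8000), x_end = c(4000, 8000, 15000),
#'   y_start = c(0.01, 0.01, 0.55), y_end = c(0.01, 0.55, 0.12),
#'   mean_signal = c(0.01, 0.3, 0.3), label = c("B", "P", "N")
#' )
#' detect_forks(seg)  # one rightward fork, X0 = 4000, X1 = 8000
#' @export
detect_forks <- function(segments, t_pulse = 2) {
  lab <- segments$label
  n <- length(lab)
  empty <- tibble::tibble(
    direction = character(0), X0 = numeric(0), X1 = numeric(0),
    speed = numeric(0), d_y = numeric(0),
    seg_first = integer(0), seg_last = integer(0)
  )
  if (n < 3L) return(empty)
  # breakpoints: segment s spans [bx[s], bx[s+1]) with fitted values by
  bx <- c(segments$x_start, segments$x_end[n])
  by <- c(segments$y_start, segments$y_end[n])
  # the two patterns are searched independently, each scan finding
  # non-overlapping matches left-to-right; exclusions are applied per match
  # afterwards, so a rejected match of one pattern never blocks the other.
  # Surviving matches cannot overlap beyond a shared boundary B: a kept
  # rightward match never ends before a B, a kept leftward match never
  # starts after one.
  res_dir <- character(0); res_x0 <- res_x1 <- res_dy <- numeric(0)
  res_sf <- res_sl <- integer(0)
  # rightward pass: B P (P|A)* N+, not followed by B
  i <- 1L
  while (i < n) {
    if (lab[i] == "B" && lab[i + 1L] == "P") {
      k <- i + 2L
      while (k <= n && lab[k] %in% c("P", "A")) k <- k + 1L
      if (k <= n && lab[k] == "N") {
        e <- k
        while (e <= n && lab[e] == "N") e <- e + 1L       # N-run = k..e-1
        rejected <- e <= n && lab[e] == "B"
        if (!rejected) {
          res_dir <- c(res_dir, "right")
          res_x0 <- c(res_x0, bx[i + 1L]); res_x1 <- c(res_x1, bx[k])
          res_dy <- c(res_dy, by[k] - by[i + 1L])
          res_sf <- c(res_sf, i); res_sl <- c(res_sl, e - 1L)
        }
        i <- e
      } else {
        i <- k            # no B inside the pulse run; resume at its end
      }
    } else {
      i <- i + 1L
    }
  }
  # leftward pass: P+ (N|A)* N B, not preceded by B
  i <- 1L
  while (i <= n) {
    if (lab[i] == "P") {
      j <- i
      while (j <= n && lab[j] == "P") j <- j + 1L        # P-run = i..j-1
      k <- j
      while (k <= n && lab[k] %in% c("N", "A")) k <- k + 1L
      if (k <= n && lab[k] == "B" && k > j && lab[k - 1L] == "N") {
        rejected <- i > 1L && lab[i - 1L] == "B"
        if (!rejected) {
          res_dir <- c(res_dir, "left")
          res_x0 <- c(res_x0, bx[k]); res_x1 <- c(res_x1, bx[j])
          res_dy <- c(res_dy, by[j] - by[k])
          res_sf <- c(res_sf, i); res_sl <- c(res_sl, k)
        }
        i <- k + 1L       # resume after the match
      } else {
        i <- k            # later starts inside this run fail identically
      }
    } else {
      i <- i + 1L
    }
  }
  if (!length(res_dir)) return(empty)
  o <- order(res_sf)
  tibble::new_tibble(
    list(direction = res_dir[o], X0 = res_x0[o], X1 = res_x1[o],
         speed = abs(res_x1[o] - res_x0[o]) / t_pulse, d_y = res_dy[o],
         seg_first = res_sf[o], seg_last = res_sl[o]),
    nrow = length(res_dir)
  )
}

#' Fork speed from its landmark positions
#'
#' @param x0,x1 Positions (bp) of the start of BrdU incorporation and of the
#'   chase; vectorised.
#' @param t_pulse Pulse duration in minutes.
#' @return Speed in bp/min, `|x1 - x0| / t_pulse`.
#' @export
measure_speed <- function(x0, x1, t_pulse = 2) {
  stopifnot(t_pulse > 0)
  if (any(x0 == x1)) stop("degenerate fork: X0 == X1")
  abs(x1 - x0) / t_pulse
}

#' Call initiation and termination events from a read's forks
#'
#' On reads carrying several forks, a diverging pair (a leftward fork
#' followed, in genomic order, by a rightward fork) marks an initiation event
#' at the midpoint of their facing `X0` positions; a converging pair
#' (rightward then leftward) marks a termination event at the midpoint of the
#' facing `X1` positions.
#'
#' @param forks Fork tibble of one read (see [detect_forks()]).
#' @return A tibble with columns `kind` (`"initiation"`/`"termination"`) and
#'   `position`; zero rows for reads with fewer than two forks.
#' @export
call_events <- function(forks) {
  empty <- tibble::tibble(kind = character(0), position = numeric(0))
  if (nrow(forks) < 2L) return(empty)
  o <- order(pmin(forks$X0, forks$X1))
  f <- forks[o, ]
  kind <- character(0); posn <- numeric(0)
  for (i in seq_len(nrow(f) - 1L)) {
    if (f$direction[i] == "left" && f$direction[i + 1L] == "right") {
      kind <- c(kind, "initiation")
      posn <- c(posn, (f$X0[i] + f$X0[i + 1L]) / 2)
    } else if (f$direction[i] == "right" && f$direction[i + 1L] == "left") {
      kind <- c(kind, "termination")
      posn <- c(posn, (f$X1[i] + f$X1[i + 1L]) / 2)
    }
  }
  tibble::tibble(kind = kind, position = posn)
}

#' Remove forks overlapping mapping gaps
#'
#' Discontinuities introduced at the mapping step interfere with speed
#' measurement; forks whose `[min(X0, X1), max(X0, X1)]` interval intersects
#' a recorded gap are dropped.
#'
#' @param forks Fork tibble.
#' @param gaps Tibble with `gap_start`, `gap_end` (0-based half-open), or
#'   `NULL`.
#' @return The filtered fork tibble.
#' @export
filter_gap_forks <- function(forks, gaps) {
  if (is.null(gaps) || !nrow(gaps) || !nrow(forks)) return(forks)
  lo <- pmin(forks$X0, forks$X1)
  hi <- pmax(forks$X0, forks$X1)
  hit <- vapply(seq_len(nrow(forks)), function(i) {
    any(lo[i] < gaps$gap_end & hi[i] > gaps$gap_start)
  }, logical(1))
  forks[!hit, ]
}

#' Leading- versus lagging-strand classification
#'
#' Nanopore sequencing reads the nascent, BrdU-substituted strand, so under
#' the default `"nascent"` convention a rightward fork detected on a
#' forward-mapped read corresponds to leading-strand synthesis, and the three
#' other combinations follow by symmetry. `"template"` flips the mapping.
#'
#' @param direction `"left"` or `"right"` (vectorised).
#' @param strand `"+"` or `"-"` read mapping strand (vectorised).
#' @param convention `"nascent"` (default) or `"template"`.
#' @return Character vector, `"leading"` or `"lagging"`.
#' @export
classify_strand <- function(direction, strand,
                            convention = c("nascent", "template")) {
  convention <- match.arg(convention)
  lead <- (direction == "right") == (strand == "+")
  if (convention == "template") lead <- !lead
  ifelse(lead, "leading", "lagging")
}
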