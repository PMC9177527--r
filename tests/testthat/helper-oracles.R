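# Independent reference implementations used as oracles. They deliberately
# share no code with the package: plain recursive RDP, windowed O(n * w)
# smoothing loops, and a two-pass regex fork matcher mirroring the pattern
# definitions.

naive_rdp <- function(x, y, eps) {
  rec <- function(i1, i2) {
    if (i2 - i1 < 2) return(c(i1, i2))
    ii <- i1:i2
    chord <- y[i1] + (y[i2] - y[i1]) * (x[ii] - x[i1]) / (x[i2] - x[i1])
    dev <- abs(y[ii] - chord)
    dev[c(1, length(dev))] <- 0
    m <- which.max(dev)
    if (dev[m] <= eps) return(c(i1, i2))
    j <- i1 + m - 1L
    c(rec(i1, j), rec(j, i2))
  }
  sort(unique(rec(1L, length(x))))
}

# Two-stage smoothing by direct window loops (box then truncated Gaussian),
# weights renormalised over available values; returns the trimmed interior.
naive_smooth <- function(positions, probs, start, end, w1 = 100, w2 = 2500,
                         gauss_sd = w2 / 6) {
  L <- end - start
  val <- rep(NA_real_, L)
  val[positions - start + 1] <- probs
  h1 <- w1 %/% 2
  s1 <- vapply(seq_len(L), function(i) {
    win <- max(1, i - h1):min(L, i + h1)
    v <- val[win]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  hk <- w2 %/% 2
  idx <- (w2 + 1):(L - w2)
  s2 <- vapply(idx, function(i) {
    win <- max(1, i - hk):min(L, i + hk)
    w <- exp(-0.5 * ((win - i) / gauss_sd)^2)
    v <- s1[win]
    ok <- !is.na(v)
    if (!any(ok)) NA_real_ else sum(w[ok] * v[ok]) / sum(w[ok])
  }, numeric(1))
  list(pos = start + idx - 1, val = s2)
}

# Fork matching oracle: two independent non-overlapping regex passes over
# the label string ("BP(P|A)*N+" rightward, "P+(N|A)*NB" leftward) followed
# by the boundary-B exclusions. Returns a data.frame of kept matches with
# 1-based first/last segment indices.
regex_forks <- function(labels) {
  s <- paste(labels, collapse = "")
  n <- nchar(s)
  collect <- function(pattern) {
    m <- gregexpr(pattern, s)[[1]]
    if (m[1] == -1) return(NULL)
    data.frame(first = as.integer(m),
               last = as.integer(m) + attr(m, "match.length") - 1L)
  }
  right <- collect("BP(P|A)*N+")
  if (!is.null(right)) {
    keep <- right$last == n | substring(s, right$last + 1, right$last + 1) != "B"
    right <- right[keep, , drop = FALSE]
  }
  left <- collect("P+(N|A)*NB")
  if (!is.null(left)) {
    keep <- left$first == 1 | substring(s, left$first - 1, left$first - 1) != "B"
    left <- left[keep, , drop = FALSE]
  }
  out <- rbind(
    if (!is.null(right) && nrow(right)) cbind(right, direction = "right"),
    if (!is.null(left) && nrow(left)) cbind(left, direction = "left")
  )
  if (is.null(out)) return(data.frame(first = integer(), last = integer(),
                                      direction = character()))
  out[order(out$first), , drop = FALSE]
}

# Segment tibble from a label string, with synthetic breakpoints: segment i
# spans [1000 * (i-1), 1000 * i) and y values consistent with the labels
# (P rises by 0.3, N falls by 0.3, flats keep their level; B sits at 0.01).
segments_from_labels <- function(labels) {
  n <- length(labels)
  y <- numeric(n + 1)
  y[1] <- if (labels[1] %in% c("B", "P")) 0.01 else 0.4
  for (i in seq_len(n)) {
    y[i + 1] <- switch(labels[i],
      P = y[i] + 0.3,
      N = max(y[i] - 0.3, 0.01),
      y[i]
    )
  }
  tibble::tibble(
    x_start = 1000 * (seq_len(n) - 1), x_end = 1000 * seq_len(n),
    y_start = y[-(n + 1)], y_end = y[-1],
    mean_signal = ifelse(labels == "B", 0.01,
                  ifelse(labels == "A", 0.4, (y[-(n + 1)] + y[-1]) / 2)),
    label = labels
  )
}

# A well-separated bimodal sample for background-threshold tests.
bimodal_windows <- function(n, seed) {
  set.seed(seed)
  c(abs(rnorm(n, 0.005, 0.002)), rnorm(n, 0.30, 0.05))
}
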