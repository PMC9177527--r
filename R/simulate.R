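#' Kinetic parameters of the pulse-chase BrdU incorporation model
#'
#' Intracellular BrdU availability during a pulse-chase experiment is
#' modelled as zero before the pulse, an exponential rise
#' `As(t) = M (1 - exp(-t / tau1))` during the pulse, and an exponential
#' relaxation `Ds(t) = As(t_pulse) + (m - As(t_pulse)) (1 - exp(-(t -
#' t_pulse) / tau2))` towards the asymptotic chase level `m` afterwards.
#' The defaults reproduce the canonical signal shape of 2-min pulse-labelled
#' yeast reads: the signal rises from 0 to a peak of about 0.5 at the end of
#' the pulse (`As(2) = 0.80 M` with `tau1 = 1.25`, so the ascent is still
#' visibly climbing when the chase starts and the track shows a peak rather
#' than a plateau, with the ascending slope steeper than the descending one
#' throughout) and relaxes towards about 0.1 during the chase. Real
#' libraries show fork-to-fork variability, emulated by [sample_kinetics()].
#'
#' @param M Saturating BrdU signal level (unitless, in `(0, 1]`).
#' @param tau1 Characteristic intake time (min).
#' @param m Asymptotic chase signal level (unitless, `0 < m < M`).
#' @param tau2 Characteristic outtake time (min).
#' @param t_pulse Pulse duration (min).
#' @return A list of class `kinetic_params`.
#' @export
kinetic_params <- function(M = 0.62, tau1 = 1.25, m = 0.10, tau2 = 5,
                           t_pulse = 2) {
  if (!(m > 0 && m < M && M <= 1)) stop("need 0 < m < M <= 1")
  if (!(tau1 > 0 && tau2 > 0 && t_pulse > 0)) stop("tau1, tau2, t_pulse must be > 0")
  structure(list(M = M, tau1 = tau1, m = m, tau2 = tau2, t_pulse = t_pulse),
            class = "kinetic_params")
}

#' Draw per-fork kinetic parameters around a base set
#'
#' Applies independent mean-preserving log-normal jitter (coefficient of
#' variation `cv`) to `M`, `tau1`, `m` and `tau2`, clamping the results to
#' the model constraints `0 < m < M <= 1`.
#'
#' @param n Number of parameter sets.
#' @param base A [kinetic_params()] list.
#' @param cv Coefficient of variation of the jitter.
#' @return A tibble with columns `M`, `tau1`, `m`, `tau2`, `t_pulse`.
#' @export
sample_kinetics <- function(n, base = kinetic_params(), cv = 0.2) {
  sdl <- sqrt(log(1 + cv^2))
  jit <- function(mu) stats::rlnorm(n, meanlog = log(mu) - sdl^2 / 2, sdlog = sdl)
  M <- pmin(jit(base$M), 1)
  m <- pmin(jit(base$m), 0.8 * M)
  tibble::tibble(M = M, tau1 = jit(base$tau1), m = m, tau2 = jit(base$tau2),
                 t_pulse = base$t_pulse)
}

#' Noise model parameters for simulated traces
#'
#' An empirical read-level noise model: a per-read background offset drawn
#' from a log-normal distribution (shape 1.98, location -4.09e-06, scale
#' 0.001, fitted on unlabelled DNA) and redrawn while outside
#' `[offset_min, offset_max]`; the offset signal truncated at 1; only a
#' fraction `p_t` of positions (the thymidines) carry a value; and each
#' thymidine emits `Binomial(n, p) / n` with `n` uniform on `n_trials`,
#' mimicking per-site probability calls peaking at 0 or 1.
#'
#' @param offset_shape,offset_loc,offset_scale Log-normal parameters in the
#'   shape/location/scale convention: `O = loc + scale * exp(shape * Z)`.
#' @param offset_min,offset_max Accepted offset range (redraw outside it).
#' @param p_t Fraction of positions that are thymidines (valued).
#' @param n_trials Candidate binomial trial counts.
#' @return A list of class `noise_params`.
#' @export
noise_params <- function(offset_shape = 1.98, offset_loc = -4.09e-06,
                         offset_scale = 0.001, offset_min = 1e-7,
                         offset_max = 0.2, p_t = 0.23, n_trials = c(1L, 2L, 3L)) {
  structure(list(offset_shape = offset_shape, offset_loc = offset_loc,
                 offset_scale = offset_scale, offset_min = offset_min,
                 offset_max = offset_max, p_t = p_t,
                 n_trials = as.integer(n_trials)),
            class = "noise_params")
}

#' Intracellular BrdU level as a function of time
#'
#' @param t Time since the start of the pulse (min); vectorised.
#' @param params A [kinetic_params()] list.
#' @return BrdU signal level: 0 for `t < 0`, the exponential rise during the
#'   pulse and the exponential relaxation towards `m` during the chase.
#' @examples
#' kp <- kinetic_params()
#' brdu_level(c(-1, 0, 2, 100), kp)
#' @export
brdu_level <- function(t, params) {
  p <- params
  As_end <- p$M * (1 - exp(-p$t_pulse / p$tau1))
  # clamped form: the ascent evaluated at t clamped to [0, t_pulse] plus the
  # chase relaxation evaluated at max(t - t_pulse, 0); each term vanishes
  # outside its phase, so no logical subsetting is needed
  p$M * (1 - exp(-pmin.int(pmax.int(t, 0), p$t_pulse) / p$tau1)) +
    (p$m - As_end) * (1 - exp(-pmax.int(t - p$t_pulse, 0) / p$tau2))
}

#' Stand-in sampler for the true fork-speed distribution
#'
#' A two-component Gaussian mixture: a dominant narrow mode (mean 2486
#' bp/min, sd 150, weight 2/3) representing the bulk of fork speeds in
#' normally growing yeast, plus a broad component (mean 1800, sd 700, weight
#' 1/3) for the dispersed tail, truncated to `(min_speed, max_speed)`.
#'
#' @param n Number of speeds to draw.
#' @param means,sds,weights Mixture parameters.
#' @param min_speed,max_speed Truncation bounds (bp/min).
#' @return Numeric vector of speeds (bp/min).
#' @export
sample_true_speeds <- function(n, means = c(2486, 1800), sds = c(150, 700),
                               weights = c(2, 1) / 3,
                               min_speed = 50, max_speed = 5000) {
  out <- numeric(0)
  while (length(out) < n) {
    k <- sample.int(length(weights), n, replace = TRUE, prob = weights)
    v <- stats::rnorm(n, means[k], sds[k])
    out <- c(out, v[v > min_speed & v < max_speed])
  }
  out[seq_len(n)]
}

# Per-read offset: log-normal with redraw outside the accepted range.
draw_offsets <- function(n, np) {
  o <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    cand <- np$offset_loc +
      np$offset_scale * exp(np$offset_shape * stats::rnorm(length(todo)))
    ok <- cand >= np$offset_min & cand <= np$offset_max
    o[todo[ok]] <- cand[ok]
    todo <- todo[!ok]
  }
  o
}

# Turn a dense noise-free profile (one value per position of a read) into
# emitted per-position probabilities. Noise-free reads are valued everywhere;
# noisy reads get the offset + thymidine masking + binomial quantisation.
emit_signal <- function(profile, noise) {
  L <- length(profile)
  if (is.null(noise)) {
    return(list(rel_pos = 0:(L - 1L), prob = profile))
  }
  off <- draw_offsets(1L, noise)
  p <- pmin(profile + off, 1)
  tmask <- which(stats::runif(L) < noise$p_t)
  ntr <- sample(noise$n_trials, length(tmask), replace = TRUE)
  val <- stats::rbinom(length(tmask), ntr, p[tmask]) / ntr
  list(rel_pos = tmask - 1L, prob = val)
}

#' Simulate reads carrying a single replication fork
#'
#' Each read carries one fork of known speed: a background stretch replicated
#' before the pulse, the pulse track of length `v * t_pulse`, and a chase
#' tail, converted from the time-domain kinetic model by `BrdU(x) =
#' b(x / v)`. Fork direction and mapping strand are randomised; kinetic
#' parameters are drawn per fork with [sample_kinetics()]. With
#' `noise = NULL` the noise-free profile is emitted at every position;
#' otherwise the [noise_params()] model is applied.
#'
#' @param n_reads Number of reads.
#' @param speeds True speeds (bp/min): a numeric vector of length `n_reads`,
#'   or `NULL` to draw from [sample_true_speeds()].
#' @param kinetics Base [kinetic_params()]; per-fork jitter controlled by
#'   `kinetics_cv` (0 disables it).
#' @param kinetics_cv Coefficient of variation of the per-fork jitter.
#' @param noise A [noise_params()] list, or `NULL` for noise-free reads.
#' @param pre_range,post_range Ranges (bp) of the pre-pulse background and of
#'   the chase tail flanking the track; both leave at least 2.5 kb on each
#'   side after trimming.
#' @param seed Optional RNG seed for reproducibility.
#' @return A list with `traces` (a [trace_tbl]) and `truth` (a tibble with
#'   `read_id`, `v_true`, `direction`, `X0_true`, `X1_true` and the kinetic
#'   parameters used).
#' @examples
#' sim <- simulate_single_forks(2, speeds = c(2000, 2500), seed = 1)
#' sim$truth
#' @export
simulate_single_forks <- function(n_reads, speeds = NULL,
                                  kinetics = kinetic_params(),
                                  kinetics_cv = 0.2,
                                  noise = noise_params(),
                                  pre_range = c(4000, 7000),
                                  post_range = c(7000, 12000),
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(speeds)) speeds <- sample_true_speeds(n_reads)
  stopifnot(length(speeds) == n_reads, all(speeds > 0))
  kp <- if (kinetics_cv > 0) sample_kinetics(n_reads, kinetics, kinetics_cv) else
    tibble::as_tibble(unclass(kinetics))[rep(1, n_reads), ]
  dirs <- sample(c("left", "right"), n_reads, replace = TRUE)
  strands <- sample(c("+", "-"), n_reads, replace = TRUE)
  pre <- stats::runif(n_reads, pre_range[1], pre_range[2])
  post <- stats::runif(n_reads, post_range[1], post_range[2])
  sig <- vector("list", n_reads)
  X0 <- X1 <- numeric(n_reads)
  ends <- numeric(n_reads)
  for (i in seq_len(n_reads)) {
    kpi <- kinetic_params(kp$M[i], kp$tau1[i], kp$m[i], kp$tau2[i], kp$t_pulse[i])
    track <- speeds[i] * kpi$t_pulse
    L <- as.integer(round(pre[i] + track + post[i]))
    x <- 0:(L - 1L)
    if (dirs[i] == "right") {
      X0[i] <- round(pre[i]); X1[i] <- round(pre[i] + track)
      t_rel <- (x - X0[i]) / speeds[i]
    } else {
      X0[i] <- L - round(pre[i]); X1[i] <- X0[i] - round(track)
      t_rel <- (X0[i] - x) / speeds[i]
    }
    profile <- brdu_level(t_rel, kpi)
    em <- emit_signal(profile, noise)
    sig[[i]] <- tibble::new_tibble(
      list(position = em$rel_pos, prob = em$prob), nrow = length(em$rel_pos)
    )
    ends[i] <- L
  }
  ids <- sprintf("simread_%06d", seq_len(n_reads))
  traces <- trace_tbl(ids, "sim", 0, ends, strands, sig, .validated = TRUE)
  truth <- tibble::tibble(
    read_id = ids, v_true = speeds, direction = dirs,
    X0_true = X0, X1_true = X1,
    M = kp$M, tau1 = kp$tau1, m = kp$m, tau2 = kp$tau2,
    t_pulse = kp$t_pulse
  )
  list(traces = traces, truth = truth)
}

# Truncated log-normal read-length sampler (inverse-CDF on the truncated
# probability mass).
sample_read_lengths <- function(n, meanlog, sdlog, lo, hi) {
  plo <- stats::plnorm(lo, meanlog, sdlog)
  phi <- stats::plnorm(hi, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, plo, phi), meanlog, sdlog)
}

#' Simulate multi-fork genome segments sliced into reads
#'
#' Replication of 300 kb DNA segments: six origins uniformly positioned (one
#' per 50 kb on average), firing times uniform on 0-30 min, one fork speed
#' per segment drawn from `speed_sampler`. A configuration is accepted only
#' when every origin fires actively (no position is passively replicated
#' before its origin fires), yielding twelve forks; converging forks
#' annihilate where their progress meets. The pulse moment is drawn uniformly
#' between the earliest firing time and three fifths of the latest one
#' (segments with an empty interval are redrawn). BrdU is deposited at each
#' position according to the time elapsed between the pulse start and the
#' moment the position was replicated, with per-fork kinetic parameters.
#' Segments are finally sliced into reads whose lengths follow a truncated
#' log-normal distribution on `[slice_min, slice_max]`.
#'
#' @param n_reads Total number of reads to produce.
#' @param speed_sampler Function `n -> speeds` for per-segment speeds.
#' @param kinetics,kinetics_cv,noise,seed As in [simulate_single_forks()].
#' @param segment_len Segment length (bp).
#' @param n_origins Origins per segment.
#' @param fire_max Upper bound (min) of the uniform firing-time draw.
#' @param slice_meanlog,slice_sdlog Log-normal read-length parameters.
#'   Defaults give a 13 kb median / ~15 kb mean after truncation, matching
#'   the average length of experimental nanopore reads the slicing emulates.
#' @param slice_min,slice_max Read-length truncation bounds (bp).
#' @param max_attempts Rejection-sampling cap per segment.
#' @return A list with `traces` (a [trace_tbl]), `truth` (read-level:
#'   `read_id`, `segment_id`, `v_true`, `pulse_time`) and `fork_truth`
#'   (per simulated fork: `segment_id`, `chrom`, `origin`, `direction`,
#'   `X0_true`, `X1_true`, `region_start`, `region_end`, `complete`).
#' @export
simulate_genome <- function(n_reads,
                            speed_sampler = sample_true_speeds,
                            kinetics = kinetic_params(),
                            kinetics_cv = 0.2,
                            noise = noise_params(),
                            seed = NULL,
                            segment_len = 300000L,
                            n_origins = 6L,
                            fire_max = 30,
                            slice_meanlog = log(13000),
                            slice_sdlog = 0.5,
                            slice_min = 5000,
                            slice_max = 300000,
                            max_attempts = 1000L) {
  if (!is.null(seed)) set.seed(seed)
  reads <- list(); read_truth <- list(); fork_truth <- list()
  total <- 0L
  seg_i <- 0L
  while (total < n_reads) {
    seg_i <- seg_i + 1L
    seg <- draw_segment(speed_sampler, segment_len, n_origins, fire_max,
                        max_attempts)
    chrom <- sprintf("seg%05d", seg_i)
    kp <- if (kinetics_cv > 0) sample_kinetics(2L * n_origins, kinetics, kinetics_cv) else
      tibble::as_tibble(unclass(kinetics))[rep(1, 2L * n_origins), ]
    field <- replication_field(seg, segment_len)
    profile <- numeric(segment_len)
    tt <- field$time - seg$t_p
    for (f in seq_len(2L * n_origins)) {
      msk <- field$fork_id == f
      if (!any(msk)) next
      kpf <- kinetic_params(kp$M[f], kp$tau1[f], kp$m[f], kp$tau2[f], kp$t_pulse[f])
      profile[msk] <- brdu_level(tt[msk], kpf)
    }
    ft <- fork_truth_table(seg, segment_len, chrom, t_pulse = kinetics$t_pulse)
    ft$segment_id <- seg_i
    fork_truth[[seg_i]] <- ft
    # slice into reads
    lens <- round(sample_read_lengths(
      ceiling(segment_len / slice_min) + 1L,
      slice_meanlog, slice_sdlog, slice_min, slice_max))
    cuts <- pmin(cumsum(lens), segment_len)
    cuts <- c(0, cuts[seq_len(which(cuts == segment_len)[1])])
    for (r in seq_len(length(cuts) - 1L)) {
      if (total >= n_reads) break
      st <- cuts[r]; en <- cuts[r + 1L]
      if (en - st < 2L) next
      total <- total + 1L
      em <- emit_signal(profile[(st + 1L):en], noise)
      id <- sprintf("genread_%06d", total)
      reads[[total]] <- list(
        read_id = id, chrom = chrom, start = st, end = en,
        strand = sample(c("+", "-"), 1L),
        signal = tibble::new_tibble(
          list(position = st + em$rel_pos, prob = em$prob),
          nrow = length(em$rel_pos)
        )
      )
      read_truth[[total]] <- tibble::tibble(
        read_id = id, segment_id = seg_i, v_true = seg$v,
        pulse_time = seg$t_p
      )
    }
  }
  traces <- trace_tbl(
    read_id = vapply(reads, `[[`, character(1), "read_id"),
    chrom = vapply(reads, `[[`, character(1), "chrom"),
    start = vapply(reads, `[[`, numeric(1), "start"),
    end = vapply(reads, `[[`, numeric(1), "end"),
    strand = vapply(reads, `[[`, character(1), "strand"),
    signal = lapply(reads, `[[`, "signal"),
    .validated = TRUE
  )
  list(traces = traces,
       truth = dplyr::bind_rows(read_truth),
       fork_truth = dplyr::bind_rows(fork_truth))
}

# One accepted segment configuration: origins, firing times, speed, pulse
# moment. The speed is drawn once per segment and the origin/firing-time
# configuration is redrawn until every origin fires actively, so the
# segment speed distribution equals the sampler's (a joint rejection would
# skew accepted speeds low, since fast forks passively replicate late
# origins more often). Active-origin condition: with equal speeds the
# replication-time field is T(x) = min_j (t_j + |x - x_j| / v); origin k is
# active iff it fires before any other fork reaches it.
draw_segment <- function(speed_sampler, segment_len, n_origins, fire_max,
                         max_attempts) {
  v <- speed_sampler(1L)
  for (a in seq_len(max_attempts)) {
    x <- sort(stats::runif(n_origins, 0, segment_len))
    t <- stats::runif(n_origins, 0, fire_max)
    active <- vapply(seq_len(n_origins), function(k) {
      others <- setdiff(seq_len(n_origins), k)
      t[k] < min(t[others] + abs(x[k] - x[others]) / v)
    }, logical(1))
    if (!all(active)) next
    lo <- min(t); hi <- 3 / 5 * max(t)
    if (hi <= lo) next
    t_p <- stats::runif(1L, lo, hi)
    return(list(x = x, t = t, v = v, t_p = t_p))
  }
  stop("no valid origin configuration for speed ", round(v), " bp/min after ",
       max_attempts, " attempts; review simulation parameters")
}

# Replication-time field and fork ownership on the 1 bp lattice, by a
# prefix/suffix-minimum sweep: with one speed per segment,
# T(x) = min_j (t_j + |x - x_j| / v) splits into a rightward part
# min_{x_j <= x} (t_j - x_j/v) + x/v and a leftward part
# min_{x_j >= x} (t_j + x_j/v) - x/v, each computable by a cumulative
# minimum over the sorted origins. Fork ids: origin j contributes forks
# 2j-1 (leftward) and 2j (rightward).
replication_field <- function(seg, segment_len) {
  xg <- seq_len(segment_len) - 1
  n <- length(seg$x)
  a_r <- seg$t - seg$x / seg$v
  a_l <- seg$t + seg$x / seg$v
  pm <- cummin(a_r)
  pm_arg <- cummax(seq_len(n) * (a_r == pm))          # index achieving prefix min
  sm_rev <- cummin(rev(a_l))
  sm <- rev(sm_rev)
  sm_arg_rev <- cummax(seq_len(n) * (rev(a_l) == sm_rev))
  sm_arg <- rev(n + 1L - sm_arg_rev)
  band <- findInterval(xg, seg$x)                      # 0..n
  right_time <- rep(Inf, segment_len)
  left_time <- rep(Inf, segment_len)
  has_r <- band > 0L
  has_l <- band < n
  right_time[has_r] <- pm[band[has_r]] + xg[has_r] / seg$v
  left_time[has_l] <- sm[band[has_l] + 1L] - xg[has_l] / seg$v
  rightward <- right_time <= left_time
  owner <- integer(segment_len)
  owner[rightward] <- pm_arg[band[rightward]]
  owner[!rightward] <- sm_arg[band[!rightward] + 1L]
  list(time = pmin(right_time, left_time),
       fork_id = (owner - 1L) * 2L + rightward + 1L)
}

# Ground-truth fork records: pulse-start (X0) and chase-start (X1) positions
# along each fork's path, with the region the fork owns and whether the
# labelled track is complete (both landmarks inside the owned region).
fork_truth_table <- function(seg, segment_len, chrom, t_pulse = 2) {
  n <- length(seg$x)
  # meeting points between adjacent active origins
  b <- c(0, (seg$x[-n] + seg$x[-1]) / 2 + seg$v * (seg$t[-1] - seg$t[-n]) / 2,
         segment_len)
  rows <- vector("list", 2L * n)
  for (j in seq_len(n)) {
    for (d in c(-1, 1)) {
      f <- (j - 1L) * 2L + if (d > 0) 2L else 1L
      reg <- if (d > 0) c(seg$x[j], b[j + 1L]) else c(b[j], seg$x[j])
      born_before_pulse <- seg$t_p >= seg$t[j]
      # landmarks clamp to the origin for forks born after the pulse start
      # (no pre-pulse background) or after the pulse end (no track at all)
      X0 <- seg$x[j] + d * seg$v * max(seg$t_p - seg$t[j], 0)
      X1 <- seg$x[j] + d * seg$v * max(seg$t_p + t_pulse - seg$t[j], 0)
      inside <- function(p) p >= reg[1] && p <= reg[2]
      complete <- born_before_pulse && inside(X0) && inside(X1) &&
        (if (d > 0) X1 < reg[2] else X1 > reg[1])
      rows[[f]] <- tibble::tibble(
        segment_id = NA_integer_, chrom = chrom, origin = j,
        direction = if (d > 0) "right" else "left",
        X0_true = X0, X1_true = X1,
        region_start = reg[1], region_end = reg[2],
        complete = complete
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Autocorrelation of the high-frequency component of BrdU signals
#'
#' Characterises signal noise: for each trace the signal is smoothed with a
#' 100 bp and a 1000 bp rolling mean; subtracting the latter removes slow
#' BrdU variations, leaving the local fluctuations whose lag autocorrelation
#' is computed and averaged over traces. Comparing the curve between
#' experimental and simulated reads checks that the simulated noise has the
#' right correlation structure.
#'
#' @param traces A [trace_tbl] tibble (at least a handful of reads; the
#'   curve stabilises above ~100).
#' @param lag_max Maximum lag (bp).
#' @return A tibble with columns `lag` (bp) and `acf`.
#' @export
noise_autocorrelation <- function(traces, lag_max = 2000) {
  curves <- purrr::pmap(
    list(traces$signal, traces$start, traces$end),
    function(sig, st, en) {
      L <- as.integer(en - st)
      if (L < 4 * lag_max) return(NULL)
      v <- numeric(L); a <- numeric(L)
      i <- as.integer(sig$position - st) + 1L
      ok <- !is.na(sig$prob)
      v[i[ok]] <- sig$prob[ok]; a[i[ok]] <- 1
      s100 <- box_mean(v, a, 100L)
      s1000 <- box_mean(v, a, 1000L)
      d <- s100 - s1000
      d <- d[is.finite(d)]
      if (length(d) < 2 * lag_max) return(NULL)
      as.numeric(stats::acf(d, lag.max = lag_max, plot = FALSE,
                            demean = TRUE)$acf)
    }
  )
  curves <- curves[!vapply(curves, is.null, logical(1))]
  if (!length(curves)) stop("no trace long enough for the requested lag range")
  avg <- Reduce(`+`, curves) / length(curves)
  tibble::tibble(lag = seq_along(avg) - 1L, acf = avg)
}

box_mean <- function(v, a, w) {
  h <- w %/% 2L
  L <- length(v)
  cv <- c(0, cumsum(v)); ca <- c(0, cumsum(a))
  g <- seq_len(L)
  lo <- pmax(g - h, 1L); hi <- pmin(g + h, L)
  den <- ca[hi + 1L] - ca[lo]
  out <- (cv[hi + 1L] - cv[lo]) / den
  out[den == 0] <- NA_real_
  out
}
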