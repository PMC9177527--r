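#' Build a measured-speed response library from simulated forks
#'
#' The measured fork-speed distribution is a distorted image of the true one:
#' smoothing, segmentation and noise bias and disperse individual
#' measurements in a speed-dependent way. This function characterises that
#' response by simulating `n_reads` noisy single-fork reads with true speeds
#' uniform on (50, 5000) bp/min, measuring them with the full pipeline, and
#' summarising, for each of 44 true-speed classes centred on `k * 100` bp/min
#' (windows of width 400 bp/min, overlapping by construction so each class
#' has enough members), the distribution of measured speeds as a
#' five-component Gaussian mixture.
#'
#' @param n_reads Number of simulated reads (the reference experiment used
#'   100,000; a few thousand give a usable library for testing).
#' @param seed RNG seed.
#' @param noise A [noise_params()] list or `NULL`.
#' @param params A [fork_params()] list.
#' @param n_components Mixture components per class.
#' @param min_class Minimum measured forks per class; fewer raises an error
#'   advising a larger `n_reads`.
#' @param speed_range True-speed range of the uniform library.
#' @param ... Passed to [evaluate_single_forks()].
#' @return An object of class `response_library`: a tibble with one row per
#'   class (`k`, `center`, `n`, and a `mixture` list-column of
#'   weight/mean/sd tibbles).
#' @export
build_response_library <- function(n_reads = 100000, seed = NULL,
                                   noise = noise_params(),
                                   params = fork_params(),
                                   n_components = 5L, min_class = 50L,
                                   speed_range = c(50, 5000), ...) {
  if (!is.null(seed)) set.seed(seed)
  speeds <- stats::runif(n_reads, speed_range[1], speed_range[2])
  ev <- evaluate_single_forks(n_reads, speeds = speeds, noise = noise,
                              params = params, seed = NULL, ...)
  pairs <- ev[ev$detected, c("v_true", "speed")]
  centers <- (1:44) * 100
  rows <- vector("list", length(centers))
  for (k in seq_along(centers)) {
    sel <- pairs$speed[pairs$v_true >= centers[k] - 200 &
                       pairs$v_true < centers[k] + 200]
    if (length(sel) < min_class) {
      stop("class k=", k, " (center ", centers[k], " bp/min) has only ",
           length(sel), " measured forks (< ", min_class,
           "); increase n_reads")
    }
    rows[[k]] <- tibble::tibble(
      k = k, center = centers[k], n = length(sel),
      mixture = list(fit_gaussian_mixture(sel, n_components))
    )
  }
  structure(dplyr::bind_rows(rows), class = c("response_library", "tbl_df",
                                              "tbl", "data.frame"))
}

# 1D Gaussian mixture via EM (mclust, unequal variances, deterministic
# model-based hierarchical initialisation); large samples are initialised
# from an evenly spaced subset of the sorted data (quadratic-cost
# agglomeration on the full sample is neither needed nor affordable), which
# keeps the fit deterministic. Falls back to fewer components when a fit
# with the requested number degenerates.
fit_gaussian_mixture <- function(x, g, max_init = 2000L) {
  mclustBIC <- mclust::mclustBIC   # Mclust() resolves this in the caller frame
  init <- if (length(x) > max_init) {
    list(subset = order(x)[round(seq(1, length(x), length.out = max_init))])
  } else NULL
  for (gg in seq(g, 1L)) {
    fit <- tryCatch(
      mclust::Mclust(x, G = gg, modelNames = "V", verbose = FALSE,
                     initialization = init),
      error = function(e) NULL
    )
    if (!is.null(fit) && !is.null(fit$parameters)) {
      p <- fit$parameters
      sd <- sqrt(as.numeric(p$variance$sigmasq))
      if (length(sd) == 1L) sd <- rep(sd, length(p$mean))
      return(tibble::tibble(weight = as.numeric(p$pro),
                            mean = as.numeric(p$mean), sd = sd))
    }
  }
  stop("Gaussian mixture fit failed")
}

# Per-class probability mass over histogram bins, columns normalised to 1.
response_matrix <- function(library, breaks) {
  nb <- length(breaks) - 1L
  A <- matrix(0, nb, nrow(library))
  for (k in seq_len(nrow(library))) {
    mx <- library$mixture[[k]]
    mass <- numeric(nb)
    for (j in seq_len(nrow(mx))) {
      mass <- mass + mx$weight[j] *
        (stats::pnorm(breaks[-1], mx$mean[j], mx$sd[j]) -
         stats::pnorm(breaks[-length(breaks)], mx$mean[j], mx$sd[j]))
    }
    tot <- sum(mass)
    A[, k] <- if (tot > 0) mass / tot else 0
  }
  A
}

#' Estimate the true fork-speed distribution by deconvolution
#'
#' Finds non-negative weights over the 44 true-speed classes such that the
#' weighted sum of their measured-speed response distributions best fits (in
#' least squares) the histogram of observed speeds on 100 bp/min bins over
#' (0, 5000]. The fit is repeated with each independently simulated response
#' library supplied and the weight sets averaged; the averaged discrete
#' distribution is finally fitted with a six-component Gaussian mixture to
#' produce a continuous estimate.
#'
#' @param observed_speeds Measured fork speeds (bp/min), at least 1000.
#' @param libraries A `response_library` or a list of them (one per
#'   independent repeat).
#' @param bin Histogram bin width (bp/min).
#' @param max_speed Histogram upper bound (bp/min).
#' @param mixture_components Components of the continuous fit.
#' @param fit_sample_size Draws from the discrete estimate used for the
#'   continuous mixture fit.
#' @param seed RNG seed for the continuous-fit draw.
#' @return An object of class `speed_deconv`: list with `weights` (tibble
#'   `center`, `weight`, summing to 1), `mixture` (tibble `weight`, `mean`,
#'   `sd`), `n_observed`, `n_libraries`. [tidy()][generics::tidy] returns the
#'   weights, [glance()][generics::glance] the mode and mass summaries.
#' @export
deconvolve_speeds <- function(observed_speeds, libraries, bin = 100,
                              max_speed = 5000, mixture_components = 6L,
                              fit_sample_size = 20000L, seed = NULL) {
  if (inherits(libraries, "response_library")) libraries <- list(libraries)
  obs <- observed_speeds[observed_speeds > 0 & observed_speeds <= max_speed &
                         !is.na(observed_speeds)]
  if (length(obs) < 1000) stop("need at least 1000 observed speeds")
  breaks <- seq(0, max_speed, by = bin)
  h <- graphics::hist(obs, breaks = breaks, plot = FALSE)$counts
  if (sum(h) == 0) stop("observed speed histogram is empty")
  h <- h / sum(h)
  ws <- vapply(libraries, function(lib) {
    A <- response_matrix(lib, breaks)
    w <- pracma::lsqnonneg(A, h)$x
    if (sum(w) <= 0) stop("degenerate non-negative fit (all-zero weights)")
    w / sum(w)
  }, numeric(44))
  w_bar <- rowMeans(ws)
  centers <- libraries[[1]]$center
  if (!is.null(seed)) set.seed(seed)
  draw <- centers[sample.int(44, fit_sample_size, replace = TRUE,
                             prob = w_bar)] +
    stats::runif(fit_sample_size, -bin / 2, bin / 2)
  mix <- fit_gaussian_mixture(draw, mixture_components)
  structure(
    list(weights = tibble::tibble(center = centers, weight = w_bar),
         mixture = mix, n_observed = length(obs),
         n_libraries = length(libraries)),
    class = "speed_deconv"
  )
}

mixture_density <- function(mix, x) {
  rowSums(vapply(seq_len(nrow(mix)), function(j) {
    mix$weight[j] * stats::dnorm(x, mix$mean[j], mix$sd[j])
  }, numeric(length(x))))
}

#' Mode of a deconvolved speed estimate
#'
#' Deterministic density maximiser of the fitted continuous mixture on a
#' 1 bp/min grid.
#'
#' @param x A `speed_deconv` object.
#' @param range Search range (bp/min).
#' @return The mode in bp/min.
#' @export
deconv_mode <- function(x, range = c(1, 5000)) {
  grid <- seq(range[1], range[2], by = 1)
  grid[which.max(mixture_density(x$mixture, grid))]
}

#' @export
print.speed_deconv <- function(x, ...) {
  cat("<speed_deconv> deconvolved true fork-speed distribution\n")
  cat("  observed speeds: ", x$n_observed, "; libraries averaged: ",
      x$n_libraries, "\n", sep = "")
  cat("  mode of continuous fit: ", deconv_mode(x), " bp/min\n", sep = "")
  invisible(x)
}

#' @rdname deconvolve_speeds
#' @param x A `speed_deconv` object.
#' @param ... Unused.
#' @export
tidy.speed_deconv <- function(x, ...) x$weights

#' @rdname deconvolve_speeds
#' @export
glance.speed_deconv <- function(x, ...) {
  mode <- deconv_mode(x)
  w <- x$weights
  tibble::tibble(
    mode = mode,
    mass_within_200 = sum(w$weight[abs(w$center - mode) <= 200]),
    n_observed = x$n_observed,
    n_libraries = x$n_libraries,
    n_components = nrow(x$mixture)
  )
}

#' Sample speeds from a deconvolved estimate
#'
#' @param x A `speed_deconv` object.
#' @param n Number of draws.
#' @param range Truncation bounds (bp/min).
#' @return Numeric vector of speeds.
#' @export
sample_deconv_speeds <- function(x, n, range = c(50, 5000)) {
  mix <- x$mixture
  out <- numeric(0)
  while (length(out) < n) {
    k <- sample.int(nrow(mix), n, replace = TRUE, prob = mix$weight)
    v <- stats::rnorm(n, mix$mean[k], mix$sd[k])
    out <- c(out, v[v > range[1] & v < range[2]])
  }
  out[seq_len(n)]
}

#' Round-trip validation of a deconvolved estimate
#'
#' Simulates reads whose true speeds follow the continuous estimate, measures
#' them with the full pipeline, and returns the total-variation distance (on
#' 100 bp/min bins) between the re-measured speed distribution and the
#' originally observed one. A small distance indicates that the estimated
#' true distribution, pushed back through the measurement process,
#' reproduces what was observed.
#'
#' @param estimate A `speed_deconv` object.
#' @param observed_speeds The measured speeds the estimate was fitted to.
#' @param n_reads Number of validation reads.
#' @param seed RNG seed.
#' @param noise,params As in [evaluate_single_forks()].
#' @param bin,max_speed Histogram settings.
#' @return Total-variation distance in `[0, 1]`.
#' @export
roundtrip_check <- function(estimate, observed_speeds, n_reads = 20000,
                            seed = NULL, noise = noise_params(),
                            params = fork_params(), bin = 100,
                            max_speed = 5000) {
  if (!is.null(seed)) set.seed(seed)
  v <- sample_deconv_speeds(estimate, n_reads)
  ev <- evaluate_single_forks(n_reads, speeds = v, noise = noise,
                              params = params, seed = NULL)
  remeasured <- ev$speed[ev$detected]
  breaks <- seq(0, max_speed, by = bin)
  clip <- function(x) x[x > 0 & x <= max_speed & !is.na(x)]
  p <- graphics::hist(clip(remeasured), breaks = breaks, plot = FALSE)$counts
  q <- graphics::hist(clip(observed_speeds), breaks = breaks, plot = FALSE)$counts
  sum(abs(p / sum(p) - q / sum(q))) / 2
}
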