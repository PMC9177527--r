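#' Replication fork directionality (RFD) track
#'
#' Bins the genome into non-overlapping windows and computes, per window, the
#' coverage of rightward- and leftward-moving fork tracks and the
#' directionality `RFD = (R - L) / (R + L)`, where R and L are the rightward
#' and leftward coverages. Windows with zero coverage have missing RFD.
#'
#' @param forks Fork tibble with columns `chrom`, `X0`, `X1`, `direction`
#'   (a [call_forks()] fork table works as is).
#' @param bin_size Window width (bp).
#' @return A tibble of class `rfd_track` with columns `chrom`, `start`,
#'   `end`, `n_right`, `n_left`, `total`, `rfd`.
#' @examples
#' fk <- tibble::tibble(chrom = "chrI", X0 = c(0, 500), X1 = c(1000, 1500),
#'                      direction = c("right", "right"))
#' compute_rfd(fk, bin_size = 500)
#' @export
compute_rfd <- function(forks, bin_size = 100) {
  out <- lapply(split(forks, forks$chrom), function(f) {
    lo <- pmin(f$X0, f$X1)
    hi <- pmax(f$X0, f$X1)
    max_end <- max(hi)
    n_bins <- ceiling(max_end / bin_size)
    covr <- bin_coverage(lo[f$direction == "right"], hi[f$direction == "right"],
                         bin_size, n_bins)
    covl <- bin_coverage(lo[f$direction == "left"], hi[f$direction == "left"],
                         bin_size, n_bins)
    tot <- covr + covl
    tibble::tibble(
      chrom = f$chrom[1],
      start = (seq_len(n_bins) - 1) * bin_size,
      end = seq_len(n_bins) * bin_size,
      n_right = covr, n_left = covl, total = tot,
      rfd = ifelse(tot > 0, (covr - covl) / tot, NA_real_)
    )
  })
  res <- dplyr::bind_rows(out)
  class(res) <- c("rfd_track", class(res))
  res
}

# Number of intervals [lo, hi) overlapping each bin by >= 1 bp.
bin_coverage <- function(lo, hi, bin_size, n_bins) {
  cov <- numeric(n_bins)
  if (!length(lo)) return(cov)
  first <- pmax(floor(lo / bin_size), 0) + 1
  last <- pmin(ceiling(hi / bin_size), n_bins)
  for (i in seq_along(first)) {
    if (last[i] >= first[i]) {
      cov[first[i]:last[i]] <- cov[first[i]:last[i]] + 1
    }
  }
  cov
}

#' Multi-scale genomic map of fork speed
#'
#' Reduces each fork to its centre (midpoint of the X0-X1 span), bins
#' centres into non-overlapping windows at each requested width, and per
#' window reports the fork count, the median speed with its 98% confidence
#' interval (exact binomial order-statistic method), and one-sided
#' Mann-Whitney-Wilcoxon p-values comparing the window's speed distribution
#' with the genome-wide one. P-values are Holm-corrected separately for the
#' slower and the faster families, each across all windows of all widths;
#' windows reach status `slower`/`faster` at adjusted p below `alpha`, `ns`
#' otherwise, and `na` when they contain no fork.
#'
#' @param forks Fork tibble (`chrom`, `X0`, `X1`, `speed`).
#' @param widths Window widths in bp.
#' @param alpha Significance level on the adjusted p-values.
#' @return A tibble of class `speed_map`: `chrom`, `width`, `start`, `end`,
#'   `n_forks`, `median_speed`, `ci_lo`, `ci_hi`, `p_slower`, `p_faster`
#'   (Holm-adjusted), `status`.
#' @export
speed_map <- function(forks, widths = c(1:10, 15, 20) * 1000, alpha = 0.01) {
  all_speeds <- forks$speed
  ctr <- (forks$X0 + forks$X1) / 2
  maps <- list()
  for (w in widths) {
    for (ch in unique(forks$chrom)) {
      sel <- forks$chrom == ch
      x <- ctr[sel]
      sp <- forks$speed[sel]
      n_bins <- ceiling(max(x) / w)
      bin <- pmin(floor(x / w), n_bins - 1) + 1
      rows <- lapply(seq_len(n_bins), function(b) {
        s <- sp[bin == b]
        n <- length(s)
        if (n == 0) {
          return(tibble::tibble(
            chrom = ch, width = w, start = (b - 1) * w, end = b * w,
            n_forks = 0L, median_speed = NA_real_, ci_lo = NA_real_,
            ci_hi = NA_real_, p_slower = NA_real_, p_faster = NA_real_
          ))
        }
        ci <- median_ci(s, conf = 0.98)
        ps <- stats::wilcox.test(s, all_speeds, alternative = "less",
                                 exact = FALSE)$p.value
        pf <- stats::wilcox.test(s, all_speeds, alternative = "greater",
                                 exact = FALSE)$p.value
        tibble::tibble(
          chrom = ch, width = w, start = (b - 1) * w, end = b * w,
          n_forks = n, median_speed = stats::median(s),
          ci_lo = ci[1], ci_hi = ci[2], p_slower = ps, p_faster = pf
        )
      })
      maps[[length(maps) + 1L]] <- dplyr::bind_rows(rows)
    }
  }
  res <- dplyr::bind_rows(maps)
  res$p_slower <- stats::p.adjust(res$p_slower, method = "holm")
  res$p_faster <- stats::p.adjust(res$p_faster, method = "holm")
  res$status <- dplyr::case_when(
    res$n_forks == 0 ~ "na",
    !is.na(res$p_slower) & res$p_slower < alpha ~ "slower",
    !is.na(res$p_faster) & res$p_faster < alpha ~ "faster",
    TRUE ~ "ns"
  )
  class(res) <- c("speed_map", class(res))
  res
}

# Exact binomial order-statistic confidence interval for the median.
median_ci <- function(x, conf = 0.98) {
  n <- length(x)
  s <- sort(x)
  if (n < 2) return(c(s[1], s[n]))
  alpha <- 1 - conf
  l <- stats::qbinom(alpha / 2, n, 0.5)
  u <- n - l + 1L
  l <- max(l, 1L)
  u <- min(u, n)
  c(s[l], s[u])
}

#' Permutation envelope of per-window median speeds
#'
#' Keeps fork locations fixed, permutes the speed labels across forks
#' `n_shuffles` times, recomputes every window's median speed per shuffle and
#' returns the overall median together with the 1st and 99th percentiles of
#' the shuffled medians. The envelope shows the local median variation
#' expected under spatial homogeneity of fork speed.
#'
#' @param forks Fork tibble.
#' @param n_shuffles Number of permutations.
#' @param width Window width (bp).
#' @param seed RNG seed.
#' @return A tibble: `chrom`, `start`, `end`, `n_forks`, `shuffled_median`,
#'   `lower` (1st percentile), `upper` (99th percentile).
#' @export
shuffle_envelope <- function(forks, n_shuffles = 1000, width = 20000,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ctr <- (forks$X0 + forks$X1) / 2
  key <- paste(forks$chrom, floor(ctr / width))
  groups <- split(seq_len(nrow(forks)), key)
  sp <- forks$speed
  meds <- matrix(NA_real_, n_shuffles, length(groups))
  for (s in seq_len(n_shuffles)) {
    perm <- sp[sample.int(length(sp))]
    meds[s, ] <- vapply(groups, function(ii) stats::median(perm[ii]),
                        numeric(1))
  }
  parts <- strsplit(names(groups), " ")
  tibble::tibble(
    chrom = vapply(parts, `[`, character(1), 1),
    start = as.numeric(vapply(parts, `[`, character(1), 2)) * width,
    end = (as.numeric(vapply(parts, `[`, character(1), 2)) + 1) * width,
    n_forks = lengths(groups),
    shuffled_median = apply(meds, 2, stats::median),
    lower = apply(meds, 2, stats::quantile, probs = 0.01),
    upper = apply(meds, 2, stats::quantile, probs = 0.99)
  )
}

#' Fork speeds grouped by overlapped genomic features
#'
#' Tests each fork span for overlap (minimum one nucleotide) with each
#' feature. Forks overlapping two or more features are removed from the
#' grouped summaries (exclusive-level rule). When an `rfd` track is supplied,
#' stranded features are additionally labelled co-directional (`CD`) when
#' their transcription direction matches the majority fork direction over the
#' feature (sign of the mean RFD) and head-on (`HO`) otherwise.
#'
#' @param forks Fork tibble (needs `chrom`, `X0`, `X1`, `speed`; a `sample`
#'   column is used for per-sample summaries when present).
#' @param features A BED file path or a tibble with `chrom`, `start`, `end`
#'   and optionally `name`, `strand`.
#' @param rfd Optional [compute_rfd()] track for CD/HO orientation.
#' @return A list with `forks` (per-fork feature assignment, multi-feature
#'   forks flagged) and `summary` (per sample x feature group: mean speed,
#'   n).
#' @export
feature_overlap_speeds <- function(forks, features, rfd = NULL) {
  if (is.character(features)) features <- read_bed(features)
  features <- tibble::as_tibble(features)
  if (!"name" %in% names(features)) {
    features$name <- paste0("feature_", seq_len(nrow(features)))
  }
  fg <- GenomicRanges::GRanges(
    forks$chrom,
    IRanges::IRanges(pmin(forks$X0, forks$X1) + 1, pmax(forks$X0, forks$X1))
  )
  ftg <- GenomicRanges::GRanges(
    features$chrom, IRanges::IRanges(features$start + 1, features$end)
  )
  hits <- GenomicRanges::findOverlaps(fg, ftg, minoverlap = 1L)
  n_hits <- tabulate(S4Vectors::queryHits(hits), nbins = nrow(forks))
  first_hit <- rep(NA_integer_, nrow(forks))
  first_hit[S4Vectors::queryHits(hits)[!duplicated(S4Vectors::queryHits(hits))]] <-
    S4Vectors::subjectHits(hits)[!duplicated(S4Vectors::queryHits(hits))]
  out <- forks
  out$feature <- ifelse(n_hits == 1, features$name[first_hit], NA_character_)
  out$n_features <- n_hits
  out$multi_feature <- n_hits > 1
  if (!is.null(rfd) && "strand" %in% names(features)) {
    orient <- vapply(seq_len(nrow(features)), function(i) {
      sel <- rfd$chrom == features$chrom[i] & rfd$end > features$start[i] &
        rfd$start < features$end[i] & !is.na(rfd$rfd)
      if (!any(sel)) return(NA_real_)
      mean(rfd$rfd[sel])
    }, numeric(1))
    cd <- ifelse(is.na(orient), NA_character_,
          ifelse((features$strand == "+") == (orient > 0), "CD", "HO"))
    names(cd) <- features$name
    out$orientation_class <- ifelse(is.na(out$feature), NA_character_,
                                    cd[out$feature])
  }
  if (!"sample" %in% names(out)) out$sample <- NA_character_
  keep <- !is.na(out$feature) & !out$multi_feature
  summary <- dplyr::summarise(
    dplyr::group_by(out[keep, ], .data$sample, .data$feature),
    mean_speed = mean(.data$speed), n = dplyr::n(), .groups = "drop"
  )
  list(forks = out, summary = summary)
}

# Minimal BED reader (3-6 columns, 0-based half-open).
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 3) stop("malformed BED: fewer than 3 columns")
  bad <- which(!is.finite(df[[2]]) | !is.finite(df[[3]]) | df[[2]] >= df[[3]])
  if (length(bad)) stop("malformed BED interval on line ", bad[1])
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  if (ncol(df) >= 6) names(df)[6] <- "strand"
  tibble::as_tibble(df)
}

#' Fork speed versus replication timing
#'
#' Computes each fork's mean replication timing over its span (coverage-
#' weighted over the timing intervals it overlaps), drops forks without
#' timing coverage, and returns Spearman's correlation between speed and
#' timing.
#'
#' @param forks Fork tibble.
#' @param timing A tibble with `chrom`, `start`, `end`, `value` (0-based
#'   half-open intervals; values typically normalised to 0-1 over S phase),
#'   or the path of a fixed-/variable-step wiggle file (1-based, converted).
#' @param min_coverage Minimum fraction of forks with timing coverage.
#' @return A list: `rho`, `p_value`, `n`, and `data` (per-fork speed and
#'   mean timing).
#' @export
speed_vs_timing <- function(forks, timing, min_coverage = 0.5) {
  if (is.character(timing)) timing <- read_wig(timing)
  timing <- tibble::as_tibble(timing)
  tg <- GenomicRanges::GRanges(
    timing$chrom, IRanges::IRanges(timing$start + 1, timing$end)
  )
  fg <- GenomicRanges::GRanges(
    forks$chrom,
    IRanges::IRanges(pmin(forks$X0, forks$X1) + 1, pmax(forks$X0, forks$X1))
  )
  hits <- suppressWarnings(GenomicRanges::findOverlaps(fg, tg))
  if (!length(hits)) stop("timing track does not intersect any fork span")
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(fg)[S4Vectors::queryHits(hits)],
    IRanges::ranges(tg)[S4Vectors::subjectHits(hits)]
  ))
  num <- tapply(ov * timing$value[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits), sum)
  den <- tapply(ov, S4Vectors::queryHits(hits), sum)
  mt <- rep(NA_real_, nrow(forks))
  mt[as.integer(names(num))] <- num / den
  ok <- !is.na(mt)
  if (mean(ok) < min_coverage) {
    stop("timing track covers only ", round(100 * mean(ok)),
         "% of fork spans (need ", round(100 * min_coverage), "%)")
  }
  sp <- forks$speed[ok]
  if (stats::sd(sp) == 0 || stats::sd(mt[ok]) == 0) {
    stop("zero variance in speed or timing; correlation undefined")
  }
  ct <- suppressWarnings(
    stats::cor.test(sp, mt[ok], method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = sum(ok),
       data = tibble::tibble(speed = sp, timing = mt[ok]))
}

# Wiggle input via rtracklayer (1-based in the file; returned 0-based
# half-open like everything else here).
read_wig <- function(path) {
  gr <- rtracklayer::import(path, format = "wig")
  tibble::tibble(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1,
    end = BiocGenerics::end(gr),
    value = S4Vectors::mcols(gr)$score
  )
}

#' Descriptive summary of a sample's fork speeds
#'
#' The quantities of the standard half-eye display: mean, median, 50% and
#' 95% intervals and the number of measurements.
#'
#' @param forks Fork tibble (uses the `speed` column).
#' @return A one-row tibble: `n`, `mean`, `median`, `q25`, `q75`, `q2.5`,
#'   `q97.5`.
#' @export
summarize_sample <- function(forks) {
  s <- forks$speed
  stopifnot(length(s) >= 1)
  q <- stats::quantile(s, c(0.25, 0.75, 0.025, 0.975), names = FALSE)
  tibble::tibble(
    n = length(s), mean = mean(s), median = stats::median(s),
    q25 = q[1], q75 = q[2], q2.5 = q[3], q97.5 = q[4]
  )
}
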