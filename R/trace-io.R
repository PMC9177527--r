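#' Per-read BrdU probability traces
#'
#' A trace table holds one row per mapped read with its per-thymidine BrdU
#' probabilities attached to reference coordinates. Coordinates are 0-based
#' half-open throughout the package: a read covers `[start, end)` and every
#' thymidine position satisfies `start <= position < end`.
#'
#' @param read_id Character vector of read identifiers.
#' @param chrom Character vector of reference sequence names.
#' @param start,end Numeric, reference span of the read (0-based half-open).
#' @param strand Character, `"+"` or `"-"` (mapping strand).
#' @param signal List of data frames with columns `position` (sorted,
#'   strictly increasing reference positions of thymidine calls) and `prob`
#'   (BrdU probability in `[0, 1]`).
#' @param gaps List of data frames with columns `gap_start`, `gap_end`
#'   (0-based half-open reference intervals of mapping discontinuities), or
#'   `NULL` entries when a read has none.
#'
#' @param .validated Internal fast path: skip per-read invariant checks for
#'   signal lists produced by trusted code (the simulators).
#' @return A tibble of class `trace_tbl` with one row per read.
#' @examples
#' tr <- trace_tbl("r1", "chrI", 0, 6000, "+",
#'                 list(data.frame(position = c(10, 20), prob = c(0.1, 0.9))))
#' tr
#' @export
trace_tbl <- function(read_id, chrom, start, end, strand,
                      signal, gaps = NULL, .validated = FALSE) {
  n <- length(read_id)
  if (is.null(gaps)) gaps <- rep(list(NULL), n)
  out <- tibble::new_tibble(
    list(
      read_id = as.character(read_id),
      chrom = rep_len(as.character(chrom), n),
      start = rep_len(as.numeric(start), n),
      end = rep_len(as.numeric(end), n),
      strand = rep_len(as.character(strand), n),
      signal = if (.validated) signal else lapply(signal, function(s) {
        s <- tibble::as_tibble(s)
        stopifnot(all(c("position", "prob") %in% names(s)))
        s
      }),
      gaps = lapply(gaps, function(g) if (is.null(g)) NULL else tibble::as_tibble(g))
    ),
    nrow = n
  )
  if (.validated) {
    class(out) <- unique(c("trace_tbl", class(out)))
    return(out)
  }
  validate_traces(out)
}

validate_traces <- function(x) {
  for (i in seq_len(nrow(x))) {
    s <- x$signal[[i]]
    if (nrow(s)) {
      if (any(diff(s$position) <= 0)) {
        stop("trace ", x$read_id[i], ": positions must be strictly increasing")
      }
      if (any(s$position < x$start[i] | s$position >= x$end[i])) {
        stop("trace ", x$read_id[i], ": positions outside [start, end)")
      }
      bad <- !is.na(s$prob) & (s$prob < 0 | s$prob > 1)
      if (any(bad)) stop("trace ", x$read_id[i], ": probabilities outside [0, 1]")
    }
  }
  class(x) <- unique(c("trace_tbl", class(x)))
  x
}

#' Read per-thymidine BrdU traces from a tab-separated file
#'
#' The interchange format is a TSV with header
#' `read_id chrom start end strand position probability`, one row per
#' thymidine call, rows grouped by read and sorted by position within a read.
#' It carries no mapping-gap information (`gaps` are empty).
#'
#' @param path Path to the TSV file.
#' @return A [trace_tbl] tibble.
#' @seealso [write_traces()] for the inverse, [read_traces_bam()] for
#'   modified-base BAM input.
#' @export
read_traces <- function(path) {
  cols <- readr::cols(
    read_id = readr::col_character(), chrom = readr::col_character(),
    start = readr::col_double(), end = readr::col_double(),
    strand = readr::col_character(), position = readr::col_double(),
    probability = readr::col_double()
  )
  df <- readr::read_tsv(path, col_types = cols, progress = FALSE)
  req <- c("read_id", "chrom", "start", "end", "strand", "position", "probability")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!is.na(df$probability) & (df$probability < 0 | df$probability > 1))
  if (length(bad)) {
    stop("probability outside [0, 1] on line ", bad[1] + 1L,
         " (value ", df$probability[bad[1]], ")")
  }
  # preserve file order of reads
  ids <- unique(df$read_id)
  grp <- split(df, factor(df$read_id, levels = ids))
  unsrt <- vapply(grp, function(g) any(diff(g$position) <= 0), logical(1))
  if (any(unsrt)) {
    stop("positions not strictly increasing within read ",
         names(grp)[which(unsrt)[1]])
  }
  trace_tbl(
    read_id = ids,
    chrom = vapply(grp, function(g) g$chrom[1], character(1)),
    start = vapply(grp, function(g) g$start[1], numeric(1)),
    end = vapply(grp, function(g) g$end[1], numeric(1)),
    strand = vapply(grp, function(g) g$strand[1], character(1)),
    signal = lapply(grp, function(g) tibble::tibble(position = g$position, prob = g$probability))
  )
}

#' Write traces to the tab-separated interchange format
#'
#' @param traces A [trace_tbl] tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  long <- purrr::pmap(
    list(traces$read_id, traces$chrom, traces$start, traces$end,
         traces$strand, traces$signal),
    function(id, ch, st, en, sd, sig) {
      tibble::tibble(read_id = id, chrom = ch, start = st, end = en,
                     strand = sd, position = sig$position,
                     probability = sig$prob)
    }
  )
  readr::write_tsv(dplyr::bind_rows(long), path, progress = FALSE)
  invisible(path)
}

#' Read BrdU traces from a modified-base BAM file
#'
#' Extracts per-thymidine modification probabilities from the MM/ML (or
#' legacy Mm/Ml) base-modification tags of mapped, primary alignments.
#' Modification scores are decoded to probabilities with the modified-base
#' convention `p = (score + 0.5) / 256` and positions are projected onto the
#' reference through the CIGAR. Reference deletions and skips longer than
#' `min_gap_len` are recorded as gaps. Unmapped, secondary and supplementary
#' records are skipped; records without modification tags are skipped with a
#' warning.
#'
#' @param path Path to an indexed or unindexed BAM file.
#' @param min_gap_len Record reference gaps longer than this many bp.
#' @param mod_code Optional single modification code (e.g. `"b"`); by default
#'   every reported modification call on a thymidine base is used.
#' @return A [trace_tbl] tibble.
#' @export
read_traces_bam <- function(path, min_gap_len = 100, mod_code = NULL) {
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "strand", "pos", "cigar", "seq"),
    tag = c("MM", "ML", "Mm", "Ml"),
    flag = Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE,
      isSecondaryAlignment = FALSE,
      isSupplementaryAlignment = FALSE
    )
  )
  res <- Rsamtools::scanBam(path, param = param)[[1]]
  n <- length(res$qname)
  if (n == 0) {
    return(trace_tbl(character(), character(), numeric(), numeric(),
                     character(), list()))
  }
  pick_tag <- function(primary, legacy, i) {
    v <- primary[[i]]
    if (is.null(v) || (length(v) == 1 && is.na(v))) v <- legacy[[i]]
    v
  }
  mm_tag <- res$tag$MM
  mm_legacy <- res$tag$Mm
  if (is.null(mm_tag)) mm_tag <- rep(NA_character_, n)
  if (is.null(mm_legacy)) mm_legacy <- rep(NA_character_, n)
  ml_tag <- if (is.null(res$tag$ML)) vector("list", n) else res$tag$ML
  ml_legacy <- if (is.null(res$tag$Ml)) vector("list", n) else res$tag$Ml
  seqs <- as.character(res$seq)
  strands <- as.character(res$strand)
  starts0 <- res$pos - 1L

  keep <- logical(n)
  sig <- vector("list", n)
  gap <- vector("list", n)
  ends0 <- numeric(n)
  for (i in seq_len(n)) {
    mm <- if (!is.na(mm_tag[i])) mm_tag[i] else mm_legacy[i]
    ml <- pick_tag(ml_tag, ml_legacy, i)
    if (is.na(mm) || !nzchar(mm) || is.null(ml)) {
      warning("read ", res$qname[i], ": missing MM/ML modification tags; skipped")
      next
    }
    parsed <- parse_mod_tags(mm, as.integer(ml), seqs[i], strands[i],
                             mod_code = mod_code)
    proj <- project_query_to_ref(res$cigar[i], starts0[i], nchar(seqs[i]),
                                 qname = res$qname[i],
                                 min_gap_len = min_gap_len)
    ref <- proj$refmap[parsed$qpos]
    ok <- !is.na(ref)
    o <- order(ref[ok])
    pos <- ref[ok][o]
    prob <- parsed$prob[ok][o]
    dup <- duplicated(pos)
    sig[[i]] <- tibble::tibble(position = pos[!dup], prob = prob[!dup])
    gap[[i]] <- proj$gaps
    ends0[i] <- proj$ref_end
    keep[i] <- TRUE
  }
  idx <- which(keep)
  if (!length(idx)) {
    return(trace_tbl(character(), character(), numeric(), numeric(),
                     character(), list()))
  }
  trace_tbl(
    read_id = res$qname[idx],
    chrom = as.character(res$rname)[idx],
    start = starts0[idx], end = ends0[idx], strand = strands[idx],
    signal = sig[idx], gaps = gap[idx]
  )
}

# Decode MM/ML tags to query positions (1-based, in aligned/SEQ orientation)
# and probabilities. MM deltas count skipped occurrences of the fundamental
# base in the original read orientation; reverse-strand alignments store SEQ
# reverse-complemented, so thymidines of the original read appear as 'A'
# scanned from the 3' end of SEQ.
parse_mod_tags <- function(mm, ml, seq, strand, mod_code = NULL) {
  items <- strsplit(sub(";$", "", mm), ";", fixed = TRUE)[[1]]
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  qpos_all <- integer(0)
  prob_all <- numeric(0)
  consumed <- 0L
  for (it in items) {
    fields <- strsplit(it, ",", fixed = TRUE)[[1]]
    head <- fields[1]
    deltas <- as.integer(fields[-1])
    m <- regmatches(head, regexec("^([ACGTUN])([-+])([a-zA-Z0-9]+)([.?]?)$", head))[[1]]
    if (!length(m)) stop("malformed MM tag item: ", it)
    base <- m[2]; codes <- m[4]
    n_codes <- if (grepl("^[0-9]+$", codes)) 1L else nchar(codes)
    n_vals <- length(deltas) * n_codes
    probs <- (ml[(consumed + 1L):(consumed + n_vals)] + 0.5) / 256
    consumed <- consumed + n_vals
    use <- base %in% c("T", "U") &&
      (is.null(mod_code) || grepl(mod_code, codes, fixed = TRUE))
    if (!use) next
    if (n_codes > 1L) {
      probs <- matrix(probs, ncol = n_codes, byrow = TRUE)
      if (!is.null(mod_code)) {
        j <- regexpr(mod_code, codes, fixed = TRUE)
        probs <- probs[, j, drop = TRUE]
      } else {
        probs <- apply(probs, 1, max)
      }
    }
    if (strand == "-") {
      occ <- rev(which(chars == "A"))
    } else {
      occ <- which(chars %in% c("T", "U"))
    }
    rank <- cumsum(deltas + 1L)
    ok <- rank <= length(occ)
    qpos_all <- c(qpos_all, occ[rank[ok]])
    prob_all <- c(prob_all, probs[ok])
  }
  list(qpos = qpos_all, prob = prob_all)
}

# Walk a CIGAR string: reference position (0-based) for every query position
# of SEQ, plus reference gaps (D/N ops) longer than min_gap_len.
project_query_to_ref <- function(cigar, start0, seq_len, qname = "?",
                                 min_gap_len = 100) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  refmap <- rep(NA_real_, seq_len)
  gs <- numeric(0); ge <- numeric(0)
  q <- 0L; r <- start0
  for (k in seq_along(ops)) {
    op <- ops[k]; len <- lens[k]
    if (op %in% c("M", "=", "X")) {
      refmap[(q + 1L):(q + len)] <- r + 0:(len - 1L)
      q <- q + len; r <- r + len
    } else if (op %in% c("I", "S")) {
      q <- q + len
    } else if (op %in% c("D", "N")) {
      if (len > min_gap_len) { gs <- c(gs, r); ge <- c(ge, r + len) }
      r <- r + len
    } else if (op == "H" || op == "P") {
      # consumes neither SEQ nor reference
    } else {
      stop("malformed CIGAR for read ", qname, ": unknown op '", op, "'")
    }
  }
  if (q != seq_len) {
    stop("malformed CIGAR for read ", qname,
         ": query length ", q, " != SEQ length ", seq_len)
  }
  gaps <- if (length(gs)) tibble::tibble(gap_start = gs, gap_end = ge) else NULL
  list(refmap = refmap, gaps = gaps, ref_end = r)
}
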