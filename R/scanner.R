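# Spacer-aware sliding-window p53RE scanner.
#
# At every chromosomal position eight scoring attempts are made: spacers
# 0-3 nt between the two decamer half-sites, on both strands. The window
# (20 + spacer nt) is reduced to a 20-nt core by concatenating its first and
# last 10 nt; a fast prefilter requires >= 3 of the 4 consensus core C/G
# bases (C at core positions 4 and 14, G at 7 and 17) before PWM scoring.

# 1-based core positions and required bases of the CWWG core in each decamer
PREFILTER_POS <- c(4L, 7L, 14L, 17L)
PREFILTER_BASE <- c("C", "G", "C", "G")

#' Reverse complement of DNA strings
#'
#' @param seq Character vector over A/C/G/T/N (case-insensitive).
#' @return Character vector of reverse complements (upper case). `N` maps to
#'   `N`; applying twice is the identity.
#' @export
#' @examples
#' reverse_complement("AAAC")
reverse_complement <- function(seq) {
  seq <- toupper(as.character(seq))
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) abort("sequence contains characters outside A/C/G/T/N")
  vapply(seq, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Concatenate the half-sites of a window into a 20-nt core
#'
#' @param window A DNA string of length `20 + spacer`.
#' @param spacer Spacer length in nt (0-3).
#' @return The 20-nt core: first 10 nt followed by last 10 nt of the window.
#' @export
concatenate_core <- function(window, spacer) {
  window <- toupper(as.character(window))
  if (any(nchar(window) != CORE_LEN + spacer)) {
    abort(paste0("window length must be ", CORE_LEN, " + spacer"))
  }
  paste0(substr(window, 1L, HALF_LEN),
         substr(window, nchar(window) - HALF_LEN + 1L, nchar(window)))
}

#' Consensus-core prefilter
#'
#' Counts matches at the four consensus core positions of the concatenated
#' 20-mer (C at positions 4 and 14, G at 7 and 17 of the RRRCWWGYYY x2
#' consensus). A core passes when at least 3 of 4 match. `N` never matches.
#'
#' @param core Character vector of 20-nt cores.
#' @return A tibble with columns `core`, `core_matches` (0-4) and `passes`.
#' @export
core_prefilter <- function(core) {
  core <- toupper(as.character(core))
  if (any(nchar(core) != CORE_LEN)) {
    abort(paste0("core length must be ", CORE_LEN))
  }
  m <- vapply(seq_along(PREFILTER_POS), function(k) {
    substr(core, PREFILTER_POS[k], PREFILTER_POS[k]) == PREFILTER_BASE[k]
  }, logical(length(core)))
  if (length(core) == 1L) m <- matrix(m, nrow = 1L)
  core_matches <- as.integer(rowSums(m))
  tibble(core = core, core_matches = core_matches,
         passes = core_matches >= 3L)
}

#' Enumerate the eight candidates at one position
#'
#' One candidate per spacer (0-3) x strand that fits within the sequence;
#' exactly eight at interior positions, fewer near the sequence end. The
#' reverse-strand candidate scores the reverse complement of the identical
#' forward window.
#'
#' @param seq A single DNA string.
#' @param pos 0-based offset of the window start.
#' @return A tibble with columns `start`, `spacer`, `strand`, `window`,
#'   `core`.
#' @export
enumerate_candidates <- function(seq, pos) {
  seq <- toupper(as.character(seq)[1])
  n <- nchar(seq)
  out <- list()
  for (s in 0:MAX_SPACER) {
    len <- CORE_LEN + s
    if (pos + len > n) next
    fwd_window <- substr(seq, pos + 1L, pos + len)
    rc <- reverse_complement(fwd_window)
    out[[length(out) + 1L]] <- tibble(
      start = pos, spacer = s, strand = c("+", "-"),
      window = c(fwd_window, rc),
      core = c(concatenate_core(fwd_window, s), concatenate_core(rc, s)))
  }
  if (length(out) == 0) {
    return(tibble(start = integer(), spacer = integer(),
                  strand = character(), window = character(),
                  core = character()))
  }
  bind_rows(out)
}

#' Select the reported response element among co-located candidates
#'
#' Candidates are filtered by the consensus-core prefilter and by
#' `score > threshold`; among survivors the reported element has the
#' shortest spacer, with ties within a spacer broken by the larger score and
#' then by strand (`+` before `-`). `selection = "score-first"` swaps the
#' first two keys (largest score, then shortest spacer).
#'
#' @param candidates A tibble as returned by [enumerate_candidates()].
#' @param wm A `p53_pwm` object.
#' @param threshold Minimum score (exclusive).
#' @param selection `"spacer-first"` (default) or `"score-first"`.
#' @return A one-row tibble (`start`, `spacer`, `strand`, `core`, `score`,
#'   `core_matches`) or a zero-row tibble if no candidate survives.
#' @export
select_re_at_position <- function(candidates, wm, threshold,
                                  selection = c("spacer-first", "score-first")) {
  selection <- match.arg(selection)
  empty <- tibble(start = integer(), spacer = integer(), strand = character(),
                  core = character(), score = numeric(),
                  core_matches = integer())
  if (nrow(candidates) == 0) return(empty)
  pf <- core_prefilter(candidates$core)
  cand <- candidates |>
    mutate(core_matches = pf$core_matches,
           score = ifelse(pf$passes, score_core(wm, .data$core), -Inf)) |>
    filter(pf$passes, .data$score > threshold)
  if (nrow(cand) == 0) return(empty)
  strand_rank <- match(cand$strand, c("+", "-"))
  ord <- if (selection == "spacer-first") {
    order(cand$spacer, -cand$score, strand_rank)
  } else {
    order(-cand$score, cand$spacer, strand_rank)
  }
  cand[ord[1], c("start", "spacer", "strand", "core", "score", "core_matches")]
}

# Vectorized single-chromosome scan. `codes` is the integer-encoded sequence
# (A=1..T=4, N=5). Returns score/core_matches vectors for every (spacer,
# strand) that fits, from which the per-position selection is made.
scan_chrom_codes <- function(codes, wm, threshold, selection) {
  n <- length(codes)
  w5 <- rbind(wm$weights, N = -Inf)
  comp <- c(4L, 3L, 2L, 1L, 5L)        # A<->T, C<->G, N->N
  ccodes <- comp[codes]

  best <- NULL   # running selection: list of vectors over positions 1..n20
  n20 <- n - CORE_LEN + 1L
  if (n20 < 1L) {
    return(tibble(start = integer(), spacer = integer(), strand = character(),
                  score = numeric(), core_matches = integer()))
  }
  best_spacer <- rep(NA_integer_, n20)
  best_strand <- rep(NA_character_, n20)
  best_score <- rep(-Inf, n20)
  best_cm <- rep(NA_integer_, n20)

  # candidate keys in priority order for spacer-first: spacer asc, then we
  # resolve score/strand within; for score-first we gather all then pick.
  all_cand <- vector("list", 8L)
  k <- 0L
  for (s in 0:MAX_SPACER) {
    len <- CORE_LEN + s
    npos <- n - len + 1L
    if (npos < 1L) next
    pos <- seq_len(npos)
    # forward: core base j comes from genome index pos + off(j)
    fwd_score <- numeric(npos)
    for (j in seq_len(CORE_LEN)) {
      off <- if (j <= HALF_LEN) j - 1L else s + j - 1L
      fwd_score <- fwd_score + w5[cbind(codes[pos + off], j)]
    }
    fwd_cm <- (codes[pos + 3L] == 2L) + (codes[pos + 6L] == 3L) +
      (codes[pos + s + 13L] == 2L) + (codes[pos + s + 16L] == 3L)
    # reverse: core base j = complement of genome index pos+len-j (j<=10)
    # or pos+20-j (j>10)
    rev_score <- numeric(npos)
    for (j in seq_len(CORE_LEN)) {
      off <- if (j <= HALF_LEN) len - j else CORE_LEN - j
      rev_score <- rev_score + w5[cbind(ccodes[pos + off], j)]
    }
    rev_cm <- (codes[pos + len - 4L] == 3L) + (codes[pos + len - 7L] == 2L) +
      (codes[pos + 6L] == 3L) + (codes[pos + 3L] == 2L)
    for (strand in c("+", "-")) {
      sc <- if (strand == "+") fwd_score else rev_score
      cm <- if (strand == "+") as.integer(fwd_cm) else as.integer(rev_cm)
      pass <- cm >= 3L & sc > threshold & is.finite(sc)
      k <- k + 1L
      all_cand[[k]] <- list(spacer = s, strand = strand, npos = npos,
                            score = sc, cm = cm, pass = pass)
    }
  }
  all_cand <- all_cand[seq_len(k)]

  if (selection == "spacer-first") {
    # process spacers in ascending order; within a spacer prefer the higher
    # score, ties to "+"; a position already claimed by a shorter spacer is
    # never overwritten
    for (s in 0:MAX_SPACER) {
      pair <- Filter(function(cc) cc$spacer == s, all_cand)
      if (length(pair) == 0) next
      fp <- pair[[1]]; rp <- pair[[2]]
      npos <- fp$npos
      idx <- seq_len(npos)
      use_f <- fp$pass & (!rp$pass | fp$score >= rp$score)
      use_r <- rp$pass & !use_f
      claim <- (use_f | use_r) & is.na(best_spacer[idx])
      cf <- claim & use_f
      cr <- claim & use_r
      best_spacer[idx][cf] <- s; best_strand[idx][cf] <- "+"
      best_score[idx][cf] <- fp$score[cf]; best_cm[idx][cf] <- fp$cm[cf]
      best_spacer[idx][cr] <- s; best_strand[idx][cr] <- "-"
      best_score[idx][cr] <- rp$score[cr]; best_cm[idx][cr] <- rp$cm[cr]
    }
  } else {
    # score-first: max passing score, ties to smaller spacer then "+"
    for (cc in all_cand) {
      idx <- seq_len(cc$npos)
      sc <- ifelse(cc$pass, cc$score, -Inf)
      better <- sc > best_score[idx]
      best_spacer[idx][better] <- cc$spacer
      best_strand[idx][better] <- cc$strand
      best_score[idx][better] <- sc[better]
      best_cm[idx][better] <- cc$cm[better]
    }
    best_spacer[!is.finite(best_score)] <- NA_integer_
  }

  hit <- which(!is.na(best_spacer))
  tibble(start = hit - 1L, spacer = best_spacer[hit],
         strand = best_strand[hit], score = best_score[hit],
         core_matches = best_cm[hit])
}

#' Scan sequence for p53 response elements
#'
#' Applies the eight-candidate selection at every offset of every sequence.
#' At most one element is reported per start offset; overlapping elements
#' from adjacent offsets are retained (per-peak deduplication happens later
#' in [best_re_for_peak()]).
#'
#' @param seqs Named character vector of DNA sequences (names are chromosome
#'   names), a single unnamed string (chromosome `"chr"`), or a
#'   `Biostrings::DNAStringSet`.
#' @param wm A `p53_pwm` object.
#' @param threshold Absolute score threshold (exclusive). If `NULL`,
#'   `threshold_frac * max_score(wm)` is used.
#' @param threshold_frac Fraction of the maximum achievable score; default
#'   0.8.
#' @param selection Tie rule passed to the per-position selection; see
#'   [select_re_at_position()].
#' @return A tibble of response elements sorted by (`chrom`, `start`):
#'   columns `chrom`, `start`, `end` (0-based half-open footprint of
#'   `20 + spacer` nt), `strand`, `spacer`, `score`, `core`, `core_matches`.
#' @export
scan_sequence <- function(seqs, wm, threshold = NULL, threshold_frac = 0.8,
                          selection = c("spacer-first", "score-first")) {
  selection <- match.arg(selection)
  if (inherits(seqs, "DNAStringSet")) {
    seqs <- setNames(as.character(seqs), names(seqs))
  }
  nm <- names(seqs)
  seqs <- as.character(seqs)
  names(seqs) <- nm
  if (is.null(names(seqs))) {
    names(seqs) <- if (length(seqs) == 1) "chr" else
      paste0("chr", seq_along(seqs))
  }
  if (is.null(threshold)) threshold <- threshold_frac * max_score(wm)
  if (!is.finite(threshold)) abort("threshold must be finite")
  out <- purrr::map(names(seqs), function(chrom) {
    codes <- seq_to_index(seqs[[chrom]])
    hits <- scan_chrom_codes(codes, wm, threshold, selection)
    if (nrow(hits) == 0) return(NULL)
    win_end <- hits$start + CORE_LEN + hits$spacer
    window <- substring(seqs[[chrom]], hits$start + 1L, win_end)
    core_fwd <- paste0(substr(window, 1L, HALF_LEN),
                       substring(window, nchar(window) - HALF_LEN + 1L))
    core <- ifelse(hits$strand == "+", core_fwd, NA)
    rev_idx <- which(hits$strand == "-")
    if (length(rev_idx) > 0) {
      rc <- reverse_complement(window[rev_idx])
      core[rev_idx] <- paste0(substr(rc, 1L, HALF_LEN),
                              substring(rc, nchar(rc) - HALF_LEN + 1L))
    }
    tibble(chrom = chrom, start = hits$start, end = win_end,
           strand = hits$strand, spacer = hits$spacer, score = hits$score,
           core = core, core_matches = hits$core_matches)
  })
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), spacer = integer(), score = numeric(),
                  core = character(), core_matches = integer()))
  }
  arrange(res, .data$chrom, .data$start)
}

#' Assign the best response element to each peak
#'
#' The best element for a peak is the one whose footprint midpoint lies
#' nearest the peak summit (the position of maximal binding signal), among
#' elements overlapping the peak interval; ties are broken by the higher
#' score, then the lower start. Peaks with no overlapping element keep `NA`
#' columns and count as "no canonical RE".
#'
#' @param peaks Tibble with columns `chrom`, `start`, `end`, `summit` (plus
#'   any others, carried through).
#' @param res Tibble of response elements from [scan_sequence()].
#' @return `peaks` with added columns `re_start`, `re_end`, `re_strand`,
#'   `re_spacer`, `re_score`, `re_core`, `re_distance` (midpoint-to-summit
#'   distance in bp).
#' @export
best_re_for_peak <- function(peaks, res) {
  stopifnot(all(c("chrom", "start", "end", "summit") %in% names(peaks)))
  add <- tibble(re_start = rep(NA_integer_, nrow(peaks)),
                re_end = NA_integer_, re_strand = NA_character_,
                re_spacer = NA_integer_, re_score = NA_real_,
                re_core = NA_character_, re_distance = NA_real_)
  if (nrow(res) > 0) {
    for (i in seq_len(nrow(peaks))) {
      cand <- res[res$chrom == peaks$chrom[i] &
                    res$start < peaks$end[i] & res$end > peaks$start[i], ]
      if (nrow(cand) == 0) next
      mid <- (cand$start + cand$end) / 2
      d <- abs(mid - peaks$summit[i])
      ord <- order(d, -cand$score, cand$start)
      b <- cand[ord[1], ]
      add$re_start[i] <- b$start; add$re_end[i] <- b$end
      add$re_strand[i] <- b$strand; add$re_spacer[i] <- b$spacer
      add$re_score[i] <- b$score; add$re_core[i] <- b$core
      add$re_distance[i] <- d[ord[1]]
    }
  }
  dplyr::bind_cols(peaks, add)
}

#' Scan for p53RE half-sites (decamers)
#'
#' Scores every 10-mer on both strands against the averaged half matrix (the
#' position-wise mean of matrix columns 1-10 and 11-20) and reports hits
#' above `half_threshold`.
#'
#' @inheritParams scan_sequence
#' @param half_threshold Minimum half-site score (exclusive).
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`, `score`.
#' @export
find_halfsites <- function(seqs, wm, half_threshold) {
  if (inherits(seqs, "DNAStringSet")) {
    seqs <- setNames(as.character(seqs), names(seqs))
  }
  nm <- names(seqs)
  seqs <- as.character(seqs)
  names(seqs) <- nm
  if (is.null(names(seqs))) {
    names(seqs) <- if (length(seqs) == 1) "chr" else
      paste0("chr", seq_along(seqs))
  }
  half <- (wm$weights[, 1:HALF_LEN] + wm$weights[, HALF_LEN + 1:HALF_LEN]) / 2
  w5 <- rbind(half, N = -Inf)
  comp <- c(4L, 3L, 2L, 1L, 5L)
  out <- purrr::map(names(seqs), function(chrom) {
    codes <- seq_to_index(seqs[[chrom]])
    n <- length(codes)
    npos <- n - HALF_LEN + 1L
    if (npos < 1L) return(NULL)
    pos <- seq_len(npos)
    fwd <- numeric(npos); rev <- numeric(npos)
    ccodes <- comp[codes]
    for (j in seq_len(HALF_LEN)) {
      fwd <- fwd + w5[cbind(codes[pos + j - 1L], j)]
      rev <- rev + w5[cbind(ccodes[pos + HALF_LEN - j], j)]
    }
    hits <- bind_rows(
      tibble(start = pos - 1L, strand = "+", score = fwd)[fwd > half_threshold, ],
      tibble(start = pos - 1L, strand = "-", score = rev)[rev > half_threshold, ])
    if (nrow(hits) == 0) return(NULL)
    mutate(hits, chrom = chrom, end = .data$start + HALF_LEN,
           .before = 1)[, c("chrom", "start", "end", "strand", "score")]
  })
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), score = numeric()))
  }
  arrange(res, .data$chrom, .data$start, .data$strand)
}
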