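# Spacer-aware scanner: candidate enumeration, prefilter, selection, and
# equivalence with an exhaustive slicing oracle.

test_that("reverse complement is correct and involutive", {
  expect_identical(reverse_complement("ACGT"), "ACGT")
  expect_identical(reverse_complement("AAAC"), "GTTT")
  expect_identical(reverse_complement("ANT"), "ANT")
  expect_error(reverse_complement("ACGU"), "outside")
  set.seed(501)
  for (i in 1:20) {
    s <- random_seq(20)
    expect_identical(reverse_complement(reverse_complement(s)), s)
    expect_identical(reverse_complement(s), oracle_revcomp(s))
  }
})

test_that("eight candidates are enumerated at interior positions", {
  set.seed(502)
  seq <- random_seq(30)
  cand <- enumerate_candidates(seq, 0)
  expect_equal(nrow(cand), 8L)
  expect_equal(sort(unique(cand$spacer)), 0:3)
  expect_setequal(unique(cand$strand), c("+", "-"))
  expect_false(any(duplicated(cand[, c("spacer", "strand")])))
  for (i in seq_len(nrow(cand))) {
    w <- substr(seq, 1, 20 + cand$spacer[i])
    if (cand$strand[i] == "-") w <- oracle_revcomp(w)
    expect_identical(cand$window[i], w)
    expect_identical(cand$core[i],
                     paste0(substr(w, 1, 10),
                            substr(w, nchar(w) - 9, nchar(w))))
  }
})

test_that("candidate count shrinks near the sequence end", {
  seq <- random_seq(30)
  expect_equal(nrow(enumerate_candidates(seq, 9)), 4L)   # room for 21 nt
  expect_equal(nrow(enumerate_candidates(seq, 10)), 2L)  # room for 20 nt
  expect_equal(nrow(enumerate_candidates(seq, 11)), 0L)
})

test_that("half-site concatenation drops exactly the spacer", {
  expect_identical(concatenate_core(CANON, 0), CANON)
  expect_identical(
    concatenate_core(paste0(strrep("A", 10), "NNN", strrep("T", 10)), 3),
    paste0(strrep("A", 10), strrep("T", 10)))
  expect_error(concatenate_core(CANON, 2), "length")
  set.seed(503)
  w <- random_seq(23)
  expect_identical(concatenate_core(w, 3),
                   paste0(substr(w, 1, 10), substr(w, 14, 23)))
})

test_that("core prefilter counts consensus C/G matches and requires 3 of 4", {
  expect_equal(core_prefilter(CANON)$core_matches, 4L)
  expect_true(core_prefilter(CANON)$passes)
  allA <- strrep("A", 20)
  expect_equal(core_prefilter(allA)$core_matches, 0L)
  expect_false(core_prefilter(allA)$passes)
  three <- CANON
  substr(three, 4, 4) <- "A"
  expect_equal(core_prefilter(three)$core_matches, 3L)
  expect_true(core_prefilter(three)$passes)
  two <- three
  substr(two, 7, 7) <- "T"
  expect_false(core_prefilter(two)$passes)
  set.seed(504)
  for (i in 1:50) {
    core <- random_core()
    expect_equal(core_prefilter(core)$core_matches,
                 oracle_prefilter_matches(core))
  }
})

test_that("selection prefers the shortest spacer, then score, then strand", {
  wm <- build_pwm(generate_training_set(30, 0.05, seed = 505))
  # same strong core planted as spacer-0 and spacer-2 candidates
  cand <- tibble::tibble(
    start = 0L, spacer = c(0L, 2L), strand = "+",
    window = c(CANON, paste0(substr(CANON, 1, 10), "AA",
                             substr(CANON, 11, 20))),
    core = c(CANON, CANON))
  sel <- select_re_at_position(cand, wm, threshold = 0)
  expect_equal(sel$spacer, 0L)
  single <- cand[2, ]
  expect_equal(select_re_at_position(single, wm, 0)$spacer, 2L)
  expect_equal(nrow(select_re_at_position(cand, wm, threshold = 1e6)), 0L)

  set.seed(506)
  for (i in 1:25) {
    pos <- sample(0:50, 1)
    seq <- random_seq(100)
    cands <- enumerate_candidates(seq, pos)
    thr <- -20
    for (mode in c("spacer-first", "score-first")) {
      got <- select_re_at_position(cands, wm, thr, selection = mode)
      pf <- vapply(cands$core, oracle_prefilter_matches, numeric(1))
      sc <- vapply(cands$core, function(cc) oracle_score(wm, cc), numeric(1))
      keep <- pf >= 3 & sc > thr
      if (!any(keep)) {
        expect_equal(nrow(got), 0L)
      } else {
        sub <- cands[keep, ]
        key <- if (mode == "spacer-first") {
          order(sub$spacer, -sc[keep], match(sub$strand, c("+", "-")))
        } else {
          order(-sc[keep], sub$spacer, match(sub$strand, c("+", "-")))
        }
        expect_equal(got$spacer, sub$spacer[key[1]])
        expect_equal(got$strand, sub$strand[key[1]])
        expect_equal(got$score, sc[keep][key[1]], tolerance = 1e-12)
      }
    }
  }
})

test_that("scan finds nothing in homopolymer and finds a planted consensus", {
  wm <- build_pwm(generate_training_set(30, 0.05, seed = 507))
  expect_equal(nrow(scan_sequence(strrep("A", 500), wm, threshold_frac = 0.5)),
               0L)
  set.seed(508)
  # low-scoring AT-rich background so only the plant passes
  bg <- function(n) paste(sample(c("A", "T"), n, replace = TRUE),
                          collapse = "")
  seq <- paste0(bg(100), CANON, bg(80))
  res <- scan_sequence(seq, wm, threshold = 0.9 * max_score(wm))
  expect_equal(nrow(res), 1L)
  expect_equal(res$start, 100L)
  expect_equal(res$spacer, 0L)
  expect_equal(res$end, 120L)
  expect_equal(res$core, CANON)
})

test_that("scan matches the exhaustive slicing oracle on random sequence", {
  wm <- build_pwm(generate_training_set(40, 0.12, seed = 509))
  set.seed(510)
  thr <- 0.55 * max_score(wm)
  for (rep in 1:3) {
    seq <- random_seq(1000)
    got <- scan_sequence(seq, wm, threshold = thr)
    want <- oracle_scan(seq, wm, thr)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(got$start, want$start)
      expect_equal(got$spacer, want$spacer)
      expect_equal(got$strand, want$strand)
      expect_equal(got$score, want$score, tolerance = 1e-10)
      expect_equal(got$core, want$core)
      expect_equal(got$core_matches, want$core_matches)
    }
  }
})

test_that("scanning the reverse complement reflects the element set", {
  wm <- build_pwm(generate_training_set(40, 0.12, seed = 511))
  set.seed(512)
  thr <- 0.55 * max_score(wm)
  for (rep in 1:3) {
    seq <- random_seq(600)
    fwd <- scan_sequence(seq, wm, threshold = thr)
    rev <- scan_sequence(reverse_complement(seq), wm, threshold = thr)
    # reflect: an element [s, e) maps to [L - e, L - s) with flipped strand
    L <- nchar(seq)
    refl <- sort(paste(L - fwd$end, fwd$spacer,
                       ifelse(fwd$strand == "+", "-", "+"),
                       round(fwd$score, 9)))
    expect_identical(sort(paste(rev$start, rev$spacer, rev$strand,
                                round(rev$score, 9))), refl)
  }
})

test_that("raising the threshold only removes elements", {
  wm <- build_pwm(generate_training_set(40, 0.12, seed = 513))
  set.seed(514)
  seq <- random_seq(2000)
  lo <- scan_sequence(seq, wm, threshold = 0.5 * max_score(wm))
  hi <- scan_sequence(seq, wm, threshold = 0.7 * max_score(wm))
  expect_true(all(paste(hi$start, hi$spacer, hi$strand) %in%
                    paste(lo$start, lo$spacer, lo$strand)))
  expect_lte(nrow(hi), nrow(lo))
})

test_that("best element per peak is the one nearest the summit", {
  res <- tibble::tibble(
    chrom = "chr1", start = c(100L, 140L), end = c(120L, 160L),
    strand = "+", spacer = 0L, score = c(30, 25), core = CANON,
    core_matches = 4L)
  peaks <- tibble::tibble(chrom = "chr1", start = 90L, end = 200L,
                          summit = 120L, density = 50)
  out <- best_re_for_peak(peaks, res)
  expect_equal(out$re_start, 100L)  # midpoint 110 vs 150: distance 10 vs 30
  expect_equal(out$re_distance, 10)

  # no overlapping element -> NA columns
  far <- tibble::tibble(chrom = "chr1", start = 500L, end = 520L,
                        strand = "+", spacer = 0L, score = 30, core = CANON,
                        core_matches = 4L)
  expect_true(is.na(best_re_for_peak(peaks, far)$re_start))

  set.seed(515)
  for (i in 1:20) {
    n_re <- sample(1:6, 1)
    res_r <- tibble::tibble(
      chrom = "chr1", start = sample(0:180, n_re),
      strand = "+", spacer = sample(0:3, n_re, TRUE),
      score = runif(n_re, 10, 40), core = CANON, core_matches = 4L)
    res_r$end <- res_r$start + 20L + res_r$spacer
    pk <- tibble::tibble(chrom = "chr1", start = 0L, end = 250L,
                         summit = sample(0:249, 1), density = 1)
    got <- best_re_for_peak(pk, res_r)
    d <- abs((res_r$start + res_r$end) / 2 - pk$summit)
    best <- order(d, -res_r$score, res_r$start)[1]
    expect_equal(got$re_start, res_r$start[best])
  }
})

test_that("half-site scan matches a brute-force 10-mer oracle", {
  wm <- build_pwm(generate_training_set(30, 0.05, seed = 516))
  half <- (wm$weights[, 1:10] + wm$weights[, 11:20]) / 2
  # canonical decamer: maximal averaged-half score at its own offset
  set.seed(517)
  seq <- paste0(random_seq(50), "GGGCATGCCC", random_seq(40))
  hmax <- sum(apply(half, 2, max))
  hits <- find_halfsites(seq, wm, half_threshold = 0.95 * hmax)
  expect_true(50 %in% hits$start)
  expect_equal(nrow(find_halfsites(strrep("T", 200), wm, 0)), 0L)

  thr <- 0.5 * hmax
  got <- find_halfsites(seq, wm, thr)
  want <- list()
  for (pos in 0:(nchar(seq) - 10)) {
    for (strand in c("+", "-")) {
      w <- substr(seq, pos + 1, pos + 10)
      if (strand == "-") w <- oracle_revcomp(w)
      chars <- strsplit(w, "", fixed = TRUE)[[1]]
      sc <- sum(half[cbind(chars, 1:10)])
      if (sc > thr) want[[length(want) + 1]] <-
          data.frame(start = pos, strand = strand, score = sc)
    }
  }
  want <- do.call(rbind, want)
  want <- want[order(want$start, want$strand), ]
  expect_equal(got$start, want$start)
  expect_equal(got$strand, want$strand)
  expect_equal(got$score, want$score, tolerance = 1e-10)
})
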