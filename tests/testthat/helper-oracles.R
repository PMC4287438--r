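# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's vectorized code paths: everything here works by string
# slicing and explicit loops.

CANON <- "GGGCATGCCCGGGCATGCCC"

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

random_core <- function() random_seq(20)

random_pwm <- function(n_train = 30, rate = 0.15) {
  build_pwm(generate_training_set(n_train, rate))
}

# per-position lookup-and-sum, straight off the weight matrix
oracle_score <- function(wm, core) {
  chars <- strsplit(core, "", fixed = TRUE)[[1]]
  total <- 0
  for (j in seq_along(chars)) {
    if (chars[j] == "N") return(-Inf)
    total <- total + wm$weights[chars[j], j]
  }
  total
}

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(map[strsplit(s, "", fixed = TRUE)[[1]]])), collapse = "")
}

oracle_prefilter_matches <- function(core) {
  sum(substr(core, 4, 4) == "C", substr(core, 7, 7) == "G",
      substr(core, 14, 14) == "C", substr(core, 17, 17) == "G")
}

# exhaustive all-offsets / all-spacers / all-strands scan by slicing
oracle_scan <- function(seq, wm, threshold, selection = "spacer-first") {
  n <- nchar(seq)
  rows <- list()
  for (pos in 0:(n - 20)) {
    cands <- list()
    for (s in 0:3) {
      if (pos + 20 + s > n) next
      window <- substr(seq, pos + 1, pos + 20 + s)
      for (strand in c("+", "-")) {
        w <- if (strand == "+") window else oracle_revcomp(window)
        core <- paste0(substr(w, 1, 10), substr(w, nchar(w) - 9, nchar(w)))
        cm <- oracle_prefilter_matches(core)
        if (cm < 3) next
        sc <- oracle_score(wm, core)
        if (!(sc > threshold)) next
        cands[[length(cands) + 1]] <- data.frame(
          start = pos, spacer = s, strand = strand, score = sc,
          core = core, core_matches = cm, stringsAsFactors = FALSE)
      }
    }
    if (length(cands) == 0) next
    cand <- do.call(rbind, cands)
    key_strand <- match(cand$strand, c("+", "-"))
    ord <- if (selection == "spacer-first") {
      order(cand$spacer, -cand$score, key_strand)
    } else {
      order(-cand$score, cand$spacer, key_strand)
    }
    rows[[length(rows) + 1]] <- cand[ord[1], ]
  }
  if (length(rows) == 0) {
    return(data.frame(start = integer(), spacer = integer(),
                      strand = character(), score = numeric(),
                      core = character(), core_matches = integer()))
  }
  do.call(rbind, rows)
}

# per-base average of a step track over [start, end), NA where uncovered
oracle_track_mean <- function(track, chrom, start, end) {
  vals <- c()
  for (b in start:(end - 1)) {
    hit <- which(track$chrom == chrom & track$start <= b & track$end > b)
    if (length(hit) == 1) vals <- c(vals, track$value[hit])
  }
  if (length(vals) == 0) NA_real_ else mean(vals)
}

# tiny fixture study shared by annotation/pipeline tests
small_sim <- function(seed = 11, n_res = 120, ...) {
  generate_study(simulation_config(seed = seed, n_chroms = 2L,
                                   chrom_length = 60000L,
                                   n_res = as.integer(n_res), ...),
                 outdir = NULL)
}
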