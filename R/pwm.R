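# Position weight matrix construction and scoring for p53RE cores.
#
# A "core" is the 20-nt concatenation of the two decamer half-sites
# (RRRCWWGYYY x2); spacer bases never enter the matrix or the score.

new_p53_freq <- function(counts, n) {
  structure(list(counts = counts, n_sequences = n), class = "p53_freq")
}

#' Tally per-position base frequencies from training p53RE cores
#'
#' @param training Character vector of 20-nt cores over A/C/G/T, or a data
#'   frame with a `core20` column (the training-set TSV schema).
#' @return A `p53_freq` object: a 4 x 20 count matrix (rows A,C,G,T) plus the
#'   number of training sequences. Every column sums to `n_sequences`.
#' @export
#' @examples
#' fm <- build_frequency_matrix(c("GGGCATGCCCGGGCATGCCC", "AGGCATGCCCGGGCATGCCC"))
#' fm$counts[, 1]
build_frequency_matrix <- function(training) {
  if (is.data.frame(training)) {
    if (!"core20" %in% names(training)) {
      abort("training table must have a `core20` column")
    }
    training <- training$core20
  }
  training <- toupper(as.character(training))
  if (length(training) == 0) abort("no training sequences")
  bad_len <- which(nchar(training) != CORE_LEN)
  if (length(bad_len) > 0) {
    abort(paste0("training sequence ", bad_len[1], " has length ",
                 nchar(training)[bad_len[1]], ", expected ", CORE_LEN))
  }
  bad_chr <- which(!grepl("^[ACGT]+$", training))
  if (length(bad_chr) > 0) {
    abort(paste0("training sequence ", bad_chr[1],
                 " contains characters outside A/C/G/T"))
  }
  mat <- do.call(rbind, strsplit(training, "", fixed = TRUE))
  counts <- vapply(seq_len(CORE_LEN), function(j) {
    tabulate(match(mat[, j], DNA_BASES), nbins = 4L)
  }, integer(4))
  dimnames(counts) <- list(base = DNA_BASES, pos = seq_len(CORE_LEN))
  new_p53_freq(counts, length(training))
}

#' Convert a frequency matrix to a log-odds position weight matrix
#'
#' Per-column probabilities are smoothed as
#' `p[b, j] = (counts[b, j] + pseudocount * background[b]) / (n + pseudocount)`
#' (so each column's probabilities sum to 1) and weights are
#' `log2(p[b, j] / background[b])`, in bits.
#'
#' @param fm A `p53_freq` object from [build_frequency_matrix()].
#' @param background Per-base probabilities (A, C, G, T), summing to 1.
#' @param pseudocount Non-negative smoothing mass distributed by background.
#'   With `pseudocount = 0` every count must be positive.
#' @param source Free-text provenance tag stored on the matrix.
#' @return A `p53_pwm` object holding the 4 x 20 weight matrix, the
#'   background, the pseudocount and the source tag.
#' @export
frequency_to_weight <- function(fm, background = rep(0.25, 4), pseudocount = 1,
                                source = "training") {
  stopifnot(inherits(fm, "p53_freq"))
  background <- unname(background)
  if (length(background) != 4 || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-9) {
    abort("background must be 4 positive probabilities summing to 1")
  }
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount < 0) {
    abort("pseudocount must be a single non-negative number")
  }
  if (pseudocount == 0 && any(fm$counts == 0)) {
    abort("log of zero: zero count with zero pseudocount")
  }
  p <- (fm$counts + pseudocount * background) / (fm$n_sequences + pseudocount)
  weights <- log2(p / background)
  dimnames(weights) <- dimnames(fm$counts)
  structure(
    list(weights = weights, background = setNames(background, DNA_BASES),
         pseudocount = pseudocount, source = source),
    class = "p53_pwm")
}

#' Build a PWM directly from training cores
#'
#' Convenience wrapper chaining [build_frequency_matrix()] and
#' [frequency_to_weight()].
#'
#' @inheritParams build_frequency_matrix
#' @inheritParams frequency_to_weight
#' @return A `p53_pwm` object.
#' @export
build_pwm <- function(training, background = rep(0.25, 4), pseudocount = 1,
                      source = "training") {
  frequency_to_weight(build_frequency_matrix(training),
                      background = background, pseudocount = pseudocount,
                      source = source)
}

#' Score 20-nt cores against a PWM
#'
#' The score of a core is the sum over positions of the weight of the observed
#' base (bits). A core containing `N` scores `-Inf`: unassembled sequence can
#' never be a confident response element.
#'
#' @param wm A `p53_pwm` object.
#' @param cores Character vector of 20-nt cores over A/C/G/T/N.
#' @return Numeric vector of scores, one per core.
#' @export
score_core <- function(wm, cores) {
  stopifnot(inherits(wm, "p53_pwm"))
  cores <- toupper(as.character(cores))
  if (any(nchar(cores) != CORE_LEN)) {
    abort(paste0("all cores must have length ", CORE_LEN))
  }
  w5 <- rbind(wm$weights, N = -Inf)
  vapply(cores, function(core) {
    idx <- base_index(strsplit(core, "", fixed = TRUE)[[1]])
    sum(w5[cbind(idx, seq_len(CORE_LEN))])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Maximum achievable PWM score
#'
#' @param wm A `p53_pwm` object.
#' @return Sum of the per-column maxima (bits).
#' @export
max_score <- function(wm) {
  stopifnot(inherits(wm, "p53_pwm"))
  sum(apply(wm$weights, 2, max))
}

#' Highest-scoring core of a PWM
#'
#' Per-column argmax; ties broken alphabetically (A < C < G < T).
#'
#' @param wm A `p53_pwm` object.
#' @return A single 20-character string.
#' @export
consensus_core <- function(wm) {
  stopifnot(inherits(wm, "p53_pwm"))
  paste(DNA_BASES[apply(wm$weights, 2, which.max)], collapse = "")
}

#' @export
print.p53_pwm <- function(x, ...) {
  cat("<p53_pwm> 4 x 20 log-odds matrix (bits)\n")
  cat("  source:      ", x$source, "\n")
  cat("  background:  ", paste(sprintf("%s=%.3g", DNA_BASES, x$background),
                               collapse = " "), "\n")
  cat("  pseudocount: ", x$pseudocount, "\n")
  cat("  max score:   ", sprintf("%.3f", max_score(x)), "\n")
  cat("  consensus:   ", consensus_core(x), "\n")
  invisible(x)
}

#' @export
print.p53_freq <- function(x, ...) {
  cat("<p53_freq> 4 x 20 count matrix over", x$n_sequences, "sequences\n")
  invisible(x)
}

#' Tidy a PWM into a long tibble
#'
#' @param x A `p53_pwm` object.
#' @param ... Unused.
#' @return A tibble with columns `position`, `base`, `weight`.
#' @exportS3Method generics::tidy
tidy.p53_pwm <- function(x, ...) {
  tibble(
    position = rep(seq_len(CORE_LEN), each = 4L),
    base = rep(DNA_BASES, CORE_LEN),
    weight = as.vector(x$weights))
}

#' Write a PWM to a TSV file
#'
#' 20 data rows with columns `pos`, `A`, `C`, `G`, `T`, preceded by
#' `#background=` , `#pseudocount=` and `#source=` header lines.
#'
#' @param wm A `p53_pwm` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(wm, path) {
  stopifnot(inherits(wm, "p53_pwm"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#background=", paste(format(wm$background, digits = 17),
                                 collapse = ",")),
    paste0("#pseudocount=", format(wm$pseudocount, digits = 17)),
    paste0("#source=", wm$source),
    paste(c("pos", DNA_BASES), collapse = "\t")), con)
  for (j in seq_len(CORE_LEN)) {
    writeLines(paste(c(j, format(wm$weights[, j], digits = 17)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a PWM written by [write_pwm()]
#'
#' @param path Path to a PWM TSV file.
#' @return A `p53_pwm` object; round-trips with the writer to 1e-12.
#' @export
load_weight_matrix <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta <- lines[is_meta]
  body <- lines[!is_meta & nzchar(lines)]
  get_meta <- function(key) {
    hit <- meta[startsWith(meta, paste0("#", key, "="))]
    if (length(hit) != 1) abort(paste0("PWM file missing #", key, "= header"))
    sub(paste0("^#", key, "="), "", hit)
  }
  background <- as.numeric(strsplit(get_meta("background"), ",")[[1]])
  pseudocount <- as.numeric(get_meta("pseudocount"))
  source <- get_meta("source")
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, c("pos", DNA_BASES))) {
    abort(paste0("line ", which(!is_meta)[1],
                 ": expected header 'pos\\tA\\tC\\tG\\tT'"))
  }
  rows <- body[-1]
  if (length(rows) != CORE_LEN) {
    abort(paste0("expected ", CORE_LEN, " data rows, found ", length(rows)))
  }
  weights <- matrix(NA_real_, 4, CORE_LEN,
                    dimnames = list(base = DNA_BASES, pos = seq_len(CORE_LEN)))
  body_line_no <- which(!is_meta)[-1]
  for (i in seq_along(rows)) {
    f <- strsplit(rows[i], "\t", fixed = TRUE)[[1]]
    vals <- suppressWarnings(as.numeric(f))
    if (length(f) != 5 || anyNA(vals)) {
      abort(paste0("line ", body_line_no[i], ": malformed PWM row"))
    }
    if (vals[1] != i) {
      abort(paste0("line ", body_line_no[i], ": expected pos ", i))
    }
    weights[, i] <- vals[-1]
  }
  structure(
    list(weights = weights, background = setNames(background, DNA_BASES),
         pseudocount = pseudocount, source = source),
    class = "p53_pwm")
}
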