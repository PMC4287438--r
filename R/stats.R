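# Stratified summaries: deciles, group-mean regressions, fold-change
# classes, enrichment ratios, trend and TE-family enrichment tests.

#' log2(x + 1) transform
#'
#' The standard transform applied to DHS signal before decile averaging.
#'
#' @param x Non-negative numeric vector.
#' @return `log2(x + 1)`.
#' @export
log2p1 <- function(x) {
  if (any(x < 0, na.rm = TRUE)) abort("log2p1 requires non-negative input")
  log2(x + 1)
}

#' Classify genes by expression fold change
#'
#' Three-way partition into `up` (`fold_change > up_fc`), `down`
#' (`fold_change < down_fc`) and `unchanged`. Boundary values are
#' `unchanged` (strict inequalities).
#'
#' @param genes Tibble with a `fold_change` column (linear-scale
#'   treated/untreated ratio).
#' @param up_fc,down_fc Thresholds; defaults 1.2 and 0.8.
#' @return `genes` with an added `class` factor column
#'   (`up`/`down`/`unchanged`).
#' @export
classify_fold_change <- function(genes, up_fc = 1.2, down_fc = 0.8) {
  stopifnot("fold_change" %in% names(genes))
  if (any(genes$fold_change <= 0, na.rm = TRUE)) {
    abort("fold changes must be positive")
  }
  cls <- dplyr::case_when(
    genes$fold_change > up_fc ~ "up",
    genes$fold_change < down_fc ~ "down",
    TRUE ~ "unchanged")
  mutate(genes, class = factor(cls, levels = c("down", "unchanged", "up")))
}

#' Assign values to deciles D1 (weakest) .. D10 (strongest)
#'
#' Values are stably sorted (ties keep input order) and split into 10
#' contiguous groups whose sizes differ by at most one; when `n` is not a
#' multiple of 10 the earlier deciles take the extra members.
#'
#' @param values Numeric vector, length >= 10.
#' @return Ordered factor of labels `D1`..`D10`, parallel to `values`.
#' @export
decile_assign <- function(values) {
  n <- length(values)
  if (n < 10) abort("need at least 10 values for deciles")
  sizes <- rep(n %/% 10L, 10L)
  extra <- n %% 10L
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  labels <- paste0("D", 1:10)
  lab_sorted <- rep(labels, times = sizes)
  out <- character(n)
  out[order(values)] <- lab_sorted   # order() is stable for ties
  factor(out, levels = labels, ordered = TRUE)
}

#' Decile table of annotated elements
#'
#' Orders records by `order_by` (default the PWM score of the best element),
#' assigns deciles, and reports per-decile counts, means of the requested
#' metrics, and the spacer-length frequency distribution. DHS is transformed
#' `log2(x + 1)` before averaging when a `dhs_nt` column is present.
#'
#' @param annotated Tibble from [annotate_peaks()] (rows without a best
#'   element are dropped first).
#' @param order_by Column name used for the decile ordering.
#' @param metrics Character vector of columns to average per decile; only
#'   those present are used.
#' @return A `p53_decile_table`: a tibble with one row per decile, columns
#'   `decile`, `n`, `mean_<metric>` and `spacer_freq_0`..`spacer_freq_3`.
#' @export
decile_table <- function(annotated, order_by = "re_score",
                         metrics = c("re_score", "density", "dhs_log2p1",
                                     "tss_distance_kb", "mean_phylop",
                                     "pct_identity_mouse")) {
  d <- filter(annotated, !is.na(.data[[order_by]]))
  if ("dhs_nt" %in% names(d)) d$dhs_log2p1 <- log2p1(d$dhs_nt)
  if ("tss_distance" %in% names(d)) d$tss_distance_kb <- d$tss_distance / 1000
  metrics <- intersect(metrics, names(d))
  d$decile <- decile_assign(d[[order_by]])
  base <- d |>
    group_by(.data$decile) |>
    summarise(n = dplyr::n(),
              across(all_of(metrics), ~ mean(.x, na.rm = TRUE),
                     .names = "mean_{.col}"),
              .groups = "drop")
  if ("re_spacer" %in% names(d)) {
    sp <- d |>
      group_by(.data$decile) |>
      summarise(
        spacer_freq_0 = mean(.data$re_spacer == 0, na.rm = TRUE),
        spacer_freq_1 = mean(.data$re_spacer == 1, na.rm = TRUE),
        spacer_freq_2 = mean(.data$re_spacer == 2, na.rm = TRUE),
        spacer_freq_3 = mean(.data$re_spacer == 3, na.rm = TRUE),
        .groups = "drop")
    base <- left_join(base, sp, by = "decile")
  }
  structure(base, class = c("p53_decile_table", class(base)),
            order_by = order_by)
}

#' Ordinary least squares on group means
#'
#' The regression the figure-level analyses use: one point per group (decile
#' or chromatin state), `y` mean regressed on `x` mean. `r_squared` is the
#' squared Pearson correlation of the means.
#'
#' @param group_means_x,group_means_y Numeric vectors of equal length >= 3.
#' @return A `p53_reg` object with fields `slope`, `intercept`, `r_squared`,
#'   `n_points`, `p_value` (slope t-test) and the underlying `lm` fit.
#'   Supports [tidy()] and [glance()].
#' @export
group_mean_regression <- function(group_means_x, group_means_y) {
  x <- as.numeric(group_means_x)
  y <- as.numeric(group_means_y)
  if (length(x) != length(y) || length(x) < 3) {
    abort("need equal-length x and y with at least 3 points")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("group means must be finite")
  }
  if (sd(x) == 0) abort("degenerate regressor: zero x-variance")
  fit <- lm(y ~ x)
  r2 <- if (sd(y) == 0) 0 else stats::cor(x, y)^2
  # a perfect fit makes the t-test degenerate; report p = 0 silently
  p <- suppressWarnings(summary(fit)$coefficients["x", "Pr(>|t|)"])
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = r2, n_points = length(x), p_value = unname(p),
         fit = fit),
    class = "p53_reg")
}

#' @export
print.p53_reg <- function(x, ...) {
  cat(sprintf(
    "<p53_reg> slope %.4g, intercept %.4g, r^2 = %.3f (n = %d, p = %.3g)\n",
    x$slope, x$intercept, x$r_squared, x$n_points, x$p_value))
  invisible(x)
}

#' @rdname group_mean_regression
#' @param x A `p53_reg` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.p53_reg <- function(x, ...) {
  tibble(term = c("(Intercept)", "x"),
         estimate = c(x$intercept, x$slope))
}

#' @rdname group_mean_regression
#' @exportS3Method generics::glance
glance.p53_reg <- function(x, ...) {
  tibble(r.squared = x$r_squared, slope = x$slope, p.value = x$p_value,
         nobs = x$n_points)
}

#' Enrichment ratio of a feature between gene classes
#'
#' Frequency of a mark among up-regulated genes divided by its frequency
#' among down-regulated genes.
#'
#' @param freq_up,freq_down Proportions in `[0, 1]`.
#' @return `freq_up / freq_down`.
#' @export
enrichment_ratio <- function(freq_up, freq_down) {
  stopifnot(freq_up >= 0, freq_up <= 1, freq_down >= 0, freq_down <= 1)
  if (freq_down == 0) abort("undefined ratio: zero frequency in down class")
  freq_up / freq_down
}

#' Cochran-Armitage trend test over ordered categories
#'
#' Tests for a linear trend in the success proportion across `k` ordered
#' categories (e.g. repressive-mark frequency across H3K4me3 quintiles),
#' with integer scores `1..k` and a two-sided normal-approximation p-value.
#'
#' @param counts A 2 x k matrix: row 1 successes, row 2 failures, ordered
#'   columns.
#' @return A tibble with `statistic` (signed z: positive means the
#'   proportion increases with the category score) and `p_value`.
#' @export
trend_test <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2 || ncol(counts) < 3) {
    abort("counts must be a 2 x k matrix with k >= 3")
  }
  if (any(counts < 0) || any(colSums(counts) == 0) ||
      all(counts[1, ] == 0) || all(counts[2, ] == 0)) {
    abort("counts must be non-negative with non-degenerate margins")
  }
  k <- ncol(counts)
  tt <- suppressWarnings(
    prop.trend.test(counts[1, ], colSums(counts), score = seq_len(k)))
  # sign from the score-weighted deviation of successes from expectation
  expctd <- sum(counts[1, ]) * colSums(counts) / sum(counts)
  z <- sqrt(unname(tt$statistic)) * sign(sum(seq_len(k) *
                                               (counts[1, ] - expctd)))
  tibble(statistic = z, p_value = unname(tt$p.value))
}

#' Transposable-element family enrichment among response elements
#'
#' Fold enrichment of each family among elements relative to its genomic
#' base fraction, with a one-sided binomial test (count successes in `n_res`
#' trials at probability = genome fraction) and Benjamini-Hochberg
#' correction across families.
#'
#' @param re_family_counts Named integer vector (or tibble with `family`,
#'   `count`): elements assigned to each family.
#' @param genome_family_fractions Named numeric vector of genomic base
#'   fractions per family.
#' @param n_res Total number of response elements.
#' @return A tibble `family`, `count`, `genome_fraction`, `fold`, `p_value`,
#'   `q_value`, sorted by `q_value`.
#' @export
te_family_enrichment <- function(re_family_counts, genome_family_fractions,
                                 n_res) {
  if (is.data.frame(re_family_counts)) {
    re_family_counts <- setNames(re_family_counts$count,
                                 re_family_counts$family)
  }
  fams <- names(re_family_counts)
  frac <- genome_family_fractions[fams]
  if (anyNA(frac)) {
    missing_f <- fams[is.na(frac)]
    if (any(re_family_counts[missing_f] > 0)) {
      abort(paste0("background missing family: ",
                   paste(missing_f[re_family_counts[missing_f] > 0],
                         collapse = ", ")))
    }
    frac[is.na(frac)] <- 0
  }
  counts <- as.integer(re_family_counts)
  if (any(counts > n_res)) abort("family count exceeds n_res")
  fold <- ifelse(frac > 0, (counts / n_res) / frac, ifelse(counts > 0, NA, 0))
  p <- vapply(seq_along(fams), function(i) {
    if (frac[i] <= 0) return(1)
    binom.test(counts[i], n_res, p = frac[i],
               alternative = "greater")$p.value
  }, numeric(1))
  tibble(family = fams, count = counts,
         genome_fraction = unname(frac), fold = unname(fold),
         p_value = p, q_value = p.adjust(p, method = "BH")) |>
    arrange(.data$q_value, .data$family)
}

#' Per-state means, SEMs and pairwise comparisons
#'
#' For each chromatin state: `n`, mean and standard error of the mean for
#' each requested metric. Requested state pairs are compared with Welch
#' two-sample t-tests, Benjamini-Hochberg-corrected per metric across pairs.
#'
#' @param annotated Tibble with a state column and metric columns.
#' @param metrics Character vector of metric column names.
#' @param state_col Name of the state column (default `"state7"`).
#' @param pairs Optional list of length-2 character vectors of state labels
#'   to compare; `NULL` compares all pairs present.
#' @return A list with `summary` (one row per state x metric: `state`,
#'   `metric`, `n`, `mean`, `sem`) and `tests` (one row per pair x metric:
#'   `state_a`, `state_b`, `metric`, `statistic`, `p_value`, `q_value`).
#'   States with `n < 2` get `NA` SEM and are skipped in tests.
#' @export
group_summaries_by_state <- function(annotated, metrics,
                                     state_col = "state7", pairs = NULL) {
  stopifnot(state_col %in% names(annotated))
  d <- filter(annotated, !is.na(.data[[state_col]]),
              .data[[state_col]] != "excluded")
  summary <- purrr::map_dfr(metrics, function(m) {
    d |>
      group_by(state = .data[[state_col]]) |>
      summarise(metric = m,
                n = sum(!is.na(.data[[m]])),
                mean = mean(.data[[m]], na.rm = TRUE),
                sem = ifelse(sum(!is.na(.data[[m]])) >= 2,
                             sd(.data[[m]], na.rm = TRUE) /
                               sqrt(sum(!is.na(.data[[m]]))), NA_real_),
                .groups = "drop")
  })
  states <- unique(d[[state_col]])
  if (is.null(pairs)) {
    pairs <- utils::combn(sort(states), 2, simplify = FALSE)
  }
  tests <- purrr::map_dfr(metrics, function(m) {
    purrr::map_dfr(pairs, function(pr) {
      a <- d[[m]][d[[state_col]] == pr[1]]
      b <- d[[m]][d[[state_col]] == pr[2]]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) < 2 || length(b) < 2) {
        return(tibble(state_a = pr[1], state_b = pr[2], metric = m,
                      statistic = NA_real_, p_value = NA_real_))
      }
      tt <- tryCatch(t.test(a, b), error = function(e) NULL)
      if (is.null(tt)) {   # e.g. both groups essentially constant
        return(tibble(state_a = pr[1], state_b = pr[2], metric = m,
                      statistic = NA_real_, p_value = NA_real_))
      }
      tibble(state_a = pr[1], state_b = pr[2], metric = m,
             statistic = unname(tt$statistic), p_value = tt$p.value)
    })
  })
  tests <- tests |>
    group_by(.data$metric) |>
    mutate(q_value = p.adjust(.data$p_value, method = "BH")) |>
    ungroup()
  list(summary = summary, tests = tests)
}
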