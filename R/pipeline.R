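# Pipeline driver: build-pwm -> scan -> annotate -> summarize, with a run
# manifest recording per-stage record counts so bookkeeping ratios (e.g.
# the fraction of peaks with a canonical element) are first-class outputs.

#' Genomic base fraction of each repeat family
#'
#' @param repeats Tibble `chrom`, `start`, `end`, `family`.
#' @param genome_bp Total genome size in bp.
#' @return Named numeric vector of per-family base fractions.
#' @export
repeat_genome_fractions <- function(repeats, genome_bp) {
  agg <- repeats |>
    group_by(.data$family) |>
    summarise(bp = sum(.data$end - .data$start), .groups = "drop")
  setNames(agg$bp / genome_bp, agg$family)
}

#' Decile and state-stratified summaries of an annotated peak table
#'
#' Reproduces the figure-level statistics: the PWM-score decile table
#' (density, DHS, conservation, TSS distance, spacer frequencies), the
#' group-mean regressions of decile-mean density on decile-mean PWM score,
#' log2(DHS + 1) and PhyloP, per-state summaries with Welch pairwise tests,
#' and TE-family enrichment against genomic base fractions.
#'
#' @param annotated Output of [annotate_peaks()].
#' @param repeats Optional repeat catalogue (for family enrichment).
#' @param genome_bp Genome size in bp (required with `repeats`).
#' @return A `p53_summary` list: `deciles`, `regressions` (tibble with one
#'   row per regression: `response`, `predictor`, `slope`, `intercept`,
#'   `r_squared`, `p_value`), `reg_objects`, `state_summary`, `state_tests`,
#'   `te_enrichment` (or `NULL`), and `counts`.
#' @export
summarize_study <- function(annotated, repeats = NULL, genome_bp = NULL) {
  dec <- decile_table(annotated)
  regs <- list()
  if (all(c("mean_re_score", "mean_density") %in% names(dec))) {
    regs$density_vs_pwm <- group_mean_regression(dec$mean_re_score,
                                                 dec$mean_density)
  }
  if (all(c("mean_dhs_log2p1", "mean_density") %in% names(dec))) {
    regs$density_vs_dhs <- group_mean_regression(dec$mean_dhs_log2p1,
                                                 dec$mean_density)
  }
  if (all(c("mean_mean_phylop", "mean_density") %in% names(dec))) {
    regs$density_vs_phylop <- group_mean_regression(dec$mean_mean_phylop,
                                                    dec$mean_density)
  }
  reg_tbl <- purrr::imap_dfr(regs, function(r, nm) {
    tibble(response = "density",
           predictor = sub("^density_vs_", "", nm),
           slope = r$slope, intercept = r$intercept,
           r_squared = r$r_squared, p_value = r$p_value)
  })
  state_metrics <- intersect(c("density", "re_score", "mean_phylop",
                               "re_spacer"), names(annotated))
  st <- group_summaries_by_state(annotated, state_metrics)
  te_enr <- NULL
  if (!is.null(repeats) && "te_family" %in% names(annotated)) {
    if (is.null(genome_bp)) abort("genome_bp required with repeats")
    with_re <- filter(annotated, !is.na(.data$re_start))
    fam_counts <- table(factor(with_re$te_family,
                               levels = unique(repeats$family)))
    te_enr <- te_family_enrichment(
      setNames(as.integer(fam_counts), names(fam_counts)),
      repeat_genome_fractions(repeats, genome_bp),
      n_res = nrow(with_re))
  }
  counts <- c(peaks = nrow(annotated),
              peaks_with_re = sum(!is.na(annotated$re_start)),
              te_overlap = if ("te_family" %in% names(annotated)) {
                sum(!is.na(annotated$te_family))
              } else NA_integer_)
  structure(list(deciles = dec, regressions = reg_tbl, reg_objects = regs,
                 state_summary = st$summary, state_tests = st$tests,
                 te_enrichment = te_enr, counts = counts),
            class = "p53_summary")
}

#' @export
print.p53_summary <- function(x, ...) {
  cat("<p53_summary>\n")
  cat(sprintf("  peaks: %d; with canonical RE: %d (%.1f%%)\n",
              x$counts["peaks"], x$counts["peaks_with_re"],
              100 * x$counts["peaks_with_re"] / x$counts["peaks"]))
  if (!is.na(x$counts["te_overlap"])) {
    cat(sprintf("  TE overlap: %d (%.1f%%)\n", x$counts["te_overlap"],
                100 * x$counts["te_overlap"] / x$counts["peaks"]))
  }
  if (nrow(x$regressions) > 0) {
    cat("  decile-mean regressions:\n")
    for (i in seq_len(nrow(x$regressions))) {
      cat(sprintf("    density ~ %-10s slope %8.3f  r^2 %.3f\n",
                  x$regressions$predictor[i], x$regressions$slope[i],
                  x$regressions$r_squared[i]))
    }
  }
  invisible(x)
}

#' Pipeline configuration
#'
#' @param genome,training,peaks,chromhmm7,chromhmm15,repeats,dhs,phylop,
#'   genes,expression Input file paths (`chromhmm15`, `repeats`, `dhs`,
#'   `phylop`, `genes`, `expression` may be `NULL`).
#' @param threshold_frac Scanner threshold as a fraction of the maximum
#'   achievable PWM score.
#' @param selection Scanner tie rule (`"spacer-first"` or `"score-first"`).
#' @param tss_halfwidth Window half-width for TSS-level signal (bp).
#' @param min_te_overlap_frac Minimum repeat overlap fraction.
#' @param up_fc,down_fc Fold-change class thresholds.
#' @param seed Seed recorded in the manifest.
#' @return A `p53_pipeline_config` list.
#' @export
pipeline_config <- function(genome, training, peaks, chromhmm7,
                            chromhmm15 = NULL, repeats = NULL, dhs = NULL,
                            phylop = NULL, genes = NULL, expression = NULL,
                            threshold_frac = 0.8,
                            selection = "spacer-first",
                            tss_halfwidth = 1000L,
                            min_te_overlap_frac = 0,
                            up_fc = 1.2, down_fc = 0.8, seed = 1L) {
  structure(
    list(paths = list(genome = genome, training = training, peaks = peaks,
                      chromhmm7 = chromhmm7, chromhmm15 = chromhmm15,
                      repeats = repeats, dhs = dhs, phylop = phylop,
                      genes = genes, expression = expression),
         threshold_frac = threshold_frac, selection = selection,
         tss_halfwidth = as.integer(tss_halfwidth),
         min_te_overlap_frac = min_te_overlap_frac,
         up_fc = up_fc, down_fc = down_fc, seed = as.integer(seed)),
    class = "p53_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file holds the [pipeline_config()] arguments; relative input
#' paths are resolved against the YAML file's directory.
#'
#' @param path Path to a YAML file.
#' @return A `p53_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  path_args <- intersect(names(y), c("genome", "training", "peaks",
                                     "chromhmm7", "chromhmm15", "repeats",
                                     "dhs", "phylop", "genes", "expression"))
  for (a in path_args) {
    if (!is.null(y[[a]]) && !grepl("^/", y[[a]])) {
      y[[a]] <- file.path(dirname(path), y[[a]])
    }
  }
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Stages: load inputs, build the PWM from the training set, scan the
#' genome, assign the best element per peak, annotate with chromatin
#' state/genes/signals/repeats, summarize. Outputs (`res.bed`,
#' `annotated.tsv`, `decile_table.tsv`, `state_summary.tsv`,
#' `regressions.tsv`, `te_enrichment.tsv`, `manifest.yaml`) are written to
#' `outdir` when given.
#'
#' @param config A `p53_pipeline_config` (or a path to a YAML config).
#' @param outdir Optional output directory.
#' @return A list with `pwm`, `res`, `annotated`, `genes`, `summary` and
#'   `manifest`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "p53_pipeline_config"))
  p <- config$paths
  needed <- p[!vapply(p, is.null, logical(1))]
  missing_f <- needed[!vapply(needed, file.exists, logical(1))]
  if (length(missing_f) > 0) {
    abort(paste0("missing input file(s): ",
                 paste(unlist(missing_f), collapse = ", ")))
  }

  genome <- read_fasta(p$genome)
  training <- read_tsv_table(p$training, required = "core20")
  peaks <- read_peaks(p$peaks)
  seg7 <- read_segmentation(p$chromhmm7, "hmm7")
  seg15 <- if (!is.null(p$chromhmm15)) {
    read_segmentation(p$chromhmm15, "hmm15")
  }
  repeats <- if (!is.null(p$repeats)) {
    read_bed(p$repeats) |> dplyr::rename(family = "name")
  }
  dhs <- if (!is.null(p$dhs)) read_bedgraph(p$dhs)
  phylop <- if (!is.null(p$phylop)) read_bedgraph(p$phylop)
  genes <- if (!is.null(p$genes)) read_genes(p$genes, p$expression)

  wm <- build_pwm(training, source = paste0("training:", basename(p$training)))
  res <- scan_sequence(genome, wm, threshold_frac = config$threshold_frac,
                       selection = config$selection)
  annotated <- annotate_peaks(peaks, res, seg7, seg15, genes = genes,
                              phylop = phylop, dhs = dhs, repeats = repeats)
  summary <- summarize_study(annotated, repeats = repeats,
                             genome_bp = sum(nchar(genome)))

  manifest <- list(
    seed = config$seed,
    config_hash = rlang::hash(config),
    threshold = config$threshold_frac * max_score(wm),
    stages = list(
      build_pwm = list(training_sequences = nrow(training)),
      scan = list(elements_found = nrow(res)),
      annotate = list(peaks_in = nrow(peaks),
                      peaks_with_re = unname(summary$counts["peaks_with_re"]),
                      peaks_with_te = unname(summary$counts["te_overlap"])),
      summarize = list(deciles = nrow(summary$deciles))))

  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    write_bed(res |>
                select("chrom", "start", "end") |>
                mutate(name = sprintf("re%05d", dplyr::row_number()),
                       score = res$score, strand = res$strand,
                       spacer = res$spacer, core20 = res$core,
                       core_matches = res$core_matches),
              file.path(outdir, "res.bed"))
    readr::write_tsv(annotated, file.path(outdir, "annotated.tsv"))
    readr::write_tsv(summary$deciles, file.path(outdir, "decile_table.tsv"))
    readr::write_tsv(summary$state_summary,
                     file.path(outdir, "state_summary.tsv"))
    readr::write_tsv(summary$regressions,
                     file.path(outdir, "regressions.tsv"))
    if (!is.null(summary$te_enrichment)) {
      readr::write_tsv(summary$te_enrichment,
                       file.path(outdir, "te_enrichment.tsv"))
    }
    yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  }
  list(pwm = wm, res = res, annotated = annotated, genes = genes,
       summary = summary, manifest = manifest)
}
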