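# Chromatin-context annotation of peaks and response elements.
#
# Segmentations, signal tracks, gene tables and repeat catalogues all arrive
# as tibbles (0-based half-open intervals); overlap queries run through
# IRanges behind this surface.

interval_overlaps <- function(q_chrom, q_start, q_end, s_chrom, s_start, s_end) {
  # findOverlaps on a per-genome basis; returns a tibble (q_idx, s_idx, width)
  q <- split(seq_along(q_chrom), q_chrom)
  s <- split(seq_along(s_chrom), s_chrom)
  hits <- list()
  for (chrom in intersect(names(q), names(s))) {
    qi <- q[[chrom]]; si <- s[[chrom]]
    qr <- IRanges::IRanges(start = q_start[qi] + 1L, end = q_end[qi])
    sr <- IRanges::IRanges(start = s_start[si] + 1L, end = s_end[si])
    ov <- IRanges::findOverlaps(qr, sr)
    if (length(ov) == 0) next
    qh <- qi[S4Vectors::queryHits(ov)]
    sh <- si[S4Vectors::subjectHits(ov)]
    width <- pmin(q_end[qh], s_end[sh]) - pmax(q_start[qh], s_start[sh])
    hits[[chrom]] <- tibble(q_idx = qh, s_idx = sh, width = width)
  }
  if (length(hits) == 0) {
    return(tibble(q_idx = integer(), s_idx = integer(), width = integer()))
  }
  bind_rows(hits)
}

#' Chromatin state at genomic positions
#'
#' Looks up the 7-state segmentation at each position; where the 7-state
#' model made no call, the 15-state label is collapsed through
#' [chromhmm15_collapse()]. 15-state labels 14/15 (repetitive) map to the
#' `"excluded"` sentinel; positions covered by neither model return `NA`
#' ("uncalled").
#'
#' @param seg7 Tibble `chrom`, `start`, `end`, `state` with 7-state labels.
#' @param seg15 Tibble `chrom`, `start`, `end`, `state` with labels
#'   `"1"`..`"15"`. May be `NULL` if no fallback is available.
#' @param chrom,position Vectors of query chromosomes and 0-based positions.
#' @param collapse Named character vector mapping 15-state to 7-state labels;
#'   override to emulate a different combined-model dialect.
#' @return Character vector: a 7-state label, `"excluded"`, or `NA`.
#' @export
assign_state <- function(seg7, seg15, chrom, position,
                         collapse = chromhmm15_collapse()) {
  known <- unique(c(seg7$chrom, if (!is.null(seg15)) seg15$chrom))
  if (!all(chrom %in% known)) {
    abort(paste0("position on unknown chromosome: ",
                 paste(unique(setdiff(chrom, known)), collapse = ", ")))
  }
  out <- rep(NA_character_, length(position))
  ov7 <- interval_overlaps(chrom, position, position + 1L,
                           seg7$chrom, seg7$start, seg7$end)
  out[ov7$q_idx] <- seg7$state[ov7$s_idx]
  if (!is.null(seg15)) {
    miss <- which(is.na(out))
    if (length(miss) > 0) {
      ov15 <- interval_overlaps(chrom[miss], position[miss],
                                position[miss] + 1L,
                                seg15$chrom, seg15$start, seg15$end)
      out[miss[ov15$q_idx]] <- unname(collapse[seg15$state[ov15$s_idx]])
    }
  }
  out
}

#' Nearest gene (by TSS) for each peak summit
#'
#' @param peaks Tibble with `chrom` and `summit` columns.
#' @param genes Tibble with `gene_id`, `chrom`, `tss` columns (plus any
#'   others, ignored here).
#' @return `peaks` with added `gene_id` and `tss_distance` (unsigned bp;
#'   ties broken by the lower TSS coordinate). Peaks on chromosomes with no
#'   gene get `NA`.
#' @export
nearest_gene <- function(peaks, genes) {
  gene_id <- rep(NA_character_, nrow(peaks))
  tss_distance <- rep(NA_real_, nrow(peaks))
  by_chrom <- split(seq_len(nrow(genes)), genes$chrom)
  for (i in seq_len(nrow(peaks))) {
    gi <- by_chrom[[peaks$chrom[i]]]
    if (is.null(gi)) next
    d <- abs(peaks$summit[i] - genes$tss[gi])
    ord <- order(d, genes$tss[gi])
    gene_id[i] <- genes$gene_id[gi[ord[1]]]
    tss_distance[i] <- d[ord[1]]
  }
  dplyr::bind_cols(peaks, tibble(gene_id = gene_id,
                                 tss_distance = tss_distance))
}

# base-weighted mean of a step track over a set of (chrom,start,end)
# intervals grouped by an element id; uncovered bases are excluded
track_mean_over <- function(track, chrom, start, end, id) {
  ov <- interval_overlaps(chrom, start, end, track$chrom, track$start,
                          track$end)
  out <- rep(NA_real_, max(id))
  if (nrow(ov) > 0) {
    agg <- tibble(id = id[ov$q_idx], w = ov$width,
                  v = track$value[ov$s_idx]) |>
      group_by(.data$id) |>
      summarise(mean = sum(.data$w * .data$v) / sum(.data$w))
    out[agg$id] <- agg$mean
  }
  out
}

#' Mean signal over the 20 core bases of each response element
#'
#' Averages a step track (e.g. PhyloP) base-by-base over the two 10-nt
#' half-sites of each element; spacer bases are excluded, uncovered bases are
#' excluded from the mean, and an element with no covered core base returns
#' `NA`.
#'
#' @param track Tibble `chrom`, `start`, `end`, `value` (sorted,
#'   non-overlapping; a bedGraph).
#' @param res Tibble of response elements ([scan_sequence()] output).
#' @return Numeric vector, one mean per element.
#' @export
mean_signal_over_re <- function(track, res) {
  n <- nrow(res)
  if (n == 0) return(numeric(0))
  # two half-site intervals per element, same element id
  chrom <- rep(res$chrom, 2L)
  start <- c(res$start, res$start + HALF_LEN + res$spacer)
  end <- c(res$start + HALF_LEN, res$end)
  track_mean_over(track, chrom, start, end, rep(seq_len(n), 2L))
}

#' Mean signal in a window around each TSS
#'
#' @param track Tibble `chrom`, `start`, `end`, `value`.
#' @param genes Tibble with `chrom` and `tss` columns.
#' @param halfwidth Window half-width in bp (default 1000): the window is
#'   `[tss - halfwidth, tss + halfwidth)`.
#' @return Numeric vector of window means (`NA` where the track has no
#'   coverage).
#' @export
signal_at_tss <- function(track, genes, halfwidth = 1000L) {
  stopifnot(halfwidth > 0)
  n <- nrow(genes)
  if (n == 0) return(numeric(0))
  track_mean_over(track, genes$chrom, pmax(genes$tss - halfwidth, 0L),
                  genes$tss + halfwidth, seq_len(n))
}

#' Transposable-element family of each response element
#'
#' Assigns the family of the repeat interval with the largest base overlap
#' with the element footprint (half-sites plus spacer); ties go to the longer
#' repeat, then the lower start. Elements overlapping no repeat get `NA`.
#'
#' @param res Tibble of response elements.
#' @param repeats Tibble `chrom`, `start`, `end`, `family`.
#' @param min_overlap_frac Minimum overlap as a fraction of the element
#'   footprint (default 0: any overlap of >= 1 bp counts).
#' @return Character vector of family labels (or `NA`), one per element.
#' @export
te_assign <- function(res, repeats, min_overlap_frac = 0) {
  n <- nrow(res)
  if (n == 0) return(character(0))
  out <- rep(NA_character_, n)
  ov <- interval_overlaps(res$chrom, res$start, res$end,
                          repeats$chrom, repeats$start, repeats$end)
  if (nrow(ov) > 0) {
    ov <- ov[ov$width >= min_overlap_frac * (res$end - res$start)[ov$q_idx], ,
             drop = FALSE]
    if (nrow(ov) > 0) {
      rep_len <- repeats$end[ov$s_idx] - repeats$start[ov$s_idx]
      ord <- order(ov$q_idx, -ov$width, -rep_len, repeats$start[ov$s_idx])
      ov <- ov[ord, ]
      keep <- !duplicated(ov$q_idx)
      out[ov$q_idx[keep]] <- repeats$family[ov$s_idx[keep]]
    }
  }
  out
}

#' Annotate peaks with their best element and chromatin context
#'
#' One row per peak: chromatin state at the summit (7-state with 15-state
#' fallback), nearest gene and TSS distance, state at that TSS, best-element
#' fields, mean PhyloP over the element core, baseline DHS over the element
#' footprint, and TE family.
#'
#' @param peaks Tibble `chrom`, `start`, `end`, `summit`, `density`.
#' @param res [scan_sequence()] output.
#' @param seg7,seg15 Segmentations (see [assign_state()]).
#' @param genes Gene table with `gene_id`, `chrom`, `tss`.
#' @param phylop,dhs Signal tracks (may be `NULL` to skip).
#' @param repeats Repeat catalogue (may be `NULL` to skip).
#' @param collapse 15-to-7 state collapse table.
#' @return A tibble with one row per peak and the annotation columns
#'   described above.
#' @export
annotate_peaks <- function(peaks, res, seg7, seg15 = NULL, genes = NULL,
                           phylop = NULL, dhs = NULL, repeats = NULL,
                           collapse = chromhmm15_collapse()) {
  ann <- best_re_for_peak(peaks, res)
  ann$state7 <- assign_state(seg7, seg15, ann$chrom, ann$summit,
                             collapse = collapse)
  if (!is.null(genes)) {
    ann <- nearest_gene(ann, genes)
    gi <- match(ann$gene_id, genes$gene_id)
    ann$state7_tss <- ifelse(is.na(gi), NA_character_,
                             assign_state(seg7, seg15, genes$chrom[pmax(gi, 1)],
                                          genes$tss[pmax(gi, 1)],
                                          collapse = collapse))
  }
  has_re <- !is.na(ann$re_start)
  re_tbl <- tibble(chrom = ann$chrom[has_re], start = ann$re_start[has_re],
                   end = ann$re_end[has_re], spacer = ann$re_spacer[has_re])
  if (!is.null(phylop)) {
    ann$mean_phylop <- NA_real_
    if (any(has_re)) ann$mean_phylop[has_re] <- mean_signal_over_re(phylop, re_tbl)
  }
  if (!is.null(dhs)) {
    ann$dhs_nt <- NA_real_
    if (any(has_re)) {
      ann$dhs_nt[has_re] <- track_mean_over(
        dhs, re_tbl$chrom, re_tbl$start, re_tbl$end, seq_len(nrow(re_tbl)))
    }
  }
  if (!is.null(repeats)) {
    ann$te_family <- NA_character_
    if (any(has_re)) ann$te_family[has_re] <- te_assign(re_tbl, repeats)
  }
  ann
}
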