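# Readers and writers for the plain-text formats the pipeline consumes:
# FASTA (via Biostrings), BED (0-based half-open, tab-separated, no track
# lines), bedGraph, and TSV side tables. All readers return tibbles and
# report malformed lines with their file and line number.

#' Read a (multi-record) FASTA file
#'
#' @param path Path to an uncompressed FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path, width = 70L)
  invisible(path)
}

parse_tab_file <- function(path, n_min, what) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#") &
    !startsWith(lines, "track")
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < n_min)) {
    bad <- which(keep)[which(nf < n_min)[1]]
    abort(paste0(path, ":", bad, ": ", what, " line has ", nf[nf < n_min][1],
                 " fields, expected >= ", n_min))
  }
  list(fields = fields, line_no = which(keep))
}

#' Read a BED file
#'
#' Tab-separated, 0-based half-open, no header. Columns beyond the third are
#' taken in BED order: `name`, `score`, `strand`, then any extras named via
#' `extra_cols`.
#'
#' @param path Path to the BED file.
#' @param extra_cols Optional character vector naming columns 7, 8, ... .
#' @return A tibble with `chrom`, `start`, `end` and any further columns
#'   present.
#' @export
read_bed <- function(path, extra_cols = character()) {
  p <- parse_tab_file(path, 3L, "BED")
  if (length(p$fields) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  nf <- min(lengths(p$fields))
  cols <- c("chrom", "start", "end", "name", "score", "strand",
            extra_cols)[seq_len(min(nf, 6L + length(extra_cols)))]
  m <- do.call(rbind, lapply(p$fields, `[`, seq_along(cols)))
  out <- as_tibble(setNames(as.data.frame(m, stringsAsFactors = FALSE), cols))
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  bad <- which(is.na(out$start) | is.na(out$end) | out$start < 0 |
                 out$start >= out$end)
  if (length(bad) > 0) {
    abort(paste0(path, ":", p$line_no[bad[1]],
                 ": invalid BED interval (need 0 <= start < end)"))
  }
  if ("score" %in% cols) {
    out$score <- suppressWarnings(as.numeric(out$score))
  }
  out
}

#' Write intervals to BED
#'
#' @param x Tibble whose columns are written in order (must start with
#'   `chrom`, `start`, `end`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  stopifnot(identical(names(x)[1:3], c("chrom", "start", "end")))
  readr::write_tsv(x, path, col_names = FALSE)
  invisible(path)
}

#' Read a chromatin-state segmentation (BED4)
#'
#' @param path BED4 file: `chrom start end state`.
#' @param dialect `"hmm7"` or `"hmm15"`; checked against the label
#'   vocabulary.
#' @return Tibble `chrom`, `start`, `end`, `state`, sorted; overlapping
#'   intervals within a chromosome are an error.
#' @export
read_segmentation <- function(path, dialect = c("hmm7", "hmm15")) {
  dialect <- match.arg(dialect)
  seg <- read_bed(path)
  if (!"name" %in% names(seg)) abort(paste0(path, ": segmentation needs 4 columns"))
  seg <- dplyr::rename(seg, state = "name") |>
    arrange(.data$chrom, .data$start)
  vocab <- if (dialect == "hmm7") HMM7_STATES else as.character(1:15)
  bad <- setdiff(unique(seg$state), vocab)
  if (length(bad) > 0) {
    abort(paste0(path, ": unknown ", dialect, " state label(s): ",
                 paste(bad, collapse = ", ")))
  }
  ov <- seg |>
    group_by(.data$chrom) |>
    mutate(overlap = .data$start < dplyr::lag(.data$end, default = -1L)) |>
    ungroup()
  if (any(ov$overlap)) {
    i <- which(ov$overlap)[1]
    abort(paste0(path, ": overlapping segmentation intervals at ",
                 seg$chrom[i], ":", seg$start[i], " and the preceding interval"))
  }
  seg[, c("chrom", "start", "end", "state")]
}

#' Read a bedGraph signal track
#'
#' @param path bedGraph file: `chrom start end value`, no track lines.
#' @return Tibble `chrom`, `start`, `end`, `value`, sorted by (`chrom`,
#'   `start`); unsorted input is sorted on load.
#' @export
read_bedgraph <- function(path) {
  p <- parse_tab_file(path, 4L, "bedGraph")
  if (length(p$fields) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  value = numeric()))
  }
  m <- do.call(rbind, lapply(p$fields, `[`, 1:4))
  out <- tibble(chrom = m[, 1],
                start = suppressWarnings(as.integer(m[, 2])),
                end = suppressWarnings(as.integer(m[, 3])),
                value = suppressWarnings(as.numeric(m[, 4])))
  bad <- which(is.na(out$start) | is.na(out$end) | is.na(out$value) |
                 out$start < 0 | out$start >= out$end)
  if (length(bad) > 0) {
    abort(paste0(path, ":", p$line_no[bad[1]], ": invalid bedGraph line"))
  }
  arrange(out, .data$chrom, .data$start)
}

#' Write a signal track to bedGraph
#'
#' @param track Tibble `chrom`, `start`, `end`, `value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  readr::write_tsv(track[, c("chrom", "start", "end", "value")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Read a TSV side table with a required schema
#'
#' @param path Path to a tab-separated file with a header row.
#' @param required Character vector of column names that must be present.
#' @return A tibble.
#' @export
read_tsv_table <- function(path, required = character()) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(required, names(out))
  if (length(missing_cols) > 0) {
    abort(paste0(path, ": missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out
}

#' Read the peak table
#'
#' BED6+ with the density (overlapping-read count at the signal maximum) in
#' the score column and the summit offset in column 7.
#'
#' @param path Peak BED path.
#' @return Tibble `chrom`, `start`, `end`, `name`, `density`, `summit`.
#' @export
read_peaks <- function(path) {
  x <- read_bed(path, extra_cols = "summit")
  stopifnot(all(c("name", "score", "summit") %in% names(x)))
  x$summit <- as.integer(x$summit)
  bad <- which(x$summit < x$start | x$summit >= x$end)
  if (length(bad) > 0) {
    abort(paste0(path, ": summit outside peak interval at row ", bad[1]))
  }
  x |>
    dplyr::rename(density = "score") |>
    select("chrom", "start", "end", "name", "density", "summit")
}

#' Read the gene table (BED6 + expression side table)
#'
#' @param bed_path BED6 of genes: name column is the gene id; the TSS is the
#'   `start` for `+` genes and `end - 1` for `-` genes.
#' @param expr_path TSV with columns `gene_id`, `expr_nt`, `expr_4h`,
#'   `expr_18h` (log2-scale intensities) and optionally `fold_change`,
#'   `pct_identity_mouse`.
#' @return Tibble keyed by `gene_id` with `chrom`, `tss`, `strand` and the
#'   expression columns; `fold_change` (linear scale, treated/NT at 18 h) is
#'   computed from the intensities when absent.
#' @export
read_genes <- function(bed_path, expr_path = NULL) {
  g <- read_bed(bed_path)
  stopifnot(all(c("name", "strand") %in% names(g)))
  genes <- tibble(gene_id = g$name, chrom = g$chrom,
                  tss = ifelse(g$strand == "+", g$start, g$end - 1L),
                  strand = g$strand)
  if (!is.null(expr_path)) {
    expr <- read_tsv_table(expr_path,
                           required = c("gene_id", "expr_nt", "expr_4h",
                                        "expr_18h"))
    genes <- left_join(genes, expr, by = "gene_id")
    if (!"fold_change" %in% names(genes)) {
      genes$fold_change <- 2^(genes$expr_18h - genes$expr_nt)
    }
  }
  genes
}
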