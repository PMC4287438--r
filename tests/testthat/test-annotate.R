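# Chromatin-state assignment, nearest gene, signal averaging, TE overlap.

seg7_fix <- tibble::tibble(
  chrom = "chr1", start = c(0L, 1000L, 5000L), end = c(500L, 2000L, 6000L),
  state = c("Promoter", "Enhancer", "Repressed"))
seg15_fix <- tibble::tibble(
  chrom = "chr1", start = c(2000L, 3000L, 4000L),
  end = c(2500L, 3500L, 4500L),
  state = c("4", "14", "12"))

test_that("state assignment uses the 7-state call with 15-state fallback", {
  expect_identical(assign_state(seg7_fix, seg15_fix, "chr1", 1200L),
                   "Enhancer")
  # gap in the 7-state track, 15-state "4" collapses to Enhancer
  expect_identical(assign_state(seg7_fix, seg15_fix, "chr1", 2100L),
                   "Enhancer")
  # repetitive 15-state label is excluded, not mapped
  expect_identical(assign_state(seg7_fix, seg15_fix, "chr1", 3200L),
                   "excluded")
  # uncovered by both -> uncalled
  expect_true(is.na(assign_state(seg7_fix, seg15_fix, "chr1", 800L)))
  expect_error(assign_state(seg7_fix, seg15_fix, "chrX", 10L),
               "unknown chromosome")
})

test_that("state assignment agrees with a linear interval scan", {
  set.seed(601)
  pos <- sample(0:6500, 200, replace = TRUE)
  got <- assign_state(seg7_fix, seg15_fix, rep("chr1", 200), pos)
  collapse <- chromhmm15_collapse()
  for (i in seq_along(pos)) {
    hit7 <- which(seg7_fix$start <= pos[i] & seg7_fix$end > pos[i])
    want <- if (length(hit7) == 1) {
      seg7_fix$state[hit7]
    } else {
      hit15 <- which(seg15_fix$start <= pos[i] & seg15_fix$end > pos[i])
      if (length(hit15) == 1) unname(collapse[seg15_fix$state[hit15]])
      else NA_character_
    }
    expect_identical(got[i], want)
  }
})

test_that("nearest gene minimizes summit-TSS distance with stable ties", {
  genes <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chr1",
                          tss = c(1000L, 5000L), strand = "+")
  pk <- function(s) tibble::tibble(chrom = "chr1", start = s - 10L,
                                   end = s + 10L, summit = s)
  expect_equal(nearest_gene(pk(1000L), genes)$tss_distance, 0)
  out <- nearest_gene(pk(1500L), genes)
  expect_identical(out$gene_id, "g1")
  expect_equal(out$tss_distance, 500)
  # equidistant: lower TSS wins
  expect_identical(nearest_gene(pk(3000L), genes)$gene_id, "g1")
  # unknown chromosome -> NA
  expect_true(is.na(nearest_gene(tibble::tibble(chrom = "chr9", start = 0L,
                                                end = 1L, summit = 0L),
                                 genes)$gene_id))

  set.seed(602)
  genes_r <- tibble::tibble(gene_id = paste0("g", 1:30), chrom = "chr1",
                            tss = sample(0:100000, 30), strand = "+")
  for (i in 1:25) {
    s <- sample(0:100000, 1)
    got <- nearest_gene(pk(s), genes_r)
    d <- abs(s - genes_r$tss)
    want <- genes_r$gene_id[order(d, genes_r$tss)[1]]
    expect_identical(got$gene_id, want)
  }
})

test_that("nearest-gene distance is invariant under coordinate reflection", {
  set.seed(603)
  L <- 50000L
  genes <- tibble::tibble(gene_id = paste0("g", 1:10), chrom = "chr1",
                          tss = sample(0:L, 10), strand = "+")
  for (i in 1:10) {
    s <- sample(0:L, 1)
    fwd <- nearest_gene(tibble::tibble(chrom = "chr1", start = s, end = s + 1L,
                                       summit = s), genes)
    refl <- nearest_gene(tibble::tibble(chrom = "chr1", start = L - s,
                                        end = L - s + 1L, summit = L - s),
                         dplyr::mutate(genes, tss = L - tss))
    expect_equal(fwd$tss_distance, refl$tss_distance)
  }
})

test_that("mean signal over the element core excludes spacer and gaps", {
  re <- tibble::tibble(chrom = "chr1", start = 100L, end = 123L,
                       strand = "+", spacer = 3L, score = 1,
                       core = CANON, core_matches = 4L)
  const <- tibble::tibble(chrom = "chr1", start = 0L, end = 1000L,
                          value = 1.5)
  expect_equal(mean_signal_over_re(const, re), 1.5)
  # only the first half-site covered: defined mean over covered bases
  half <- tibble::tibble(chrom = "chr1", start = 100L, end = 110L,
                         value = 2.0)
  expect_equal(mean_signal_over_re(half, re), 2.0)
  none <- tibble::tibble(chrom = "chr1", start = 500L, end = 600L,
                         value = 9)
  expect_true(is.na(mean_signal_over_re(none, re)))
  # spacer-only coverage contributes nothing
  spacer_only <- tibble::tibble(chrom = "chr1", start = 110L, end = 113L,
                                value = 7)
  expect_true(is.na(mean_signal_over_re(spacer_only, re)))

  # step track: per-base brute force over the two half-sites
  set.seed(604)
  breaks <- sort(sample(95:130, 8))
  step <- tibble::tibble(chrom = "chr1", start = breaks[-8], end = breaks[-1],
                         value = round(runif(7), 3))
  got <- mean_signal_over_re(step, re)
  core_bases <- c(100:109, 113:122)
  want <- oracle_track_mean(step, "chr1", 100, 123)  # not this: core only
  vals <- c()
  for (b in core_bases) {
    hit <- which(step$start <= b & step$end > b)
    if (length(hit) == 1) vals <- c(vals, step$value[hit])
  }
  expect_equal(got, mean(vals))
})

test_that("mean signal is invariant to splitting track intervals", {
  re <- tibble::tibble(chrom = "chr1", start = 50L, end = 70L,
                       strand = "+", spacer = 0L, score = 1, core = CANON,
                       core_matches = 4L)
  whole <- tibble::tibble(chrom = "chr1", start = c(40L, 60L),
                          end = c(60L, 80L), value = c(2, 4))
  split <- tibble::tibble(chrom = "chr1", start = c(40L, 50L, 60L, 70L),
                          end = c(50L, 60L, 70L, 80L), value = c(2, 2, 4, 4))
  expect_equal(mean_signal_over_re(whole, re), mean_signal_over_re(split, re))
})

test_that("TSS-window signal equals a brute-force window mean", {
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", tss = 5000L,
                          strand = "+")
  const <- tibble::tibble(chrom = "chr1", start = 0L, end = 10000L,
                          value = 3.3)
  expect_equal(signal_at_tss(const, genes), 3.3)
  empty <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), value = numeric())
  expect_true(is.na(signal_at_tss(empty, genes)))
  set.seed(605)
  breaks <- sort(sample(3500:6500, 10))
  step <- tibble::tibble(chrom = "chr1", start = breaks[-10],
                         end = breaks[-1], value = round(runif(9), 3))
  expect_equal(signal_at_tss(step, genes, halfwidth = 400L),
               oracle_track_mean(step, "chr1", 4600, 5400))
})

test_that("TE assignment picks the maximal-overlap family", {
  re <- tibble::tibble(chrom = "chr1", start = 100L, end = 120L,
                       strand = "+", spacer = 0L, score = 1, core = CANON,
                       core_matches = 4L)
  reps <- tibble::tibble(chrom = "chr1", start = c(50L, 115L),
                         end = c(115L, 300L), family = c("MER61", "Alu"))
  # overlap 15 bp (MER61) vs 5 bp (Alu)
  expect_identical(te_assign(re, reps), "MER61")
  inside <- tibble::tibble(chrom = "chr1", start = c(90L), end = c(200L),
                           family = "MER61")
  expect_identical(te_assign(re, inside), "MER61")
  expect_true(is.na(te_assign(re, tibble::tibble(chrom = "chr1",
                                                 start = 500L, end = 600L,
                                                 family = "L2"))))
  expect_true(is.na(te_assign(re, reps, min_overlap_frac = 0.9)))

  # shifting an element wholly inside one repeat keeps the family
  for (s in seq(95L, 175L, by = 20L)) {
    re_s <- dplyr::mutate(re, start = s, end = s + 20L)
    expect_identical(te_assign(re_s, inside |>
                                 dplyr::mutate(end = 400L)), "MER61")
  }
})

test_that("annotate_peaks assembles all context columns", {
  sim <- small_sim(seed = 606)
  res <- scan_sequence(sim$genome, sim$pwm, threshold_frac = 0.7)
  ann <- annotate_peaks(sim$peaks, res, sim$seg7, sim$seg15,
                        genes = sim$genes, phylop = sim$phylop,
                        dhs = sim$dhs, repeats = sim$repeats)
  expect_equal(nrow(ann), nrow(sim$peaks))
  expect_true(all(c("state7", "gene_id", "tss_distance", "state7_tss",
                    "re_score", "mean_phylop", "dhs_nt", "te_family") %in%
                    names(ann)))
  # summits sit inside planted state intervals
  expect_true(mean(!is.na(ann$state7)) > 0.9)
  has_re <- !is.na(ann$re_start)
  expect_true(mean(has_re) > 0.5)
  # planted PhyloP is recovered at the element (constant over footprint)
  tr <- sim$truth
  m <- match(paste(ann$chrom[has_re], ann$re_start[has_re]),
             paste(tr$chrom, tr$start))
  ok <- !is.na(m)
  expect_gt(stats::cor(ann$mean_phylop[has_re][ok], tr$phylop[m[ok]]), 0.99)
})
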