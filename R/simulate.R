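# Seeded synthetic study generator.
#
# Emulates the inputs of a stress-induced p53 ChIP-seq study: a random
# genome with planted response elements of graded PWM strength (spacers
# 0-3), peak densities log-linearly coupled to element strength, DHS
# inversely coupled, PhyloP set by chromatin state and TE family (L2/Alu
# strongly negative), a 7-state segmentation with deliberate gaps backed by
# a 15-state track, RepeatMasker-style repeats, and linked genes whose
# induction is largest in repressed/CTCF chromatin with H3K4me3 changes
# coupled to expression changes.

with_seed_local <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Default transposable-element families of the simulation
#'
#' Per family: genomic base fraction, per-element assignment probability
#' (the endogenous retroviral families MER61/LTR10B/MLT1H are planted at 5x
#' their genomic fraction), a PWM strength bonus, and the family PhyloP
#' mean (Alu and L2 strongly negative, i.e. fast-evolving).
#'
#' @return A tibble with columns `family`, `genome_fraction`, `re_prob`,
#'   `strength_bonus`, `phylop_mean`.
#' @export
default_te_families <- function() {
  tibble(
    family = c("MER61", "LTR10B", "MLT1H", "Alu", "L2", "MIR"),
    genome_fraction = c(0.004, 0.003, 0.004, 0.100, 0.030, 0.025),
    re_prob = c(0.020, 0.015, 0.020, 0.150, 0.060, 0.040),
    strength_bonus = c(0.06, 0.05, 0.05, 0.02, 0.01, 0.01),
    phylop_mean = c(0.30, 0.25, 0.25, -1.50, -2.00, 0.00))
}

#' Simulation configuration
#'
#' Defaults define the emulated study conditions: ~3,000 occupied elements
#' on a 3 Mb genome, PWM strength fractions 0.55-1.0 of the maximum score,
#' rare spacers, a log-linear strength-to-density coupling of +2 and a
#' strength-to-DHS coupling of -1.5, and a chromatin-state mix dominated by
#' enhancers, promoters and repressed chromatin.
#'
#' @param seed Integer seed; every random draw flows from it.
#' @param n_chroms,chrom_length Genome shape (bp).
#' @param n_res Number of planted occupied elements.
#' @param strength_range PWM-fraction interval the planted strengths are
#'   drawn from (uniform).
#' @param spacer_probs Probabilities of spacers 0-3.
#' @param density_coupling Beta in `density = exp(a + beta * frac + e)`.
#' @param dhs_coupling Gamma (<= 0) in `dhs = exp(a + gamma * frac + e)`.
#' @param phylop_coupling Slope of PhyloP on (centred) strength fraction.
#' @param state_mix Probabilities over the 7 chromatin states.
#' @param te_families Family table, see [default_te_families()].
#' @param density_alpha,density_sd,dhs_alpha,dhs_sd,phylop_sd Noise-model
#'   constants (log scale for density/DHS).
#' @param spacer_penalty Strength-fraction penalty per spacer nt (spaced
#'   sites are planted weaker, via degraded half-site junction targets).
#' @param seg7_gap_frac Fraction of element regions left uncalled by the
#'   7-state track and covered only by the 15-state track.
#' @param n_training,training_mutation_rate Training set used to build the
#'   generator's reference PWM.
#' @return A `p53_sim_config` list.
#' @export
simulation_config <- function(seed = 1L, n_chroms = 3L, chrom_length = 1e6L,
                              n_res = 3000L,
                              strength_range = c(0.55, 1.0),
                              spacer_probs = c(0.85, 0.06, 0.05, 0.04),
                              density_coupling = 2.0,
                              dhs_coupling = -1.5,
                              phylop_coupling = -0.8,
                              state_mix = c(Promoter = 0.20,
                                            PromoterFlank = 0.05,
                                            Enhancer = 0.26,
                                            WeakEnhancer = 0.05,
                                            CTCF = 0.04,
                                            Transcribed = 0.10,
                                            Repressed = 0.30),
                              te_families = default_te_families(),
                              density_alpha = 2.3, density_sd = 0.35,
                              dhs_alpha = 1.5, dhs_sd = 0.4,
                              phylop_sd = 0.15,
                              spacer_penalty = 0.05,
                              seg7_gap_frac = 0.08,
                              n_training = 103L,
                              training_mutation_rate = 0.1) {
  stopifnot(chrom_length >= 10000, n_res >= 10,
            abs(sum(spacer_probs) - 1) < 1e-9,
            abs(sum(state_mix) - 1) < 1e-9,
            length(state_mix) == 7,
            strength_range[1] > 0, strength_range[2] <= 1,
            strength_range[1] <= strength_range[2],
            sum(te_families$re_prob) < 1)
  slot_len <- floor(n_chroms * chrom_length / n_res)
  if (slot_len < 900) {
    abort("n_res too dense for the genome: need >= 900 bp per element")
  }
  structure(
    list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
         chrom_length = as.integer(chrom_length), n_res = as.integer(n_res),
         strength_range = strength_range, spacer_probs = spacer_probs,
         density_coupling = density_coupling, dhs_coupling = dhs_coupling,
         phylop_coupling = phylop_coupling,
         state_mix = state_mix, te_families = te_families,
         density_alpha = density_alpha, density_sd = density_sd,
         dhs_alpha = dhs_alpha, dhs_sd = dhs_sd, phylop_sd = phylop_sd,
         spacer_penalty = spacer_penalty, seg7_gap_frac = seg7_gap_frac,
         n_training = as.integer(n_training),
         training_mutation_rate = training_mutation_rate),
    class = "p53_sim_config")
}

#' Generate a training set of p53RE cores
#'
#' Mutated copies of the canonical core (two RRRCWWGYYY decamers
#' instantiated as `GGGCATGCCC` twice), each base substituted independently
#' with probability `mutation_rate`. Stands in for a curated set of
#' experimentally validated elements.
#'
#' @param n Number of sequences (>= 10).
#' @param mutation_rate Per-base substitution probability in `[0, 0.3]`.
#' @param seed Optional seed; when given, the global RNG state is left
#'   untouched.
#' @return Character vector of `n` 20-nt cores.
#' @export
generate_training_set <- function(n = 103L, mutation_rate = 0.1,
                                  seed = NULL) {
  stopifnot(n >= 10, mutation_rate >= 0, mutation_rate <= 0.3)
  with_seed_local(seed, {
    canon <- strsplit(CANONICAL_CORE, "", fixed = TRUE)[[1]]
    vapply(seq_len(n), function(i) {
      b <- canon
      hit <- runif(CORE_LEN) < mutation_rate
      if (any(hit)) {
        b[hit] <- vapply(b[hit], function(orig) {
          sample(setdiff(DNA_BASES, orig), 1L)
        }, character(1))
      }
      paste(b, collapse = "")
    }, character(1))
  })
}

# Greedily degrade the canonical core toward `target` (absolute score):
# repeatedly apply the single substitution that brings the score closest to
# the target, never dropping below 3 intact prefilter bases.
#
# The controlled quantity is the *effective* locus score: the maximum of
# the forward reading and the reverse-complement reading of the same
# footprint (the canonical core is palindromic, so the scanner is free to
# report whichever strand reads stronger — both must be degraded together
# or planted strengths would not be the strengths the scanner sees).
degrade_core_to <- function(wm, target) {
  w <- wm$weights
  comp <- c(4L, 3L, 2L, 1L)
  idx <- base_index(strsplit(CANONICAL_CORE, "", fixed = TRUE)[[1]])
  fwd <- sum(w[cbind(idx, seq_len(CORE_LEN))])
  rc_idx <- rev(comp[idx])
  rc <- sum(w[cbind(rc_idx, seq_len(CORE_LEN))])
  eff <- max(fwd, rc)
  pf_intact <- rep(TRUE, 4L)
  repeat {
    if (eff <= target) break
    best <- NULL
    for (j in seq_len(CORE_LEN)) {
      # mutating a forward prefilter base also breaks the mirrored
      # reverse-complement prefilter base, so one constraint covers both
      pf_k <- match(j, PREFILTER_POS)
      if (!is.na(pf_k) && pf_intact[pf_k] && sum(pf_intact) <= 3L) next
      jr <- CORE_LEN + 1L - j   # mirrored position in the rc reading
      for (b in 1:4) {
        if (b == idx[j]) next
        df <- w[b, j] - w[idx[j], j]
        dr <- w[comp[b], jr] - w[comp[idx[j]], jr]
        new_eff <- max(fwd + df, rc + dr)
        if (new_eff >= eff) next
        cand_err <- abs(new_eff - target)
        if (is.null(best) || cand_err < best$err) {
          best <- list(j = j, b = b, df = df, dr = dr, err = cand_err)
        }
      }
    }
    if (is.null(best) || best$err >= abs(eff - target)) break
    pf_k <- match(best$j, PREFILTER_POS)
    if (!is.na(pf_k)) pf_intact[pf_k] <- FALSE
    idx[best$j] <- best$b
    fwd <- fwd + best$df
    rc <- rc + best$dr
    eff <- max(fwd, rc)
  }
  list(core = paste(DNA_BASES[idx], collapse = ""), score = eff)
}

# trim sorted intervals so they do not overlap (earlier interval wins)
trim_overlaps <- function(x) {
  x <- arrange(x, .data$chrom, .data$start)
  out <- x |>
    group_by(.data$chrom) |>
    mutate(start = pmax(.data$start,
                        cummax(dplyr::lag(.data$end, default = 0L)))) |>
    ungroup() |>
    filter(.data$start < .data$end)
  out
}

state_param <- function(states, table) {
  unname(table[states])
}

#' Generate a complete synthetic study
#'
#' Produces a truth table plus every input file of the analysis (genome
#' FASTA, training set, peak BED with densities, 7- and 15-state
#' segmentation BEDs, repeat BED, DHS/PhyloP/H3K4me3 bedGraphs, gene BED,
#' expression TSV). With `outdir = NULL` nothing is written and the same
#' tables are returned in memory.
#'
#' @param config A [simulation_config()].
#' @param outdir Output directory (created if needed), or `NULL`.
#' @param sequences If `FALSE`, skip building the genome sequence (fast
#'   truth-only mode for replicate studies; no FASTA is written).
#' @return A list with elements `truth`, `training`, `peaks`, `genes`,
#'   `expression`, `seg7`, `seg15`, `repeats`, `dhs`, `phylop`,
#'   `h3k4me3_nt`, `h3k4me3_trt`, `genome` (named character or `NULL`),
#'   `pwm` (the generator's reference matrix) and `files` (named paths, if
#'   written).
#' @export
generate_study <- function(config = simulation_config(), outdir = NULL,
                           sequences = TRUE) {
  stopifnot(inherits(config, "p53_sim_config"))
  set.seed(config$seed)
  n <- config$n_res
  n_chroms <- config$n_chroms
  chrom_len <- config$chrom_length
  chroms <- paste0("chr", seq_len(n_chroms))

  training <- generate_training_set(config$n_training,
                                    config$training_mutation_rate)
  wm <- build_pwm(training, source = "synthetic-training")
  wmax <- max_score(wm)

  # --- element placement: one element per fixed-length slot -------------
  slots_per_chrom <- diff(round(seq(0, n, length.out = n_chroms + 1)))
  slot_chrom <- rep(chroms, slots_per_chrom)
  slot_len <- chrom_len %/% max(slots_per_chrom)
  slot_index <- unlist(lapply(slots_per_chrom, seq_len)) - 1L
  slot_start <- slot_index * slot_len

  spacer <- sample(0:MAX_SPACER, n, replace = TRUE,
                   prob = config$spacer_probs)
  # elements live in the first ~40% of the slot; background repeats are
  # placed in the back 40% so they never touch a planted element
  re_offset <- floor(runif(n, 200, 0.38 * slot_len))
  re_start <- slot_start + re_offset
  strand <- sample(c("+", "-"), n, replace = TRUE)
  state <- sample(names(config$state_mix), n, replace = TRUE,
                  prob = config$state_mix)
  te <- config$te_families
  fam_draw <- runif(n)
  fam_cut <- cumsum(te$re_prob)
  te_family <- rep(NA_character_, n)
  for (i in rev(seq_len(nrow(te)))) {
    te_family[fam_draw <= fam_cut[i]] <- te$family[i]
  }

  target_frac <- runif(n, config$strength_range[1], config$strength_range[2])
  target_frac <- pmax(target_frac - config$spacer_penalty * spacer,
                      config$strength_range[1])
  bonus <- te$strength_bonus[match(te_family, te$family)]
  target_frac <- pmin(target_frac + ifelse(is.na(bonus), 0, bonus), 1)

  degraded <- lapply(target_frac * wmax, function(t) degrade_core_to(wm, t))
  core <- vapply(degraded, `[[`, character(1), "core")
  score <- vapply(degraded, `[[`, numeric(1), "score")
  frac <- score / wmax

  # --- couplings --------------------------------------------------------
  mid_frac <- mean(config$strength_range)
  density <- pmax(1, round(exp(config$density_alpha +
                                 config$density_coupling * frac +
                                 rnorm(n, 0, config$density_sd))))
  dhs <- exp(config$dhs_alpha + config$dhs_coupling * frac +
               rnorm(n, 0, config$dhs_sd))
  state_phylop <- c(Promoter = 1.2, PromoterFlank = 0.9, Enhancer = 0.8,
                    WeakEnhancer = 0.6, CTCF = 0.3, Transcribed = 0.2,
                    Repressed = 0.0)
  fam_phylop <- te$phylop_mean[match(te_family, te$family)]
  phylop <- ifelse(is.na(fam_phylop), state_param(state, state_phylop),
                   fam_phylop) +
    config$phylop_coupling * (frac - mid_frac) +
    rnorm(n, 0, config$phylop_sd)

  re_end <- re_start + CORE_LEN + spacer
  re_mid <- (re_start + re_end) %/% 2L
  peak_start <- pmax(re_mid - 150L, 0L)
  peak_end <- pmin(re_mid + 150L, chrom_len)
  summit <- re_mid + sample(-5:5, n, replace = TRUE)
  summit <- pmin(pmax(summit, peak_start), peak_end - 1L)

  # --- genes ------------------------------------------------------------
  tss_meanlog <- c(Promoter = log(600), PromoterFlank = log(2000),
                   Enhancer = log(32000), WeakEnhancer = log(15000),
                   CTCF = log(20000), Transcribed = log(30000),
                   Repressed = log(70000))
  tss_dist <- round(exp(rnorm(n, state_param(state, tss_meanlog), 0.5)))
  tss <- re_mid + sample(c(-1L, 1L), n, replace = TRUE) * tss_dist
  tss <- pmin(pmax(tss, 1100L), chrom_len - 1100L)
  gene_strand <- sample(c("+", "-"), n, replace = TRUE)
  gene_id <- sprintf("gene%05d", seq_len(n))

  h_meanlog <- c(Promoter = log(40), PromoterFlank = log(15),
                 Enhancer = log(8), WeakEnhancer = log(6), CTCF = log(2),
                 Transcribed = log(10), Repressed = log(1.5))
  h3k4me3_nt <- exp(rnorm(n, state_param(state, h_meanlog), 0.45))
  fc_mean <- c(Promoter = 0.1, PromoterFlank = 0.6, Enhancer = 0.8,
               WeakEnhancer = 0.7, CTCF = 2.0, Transcribed = 0.6,
               Repressed = 2.0)
  log2fc <- rnorm(n, state_param(state, fc_mean), 0.7) +
    0.4 * (frac - mid_frac)
  # TE-embedded elements are mostly silent; L2/MIR are the exapted
  # exceptions with larger responses at nearby genes
  damp <- rep(1, n)
  damp[!is.na(te_family) & te_family %in% c("MER61", "LTR10B", "MLT1H",
                                            "Alu")] <- 0.3
  damp[!is.na(te_family) & te_family %in% c("L2", "MIR")] <- 1.3
  log2fc <- log2fc * damp
  dh3 <- 0.8 * log2fc + rnorm(n, 0, 0.8)
  h3k4me3_trt <- h3k4me3_nt * 2^dh3
  expr_nt <- 5 + 0.8 * log2(h3k4me3_nt + 1) + rnorm(n, 0, 0.5)
  expr_18h <- expr_nt + log2fc
  expr_4h <- expr_nt + 0.6 * log2fc + rnorm(n, 0, 0.3)
  pct_identity <- pmin(pmax(60 + 15 * phylop + rnorm(n, 0, 8), 0), 100)

  truth <- tibble(
    re_id = sprintf("re%05d", seq_len(n)), chrom = slot_chrom,
    start = re_start, end = re_end, spacer = spacer, strand = strand,
    core = core, target_frac = target_frac, pwm_frac = frac,
    score = score, state = state, te_family = te_family,
    density = density, dhs = dhs, phylop = phylop,
    gene_id = gene_id, tss = tss, tss_distance = abs(tss - re_mid),
    fold_change = 2^log2fc, h3k4me3_nt = h3k4me3_nt,
    h3k4me3_trt = h3k4me3_trt,
    expr_nt = expr_nt, expr_4h = expr_4h, expr_18h = expr_18h,
    pct_identity_mouse = pct_identity)

  peaks <- tibble(chrom = slot_chrom, start = peak_start, end = peak_end,
                  name = truth$re_id, density = density, summit = summit)
  genes <- tibble(gene_id = gene_id, chrom = slot_chrom, tss = tss,
                  strand = gene_strand)
  expression <- tibble(gene_id = gene_id, expr_nt = expr_nt,
                       expr_4h = expr_4h, expr_18h = expr_18h,
                       fold_change = 2^log2fc,
                       pct_identity_mouse = pct_identity)

  # --- segmentation: state intervals around elements and TSSs; a fraction
  # of element regions is deliberately absent from the 7-state track and
  # called only by the 15-state model; chromosome tails carry 15-state
  # repetitive labels (14/15), which the analysis must exclude ------------
  gap7 <- runif(n) < config$seg7_gap_frac
  state15_of7 <- c(Promoter = "1", PromoterFlank = "3", Enhancer = "4",
                   WeakEnhancer = "6", CTCF = "8", Transcribed = "10",
                   Repressed = "12")
  seg_feat <- bind_rows(
    tibble(chrom = slot_chrom, start = pmax(re_mid - 300L, 0L),
           end = pmin(re_mid + 300L, chrom_len), state = state, gap = gap7),
    tibble(chrom = slot_chrom, start = pmax(tss - 300L, 0L),
           end = pmin(tss + 300L, chrom_len), state = state, gap = FALSE))
  seg_feat <- trim_overlaps(seg_feat)
  seg7 <- seg_feat |>
    filter(!.data$gap) |>
    select("chrom", "start", "end", "state")
  seg15 <- seg_feat |>
    filter(.data$gap) |>
    mutate(state = unname(state15_of7[.data$state])) |>
    select("chrom", "start", "end", "state")
  tails <- tibble(chrom = chroms,
                  start = chrom_len - 500L, end = chrom_len,
                  state = rep(c("14", "15"), length.out = n_chroms))
  seg15 <- trim_overlaps(bind_rows(seg15, tails))

  # --- repeats: an interval around each TE-embedded element plus
  # background intervals realizing the per-family genomic fractions ------
  te_idx <- which(!is.na(te_family))
  rep_re <- tibble(chrom = slot_chrom[te_idx],
                   start = pmax(re_start[te_idx] -
                                  sample(20:150, length(te_idx), TRUE), 0L),
                   end = pmin(re_end[te_idx] +
                                sample(20:150, length(te_idx), TRUE),
                              chrom_len),
                   family = te_family[te_idx])
  genome_bp <- as.numeric(n_chroms) * chrom_len
  bg_list <- list()
  free_slots <- sample(seq_len(n))   # one background repeat per slot at most
  slot_ptr <- 1L
  for (i in seq_len(nrow(te))) {
    planted_bp <- sum((rep_re$end - rep_re$start)[rep_re$family ==
                                                    te$family[i]])
    need_bp <- te$genome_fraction[i] * genome_bp - planted_bp
    if (need_bp <= 0) next
    n_int <- ceiling(need_bp / 300)
    take <- free_slots[seq(slot_ptr, length.out = n_int)]
    take <- take[!is.na(take)]
    slot_ptr <- slot_ptr + n_int
    if (length(take) == 0) next
    width <- min(as.integer(round(need_bp / length(take))),
                 as.integer(0.35 * slot_len))
    bg_lo <- as.integer(ceiling(0.6 * slot_len))
    bg_start <- slot_start[take] +
      sample(bg_lo:(slot_len - width - 10L), length(take), replace = TRUE)
    bg_list[[i]] <- tibble(chrom = slot_chrom[take], start = bg_start,
                           end = bg_start + width, family = te$family[i])
  }
  repeats <- bind_rows(rep_re, bg_list) |>
    arrange(.data$chrom, .data$start)

  # --- signal tracks ----------------------------------------------------
  dhs_track <- trim_overlaps(tibble(chrom = slot_chrom, start = peak_start,
                                    end = peak_end,
                                    value = round(dhs, 4))) |>
    select("chrom", "start", "end", "value")
  phylop_track <- tibble(chrom = slot_chrom, start = re_start, end = re_end,
                         value = round(phylop, 4))
  h_nt_track <- trim_overlaps(
    tibble(chrom = slot_chrom, start = pmax(tss - 1000L, 0L),
           end = pmin(tss + 1000L, chrom_len),
           value = round(h3k4me3_nt, 4))) |>
    select("chrom", "start", "end", "value")
  h_trt_track <- trim_overlaps(
    tibble(chrom = slot_chrom, start = pmax(tss - 1000L, 0L),
           end = pmin(tss + 1000L, chrom_len),
           value = round(h3k4me3_trt, 4))) |>
    select("chrom", "start", "end", "value")

  # --- genome sequence with planted windows -----------------------------
  genome <- NULL
  if (sequences) {
    genome <- setNames(vector("list", n_chroms), chroms)
    for (ci in seq_len(n_chroms)) {
      genome[[ci]] <- sample(DNA_BASES, chrom_len, replace = TRUE)
    }
    for (i in seq_len(n)) {
      sp_bases <- if (spacer[i] > 0) {
        sample(DNA_BASES, spacer[i], replace = TRUE)
      } else character(0)
      window <- c(substring(core[i], 1:HALF_LEN, 1:HALF_LEN), sp_bases,
                  substring(core[i], HALF_LEN + 1:HALF_LEN,
                            HALF_LEN + 1:HALF_LEN))
      if (strand[i] == "-") {
        window <- rev(chartr("ACGT", "TGCA", window))
      }
      ci <- match(slot_chrom[i], chroms)
      genome[[ci]][(re_start[i] + 1L):re_end[i]] <- window
    }
    genome <- vapply(genome, paste, character(1), collapse = "")
  }

  out <- list(truth = truth, training = training, peaks = peaks,
              genes = genes, expression = expression, seg7 = seg7,
              seg15 = seg15, repeats = repeats, dhs = dhs_track,
              phylop = phylop_track, h3k4me3_nt = h_nt_track,
              h3k4me3_trt = h_trt_track, genome = genome, pwm = wm,
              config = config, files = NULL)

  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) {
      ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      if (!ok) abort(paste0("cannot create output directory: ", outdir))
    }
    f <- function(x) file.path(outdir, x)
    files <- c(genome = f("genome.fa"), training = f("training.tsv"),
               peaks = f("peaks.bed"), chromhmm7 = f("chromhmm7.bed"),
               chromhmm15 = f("chromhmm15.bed"), repeats = f("repeats.bed"),
               dhs = f("dhs.bedgraph"), phylop = f("phylop.bedgraph"),
               h3k4me3_nt = f("h3k4me3_nt.bedgraph"),
               h3k4me3_trt = f("h3k4me3_trt.bedgraph"),
               genes = f("genes.bed"), expression = f("expression.tsv"),
               truth = f("truth.tsv"))
    if (sequences) write_fasta(genome, files["genome"])
    readr::write_tsv(tibble(id = sprintf("t%03d", seq_along(training)),
                            core20 = training), files["training"])
    write_bed(tibble(chrom = peaks$chrom, start = peaks$start,
                     end = peaks$end, name = peaks$name,
                     score = peaks$density, strand = ".",
                     summit = peaks$summit),
              files["peaks"])
    write_bed(seg7 |> dplyr::rename(name = "state"), files["chromhmm7"])
    write_bed(seg15 |> dplyr::rename(name = "state"), files["chromhmm15"])
    write_bed(repeats |> dplyr::rename(name = "family"), files["repeats"])
    write_bedgraph(dhs_track, files["dhs"])
    write_bedgraph(phylop_track, files["phylop"])
    write_bedgraph(h_nt_track, files["h3k4me3_nt"])
    write_bedgraph(h_trt_track, files["h3k4me3_trt"])
    gene_bed <- tibble(chrom = genes$chrom,
                       start = ifelse(genes$strand == "+", genes$tss,
                                      pmax(genes$tss - 1999L, 0L)),
                       end = ifelse(genes$strand == "+",
                                    pmin(genes$tss + 2000L, chrom_len),
                                    genes$tss + 1L),
                       name = genes$gene_id, score = 0L,
                       strand = genes$strand)
    write_bed(gene_bed, files["genes"])
    readr::write_tsv(expression, files["expression"])
    readr::write_tsv(truth, files["truth"])
    out$files <- files
  }
  out
}
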