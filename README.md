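# p53re

Spacer-aware discovery of p53 response elements (p53REs) and analysis of
how their sequence content interacts with chromatin context.

## The problem

The p53 response element is two `RRRCWWGYYY` decamer half-sites (R =
purine, W = A/T, Y = pyrimidine) separated by a short spacer. After a
stress such as DNA damage, p53 occupies thousands of such sites
genome-wide, and occupancy and downstream transactivation depend jointly
on the element's similarity to the consensus and on its chromatin context
(accessibility, H3K4me3, chromatin state, transposable-element origin,
evolutionary conservation). `p53re` is for analysts who have ChIP-seq peak
tables plus the usual context tracks and want to run that integrative
analysis as a single reproducible pipeline — and for anyone who wants to
validate the machinery on a fully synthetic study first.

## The model in brief

A position weight matrix is built from validated 20-nt p53RE cores with a
background-weighted pseudocount κ:

    p[b,j] = (c[b,j] + κ·π[b]) / (n + κ),    w[b,j] = log2(p[b,j] / π[b])

and a core scores `Σⱼ w[xⱼ,j]` (bits). The scanner makes **eight** scoring
attempts at every position — spacers 0–3 nt × both strands — reducing each
20–23-nt window to a 20-nt core by concatenating its first and last 10 nt,
prefiltering on ≥3 of the 4 consensus core C/G bases (C at core positions
4 and 14, G at 7 and 17), and reporting per position the surviving
candidate with the shortest spacer (ties: larger score, then `+` strand).
Each peak is then assigned the element nearest its summit; elements are
annotated with 7-state chromatin state (15-state fallback; repetitive
states excluded), nearest TSS, mean PhyloP over the 20 core bases, DHS,
and repeat family; and the stratified statistics (PWM-score deciles,
group-mean regressions, fold-change classes up FC > 1.2 / down FC < 0.8,
Cochran–Armitage trend test, binomial TE-family enrichment with BH
correction) are computed on top.

## Worked example

Everything runs off a seeded synthetic study, so the numbers below are
exactly reproducible:

```r
library(p53re)

sim <- generate_study(simulation_config(seed = 7, n_chroms = 2L,
                                        chrom_length = 100000L,
                                        n_res = 200L))
res <- scan_sequence(sim$genome, sim$pwm, threshold_frac = 0.7)
ann <- annotate_peaks(sim$peaks, res, sim$seg7, sim$seg15,
                      genes = sim$genes, phylop = sim$phylop,
                      dhs = sim$dhs, repeats = sim$repeats)
summ <- summarize_study(ann, repeats = sim$repeats,
                        genome_bp = sum(nchar(sim$genome)))
summ
#> <p53_summary>
#>   peaks: 200; with canonical RE: 194 (97.0%)
#>   TE overlap: 56 (28.0%)
#>   decile-mean regressions:
#>     density ~ pwm        slope    2.977  r^2 0.922
#>     density ~ dhs        slope  -60.581  r^2 0.870
#>     density ~ phylop     slope  -11.886  r^2 0.191
```

194 of the 200 simulated peaks carry a canonical element; occupancy (peak
density) rises with element strength across PWM deciles (positive slope,
r² = 0.92), while pre-existing accessibility (DHS) and conservation
(PhyloP) fall with it (negative slopes) — the planted content-vs-context
couplings, recovered end to end. Individual pieces are available too:

```r
glance(summ$reg_objects$density_vs_pwm)
#> # A tibble: 1 × 4
#>   r.squared slope   p.value  nobs
#> 1     0.922  2.98 0.0000105    10

autoplot(summ$deciles, "mean_density")   # decile trend
plot_spacer_frequencies(summ$deciles)    # spacers concentrate in weak deciles
plot_te_enrichment(summ$te_enrichment)   # retroviral families enriched
```

`run_pipeline()` drives the same stages from files (FASTA, BED, bedGraph,
TSV; see `pipeline_config()` / a YAML config) and writes `res.bed`,
`annotated.tsv`, `decile_table.tsv`, `state_summary.tsv`,
`regressions.tsv`, `te_enrichment.tsv` and a run manifest with per-stage
record counts.

See `vignettes/p53re-methods.Rmd` for the full model description, the
design decisions and the generator's assumptions.

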