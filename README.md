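# medipdiff

Differential DNA methylation analysis for two-colour MeDIP promoter tiling
arrays, with the validation-arm statistics that typically accompany such
studies in metabolic programming research.

## What it is for

MeDIP-chip experiments immunoprecipitate methylated DNA with an
anti-5-methylcytosine antibody and hybridise the enriched (MeDIP) and total
(Input) channels to a promoter tiling array — probes covering roughly
−1,300 to +500 bp around each transcription start site. `medipdiff` is for
analysts who need the full downstream pipeline for a two-group comparison
(e.g. offspring of high-fat-diet vs control-diet dams, three arrays per
group), plus the wet-lab validation statistics, in one tested package:

- per-probe, per-sample enrichment `r = log2(MeDIP/Input)`;
- sliding-window (750 bp) peak detection on the group-mean track: each
  probe's window is scored `−log10 p` by a one-sided Kolmogorov–Smirnov
  test against the array-wide distribution; peaks are runs of ≥ 2 probes
  scoring ≥ 2, and peaks within 500 bp are merged;
- the region-level differential statistic
  `M′ = mean r(treatment) − mean r(control)` over member probes and
  samples, with the two-criterion filter (a group median ≥ 0.3 with
  direction from the sign of M′; at least half of member probes with
  replicate CV ≤ 0.8 in both groups) yielding differential enrichment
  peaks (DEPs);
- CpG-density promoter classes (HCP / ICP / LCP) from windowed CpG
  observed/expected ratio and GC fraction, and DEP tallies by direction,
  class and chromosome;
- bisulfite-sequencing-PCR clone analysis: per-CpG methylation calls,
  conversion-efficiency QC, site/region/subject-level ratios, lollipop
  grids;
- metabolic statistics: HOMA-IR, OGTT trapezoidal AUC, comparative-Ct
  (2^−ΔΔCt) relative expression, two-way factorial ANOVA
  (maternal diet × offspring diet), Welch t from summary statistics.

A fully seeded synthetic-data generator emulates the study design — two
groups × three replicates, class-targeted promoter sequences, planted
hyper-/hypomethylated regions with chosen effect sizes, bisulfite clones,
factorial phenotypes — so every step can be validated against known truth.
See the methods vignette (`vignettes/medip-differential-methylation.Rmd`)
for the model, the design decisions and their rationale.

## Worked example

Simulate a 500-promoter array (≈ 4,000 probes) with 20 planted DMRs of
effect 1.5 log2 units, run the pipeline, and compare against the planted
truth:

```r
library(medipdiff)

set.seed(20)
planted <- data.frame(promoter = sample(500, 20),
                      direction = rep(c("hyper", "hypo"), 10), effect = 1.5)
cfg <- sim_config(n_promoters = 500, planted_dmrs = planted, seed = 20)
proms  <- gen_promoter_set(cfg)
design <- gen_array_design(proms$promoters, cfg)
expt   <- gen_medip_experiment(design, cfg)

res <- run_medip_pipeline(expt$intensities, design,
                          promoters = proms$promoters,
                          sequences = proms$sequences)
print(res$tally)
#> Differential enrichment peaks: 20 total (10 hyper, 10 hypo)
#>   hyper by CpG class: HCP 5 (50.00%), ICP 3 (30.00%), LCP 2 (20.00%)
#>   hypo by CpG class: HCP 5 (50.00%), ICP 5 (50.00%), LCP 0 (0.00%)

head(as.data.frame(res$deps)[c("chrom", "start", "end", "n_probes",
                               "mprime", "direction", "gene_ids",
                               "cpg_class")], 4)
#>   chrom   start     end n_probes    mprime direction   gene_ids cpg_class
#> 1 chr04  521300  521570        2 -1.928465      hypo gene_00180       ICP
#> 2 chr03 1063220 1064370        6  1.898334     hyper gene_00363       ICP
#> 3 chr03  945220  946370        6 -1.722125      hypo gene_00323       ICP
#> 4 chr03 1311020 1312170        6  1.712181     hyper gene_00447       HCP

ev <- evaluate_recovery(res$deps, expt$truth)
sprintf("recall %.3f  precision %.3f  direction %.3f", ev$recall,
        ev$precision, ev$direction_accuracy)
#> "recall 1.000  precision 1.000  direction 1.000"
```

All 20 planted regions are recovered with the correct direction, and each
DEP's `mprime` estimates the planted ±1.5 effect. The tally percentages
are per direction (counts/direction total × 100).

Validation-arm statistics work the same way from synthetic or real inputs:

```r
amp <- synthetic_amplicon(301, 30)   # 301-bp amplicon, 30 CpGs
cs  <- gen_bsp_clones(amp, meth_profile = 0.6, n_subjects = 2,
                      clones_per_subject = 10, seed = 2)
mc  <- qc_filter(call_clones(cs))
methylation_ratio(mc, "region")
#> 0.633
cat(lollipop_report(mc)[1:2], sep = "\n")
#> subject01_clone01      ●○●●○○●○●●●●○●●○○●●●○●○●●●●●○●
#> subject01_clone02      ●○●○●●●○●●●○○●○●○●●●●●●●●●●●○○

ph <- gen_phenotypes(seed = 3)
ph$homa <- homa_ir(ph$fasting_glucose, ph$fasting_insulin)
twoway_anova(ph$homa, ph$maternal_diet, ph$offspring_diet)
#> Two-way factorial ANOVA (balanced)
#>                ss df       f          p
#> A         23.5532  1  37.899 4.3002e-07
#> B         85.2192  1 137.123 7.7891e-14
#> A:B        7.2218  1  11.620 1.6216e-03
#> Residuals 22.3732 36      NA         NA
```

Here both diet factors and their interaction shift HOMA-IR, as planted in
the default phenotype means.

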