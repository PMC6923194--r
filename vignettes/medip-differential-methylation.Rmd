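---
title: "Differential methylation from MeDIP promoter tiling arrays: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential methylation from MeDIP promoter tiling arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medipdiff)
```

# The measurement and the model

MeDIP-chip quantifies DNA methylation by immunoprecipitating methylated
genomic fragments with an anti-5-methylcytosine antibody and co-hybridising
the enriched material (MeDIP channel) and total genomic input (Input
channel) to a tiling array. On a promoter array, probes tile a window
around each transcription start site — here ~1,300 bp upstream to 500 bp
downstream, strand-aware — and the quantity of interest per probe and
sample is the log2 enrichment

$$ r_{ps} = \log_2 \frac{\mathrm{MeDIP}_{ps}}{\mathrm{Input}_{ps}}. $$

`medipdiff` implements the complete downstream analysis for a two-group
design (a treatment group, by default labelled HF-CON, against a control
group, CON-CON, with three replicates each):

1. **Sliding-window peak detection** (`window_score()`, `find_peaks()`,
   `merge_peaks()`). For every probe, the probes whose midpoints lie within
   375 bp (a 750-bp window) on the same chromosome form its window. The
   window's group-mean enrichment values are compared against the
   array-wide distribution with a one-sided two-sample Kolmogorov–Smirnov
   test (alternative: window stochastically greater), and the probe is
   scored $-\log_{10} p$ using the classic one-sided asymptotic tail
   $p = \exp(-2 D^2 nm/(n+m))$. Peaks are maximal runs of at least two
   consecutive probes scoring at least 2 (ties included), and peaks within
   500 bp of each other are merged to a fixed point.
2. **Differential scoring and filtering** (`region_mprime()`,
   `filter_deps()`). A candidate region's differential statistic is
   $$ M' = \overline{r}_{\text{treatment}} - \overline{r}_{\text{control}}, $$
   the unweighted arithmetic mean of member-probe enrichment over each
   group's samples. A region is kept as a differential enrichment peak
   (DEP) when (i) at least one group's median member enrichment is
   $\ge 0.3$ and $M' \neq 0$ — positive $M'$ is a hypermethylated DEP,
   negative a hypomethylated DEP — and (ii) in each group separately at
   least half of the member probes have an across-replicate coefficient of
   variability (SD/mean of the linear MeDIP/Input ratio) of at most 0.8.
3. **CpG-density promoter classes** (`classify_promoter()`). Promoters are
   classified from 500-bp windows slid at 5-bp steps (plus a final window
   flush with the sequence end): HCP if some window has CpG
   observed/expected ratio > 0.75 *and* GC fraction > 0.55; LCP if no
   window reaches ratio 0.48; ICP otherwise.
4. **Validation-arm statistics**: bisulfite-clone methylation calls and
   ratios with conversion QC (`call_clones()`, `methylation_ratio()`,
   `qc_filter()`), comparative-Ct relative expression (`ddct()`), HOMA-IR
   (`homa_ir()`), OGTT trapezoidal AUC (`ogtt_auc()`), and two-way
   factorial ANOVA (`twoway_anova()`).

# Decisions where the method description is silent

Several components of the published NimbleScan-style pipeline are not fully
specified anywhere public; the package makes each choice explicit,
documents it, and keeps it swappable.

**The per-window test statistic.** The window size (750 bp), probe-count
minimum (2), score cutoff ($-\log_{10} p \ge 2$) and merge distance
(500 bp) are stated parameters of the procedure, but the per-window test is
vendor-internal. We use the one-sided two-sample KS test of the window
against the array-wide distribution, the statistic family used by ACME-type
tiling scorers; it is isolated inside `window_score()` so a one-sided
Wilcoxon (or anything else mapping a window to $-\log_{10} p$) can replace
it without touching peak assembly. Scores are computed on the **group-mean
track**; whether the original scored each sample separately and intersected
is unstated, and group-mean scoring is the documented default.

**Candidate regions from two one-group callers.** A one-group peak caller
only finds regions *high* against the array background. Hypermethylation
candidates therefore come from peaks in the treatment track and
hypomethylation candidates from peaks in the control track; the two lists
are unioned (overlapping candidates fused) before filtering, and direction
is assigned from the sign of $M'$. This reading also explains why the
filter's criterion 1 requires only "one of the two groups" to clear the
median threshold.

**A symmetric direction rule.** The filter criterion as printed ("$M' > 0$")
describes only the hypermethylated case; since the study reports
hypomethylated DEPs as well, the rule is implemented symmetrically:
direction is the sign of $M'$, and criterion 1's median test applies to the
better of the two groups. Similarly, criterion 2's "may have" is read as
"must have" — as a permission it would filter nothing.

**Medians and means.** "Average" in $M'$ is the unweighted mean over all
member-probe × sample values. The criterion-1 median is taken over all
member-probe × within-group-sample enrichment values, with the usual
midpoint convention for even counts. The median could alternatively be
taken over per-probe group means; at three replicates the two differ little,
and the choice is recorded here rather than silently embedded.

**No between-array normalisation by default.** The original description
names none. `log_ratio(center_medians = TRUE)` provides optional per-sample
median-centring behind a flag, default off.

**Classifier thresholds.** The HCP/ICP/LCP thresholds (0.75/0.55, 0.48,
500-bp window, 5-bp step) follow the widely used Weber-style scheme the
study cites; all four are parameters of `classify_promoter()`. N bases are
excluded from all counts and windows with more than 10% N are skipped;
the reverse strand is not scanned separately because CpG is its own
reverse complement and GC content is strand-symmetric.

**Promoter annotation of merged regions.** A DEP spanning probes of several
promoters carries all their gene ids (so unique annotated genes can number
fewer than DEPs); its CpG class is that of the promoter contributing most
member probes. The original's exact DMR-to-gene rule is unstated; this is a
documented choice, not a claim about the original.

# The synthetic-data generator

The generator (`sim_config()`, `gen_promoter_set()`, `gen_array_design()`,
`gen_medip_experiment()`, `gen_bsp_clones()`, `gen_phenotypes()`) exists to
give the pipeline inputs with known truth. It emulates the study design —
two groups × three replicates, promoters spanning −1,300..+500 bp of TSSs
on multiple chromosomes with alternating strand, planted hyper- and
hypomethylated regions — not the physics of hybridisation.

**Signal model.** No intensity distribution is published for this assay;
the model here is a deliberate stand-in, chosen as the simplest one under
which $M'$ and the replicate CV are well defined. Each probe draws a
baseline log2 enrichment $b_p \sim N(\mu_{\text{base}}, \sigma^2)$
(defaults $\mu_{\text{base}} = 0.5$, so unplanted promoters straddle the
0.3 median threshold realistically, and $\sigma = 0.3$), shared by both
groups. A planted region raises all of its promoter's probes by `effect`
log2 units *in the group where the region is methylated*: the treatment
group for hyper regions, the control group for hypo regions. Both
directions therefore produce a callable peak in the corresponding group
track, and the region's expected $M'$ is $+\text{effect}$ or
$-\text{effect}$; a pure subtraction in the treatment group would make
hypomethylated regions invisible to any one-group peak caller. Planted
regions must be covered by at least two probes, or the generator errors
(the caller requires two).

**Replicate noise.** Per replicate, the linear MeDIP/Input ratio is the
group-level $2^{\text{enrichment}}$ times unit-mean lognormal noise. The
requested `replicate_cv` is the *expected sample CV across replicates*: a
sample CV from three lognormal draws underestimates the population CV
substantially (by ~30% at CV 0.8), so the generator solves numerically for
the lognormal scale whose expected $n$-replicate sample CV equals the
target, using a fixed panel of normal deviates so the calibration is
deterministic. The Input channel is lognormal around a fixed brightness
(meanlog $\log 1000$, sdlog 0.2); because the per-sample ratio is exact,
Input noise cancels from MeDIP/Input and both channels are strictly
positive by construction. The noise has unit mean on the linear scale, so
its (negative) mean on the log scale is identical in both groups and
cancels exactly from $M'$ — the estimator is unbiased by construction, and
the Monte-Carlo tests confirm it.

**Sequences by target class.** Promoter sequences are sampled from a
controlled dinucleotide model — bases drawn i.i.d., every accidental CG
broken, then CG dinucleotides planted at a class-specific density (HCP
~0.105/bp on a GC-rich background, ICP ~0.034/bp, LCP ~0.002/bp). Each
emitted sequence is verified with `classify_promoter()` and resampled on
failure (bounded retries, then an explicit error), so generator/classifier
agreement is structural. An unreachable request — parameters implying, say,
an observed/expected ratio no 500-bp window can attain at the required GC —
surfaces as that explicit failure rather than silent drift.

**Scales.** The default desk scale is 500 promoters × 8 probes (50-bp
probes at 220-bp spacing across the 1,800-bp window) ≈ 4,000 probes, so a
full simulated experiment runs in well under a second; the published scale
(22,327 promoters, ~180,000 probes) is a configuration away and is
exercised as a geometry check in the tests. Probe spacing of 220 bp was
fixed once so that a 750-bp window holds 3 interior probes — enough for the
KS score to clear the cutoff over a planted region while keeping the
false-peak rate low — and is not tuned per experiment.

**Clones and phenotypes.** Bisulfite clones apply the chemistry literally:
CpG cytosines stay C with their site probability, non-CpG cytosines convert
to T with probability `conversion_rate` (independent Bernoulli failures,
the standard QC assumption). Phenotypes are drawn from 2×2 cell-mean tables
with normal within-cell noise; the default means encode the qualitative
pattern of a maternal/offspring high-fat-diet study (offspring-diet effect
on weight, both-diet effects on glycaemia, an interaction on insulin) at
realistic 8-week mouse magnitudes, and OGTT series are sampled at 0, 30,
60 and 120 minutes.

**What the generator does not model** — and hence what passing tests do not
show about real data: dye bias, spatial artifacts, probe-sequence effects,
fragment-level MeDIP enrichment kinetics, CpG-density-dependent antibody
efficiency, and between-array scale differences. Recovery rates on this
synthetic model are a check of the pipeline's logic, not a sensitivity
claim for any real array.

# Statistical conventions in the validation arm

* **Subjects, not clones, are the unit** for group comparisons of
  methylation: clones within a mouse are pooled
  (`methylation_ratio(level = "subject")`) before any ANOVA, matching a
  design with ten mice per group. Ambiguous calls are excluded from
  denominators rather than counted unmethylated, avoiding downward bias;
  all-ambiguous strata are reported missing, never zero.
* **HOMA-IR** uses the standard Matthews definition,
  glucose (mmol/L) × insulin (µIU/mL) / 22.5, since the study cites but
  does not print a formula.
* **OGTT AUC** is the total trapezoidal AUC over 0–120 min; the incremental
  variant (baseline rectangle subtracted) sits behind a flag because the
  cited computation is ambiguous between the two.
* **2^−ΔΔCt** anchors to the control-group mean ΔCt, making the calibrator
  group's geometric-mean fold exactly 1 — an identity the tests assert to
  machine precision.
* **Two-way ANOVA** uses the textbook orthogonal partition on balanced
  designs (via `stats::anova`) and Type-II sums of squares (via
  `car::Anova`) otherwise; a zero-variance response reports NA F and p
  rather than erroring. Null calibration (rejection rates near 0.05 per
  term at n = 10/cell) and power for a 2-SD main effect are checked by
  simulation in the test suite.
* **Welch t from summaries** (`t_from_summary()`) accepts SD or SEM
  dispersion. Published group summaries of the form "mean ± SEM" with
  n = 20/group do not reproduce a p < 0.01 by a summary t test (t ≈ 2.3);
  either the printed dispersions are SDs or the n differs. The function
  supports both readings and the package pins no result to that ambiguity.

# Numerical notes

* Coordinates are 0-based half-open internally and BED-style on disk; the
  TSV probe table is the authoritative design format and round trips are
  tested. Positivity of intensities is enforced at construction and read
  time, so enrichment is finite everywhere.
* The one-sided KS score is computed from strictly-less counts against the
  pooled array distribution; it agrees with `stats::ks.test`'s one-sided
  statistic, including under ties, and windows with fewer than two probes
  score 0. Scores at exactly the cutoff are kept ($\ge$, not $>$).
* Peak merging measures the genomic gap between peak boundary coordinates
  (not probe counts); with sorted input a single left-to-right pass reaches
  the fixed point, making the operation idempotent — both properties are
  tested against a repeated-pairwise-merge oracle.
* Determinism: every generator runs under `withr::with_seed` from the
  configuration seed, so equal configurations give bit-identical output.

# Problem sizes used by the checks

The test suite and the acceptance script run: 1,000 random score vectors
(length ≤ 50) against the peak-caller enumeration oracle; 200 randomized
peaks against the brute-force filter predicate; 50 seeded synthetic
experiments at 500 promoters / ~4,000 probes / 20 planted DMRs (effect 1.5,
noise SD 0.3, 3 vs 3) for recovery; 1,000 random 500-mers for the CpG
ratio oracle; 1,000 clones per methylation level for the BSP binomial
check; and 2,000 null simulations (n = 10/cell) for ANOVA calibration.
These sizes were chosen so the whole battery completes in a few minutes on
one core while leaving Monte-Carlo error well inside the asserted bounds.

# Known limitations

* The signal model is additive Gaussian on log2 enrichment with lognormal
  replicate noise; real MeDIP-chip data show intensity-dependent variance
  and CpG-density-dependent enrichment that are not modelled.
* The headline DMR counts of the motivating study derive from deposited
  array data and a vendor scoring routine; they are not reproducible at
  desk scale and the package does not claim to reproduce them — it
  reproduces the *procedure* and the in-paper arithmetic.
* The promoter classifier reproduces a Weber-style scheme with published
  defaults; the study's own thresholds are unpublished, so its exact
  HCP/ICP/LCP partition is not an acceptance claim.
* Pathway/GO enrichment of DMR genes requires an external annotation
  service and is out of scope.
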