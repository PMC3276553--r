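---
title: "Epigenetic instability indices: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epigenetic instability indices: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epistab)
```

## The problem

Carcinogenesis is accompanied by two distinct waves of DNA methylation
change at stem-cell-associated loci. Promoters of Polycomb group target
genes (PCGTs) — loci bound by PRC2 components or carrying H3K27me3 in
embryonic stem cells, normally unmethylated in differentiated tissue —
gain methylation very early, before any morphological abnormality.
Conversely, CpGs that are highly methylated in embryonic stem cells and in
normal tissue (MESC CpGs) progressively lose methylation as lesions
advance from pre-dysplastic tissue through dysplasia to invasive cancer
and metastasis. The loss, unlike the gain, tracks malignancy, which makes
a per-tumour summary of MESC demethylation a candidate prognostic
statistic.

`epistab` implements that summary — the Epigenetic Instability Index
family — together with the locus-set derivation, quality control,
differential methylation, enrichment, and outcome analyses around it, on
beta-value arrays of the Infinium 27k type (one beta in $[0,1]$ per CpG
per sample).

## Locus sets

**MESC CpGs** are derived from strand-resolved whole-genome bisulfite
read counts. The methylation level of a strand is $C/(C+T)$; the overall
level is the mean of the two strand levels (or the covered strand's level
when one strand has no reads). A site qualifies when the total C+T count
over both strands is at least `coverage_min` (default 5) and the overall
level strictly exceeds `level_min` (default 0.8). The coverage rule has a
stricter per-strand reading — at least `coverage_min` on *each* strand —
exposed as `derive_mesc(per_strand = TRUE)`; the total-across-strands rule
is the default because it is the operational form of the published
definition. The derivation is monotone: raising either threshold can only
shrink the set.

**PCGT CpGs** and array manifests are loaded from delimited tables
(`load_locus_table()`, `read_manifest()`), with duplicate probe rows
collapsed and counted. **PMD membership** (partially methylated domains)
is resolved by genomic overlap against BED intervals with conventional
0-based half-open semantics: a probe at 1-based position $p$ is inside
$[\mathrm{start},\mathrm{end})$ iff $\mathrm{start}+1 \le p \le
\mathrm{end}$.

## Beta values and quality control

Beta is computed exactly as
$\beta = \max(M,0)\,/\,[\max(M,0)+\max(U,0)+100]$ from background-
corrected methylated/unmethylated intensities, so $\beta \in [0,1)$.
Sample QC excludes arrays whose bisulfite-conversion control intensity is
*strictly below* 4000 (a sample at exactly 4000 is retained — the
published rule is a strict inequality). Total-intensity outliers
(annotation column `total_intensity`, screened at median $\pm 3 \times$
IQR across samples) are flagged but excluded only on request, and a
per-sample bimodality coefficient of the beta distribution is reported
for manual review without ever auto-excluding: visual histogram
inspection cannot be faithfully automated, so the package reports rather
than decides. Probe QC keeps probes detected above background
(detection $p < 0.05$) in at least 95% of samples; both numbers are
conventional Infinium practice, stated here as package defaults rather
than facts about any published cohort. Missing betas propagate as
missing; per-CpG analyses use pairwise-complete samples.

## Differential methylation and skew

`fit_cpg_models()` fits, per probe, an ordinary least squares model of
beta on case/control status plus covariates — the standard EWAS
orientation, with the effect read as the covariate-adjusted beta
difference and a two-sided $t$ test on the status coefficient. Chip is
entered as a categorical covariate; this is the simpler of the two
published batch-handling options (the alternative being an
empirical-Bayes location/scale adjustment) and is the package default.
No multiple-testing correction is applied by default because the
downstream calls use stage-specific raw-p thresholds (0.1 for the
pre-dysplasia and dysplasia comparisons, 0.001 for invasive cancer);
Benjamini-Hochberg reporting is available behind `fdr = TRUE`. The
hyper/hypo skew within a locus category is tested with the exact
two-sided binomial test against 0.5.

## Enrichment

All enrichment uses the two-tailed Fisher exact test with the sample
odds ratio $ad/bc$, the full array (after QC) as the reference universe,
and a Woolf log-OR normal 95% CI. The published analyses do not state a
CI method; Woolf with a Haldane–Anscombe 0.5 correction on zero cells
(flagged in the result) was chosen as the conventional closed form.
Tables with an empty margin are flagged degenerate and carry no p-value.

Two baseline-aware variants control for starting methylation:

* `baseline_matched_enrichment()` restricts the universe to probes
  unmethylated in normals (mean $\beta < 0.2$) for hypermethylation, or
  methylated (mean $\beta > 0.4$) for hypomethylation, and selects probes
  whose case mean moves strictly in the stated direction. The selection
  can additionally be intersected with a supervised significance list
  (`sig_probes`); the plain mean-movement form is the default because it
  is the variant defined purely by the baseline criterion, and the gated
  form is a strict subset of it.
* `control_matched_enrichment()` compares target probes against
  non-target probes whose normal mean beta lies in the same band, so that
  any enrichment is demonstrably independent of baseline methylation.

## The instability indices

Betas are discretized into three states: unmethylated (0) for
$\beta < 0.25$, hemimethylated (1) for $0.25 \le \beta \le 0.7$ (both
boundaries inclusive), methylated (2) for $\beta > 0.7$. A CpG is
**stable** when all non-missing normal samples (at least 2) share one
state; its normal mean beta is stored as the reference point. A
**transition** is called in a tumour sample iff the tumour state differs
from the stable state *and* $|\beta_t - \bar\beta_N| \ge 0.10$. The 10%
buffer makes calls robust to the threshold placement: a shift from 0.71
to 0.69 trespasses a boundary but is not a biological change. The buffer
is measured against the mean beta across normals — stability is defined
on the normal cohort, so its mean is the natural reference — with the
minimum distance to any single normal available behind a flag.

Four indices are computed per tumour sample, one per transition type,
each the fraction of stable CpGs with the corresponding baseline state
(non-missing in that sample) that transition:

* `f_0_gain` — $0 \to 1/2$ (methylation gain from unmethylated);
* `f_1_gain` — $1 \to 2$; `f_1_loss` — $1 \to 0$ (shared denominator,
  so their sum is at most 1);
* `f_2_loss` — $2 \to 0/1$, the **Demethylation Instability Index
  (DeMI)**.

Restricted to locus sets these give the three stem-cell indices:
PCGT $0 \to 1/2$, MESC $1 \to 0$ and MESC $2 \to 0/1$ (the prognostic
DeMI; very few PCGT CpGs are methylated in normal tissue, so the other
PCGT indices are usually undefined). The **combined DeMI** pools the
$1\to0$ and $2\to0/1$ transitions over the pooled state-1/2 denominator
(a micro-average, keeping the statistic a fraction of CpGs rather than a
mean of two fractions). Zero-denominator indices are reported as `NA`,
never as 0 — coercing them to 0 would bias downstream survival models
toward stability. `hypo_frequency()` ranks stable MESC CpGs by the
fraction of tumours with a qualifying demethylation transition,
descending, ties broken alphabetically by probe id for determinism.

```{r example}
st <- data.frame(probe_id = paste0("m", 1:4), stable_state = 2L,
                 normal_mean_beta = c(0.80, 0.85, 0.90, 0.75),
                 n_normals = 3L)
class(st) <- c("stable_set", "data.frame")
tumour <- setNames(c(0.68, 0.73, 0.20, 0.69), st$probe_id)
# probe 1: state 1, |delta| = 0.12 -> transition; probe 2: still state 2;
# probe 3: state 0, |delta| = 0.70 -> transition; probe 4: blocked by buffer
epi_indices(tumour, st)$demi   # 2/4
```

## Outcome analyses

Survival association uses Cox proportional hazards (`survival::coxph`)
on the continuous index, standardized by default so the hazard ratio is
per SD; a tertile-contrast mode (`tertile = TRUE`, upper vs lower,
middle dropped) matches the Kaplan–Meier presentation, and both modes
label their scale in the output. Published multivariate models included
the clinical factors univariately associated with survival;
`screen_covariates()` reproduces that screen at a configurable alpha and
logs every keep/drop decision rather than deciding silently. Tertiles
use ranked splits with ties broken by input order (logged), which keeps
group sizes deterministic under heavy ties. The metastasis-vs-primary
shift uses the one-tailed Wilcoxon rank-sum test (exact for up to 25
untied values per group, normal approximation with continuity correction
otherwise), and discrimination is quantified by the rank-based AUC with a
DeLong 95% CI.

TET analysis correlates each hypomethylated CpG's betas with per-sample
TET mRNA expression — Spearman by default, because RT-PCR expression
scales are arbitrary; Pearson behind a flag — calls a CpG significantly
anti-correlated when $\rho < 0$ and $p < 0.05$ (alpha configurable, the
published analysis states none), and tests MESC enrichment among the
anti-correlated set against the remaining hypomethylated CpGs.

## The synthetic cohort generator

`sim_config()` + `simulate_*()` generate every input the pipeline
consumes, with planted ground truth emitted as a first-class truth table
so recovery tests never re-infer what was planted. The generator
emulates:

* beta-distributed betas per locus class (MESC near 0.85 with a
  hemimethylated subset near 0.5, PCGT near 0.08, other probes a
  low/mid/high mixture), precision `concentration = 200` (`Inf` for
  noise-free fixtures);
* a monotone stage gradient of MESC loss probabilities, default
  0.05/0.10/0.20/0.35 for before-dysplasia/dysplasia/cancer/metastasis —
  package defaults mirroring the qualitative published progression, not
  published rates;
* between-tumour heterogeneity: each case sample draws its own
  alteration probability from a Beta distribution around the stage value
  (precision `stage_dispersion = 6`), taken as stratified quantiles so
  the cohort mean sits exactly on the stage value. Real tumours vary
  widely in instability — this is what makes tertile survival analysis
  meaningful — and the stratification keeps planted-rate recovery exact
  in expectation;
* planted changes that always cross a state boundary by more than the
  buffer (gains move PCGT probes to mean 0.55, losses move MESC probes
  to mean 0.08), so with noise disabled the truth table is exactly
  recoverable;
* chip batch effects as logit-scale shifts (total spread
  `chip_shift = 0.15`) with 12 samples per chip;
* exponential survival with log hazard linear in standardized DeMI
  (default HR 1.8 per SD) and independent exponential censoring tuned to
  a 30% censoring fraction;
* TET expression linear in the per-sample demethylation burden plus
  Gaussian noise.

Cohort sizes default to 15 normals and 75/18/48/20 cases for the four
stages, the magnitudes of the corresponding published cohorts. What the
generator does **not** emulate: stromal/immune admixture (published
evidence implicates stroma in part of the MESC signal), HPV genotype
structure, probe-level detection failure patterns, raw intensity/idat
artefacts, and realistic between-probe correlation. Passing tests
therefore demonstrate that the statistics recover what the model plants
under array-like noise — not that any biological cohort will show these
effect sizes.

## Numerical choices and degenerate inputs

* Thresholds are applied exactly as written: state boundaries 0.25/0.7
  inclusive for the hemimethylated state, MESC level strictly > 0.8,
  bisulfite control strictly < 4000, buffer $\ge$ 0.10.
* Both-strand zero coverage is an error, not a 0/0 level; empty locus
  sets, empty enrichment margins, all-excluded QC, zero-event Cox fits
  and constant indices all raise structured, named conditions instead of
  propagating NaN.
* Determinism throughout: simulator outputs are byte-identical given a
  config, rankings break ties by id, tertiles by input order.

## Validation strategy and problem sizes

The test suite checks each statistic against an independent brute-force
oracle: Fisher p against full hypergeometric enumeration for every 2x2
table with universe up to 60, Wilcoxon exact p against complete
permutation enumeration up to 7 per group, binomial skew against doubled
tail sums, transition calling against a literal reimplementation of both
rules on a beta grid, and AUC against exhaustive pair concordance.
Recovery tests run at 2,000 probes with around 100 tumours per cohort
and 100 replicate cohorts of n = 300 for survival coverage — sizes at
which the binomial/Monte-Carlo error of the checked quantities is an
order of magnitude below the asserted tolerances. `scripts/acceptance.R`
re-runs the same computations end to end from a single seed and writes
the headline numbers as JSON.

## Known limitations

Per-CpG supervised tests are underpowered at realistic per-probe
alteration frequencies (a probe altered in 20% of cases moves its mean
by only a fifth of the full beta swing against a bimodal residual), so
stage-specific raw thresholds, not FDR control, drive the call lists —
as in the published analysis. The empirical-Bayes alternative to
chip-as-covariate batch handling is not implemented. Region-level
(DMR) calling, continuous (non-discretized) instability scores, and
PMD segmentation from WGBS are out of scope; PMDs are consumed as an
annotation table.
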