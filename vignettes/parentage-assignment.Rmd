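---
title: "Likelihood-based parentage assignment with reduced SNP panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Likelihood-based parentage assignment with reduced SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Black soldier fly breeding programs need pedigrees to run pedigree-based
selection, but individuals cannot be tagged and tracked in mass rearing.
Parentage assignment inverts the problem: genotype candidate parents and
offspring at a reduced panel of informative SNPs and reconstruct the
pedigree statistically. This vignette documents the models, parameter
choices and numerical decisions behind the package, and what its
simulation-based validation does and does not demonstrate.

## The likelihood model

All genotypes are biallelic and coded as the dosage of the alternate
allele (0/1/2, `NA` missing). At a locus with alternate-allele frequency
$p$, Hardy–Weinberg genotype probabilities are
$(q^2,\,2pq,\,p^2)$ with $q = 1-p$.

**Observation (mistyping) model.** A recorded call equals the true
genotype with probability $1-e$ and is otherwise a fresh draw from the
Hardy–Weinberg genotype distribution at that locus:
$P(g^{obs}\mid g^{true}) = (1-e)\,\mathbf{1}[g^{obs}=g^{true}] + e\,P_{HWE}(g^{obs})$.
This classical replacement model keeps the simulation and the inference
consistent: `corrupt()` corrupts simulated genotypes with exactly the
error process that `lod_single()`/`lod_pair()` marginalise over. The
default $e = 0.05$ reflects the error level typical of
genotyping-by-sequencing SNP data.

**Single-parent score.** For observed offspring $g_o$ and candidate $g_c$,

$$\mathrm{LOD} \;=\; \ln\frac{\sum_{t_c} P_{HWE}(t_c)\,P(g_c\mid t_c)\sum_{t_o} T_1(t_o\mid t_c)\,P(g_o\mid t_o)}{\big[\sum_{t_c} P_{HWE}(t_c)P(g_c\mid t_c)\big]\big[\sum_{t_o} P_{HWE}(t_o)P(g_o\mid t_o)\big]}$$

where $T_1(t_o \mid t_c)$ transmits one allele from the candidate by
Mendelian rules and draws the other from the population. Natural
logarithms are used throughout (the magnitudes of published critical
scores are consistent with either base; natural log is fixed and
documented here). With $e = 0$, opposing homozygotes give $-\infty$ —
the classical Mendelian exclusion; with $e > 0$ every score is finite.
The parent-pair score conditions on both candidates via the full
Mendelian transmission table. Per-locus tables over all observed-genotype
combinations are precomputed per panel, so scoring is a table lookup.
Every per-locus value is tested against an independently written
brute-force enumeration over true-genotype states (tolerance $10^{-10}$).

**A-LOD and missing data.** A candidate's assignment score is the sum of
per-locus LODs over loci where all genotypes involved are typed; missing
loci are skipped. An offspring typed at fewer than `min_typed_frac`
(default 50%) of the panel is not classifiable.

## Threshold calibration

A most-likely candidate is only *trusted* if its A-LOD clears a critical
threshold (C-LOD) calibrated by Monte Carlo (`calibrate()`), following
the convention established by the Cervus software family:

1. Simulate `n_offspring` (default 10,000) true parent pairs from the
   panel's allele frequencies; with probability `inbreeding_rate` the two
   parents are full sibs of each other (their offspring then has
   F = 0.25).
2. Build each offspring's candidate set: the true parent plus
   `n_candidates - 1` (default 46) relatives of the true parent —
   full sibs when `relatedness = 0.5`, unrelated individuals when 0.
   Candidate genotypes are resampled per offspring.
3. Apply typing (`prop_typed`, default 0.95) and mistyping (`e`) to all
   observed genotypes, score every candidate, and record the most-likely
   candidate's A-LOD and whether it is the true parent.
4. The C-LOD at confidence $\gamma$ is the smallest observed threshold
   $t$ such that among assignments with A-LOD $\ge t$ a fraction
   $\ge\gamma$ are true parents. If the criterion already holds with no
   threshold, the sentinel $-999.0$ is reported (complete separation);
   if no threshold attains it, $+999.0$ (underpowered panel). Because
   classification uses `a_lod >= c_lod`, the sentinels behave correctly
   with no special-casing.

Assignments then fall into four classes: `strict`
(A-LOD $\ge$ C-LOD$_{95\%}$), `relaxed` (between the two thresholds),
`unassigned_most_likely` (positive A-LOD below the relaxed threshold)
and `unassigned_not_most_likely` (no candidate with a positive A-LOD).
The trigger separating the two unassigned classes is not standardised
anywhere; the positive-A-LOD rule is this package's choice and is
stated here so downstream users can interpret the class counts.

**A deliberately hard relatives model.** Making *every* false candidate a
full sib of the true parent is the most pessimistic reading of
"candidates related with r = 0.5". Combined with 100% inbreeding (the
true parents also full sibs of each other), the kinship gap between the
true parent (0.375) and a false candidate (0.25) narrows enough that a
192-locus high-MAF panel sits almost exactly at the 95% accuracy
boundary — the strict C-LOD then flips between the $-999$ sentinel and a
finite value depending on the simulation seed. Tools that treat the
relatedness dial as "the two mates are related, candidates otherwise
unrelated" face an easier problem and report complete separation across
the whole inbreeding grid. At the default 0% inbreeding rate the two
formulations agree: the 192-SNP panel separates completely and all
assignments are strict.

## The synthetic population

`build_design()` reproduces the experimental structure: per colony and
family, four candidate mating pairs per breeding round; the first pair is
retained, sequenced, and parents both the next round's pairs and the two
sequenced larvae. Family lines are therefore maintained by strict
full-sib mating, and larval inbreeding follows the full-sib recurrence
$F_t = \tfrac14(1 + 2F_{t-1} + F_{t-2})$: 0, 0.25, 0.375 across the
three rounds. `expected_inbreeding()` computes F for any pedigree member
by memoised recursive kinship (equivalent to path counting) and the test
suite verifies both the recurrence values and the realised heterozygosity
deficit of simulated larvae.

Choices a scientist had to make where the design leaves freedom:

- **Founder allele frequencies** are uniform on a configurable MAF
  interval (default (0.05, 0.5]), with the minor allele assigned to
  reference or alternate at random. Real MAF spectra are not uniform,
  but the downstream analyses depend only on the panel's realised MAF
  tiers, which are filtered explicitly.
- **Retention** of "the" pair among the four candidates is by index
  (deterministic); in reality retention was phenotype-based, which is
  irrelevant to genotype structure.
- **Sexes** are labels within a pair; no sex chromosomes are simulated
  (the genome's seven chromosome-scale sequences are treated as
  autosomes).
- **Read depths**, when requested, are Poisson draws around marker-level
  lognormal means (default grand mean 20x, log-sd 0.3), mimicking the
  systematic coverage differences between reduced-representation loci
  that the depth filters act on.
- **Generation indexing**: founders are generation 0; the three breeding
  rounds produce larvae of generations 1–3.
- **Seeds**: every stage derives its own RNG stream from one root seed,
  so reruns are bit-identical and stages are insensitive to each other's
  draw counts.
- **Post-QC subsampling**: the study's quality control left 47 couples
  (19 + 28 by colony) and 75 larvae (23 + 52). `subsample_to_study()`
  reproduces those counts by seeded sampling, keeping only larvae whose
  parent couple is retained; the real attrition mechanism (sample-level
  QC) is otherwise represented only through the error model.

What the simulation does **not** emulate — and hence what passing tests
do not demonstrate about real data: linkage between loci (loci segregate
independently; the LD filter is exercised only by duplicated/correlated
fixtures), ascertainment bias in SNP discovery, depth-dependent genotype
likelihoods, null alleles or allele dropout structure beyond uniform
mistyping, between-colony divergence (colonies are simulated from the
same frequency spectrum, so simulated F_ST is ~0 rather than the weak
real differentiation), and laboratory batch effects.

## The filter cascade

`run_cascade()` applies, in a fixed order: monomorphic removal; markers
shared across colonies; sample missingness (≤30%), sample median depth
(1–27x), sample heterozygosity (0.14–0.61); marker MAF (≥0.3), minor
allele count (≥4), mean depth (15–75x), missingness (≤5%), SNP position
within the 40th–70th bp of its RAD locus (inclusive bounds), one SNP per
RAD locus (first by position), Hardy–Weinberg exact test (P ≥ 0.05,
pooled samples), trio Mendelian error rate (≤3%), and greedy windowed LD
pruning (r² > 0.5, 50-variant window sliding by 5). Statistics are
recomputed after every sample-removal step, each step's removals are
reported, and `NULL` thresholds disable a step without hiding it from
the report.

Decisions worth knowing:

- **LD windows are in variant counts**, not base pairs: the pruning
  semantics follow the common `--indep-pairwise 50 5 0.5` convention
  whose window argument counts variants. Ties (equal r²) remove the
  later-positioned member, making pruning deterministic.
- **The observed-heterozygosity marker filter is off by default**
  (`marker_max_obs_het = NULL`): the assignment pipeline deliberately
  retains maximally heterozygous markers, and an Ho ≤ 0.5 cut would
  decimate a high-MAF panel through sampling noise alone. Pass 0.5 to
  reproduce the population-statistics style of filtering.
- **The Hardy–Weinberg test is the exact conditional test** (summing the
  probabilities of all heterozygote counts no more probable than the
  observed one, given the minor-allele count), not the chi-square
  approximation — the per-family sample sizes this pipeline sees are far
  too small for the asymptotic test. It is verified against full
  enumeration for all configurations up to n = 20.
- **Mendelian filtering is per-marker** (error rate across evaluable
  trios, threshold 3%); no per-trio removal is done.
- **Idempotence and scale.** Re-running the cascade on its own output
  removes nothing *provided the surviving panel is large enough that
  per-sample statistics are stable* — the sample heterozygosity bounds
  are absolute numbers that were calibrated to a ~500-marker panel. On a
  panel of a few dozen markers, per-sample heterozygosity has a standard
  error of ~0.1 and fixed bounds of 0.14–0.61 will clip samples on
  re-entry. The test suite exercises idempotence at a realistic surviving
  panel size (several hundred markers).

## Marker informativeness

`locus_stats()` reports per-locus MAF, observed and expected
heterozygosity, their difference, nucleotide diversity, F_IS and PIC.
Conventions: nucleotide diversity at a variant site is expected
heterozygosity with the small-sample correction $2n/(2n-1)$ on the
allele count; $F_{IS} = 1 - H_o/H_e$, reported as 0 at monomorphic loci;
PIC uses the Botstein formula
$1 - \sum p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$. F_ST is the Weir–Cockerham
(1984) per-locus estimator with an unweighted mean across evaluable loci
— different estimators (e.g. AMOVA-based ones) differ by small constant
offsets, which matters when comparing numbers across tools.

Non-exclusion probabilities (`nonexclusion()`) are the probability that
a random unrelated candidate (or pair) is genotypically compatible with
a random offspring, computed under HWE with error-free genotypes — the
classical panel-power summary. The implementation uses the biallelic
closed forms (Jamieson & Taylor); an exhaustive enumeration over
genotype configurations is kept as a second route and as the oracle in
tests (agreement to $10^{-12}$). Multilocus values multiply per-locus
probabilities, assuming independent loci — which the LD-pruning step is
there to justify. Error-aware assignment power is handled by the
calibration simulation instead, so the two power summaries answer
different questions.

## Problem sizes used in validation

The packaged tests simulate the full 288-sample design with panels of
~50–500 loci, calibrate on 10,000 offspring with 47 candidates (the
analysis-scale configuration), and verify the filter cascade's
idempotence on an 8,000-locus input that leaves a ~370-marker panel.
The acceptance script runs two 10,000-offspring calibrations and the
full assignment of 75 larvae against 47 couples on 192- and 118-locus
panels. These sizes were chosen to match the study design where it is
pinned and to keep every statistic's Monte-Carlo error well inside the
tolerances asserted.

## Known limitations

- Relatedness between candidates and the true parent supports r = 0 and
  r = 0.5 (unrelated / full sib); intermediate kinship structures are
  not simulated.
- Only biallelic SNPs are handled; multiallelic records are skipped on
  input.
- The calibration assumes candidate sets of constant size; the study
  design's within-colony, within-generation restriction (12 couples per
  set) is applied at assignment time, while calibration conservatively
  uses the full 47-candidate pool.
- No multigenerational pedigree reconstruction or sibship inference:
  each offspring is assigned independently.
- Genotype likelihoods from low-coverage sequencing are out of scope;
  calls are hard genotypes plus the mistyping model.
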