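---
title: "Detecting runs of homozygosity and ROH islands with rohscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting runs of homozygosity and ROH islands with rohscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

rohscan implements a complete runs-of-homozygosity (ROH) workflow for
biallelic SNP-array genotypes of the OvineSNP50 kind: quality control of
PLINK text PED/MAP panels, consecutive-runs ROH detection, genomic
inbreeding from ROH (F_ROH) and from excess homozygosity (F_HOM), per-marker
incidence of common runs, ROH-island calling with population-sharing
classes, and a one-way breed-effect model on per-sample island SNP
proportions. A multi-breed genotype simulator with planted
identical-by-descent (IBD) segments provides exact ground truth, and every
stage is validated against it or against brute-force oracles.

## The model and its assumptions

A run of homozygosity is a contiguous stretch of homozygous genotypes in one
individual, evidence that both chromosome copies descend from a common
ancestor. Long runs indicate recent inbreeding (little recombination has
broken them up); short runs reflect ancient common ancestry. Summing run
lengths gives the genomic inbreeding coefficient

$$F_{ROH} = L_{ROH} / L_{AUTO},$$

the fraction of the SNP-covered autosome (length $L_{AUTO}$) lying in runs.
Regions where runs from many animals pile up — ROH islands — mark loci under
directional selection or strong drift.

All analyses operate on genotype *status* (homozygous / heterozygous /
missing); which allele is which is irrelevant and the PED reader's
allele-coding convention (reference = lexicographically smaller observed
allele) is arbitrary by design.

## Run criteria and their defaults

`roh_params()` carries the consecutive-runs criteria, with the conventional
50k-chip settings as defaults:

| parameter | default | meaning |
|---|---|---|
| `min_length_bp` | 1 Mb | minimum run span; excludes short LD-driven runs |
| `min_snps` | 30 | minimum markers per run |
| `max_het` | 1 | heterozygous calls tolerated inside a run |
| `max_missing` | 1 | missing calls tolerated inside a run |
| `min_density_bp_per_snp` | 100 kb | maximum average marker spacing in a run |
| `max_gap_bp` | 250 kb | maximum gap between consecutive genotyped members |

Three points the criteria leave open were fixed as follows and are part of
this package's operative definition:

* **Maximality and scan order.** The detector performs a greedy
  left-to-right scan per animal and chromosome: among all criterion-
  compliant windows it emits the one with the smallest start (ties: largest
  end), then resumes after its end, yielding maximal, non-overlapping runs.
  Heterozygous and missing markers may occur only strictly inside a run,
  never at its ends. A brute-force enumeration of every candidate window
  with the same selection rule is kept in the test suite as an independent
  oracle; the two agree exactly on hundreds of random chromosomes.
* **Budgets are independent.** One heterozygous *and* one missing call may
  co-occur in the same run (budgets of 1 each, not a shared budget).
* **Gap distance skips missing markers.** The 250 kb rule applies between
  consecutive *genotyped* members; a missing member does not reset the
  distance. Density is evaluated globally over the run
  (span / markers ≤ 100 kb), not locally.
* **Length bins are half-open**, lower-inclusive: [1,6), [6,12), [12,24),
  [24,48), [48,∞) Mb. The bin labels alone do not decide where 6 Mb exactly
  falls; lower-inclusive was chosen and is tested.

One consequence of maximality worth knowing: *relaxing* `max_het` or
`max_gap_bp` can merge two formerly separate runs into one, so the run
*count* is not monotone in those thresholds (total detected length almost
always is). Count-monotonicity does hold for the pure admissibility
thresholds (`min_snps`, `min_length_bp`, density), and the tests assert
exactly that.

## Quality control

Filters follow the usual chip-QC order — autosome restriction (at read
time), marker call rate ≥ 95%, MAF ≥ 1%, then per-animal missingness ≤ 2% —
with *strict-inequality removal*: a marker at exactly 95% call rate or
exactly 1% MAF, or an animal at exactly 2% missingness, is kept. The order
is configurable (and logged) because marginal counts depend on it; whether
MAF should be computed before or after dropping high-missingness animals is
a genuine judgement call, and the default computes it before. No LD pruning
is performed anywhere.

The pipeline is idempotent on panels inside its domain (per-animal
missingness under the threshold). On heavily missing data, removing animals
shifts the MAF denominators and a second pass can remove more markers; if
that matters for your data, iterate `qc_apply()` to a fixed point and say so
in your methods.

## Inbreeding coefficients

`f_roh()` divides total run length by $L_{AUTO}$; by default $L_{AUTO}$ is
computed from the post-QC map (sum over chromosomes of covered span), with
the 2453 Mb OvineSNP50 constant available via the `l_auto` argument. The
mode used is recorded on the output. `f_hom()` is the method-of-moments
excess-homozygosity estimator
$F_{HOM} = (O_{hom} - E_{hom}) / (N - E_{hom})$ with
$E_{hom} = \sum_j (1 - 2 p_j q_j)$ over the animal's non-missing markers,
using allele frequencies estimated from the full post-QC panel — the
conventional meaning of "observed versus expected heterozygosity"
inbreeding. Breed summaries report means with sample (n−1) standard
deviations; single-animal breeds report the SD as missing.

## Islands and the breed-effect model

`incidence_per_snp()` counts, for every marker, the distinct animals with at
least one run covering it (an animal counts once however many runs it has
there). `call_islands()` reports maximal stretches of consecutive markers
with incidence strictly greater than `min_samples` (default 20), provided
the stretch spans more than 1 Mb and holds at least 30 markers. Merging
across sub-threshold gaps is off by default (`max_gap_bp = 0`) and, when
enabled, sub-threshold markers never become members. A population
*contributes* to an island when at least one of its animals has a run
overlapping at least one member marker — deliberately the weakest sensible
rule, since islands are population-level objects. Sharing classes partition
islands exactly: unique (1 population), shared (2–3), common (more than 3).

Per sample, the proportion of an island's member markers covered by that
sample's runs is modelled as

$$\text{proportion} = \mu + B_i + e,$$

a one-way fixed-effects ANOVA with sum-to-zero breed effects $B_i$, fitted
per island by least squares with the standard F test. No multiple-testing
correction is applied across islands; raw p-values are emitted. Islands
with fewer than two breeds carrying two samples are skipped with a note.

## The synthetic-data generator

`simulate_panel()` emulates a multi-breed 50k-style chip panel: 26 autosomes
of 94 Mb (2444 Mb total), markers at 50 kb mean spacing with ±25 kb jitter,
and one oversized (400 kb) inter-marker gap per chromosome so the 250 kb gap
rule is genuinely exercised. Base B-allele frequencies are Beta(2, 2)
rescaled to [0.05, 0.95] — the intermediate-frequency profile of an
ascertained array — with per-breed Balding–Nichols drift (Fst 0.05), giving
outbred heterozygosity around 0.38. Each animal is two independent
haplotypes; autozygosity is planted by copying haplotype 1 over haplotype 2
inside non-overlapping intervals until their summed length hits the breed's
`f_target` exactly (the last interval is truncated to land on target).
Genotype-status errors (hom ↔ het flips) and missingness are applied last.
Planted intervals are kept at least 1 Mb apart so truth segments stay
distinct under the gap rule.

Planted segment lengths follow a mixture over the five length bins with
weights (0.882, 0.080, 0.025, 0.010, 0.003), the empirical shape of sheep
50k ROH, except that bin-1 lengths start at 2 Mb rather than 1 Mb: a
1.0–1.45 Mb segment carries fewer than 30 markers at 50 kb spacing and is
invisible to the detector by definition, which would contaminate recovery
statistics with a detectability artefact rather than estimator error.

What the generator does *not* model: linkage disequilibrium (markers are
exchangeable given frequencies), recombination maps, sex chromosomes, and
pedigree structure. Chance-ROH inflation from LD in real data is therefore
absent here; passing recovery tests says the detector and estimators are
correct *given* the run definition, not that the 1 Mb threshold removes all
LD artefacts in real sheep data.

## Numerical behaviour of recovery, measured honestly

Two intrinsic properties of the consecutive-runs definition show up in
recovery experiments and are worth stating plainly:

* **Boundary extension.** Outside a planted segment the background is
  heterozygous only with probability ≈ 0.4 per marker, so a detected run
  legitimately extends past the planted boundary through chance-homozygous
  flankers and may absorb one flanking heterozygote (the ≤1-het rule),
  roughly $3(1-p)/p + 1$ markers in total at background heterozygosity $p$.
  Exact boundary equality therefore only holds when the flanks are
  heterozygous, and is asserted on constructed fixtures with heterozygous
  flanks; on random backgrounds, recovery is asserted as a detected run
  *covering* the planted interval's first-to-last covered marker, with the
  (small) boundary slack measured.
* **F_ROH inflation.** The same extension inflates $F_{ROH}$ by about
  $F_{true}\,(ext - s)/\bar L$ for spacing $s$ and mean planted segment
  length $\bar L$. At the defaults this is ≈ +0.002 at $F_{true} = 0.05$,
  ≈ +0.005 at 0.15 and ≈ +0.012 at 0.30 — the highest level sits just
  outside a ±0.01 band, and the acceptance test reports that honestly
  rather than retuning the generator to pass. Rank order of breed-level
  inbreeding is always preserved. An interval straddling one of the map's
  oversized gaps cannot be a single run under the gap rule, so recovery
  statistics count it as two detectable fragments, not as a miss.

## Problem sizes used by the tests

The suite and the acceptance script run at desk scale, chosen so the whole
battery completes in a few minutes: oracle equivalence on 100 random
chromosomes of 100–500 markers; planted-segment recovery on 3 breeds × 20
animals over 2 chromosomes × ~2000 markers (error-free and at 0.1%
genotyping error); F_ROH recovery on the full 26-chromosome default genome
with 6 animals per planted level (0.05 / 0.15 / 0.30); the F_HOM null on 100
animals × ~41k markers; island validation on 80 animals × 2 chromosomes;
ANOVA calibration on 500 null islands (Kolmogorov–Smirnov uniformity) and a
+0.3 planted breed effect (n = 20 per breed, residual SD 0.1) whose recovery
is measured as the mean estimate over 25 replicate islands — a single
replicate has sampling SE ≈ 0.032, so the replicate mean (SE ≈ 0.006) is the
meaningful measure of estimator accuracy.

## Known limitations

* No LD simulation, hence no measurement of LD-driven false-positive runs.
* The island clustering is the consecutive-above-threshold definition; other
  tools use proprietary clustering and may split or merge differently near
  threshold boundaries. The `min_samples` threshold is configurable for
  sensitivity analysis.
* Binary PLINK (BED/BIM/FAM) and VCF input are out of scope; convert to
  text PED/MAP first.
* Functional annotation of islands (QTL databases, gene ontology) is out of
  scope; the island table carries coordinates for external annotation.
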