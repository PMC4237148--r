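---
title: "Separating neutral and selected differentiation in structured SNP data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating neutral and selected differentiation in structured SNP data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoscan)
```

## The problem

Killer whale ecotypes — prey-specialised population classes such as the
fish-eating "residents" and mammal-eating "transients" of the North
Pacific — stay genetically distinct despite overlapping ranges and high
mobility. Two forces can produce that pattern: genetic drift in small,
socially structured populations, and divergent selection at ecologically
relevant loci. `ecoscan` separates the two signals in a biallelic SNP
matrix: it estimates a genome-wide neutral baseline of differentiation,
flags loci whose differentiation is inconsistent with that baseline, and
then contrasts how the neutral and outlier locus sets partition the
populations.

## The statistical model

### Weir–Cockerham θ

All differentiation is measured with the Weir & Cockerham (1984)
variance-components estimator. For one locus over $r$ populations with
diploid sample sizes $n_k$, allele frequencies $\tilde p_k$ and observed
heterozygote proportions $\tilde h_k$, the estimator decomposes allele
frequency variance into among-population ($a$), among-individual ($b$)
and within-individual ($c$) components and reports
$\hat\theta = a/(a+b+c)$. Multi-locus and pairwise values combine the
components as a ratio of sums over loci, the standard weighting that keeps
low-information loci from dominating. $\hat\theta$ may be slightly
negative at low differentiation; values are reported as computed, not
clamped, because the scan's tail probabilities need the estimator's full
sampling distribution. A longhand transcription of the 1984 components is
frozen in the test suite as an independent oracle.

### The neutral envelope

The outlier scan follows the FDIST logic: simulate the joint neutral
distribution of (He, $\hat\theta$) at the observed sample configuration,
then ask how extreme each observed locus is *conditional on its
heterozygosity*. The neutral generative model is Balding–Nichols drift:
an ancestral frequency $p \sim \mathrm{Uniform}(0.01, 0.99)$, population
frequencies

$$p_k \sim \mathrm{Beta}\!\left(\frac{p(1-F)}{F},\; \frac{(1-p)(1-F)}{F}\right),$$

and genotype-class counts per population drawn multinomially under
Hardy–Weinberg (equivalent in distribution to two binomial allele draws
per individual, but vectorised). Simulated loci that come out monomorphic
are discarded and redrawn, mirroring the variable-SNP ascertainment of the
observed data. Crucially, simulated (He, $\hat\theta$) pairs go through
the *same* Weir–Cockerham code path as the observed loci, so estimator
bias at the real sample sizes cancels out of the comparison.

This analytic drift model replaces the coalescent island model of the
original FDIST tools. It matches the target mean exactly, is orders of
magnitude faster, and has closed-form moments
($\mathrm{Var}(p_k) = F\,p(1-p)$, checked as a simulation invariant), but
results on real data can differ in detail from LOSITAN's.

### Bisection calibration

The drift parameter $F$ is not set directly: it is calibrated by bisection
on $[0, 0.95)$ until the mean (ratio-of-sums) simulated $\hat\theta$
matches the observed neutral baseline within $10^{-3}$, with at most 60
steps and an error carrying the bracketing trace on failure. Every
bisection step evaluates the full simulation size (default 50,000 loci),
where the Monte-Carlo standard error of the mean ($\approx 4\times10^{-4}$)
sits safely below the tolerance; a typical calibration converges in about
ten evaluations and a couple of seconds.

### Conditional tails, FDR, and the iterated baseline

Simulated loci are cut into equal-count He bins (default 50). Each
observed locus receives an upper-tail probability
$(r + 0.5)/(m + 1)$, where $r$ counts simulated $\hat\theta$ values in its
bin at or above the observed one and $m$ is the bin size — the half-count
convention avoids exact zeros while preserving ranking; the lower tail is
analogous. Benjamini–Hochberg control at FDR 0.1 is applied *separately*
to the two tails, because positive and balancing candidates are distinct
scientific claims reported separately. Loci above every simulated value in
their bin are additionally flagged `best_supported` (outlier probability 1
at the simulation resolution); only those, plus fixed-difference loci,
feed the enrichment analysis.

Because planted or real selected loci inflate a naive all-locus mean, the
baseline is iterated: compute the neutral-set mean $\hat\theta$, rebuild
the envelope at that target, reclassify, and repeat until the neutral set
is unchanged (at most 20 iterations, with a non-convergence flag
otherwise).

Two numerical choices matter here:

* **Bin-count cap.** The smallest tail probability a bin of $m$ simulated
  loci can resolve is about $1/m$. BH at rate $q$ over $L$ observed loci
  needs tail probabilities down to roughly $q\,k/L$ for modest hit counts
  $k$, so bins must be large enough that the resolution floor sits below
  those thresholds — otherwise even a locus with $\hat\theta = 1$ cannot
  be declared significant. The effective bin count is therefore capped at
  `n_sims / 1000` (inactive at the 50,000-simulation default: all 50 bins
  stand; a 5,000-simulation quick scan gets 5 coarser bins instead of 50
  unusable ones).
* **Envelope reuse across iterations.** Each iteration reuses the same
  seed, and the envelope is only rebuilt when the baseline moves by at
  least the calibration tolerance ($10^{-3}$) — within that band the
  existing envelope already satisfies its contract for the new target.
  Rebuilding on sub-tolerance shifts re-randomises borderline loci and can
  cycle the neutral set forever; with reuse, a stable neutral set is an
  exact fixed point and convergence is detected exactly.

### Fixed differences

A locus is a fixed difference between samples A and B when every A
individual is homozygous for one allele and every B individual for the
other. Under a panmictic null with pooled frequency $\hat p$, the chance
of reciprocal monomorphism is
$\hat p^{2n_A}(1-\hat p)^{2n_B} + (1-\hat p)^{2n_A}\hat p^{2n_B}$; the
count over loci is then Poisson-binomial, computed exactly by dynamic
programming up to $10^4$ loci (a Poisson approximation beyond), and the
pair is starred when $P(X \ge \text{observed}) \le 0.05$. No
multiple-testing correction is applied across pairs by default, matching
the per-pair presentation of such tables; the per-locus formalisation of
the "binomial distribution test" is an interpretation, recorded here.

### Ecotype contrasts

The headline statistic is the ratio set: for ecotypes A and B, every
between-ecotype population pair's $F_{ST}$ divided by every within-ecotype
pair's $F_{ST}$, giving $|{\rm between}| \times |{\rm within}|$ ratios per
locus set. Neutral and outlier ratio sets are compared with a Mann–Whitney
U test: midranks for ties, tie-corrected variance, continuity correction,
$Z$ negative when the first (neutral) set is stochastically smaller, and
an exact null distribution when $mn \le 400$ with no ties. The
allelic-difference contrasts build 2×2 tables from summed mean pairwise
differences (rows = locus set, columns = between/within ecotype, or
resident-vs-outgroup / transient-vs-outgroup) rounded to counts and apply
Yates-corrected χ². The cell construction from summed distances is itself
an interpretation — the printed χ² values of the motivating study are not
reproduction targets for that reason.

### Enrichment and units

SNPs link to genes when at most 5 kb separates the SNP from the gene span
(closed 1-based coordinates; a SNP at 10,000 links to a gene starting at
15,001 but not 15,002). Term overrepresentation uses the two-tailed Fisher
exact convention (sum of all tables at most as probable as the observed
one) with BH correction across terms, treating terms as flat labels
without ontology-graph propagation. The negative control draws ten random
gene lists from the neutral-locus pool, matched in length to the candidate
list, and reports how many show any significant term. Demographic
conversions use $N_e = \theta/(4\mu L)$, years $= 2 N_e T g$, migrants per
generation $= \nu M/2$, and expected divergence $2\mu T_{\rm div}/g$, with
$\mu = 2.34\times10^{-8}$, $L = 1.45$ Mb, $g = 25.7$ y as defaults.

## The simulator and what passing tests mean

`simulate_dataset()` draws a two-level hierarchy: ecotype frequencies by
Balding–Nichols drift around the ancestral frequency, population
frequencies by a second Balding–Nichols step within each ecotype, and
genotypes binomially per individual. Defaults mirror the motivating survey
design: nine populations in ecotype groups of (4, 2, 3) with diploid
sample sizes (13, 17, 13, 9, 21, 16, 7, 6, 13); 3,000 loci split
2,670 neutral / 150 positive / 150 balancing / 30 fixed;
$F_{\rm ecotype}$ 0.05 for neutral and 0.5 for positive loci,
$F_{\rm population}$ 0.02; ancestral frequencies Uniform(0.05, 0.95) to
mimic variable-SNP ascertainment; balancing loci pin $p$ near 0.5 with
$F \approx 10^{-3}$ at both levels; fixed loci assign the reference allele
to one designated ecotype deterministically. Loci sit at uniform distinct
1-based positions on one synthetic contig (~10 kb mean spacing);
monomorphic draws are redrawn at most 100 times.

```{r quick-example, eval = FALSE}
cfg <- simulation_config(seed = 1)
sim <- simulate_dataset(cfg)
scan <- iterate_baseline(sim$genotypes, sim$popmap, fdr = 0.1,
                         n_sims = 50000, seed = 1)
table(scan$classification$label, sim$truth$class)
```

The generator is deliberately an exchangeable drift model, not a
reconstruction of any real divergence history: no linkage disequilibrium,
no coalescent genealogy, no missing data (an optional flag aside), no
sequencing error. Passing tests therefore demonstrate that the statistics
and the scan behave correctly under hierarchical drift with known truth —
they do not certify behaviour under LD, ascertainment quirks, or model
misspecification in real data. Two honest consequences at the default
design: detection of *balancing* selection has very low power (a locus
with true $F \approx 0$ sits well inside the null's lower tail at these
sample sizes — a known weakness of FDIST-type lower-tail tests), and the
realised FDR on pure-null data is conservative (far below the nominal
0.1), because the half-count tail floor and BH discreteness both bite in
the same direction.

## Problem sizes and runtime

The shipped analyses use the full study design (115 samples, 3,000 loci,
50,000-locus envelopes): one envelope calibration takes ~2 s and a full
iterated scan ~5–10 s on one CPU. The FDR-calibration study in the
acceptance script runs twenty pure-null datasets at that size in about a
minute; the pipeline-determinism check uses a reduced configuration
(36 samples, ~350 loci, 5,000-locus envelopes) because it exercises
bookkeeping, not statistics.

## Known limitations

* The neutral null is exchangeable across populations; real hierarchical
  structure (shared ecotype-level drift) widens the between-locus spread
  of $\hat\theta$ relative to the calibrated null, which the iterated
  baseline only partly absorbs.
* "Mean coverage below 20×" is interpreted as the per-site mean across
  samples, and "genotype quality below Q20" per genotype (a locus is
  dropped if any genotype falls below); both interpretations are stated in
  the filter's documentation.
* Mean pairwise allelic (dosage Manhattan) differences stand in for
  per-site nucleotide differences; both raw and per-locus-normalised
  variants are available.
* The χ² contrasts' cell construction and the fixed-difference count null
  are formalisations of under-specified published procedures; they are
  validated against enumeration oracles, not against the original tools.
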