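---
title: "Methods: models, parameters, and design choices in hervscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its own statistical machinery: the
models it fits, the assumptions they carry, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the numerical decisions taken where the design was genuinely open. Nothing
here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The screening problem

A DNA-barcode pMHC-multimer screen tests a single blood or bone-marrow
sample against on the order of a thousand peptide–MHC specificities at once.
Every peptide–MHC multimer carries a unique DNA barcode; multimer-binding
CD8+ T cells are sorted and their associated barcodes sequenced. A barcode
strongly over-represented in the sorted sample relative to the unsorted
multimer pool (sequenced as **triplicate baseline samples**) marks a T cell
population specific for that pMHC. The package covers the computational
chain from antigen-library design through barcode statistics to cohort-level
inference for a three-class design: healthy donors, patients before
("pre-AZA") and after ("post-AZA") DNA-demethylating therapy.

## 2. Peptide library construction

Transcripts are translated from the **first ATG anywhere on the sense
strand**, which fixes the reading frame, until the first stop codon;
without a stop, translation runs to the last complete codon. This is a
deliberately literal single-ORF rule: alternative downstream start codons,
other frames and the reverse strand are ignored, because deposited HERV
transcript records are conventionally translated as-is. Codons containing
ambiguity characters translate to `X`, and peptides containing `X` are
removed before binding prediction, whose behaviour on non-standard residues
is undefined.

Proteins are chopped into all overlapping 9–11mers (a protein shorter than
9 residues yields none — the "long enough" exclusion), and each
(peptide, allele) pair is kept when the predicted percentile rank is
**≤ 2**, compared inclusively at the precision of the rank source, so a
rank of exactly 2.0 enters the library. Deduplication is **per allele**: a
peptide binding two alleles is two library entries (and two multimers in the
screen), while repeats of a peptide across transcripts of one locus count
that locus once. `source_loci` is the union of contributing loci and
`occurrences` its size, so multi-locus peptides (common within the HERVK
family) remain single catalog rows with full locus attribution.

## 3. Barcode enrichment statistics

For each experiment (one sorted sample plus its three baseline replicates):

1. **TMM normalization.** Factors are computed from doubly-trimmed,
   variance-weighted log count-fraction ratios against a reference column
   (the sample whose 75th-percentile fraction is closest to the mean), trim
   fractions 0.3 on M and 0.05 on A, rescaled to geometric mean 1 — the
   standard trimmed-mean-of-M-values estimator; the unit tests verify
   equality with edgeR's implementation to 1e-10.
2. **Fold change.** log2 of the sorted sample's normalized count fraction
   over the mean normalized baseline fraction, with a pseudo-fraction
   π = 0.5 / median(effective library size) added to numerator and
   denominator so zero counts stay finite. π is configurable; 0.5 reads at
   the median depth is small enough not to bias calls at screen depths.
3. **NB test.** One-sided upper-tail
   p = P(X ≥ c\_obs), X ~ NB(μ, μ + φμ²) with **fixed dispersion φ = 0.1**
   (size 1/φ = 10), where μ is the mean normalized baseline fraction
   rescaled to the sorted sample's effective library size. Two degenerate
   cases: c\_obs = 0 gives p = 1 (the upper tail is the whole mass), and
   μ = 0 with c\_obs > 0 floors μ at 0.5 read-equivalents so a barcode
   absent from the baselines cannot yield p = 0 numerically.
4. **FDR.** Benjamini–Hochberg within the experiment (each sorted sample is
   tested individually, so multiplicity is per experiment, not pooled).
5. **Dual filter.** A detection requires FDR < 0.001 **and** a raw read
   fraction ≥ 0.001 of the sample's barcode reads. The fraction filter uses
   raw, pre-normalization counts: it guards against calls driven by noise in
   low-count baselines, which normalization cannot repair.

A calibration nuance worth stating: the test plugs the three-replicate
baseline mean in as the known NB mean. Estimation noise from only three
replicates makes the raw tail test anti-conservative (simulations in the
test suite put the α = 0.05 rejection rate near 0.09 under the plug-in,
versus 0.0475 at the true mean). This is a property of the stated method,
not a defect of the implementation; the stringent FDR cutoff plus the
fraction filter absorb it, and the suite verifies the end-to-end false-call
rate stays below 0.002 per (sample, barcode) pair on null screens while
50-fold planted responders are detected with sensitivity above 0.95.

## 4. Response catalog

Detections collapse over timepoints into one row per individual per class: a
(peptide, allele) cell is positive if **any** sample of that individual in
that class detected it, negative if tested and never detected, and
not-tested when the individual lacks the restricting allele or the entry was
absent from those samples' panels. Classification pools pre- and post-AZA
rows as "patient", matching the published catalog's labels.

The per-HERV **reactivity score** is the ratio of positive to tested peptide
observations summed over patient rows. The denominator counts tested
peptide-slots per individual-class row rather than library size once —
"tested across the patient samples" — but rows, not raw samples, are the
unit, which makes the score invariant to how many timepoints an individual
contributed (collapsing duplicate samples changes nothing). Multi-locus
peptides credit every source locus. The **epitope proportion** divides the
number of distinct entries of a locus ever positive in a patient row by the
number predicted for that locus, and feeds the expression–recognition
correlation.

## 5. Bayesian cohort models

All models run 3 chains × 10,000 iterations with 5,000 warm-up by default
(15,000 post-warmup draws), with split-R̂ and ESS computed in-package
(flagged at R̂ ≥ 1.01); credible intervals are **equal-tailed** 50 % and
90 % quantile intervals, matching the eye-plot convention.

**Responder proportions.** Each class's responder count is Binomial(n, p)
with a Beta(1, 1) prior, so the posterior is exactly Beta(k+1, n−k+1) and is
drawn by conjugate sampling — the tests verify MCMC quantiles against the
closed form to ±0.01. Contrast probabilities P(p₁ > p₂) come from draws
paired by index. The same model, applied to pooled per-class viral-peptide
counts, gives the viral-recognition posterior.

**HLA-corrected regression.** Observations are per (individual, allele):
n\_i positives of N\_i tested, with
logit(p\_i) = β₀ + β\_HLA[i] + β\_class[i], fitted with JAGS. Both
coefficient blocks satisfy **exact** sum-to-zero constraints, parameterized
as K−1 free coefficients with the last set to minus their sum (a hard
constraint, not a soft prior — the tests check it to 1e-10 in every draw).
Priors are weakly-informative Normal(0, 2.5) on the intercept and free
coefficients; `prior_sensitivity()` refits a model across a grid of prior
scales and reports the maximum posterior-median shift, so the robustness of
any reported contrast to the prior choice can be demonstrated rather than
assumed. Derived quantities are computed **per draw** —
p\_class = logistic(β₀ + β\_class), pairwise log fold changes
log(p₁/p₂), and P(log fold change > 0) — so their credible intervals
propagate full posterior uncertainty. N\_i counts peptides tested per
individual **per allele panel**, taken from the responder-matrix
denominators.

**Viral normalization.** The HLA-corrected HERV class proportions are
divided, draw by draw, by the viral class proportions — the viral response
acts as an internal control for overall T cell reactivity — and contrasts
are computed on the normalized ratios. Draws with a zero-valued viral
proportion would be excluded with a logged count (the Beta posterior makes
this a theoretical concern only).

**Clinical outcome.** Responder/non-responder status is regressed on HLA
indicators and indicators for any HERV and any viral response plus their
interaction. The three antigen coefficients share a hierarchical
Normal(0, τ) prior with τ ~ half-Normal(1): this regularization keeps
posteriors finite under complete separation (verified on a perfectly
separated 10-patient toy) and shrinks honestly when the data are
uninformative.

**Diagnostics.** Split-R̂ halves each chain before computing the potential
scale reduction factor; ESS uses the combined-chain autocorrelation with
Geyer's initial-positive-sequence truncation, cross-checked against coda in
the tests.

## 6. Exact rank tests

Both the Mann–Whitney–Wilcoxon and the Wilcoxon signed-rank tests are exact
**conditional on the observed tie pattern**: ties receive midranks, doubled
to stay on integers, and the permutation null is built by a counted-shift
convolution — over all choose(n, n\_x) group labelings for the rank sum, or
all 2ⁿ sign assignments for the signed rank. This equals full enumeration
(the tests verify exact equality across random tied configurations at
n ≤ 8) at polynomial rather than exponential cost. Two-sided p-values double
the smaller tail, capped at 1; zero paired differences are dropped, and
all-zero differences give p = 1 with a warning.

## 7. Expression analysis

All TPM values are floored at 0.05 **before any log or mean** (including
the healthy-donor mean), and every fold change is log2(x) − log2(y). The
vs-healthy mode compares each patient column to the per-locus mean of
floored healthy columns; the paired mode uses only individuals with both
pre- and post-treatment columns, dropping the rest with a logged count.
Heatmap values are clamped to ±6. Spearman correlation uses midranks with a
two-tailed t-approximation p-value by default; an exact permutation option
exists for n ≤ 8 loci (the full factorial of larger n is not tractable, and
at the ~50-locus scale of interest the t-approximation is standard). The
immunogenic-vs-non-immunogenic comparison reuses the exact rank test.

## 8. The synthetic-data generator

`sim_config()` defaults define the emulated study: 66 HERV loci of which
57/66 carry a translatable ORF; 27 healthy donors; 34 patients (33 with a
pre-treatment and 34 with a post-treatment sample); the four HLA alleles
A\*01:01, A\*02:01, B\*07:02, B\*08:01 with 1–4 alleles per individual drawn
uniformly (the real allele-count distribution is unknown and only matters
for coverage of the HLA correction); a binder-calling rate of 1.9 %; triplicate
baselines at mean depth 100 with NB dispersion 0.1 (the package-wide NB
parametrization is variance = μ + φμ², the edgeR convention); 50-fold
enrichment of true responders; and log-normal TPM with a +2 log2
disease shift at noise s.d. 0.5.

Planted ORFs are 30–150 amino acids, which reproduces the published
library's scale (~1,000–1,200 entries from ~55,000 peptide–allele pairs);
non-ORF loci either contain no ATG at all or an ORF under 27 nt, exercising
the "long enough" exclusion. Transcript variants of one locus share their
planted ORF, so same-locus deduplication is exercised naturally.

Per-peptide recognition is Bernoulli per individual, restricted to carried
alleles. The per-class probabilities are **synthetic choices, not estimates
from any publication**: healthy 1e-4, pre 8e-4, post 8e-4 per HERV peptide,
picked so that with realistic per-person panels (~300–1,100 entries) the
implied proportion of individuals with at least one response reproduces the
cohort-level pattern (roughly 0.15 for healthy donors and 0.5 for patients).
Viral control probabilities (0.25 / 0.135 / 0.18) encode the opposite
gradient — patients' reduced anti-viral reactivity. A single Bernoulli rate
per class cannot simultaneously match published individual-level and
peptide-level proportions; the generator prioritizes the individual-level
structure, which drives the headline contrasts. Patients' pre and post
samples share the individual's truth by default, with an optional
post-only gain probability (default 0), so the "post" probability entry
takes effect only through that gain channel.

The mock rank provider hashes (peptide, allele, seed) to a deterministic
uniform variate and maps it so that P(rank ≤ 2) equals the configured
binder rate exactly in the marginal; peptides with non-standard residues
receive the sentinel rank 100. All generators restore the caller's RNG
state and are byte-identical under a fixed seed.

**What the generator does not emulate** — and hence what passing tests do
not establish about real screens: read-level structure (demultiplexing,
clonality/UMI noise are reduced to a distinct-tag count), barcode-specific
baseline abundance differences (all barcodes share one baseline depth),
correlation between HERV expression and immunogenicity (expression and
recognition truth are generated independently, so the
expression–recognition Spearman on synthetic data is a null check, not a
recovery test), T cell avidity or frequency effects, and any real binding
affinity landscape behind the mock predictor.

## 9. Problem sizes used in validation

The suite validates at sizes chosen to balance statistical resolution
against a laptop-friendly run: conjugate-oracle grids at the published
cohort sizes; HLA-model parameter recovery over 50 replicates of 200
individuals (β\_class = (−0.5, 0, 0.5), N\_i = 100) with 90 % CI coverage
required in ≥ 80 % of fits; outcome-model null (n = 200) and power
(β\_VIR = 2, n = 500) simulations; detection error control over 40 null and
50 planted 1,000-barcode experiments; exact-test enumeration sweeps at
n ≤ 8; and expression recovery at 49 loci × (14 healthy + 16 + 16 patient)
samples with the ±0.2 log2 recovery band. Short-chain MCMC
(2 × 1,500 iterations) is used inside replicate loops; occasional split-R̂
flags at that length are expected and left visible.

## 10. Known limitations

- The NB enrichment test is the literal plug-in tail test described above,
  not edgeR's exact conditional two-group test; agreement is at the level
  of error control, not bit-compatibility.
- The first-ORF rule ignores downstream ORFs that real ribosomes might
  initiate; a transcript whose first ATG opens a trivially short ORF
  contributes nothing even if a long ORF follows.
- Whether the 1/1000 read-fraction filter should use clonally reduced or
  raw reads is not specified by the method's description; raw reads are
  used.
- Counting conventions for multi-locus catalog rows are ambiguous in
  published per-locus totals; this package keeps multi-locus rows intact
  and makes locus attribution explicit instead of asserting one count.
- Exact Spearman permutation p-values are limited to n ≤ 8.
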