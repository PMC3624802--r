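---
title: "Mixture-model taxonomic profiling from protein domain signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture-model taxonomic profiling from protein domain signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domainmix)
```

## The problem

Shotgun metagenomes contain anonymous reads from bacteria, archaea,
eukaryotes and viruses. Reference genome databases cover these groups very
unevenly — archaea and viruses in particular are sparse — so read-by-read
classification against genomes systematically underestimates exactly the
groups a full-range census cares about. `domainmix` takes a profile-level
route instead: it never classifies individual reads. The unit of analysis
is the metagenome's *protein signature* — the vector of relative
frequencies of protein domain families (e.g. Pfam accessions) over all
detected domain hits. Domain detection itself (HMM scanning, ORF calling)
is an upstream step; the package consumes its output as hit tables or
frequency profiles.

The key practical advantage of working at the profile level is that a
*metagenome* can serve as a reference just like a genome can. Viromes —
shotgun libraries enriched for viral DNA — supply viral reference
signatures that no genome collection provides, as long as contaminated
viromes are screened out first (see *Vetting reference signatures* below).

## The mixture model

Let `y` be the observed domain frequency profile over `D` families and
`x_1 … x_K` the reference signatures, each a column-stochastic vector over
the same families. The model reconstructs

    y  ≈  ŷ = Σ_i w_i x_i,   w_i ≥ 0,  Σ_i w_i = 1.

Under the generative reading — each domain hit falls into family `j` with
probability `p_j = Σ_i w_i x_ij` — the weights maximize the
profile-weighted log-likelihood

    L(w) = Σ_j y_j log( Σ_i w_i x_ij ),

which is concave in `w` on the simplex. `em_fit()` maximizes it with the
classical fixed-components EM update (responsibilities
`r_ij = w_i x_ij / p_j`, then `w_i ← Σ_j y'_j r_ij`). Concavity means the
fixed point reached from the uniform start is a global optimum;
initializing uniformly also makes every run deterministic. The abundance
of a taxon is then simply the sum of the weights of the references carrying
that taxon ([`aggregate_weights()`]), at any rank from superkingdom to
species.

Two details deserve care:

* **Unsupported mass.** Families observed in `y` but absent from every
  reference would force `L = −∞`. They are excluded from the likelihood
  (with `y` renormalized over the remaining families, for the likelihood
  only) but retained everywhere else; their total is reported as
  `unsupported_mass` and is fully charged to the model error below. This
  is why `align_families()` takes the *union* of the family universes
  rather than the intersection.
* **Non-uniqueness.** When references are collinear the weights are not
  identifiable; EM still converges (the likelihood is concave, not
  strictly so) and the reconstruction `ŷ` and aggregated abundances remain
  meaningful, but individual weights should then not be over-interpreted.

## Model quality: FDU and FSU

The *fraction of domain hits unexplained* is half the Manhattan distance
between observation and reconstruction,

    FDU = ½ Σ_j | y_j − ŷ_j |  ∈ [0, 1],

the share of domain-hit mass the model fails to reproduce; by symmetry an
equal share is overpredicted. Applied to two taxon-abundance vectors the
same statistic is the Bray-Curtis dissimilarity ([`bray_curtis()`]), the
standard ecological comparison of assemblages. The complementary
*fraction of sequences unexplained*, `FSU = 1 − (#reads with ≥1 hit)/#reads`,
measures how much of the data carries domain information at all. A
trustworthy composition estimate needs both to be low: low FDU says the
model fits the profile, low FSU says the profile rests on enough of the
data. A read with several hits contributes every hit to the profile but
counts once as explained — the profile is a hit-frequency distribution,
the FSU a per-sequence statistic.

## Building reference signatures

Domain frequency profiles depend on sequence length, so genome-derived
and metagenome-derived signatures are made comparable by cutting genomes
into half-overlapping 400 bp fragments before domain detection
(`fragment_sequences()`, defaults `fragment_length = 400`, `step = 200`).
Tail handling is a genuinely open choice; the package emits one extra
fragment anchored at the sequence end whenever the last regular window
leaves at least `min_tail` (default: one step, 200 bp) uncovered, so no
stretch longer than `min_tail` goes unrepresented, and no base is covered
more than twice when lengths align with the step. Phage genomes are only
admitted as references when strictly longer than 100 kbp
(`filter_min_length()`), because shorter sequences do not support a stable
frequency estimate over thousands of families. Fragmentation works on the
forward strand only; strand handling belongs to the (upstream) detection
step.

## Vetting reference signatures from viromes

Public viromes carry varying microbial contamination, and a contaminated
reference would silently absorb microbial weight as "viral".
`stepwise_eliminate()` implements a selection criterion: candidate
signatures must be reliably distinguishable from the opposing
(microbial) class by a regularized least squares classifier on the domain
frequencies. Each round runs stratified 5-fold cross-validation, repeated
10 times with fresh random partitions, so every sample is held out 10
times; the eligible sample with the highest misclassification rate over
the repeats is removed, and the procedure repeats until no test error
occurs at all.

Choices the procedure leaves open, and how this package resolves them:

* **Ridge penalty.** The penalty is chosen per repeat from the log grid
  `10^-4 … 10^2` by the same cross-validated error (ties to the smallest
  penalty). With more families than samples the solver uses the
  sample-space dual of the normal equations, which is exact.
* **Ties and eligibility.** Exactly one sample is removed per round,
  lexicographically smallest id among the worst; by default only
  candidate-class (+1) samples are eliminable, mirroring the asymmetric
  vetting of viral candidates against a trusted microbial background —
  both are configurable.
* **Stopping.** "No test error" is read literally: every sample, every
  repeat. If errors persist only among ineligible samples the procedure
  reports `stalled` rather than removing a blameless candidate, and it
  aborts (status `aborted`, partial trace preserved) rather than shrink a
  class below what stratified 5-fold cross-validation needs.
* **Prediction ties.** A decision score of exactly zero is scored as the
  positive class — an explicit, documented rule rather than an accident of
  sign conventions.

## What the synthetic generator emulates — and what it does not

All tests and the acceptance script run on synthetic data with known
ground truth, produced by the `gen_*` family and `simulate_bundle()`:

* Reference signatures are Dirichlet draws over the family universe, one
  concentration per superkingdom group (defaults 0.02–0.2), giving the
  sparse, group-structured frequency vectors real signature collections
  show. The default group proportions (82.5% bacteria, 5.8% archaea,
  2.4% eukaryotes, 9.3% viruses, the viral half split between genome- and
  metagenome-derived sources) mirror a realistic reference collection.
* The observed metagenome is a multinomial sample of 100 000 domain hits
  from the true mixture — the finite-read noise a short-read survey
  implies. Default study sizes are 2000 families and 20 references; the
  scalability check runs one fit at full deployment size (12 621 families,
  2096 signatures).
* Hit tables give each read a single hit with probability 0.7, planting
  an FSU of 0.3 — mid-range for real surveys.
* The two-class sets for vetting are Dirichlet classes whose mean
  distributions are tilted apart along a random log-linear direction to a
  prescribed symmetric Kullback–Leibler divergence (default 3, with
  within-class concentration 100); contamination is planted by drawing
  labeled candidates from the opposing class.

What passing these tests shows is that the estimator, the quality indices
and the vetting procedure do what they claim *under the model's own
assumptions*. What they cannot show: real signatures are not Dirichlet
draws (families are correlated through genome content and domain
co-occurrence), real hit noise includes detection error, not just
sampling, and real contamination is a mixture within a sample, not a
wholesale label flip. Results on real data therefore depend on the
quality and coverage of the reference collection in a way no synthetic
test can certify — which is exactly why the package always reports FDU
and FSU next to any composition estimate.

## Numerical choices

* EM stops when the relative log-likelihood change drops below `rel_tol`
  (default `1e-9`) or after `max_iter` (default 10 000) iterations; the
  `converged` flag records which. For exactness experiments (noise-free
  recovery) a tighter `rel_tol = 1e-15` is appropriate and cheap at small
  sizes; the default is a screening tolerance chosen for large reference
  collections.
* Mixture densities are floored at `1e-300` inside logarithms, so the
  likelihood stays finite even when a weight hits the simplex boundary.
* Unit-sum validation uses a `1e-9` tolerance throughout; normalization
  passes already-normalized vectors through unchanged, which makes it
  exactly idempotent.
* All family ids, taxa and sample ids are ordered by C-locale
  (radix) sort, making every output byte-stable across platforms and
  locales.
* All generators and the cross-validation partition stream are pure
  functions of their integer seed; the stepwise elimination derives one
  sub-seed per round from its master seed.

## Limitations

The method is restricted to the protein-coding part of a metagenome and
inherits the feature universe of whatever domain detection produced the
input; hits are counted per hit, not per predicted gene. It reports
mixture weights, not read assignments — there is deliberately no
read-level classification. Weights below the noise floor (FDU-sized
fractions) should be read as "consistent with zero"; the package applies
no sparsity threshold and reports all weights.
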