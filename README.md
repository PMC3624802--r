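# domainmix

Taxonomic profiling of metagenomes from protein domain signatures.

Shotgun metagenomes mix DNA from bacteria, archaea, eukaryotes and
viruses, and reference genome databases cover those groups very unevenly
— archaea and viruses worst of all. `domainmix` estimates the taxonomic
composition of a metagenome without classifying a single read. Its unit
of analysis is the metagenome's *protein signature*: the vector **y** of
relative frequencies of protein domain families (e.g. Pfam accessions)
over all detected domain hits. That signature is reconstructed as a
convex combination of taxonomically labeled reference signatures
**x**₁ … **x**_K:

    y ≈ ŷ = Σᵢ wᵢ xᵢ,   wᵢ ≥ 0,  Σᵢ wᵢ = 1

The mixture weights **w** maximize the concave profile log-likelihood
L(w) = Σⱼ yⱼ log(Σᵢ wᵢ xᵢⱼ) and are estimated by expectation-maximization;
the abundance of any taxon is the sum of the weights of its reference
signatures. Because references are *profiles*, whole viral metagenomes
can serve as reference signatures alongside fragmented genomes — which is
what makes realistic virus fractions estimable at all.

Two indices qualify every estimate:

* **FDU** (fraction of domain hits unexplained) = ½·Σⱼ|yⱼ − ŷⱼ|, the
  model approximation error in [0, 1] — the same statistic as the
  Bray-Curtis dissimilarity between two abundance profiles;
* **FSU** (fraction of sequences unexplained) = fraction of reads
  without any domain hit, the statistical coverage of the profile.

The package also builds reference signatures from genome sequences
(half-overlapping 400 bp fragmentation, >100 kbp phage length filter),
vets candidate virome signatures by repeated cross-validated stepwise
elimination with regularized least squares classifiers, and generates
complete synthetic fixtures with known ground truth. Domain detection
itself (ORF calling, HMM scanning) is an upstream step; `domainmix`
consumes its output as hit tables or frequency profiles.

Intended users: microbiome and virome researchers who want a fast,
full-range (all domains of life + viruses) first-instance composition
estimate with an explicit model-quality readout.

## Worked example

```r
library(domainmix)

# a synthetic world with known ground truth: 2000 domain families,
# 20 reference signatures across four superkingdoms, 100k sampled hits
dir <- tempfile()
paths <- simulate_bundle(simulation_spec(), seed = 42, out_dir = dir)

profile <- read_profile_table(paths$profile)
refs    <- read_signature_table(paths$refs)
tax     <- read_taxonomy_table(paths$taxonomy)

al  <- align_families(profile, refs)
fit <- em_fit(al$profile, al$refs)
fit
#> <mixture_fit> 20 signatures, 28 iterations (converged)
#>   log-likelihood: -6.6297717   FDU: 0.0426   unsupported mass: 0
#>   Bacteria_sig004                  0.1339
#>   Bacteria_sig011                  0.1107
#>   ...

aggregate_weights(fit, tax, rank = "superkingdom")
#> <taxonomic_profile> rank = superkingdom
#>   Bacteria                        0.8630
#>   Eukaryota                       0.0791
#>   Viruses                         0.0565
#>   Archaea                         0.0015

fsu(read_hit_table(paths$hits))
#> [1] 0.2989122
```

The fitted superkingdom fractions sit within 0.01 (L1) of the planted
truth recorded in `truth.json` (Bacteria 0.8648, Eukaryota 0.0782,
Viruses 0.0553, Archaea 0.0018); the FDU of 0.043 is pure multinomial
sampling noise (the profile was drawn from inside the reference hull),
and the FSU recovers the planted per-read hit probability of 0.7.

The same pipeline is available from a shell via the thin CLI wrapper:

```sh
Rscript inst/cli/domainmix simulate --seed 42 --out fixture
Rscript inst/cli/domainmix fit --hits fixture/hits.tsv \
    --refs fixture/signatures.tsv --taxonomy fixture/taxonomy.tsv \
    --rank superkingdom --rank phylum --out run1
```

which writes `weights.tsv`, one `profile_<rank>.tsv` per rank, a
`summary.json` (FDU, FSU, iterations) and a `manifest.json` with the full
configuration and input checksums, from which any run can be reproduced
byte-for-byte.

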