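---
title: "Methods: rare loss-of-function triplet analysis in small cohorts"
author: "RareTriplet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare loss-of-function triplet analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RareTriplet)
```

## The problem

When a handful of individuals in a small, deeply selected cohort (say, ~100
samples) turn out to carry the *same* rare heterozygous loss-of-function
variant, two questions decide whether the observation is worth reporting:

1. **Could the sharing be an artifact of the cohort's structure?** Cryptic
   relatedness or shared ancestry would make co-occurrence unremarkable, and
   a shared local haplotype indicates a single founder allele rather than
   recurrent mutation.
2. **How surprising is the sharing under the null?** A carrier-based exact
   enrichment test against reference-population counts, a closed-form
   probability that *some* trio of the cohort shares *some* comparably rare
   variant, and a conservative genome-wide multiple-testing adjustment each
   answer a different version of this question.

RareTriplet implements this complete analysis path, together with a
synthetic-cohort generator carrying known ground truth so that every stage
is testable without access to any private genomes.

## The statistical core

### Carrier-enrichment exact test

Carriers (individuals with dosage ≥ 1, not alleles) are tabulated for the
cohort and a reference population, e.g. 3/98 cohort carriers/non-carriers
against 56/589,929 reference individuals. Conditional on the margins, the
cohort carrier count $X$ follows a hypergeometric distribution, and the
default one-sided enrichment p-value is the upper tail
$P(X \ge a)$, evaluated in log space via the exact hypergeometric mass
(`fisherCarrierTest()`). A two-sided option sums the probabilities of all
tables no more likely than the observed one, the same convention
`stats::fisher.test()` uses; on the strongly asymmetric tables this package
targets, the two coincide. The one-sided convention is the documented
default because enrichment is the directional question asked of these data;
the test suite verifies both variants against a full enumeration of the
conditional distribution built from binomial coefficients alone.

### Trio random-occurrence probability and FDR

The chance that one specific trio of samples shares a variant of population
frequency $\mathrm{MAF}$ is $\mathrm{MAF}^3$ per eligible site. Aggregating
over sites, `trioProbability()` computes

$$P_{\mathrm{trio}} = N_{\mathrm{SNPs}} \times \mathrm{MAF}^3,$$

with $N_{\mathrm{SNPs}} = n_{\mathrm{genes}} \times \ell_{\mathrm{median}} /
1000$ under the default per-kilobase scale (20,000 genes × 26.288 kb =
525,760 effective sites; roughly one polymorphic site per kilobase of gene
sequence). The per-base-pair scale is also implemented (`lengthUnit =
"bp"`) and clearly labelled in all output: it is 1000-fold larger, and
chaining it through the trio count yields a value far above 1 that cannot
be read as a probability — the package flags rather than silently corrects
this scale ambiguity, because only the per-kilobase scale produces an
internally consistent probability chain.

With defaults the per-trio probability is $6.57 \times 10^{-8}$. Multiplied
by the number of possible trios in a 100-sample cohort,
$\binom{100}{3} = 161{,}700$ (`nTrios()`), the estimated probability that
*any* trio shares such a variant by chance is $\approx 0.0106$ — about 1%,
interpretable as the false discovery rate of the observed trio
(`fdrEstimate()`). The linear (union-bound) form $\min(1, p \cdot
N_{\mathrm{trios}})$ is primary; the exact complement form
$1 - (1-p)^{N_{\mathrm{trios}}}$ is reported alongside and agrees to four
decimals whenever the product is small. The trio count uses the cohort size
actually supplied; analyses of an $n{+}1$-sized cohort that quote
$\binom{100}{3}$ remain reproducible by setting `cohortN = 100`.

### Conservative Bonferroni adjustment

`bonferroniAdjust()` multiplies the unrounded enrichment p-value by
externally supplied genome-wide counts of high-confidence loss-of-function
variants (defaults 443,769 and 179,774, two published census figures for
large human cohorts) and caps at 1. These counts are literature constants,
deliberately *not* estimated from the data: a 100-sample cohort harbors far
fewer distinct LoF variants than a 100,000-sample census, so the adjustment
is conservative by construction.

```{r rarity-example}
rarityReport(carrierTable(3, 98, 56, 589929))
```

## Cohort-structure checks

### Kinship

`estimateKinship()` uses the KING-robust heterozygote-concordance moment
estimator,

$$\hat\phi_{ij} = \frac{N_{Aa,Aa} - 2N_{AA,aa}}{N^{(i)}_{Aa} + N^{(j)}_{Aa}},$$

restricted to sites genotyped in both samples. It was chosen over
projection-based estimators (PC-Relate and kin) because it is fully
determined by the genotypes alone — no reference panel, no ancestry
adjustment, no tuning — and because the claims the pipeline makes
(unrelatedness verdicts on a 0–0.5 scale) are estimator-agnostic. The
kinship report header records the estimator so that downstream consumers
know a moment method, not PC-Relate, produced the values. Estimates are
produced per minor-allele-frequency stratum (all polymorphic variants,
MAF > 0.1, MAF > 0.05, computed from within-cohort frequencies); for a
homogeneous cohort the three columns should agree closely, and the test
suite asserts they do within ±0.05. The unrelatedness verdict uses the
conventional cutoff φ < 0.044, the midpoint between third-degree relatives
and unrelated pairs; it is configurable.

The estimator's sampling noise matters for interpretation: for unrelated
pairs its standard deviation is ≈ 0.012 at 5,000 SNPs and shrinks like
$L^{-1/2}$. Single-pair estimates at a few thousand sites therefore scatter
by a few hundredths around their expectation, which is why validation
asserts Monte-Carlo recovery of the expected values (0.25 for
parent–offspring and full siblings, 0 for unrelated) rather than
per-pair precision beyond that noise floor, and why the verdict test uses
20,000 sites, where the 0.044 cutoff sits more than 6 standard deviations
from 0.

### Population structure

`hweNormalizedPca()` performs PCA under Hardy–Weinberg scaling: each
variant is centered by $2\hat p$ and scaled by $\sqrt{2\hat p(1-\hat p)}$,
with $\hat p$ the alternate-allele frequency *of the analyzed samples
themselves* — the input matrix is the analysis universe; merging with an
external reference panel is out of scope. Missing calls are mean-imputed
per variant before normalization; monomorphic and zero-variance variants
are dropped and counted (the normalization is undefined at $\hat p \in
\{0, 1\}$, and an all-heterozygote column carries no information). Scores
come from the singular value decomposition of the normalized
samples-by-SNPs matrix; because components are sign-ambiguous, each
component's sign is fixed so its largest-magnitude score is positive.
`subsampleSnps()` provides the seeded random site subsample; the fraction
is an explicit parameter throughout.

### Local linkage disequilibrium

`ldScan()` compares a focal variant with every variant within ±100 kb
(inclusive at the boundary) that has at least three non-reference calls,
both thresholds configurable. $r^2$ is the squared composite
genotype-dosage correlation — the appropriate choice for unphased data —
and $D'$ is computed from maximum-likelihood two-locus haplotype
frequencies obtained by EM (`emHaplotypeFreqs()`; at most 50 iterations,
convergence tolerance $10^{-8}$ on the largest frequency change; only the
double-heterozygote class is phase-ambiguous). Partners with $r^2 \ge
0.999$ — a floating-point guard, not literal equality — are reported as the
candidate regional haplotype (`perfectLdPartners()`). On phased data,
direct haplotype counting (`haplotypeDPrime()`) serves as the oracle: the
EM estimate provably coincides with it whenever no double heterozygotes
occur, and converges to it when strong LD pins the ambiguous phase, the
two situations the test suite checks.

## The synthetic cohort generator

`simulateCohort()` emulates the statistical structure the analysis
assumes, with every planted feature recorded in a `TruthSet`:

- **Planted triplet.** One stop-gain variant heterozygous in exactly
  `nCarriers` samples (default 3), annotated with a reference frequency of
  $4.276 \times 10^{-5}$, flanked by two intergenic partners placed on the
  same carrier haplotype — perfect LD by construction.
- **Background variation.** Sites drawn independently per haplotype from
  per-cluster allele frequencies under a Balding–Nichols model (ancestral
  frequency uniform on `backgroundMafRange`, cluster frequencies Beta with
  variance set by `clusterFst`). Two clusters with configurable fractions
  support PCA validation; the default is a single panmictic population.
- **Pedigree pairs.** Parent–offspring and full-sibling pairs generated by
  Mendelian transmission from simulated parental haplotypes. Transmission
  is per site rather than whole-haplotype: background sites are in linkage
  equilibrium, so free recombination between sites changes no downstream
  statistic, while whole-haplotype transmission would make a sibling
  pair's *realized* kinship trimodal (0, 0.25 or 0.5 with no
  recombination) and thus unusable for validating the 0.25 expectation.
  The planted triplet haplotype itself is intact; carriers are never
  pedigree members.
- **Determinism.** All randomness flows from the configuration seed;
  identical configurations produce byte-identical VCFs, and the caller's
  RNG state is untouched.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: sequencing and genotyping error,
within-region background LD, recombination maps, genotype-calling
missingness patterns beyond a uniform rate, and selection. The simulator
validates the *statistical machinery*, not the wet-lab pipeline upstream
of it.

## Numerical and interface choices

- Dosages are 0/1/2/`NA`; carriers are dosage ≥ 1 everywhere (the analysis
  targets heterozygous sharing but must count homozygotes as carriers).
- A variant with *missing* reference frequency passes the rarity filter by
  default — absence from the reference is itself evidence of rarity — with
  a strict mode (`missingMaf = "fail"`) available.
- Loss-of-function is operationalized as the single consequence term
  `stop_gained`; frameshift and splice classes are deliberately out of
  scope (`lofTerms` is exposed for users who disagree).
- The gene panel is an input artifact (gene list plus optional BED
  intervals), not something the package computes: panel construction from
  expression atlases and phenotype ontologies is a curation task with no
  algorithmic definition. A variant with no gene annotation can still match
  the panel positionally through the BED intervals.
- VCF 4.2 round-tripping goes through Bioconductor's VariantAnnotation;
  multi-allelic records are split into per-alternate biallelic records
  with per-allele dosages. Reference frequencies survive the float
  round-trip to about 7 significant digits.
- Missing genotypes: pairwise deletion for kinship, mean imputation for
  PCA, pairwise-complete correlation for LD — each the standard choice for
  its statistic.

## Problem sizes used in validation

The shipped tests validate kinship recovery on cohorts of 12 samples at
5,000 SNPs over 10 seeds (with verdict tests at 100 samples and 20,000
SNPs), end-to-end triplet recovery on 100-sample, 1,000-variant cohorts
over 10 seeds, PCA separation at $F_{st} = 0.05$ with 2,000 SNPs over 10
seeds, exact-test enumeration equivalence over all 2×2 tables with total
≤ 60, and null calibration of the enrichment test over 10,000 simulated
cohorts. These sizes were chosen so the full statistical argument runs in
minutes on a laptop while keeping Monte-Carlo noise well inside the
asserted bounds.

## Limitations

- The enrichment test conditions on reference carrier counts taken as
  fixed truth; uncertainty in the reference database is not propagated.
- The trio probability treats sites as independent and equally rare at the
  nominal MAF; it is an order-of-magnitude device, not a calibrated
  genome-wide model, and its site-count scale ambiguity is flagged in all
  output.
- KING-robust kinship assumes a reasonably homogeneous cohort; in strongly
  admixed cohorts, moment estimates of unrelated pairs can be biased
  negative. The PCA stage exists precisely to check that assumption.
- $D'$ from EM inherits the usual instability of haplotype-frequency
  estimation at very rare alleles; $r^2$ is the primary LD measure and the
  perfect-LD call uses it alone.
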