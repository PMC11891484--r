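---
title: "Methods: diversity, inbreeding and genetic load from SNP panels"
author: "popgenload"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, inbreeding and genetic load from SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models and
the assumptions behind them, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical
conventions adopted where a choice had to be made.

# The data model

Everything downstream operates on a `VariantPanel`, a
`RangedSummarizedExperiment` of biallelic SNPs (rows) by samples (columns)
whose `gt` assay holds ALT-allele dosages 0/1/2 with `NA` for missing
calls. A `PolarizedVariantPanel` is the same object restricted to sites
where the reference allele *is* the ancestral allele, so dosage reads
directly as derived-allele dosage. Polarization **drops** sites whose
ancestral state equals ALT rather than re-orienting them — a deliberate
convention: flipped sites would mix two error processes (ancestral
misassignment and reference error) into the derived-allele counts, and the
drop counts are reported so the loss is visible.

The filter cascade runs in a fixed order (quality, biallelicity, depth
masking, missingness, MAF) because the steps interact: depth masking
changes missingness, and missingness changes allele frequencies. Depth
bounds are fixed integers rather than multiples of the realised mean depth
so that the same configuration always selects the same sites. The cascade
is idempotent, and the per-step removals plus survivors always sum to the
input count — both are enforced by tests.

# Diversity statistics

*Windowed π* tiles chromosomes with non-overlapping windows (default
100 kb in field use; tests use windows equal to their toy chromosomes) and
sums the per-site unbiased heterozygosity 2·n_alt(n−n_alt)/(n(n−1)),
divided by window length — so windows with no SNPs are 0, and the
statistic is per-base-pair, comparable across windows regardless of SNP
density. Its correctness is pinned to an exhaustive haplotype-pair
comparison oracle on small phased toys.

*Tajima's D* uses the 1989 constants exactly as published; `S = 0` returns
`NA` rather than 0 because the statistic is undefined there.

*F*~ST~ is Weir–Cockerham 1984 for two populations, aggregated as the
ratio of summed variance components (the "weighted" convention of the
standard VCF tooling) rather than the mean of per-site ratios, which is
noisier and biased at low-information sites. Negative estimates are
reported as computed; the estimator has an O(1/n) negative small-sample
term at undifferentiated sites, which is why the "identical populations"
check asserts |θ̂| small rather than zero. Sites where either population
has fewer than two called diploids, or that are globally monomorphic, are
skipped.

*Individual F* follows the `--het` convention: observed versus expected
homozygosity with the expectation computed from panel-wide allele
frequencies and the n/(n−1) finite-sample correction, over the
individual's non-missing calls at panel-polymorphic sites. Population
F~IS~ is the mean over members.

*LD decay* uses genotype r² (squared Pearson correlation of dosages over
mutually called samples), not haplotype EM — it requires no phasing and
matches what the standard decay tools compute by default. The half-decay
distance is the midpoint of the first distance bin whose mean r² falls to
half the maximum bin mean. Unlinked sites converge to the 1/n correlation
floor, not to zero; tests assert that floor explicitly.

# Runs of homozygosity

The detector reproduces the PLINK scanning-window logic: windows of
`windowSnps` consecutive SNPs are homozygous if they contain at most
`windowMaxHet` heterozygous and `windowMaxMissing` missing calls; a SNP's
hit rate is the fraction of covering windows that are homozygous; hit SNPs
(rate ≥ `hitThreshold`) form candidate runs; runs split at inter-SNP gaps
≥ `maxGapKb`; surviving segments must satisfy `minSnps` (non-missing),
`minKb`, and the `densityKbPerSnp` spacing cap. The four headline
parameters default to 10 SNPs / 100 kb / 10 kb-per-SNP / 100 kb; the
window machinery defaults to the cited tool's 50 / 1 / 5 / 0.05 since
only the four headline flags are commonly reported.

Conventions worth stating: coordinates are 1-based inclusive and segment
length is end − start + 1; missing genotypes inside a segment do not count
toward `minSnps`; chromosomes shorter than one window are scanned as a
single window. The thresholds apply to assembled maximal runs, not to
sub-intervals — a run that fails the density cap is discarded whole, as
the scanning tools do. The independent validation is an exhaustive
interval search (all (start, end) pairs, maximality under the hereditary
hit/gap constraints, then thresholds) run on 100+ random chromosomes; note
that a homozygous run shorter than the scanning window that is flanked by
heterozygous sites is invisible to both — windows straddling the flanks
contain too many heterozygotes — so toy fixtures use windows smaller than
their planted runs.

F~ROH~ divides by `lAuto`, a **required** argument: whether the
denominator is the anchored or the full assembly length changes every
value, so the package refuses to guess. Length classes default to
short < 200 kb ≤ medium ≤ 400 kb < long, configurable.

# Kinship

The between-family KING-robust estimator was chosen over the within-family
variant because population samples are the use case and it is robust to
structure (no allele-frequency estimate enters). Sites below 5% MAF are
excluded by default for estimator stability (configurable to 0). Degree
cutoffs are the powers-of-two midpoints (2^−3/2^, 2^−5/2^, 2^−7/2^,
2^−9/2^); within first degree, parent–offspring is separated from full
siblings by the opposing-homozygote rate (default < 0.005 ⇒ PO), since PO
pairs cannot show opposing homozygotes without genotyping error. Pairs
with fewer than `minSites` (default 100) mutually called polymorphic sites
are refused rather than estimated. The estimate is exactly symmetric and
invariant to allele-label swaps; both are tested, as is ≥95%
degree-recovery accuracy on simulated pedigrees (100 pedigrees × 5
relationship types at 2 × 10⁴ unlinked sites).

# Mutation classes and genetic load

Effect annotation assigns one category per site using the precedence
splicing > stop-gain > stop-loss > start-loss > nonsynonymous > synonymous
> UTR > intronic > upstream/downstream > intergenic (ties across
transcripts resolved the same way). Splicing means within 2 bp of an
intron boundary — the canonical donor/acceptor dinucleotides. Start-loss
is any change to the initiator ATG. Transcripts whose CDS length is not a
multiple of 3 are skipped with a warning. One transcript per gene is
assumed in toy data. Because categories are disjoint by precedence, their
percentages sum to 100; overlapping-category accountings seen in some
published tables cannot be reproduced by construction, and this is the
package's deliberate choice.

Grantham distances are computed from the published residue composition,
polarity and volume with α = 1.833, β = 0.1018, γ = 0.000399 and ρ
normalising the 190-pair mean to 100; the implementation is checked
against an independent recomputation and against published anchor entries
(Leu–Ile = 5 through Cys–Trp = 215) within ±1 of the printed integers.
RADICAL uses the strict inequality D > 150. SIFT-style deleteriousness is
**consumed, not computed**: reimplementing a protein-database method is
out of scope, so DEL status comes from a score table (real runs) or the
synthetic score generator (tests); unscored sites are excluded from DEL
counts rather than assumed benign.

Load counting is literal: each heterozygous site contributes 1 derived
allele, each homozygous-derived site 2; homozygous load is twice the
homozygous-derived genotype count; missing genotypes contribute 0 with no
rescaling, because the ratio p has a fixed denominator (2 × the polarized
SNP universe). R~p~ = p^class^/p^total^ therefore scales with the class's
share of the site universe: its raw expectation for a randomly labelled
neutral class equals that share, and the unbiasedness checks divide by the
realised label fraction before asserting a centre of 1. Comparisons of the
same class across populations — the statistic's purpose — are unaffected
by that scale. Load–population-size correlations use per-individual points
against population-level predictors (a per-population-mean variant is a
trivial aggregation away), with the analytic two-sided p-value
cross-checked against a permutation null in tests.

# Watterson N~e~ and rate conversions

The chain S = N~SNP~/L~genome~, θ~W~ = S/a~n~, N~e~ = θ~W~/(4μ) is
implemented with n counting **haploid sequences** (twice the diploid
sample count): Watterson's estimator is defined on sequences, and the
convention is stated on every output. μ is per site per year with an
explicit generation-time conversion (`perGenerationRate()`); the package
never converts silently, because the silent year/generation mix-up is the
classic failure mode of this estimator. K~S~/2T and K~S~/2μ conversions
are exact inverse arithmetic with zero-denominator errors.

# The synthetic-data generator

The forward simulator is a discrete-generation diploid Wright–Fisher model
with: multiplicative viability selection per mutation class (fitness 1,
1−hs, 1−s); island-model migration; deme splits (a new deme founded from a
parent at a given generation) and stepwise bottleneck schedules; Poisson
recombination along each chromosome; and infinite-sites mutation on finite
coordinate grids (new mutations take fresh positions; fixed and lost
columns are pruned, with fixations counted per class as ground truth). A
forward — rather than coalescent — simulator was chosen so that selection
classes and pedigree structure are exact by construction rather than
approximated. All randomness flows from one seed; the same seed produces
byte-identical VCF/popmap/truth files, which is itself a tested contract.

It emulates the features the pipeline needs to be tested against: demes
with divergence and bottlenecks, related individuals, mutation classes
under differing selection, ancestral polarization (the ancestral allele is
the simulation's 0 allele, emitted as REF with an AA tag), and — via
`makeToyGeneModels()` — genes on both strands with planted sites in every
effect category. It does **not** emulate realistic recombination maps,
gene conversion, linked-selection genomic landscapes, sequencing error or
depth heterogeneity; passing tests therefore certify the estimators'
statistical behaviour under their model assumptions, not robustness to
real-data artefacts such as reference bias or batch-variable missingness.

Pedigree genotypes use independent assortment per site on unlinked founder
panels drawn from a truncated 1/p frequency spectrum (MAF ≥ 0.05); that is
the regime kinship estimation assumes. For homozygosity-tract questions
the tests instead build selfed individuals with explicit crossover
gametes, since tracts require linkage.

## Simulation scales

Test and validation runs use desk-scale parameters chosen once: demes of
N = 30–100 diploids, chromosomes of 10–50 kb, μ = 1–2 × 10⁻⁵ per site per
generation (so that 4Nμ diversity is measurable on short sequences),
recombination up to 5 × 10⁻⁵ per bp where quasi-independent sites are
needed (F~ST~ and Watterson checks), burn-ins of ≥ 10N generations for
equilibrium claims, and 10–50 replicates per stochastic assertion with
confidence bands derived from the replicate spread. These sizes are the
package's chosen study conditions for validation; the estimators
themselves have no scale assumptions beyond their formulas.

# Known limitations

- Two-population F~ST~ only; multi-population and Nei-family estimators
  are out of scope.
- No phasing and no haplotype statistics; LD is genotype-based.
- ROH calling is the scanning-window heuristic, not an HMM; very short or
  SNP-sparse tracts below the window/density resolution are undetectable
  by design.
- Effect annotation handles SNPs against single-transcript gene models;
  indels and isoform selection are out of scope.
- The simulator's infinite-sites approximation refuses duplicate
  positions rather than modelling recurrent mutation.
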