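---
title: "Population genomics from museum specimens: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population genomics from museum specimens: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Whole-genome resequencing of historical specimens — for example museum study
skins of the silver/maroon oriole complex (MEL = *O. mellianus*, TRA, ROB,
NIG, ARD = *O. traillii* subspecies) — yields short, damaged DNA fragments at
low to medium coverage. Hard genotype calls on such data are unreliable, so
the analyses here carry genotype *likelihoods* (GLs) as far as possible:
likelihood-based SNP calling and allele frequencies, GL-aware population
structure, and filter cascades designed for degraded input. `museopop`
implements that workflow end to end, together with a coalescent simulator
that generates museum-like data with known truth, so that every analysis
stage has a parameter-recovery test.

# The simulator

`species_tree_config()` describes a rooted species tree as backward-time
population merges, per-population diploid effective sizes, optional pulse
admixture, and a per-site per-generation mutation rate. The defaults encode
the study system: five taxa on `(((MEL,TRA),ROB),(ARD,NIG))`, splits on the
order of 1e5 generations (127,000 for MEL–TRA, 224,000 for their common
ancestor with ROB), the flycatcher-calibrated mutation rate `mu = 4.6e-9`,
and the museum sampling design (6 + 5 + 3 + 1 + 1 diploids).

Each window is simulated by an independent discrete-event structured
coalescent — windows model distant 10-kb slices of the genome, selected
precisely because they are approximately unlinked, so no intra-window
recombination is modelled. Mutations fall on the genealogy as a Poisson
process (`mu` per site per generation), ancestral bases are i.i.d. uniform
and derived bases follow Jukes–Cantor. Multiple hits at one site are
excluded by construction (one mutation per segregating position), a standard
infinite-sites approximation that is accurate for the per-window mutation
counts used here.

Post-mortem damage follows the canonical deamination shape: a C at offset
`i` from the 5' end of a fragment reads as T with probability
`d5 * lambda^i`, and symmetrically G→A at the 3' end. The geometric decay is
a modelling choice — real damage profiles are shown only qualitatively in
most museomics work — and the profile estimator makes no use of it, so
recovery tests are a genuine check. Fragment lengths are log-normal
(default mean 80 bp, sd 30 bp), truncated to [20 bp, window length]; real
archives rarely publish their full fragment-length distributions, so these
defaults are plausible rather than matched. Damage alters the molecule, not
the base quality; sequencing error is applied separately at the pileup stage
at rate `10^(-Q/10)`, uniformly to the three non-true bases.

One global seed expands into per-stage, per-window sub-seeds through
`subseed()`, a fixed multiplicative scheme chosen so that nested derivations
(seed → replicate → window) cannot collide; every stage is bit-reproducible.

What the simulator does *not* emulate: alignment and mapping artefacts,
reference bias, indels, recombination within windows, base-quality
miscalibration, and contamination. Tests passing on simulated data therefore
validate the statistical machinery, not robustness to those upstream
artefacts.

# Genotype likelihoods and the filter cascade

GLs use the GATK read model: `P(base | allele) = 1 - eps` for a match and
`eps/3` otherwise, heterozygotes mixing their two alleles equally; the
genotype likelihood is the product over reads, reported as log10 and
normalized so the maximum of each triple is 0. The minor-allele frequency is
maximized by EM under Hardy–Weinberg (start 0.25, tolerance 1e-8, at most
100 iterations), and the SNP test is the likelihood ratio against
`maf = 0`. Because the null pins the frequency to the boundary of its
parameter space, the p-value uses the `0.5*delta_0 + 0.5*chi2(1)` mixture.
Sites pass at `p < 1e-6`. A third-allele test runs the same machinery on the
(major, third-most-common) pair and rejects sites significant at the same
threshold — the triallelic rejection is deliberately symmetric with the SNP
test, since the original tooling does not publish its internals.

The filter cascade mirrors the museum workflow: individual genotypes with
depth outside [10, 100] become missing; sites fail with more than one
missing individual, minor-allele frequency below 0.12 (with 16 diploids
this demands at least 4 supporting chromosomes), or a significant third
allele. `filter_sites()` recomputes all flags from scratch and is
idempotent. Two frequency readings coexist deliberately: the ML GL-based
frequency (used for filtering, mirroring ANGSD) and hard-call counts
(mirroring VCFtools); high-depth simulations confirm they agree.

Hard calls are the argmax of the GL triple. This stands in for a
haplotype-based joint caller: re-implementing such a model is out of scope,
and the downstream contract (identical filter cascade, consensus building,
windowed statistics) only needs per-site genotypes. Exact GL ties are
reported missing rather than resolved arbitrarily.

# Consensus, windows and divergence dating

Consensus sequences code heterozygotes with IUPAC ambiguity letters and mask
positions with depth below 10 (inclusive at 10) or above three times the
individual's mean depth (exclusive at the bound). Window extraction takes
10-kb windows every 100 kb (i.e. 90-kb gaps) on contigs strictly longer than
100 kb, anchored at offset 0 — the original tiling phase is unstated, and
offset 0 is the only canonical choice — and retains a window iff at least
half of its columns have data in at least half of the individuals. For
simulated data the contigs *are* the windows (`consensus_windows()`), since
the simulator builds the unlinked 10-kb design directly.

p-distances use pairwise deletion and an explicit IUPAC-aware score per
column: identical codes 0; heterozygote versus a containing homozygote 0.5;
two heterozygotes sharing one allele 0.75; anything disjoint 1. The table
corresponds to the expected allele-sharing mismatch for every pair except
identical heterozygotes, which score 0 (two R individuals carry the same
genotype); it is pinned by unit tests because published distance tools do
not document their ambiguity conventions.

Divergence times scale as `T = p / (2 * mu)` — two lineages accumulate
mutations independently after a split. The one-lineage convention `p / mu`
would halve every date; the chosen convention reproduces the magnitude of
the study system's published dates (a p-distance of 1.1684e-3 gives 127,000
generations, which at 3.7 years per generation stays under the 500,000-year
bound) and is isolated in `divergence_generations()` so the alternative is a
one-line change. Raw `p/(2mu)` dating includes the ancestral coalescent
contribution (about `2*Ne` generations in expectation). The recovery
experiment is sized from that error budget: Ne = 500 keeps the known bias
near +2%, and 100 windows of 40 kb put roughly 2,000 mutations on the
cross-population paths, for ~2.3% Poisson noise — together several standard
errors inside the 10% recovery band. The consensus step there keeps sub-MAF
variants, since dropping them would deflate p-distances.

# Window trees and topology weighting

Per-window trees are neighbor-joining on IUPAC p-distances (`ape::nj`, with
negative branch lengths clamped to zero). The study's per-window
maximum-likelihood searches are deliberately not reproduced: the quantity
consumed downstream is the distribution of *topologies*, for which NJ on
10-kb windows is an accurate, orders-of-magnitude cheaper stand-in. This
substitution is the package's most consequential simplification and is
stated here prominently.

Topology weighting iterates over combinations of one tip per group, prunes
the window tree, roots it on the outgroup tip and classifies the induced
group-level topology; weights are per-topology fractions. Exhaustive
enumeration applies up to 10,000 combinations, beyond which 1,000 uniform
samples are drawn (both thresholds are documented guesses — the reference
implementation's subsampling defaults are unpublished; sampled and
exhaustive weights agree within ±0.03 in tests). With the in-group triple
{MEL, TRA, ROB} and the island pair as outgroup there are exactly three
rooted in-group topologies. Two simulated regimes bracket the biology: deep
clean splits (the species topology takes weight > 0.95) and two splits one
generation apart (complete incomplete-lineage-sorting, all three topologies
near 1/3) — the latter mirroring the study's finding of three almost equally
frequent topologies.

# ABBA–BABA

Derived-allele frequencies are polarized by the outgroup's major allele;
sites where the outgroup is polymorphic above 0.2 minor frequency are
dropped (the source text is silent; fully polymorphic outgroup sites carry
no polarization information). Per site, `ABBA = (1-p1) p2 p3 (1-pO)` and
`BABA = p1 (1-p2) p3 (1-pO)`; `D = (sum ABBA - sum BABA)/(sum ABBA + sum BABA)`,
with significance at `|Z| > 3` from a delete-one-block jackknife.

The jackknife weights deserve a note. Blocks default to one per simulated
window (or a bp-length block on real contigs) and differ in informative
mass `m_j`. The variance estimator is the influence-weighted form
`SE^2 = g/(g-1) * sum_j [(1 - m_j/n)(D - D_(-j))]^2`, which reduces to the
classic delete-one jackknife for equal masses. The more common pseudovalue
(Busing-style) form implicitly assumes per-block variance shrinks like
`1/m_j`, which holds when a block contains many independent genealogies but
fails for single-genealogy windows, where it understates the variance by
half or more; simulation in the test suite verifies the chosen form is
calibrated in both regimes. Null calibration (no gene flow: `|Z| < 3` in at
least 95 of 100 replicates) and power (a 20% pulse from P3 into P2 detected
with `D > 0, Z > 3` in at least 95 of 100) are part of acceptance, run on a
four-population radiation with ≥3,000 informative sites per replicate.

The comparison scan enumerates individual-level tests (conspecific P1/P2
pairs against every other-taxon P3 and each outgroup individual) and the
population-level test (sister taxa as P1/P2, remaining in-group taxa as P3).
Comparisons with no informative sites — e.g. an island P3 whose private
variants the MAF filter removes — are skipped with a warning rather than
failing the scan.

# Windowed Fst

Per-site Weir–Cockerham components a (among populations), b (among
individuals within), c (within individuals) follow the 1984 two-population
diploid estimator, with per-site `Fst = a/(a+b+c)`. An independent
allele-copy ANOVA implementation (mean squares over the two copies per
individual) serves as the oracle in tests, with agreement to 1e-12.
Windows are nonoverlapping 50-kb tiles from offset 0; both the mean of
per-site ratios and the ratio of summed components are reported, because
"mean Fst" is ambiguous between the two in standard tooling. Z-scoring and
outlier calling use the mean-of-ratios by default, with the other one flag
away; negative per-site values are retained in window means, and windows
need at least 5 defined sites to enter the Z distribution (unstated in the
source; a documented choice). Outliers are `Z > 1.15` (the top-5%
convention), with the empirical top-5% set reported alongside since the two
definitions can disagree. Gene annotation is plain half-open interval
overlap against a user-supplied BED/GFF.

# Population structure

Expected dosages are the posterior mean of the genotype under the GL and a
Hardy–Weinberg prior at the site frequency, with missing individuals
mean-imputed at `2f`. PCA standardizes by `sqrt(2f(1-f))` and
eigendecomposes the individual covariance. This is a single-pass
simplification of iterative individual-allele-frequency PCA: the package
uses PCA only to display clustering, which the single pass preserves.

Admixture estimation maximizes the NGSadmix-style likelihood
`sum log sum_g GL(g) * Binom(g | 2, h)` with `h = QF'`, by EM. Q starts at
a flat Dirichlet draw. F starts at k-means centers of the expected dosages
(20 restarts, randomly seeded per replicate) plus uniform jitter rather
than at jittered pooled frequencies: starts clustered around the pooled
frequency fuse clusters into local optima at an appreciable rate, while
center-seeded starts cover the distinct clusters from the first iteration —
a deliberate deviation from the simpler initialization, adopted after the
fused-optimum failure mode appeared in testing. EM stops at a log-likelihood
gain below 1e-6 or 2,000 iterations; the trace is retained and monotonicity
is asserted in tests. Replicate runs (15 per K by default) record their
seeds; Evanno's `DeltaK = |L''(K)| / sd(L(K))` picks K on interior values,
with zero-scatter K excluded with a warning. Cluster-label alignment across
replicates is out of scope; the best-likelihood replicate per K is reported.

The structure recovery experiment simulates the study's sampling (6/5/3/1/1)
as a rapid radiation — in-group splits 45,000 and 48,000 generations ago and
the island clade at 62,000, all with Ne 20,000, the island pair joined by a
shallow 3,000-generation split — the high-ILS regime the study itself
infers, with four clusters the correct answer. Because the center-seeded EM
is effectively deterministic given a data set, naive replicates would carry
no scatter and DeltaK's denominator would degenerate to numerical noise; in
this experiment each of the 15 replicates therefore analyses its own random
draw of 1,500 passing SNPs (the same draw across all K within a replicate),
so the replicate scatter is honest data-resampling noise at a comparable
scale for every K. EM is capped at 700 iterations, far past where the
between-K likelihood differences that drive DeltaK are resolved. DeltaK is
known to gravitate toward the top level of a hierarchy; in this regime it
selects K = 4 across the seeds we examined, but the race between the K = 3
and K = 4 statistics is genuinely close on some data sets — an honest
property of the statistic, not of the implementation.

# Problem sizes and numerical choices

The simulation experiments use: 100 replicates x 400 windows x 10 kb for
D-statistic calibration and power (two diploids per population, Ne 10,000,
mu 1e-7); 100 windows x 40 kb at depth 30 with Ne 500 for divergence recovery; 40 and
300 windows for the deep and radiation topology regimes; 40 windows at
depth 20 for structure. These sizes were chosen so each experiment's
binomial/sampling error sits several-fold below the acceptance band it
feeds. Degenerate inputs are handled explicitly throughout: empty read sets
are missing data, zero-denominator frequencies and distances are NA (never
silently 0), exact GL ties are missing, SE = 0 jackknives are flagged
degenerate, and zero-variance Fst windows produce a warning and no outliers.

# Known limitations

NJ replaces per-window ML tree search; FreeBayes-style joint haplotype
calling is approximated by argmax-GL hard calls; PCA omits the iterative
individual-frequency refinement; damage is simulated and profiled but GLs
are not damage-rescaled (matching the original workflow, which also relied
on filtering rather than rescaling); no recombination within windows; no
mapping or reference-bias artefacts. Divergence dates inherit the ancestral
polymorphism bias of raw `p/(2mu)` scaling and should be read as upper
bounds for shallow splits with large Ne.
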