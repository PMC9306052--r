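---
title: "Methods: subgenome evolution and homoeolog expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subgenome evolution and homoeolog expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subgenomics)
```

`subgenomics` analyses allopolyploid genomes: codon-level divergence
between gene copies, collinear block detection, Ks-based dating of
whole-genome duplication (WGD) and speciation, outgroup-guided
subgenome phasing, and homoeolog expression bias. This vignette is the
package's account of the models it implements, the parameters that
matter, the design decisions taken where the methodology was open, and
what its synthetic ground-truth generator does and does not emulate.

## Codon-level substitution statistics

All pairwise statistics operate on a `CodonPairAlignment`: two
in-frame sequences of equal length, gaps only in whole-codon units.
Columns containing a gap, an `N` or a stop codon are excluded from
every count; ambiguity codes are never resolved.

**Ka/Ks.** We implement Nei–Gojobori (1986) counting. Synonymous site
counts per codon enumerate all three possible changes at each
position (changes producing a stop count as nonsynonymous); site
counts are averaged across the two sequences. Codons differing at
more than one position are scored by averaging over all minimal
substitution pathways with equal weights, excluding pathways through
stop codons (if every pathway is blocked, the average falls back to
all pathways). Proportions are corrected with Jukes–Cantor,
$d = -\tfrac{3}{4}\ln(1-\tfrac{4}{3}p)$. Saturation ($p \ge 3/4$)
produces an `NA` distance — a first-class value that downstream
distribution code filters explicitly and reports in its drop tallies.
NG86 was chosen over a maximum-likelihood codon model because it is
transparent and exactly testable: the test suite verifies the whole
pathway-averaged difference table against brute-force enumeration.
The cost is mild: NG86 ignores transition/transversion and
codon-frequency biases, so absolute Ks values can differ by a few
percent from ML estimators on real data; peak *locations* in a Ks
distribution, which carry the dating signal, are robust to this.

One consequence worth knowing: even when a simulated history contains
only synonymous events, pathway averaging between two synonymously
drifted codons of the same amino acid can route through a different
amino acid (Leu TTG vs CTC passes through Phe on one of two
pathways), so Ka estimates are near zero rather than exactly zero.

**4DTv.** A codon column is a fourfold-degenerate site when both
codons belong to a fourfold family *and* their first two positions
are identical — without the prefix condition a third position could
be scored under amino-acid change, where its degeneracy class is not
well defined. The statistic is the fraction of those sites whose
third positions differ by a transversion. The multiple-hit correction
$-\tfrac12\ln(1-2v)$ is available but off by default: distributions
of the raw proportion are the primary output, and the corrected value
is undefined at $v \ge 0.5$.

## Synteny chaining

Blocks are chained per chromosome pair by dynamic programming in gene
rank space (dense per-chromosome orders), maximising
$\sum \text{match} + \text{gap\_penalty}\cdot\text{gaps}$ separately
for plus and minus orientations, with both-side rank gaps bounded by
`max_gap`. Chains are accepted greedily by descending score (ties:
anchor count, then lexicographic chromosome pair) until none reaches
`min_block_genes`. Defaults mimic MCScanX: match 50, gap penalty −1
per rank unit, `max_gap` 25, and the standard five-anchor block
minimum. Before chaining, hits are filtered at E ≤ 1e-10, the best 5
hits per query are kept, and within-genome hits between genes ≤ 5
ranks apart on one chromosome are collapsed as tandem arrays (tandem
duplications otherwise masquerade as WGD blocks). Determinism is a
contract: identical inputs give identical blocks regardless of hit
order, and every emitted block is re-validated against the block
invariants. GFF3 coordinates are converted to the internal 0-based
half-open convention on read; BED is read natively.

Homoeolog pairs are anchors of blocks whose chromosomes carry
different subgenome labels (A member first, duplicates resolved to
the highest-scoring block). WGD paralog pairs are focal gene pairs
where one outgroup gene anchors exactly two focal genes that are
themselves a within-genome anchor — the "two copies with one syntenic
outgroup copy" configuration.

## Ks distributions and dating

Ks values are filtered to [0.005, 2.0] by default: the lower bound
removes allelic/assembly near-zero artifacts (recent species-specific
peaks can sit at Ks 0.02–0.03, so the bound is configurable), the
upper bound removes the saturated tail. Modes come from a Gaussian
KDE on a 512-point grid, Silverman's rule by default with a
fixed-bandwidth override for reproducibility; strict local maxima
below 5% of the maximum density are discarded as grid noise, and
modes closer than one bandwidth merge to the higher one. A mode whose
density is under twice the mean grid density is flagged
low-confidence (a flat distribution supports no narrow peak). Ages
use $T = K_s/(2\lambda)$ with $\lambda = 6.5\times10^{-9}$
substitutions/site/year (the average grass rate), always echoed in
the output metadata. Within-genome modes are labelled WGD candidates,
between-genome modes divergence candidates; ages are computed from Ks
only (the 4DTv panel is descriptive).

## Subgenome phasing

The distance between a focal and an outgroup chromosome is the mean
NG86 Ks of their single-copy syntenic ortholog alignments (saturated
values excluded) — an explicit, testable operationalisation of
"closer genetic relationship". In an allotetraploid most chromosome
pairs share no orthologs at all; such pairs are structurally absent
(NA), while pairs *with* data but fewer than `min_genes = 10` usable
values are flagged, and the matrix is rejected when more than 10% of
data-bearing pairs are that thin.

Each outgroup chromosome must claim exactly two focal chromosomes, so
the matching is solved globally (Hungarian algorithm on the
focal-by-outgroup matrix with duplicated outgroup columns) rather
than per-chromosome nearest neighbour, which could let two focal
chromosomes claim the same partner. Within a matched pair the closer
chromosome joins subgenome A — "A" is by convention the
outgroup-proximal subgenome, and `seed_partition` flips the naming
without touching partners or margins. The margin (distance difference
between the two partners) is the support for each call; margins below
0.01 are flagged low-confidence, exact ties ambiguous. When the 2:1
cardinality fails the function falls back to nearest-outgroup
labelling with a warning instead of guessing a pairing.
Neighbor-joining trees of chromosome distances (via `ape::nj`,
Q-matrix criterion and Saitou–Nei branch lengths, with negative
branches clamped to zero and the deficit moved to the sister edge)
serve as the visual companion of the assignment.

## Expression bias, DEGs and paralog divergence

HEB is $\log_2((A+c)/(B+c))$ with pseudocount $c = 0.1$ FPKM,
computed as a difference of logs so antisymmetry is exact. A pair is
testable in a sample only when its higher-expressed member reaches 1
FPKM — below that, ratios are noise. Dominance uses the ratio-2 rule,
boundary inclusive (a ratio of exactly 2 is dominant). The headline
"biased in at least one sample" set contains pairs dominant in ≥ 1
sample; each such pair's direction is the majority across its
dominant samples (ties counted separately), and both the pair-level
and event-level tallies are reported because the two denominators
answer different questions.

DEG calling keeps the standard threshold rule — raw p < 0.05 and
|log2FC| ≥ 1 — as the tested contract, with p-values from Welch's
two-sample t-test on log2(FPKM + c). Raw p is deliberate (the rule is
a fixed published threshold, documented prominently); enrichment
p-values, by contrast, are BH-adjusted within each run. The χ²
subgenome-balance test is a 1-df goodness-of-fit against a 1:1
expectation. Paralog pairs are classed 0/1/2 by how many members are
DEGs in *any* contrast (the analyses pool six treated-vs-0 h
comparisons). Enrichment is a one-sided hypergeometric
over-representation test per term.

## The synthetic allotetraploid generator

The generator is first-class, tested code, and its defaults *are* the
study conditions: 10 outgroup chromosomes × 60 genes × 300 codons;
A–B divergence Ks 0.27 (the WGD peak); focal–outgroup divergence
Ks 0.48; branch asymmetry `ks_recent = 0.03` making A the
outgroup-proximal subgenome (phasing margin ≈ 2 × 0.03); ω = 0.2;
80% retention of B copies (unbiased fractionation, matching the
absence of biased fractionation in the system emulated; a bias knob
exists for power studies); 10% A-dominant and 15% B-dominant pairs
with log2 ratios uniform on [1.5, 3]; 5% planted DEGs at ±2 log2
units; baseline FPKM lognormal(μ = 3, σ = 1); replicate noise CV 0.15
(mean-one lognormal); a 2-tissue × {0, 1, 24, 72} h × 3-replicate
design mirroring a salt-stress time course.

Sequences evolve by a proposal–acceptance scheme: Poisson numbers of
synonymous and nonsynonymous events per branch (rates $dS$ and
$d N \omega$), each event choosing a codon weighted by its current
single-nucleotide neighbour count; stop-creating changes are never
proposed. This is simpler than a codon-matrix exponential, exactly
seedable, and hits the target synonymous divergence; it is
intentionally approximate for Ka. Realized substitution counts are
recorded so estimator-recovery tests can compare against what
actually happened, not only the target. Gene orders are scrambled
into collinear runs of 8–15 genes (short tails merged so every
planted run reaches the five-gene block minimum), 10% inverted, and A
and B share each chromosome's rearrangement pattern — fractionation
then thins B inside the shared runs, which is what makes "planted
anchor" well defined. Homology hits cover all true pairs plus 5%
random noise. One RNG stream per submodule (sequences, orders,
planting, expression) derives from the master seed, so changing
expression parameters never perturbs sequences, and fixtures are
byte-identical under a fixed seed.

What the generator does **not** emulate: indels (alignments are
gap-free, so back-translation robustness is tested separately),
intergenic sequence and transposons, rate heterogeneity across genes
and lineages, GC/codon-usage bias, tandem arrays, biased
fractionation (off by default), count-based expression noise
(FPKM-scale lognormal instead of negative-binomial reads), and
regulatory correlation between homoeologs. Tests passing on the
fixture therefore demonstrate algorithmic correctness and estimator
calibration under the stated model — not robustness to every
complication of real genomes.

A note on interaction of planted effects: a pair containing a planted
DEG member genuinely becomes HEB-dominant during the treated samples
of that tissue, so constitutive-dominance recovery is evaluated on
pairs without planted DEG members; on those the planted A/B fractions
are recovered within ±3 percentage points over ≥ 2000 pairs.

## Numerical choices and degenerate inputs

Tie-breaks are deterministic everywhere: lexicographic gene ids in
hit sorting, score → anchor count → chromosome pair in chain
acceptance, alphabetical order in the A/B "closer" decision at exact
ties (flagged ambiguous). `collectKsValues` errors below `min_pairs`
(50 by default) rather than estimating a density from nothing. DEG
calling with zero variance in both groups returns p = 1 when means
agree and p = 0 otherwise, so noiseless fixtures behave sensibly.
Dating rejects non-positive λ. The NJ post-pass clamps negative
branch lengths to zero, moving the deficit to the sister edge.

## Problem sizes

The default fixture (600 outgroup genes, ~1,080 focal genes, ~480
homoeolog pairs, 24 expression samples) runs the whole pipeline in
well under a minute on one core. Estimator-recovery studies use 200
pairs × 300 codons per divergence level, mode-recovery studies 20
seeded replicates of a 2,000-draw bimodal mixture, and
dominance-recovery studies a 2,800-gene-per-subgenome truth-only
fixture (~2,240 retained pairs). These sizes give sampling errors
comfortably inside the tested tolerances (e.g. mean-Ks standard error
≈ 1% at 200 pairs) while keeping a full test run fast.

## Known limitations

NG86 Ks saturates above ~2 and the package refuses to date what it
cannot measure; dating accuracy inherits the single-rate clock
assumption in $T = K_s/2\lambda$; phasing assumes a clean
allotetraploid (2:1 chromosome correspondence) and degrades
gracefully, not cleverly, when that fails; Welch's t on three
replicates has limited power compared to count-based models, which is
acceptable here because the DEG rule under test is a threshold
contract, not a power claim; and the hypergeometric enrichment is
term-by-term, ignoring ontology structure.
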