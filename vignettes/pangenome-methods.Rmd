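---
title: "Methods: pan-genome construction, rarefaction and phylogenomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-genome construction, rarefaction and phylogenomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panforge)
```

This vignette is the package's account of the science it implements: the
models, their assumptions, the tunable parameters, what the synthetic data
generator does and does not emulate, and the numerical choices made where
the design was genuinely open.

## The pipeline at a glance

Strain-level comparative genomics of a bacterial species proceeds in four
coupled analyses, all driven by per-genome protein sets and (for ANI)
nucleotide assemblies:

1. ortholog **family construction** from all-vs-all protein similarity;
2. **pan/core rarefaction** and model fitting to classify the pan-genome as
   open or closed and to project the stable core size;
3. **average nucleotide identity** (ANI) for species delineation;
4. a **single-copy-core phylogeny**.

Each stage is exposed as a function with a tabular (tibble) surface;
`run_pipeline()` chains them.

## Ortholog families

Every unordered gene pair — within- and between-genome, self-pairs
excluded — is locally aligned (Smith–Waterman, affine gaps, BLOSUM62 with
gap open 11 / extend 1; a gap of length $L$ costs $\text{open} + L\cdot
\text{ext}$). A pair becomes an edge when **all three** thresholds hold:

| parameter | default | meaning |
|---|---|---|
| `min_identity` | 50 % | identities / alignment columns (gap columns included) |
| `min_coverage` | 0.5 | aligned span on the **longer** sequence ÷ its length |
| `max_evalue` | 1e-5 | Karlin–Altschul $E = Kmn\,e^{-\lambda S}$ |

The identity denominator (all alignment columns) and the coverage reference
(the longer sequence) are stated explicitly because both conventions vary
between tools and silently change which pairs pass. The e-value constants
default to the gapped BLOSUM62 values $\lambda = 0.267$, $K = 0.041$; they
are configurable and echoed in the run report, since the raw-score statistic
is only as meaningful as its constants.

Families are the **connected components** (single linkage) of the accepted
edge graph. Granularity-refining steps such as Markov clustering are
deliberately out of scope: components are deterministic, oracle-testable,
and the edge list is exported so a finer clustering can be layered on.
Paralogs are allowed to share a family — within-genome edges are kept — and
single-copy filtering happens only at classification time, because the
phylogeny stage needs exactly the families that are present once in every
genome.

The partition follows the standard vocabulary: **core** = present in all
genomes, **strain-specific** (singleton) = present in exactly one genome
(a family-level notion, not family-of-size-one), **accessory** = the rest.

For large inputs a shared-4-mer prefilter skips pairs that cannot plausibly
reach 50 % identity over half the longer sequence (pairs of sequences ≥ 100
aa must share ≥ 2 distinct 4-mers; shorter pairs are always aligned). The
prefilter is contractually output-equivalent to the unfiltered computation
and is tested for exact equality on small instances; `prefilter = FALSE`
disables it.

## Rarefaction and the two growth models

For a genome ordering $\pi$, $\text{pan}(x)$ counts families present in the
first $x$ genomes, $\text{core}(x)$ those present in **all** of the first
$x$, and $\text{new}(x) = \text{pan}(x) - \text{pan}(x-1)$. Orderings are
uniform random permutations; with $G \le 5$ (or whenever $G! \le$
`n_perm`) all $G!$ orderings are enumerated and the means are exact. The
default `n_perm = 100` stabilises the mean curves at negligible cost.

Two models are fitted **to the mean curves** (a single fitted curve is what
the field reports; per-permutation fitting is possible by passing any
row of the permutation matrices):

* **Heaps' law** $y = \kappa x^{\gamma} + b$ for the pan curve. The fitted
  exponent diagnoses openness: $\gamma > 0$ means the pan-genome keeps
  growing as genomes are added (open); $\gamma \le 0$ means it saturates
  (closed).
* **Exponential decay** $y = A e^{Bx} + K$ (with $B < 0$ enforced) for the
  core curve — $K$ is the projected stable core-genome size — and for the
  new-genes curve, where we define $K$ as the per-genome plateau: the
  number of new gene families each additional genome is expected to
  contribute in the long run.

Numerical choices: nonlinear least squares (Levenberg–Marquardt) with
initialisation $b_0 = \min y$, $\kappa_0 = \max y - \min y$, $\gamma_0 =
0.5$ (decay: $K_0 = y_G$, $A_0 = y_1 - y_G$, $B_0 = -0.1$), convergence
tolerance $10^{-10}$ on the sum of squares, and up to five jittered restarts
before failure is reported (never silent). An overall increasing series is
refused by the decay fit; a constant series short-circuits to the exact
solution $A = 0$, $K = \bar y$. All diagnostics (R², iterations,
convergence flag) are serialized.

A caveat worth stating: when the offset $b$ is large relative to the
power-law amplitude and noise scales with the whole of $y$, $\gamma$ and
$b$ trade off and **no** estimator can pin $\gamma$ tightly — our tests
verify recovery to ±0.05 under noise scaled to the accumulation signal
$\kappa x^\gamma$, which is the regime in which the exponent is
identifiable at all.

## Average nucleotide identity

ANI follows the BLAST-based (ANIb) recipe: the query assembly is cut into
consecutive non-overlapping **1020 bp** fragments per contig (a terminal
remainder is kept iff ≥ 100 bp; fragments never span contigs; coordinates
are 0-based half-open). Each fragment is aligned to the subject and
**retained** iff its best hit has ≥ 30 % identity over ≥ 70 % of the
fragment; the directional ANI is the mean identity of retained fragments,
and the symmetric ANI the arithmetic mean of the two directions. When no
fragment survives, ANI is reported as missing — never coerced to a number.

Aligning every 1020 bp fragment against a multi-megabase subject by full
dynamic programming is not desk-scale, so the default path seeds each
fragment with exact 15-mer matches (forward and reverse-complement strand),
takes the modal diagonal (binned ±32 bp to tolerate indels), and runs the
local alignment only against a subject window extending 64 bp beyond the
seeded diagonal. `method = "full"` performs the exhaustive alignment; the
suite asserts the two agree within 0.1 ANI point, and on substitution-only
simulations they agree exactly.

Species clusters are connected components of the graph joining pairs with
ANI **> 95 %** — the operative conspecificity rule (the literature quotes
95–96 %; the threshold is a parameter).

## Single-copy core phylogeny

Families present in every genome with exactly one member each are aligned
per family (global, BLOSUM62); for each genome pair the mismatch fraction
$p$ is pooled across families with alignment-length weights — equivalent to
recounting mismatches on the concatenated gapped alignments — and corrected
for multiple hits with the Poisson formula $d = -\ln(1 - p)$ (raw
$p$-distances are also available; $p \ge 1$ is reported as an explicit
infinite distance). A full multiple alignment with conserved-block
trimming would add little for distance-based tree building and would not be
oracle-testable; pairwise pooling preserves the distance signal the tree
needs.

The tree is Saitou–Nei neighbor joining on that matrix; negative branch
lengths are clamped to zero with the clamped deficit recorded on the tree.
On an exactly additive matrix NJ provably recovers the generating topology
and branch lengths, which the suite checks against an exhaustive
enumeration of all fifteen 5-taxon topologies. Optional support values come
from resampling **families** with replacement (a family-level bootstrap
analogue), rebuilding the tree per replicate, and reporting bipartition
frequencies.

## The synthetic pan-genome generator

`simulate_pangenome()` produces the ground truth every stage is tested
against. Genome $i$ receives: one gene per core family; each previously
introduced accessory family independently with probability `p_keep`;
`Poisson(new_rate)` newly introduced accessory families; and
`Poisson(singleton_rate)` strain-specific families. Constant per-genome
innovation yields an open pan-genome by construction — pan size grows
approximately linearly at small $G$ — which is exactly the regime the
openness classifier must detect.

Sequence level: each family has an ancestral protein (length
$\mathcal{N}(250, 50)$ aa, floored at 30) and each member is the ancestor
with i.i.d. per-site substitutions at **half** the `within_family_divergence`
rate, so that two family members differ at approximately the stated rate —
the quantity the clustering thresholds actually see. At the default 0.1,
mean pairwise within-family identity is ≈ 90 %, comfortably above the 50 %
edge threshold and far above the ≪ 30 % background of unrelated proteins,
so perfect family recovery is the correct expectation, and the tests demand
it (Rand index 1.0).

Nucleotide level: genomes are back-translated CDSs (one fixed codon per
amino acid — protein-level truth is what clustering consumes, so codon
realism is not needed) joined by per-family ancestral spacers
(`Poisson(100)` bp) that are shared across genomes, mimicking syntenic
conserved intergenic regions so conspecific simulated strains remain
alignable end-to-end. `simulate_genome_pair()` generates substitution-only
pairs (no indels) at an exact divergence $\delta$, making the expected ANI
exactly $100(1-\delta)$ — a sharp test, at the cost of not exercising
indel handling, which the retention-filter tests cover separately.

All randomness flows from one seed; identical parameters give byte-identical
FASTA output.

**What the simulator does not emulate** — and hence what passing tests do
not show about real data: operon structure and rearrangements, horizontal
transfer (accessory families appear independently, not in linked blocks),
indels within family members, paralog expansion, pseudogenes, and
base-composition structure. Real assemblies also bring fragmentation and
ambiguity codes, which only the IO-level tests touch.

## Default problem sizes

The packaged defaults (10 genomes × 50 core families, innovation rate 10,
rarefaction over 100 orderings; ANI on 100 kb pairs) are scaled-down study
conditions chosen so that every property remains sharply testable — family
recovery must be perfect, ANI must sit within 0.3 points of its constructed
value, topology recovery must be exact — while a complete run stays
desk-scale. The algorithms themselves carry no such limits; the ANI seeding
path in particular exists precisely so multi-megabase assemblies are
tractable.

## Known limitations

* Single-linkage components can chain distinct families through a promiscuous
  domain; the exported edge list allows re-clustering at finer granularity.
* The Karlin–Altschul constants are not re-estimated per scoring scheme.
* ANI seeding can miss a fragment whose best hit shares no exact 15-mer
  (relevant only beyond ~20 % divergence, far outside the species range).
* The NJ tree is a distance method; no likelihood model selection is
  attempted, and the Poisson correction ignores among-site rate variation.
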