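---
title: "Methods: AMF amplicon community analysis with amfpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AMF amplicon community analysis with amfpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Arbuscular mycorrhizal fungi (AMF, Glomeromycota) are obligate root
symbionts whose community composition in agricultural soils — e.g. in and
around vineyard rows — is surveyed by amplicon sequencing of ribosomal
markers. `amfpipe` implements a complete analysis chain for such surveys of
LSU rDNA amplicons (~700 bp, 454-style long reads): demultiplexing, read
quality control, taxonomy assignment against a curated reference database,
de novo grouping of unassignable reads, abundance normalization, diversity
and differential-abundance statistics, and microscopy-based root
colonization scoring. The experimental design it serves is a 2 x 2 x 5
layout: bulk soil away from the vines (`Bs`) versus soil associated with
grapevine roots (`Rs`), sampled at flowering (`1S`) and early fruit
development (`2S`), five replicates each.

Because deposited reads and curated AMF reference databases are not
generally redistributable, the package ships a first-class synthetic data
module that generates mock reference worlds and error-bearing reads with
complete ground truth, so that every stage of the pipeline can be tested,
calibrated and demonstrated offline.

# Read quality control

Three discard rules are applied, in a fixed order that makes the per-reason
counts sum to the input count:

1. length below 200 bases;
2. arithmetic mean Phred score below 25;
3. any base outside `A`,`C`,`G`,`T`.

Thresholds are strict "less than" for discarding: a 200-base read or a read
with mean quality exactly 25 passes. "Mean quality" is the arithmetic mean
of the Phred scores, not the mean error probability — the literal reading
of an "average quality score" rule, and the variant that is reproducible
without knowing the original tooling. Primer or quality trimming is out of
scope: the filters judge reads as they arrive.

# The alignment contract

Both taxonomy assignment and de novo clustering rest on a single pairwise
contract: a Smith–Waterman optimal local alignment with affine gaps,
BLASTN-like scoring (match +2, mismatch −3, gap open −5, gap extend −2; a
gap of length L scores `open + L·extend`), from which two statistics are
taken:

* **identity** — `100 · matches / alignment_columns`, gap columns counted;
* **query coverage** — `100 · (q_end − q_start + 1) / query_length`.

A hit "passes" when coverage ≥ 80 **and** identity ≥ 97, both bounds
inclusive. Query coverage (not subject coverage) is used because reference
sequences may be longer than reads. Only the single best local alignment is
considered per pair — no multi-segment stitching. This has a useful side
effect: a two-parent chimera aligns well to either parent over only about
half its length, fails the coverage bound, and drops out of reference
assignment, so chimera removal is implicit in the dual criterion.

Determinism matters more here than any particular tie-break, because
downstream tables must be byte-identical across runs. The engine (C++) and
the plain-R brute-force oracle in the test suite share one documented rule
set: the best-scoring end cell is chosen with smallest query end, then
smallest subject end, then state preference match > query-gap > subject-gap;
the diagonal predecessor preference is match-state first and a fresh local
start last (preferring continuation, which favours earlier alignment
starts); gap opening is preferred over extension on ties. Preferring
continuation over restart realizes the "smallest start coordinate"
intention directly in the forward pass, where a literal rule on the start
coordinate would not be implementable (the start is only known after
traceback).

The DP contract is normative: no heuristic seeding or banding is applied,
so the engine is exactly equivalent to the oracle, which the suite checks
on hundreds of random sequence pairs.

# Taxonomy assignment and de novo clustering

Each QC-passed read is aligned against every reference sequence. Among
passing hits the highest score wins, ties broken by higher identity, then
by lexicographically smallest accession — an invented but fixed order,
since multi-hit resolution is otherwise undefined. References sharing a
lineage label pool into one taxon. Reads with no passing hit form the
**de novo pool**.

The pool is dereplicated and clustered greedily (UCLUST-style centroid
clustering): unique sequences are processed in a content-based order
(decreasing multiplicity, then decreasing length, then lexicographic) and
each joins the first centroid it passes the dual criterion against, or
founds a new one. Centroid clustering was chosen over single linkage
because it is deterministic, cheap, and guarantees that every member
satisfies the criterion against its centroid; single linkage guarantees
neither, but is available behind `method = "single"` since the original
phrasing ("grouped together") is ambiguous. The content-based order makes
the clustering invariant to input read order. Cluster names `de novo_<k>`
number the founding order; they are run-local identifiers, not comparable
across datasets.

Clusters are then annotated against a local labeled database (a stand-in
for a public nucleotide database) at a looser identity bound (default 90,
coverage 80) appropriate for genus-level naming; clusters with no passing
hit fall back to `"uncultured Glomeromycota"`.

# Community tables

Counts are normalized by rarefaction: sampling without replacement
(multivariate hypergeometric) to a fixed depth, 8,000 reads by default —
the interpretation of "normalized at N sequences" that preserves count
semantics. Samples below the depth are kept unchanged and flagged rather
than dropped, because real surveys retain under-sequenced replicates. The
presence rule — a taxon is present in a (soil, time) group when at least
one replicate holds ≥ 10 reads, counted once per group — is applied after
rarefaction by default (the original order is unstated; this order is the
conservative one, judging presence on normalized counts). Venn regions over
2–4 presence sets, a per-group positive-median filter, and a taxonomic
rollup (binning each taxon by its most specific non-empty rank) complete
the descriptive layer.

# Diversity

* **Rarefaction curves** use the analytic expectation
  `E[S_m] = Σ_i (1 − C(N−N_i, m)/C(N, m))`, evaluated with log binomial
  coefficients; the curve is non-decreasing, concave and ends at the
  observed richness.
* **Alpha diversity** per replicate: observed richness, Shannon entropy in
  natural log units, and the Gini–Simpson index `1 − Σ p_i²` — the
  conventions of the phyloseq ecosystem, recorded explicitly because index
  names alone are ambiguous.
* Group differences are tested per index across the four (soil, time)
  groups either parametrically (one-way ANOVA) or nonparametrically
  (tie-corrected Kruskal–Wallis); both are exposed because published
  index p-values rarely state which was used.
* **Beta diversity**: Bray–Curtis dissimilarity on the rarefied
  replicate-level table, principal coordinates via Gower double-centering
  (negative eigenvalues are reported, their axes dropped), and one-way
  PERMANOVA in the sums-of-squared-distances formulation with
  `p = (1 + #{F_perm ≥ F_obs}) / (1 + n_perm)` under seeded label
  permutation, 999 permutations by default.

# Differential abundance

The **heat-tree** comparison aggregates counts up a root → family → genus →
leaf taxonomy tree and, per node, reports `log2((median_A + ε)/(median_B +
ε))` with ε = 0.5 (bounding the ratio when a median is zero while
preserving sign) and a two-sided exact Wilcoxon rank-sum p-value. The exact
p is computed by enumerating all assignments with midranks, because the
classical exact distribution is unavailable under ties — and tied replicate
counts are the norm in sparse taxon rows. For 5-vs-5 complete separation
this yields the exact 2/252.

The **LEfSe** layer is the single-level form: per-taxon Kruskal–Wallis
screening on relative abundances scaled to counts-per-million,
Benjamini–Hochberg adjustment (cutoff 0.05), then an LDA effect size for
survivors: over 30 stratified bootstrap rounds (two-thirds of each group,
without replacement) a linear discriminant is fitted on the single feature,
its direction normalized to unit length so that projected group means stay
on the cpm scale, and the effect is the absolute difference between the two
extreme group means; the score is `log10(max(mean effect, 1))` with a
reporting cutoff of 1.0. A cpm gap of ~10^5 therefore scores ≈ 5. Scores
are comparable within a run as an ordering; the exact internals of
published LEfSe front-ends differ in undocumented details, so scores should
not be compared across tools.

# Root colonization (Trouvelot scoring)

Each 1-cm root fragment is scored with a colonization class 0–5 and
arbuscule/vesicle classes 0–3. With `n_k` fragments in class k out of N,
the class weights (0, 1, 5, 30, 70, 95) give frequency
`F = 100(N−n₀)/N`, intensity `M = Σ w_k n_k / N` (capped at 95), intensity
in colonized fragments `m = M·N/(N−n₀)`, arbuscule richness
`a = (100·mA₃ + 50·mA₂ + 10·mA₁)/100` where `mA_j` is the share of `m`
contributed by fragments of arbuscule class j, and abundance
`A = a·M/100`; vesicles use the same machinery. The weight sets are the
classical ones of the scoring method, fixed here as the contract since
index names alone do not determine formulas. Indices are scale-free in N,
`A ≤ M` always, and `m ≥ M` whenever any fragment is uncolonized. Groups of
plants (e.g. the two sampling times) are compared per index by one-way
ANOVA with means ± SD.

# The synthetic data generator

`sim_config()` defaults encode the study conditions:

| parameter | default | rationale |
|---|---|---|
| reads per replicate | U(2,000, 12,000) | spread of real replicate depths, exercising the below-depth rarefaction branch |
| read length | ~N(700, 60), 5'-anchored | ~700 bp second-PCR amplicons |
| substitution rate | 0.005 /base | default-noise condition |
| indel rate | 5e-4 /base | minor long-read indel component |
| chimera fraction | 0.02 | typical amplicon chimera load |
| off-target fraction | 0.02 | non-AMF amplification |
| QC-defect fractions | 0.01 each | small, deterministic (`round(f·n)`) injections so QC reports can be checked exactly |
| Dirichlet concentration | 200 | replicate-to-replicate compositional noise small relative to planted effects |
| known fraction | 0.75 | both the reference-assignment and the de novo path carry real load |
| soil effect | 3 taxa × 4-fold | constructible positives for PERMANOVA/LEfSe |
| time effect | 2 taxa × 3-fold | a weaker secondary factor |

The generator emulates: per-base errors, length variation, quality strings
consistent with the QC thresholds, exact-prefix MID tags (via
`attach_mids()`), two-parent chimeras with uniform interior breakpoints,
off-target random reads, and per-replicate Dirichlet compositions with
multiplicative group effects. It does **not** emulate 454 homopolymer error
structure, flowgrams, position-dependent quality decay, or phylogenetic
correlation between taxa (reference sequences are mutually ≥10% divergent
by rejection). Passing tests therefore demonstrate correctness of the
pipeline's logic and statistics under a clean error model — not robustness
to platform-specific artifacts, nor performance on communities with
near-threshold (97–99% identity) species pairs, which real AMF databases
contain.

Determinism is part of the contract: a configuration (including its
mandatory seed) maps to byte-identical outputs, and every read is covered
exactly once by the ground truth (true taxon, role, injected defect).

# Numerical and design choices

* Exact integer scoring throughout the aligner; identity/coverage are
  derived ratios, so engine-vs-oracle equality is exact, not approximate.
* Rarefaction curves in log space (`lchoose`) to avoid overflow at depths
  in the thousands; `C(N−N_i, m)` with `m > N−N_i` contributes 0 through
  the `-Inf` log convention.
* Degenerate inputs are errors, not silent results: empty sequences,
  all-zero sample columns, singleton PERMANOVA groups, empty fragment
  sets, and invalid Trouvelot class combinations all fail loudly.
* Median over an even number of replicates uses the midpoint rule.
* The test suite and the acceptance script run the full pipeline at
  reduced problem sizes — 8 mock taxa and 50–180 reads per replicate for
  the end-to-end runs, 10,000 reads for the QC-recovery check, 500
  simulations × 99 permutations for the PERMANOVA size check — while
  keeping all noise levels, thresholds and effect sizes at their default
  study conditions. Sizes are a package choice balancing statistical
  resolution against desk-scale runtimes.

# Known limitations

* The aligner is exact but quadratic; at survey scale (10^4–10^5 reads
  against thousands of references) a production deployment would add a
  k-mer prescreen. None is included because the exact contract is the
  point of this implementation.
* LEfSe here is single-level: no subclass structure, no one-against-all
  mode.
* PERMANOVA is one-way; the two-factor design is analyzed one factor at a
  time, matching the original analysis rather than a full two-way
  decomposition.
* Annotation labels depend entirely on the supplied local database; the
  fallback label is a statement of ignorance, not a taxonomic claim.
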