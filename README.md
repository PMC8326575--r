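# amfpipe

Community analysis of arbuscular mycorrhizal fungi (AMF, Glomeromycota)
from long amplicon reads, built for the classic vineyard survey design:
bulk soil (`Bs`) versus grapevine-root-associated soil (`Rs`), sampled at
flowering (`1S`) and early fruit development (`2S`), five replicates each
(20 samples). The package takes demultiplexed or MID-tagged ~700 bp LSU
rDNA reads through:

1. **Quality control** — discard reads shorter than 200 bases, with mean
   Phred score below 25, or containing ambiguous bases; per-reason counts
   are reported and sum to the input.
2. **Taxonomy assignment** — Smith–Waterman local alignment of every read
   against a lineage-annotated reference database; a read is assigned to a
   "known" taxon when query coverage ≥ 80% **and** identity ≥ 97%
   (`identity = 100·matches/columns`, `coverage = 100·aligned span/read
   length`). Chimeras fail the coverage bound and drop out implicitly.
3. **De novo clustering** — unassigned reads are grouped greedily
   (centroid clustering under the same 80/97 dual criterion) into
   `de novo_<k>` taxa and annotated against a local labeled database.
4. **Community tables** — rarefaction to a common depth (default 8,000
   reads; shallow samples kept and flagged), the ≥10-reads presence rule,
   Venn regions, positive-median filtering, taxonomic rollup.
5. **Statistics** — analytic rarefaction curves
   `E[S_m] = Σ_i (1 − C(N−N_i,m)/C(N,m))`; Shannon (`−Σ p ln p`) and
   Gini–Simpson (`1 − Σ p²`) indices with ANOVA / Kruskal–Wallis group
   tests; Bray–Curtis distances, PCoA, and one-way PERMANOVA
   (pseudo-F, permutation p); heat-tree style per-node comparisons
   (log2 median ratio, exact Wilcoxon rank-sum) and single-level LEfSe
   (Kruskal–Wallis + BH screening, log10 LDA effect size).
6. **Root colonization** — Trouvelot class scoring of root fragments:
   frequency F%, intensity M%, arbuscule/vesicle abundance A%/V%, with
   per-index ANOVA between groups of plants.

A seeded synthetic-data module (`sim_config()`, `simulate_reference_db()`,
`simulate_reads()`) generates mock reference databases and error-bearing
reads with complete ground truth — per-read source taxon, injected QC
defects, chimeras, off-target reads, and planted differential taxa — so the
whole pipeline is testable and demonstrable without any external data.

## Worked example

Simulate a small survey, run the pipeline, and test the soil effect:

```r
library(amfpipe)

cfg <- sim_config(seed = 42, n_ref_taxa = 8,
                  reads_per_replicate = c(120, 180))
db  <- simulate_reference_db(cfg)
sim <- simulate_reads(cfg, db)

qc  <- filter_reads(sim$reads)
print(qc$report)

asg <- assign_all(qc$passed, db$reference,
                  samples = amf_design()$sample_id)
cl  <- annotate_denovo(cluster_denovo(asg$pool), db$annotation)
x   <- build_table(asg$known_counts, db$reference,
                   denovo_counts = cluster_counts(cl, asg$pool,
                                                  amf_design()$sample_id),
                   clusters = cl)
print(x)

x_r <- rarefy(x, depth = 100, seed = 1)
print(permanova(bray_curtis(x_r), amf_design()$soil, n_perm = 999, seed = 1))

res <- lefse(x, group = "soil", seed = 1)
head(res[res$significant, c("taxon", "kw_p_adj", "lda_score", "top_group")])
```

Output from this exact run:

```
Read QC report
  input: 2784  passed: 2712
  discarded - short: 24  low quality: 24  ambiguous: 24
AMF abundance table: 112 taxa x 20 samples
  known: 6  de novo: 106  below-depth samples: 0
PERMANOVA: F = 27.46, R2 = 0.6041, p = 0.001 (999 permutations)
                    taxon kw_p_adj lda_score top_group
3      Glomus macrocarpum  0.02454      4.72        Rs
4 Rhizophagus irregularis  0.00879      5.32        Rs
6    Septoglomus viscosum  0.00879      5.53        Bs
```

Reading it: the QC report attributes every discarded read to the first
failing rule (here the three engineered 1% defect fractions; 24 = 20
replicates × round(0.01 × ~120–180 reads)). The abundance table combines
the 6 known reference taxa with 106 annotated de novo clusters — the two
uncultured mock taxa plus singletons from chimeric, off-target and
high-error reads. The PERMANOVA p-value of 0.001 (the minimum attainable
with 999 permutations) reflects the soil effect planted by the simulator
(three taxa at 4-fold between `Bs` and `Rs`), and the LEfSe table lists
exactly those three planted taxa, with `lda_score` the log10 effect size
on the counts-per-million scale and `top_group` the enriched soil.

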