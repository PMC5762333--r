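# subspa — lncRNA-embedded subpathway activity for tumor transcriptomics

LncRNAs can act as miRNA sponges, competitively de-repressing the mRNAs with
which they share miRNA binding sites. `subspa` folds that regulatory layer
into pathway analysis at the subpathway level, for anyone analyzing matched
gene + lncRNA expression cohorts (RPKM-like matrices, e.g. TCGA-style
RNA-seq) with pathway topology and a table of competitive lncRNA–gene
regulations in hand.

The framework:

1. **Reconstruction.** Each KEGG pathway (KGML) becomes an undirected gene
   graph. Subpathways are the maximal gene sets with pairwise shortest-path
   distance ≤ *k* (default *k* = 3), found by thresholding the distance
   matrix and enumerating maximal cliques. Every lncRNA regulating ≥ 1 member
   gene is embedded; subpathways with < 3 genes or < 2 lncRNAs are dropped.
2. **Activity.** In each sample, the merged gene+lncRNA matrix is ranked in
   ascending order and weighted `w = r · exp(r/|N|)`; a subpathway's activity
   is

   ```
   sPA(i, s) = mean(w, members of i) − mean(w, all other features)
   ```

   z-normalized per subpathway across samples (`sPA_norm`).
3. **Tumor analyses.** Hierarchical clustering of samples (uncentered
   correlation, complete linkage); tumor-vs-normal Wilcoxon differential
   activity; pooled gene+lncRNA hypergeometric enrichment with BH
   correction; and train/test prognostic signature discovery (univariate Cox
   screen at p < 0.01, K-means risk groups, Kaplan–Meier/log-rank).

A seeded synthetic-cohort generator (`simulate_cohort()`) produces every
input the pipeline consumes — toy KGML files, regulation tables, expression
with planted multiplicative subpathway effects, activity-linked survival — so
the whole framework is testable offline.

## Worked example

```r
library(subspa)

cfg  <- sim_config(seed = 42)                      # 30 tumor vs 30 normal
sim  <- simulate_cohort(cfg)                       # pathways, regs, expression, survival
merged <- merge_profiles(sim$gene_expr, sim$lnc_expr)
prof   <- activity_profile(merged, sim$subpathways)
prof
#> activity_profile: 18 subpathways x 60 samples (0 constant row(s))

round(prof$spa_norm[1:3, 1:4], 3)
#>               T001  T002  T003  T004
#> path:90001_1 0.772 0.643 1.036 1.258
#> path:90001_2 0.749 0.598 0.865 1.314
#> path:90001_3 0.178 0.530 1.138 1.554

tumor  <- sim$design$sample_id[sim$design$condition == "tumor"]
normal <- sim$design$sample_id[sim$design$condition == "normal"]
da <- differential_activity(prof, tumor, normal)
head(da[order(da$p), c("subpathway_id", "p", "p_adjusted", "call")], 3)
#>  subpathway_id            p   p_adjusted        call
#>   path:90001_1 1.691123e-17 1.014674e-16 higher_in_A
#>   path:90001_2 1.691123e-17 1.014674e-16 higher_in_A
#>   path:90001_3 1.691123e-17 1.014674e-16 higher_in_A
```

The generator planted a four-fold expression effect on the members of
`path:90001_1` in tumor samples; that subpathway (and its overlapping
neighbors, which share most of its genes) tops the differential table, with
`higher_in_A` meaning higher activity in the tumor group. On a larger
all-tumor cohort the prognosis pipeline recovers the subpathway whose
activity drives the simulated hazard:

```r
cfg <- sim_config(seed = 42, n_tumor = 200, n_normal = 0)  # cox_beta = 0.8
sim <- simulate_cohort(cfg)
rep <- prognosis_pipeline(sim$gene_expr[, sim$clinical$sample_id],
                          sim$lnc_expr[, sim$clinical$sample_id],
                          sim$subpathways, sim$clinical, split_seed = 7)
rep
#> prognosis_report: 100 train / 100 test samples
#> signature: 3 subpathway(s) at Cox p < 0.01
#> test-set log-rank: chisq = 17.3 on 1 df, p = 3.195e-05
rep$signature
#> [1] "path:90001_1" "path:90001_2" "path:90001_3"
```

The signature contains the planted `path:90001_1` plus the two subpathways
that overlap it, and the two K-means risk groups on the held-out half
separate sharply in survival (log-rank p = 3.2e-05).

A shell interface over the same functions covers the whole chain:

```sh
Rscript inst/cli/subspa.R simulate   --seed 42 --out-dir fx
Rscript inst/cli/subspa.R reconstruct --kgml-dir fx/kgml --regulations fx/regulations.tsv --k 3 --out sub.spw
Rscript inst/cli/subspa.R activity   --subpaths sub.spw --gene-expr fx/gene_expr.tsv --lnc-expr fx/lnc_expr.tsv --out act.tsv
Rscript inst/cli/subspa.R prognosis  --subpaths sub.spw --gene-expr fx/gene_expr.tsv --lnc-expr fx/lnc_expr.tsv \
                                     --clinical fx/clinical.tsv --split-seed 7 --out report.json
```

Every subcommand writes a JSON run manifest (parameters, seeds, input
checksums, outputs) that is byte-identical across reruns.

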