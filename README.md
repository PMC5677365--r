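# sistergss

Do identical marks on the two sister histone H3 tails of a nucleosome act
**cooperatively**, **independently**, or **redundantly** on transcription?
`sistergss` implements the computational pipeline that answers this from
bulk RNA-seq of a five-strain yeast genotype series — a heterodimer-only
"wild type" (both tails modifiable), the two single-tail K-to-R mutants, the
double-tail mutant, and a methyltransferase deletion — sampled before and
after a shift to 0.05% glucose. It is written for chromatin biologists and
computational groups who want to run, audit, or stress-test this
classification on their own expression tables.

## The method

For gene *i*, strain *j*, replicate *r*, induction is the reference-gene
(ACT1) normalized log2 fold-change

    FC_ijr = log2( (RPKM_1h_ijr / RPKM_1h_ref,jr) / (RPKM_0h_ijr / RPKM_0h_ref,jr) )

averaged over replicates to FCa. After excluding zero-RPKM and
replicate-inconsistent genes, a gene is *responsive* when its replicate FCs
differ between WT and the double mutant (pooled Student t-test, p < 0.05).
Responsive genes whose single-tail response falls between the two symmetric
extremes in **both** asymmetric strains — the betweenness statistic

    Mid = (|FCa_asym − FCa_WT| + |FCa_asym − FCa_DOUBLE|) / |FCa_WT − FCa_DOUBLE|

equals 1 — form the MID subset. Skew along the interval is the Gene
Skewness Score

    GSS = log2( |FCa_asym − FCa_DOUBLE| / |FCa_asym − FCa_WT| )

(0 at the midpoint, positive toward WT, negative toward the double mutant).
MID genes are then classified: **Cluster II** (independent) differs
significantly from both endpoints; the extreme GSS values of Cluster II set
bounds `gss_max`/`gss_min`; **Cluster III** (redundant) matches WT, differs
from DOUBLE, and has GSS above `gss_max`; **Cluster I** (cooperative)
matches DOUBLE, differs from WT, and has GSS below `gss_min`. Cluster
overlaps with the *set1*∆-responsive genes and pathway-membership counts,
plus a steady-state two-strain QC comparison (Pearson r of log10(mean+1),
through-origin slope, uncentered R², and a ≥2-fold & p ≤ 0.001 DE filter),
complete the pipeline.

A synthetic-data generator (`simulate_experiment()`) emulates the full study
design with planted regulatory modes, so every stage is verifiable by
analytic identities and parameter recovery without any raw sequencing data.
See the methods vignette (`vignettes/sistergss-methods.Rmd`) for model
assumptions, numerical choices and known limitations.

## Worked example

```r
library(sistergss)

sim <- simulate_experiment(simulation_config(n_genes = 1000, seed = 42))
fc  <- average_fc(replicate_filter(compute_fc(sim$matrix, sim$design)))
responsive <- screen_responsive(fc, alpha = 0.05)      # 427 genes
mid <- build_mid_set(fc, responsive)                   # 279 genes
cls <- classify_clusters(fc, mid, alpha = 0.05)
cls
#> gene_classification: 279 MID genes
#>   I (cooperative): 10  II (independent): 193  III (redundant): 40  unassigned: 36
#>   gss_min = -3.171, gss_max = 2.641 (alpha = 0.05)

table(planted = truth_cluster(sim$truth)[cls$gene_id], assigned = cls$cluster)
#>        assigned
#> planted   I  II III UNASSIGNED
#>    I     10   1   0          4
#>    II     0 191   0         14
#>    III    0   1  40          6
#>    NONE   0   0   0         12
```

Of 1000 simulated genes, 427 pass the responsiveness screen and 279 the
betweenness gate; the classifier recovers nearly all planted independent
genes and most cooperative/redundant ones, with the remainder left
unassigned because their skewness does not clear the Cluster II-derived
bounds — the conservatism built into the published procedure (see the
vignette). `run_pipeline(matrix, design, out_dir)` performs the same chain
on real tables read with `read_expression_matrix()` / `read_sample_sheet()`
and writes `foldchange.tsv`, `classification.tsv`, `summary.json`,
`overlap.tsv`, `pathway_counts.tsv`, `qc.json` and a run log.

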