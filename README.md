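# dctyper

Consensus annotation of dendritic-cell (DC) types and activation states in
plate-based, index-sorted single-cell RNA-seq.

## The problem

Mouse spleens contain five DC populations — pDCs, pDC-like cells,
CD11c-high transitional DCs (tDCs), cDC1s and cDC2s — whose phenotypes and
transcriptomes overlap, and whose identity markers are downregulated on
activation.  During infection, activated tDCs lose CX3CR1 and gain BST2
and drift into the pDC-like sorting gate, and transcriptome clusters start
reflecting activation state rather than cell type.  A single-modality
annotation therefore systematically mislabels cells exactly where the
biology is most interesting.

`dctyper` targets index-sorted data, where each cell carries both a UMI
count profile and the surface intensities of an 11-marker panel (GFP, tdT,
B220, Ly6D, XCR1, CX3CR1, BST2, SiglecH, CCR9, CD11b, CD11c).  It assigns
a type only when two independent clusterings agree:

* a **transcriptome partition** — log-normalized counts, highly variable
  genes, PCA, kNN-Jaccard graph, Louvain at resolution γ;
* a **phenotype partition** — `asinh(x/100)` marker intensities (tdT
  excluded), same graph engine with a larger k;
* per-cell **connectivity scores** against composite UP/DN cell-type
  signatures, using the signed Kolmogorov–Smirnov statistic
  `ES = a if a > b else -b` with
  `a = max_j (j/t - p_j/n)`, `b = max_j (p_j/n - (j-1)/t)` and the
  null-score convention `tau = 0` when UP and DN enrich in the same
  direction, else `tau = (ES_up - ES_dn)/2`, max-normalized per signature.

Clusters in each modality are labeled by their highest mean score; cells
whose two labels agree get that type, a cell with one unresolved modality
is deductively reassigned to the resolved label when its score is
positive, and remaining disagreements stay NA.  Contaminant clusters
(macrophages, NK cells, proliferating cells) are removed by gene-module
scores, activation states (quiescent / intermediate / activated /
IFN-producing, the last exclusive to pDCs) are assigned from ISG,
maturation, cytokine and interferon module scores, and pairwise
differential expression uses Wilcoxon rank-sum tests with Bonferroni
correction over the gene universe.

A ground-truthed simulator (`simulate_dataset()`) generates the whole
study design — negative-binomial counts with type-specific and shared
gene programs, lognormal marker intensities with the documented
activation shifts, gate drift of activated tDCs, contaminants, and bulk
reference profiles — so the complete pipeline is testable without any
download.

## Worked example

```r
library(dctyper)

sim <- simulate_dataset(dc_sim_config(seed = 1))
cfg <- dc_config("whole", seed = 1)   # k = 9, gamma = 0.7, phenotype k = 50
ann <- run_dc_pipeline(sim$dataset, sim$reference, cfg)

ann
#> <dc_annotation> 819/819 cells typed (122 contaminant cells removed)
#>   cDC1=120, cDC2=100, pDC=289, pDClike=160, tDC=150

evaluate_annotation(ann, sim$truth)
#> # A tibble: 1 x 9
#>   n_retained n_annotated type_accuracy na_fraction state_accuracy
#>        <int>       <int>         <dbl>       <dbl>          <dbl>
#> 1        819         819             1           0          0.999
#> # i 4 more variables: drift_reassignment <dbl>,
#> #   contaminant_removed_fraction <dbl>, dc_falsely_removed <int>,
#> #   ifn_only_pdc <lgl>
```

Reading the output: of 943 simulated cells, 941 pass QC (two lack
index-sort records) and 122 contaminant cells are removed as three
flagged clusters; every retained cell is typed, type and state recovery
are at or near 100 %, all gate-drifted activated tDCs (sorted as pDC-like)
are reassigned to tDC (`drift_reassignment = 1`), and the IFN-producing
state occurs only inside the pDC compartment.  `tidy(ann)` returns the
per-cell table (`cell_id`, `type`, `state`, both cluster memberships, best
signature and score); `write_annotations()` round-trips it to TSV.

## Package tour

| Area | Functions |
| --- | --- |
| Data model & IO | `dc_dataset()`, `read_expression_dataset()`, `read_signatures_gmt()`, `write_annotations()` |
| Preprocessing | `qc_filter()`, `lognormalize()`, `select_hvg()`, `pca_embed()`, `asinh_transform()` |
| Graph engine | `build_jaccard_knn_graph()`, `louvain_partition()`, `cluster_cells()` |
| Signatures & scoring | `derive_composite_signature()`, `derive_relative_signature()`, `rank_genes()`, `ks_enrichment()`, `connectivity_score()`, `score_all()` |
| Consensus & states | `remove_contaminants()`, `label_clusters()`, `consensus_annotate()`, `assign_activation_states()`, `module_score()` |
| Differential expression | `wilcoxon_test()`, `group_markers()`, `pairwise_deg_counts()` |
| Simulation | `dc_sim_config()`, `simulate_dataset()`, `simulate_sort_labels()`, `evaluate_annotation()` |
| End to end | `dc_config()`, `run_dc_pipeline()` |

The methods vignette (`vignettes/consensus-dc-annotation.Rmd`) documents
the model, every threshold and its default, the simulator's generative
assumptions, and known limitations.
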