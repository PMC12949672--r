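# ploidynet

Co-expression network analysis of ploidy contrasts: from diploid/tetraploid
RNA-seq counts to differentially expressed transcripts, a shrinkage-correlation
network, switch-gene (master-regulator) detection, resampling-based robustness,
and genomic hotspot scanning.

## The problem

Whole-genome duplication changes the expression of thousands of transcripts.
Beyond the list of differentially expressed transcripts (DETs), the
interesting biology sits in the co-expression structure: *switch genes* are
network hubs whose correlation with their own module turns negative after
duplication — candidate master regulators of the diploid-to-tetraploid
transition. `ploidynet` is for analysts who have a transcript x library count
matrix from a nested design (genotypes within ploidy, replicates within
genotype), transcript genomic loci, and want a seeded, testable pipeline for
the whole chain — including a synthetic-data generator with planted ground
truth to validate every stage.

## Methods at a glance

* **DE layer** — CPM normalisation; low-count filter (max count < 3 across
  all libraries); `log2FC = log2(mean_4x + 1) − log2(mean_2x + 1)`; pluggable
  test statistic (Welch on log-CPM, or label permutation); Benjamini–Hochberg
  FDR; DETs at `p_adj < 0.05`, `|log2FC| > 2`; network node entry at
  `|log2FC| > 1`; consensus (intersection) DET calls.
* **Network layer** — genotype-centered expression (per-genotype mean
  subtraction, so genotype is a nested blocking factor within ploidy);
  James–Stein/Schäfer–Strimmer shrinkage correlation
  `R* = (1 − λ*) R` with analytic `λ* = Σ Var̂(r_ij) / Σ r_ij²` clipped to
  [0, 1]; unweighted edges at `|R*| ≥ τ`.
* **Switch layer** — k-means modules on correlation profiles (module count
  from the inertia curve); within-module degree z; clusterphobic coefficient
  `K_π = 1 − (k_in/k_g)²`; APCC (mean neighbour correlation); switch =
  non-isolated node with `K_π > 0.8`, `z < 2.5`, `APCC < 0`.
* **Robustness layer** — leave-one-out and stratified 80% subsampling
  (default 18 + 91 = 109 runs); edge Jaccard, module ARI, switch recovery;
  per-type and pooled summaries; consensus switch set at ≥ 50% recovery.
* **Hotspot layer** — transcript midpoints binned into 1-Mb windows; Poisson
  upper-tail enrichment of switch genes per bin (gene-density or
  uniform-length null); BH across bins; hotspot = `p_adj < 0.05`.

The methods vignette (`vignettes/ploidy-coexpression-networks.Rmd`) documents
the models, parameter defaults, numerical conventions and the generator's
design in detail.

## Worked example

```r
library(ploidynet)

# a synthetic experiment at the study design scale, with planted truth
d <- simulate_ploidy_experiment(sim_config(seed = 1))
d
#> <ploidy_dataset> 600 transcripts x 18 libraries (6 genotypes), 5 modules, 30 switch genes

res <- run_pipeline(d$counts, d$samples, d$loci, d$config$genome,
                    config = pipeline_config(seed = 1), out_dir = "out")
res
#> <pipeline_result>
#>   transcripts: 600 (retained 600), libraries: 18
#>   DETs (FDR<0.05, |log2FC|>2): 208; network nodes: 230
#>   edges: 4373 (tau = 0.45, lambda = 0.352), modules: 9
#>   switch genes: 28 (consensus: 30 of 109 runs' sets)
#>   hotspot bins: 1
```

Reading the output: of 600 transcripts, 208 are DETs at the stringent
thresholds and 230 pass the looser node-entry thresholds; the shrinkage
intensity λ = 0.352 contracts the 18-library correlations before
thresholding at τ = 0.45; 28 of the 230 nodes classify as switch genes
(27 of the 30 planted ones, with one false positive). The robustness summary
reproduces the expected stability ordering — removing 1 of 18 libraries
perturbs the network far less than removing 4:

```r
res$robustness$summary$per_type
#>          type   metric  n  mean      sd median
#> 1         LOO  jaccard 18 0.978 0.00817  0.978
#> 2         LOO      ari 18 0.979 0.01039  0.979
#> 3         LOO recovery 18 0.988 0.02122  1.000
#> 4 subsample80  jaccard 91 0.884 0.04854  0.896
#> 5 subsample80      ari 91 0.946 0.02621  0.951
#> 6 subsample80 recovery 91 0.963 0.03836  0.964
```

The planted 1-Mb hotspot (16 switch loci among 29 genes in the bin starting
at 10 Mb, expected rate λ_b = 1.35 under the gene-density null) is called
with `p_adj ≈ 8.5e-11`:

```r
hb <- res$hotspots$bins
hb[hb$is_hotspot, c("chrom", "bin_start", "gene_count", "switch_count", "lambda", "p_adj")]
#>    chrom bin_start gene_count switch_count   lambda        p_adj
#> 11  chr1     1e+07         29           16 1.353333 8.490468e-11
```

All stage artifacts (`de_table.tsv`, `edges.tsv`, `cartography.tsv`,
`switches.txt`, `robustness_*.tsv`, `hotspots.tsv`, `report.json`) land in
`out/` and are byte-identical under a fixed seed.

A thin command-line front end is installed with the package
(`inst/scripts/ploidynet`): `ploidynet simulate`, `ploidynet run-all`,
and per-stage subcommands mirroring the functions above.

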