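---
title: "Ploidy-contrast co-expression networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ploidy-contrast co-expression networks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ploidynet)
```

## The analysis in one paragraph

Whole-genome duplication (WGD) reshapes gene expression: comparing diploid
(2x) and tetraploid (4x) genotypes of the same species, many transcripts shift
in abundance, and a smaller set of *switch genes* — hubs whose correlation
with their own co-expression module turns negative after duplication — are
candidate master regulators of the transition. `ploidynet` implements that
analysis as a reusable, fully seeded pipeline: library-size normalisation and
fold-change/FDR thresholding of a transcript-by-library count matrix;
genotype-centered Pearson correlation with James–Stein shrinkage; an
unweighted co-expression network over the differentially expressed
transcripts; k-means module detection with heat-cartography metrics and
average neighbour correlation (APCC) to classify switch genes; leave-one-out
(LOO) and 80% subsampling to quantify how stable the network, its modules and
its switch layer are; and a Poisson enrichment scan for genomic bins where
switch genes cluster (hotspots). A negative-binomial simulator with planted
ground truth exercises every stage end to end.

## Differential expression layer

Counts are normalised to counts-per-million (each library rescaled to a
common total). The low-count rule removes a transcript only when its count is
below 3 in *every* library — the most permissive reading of "fewer than three
in all replicates"; the stricter per-genotype reading (keep only transcripts
with at least one genotype whose every replicate reaches 3) is available via
`filter_low_counts(per_group = TRUE)`.

Fold changes are `log2(mean_4x + 1) - log2(mean_2x + 1)` on normalised
counts; the pseudocount of 1 bounds the statistic for transcripts absent from
one group. The test statistic is deliberately pluggable — the calling rules,
not the statistic, are the substance here. Two reference statistics are
provided: a Welch t-test on `log2(CPM + 1)` (default) and a label-permutation
test of the group mean difference with add-one smoothing,
`p = (1 + #{|t*| > |t|}) / (B + 1)`; the exhaustive mode enumerates all `n!`
label orderings for small designs. Negative-binomial GLMs and precision
weights are intentionally out of scope.

Calling uses strict inequalities exactly as conventionally printed:
differentially expressed transcripts (DETs) at `p_adj < 0.05` and
`|log2FC| > 2`; network node entry at `p_adj < 0.05` and `|log2FC| > 1`.
`consensus_dets()` intersects DET sets from different statistics, the "true
DET" notion used when two analysis routes must agree.

## Correlation, shrinkage and the network

Correlations are computed on the genotype-centered matrix: per transcript,
each genotype's mean is subtracted, so genotype acts as a nested blocking
factor within ploidy and the surviving co-fluctuation is ploidy-associated
rather than genotype-driven. Transcripts flat after centering are dropped
(logged in the result).

The correlation estimator is the Schäfer–Strimmer analytic James–Stein
shrinkage toward the identity target:

$$ R^*_{ij} = (1-\lambda^*)\, r_{ij}, \qquad
   \lambda^* = \mathrm{clip}\!\left(
     \frac{\sum_{i \ne j} \widehat{\mathrm{Var}}(r_{ij})}
          {\sum_{i \ne j} r_{ij}^2}, 0, 1\right), $$

with the unbiased variance estimate
$\widehat{\mathrm{Var}}(r_{ij}) = \frac{n}{(n-1)^3}\sum_k (w_{kij}-\bar w_{ij})^2$,
$w_{kij}$ the products of row-standardised observations. The identity target
is the standard choice for correlation matrices; by default no
degrees-of-freedom correction is applied for the subtracted genotype means
(`df_correct = TRUE` rescales the variance term by $(n-1)/(n-g)$). When all
off-diagonal correlations vanish the intensity is set to 1 by convention.

The network is unweighted: an edge joins two transcripts iff
$|R^*_{ij}| \ge \tau$. No published value of $\tau$ exists for this design,
so it is a mandatory, always-logged parameter. The packaged default,
$\tau = 0.45$, was calibrated once on the simulator's default conditions
before the validation suite was frozen: with 18 libraries and 6 genotype
blocks the residual correlation noise has spread $\approx 1/\sqrt{12}$, and
after count-noise attenuation and shrinkage the planted within-module
correlation sits near $0.6{-}0.7$ and the planted switch anti-correlation
near $-0.5$; $\tau = 0.45$ is the midpoint of the band that keeps both edge
types while excluding roughly 97% of null pairs. `build_network()` itself
defaults to the more conservative 0.7 for standalone use on larger designs.

## Modules, cartography and the switch rule

Modules are k-means clusters of the rows of $R^*$ (each node's correlation
profile), 10 restarts, fixed seed. The number of modules is selected from the
inertia curve. The classical elbow — the largest second difference of inertia
— proved unreliable here: when a few large modules coexist with small
satellite groups of anti-correlated hubs (exactly the structure switch genes
create), the inertia curve decays smoothly and its maximal curvature
collapses to `k = 2`, merging modules and corrupting every downstream metric.
The default selector is therefore a diminishing-returns rule: the smallest
`k` whose next refinement improves inertia by less than 10% (`gain_min`). The
curvature elbow (on log-inertia, which makes it scale-free) remains available
via `k_select = "elbow"`.

Per node, with degree $k_g$ and within-module degree $k_{in}$:

* within-module degree z-score: $z = (k_{in} - \mu_{k_{in}})/\sigma_{k_{in}}$
  inside the node's module ($z = 0$ when $\sigma = 0$);
* clusterphobic coefficient: $K_\pi = 1 - (k_{in}/k_g)^2$ ($0$ for isolated
  nodes);
* APCC: the mean Pearson correlation between the node and its network
  neighbours, on the centered matrix (`NA` for isolated nodes; a flagged
  alternative on raw expression is not provided because the centered matrix
  is the one the network itself is built from).

A node is a **switch gene** iff it is non-isolated, $K_\pi > 0.8$,
$z < 2.5$ and $\mathrm{APCC} < 0$ — a hub whose edges mostly leave its own
module and whose neighbours it anti-correlates with. The three thresholds
follow the conventional switch region of the heat-cartography literature and
are all configurable and echoed in the run report. Hub roles ("date",
"party", "fight-club") are reported for orientation only.

These conventions avoid `NaN` propagation deliberately: $z = 0$ for
degenerate modules, $K_\pi = 0$ and APCC `NA` for isolated nodes, so an
isolated node can never be a switch.

## Robustness layer

`run_perturbations()` re-executes centering → correlation → thresholding →
modules → switch classification on perturbed library sets: one LOO run per
library (per genotype via `loo_unit = "genotype"`) plus `n_subsample_runs`
subsampling runs retaining 80% of each ploidy group, drawn without
replacement and stratified so both groups survive every run (correlations
across a ploidy contrast need both groups). Runs that would leave a ploidy
group with fewer than 2 libraries are skipped with a warning. The module
count `k` is treated as part of the reference configuration: it is selected
once on the full-library run and perturbation runs refit k-means at that
fixed `k`. Re-selecting `k` per run would conflate module-count instability
with assignment instability in the ARI and makes 100+ runs needlessly
expensive.

The default schedule is 18 LOO + 91 subsample = 109 runs, matching the run
count of an 18-library design with a round hundred-odd total; both numbers
are configurable. Three metrics compare each run with the reference: edge
Jaccard ($|E_r \cap E_p| / |E_r \cup E_p|$; 1 when both empty), module ARI
over shared nodes (undefined below 2 shared nodes; defined as 1 in the
degenerate all-singleton/all-one-cluster case, where the partitions agree),
and switch recovery ($|S_r \cap S_p|/|S_r|$; undefined for an empty reference
set). Undefined values are excluded from summaries and counted. Summaries
report per-run-type mean, sample SD and median plus pooled medians; the
consensus switch set collects genes recovered in at least `min_frac` (default
50%) of completed runs.

## Hotspot layer

Transcript loci (BED, 0-based half-open) are assigned to fixed-width bins
(default 1 Mb) by midpoint, which gives genes spanning a bin edge a unique
home. Each bin is tested for switch enrichment with a Poisson upper tail,
$p_b = P(X \ge x_b \mid \mathrm{Poisson}(\lambda_b))$, $p_b = 1$ for
$x_b = 0$. Two null rates are provided: `gene_density` (default),
$\lambda_b = S\, g_b / G$, which conditions on the local gene density and is
the right null when gene density varies along chromosomes (pericentromeric
deserts would otherwise masquerade as cold spots and gene-rich arms as
hotspots); and `uniform_length`, $\lambda_b = S\, \ell_b / L$. Multiplicity
is handled by Benjamini–Hochberg across tested bins — consistent with the FDR
control used in the expression layer — and a hotspot is a bin with
`p_adj < 0.05`. The discrete Poisson tail is conservative, which the null
calibration test confirms.

## The synthetic-data generator

The generator emulates the study design the pipeline assumes: 6 genotypes
nested in two ploidy groups (3 diploid, 3 tetraploid) with 3 replicate
libraries each. On the log2 scale, gene $g$ in library $s$ has latent mean

$$ b_g + \delta_g\,[\text{4x}] + a_{g,\mathrm{geno}(s)}
   + \sigma\left(c_g(s) f_{m(g),s} + \sqrt{1-c_g(s)^2}\,\varepsilon_{gs}\right) $$

with baseline $b_g \sim N(5.5, 1.2)$ (log2 CPM scale), planted ploidy effect
$\delta_g$, genotype intercepts $a \sim N(0, 0.5)$, latent scale
$\sigma = 1.2$, and per-module, per-library factors $f$. Counts are negative
binomial with dispersion 0.05 around means rescaled per library to a
log-normal library size (mean 5 million), so library-size normalisation is
exercised non-trivially.

Choices that make the planted truth exact rather than approximate:

* **Orthonormal module factors.** Factors are centered within genotypes and
  orthonormalised across libraries. With only $n - g \approx 12$ residual
  degrees of freedom, raw Gaussian factors carry chance inter-module sample
  correlations up to $\pm 0.5$, which would plant (and sometimes dominate)
  structure the ground truth does not record.
* **Balanced ploidy effects.** Planted $\delta_g$ are adjusted (on the
  non-switch module genes) so the expression-weighted total output is
  ploidy-invariant. Without this, Jensen's inequality makes the 4x
  transcriptome systematically larger, and library-size normalisation then
  shifts every fold change by a composition constant ($\approx -1.3$ at the
  defaults), divorcing observed from planted effects. The balanced regime is
  exactly the one in which pure library-size normalisation is the right
  method — and it mirrors dosage-compensated transcriptomes.
* **Module genes vs background.** Five modules of 60 genes sit in a 600-gene
  transcriptome; the other half is unstructured background with no ploidy
  response. Background mass keeps any single module's factor from dominating
  library totals (whole-transcriptome modules induce strong compositional
  closure correlations), and background genes stay out of the network the
  same way they would in the real analysis: they fail the node-entry
  thresholds.
* **Switch coupling.** A switch gene's factor coupling is solved from the
  target pooled neighbour correlation (`switch_anticorr`, default $-0.8$)
  with the tetraploid coupling pinned at $-1$: the strongest possible WGD
  contrast consistent with the target. A symmetric sign flip (equal coupling
  magnitude in both ploidies) cancels in the pooled correlation and leaves
  switches invisible to any correlation-based detector, so it is not used.
  Switch genes also receive a guaranteed ploidy effect ($|\delta| \ge 3$):
  they are, by construction, strong DETs — as their real counterparts must be
  to enter the network at all.
* **Loci.** Gene loci are uniform over a 50-Mb single-chromosome genome,
  except that each switch gene lands in a designated 1-Mb hotspot bin with
  probability `hotspot_fraction` (default 0.5, i.e. an expected 15 of 30
  switches in one bin).

Seeding is hierarchical: one master seed, with every component (baseline,
effects, factors, noise, library sizes, counts, loci, each subsample run)
drawing from its own stream derived by a documented integer hash
(`derive_seed()`), so adding a component never shifts the others and
identical configurations are byte-identical across platforms.

**What passing tests do and do not show.** The generator plants exactly
orthogonal modules, balanced fold changes, and NB noise with a single
dispersion. Real data have correlated modules, composition shifts,
gene-specific dispersions, batch structure and unequal genotype numbers per
ploidy. Recovery of planted truth therefore validates the machinery — the
estimators, rules and bookkeeping — not the claim that any real dataset's
switch list is correct.

## Problem sizes and determinism

The validation suite runs the full design at its study scale: 600 genes x 18
libraries for recovery tests; 5 independent seeds x (18 LOO + 20 subsample)
runs for the stability ordering; 100 replicates for hotspot power and 200 for
null calibration; 1000 random vectors for the FDR oracle; all set partitions
of up to 6 nodes for the ARI oracle. The full default pipeline (109
robustness runs) completes in well under a minute on a single core. Every
artifact file is byte-stable under a fixed seed; the run report echoes every
configurable decision and excludes wall-clock fields from its deterministic
portion.

## Known limitations

* The DE layer is a thresholding harness around a simple statistic, not a
  count-model fit; with 3 replicates per genotype its power is limited and it
  treats libraries within a genotype as exchangeable.
* Genotype centering removes ploidy-level mean structure along with genotype
  structure; correlations reflect within-genotype co-fluctuation only, and
  with $n - g$ effective degrees of freedom the correlation noise floor is
  high at this design size — which is precisely why shrinkage and the
  robustness layer exist.
* k-means on correlation profiles assumes roughly spherical module clusters;
  strongly nested or overlapping modules would call for graph clustering
  instead.
* The Poisson hotspot test treats genes as independent units; tandem arrays
  of paralogous switch genes would inflate enrichment.
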