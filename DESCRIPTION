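Package: ploidynet
Title: Ploidy-Contrast Co-Expression Networks and Switch-Gene Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing bulk RNA-seq ploidy contrasts (diploid versus
    tetraploid genotypes) through co-expression networks. Implements library-size
    normalisation, low-count filtering, fold-change/FDR thresholding and consensus
    differential-expression calls; genotype-centered Pearson correlation with
    James-Stein (Schafer-Strimmer) shrinkage and unweighted network construction;
    k-means module detection with heat-cartography metrics (within-module degree
    z-score, clusterphobic coefficient) and average neighbour correlation to
    classify switch genes (candidate master regulators); leave-one-out and
    subsampling robustness assessment (edge Jaccard, module adjusted Rand index,
    switch recovery, consensus switch sets); and Poisson enrichment scans of
    switch-gene loci over fixed-width genomic bins. Includes a negative-binomial
    simulator with planted modules, switch genes and genomic hotspots for
    end-to-end validation against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    mclust
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
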