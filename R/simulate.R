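## Synthetic ploidy-contrast experiments with planted co-expression modules,
## switch genes and genomic hotspots.

#' Configuration for a synthetic ploidy experiment
#'
#' Describes a nested diploid/tetraploid design (genotypes within ploidy,
#' replicate libraries within genotype) together with the latent structure the
#' downstream pipeline is expected to recover: correlated gene modules, planted
#' ploidy log2 fold changes, "switch" genes whose module coupling changes after
#' genome doubling, and genomic loci concentrated in hotspot bins.
#'
#' The latent expression model, on the log2 scale, is
#' `b_g + delta_g * I(4x) + a_{g,geno} + latent_sd * (c_g(s) * f_m + sqrt(1 - c_g(s)^2) * eps)`
#' where `f_m` is a per-module, per-library standard normal factor. Ordinary
#' module members use the coupling `c = sqrt(module_corr)` in both ploidies, so
#' their pairwise latent correlation is `module_corr`. Switch genes use a
#' ploidy-dependent coupling pair `(c_2x, c_4x)` solved so that their pooled
#' correlation with a module neighbour equals `switch_anticorr`, with the 4x
#' coupling pinned at -1 (maximal whole-genome-duplication contrast). Counts are
#' negative binomial with mean `2^latent / 1e6 * library_size` and dispersion
#' `nb_dispersion`; library sizes are log-normal around `lib_size_mean` so that
#' library-size normalisation is non-trivial.
#'
#' @param n_genes Number of transcripts.
#' @param n_genotypes_2x,n_genotypes_4x Number of diploid / tetraploid genotypes.
#' @param n_replicates Replicate libraries per genotype.
#' @param n_modules Number of planted co-expression modules.
#' @param module_size Genes per module. The first `n_modules * module_size`
#'   transcripts are assigned round-robin to modules; the remainder form an
#'   unstructured background (module label 0) with no factor coupling and no
#'   planted ploidy effect, emulating the bulk of a transcriptome that neither
#'   responds to ploidy nor co-fluctuates in tight modules.
#' @param module_corr Target within-module latent correlation, in `[0, 1]`.
#' @param n_switch Number of planted switch genes.
#' @param switch_anticorr Target pooled correlation between a switch gene and an
#'   ordinary member of its module, in `[-1, 0)`.
#' @param ploidy_lfc_sd Standard deviation (log2 units) of planted ploidy fold
#'   changes for non-switch genes. Switch genes always receive a fold change of
#'   magnitude at least 2.5 (they are differentially expressed by construction).
#' @param nb_dispersion Negative-binomial dispersion (`size = 1/dispersion`);
#'   `0` gives Poisson counts.
#' @param lib_size_mean Expected library size (total counts scale).
#' @param genotype_sd SD (log2 units) of per-gene genotype random intercepts.
#' @param latent_sd SD (log2 units) of the module-plus-noise latent signal.
#' @param genome Named numeric vector of chromosome lengths in bp.
#' @param hotspot_bins Data frame with columns `chrom` and `bin` (0-based 1-Mb
#'   bin index) where switch loci concentrate.
#' @param hotspot_fraction Probability that a switch gene is placed in a hotspot
#'   bin, in `[0, 1]`.
#' @param seed Integer master seed; all internal streams are derived from it via
#'   [derive_seed()].
#' @return An object of class `sim_config`.
#' @seealso [simulate_ploidy_experiment()]
#' @export
sim_config <- function(n_genes = 600L,
                       n_genotypes_2x = 3L,
                       n_genotypes_4x = 3L,
                       n_replicates = 3L,
                       n_modules = 5L,
                       module_size = 60L,
                       module_corr = 0.9,
                       n_switch = 30L,
                       switch_anticorr = -0.8,
                       ploidy_lfc_sd = 2,
                       nb_dispersion = 0.05,
                       lib_size_mean = 5e6,
                       genotype_sd = 0.5,
                       latent_sd = 1.2,
                       genome = c(chr1 = 5e7),
                       hotspot_bins = data.frame(chrom = "chr1", bin = 10L),
                       hotspot_fraction = 0.5,
                       seed = 1L) {
  cfg <- structure(
    list(n_genes = as.integer(n_genes),
         n_genotypes_2x = as.integer(n_genotypes_2x),
         n_genotypes_4x = as.integer(n_genotypes_4x),
         n_replicates = as.integer(n_replicates),
         n_modules = as.integer(n_modules),
         module_size = as.integer(module_size),
         module_corr = module_corr,
         n_switch = as.integer(n_switch),
         switch_anticorr = switch_anticorr,
         ploidy_lfc_sd = ploidy_lfc_sd,
         nb_dispersion = nb_dispersion,
         lib_size_mean = lib_size_mean,
         genotype_sd = genotype_sd,
         latent_sd = latent_sd,
         genome = genome,
         hotspot_bins = hotspot_bins,
         hotspot_fraction = hotspot_fraction,
         seed = as.integer(seed)),
    class = "sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  abort_if(!inherits(cfg, "sim_config"), "`config` must be built by sim_config()")
  for (f in c("n_genes", "n_genotypes_2x", "n_genotypes_4x", "n_replicates",
              "n_modules")) {
    abort_if(is.na(cfg[[f]]) || cfg[[f]] < 1L, "field `%s` must be a positive count", f)
  }
  abort_if(cfg$module_size < 1L, "field `module_size` must be a positive count")
  abort_if(cfg$n_modules * cfg$module_size > cfg$n_genes,
           "n_modules * module_size must be <= n_genes")
  abort_if(cfg$n_switch < 0L, "field `n_switch` must be >= 0")
  abort_if(cfg$n_switch > cfg$n_modules * cfg$module_size,
           "field `n_switch` must be <= the number of module genes")
  abort_if(cfg$module_corr < 0 || cfg$module_corr > 1,
           "field `module_corr` must be in [0, 1]")
  abort_if(cfg$switch_anticorr >= 0 || cfg$switch_anticorr < -1,
           "field `switch_anticorr` must be in [-1, 0)")
  abort_if(cfg$ploidy_lfc_sd < 0, "field `ploidy_lfc_sd` must be >= 0")
  abort_if(cfg$nb_dispersion < 0, "field `nb_dispersion` must be >= 0")
  abort_if(cfg$lib_size_mean <= 0, "field `lib_size_mean` must be > 0")
  abort_if(cfg$genotype_sd < 0, "field `genotype_sd` must be >= 0")
  abort_if(cfg$latent_sd <= 0, "field `latent_sd` must be > 0")
  abort_if(is.null(names(cfg$genome)) || any(cfg$genome <= 0),
           "field `genome` must be a named vector of positive lengths")
  abort_if(cfg$hotspot_fraction < 0 || cfg$hotspot_fraction > 1,
           "field `hotspot_fraction` must be in [0, 1]")
  hb <- cfg$hotspot_bins
  abort_if(!is.data.frame(hb) || !all(c("chrom", "bin") %in% names(hb)),
           "field `hotspot_bins` must be a data frame with columns chrom, bin")
  abort_if(!all(hb$chrom %in% names(cfg$genome)),
           "field `hotspot_bins` refers to a chromosome absent from `genome`")
  bad <- hb$bin < 0 | hb$bin * 1e6 >= cfg$genome[hb$chrom]
  abort_if(any(bad), "field `hotspot_bins` has a bin outside its chromosome")
  invisible(cfg)
}

# Solve the (c_2x, c_4x) factor couplings of a switch gene so that its pooled
# correlation with an ordinary module member equals `target` (< 0): the pooled
# correlation is w * (c_2x + c_4x) / 2 with w = sqrt(module_corr). The 4x
# coupling is pinned at the most negative feasible value so the ploidy contrast
# is maximal; unreachable targets are clamped with a warning.
switch_couplings <- function(module_corr, target) {
  w <- sqrt(module_corr)
  if (w == 0) return(c(c2 = 0, c4 = 0))
  t_f <- target / w                      # required mean coupling
  if (t_f < -1) {
    warning(sprintf(
      "switch_anticorr = %.2f is unreachable for module_corr = %.2f; clamped",
      target, module_corr), call. = FALSE)
    t_f <- -1
  }
  c2 <- min(1, max(-1, 2 * t_f + 1))
  c4 <- max(-1, 2 * t_f - c2)
  c(c2 = c2, c4 = c4)
}

#' Simulate a ploidy-contrast expression experiment
#'
#' Generates a count matrix, sample sheet, transcript loci and the planted
#' ground truth for a nested diploid/tetraploid design (see [sim_config()] for
#' the generative model). Identical `config` (including its `seed`) produces
#' byte-identical output; every stochastic component draws from its own derived
#' seed stream, so changing, say, the locus placement never alters the counts.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `ploidy_dataset`: a list with elements
#'   \describe{
#'     \item{counts}{integer matrix, transcripts x libraries.}
#'     \item{samples}{sample sheet (`library_id`, `genotype_id`, `ploidy`,
#'       `replicate`).}
#'     \item{loci}{BED6-shaped data frame of transcript loci (0-based
#'       half-open).}
#'     \item{truth}{planted structure: `module` (named integer vector),
#'       `switch_ids`, `hotspot_bins`, `ploidy_log2fc` (named numeric),
#'       `switch_in_hotspot` (named logical).}
#'     \item{latent}{the latent log2 signal matrix (diagnostic; module factor
#'       plus noise component only, before baseline/ploidy/genotype terms).}
#'   }
#' @examples
#' d <- simulate_ploidy_experiment(sim_config(n_genes = 50, n_switch = 4))
#' dim(d$counts)
#' @export
simulate_ploidy_experiment <- function(config) {
  cfg <- validate_sim_config(config)
  ds <- function(key) derive_seed(cfg$seed, paste0("ploidynet.sim.", key))

  G <- cfg$n_genes
  genotypes <- data.frame(
    genotype_id = c(sprintf("G2x_%d", seq_len(cfg$n_genotypes_2x)),
                    sprintf("G4x_%d", seq_len(cfg$n_genotypes_4x))),
    ploidy = rep(c("2x", "4x"), c(cfg$n_genotypes_2x, cfg$n_genotypes_4x)),
    stringsAsFactors = FALSE)
  samples <- do.call(rbind, lapply(seq_len(nrow(genotypes)), function(i) {
    data.frame(library_id = sprintf("%s_r%d", genotypes$genotype_id[i],
                                    seq_len(cfg$n_replicates)),
               genotype_id = genotypes$genotype_id[i],
               ploidy = genotypes$ploidy[i],
               replicate = seq_len(cfg$n_replicates),
               stringsAsFactors = FALSE)
  }))
  rownames(samples) <- NULL
  n_lib <- nrow(samples)
  gene_ids <- sprintf("TR%05d", seq_len(G))

  n_mod_genes <- cfg$n_modules * cfg$module_size
  module <- c(rep(seq_len(cfg$n_modules), length.out = n_mod_genes),
              rep(0L, G - n_mod_genes))
  switch_idx <- if (cfg$n_switch > 0L) {
    sort(with_seed(ds("switch_select"), sample.int(n_mod_genes, cfg$n_switch)))
  } else integer(0)
  is_switch <- seq_len(G) %in% switch_idx

  ## latent pieces, each from its own stream
  baseline <- with_seed(ds("baseline"), rnorm(G, mean = 5.5, sd = 1.2))
  delta <- with_seed(ds("ploidy_lfc"), {
    d <- rnorm(G, 0, cfg$ploidy_lfc_sd)
    d[module == 0L] <- 0                  # background: ploidy-unresponsive
    if (cfg$n_switch > 0L) {
      sgn <- sample(c(-1, 1), cfg$n_switch, replace = TRUE)
      d[switch_idx] <- sgn * (3 + abs(rnorm(cfg$n_switch, 0, 0.5)))
    }
    # Balance the planted effects so the expression-weighted total output is
    # ploidy-invariant (sum_g 2^(b+delta) = sum_g 2^b): the regime in which
    # library-size normalization recovers the planted fold changes without a
    # global composition shift. Switch genes keep their full planted effect;
    # the offset is absorbed by the non-switch background (3 fixed-point
    # iterations leave a negligible residual).
    resp <- module != 0L & !is_switch
    for (it in 1:8) {
      c0 <- log2(sum(2^(baseline + d)) / sum(2^baseline))
      d[resp] <- d[resp] - c0
    }
    d
  })
  intercepts <- with_seed(ds("genotype_intercepts"),
                          matrix(rnorm(G * nrow(genotypes), 0, cfg$genotype_sd),
                                 nrow = G))
  # Module factors are drawn Gaussian, centered within genotypes and then
  # orthonormalised (unit sample sd) across libraries, so the planted modules
  # are exactly uncorrelated in-sample. With only ~n - g residual degrees of
  # freedom, raw draws would carry chance inter-module correlations large
  # enough to confound the planted structure.
  factors <- with_seed(ds("module_factors"), {
    f0 <- matrix(rnorm(cfg$n_modules * n_lib), nrow = cfg$n_modules)
    for (g in unique(samples$genotype_id)) {
      idx <- which(samples$genotype_id == g)
      f0[, idx] <- f0[, idx, drop = FALSE] - rowMeans(f0[, idx, drop = FALSE])
    }
    q <- qr.Q(qr(t(f0)))[, seq_len(cfg$n_modules), drop = FALSE]
    t(q) / apply(q, 2L, sd)
  })
  eps <- with_seed(ds("gene_noise"), matrix(rnorm(G * n_lib), nrow = G))

  cc <- switch_couplings(cfg$module_corr, cfg$switch_anticorr)
  w <- sqrt(cfg$module_corr)
  is4x <- samples$ploidy == "4x"
  coupling <- matrix(w, nrow = G, ncol = n_lib)
  coupling[module == 0L, ] <- 0
  if (cfg$n_switch > 0L) {
    coupling[switch_idx, !is4x] <- cc[["c2"]]
    coupling[switch_idx, is4x] <- cc[["c4"]]
  }
  latent_signal <- cfg$latent_sd *
    (coupling * factors[pmax(module, 1L), , drop = FALSE] +
       sqrt(1 - coupling^2) * eps)

  geno_idx <- match(samples$genotype_id, genotypes$genotype_id)
  latent <- latent_signal +
    outer(baseline, rep(1, n_lib)) +
    outer(delta, as.numeric(is4x)) +
    intercepts[, geno_idx, drop = FALSE]

  lib_sizes <- with_seed(ds("lib_sizes"), {
    sdlog <- 0.25
    rlnorm(n_lib, meanlog = log(cfg$lib_size_mean) - sdlog^2 / 2, sdlog = sdlog)
  })
  rel <- 2^latent
  mu <- sweep(rel, 2L, lib_sizes / colSums(rel), `*`)
  counts <- with_seed(ds("counts"), {
    if (cfg$nb_dispersion > 0) {
      matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
             nrow = G)
    } else {
      matrix(rpois(length(mu), lambda = mu), nrow = G)
    }
  })
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(gene_ids, samples$library_id)
  dimnames(latent_signal) <- dimnames(counts)

  loci <- with_seed(ds("loci"), {
    place_loci(gene_ids, switch_idx, cfg)
  })

  truth <- list(
    module = setNames(module, gene_ids),
    switch_ids = gene_ids[switch_idx],
    hotspot_bins = cfg$hotspot_bins,
    ploidy_log2fc = setNames(delta, gene_ids),
    switch_in_hotspot = attr(loci, "switch_in_hotspot"))
  attr(loci, "switch_in_hotspot") <- NULL

  structure(list(counts = counts, samples = samples, loci = loci,
                 truth = truth, latent = latent_signal, config = cfg),
            class = "ploidy_dataset")
}

# Transcript loci: uniform over the genome, except that each switch gene is
# placed inside a randomly chosen hotspot bin with probability
# `hotspot_fraction` (1-Mb bins, midpoint strictly inside the bin).
place_loci <- function(gene_ids, switch_idx, cfg) {
  G <- length(gene_ids)
  bin_size <- 1e6
  lens <- round(runif(G, 500, 3000))
  chroms <- names(cfg$genome)
  chrom <- chroms[sample.int(length(chroms), G, replace = TRUE,
                             prob = cfg$genome / sum(cfg$genome))]
  start <- floor(runif(G, 0, cfg$genome[chrom] - lens))

  in_hot <- setNames(logical(length(switch_idx)), gene_ids[switch_idx])
  if (length(switch_idx) > 0L) {
    hot <- runif(length(switch_idx)) < cfg$hotspot_fraction
    in_hot[] <- hot
    if (any(hot)) {
      hb <- cfg$hotspot_bins
      pick <- sample.int(nrow(hb), sum(hot), replace = TRUE)
      idx <- switch_idx[hot]
      lo <- hb$bin[pick] * bin_size
      hi <- pmin(lo + bin_size, cfg$genome[hb$chrom[pick]])
      # midpoint strictly inside the bin, with margin for the gene length
      mid <- runif(length(idx), lo + lens[idx], hi - lens[idx])
      chrom[idx] <- hb$chrom[pick]
      start[idx] <- pmax(0, floor(mid - lens[idx] / 2))
    }
  }
  data.frame(chrom = chrom,
             start = as.numeric(start),
             end = as.numeric(start + lens),
             name = gene_ids,
             score = 0L,
             strand = sample(c("+", "-"), G, replace = TRUE),
             stringsAsFactors = FALSE) -> bed
  rownames(bed) <- NULL
  attr(bed, "switch_in_hotspot") <- in_hot
  bed
}

#' Write a synthetic dataset as a plain-text fixture
#'
#' Writes `counts.tsv`, `samples.tsv`, `loci.bed` and `truth.json` into
#' `directory`. Reading them back with [read_fixture()] reproduces the dataset
#' (counts integer-exact).
#'
#' @param dataset A `ploidy_dataset` from [simulate_ploidy_experiment()].
#' @param directory Output directory (created if missing).
#' @return Invisibly, a named character vector of the four file paths.
#' @export
write_fixture <- function(dataset, directory) {
  abort_if(!inherits(dataset, "ploidy_dataset"),
           "`dataset` must be a ploidy_dataset")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  abort_if(!dir.exists(directory), "cannot create directory '%s'", directory)

  counts_path <- file.path(directory, "counts.tsv")
  cdf <- data.frame(transcript_id = rownames(dataset$counts),
                    dataset$counts, check.names = FALSE)
  write.table(cdf, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)

  samples_path <- file.path(directory, "samples.tsv")
  write.table(dataset$samples, samples_path, sep = "\t", quote = FALSE,
              row.names = FALSE)

  bed_path <- file.path(directory, "loci.bed")
  loci <- dataset$loci
  loci$start <- format(loci$start, scientific = FALSE, trim = TRUE)
  loci$end <- format(loci$end, scientific = FALSE, trim = TRUE)
  write.table(loci, bed_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  truth_path <- file.path(directory, "truth.json")
  truth <- dataset$truth
  jsonlite::write_json(
    list(module = as.list(truth$module),
         switch_ids = truth$switch_ids,
         hotspot_bins = truth$hotspot_bins,
         ploidy_log2fc = as.list(truth$ploidy_log2fc),
         switch_in_hotspot = as.list(truth$switch_in_hotspot)),
    truth_path, auto_unbox = TRUE, digits = NA)

  invisible(c(counts = counts_path, samples = samples_path,
              bed = bed_path, truth = truth_path))
}

#' @export
print.ploidy_dataset <- function(x, ...) {
  cat(sprintf(
    "<ploidy_dataset> %d transcripts x %d libraries (%d genotypes), %d modules, %d switch genes\n",
    nrow(x$counts), ncol(x$counts), length(unique(x$samples$genotype_id)),
    length(unique(x$truth$module[x$truth$module > 0])),
    length(x$truth$switch_ids)))
  invisible(x)
}
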