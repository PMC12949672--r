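## Poisson enrichment of switch-gene loci over fixed-width genomic bins.

#' Tile a genome into bins and count genes per bin
#'
#' Bins tile each chromosome as `[k * bin_size, (k+1) * bin_size)`; a gene is
#' assigned to the bin containing its midpoint `floor((start + end) / 2)`
#' (unique assignment for genes spanning a bin edge).
#'
#' @param loci BED-shaped data frame (`chrom`, `start`, `end`, `name`,
#'   optionally `score`, `strand`), 0-based half-open coordinates.
#' @param genome Named numeric vector of chromosome lengths (bp), or a data
#'   frame with columns `chrom`, `length`.
#' @param bin_size Bin width in bp (default 1 Mb).
#' @return An object of class `bin_table`: list with `bins` (data frame
#'   `chrom`, `bin`, `bin_start`, `bin_end`, `gene_count`), `gene_bin` (data
#'   frame `transcript_id`, `chrom`, `bin`), `bin_size`, `genome`.
#' @export
bin_genome <- function(loci, genome, bin_size = 1e6) {
  abort_if(bin_size <= 0, "`bin_size` must be > 0")
  if (is.data.frame(genome)) {
    abort_if(!all(c("chrom", "length") %in% names(genome)),
             "`genome` data frame needs columns chrom, length")
    genome <- setNames(genome$length, genome$chrom)
  }
  need <- c("chrom", "start", "end", "name")
  abort_if(!all(need %in% names(loci)), "`loci` must have columns %s",
           paste(need, collapse = ", "))
  bad <- !(loci$chrom %in% names(genome))
  abort_if(any(bad), "locus '%s' is on unknown chromosome '%s'",
           loci$name[bad][1L], loci$chrom[bad][1L])
  bad <- loci$start < 0 | loci$start >= loci$end
  abort_if(any(bad), "locus '%s' has invalid coordinates [%s, %s)",
           loci$name[bad][1L], loci$start[bad][1L], loci$end[bad][1L])
  bad <- loci$end > genome[loci$chrom]
  abort_if(any(bad), "locus '%s' extends beyond chromosome '%s'",
           loci$name[bad][1L], loci$chrom[bad][1L])

  bins <- do.call(rbind, lapply(names(genome), function(ch) {
    n_b <- ceiling(genome[[ch]] / bin_size)
    data.frame(chrom = ch, bin = seq_len(n_b) - 1L,
               bin_start = (seq_len(n_b) - 1L) * bin_size,
               bin_end = pmin(seq_len(n_b) * bin_size, genome[[ch]]),
               stringsAsFactors = FALSE)
  }))
  mid <- floor((loci$start + loci$end) / 2)
  gene_bin <- data.frame(transcript_id = loci$name, chrom = loci$chrom,
                         bin = floor(mid / bin_size), stringsAsFactors = FALSE)
  key <- function(ch, b) paste(ch, b, sep = ":")
  cnt <- table(key(gene_bin$chrom, gene_bin$bin))
  bins$gene_count <- as.integer(cnt[key(bins$chrom, bins$bin)])
  bins$gene_count[is.na(bins$gene_count)] <- 0L
  rownames(bins) <- NULL
  structure(list(bins = bins, gene_bin = gene_bin, bin_size = bin_size,
                 genome = genome),
            class = "bin_table")
}

#' Poisson upper-tail enrichment of switch genes per bin
#'
#' Tests each bin for an excess of switch genes against a Poisson null.
#' Expected rates:
#' \describe{
#'   \item{`gene_density`}{`lambda_b = S * g_b / G` (S = mapped switch genes,
#'     G = mapped genes, `g_b` = genes in the bin); bins with no genes are not
#'     tested. This adjusts for non-uniform gene density (e.g. pericentromeric
#'     gene deserts) and is the default.}
#'   \item{`uniform_length`}{`lambda_b = S * bin_length_b / genome_length`;
#'     every bin is tested.}
#' }
#' `p_b = P(X >= x_b | Poisson(lambda_b))`, with `p_b = 1` when `x_b = 0`.
#'
#' @param bin_table A `bin_table` from [bin_genome()].
#' @param switch_ids Character vector of switch transcript ids (must all be
#'   mapped in the bin table).
#' @param rate_model `"gene_density"` (default) or `"uniform_length"`.
#' @return The `bin_table` with its `bins` data frame extended by
#'   `switch_count`, `lambda`, `p`, `tested`.
#' @export
poisson_enrichment <- function(bin_table, switch_ids,
                               rate_model = c("gene_density", "uniform_length")) {
  rate_model <- match.arg(rate_model)
  abort_if(!inherits(bin_table, "bin_table"), "`bin_table` must come from bin_genome()")
  gb <- bin_table$gene_bin
  miss <- setdiff(switch_ids, gb$transcript_id)
  abort_if(length(miss) > 0L, "switch id(s) not among mapped loci: %s",
           paste(head(miss, 5L), collapse = ", "))
  bins <- bin_table$bins
  S <- length(unique(switch_ids))
  G <- nrow(gb)
  if (S == 0L) warning("no switch genes mapped; all p-values are 1", call. = FALSE)

  key <- function(ch, b) paste(ch, b, sep = ":")
  sw <- gb[gb$transcript_id %in% switch_ids, , drop = FALSE]
  cnt <- table(key(sw$chrom, sw$bin))
  x <- as.integer(cnt[key(bins$chrom, bins$bin)])
  x[is.na(x)] <- 0L
  bins$switch_count <- x

  if (rate_model == "gene_density") {
    bins$lambda <- S * bins$gene_count / G
    bins$tested <- bins$gene_count > 0L
  } else {
    glen <- sum(bin_table$genome)
    bins$lambda <- S * (bins$bin_end - bins$bin_start) / glen
    bins$tested <- TRUE
  }
  bins$p <- ifelse(bins$switch_count == 0L, 1,
                   ppois(bins$switch_count - 1L, bins$lambda,
                         lower.tail = FALSE))
  bins$p[!bins$tested] <- NA_real_
  out <- bin_table
  out$bins <- bins
  out$rate_model <- rate_model
  out
}

#' Call hotspot bins at an FDR threshold
#'
#' Benjamini-Hochberg adjustment (via [bh_adjust()]) over the tested bins;
#' a bin is a hotspot iff `p_adj < fdr_max`.
#'
#' @param bin_table A `bin_table` with `p` computed by [poisson_enrichment()].
#' @param fdr_max FDR threshold (default 0.05).
#' @return The `bin_table` with `p_adj` and `is_hotspot` columns added.
#' @export
call_hotspots <- function(bin_table, fdr_max = 0.05) {
  abort_if(!inherits(bin_table, "bin_table") || is.null(bin_table$bins$p),
           "run poisson_enrichment() first")
  bins <- bin_table$bins
  bins$p_adj <- NA_real_
  tested <- bins$tested
  bins$p_adj[tested] <- bh_adjust(bins$p[tested])
  bins$is_hotspot <- !is.na(bins$p_adj) & bins$p_adj < fdr_max
  out <- bin_table
  out$bins <- bins
  out
}
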