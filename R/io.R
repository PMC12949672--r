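## Validated readers and writers for the package's plain-text formats.

#' Read a transcript-by-library count matrix
#'
#' Expects a tab-separated file whose first column (`transcript_id`) holds
#' transcript ids and whose remaining columns hold nonnegative integer counts,
#' one per library.
#'
#' @param path Path to `counts.tsv`.
#' @return Integer matrix with transcript row names and library column names.
#' @export
read_counts <- function(path) {
  abort_if(!file.exists(path), "file not found: %s", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  abort_if(ncol(df) < 2L, "counts file needs an id column plus >= 1 library")
  abort_if(names(df)[1L] != "transcript_id",
           "first column of counts file must be 'transcript_id'")
  ids <- as.character(df[[1L]])
  abort_if(anyDuplicated(ids) > 0L, "duplicate transcript id at row %d",
           which(duplicated(ids))[1L])
  m <- as.matrix(df[, -1L, drop = FALSE])
  bad <- which(!is.finite(m) | m < 0 | m != floor(m), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("invalid count at row %d (transcript '%s'), column '%s'",
                 bad[1L, 1L], ids[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]),
         call. = FALSE)
  }
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  validate_count_matrix(m)
  m
}

#' Read a sample sheet
#'
#' Tab-separated with columns `library_id`, `genotype_id`, `ploidy`
#' (`"2x"`/`"4x"`) and `replicate`.
#'
#' @param path Path to `samples.tsv`.
#' @return Validated data frame.
#' @export
read_samples <- function(path) {
  abort_if(!file.exists(path), "file not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  validate_samples(df)
  df
}

#' Read transcript loci from a BED file
#'
#' BED6 (or BED4+) with 0-based half-open coordinates; malformed lines are
#' rejected with their line number.
#'
#' @param path Path to a BED file.
#' @return Data frame with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
read_bed <- function(path) {
  abort_if(!file.exists(path), "file not found: %s", path)
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
  abort_if(ncol(df) < 4L, "BED file must have at least 4 columns")
  names(df)[1:4] <- c("chrom", "start", "end", "name")
  if (ncol(df) >= 5L) names(df)[5L] <- "score" else df$score <- 0L
  if (ncol(df) >= 6L) names(df)[6L] <- "strand" else df$strand <- "."
  df <- df[, c("chrom", "start", "end", "name", "score", "strand")]
  bad <- which(!is.finite(df$start) | !is.finite(df$end) |
                 df$start < 0 | df$start >= df$end)
  abort_if(length(bad) > 0L, "malformed BED record at line %d (%s)",
           bad[1L], df$name[bad[1L]])
  abort_if(anyDuplicated(df$name) > 0L, "duplicate locus name at line %d",
           which(duplicated(df$name))[1L])
  df
}

#' Read chromosome lengths
#'
#' Two-column tab-separated file: chromosome name, length in bp.
#'
#' @param path Path to `genome.tsv`.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_genome <- function(path) {
  abort_if(!file.exists(path), "file not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  abort_if(!all(c("chrom", "length") %in% names(df)),
           "genome file needs columns chrom, length")
  abort_if(any(!is.finite(df$length) | df$length <= 0),
           "chromosome lengths must be positive")
  setNames(as.numeric(df$length), df$chrom)
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param directory Directory containing `counts.tsv`, `samples.tsv`,
#'   `loci.bed` and `truth.json`.
#' @return A list with `counts`, `samples`, `loci` and `truth` in the same
#'   shapes as a `ploidy_dataset`.
#' @export
read_fixture <- function(directory) {
  counts <- read_counts(file.path(directory, "counts.tsv"))
  samples <- read_samples(file.path(directory, "samples.tsv"))
  loci <- read_bed(file.path(directory, "loci.bed"))
  tr <- jsonlite::read_json(file.path(directory, "truth.json"),
                            simplifyVector = TRUE)
  truth <- list(
    module = setNames(as.integer(unlist(tr$module)), names(tr$module)),
    switch_ids = as.character(tr$switch_ids),
    hotspot_bins = as.data.frame(tr$hotspot_bins),
    ploidy_log2fc = setNames(as.numeric(unlist(tr$ploidy_log2fc)),
                             names(tr$ploidy_log2fc)),
    switch_in_hotspot = setNames(as.logical(unlist(tr$switch_in_hotspot)),
                                 names(tr$switch_in_hotspot)))
  list(counts = counts, samples = samples, loci = loci, truth = truth)
}

# Deterministic TSV writer (fixed numeric formatting, no row names).
write_tsv <- function(df, path, digits = 10) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, digits = digits,
                                                 format = "g"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a network as GraphML
#'
#' Thin wrapper around \pkg{igraph}'s GraphML writer (requires the suggested
#' \pkg{igraph} package).
#'
#' @param network A `coexpression_network`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
export_graphml <- function(network, path) {
  abort_if(!requireNamespace("igraph", quietly = TRUE),
           "export_graphml() requires the 'igraph' package")
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = data.frame(name = network$nodes))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
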