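## Internal helpers: validation, deterministic seed streams, scoped RNG.

.MOD31 <- 2147483647

abort_if <- function(cond, fmt, ...) {
  if (isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
}

#' Derive a component seed from a master seed
#'
#' Deterministically maps a master seed and a character key to an integer seed
#' below 2^31, so that each stochastic component of the package draws from its
#' own stream. Adding a new component (new key) never shifts the stream of an
#' existing one.
#'
#' The derivation is a 31-bit polynomial hash of `key` combined with a
#' Lehmer step of the master seed: `h = sum_i 31^i key_i mod (2^31 - 1)`,
#' `s = (seed * 48271 + h) mod (2^31 - 1)`. All arithmetic is exact in double
#' precision, so the mapping is platform independent.
#'
#' @param seed Integer master seed.
#' @param key Character scalar naming the component.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, key) {
  abort_if(!is.numeric(seed) || length(seed) != 1L || is.na(seed),
           "`seed` must be a single non-missing number")
  abort_if(!is.character(key) || length(key) != 1L,
           "`key` must be a single string")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% .MOD31
  s <- abs(as.numeric(seed)) %% .MOD31
  s <- (s * 48271) %% .MOD31
  as.integer((s + h) %% .MOD31)
}

# Evaluate `code` under `set.seed(seed)` and restore the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv),
      add = TRUE
    )
  }
  set.seed(seed)
  code
}

# Sample-sheet validation shared by every module that consumes metadata.
validate_samples <- function(samples, library_ids = NULL) {
  abort_if(!is.data.frame(samples), "`samples` must be a data frame")
  need <- c("library_id", "genotype_id", "ploidy", "replicate")
  miss <- setdiff(need, names(samples))
  abort_if(length(miss) > 0L, "sample sheet is missing column(s): %s",
           paste(miss, collapse = ", "))
  abort_if(anyDuplicated(samples$library_id) > 0L,
           "duplicate library_id in sample sheet")
  bad <- setdiff(unique(samples$ploidy), c("2x", "4x"))
  abort_if(length(bad) > 0L, "unknown ploidy value(s): %s",
           paste(bad, collapse = ", "))
  if (!is.null(library_ids)) {
    miss <- setdiff(library_ids, samples$library_id)
    abort_if(length(miss) > 0L,
             "library id(s) absent from sample sheet: %s",
             paste(head(miss, 5L), collapse = ", "))
  }
  invisible(samples)
}

validate_count_matrix <- function(counts) {
  abort_if(!is.matrix(counts) || !is.numeric(counts),
           "`counts` must be a numeric matrix")
  abort_if(is.null(rownames(counts)) || is.null(colnames(counts)),
           "`counts` must have transcript row names and library column names")
  abort_if(anyDuplicated(rownames(counts)) > 0L, "duplicate transcript ids")
  abort_if(anyDuplicated(colnames(counts)) > 0L, "duplicate library ids")
  if (any(counts < 0, na.rm = TRUE)) {
    idx <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative count at transcript '%s', library '%s'",
                 rownames(counts)[idx[1L]], colnames(counts)[idx[2L]]),
         call. = FALSE)
  }
  abort_if(anyNA(counts), "`counts` contains missing values")
  invisible(counts)
}

# Canonical undirected edge keys ("a|b" with a < b) used for set comparisons.
edge_keys <- function(edges) {
  if (is.data.frame(edges)) {
    if (nrow(edges) == 0L) return(character(0))
    a <- pmin(edges$node_a, edges$node_b)
    b <- pmax(edges$node_a, edges$node_b)
    return(paste(a, b, sep = "|"))
  }
  as.character(edges)
}
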