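#' Derive a child RNG seed from a root seed and a stream label
#'
#' All stochastic functions in the package draw their randomness from
#' streams derived by mixing a root seed with a label (branch id, run
#' index, stage name).  Adding a new consumer of randomness therefore
#' does not perturb the draws of existing ones.
#'
#' @param seed integer root seed.
#' @param ... labels (coerced to character) identifying the stream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  h <- as.double(seed) %% 2147483647
  for (tok in list(...)) {
    for (b in utf8ToInt(paste(as.character(tok), collapse = ","))) {
      # 69069: classic LCG multiplier; exact in double up to 2^53
      h <- (h * 69069 + b + 1) %% 2147483647
    }
  }
  as.integer(h)
}

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' used to score inferred ancestral linkage groups against the true
#' ancestral chromosome of each orthogroup.
#'
#' @param a,b label vectors of equal length (names ignored; compared
#'   positionally).
#' @return numeric in `[-1, 1]`; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# let data.table find its own [ methods from package code
.datatable.aware <- TRUE

# stop() with sprintf-style formatting, no call in the condition
kg_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# deterministic TSV writer shared by all pipeline outputs
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
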