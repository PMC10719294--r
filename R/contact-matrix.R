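#' Binned Hi-C contact matrix for one chromosome
#'
#' @param values symmetric, non-negative numeric matrix (n x n bins).
#' @param chrom chromosome name.
#' @param bin_size bin size in bp.
#' @param balanced whether the matrix has been balanced upstream
#'   (recorded, not acted on).
#' @return an object of class `contact_matrix`.
#' @export
contact_matrix <- function(values, chrom = "chr", bin_size = 1e5,
                           balanced = FALSE) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) kg_stop("contact matrix must be square")
  if (any(values < 0)) kg_stop("negative contact values")
  if (any(abs(values - t(values)) > 1e-8 * (1 + max(values))))
    kg_stop("contact matrix must be symmetric")
  dimnames(values) <- NULL
  structure(list(chrom = as.character(chrom), bin_size = bin_size,
                 values = values, balanced = isTRUE(balanced)),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s: %d bins of %g bp%s\n", x$chrom,
              nrow(x$values), x$bin_size,
              if (x$balanced) " (balanced)" else ""))
  invisible(x)
}

#' Read a contact matrix from COO or dense text
#'
#' COO rows are `bin_i bin_j value` with 0-based bin indices; the upper
#' triangle suffices and is mirrored.  If both `(i, j)` and `(j, i)` are
#' present they must agree.  Dense input is a whitespace-separated
#' square matrix.
#'
#' @param path input file.
#' @param format `"coo"` or `"dense"`.
#' @param n_bins number of bins (COO only; default: largest index + 1).
#' @param chrom,bin_size,balanced metadata stored on the result.
#' @return a [contact_matrix()].
#' @export
read_contact_matrix <- function(path, format = c("coo", "dense"),
                                n_bins = NULL, chrom = "chr",
                                bin_size = 1e5, balanced = FALSE) {
  format <- match.arg(format)
  if (format == "dense") {
    m <- as.matrix(utils::read.table(path, header = FALSE))
    if (nrow(m) != ncol(m)) kg_stop("dense contact matrix is not square")
    return(contact_matrix(m, chrom, bin_size, balanced))
  }
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("i", "j", "value"))
  if (any(df$value < 0)) kg_stop("negative contact values in %s", path)
  n <- if (is.null(n_bins)) max(df$i, df$j) + 1L else as.integer(n_bins)
  if (any(df$i >= n | df$j >= n | df$i < 0 | df$j < 0))
    kg_stop("bin index outside [0, %d)", n)
  m <- matrix(0, n, n)
  lo <- pmin(df$i, df$j) + 1L
  hi <- pmax(df$i, df$j) + 1L
  key <- paste(lo, hi)
  for (k in which(duplicated(key))) {
    prev <- match(key[k], key)
    if (df$value[prev] != df$value[k])
      kg_stop("conflicting entries for bins (%d, %d)", lo[k] - 1L,
              hi[k] - 1L)
  }
  keep <- !duplicated(key)
  m[cbind(lo[keep], hi[keep])] <- df$value[keep]
  m[cbind(hi[keep], lo[keep])] <- df$value[keep]
  contact_matrix(m, chrom, bin_size, balanced)
}

#' Write a contact matrix as upper-triangle COO text
#'
#' Emits non-zero entries of the upper triangle (including the diagonal)
#' in row-major order, so output is deterministic and
#' `read_contact_matrix()` restores the matrix exactly.
#'
#' @param matrix a [contact_matrix()].
#' @param path output file.
#' @export
write_contact_matrix <- function(matrix, path) {
  m <- matrix$values
  idx <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  writeLines(sprintf("%d\t%d\t%.10g", idx[, 1] - 1L, idx[, 2] - 1L,
                     m[idx]), path)
  invisible(path)
}
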