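#' Reciprocal best hits between two gene sets
#'
#' A pair `(a, b)` is retained iff `b` is `a`'s unique best-scoring hit
#' in the A->B table and `a` is `b`'s unique best hit in the B->A table.
#' Ties for a gene's best hit leave that gene unpaired (conservative).
#'
#' @param hits_ab data.frame with columns `query`, `subject`, `bitscore`
#'   (larger is better) and optionally `evalue`; hits of A genes against
#'   B genes.
#' @param hits_ba the reciprocal table (B genes against A genes).
#' @param evalue_cutoff optional e-value filter applied to both tables
#'   before best-hit selection.
#' @return data.frame of class `mutual_best_hits` with columns `gene_a`,
#'   `gene_b`, `score_ab`, `score_ba`.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, evalue_cutoff = NULL) {
  clean <- function(h) {
    h <- as.data.frame(h)
    stopifnot(all(c("query", "subject", "bitscore") %in% names(h)))
    if (!is.null(evalue_cutoff) && !is.null(h$evalue))
      h <- h[h$evalue <= evalue_cutoff, , drop = FALSE]
    h
  }
  best <- function(h) {
    if (!nrow(h))
      return(data.frame(query = character(0), subject = character(0),
                        bitscore = numeric(0)))
    sp <- split(seq_len(nrow(h)), h$query)
    rows <- vapply(sp, function(i) {
      top <- i[h$bitscore[i] == max(h$bitscore[i])]
      if (length(unique(h$subject[top])) == 1L) top[1] else NA_integer_
    }, 0L)
    h[rows[!is.na(rows)], , drop = FALSE]
  }
  ab <- best(clean(hits_ab))
  ba <- best(clean(hits_ba))
  m <- merge(ab, ba, by.x = c("query", "subject"),
             by.y = c("subject", "query"),
             suffixes = c("_ab", "_ba"))
  out <- data.frame(gene_a = m$query, gene_b = m$subject,
                    score_ab = m$bitscore_ab, score_ba = m$bitscore_ba,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mutual_best_hits", "data.frame")
  out
}

#' Read a plain BLAST tabular (outfmt 6) hit table
#'
#' Only the columns needed for reciprocal-best-hit calling are kept.
#'
#' @param path BLAST `-outfmt 6` file (12 standard columns).
#' @return data.frame with columns `query`, `subject`, `pident`,
#'   `evalue`, `bitscore`.
#' @export
read_blast_hits <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = c("character", "character",
                                         rep("numeric", 10)))
  data.frame(query = df[[1]], subject = df[[2]], pident = df[[3]],
             evalue = df[[11]], bitscore = df[[12]],
             stringsAsFactors = FALSE)
}
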