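#' Read BLAST tabular alignments with aligned sequences
#'
#' Consumes BLAST `-outfmt "6 std qseq sseq"`: the 12 standard columns
#' followed by the gapped aligned query and subject strings.  Coordinates
#' are converted to 0-based half-open on the forward strand; a subject
#' hit with `sstart > send` is recorded with `s_strand == "-"` and
#' forward-strand subject coordinates.
#'
#' @param path BLAST tabular file.
#' @return data.frame of class `hsp_table` with columns `query_id`,
#'   `subject_id`, `q_start`, `q_end`, `s_start`, `s_end`, `s_strand`,
#'   `pident`, `evalue`, `bitscore`, `aligned_query`, `aligned_subject`.
#' @export
read_hsp_table <- function(path) {
  cols <- c("query_id", "subject_id", "pident", "length", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send", "evalue",
            "bitscore", "aligned_query", "aligned_subject")
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = cols, colClasses = c(
                            "character", "character", rep("numeric", 10),
                            "character", "character"))
  hsp_table(df$query_id, df$subject_id,
            q_start = df$qstart - 1, q_end = df$qend,
            s_start = ifelse(df$sstart <= df$send, df$sstart - 1,
                             df$send - 1),
            s_end = pmax(df$sstart, df$send),
            s_strand = ifelse(df$sstart <= df$send, "+", "-"),
            pident = df$pident, evalue = df$evalue,
            bitscore = df$bitscore,
            aligned_query = df$aligned_query,
            aligned_subject = df$aligned_subject)
}

#' Construct an HSP table from vectors
#'
#' Validates that aligned strings have equal length and that their
#' ungapped character counts match the stated intervals.
#'
#' @param query_id,subject_id sequence (chromosome) names.
#' @param q_start,q_end,s_start,s_end 0-based half-open coordinates.
#' @param s_strand `"+"` or `"-"` per HSP.
#' @param pident,evalue,bitscore optional BLAST statistics.
#' @param aligned_query,aligned_subject gapped alignment strings.
#' @return data.frame of class `hsp_table`.
#' @export
hsp_table <- function(query_id, subject_id, q_start, q_end, s_start,
                      s_end, s_strand = "+", pident = NA_real_,
                      evalue = NA_real_, bitscore = NA_real_,
                      aligned_query, aligned_subject) {
  df <- data.frame(query_id = as.character(query_id),
                   subject_id = as.character(subject_id),
                   q_start = as.numeric(q_start), q_end = as.numeric(q_end),
                   s_start = as.numeric(s_start), s_end = as.numeric(s_end),
                   s_strand = as.character(s_strand),
                   pident = as.numeric(pident),
                   evalue = as.numeric(evalue),
                   bitscore = as.numeric(bitscore),
                   aligned_query = as.character(aligned_query),
                   aligned_subject = as.character(aligned_subject),
                   stringsAsFactors = FALSE)
  if (any(nchar(df$aligned_query) != nchar(df$aligned_subject)))
    kg_stop("aligned strings differ in length (HSP %d)",
            which(nchar(df$aligned_query) != nchar(df$aligned_subject))[1])
  qlen <- nchar(gsub("-", "", df$aligned_query, fixed = TRUE))
  slen <- nchar(gsub("-", "", df$aligned_subject, fixed = TRUE))
  if (any(qlen != df$q_end - df$q_start))
    kg_stop("ungapped query length does not match interval (HSP %d)",
            which(qlen != df$q_end - df$q_start)[1])
  if (any(slen != df$s_end - df$s_start))
    kg_stop("ungapped subject length does not match interval (HSP %d)",
            which(slen != df$s_end - df$s_start)[1])
  class(df) <- c("hsp_table", "data.frame")
  df
}

#' Write an HSP table as BLAST tabular text
#'
#' @param hsps an [hsp_table()].
#' @param path output file.
#' @export
write_hsp_table <- function(hsps, path) {
  qlen <- nchar(hsps$aligned_query)
  mism <- mapply(function(a, b) {
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    sum(av != bv | av == "-" | bv == "-")
  }, hsps$aligned_query, hsps$aligned_subject, USE.NAMES = FALSE)
  sstart <- ifelse(hsps$s_strand == "+", hsps$s_start + 1, hsps$s_end)
  send <- ifelse(hsps$s_strand == "+", hsps$s_end, hsps$s_start + 1)
  lines <- sprintf("%s\t%s\t%.3f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%g\t%g\t%s\t%s",
                   hsps$query_id, hsps$subject_id,
                   ifelse(is.na(hsps$pident), 0, hsps$pident),
                   qlen, as.integer(mism), 0L,
                   as.integer(hsps$q_start) + 1L, as.integer(hsps$q_end),
                   as.integer(sstart), as.integer(send),
                   ifelse(is.na(hsps$evalue), 0, hsps$evalue),
                   ifelse(is.na(hsps$bitscore), 0, hsps$bitscore),
                   hsps$aligned_query, hsps$aligned_subject)
  writeLines(lines, path)
  invisible(path)
}
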