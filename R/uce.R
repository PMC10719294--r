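#' Scan alignment HSPs for ultraconserved elements
#'
#' Slides a seed window of `window` alignment columns along each HSP;
#' every window at or above `min_identity` is extended rightward column
#' by column while the cumulative identity of the growing interval
#' stays at or above the threshold.  Gap columns count as mismatches.
#' Surviving intervals are trimmed to start and end on matching columns,
#' overlapping survivors are merged (a merge that would drop the union
#' below the threshold keeps the longer interval instead), and
#' alignment-column spans are mapped back to both genomes' coordinates,
#' skipping gaps.
#'
#' @param hsps an [hsp_table()] (one or more rows).
#' @param min_identity minimum identity fraction (0 < x <= 1).
#' @param window seed window length in alignment columns.
#' @return data.frame of class `conserved_elements`, one row per
#'   element: `element_id`, `query_id`, `q_start`, `q_end`,
#'   `subject_id`, `s_start`, `s_end`, `col_start`, `col_end` (0-based
#'   half-open alignment columns), `length`, `identity`, `hsp`.
#' @export
window_scan <- function(hsps, min_identity = 0.95, window = 20L) {
  if (min_identity <= 0 || min_identity > 1)
    kg_stop("min_identity must be in (0, 1]")
  rows <- lapply(seq_len(nrow(hsps)), function(h)
    scan_one_hsp(hsps[h, ], h, min_identity, window))
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(query_id = character(0), q_start = numeric(0),
                      q_end = numeric(0), subject_id = character(0),
                      s_start = numeric(0), s_end = numeric(0),
                      col_start = integer(0), col_end = integer(0),
                      length = integer(0), identity = numeric(0),
                      hsp = integer(0))
  out <- out[order(out$query_id, out$q_start, out$subject_id, out$s_start), ]
  rownames(out) <- NULL
  out <- cbind(element_id = sprintf("uce%04d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  class(out) <- c("conserved_elements", "data.frame")
  out
}

scan_one_hsp <- function(hsp, h, min_identity, window) {
  qa <- strsplit(hsp$aligned_query, "")[[1]]
  sa <- strsplit(hsp$aligned_subject, "")[[1]]
  n <- length(qa)
  if (n < window) return(NULL)
  m <- toupper(qa) == toupper(sa) & qa != "-" & sa != "-"
  cm <- c(0, cumsum(m))
  ident <- function(i, j) (cm[j + 1] - cm[i]) / (j - i + 1)
  eps <- 1e-9
  # seed positions: windows passing the threshold
  ws <- cm[(window + 1):(n + 1)] - cm[seq_len(n - window + 1)]
  seeds <- which(ws / window >= min_identity - eps)
  if (!length(seeds)) return(NULL)
  iv <- matrix(0L, 0, 2)
  for (i in seeds) {
    j <- i + window - 1L
    while (j < n && ident(i, j + 1L) >= min_identity - eps) j <- j + 1L
    # trim to matching end columns
    lo <- i; hi <- j
    while (lo <= hi && !m[lo]) lo <- lo + 1L
    while (hi >= lo && !m[hi]) hi <- hi - 1L
    if (hi - lo + 1L >= window && ident(lo, hi) >= min_identity - eps)
      iv <- rbind(iv, c(lo, hi))
  }
  if (!nrow(iv)) return(NULL)
  iv <- unique(iv)
  iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
  merged <- iv[1, ]
  keep <- matrix(0L, 0, 2)
  for (r in seq_len(nrow(iv))[-1]) {
    if (iv[r, 1] <= merged[2] + 0L) {   # overlap
      cand <- c(merged[1], max(merged[2], iv[r, 2]))
      if (ident(cand[1], cand[2]) >= min_identity - eps) {
        merged <- cand
      } else if (diff(iv[r, ]) > diff(merged)) {
        merged <- iv[r, ]
      }
    } else {
      keep <- rbind(keep, merged)
      merged <- iv[r, ]
    }
  }
  keep <- rbind(keep, merged)
  # map alignment columns to genome coordinates (gaps consume nothing)
  qoff <- c(0, cumsum(qa != "-"))
  soff <- c(0, cumsum(sa != "-"))
  lo <- keep[, 1]; hi <- keep[, 2]
  q_start <- hsp$q_start + qoff[lo]
  q_end <- hsp$q_start + qoff[hi + 1]
  if (identical(hsp$s_strand, "-")) {
    s_start <- hsp$s_end - soff[hi + 1]
    s_end <- hsp$s_end - soff[lo]
  } else {
    s_start <- hsp$s_start + soff[lo]
    s_end <- hsp$s_start + soff[hi + 1]
  }
  data.frame(query_id = hsp$query_id, q_start = q_start, q_end = q_end,
             subject_id = hsp$subject_id, s_start = s_start,
             s_end = s_end, col_start = lo - 1L, col_end = hi,
             length = hi - lo + 1L,
             identity = (cm[hi + 1] - cm[lo]) / (hi - lo + 1),
             hsp = h, stringsAsFactors = FALSE)
}

#' Collapse elements that multi-map in the partner genome
#'
#' Elements whose query loci coincide (reciprocal overlap of at least
#' `min_overlap` of the shorter span, single linkage) are reduced to the
#' single element with the largest summed length in both genomes; ties
#' go to the lowest coordinate.
#'
#' @param elements a [window_scan()] result.
#' @param min_overlap overlap fraction (of the shorter query span)
#'   linking two elements to one locus.
#' @return filtered `conserved_elements` data.frame.
#' @export
resolve_multimapping <- function(elements, min_overlap = 0.5) {
  if (nrow(elements) < 2) return(elements)
  n <- nrow(elements)
  edges <- matrix(0L, 0, 2)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (elements$query_id[i] != elements$query_id[j]) next
    ov <- min(elements$q_end[i], elements$q_end[j]) -
      max(elements$q_start[i], elements$q_start[j])
    shorter <- min(elements$q_end[i] - elements$q_start[i],
                   elements$q_end[j] - elements$q_start[j])
    if (ov >= min_overlap * shorter) edges <- rbind(edges, c(i, j))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  keep <- vapply(split(seq_len(n), comp), function(i) {
    tot <- (elements$q_end[i] - elements$q_start[i]) +
      (elements$s_end[i] - elements$s_start[i])
    i[order(-tot, elements$q_start[i], elements$s_start[i])][1]
  }, 0L)
  out <- elements[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify conserved elements against coding annotation
#'
#' An element whose query span overlaps coding sequence over more than
#' half its length is marked `coding_removed` (and dropped by default);
#' remaining elements are `intronic` when mostly inside an intron and
#' `non_coding` otherwise.
#'
#' @param elements a [window_scan()] result (query genome coordinates).
#' @param cds,introns data.frames of intervals (`chrom`, `start`, `end`)
#'   on the query genome, e.g. from [read_bed_intervals()].
#' @param drop_coding drop `coding_removed` elements from the result.
#' @return `conserved_elements` data.frame with a `class` column.
#' @export
classify_elements <- function(elements, cds, introns,
                              drop_coding = TRUE) {
  cov_frac <- function(ints) {
    if (is.null(ints) || !nrow(ints))
      return(numeric(nrow(elements)))
    vapply(seq_len(nrow(elements)), function(k) {
      same <- ints$chrom == elements$query_id[k]
      if (!any(same)) return(0)
      ir <- IRanges::reduce(IRanges::IRanges(ints$start[same] + 1,
                                             ints$end[same]))
      el <- IRanges::IRanges(elements$q_start[k] + 1, elements$q_end[k])
      ov <- IRanges::intersect(ir, el)
      sum(IRanges::width(ov)) / IRanges::width(el)
    }, 0)
  }
  fc <- cov_frac(cds)
  fi <- cov_frac(introns)
  elements$class <- ifelse(fc > 0.5, "coding_removed",
                           ifelse(fi > 0.5, "intronic", "non_coding"))
  if (drop_coding) {
    n_removed <- sum(elements$class == "coding_removed")
    elements <- elements[elements$class != "coding_removed", ,
                         drop = FALSE]
    rownames(elements) <- NULL
    attr(elements, "n_coding_removed") <- n_removed
  }
  elements
}

#' Cluster recurrent elements by self-alignment coverage
#'
#' Single-linkage clustering over the relation "a self-hit covers at
#' least `coverage` of either element"; clusters of two or more
#' elements are flagged recurrent (unmasked repeat candidates).
#'
#' @param elements a [window_scan()] result with `element_id`.
#' @param self_hits data.frame of element-vs-element alignments with
#'   columns `query`, `subject` and `length` (aligned length in bp).
#' @param coverage coverage fraction required for linkage.
#' @return data.frame `element_id`, `cluster`, `cluster_size`,
#'   `recurrent`.
#' @export
cluster_recurrent <- function(elements, self_hits, coverage = 0.9) {
  ids <- elements$element_id
  len <- stats::setNames(elements$q_end - elements$q_start, ids)
  g <- igraph::make_empty_graph(length(ids), directed = FALSE)
  igraph::V(g)$name <- ids
  if (!is.null(self_hits) && nrow(self_hits)) {
    sh <- self_hits[self_hits$query %in% ids & self_hits$subject %in% ids &
                      self_hits$query != self_hits$subject, , drop = FALSE]
    link <- sh$length >= coverage * pmin(len[sh$query], len[sh$subject])
    if (any(link))
      g <- igraph::add_edges(g, rbind(sh$query[link], sh$subject[link]))
  }
  comp <- igraph::components(g)$membership
  size <- table(comp)
  data.frame(element_id = ids, cluster = unname(comp[ids]),
             cluster_size = as.integer(size[as.character(comp[ids])]),
             recurrent = as.integer(size[as.character(comp[ids])]) >= 2,
             stringsAsFactors = FALSE)
}
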