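#' Generate a synthetic Hi-C contact matrix
#'
#' Expected contact between bins at distance `s` is
#' `c0 * (1 + s)^(-decay_exponent)`; in `"tads"` mode the expectation is
#' further multiplied by `tad_enrichment` whenever both bins fall in the
#' same block between consecutive boundaries.  Multiplicative log-normal
#' noise with log-sd `noise_sd` is applied (mean-corrected, so the
#' expectation is preserved) and the matrix is symmetrized.
#'
#' @param n_bins number of bins (>= 10).
#' @param mode `"decay_only"` (smooth distance decay, the null model) or
#'   `"tads"` (block-enriched alternative).
#' @param decay_exponent power-law decay exponent (> 0).
#' @param tad_boundaries bin indices (0-based) separating blocks.
#' @param tad_enrichment within-block contact multiplier (> 1).
#' @param noise_sd log-normal noise sd (0 = deterministic).
#' @param seed RNG seed.
#' @param c0 contact at distance 0 before enrichment.
#' @param chrom,bin_size metadata for the result.
#' @return a [contact_matrix()].
#' @export
generate_contact_map <- function(n_bins, mode = c("decay_only", "tads"),
                                 decay_exponent = 1,
                                 tad_boundaries = integer(),
                                 tad_enrichment = 3, noise_sd = 0,
                                 seed = 1L, c0 = 100, chrom = "chrS",
                                 bin_size = 1e5) {
  mode <- match.arg(mode)
  if (n_bins < 10) kg_stop("n_bins must be >= 10")
  if (mode == "tads") {
    if (tad_enrichment <= 1) kg_stop("tad_enrichment must be > 1")
    if (any(tad_boundaries < 0 | tad_boundaries >= n_bins))
      kg_stop("tad boundaries outside [0, %d)", n_bins)
  }
  s <- abs(outer(seq_len(n_bins), seq_len(n_bins), "-"))
  expected <- c0 * (1 + s)^(-decay_exponent)
  if (mode == "tads") {
    block <- findInterval(seq_len(n_bins) - 1L, sort(tad_boundaries))
    same <- outer(block, block, "==")
    expected[same] <- expected[same] * tad_enrichment
  }
  m <- expected
  if (noise_sd > 0) {
    noise <- with_seed(derive_seed(seed, "hic"), {
      up <- matrix(0, n_bins, n_bins)
      iu <- upper.tri(up, diag = TRUE)
      up[iu] <- stats::rlnorm(sum(iu), meanlog = -noise_sd^2 / 2,
                              sdlog = noise_sd)
      up[lower.tri(up)] <- t(up)[lower.tri(up)]
      up
    })
    m <- expected * noise
  }
  contact_matrix(m, chrom = chrom, bin_size = bin_size)
}

#' Generate alignment HSPs with planted fully conserved elements
#'
#' Each HSP is a gap-free pair of random nucleotide strings whose
#' columns match with probability `background_identity`, except for
#' `n_elements` planted segments of `element_len` columns with 100%
#' identity at recorded positions.  A short guard band of forced
#' mismatches (`guard` columns) flanks each planted segment so that the
#' planted span coincides with the maximal high-identity interval and
#' the truth coordinates are unambiguous.  At most one element is
#' planted per HSP.
#'
#' @param n_hsps number of HSPs.
#' @param hsp_len alignment length in columns.
#' @param n_elements number of planted elements (<= `n_hsps`).
#' @param element_len planted element length (<= `hsp_len`).
#' @param background_identity per-column match probability outside
#'   planted segments; must be < 0.95.
#' @param seed RNG seed.
#' @param guard forced-mismatch columns flanking each element.
#' @return list with `hsps` (an [hsp_table()], query/subject ids
#'   `q1..`/`s1..`) and `truth` (data.frame of planted coordinates:
#'   `hsp`, `col_start`, `col_end` 0-based half-open alignment columns).
#' @export
plant_conserved_alignments <- function(n_hsps, hsp_len, n_elements,
                                       element_len, background_identity,
                                       seed = 1L, guard = 3L) {
  if (element_len > hsp_len) kg_stop("element_len > hsp_len")
  if (n_elements > n_hsps)
    kg_stop("at most one element per HSP: n_elements <= n_hsps required")
  if (background_identity < 0 || background_identity >= 0.95)
    kg_stop("background_identity must be in [0, 0.95)")
  bases <- c("A", "C", "G", "T")
  with_seed(derive_seed(seed, "uce"), {
    which_hsp <- sample.int(n_hsps, n_elements)
    q <- s <- character(n_hsps)
    truth <- list()
    for (h in seq_len(n_hsps)) {
      qv <- sample(bases, hsp_len, replace = TRUE)
      match <- stats::runif(hsp_len) < background_identity
      sv <- qv
      # draw a mismatching base by shifting 1-3 places in the alphabet
      mm <- !match
      sv[mm] <- bases[(match(qv[mm], bases) - 1L +
                       sample.int(3, sum(mm), replace = TRUE)) %% 4L + 1L]
      if (h %in% which_hsp) {
        lo <- sample.int(hsp_len - element_len - 2L * guard + 1L, 1) + guard
        idx <- lo:(lo + element_len - 1L)
        sv[idx] <- qv[idx]
        for (gi in c((lo - guard):(lo - 1L),
                     (lo + element_len):(lo + element_len + guard - 1L))) {
          sv[gi] <- bases[match(qv[gi], bases) %% 4L + 1L]
        }
        truth[[length(truth) + 1L]] <-
          data.frame(hsp = h, col_start = lo - 1L,
                     col_end = lo + element_len - 1L)
      }
      q[h] <- paste(qv, collapse = "")
      s[h] <- paste(sv, collapse = "")
    }
    truth <- if (length(truth)) do.call(rbind, truth)
             else data.frame(hsp = integer(0), col_start = integer(0),
                             col_end = integer(0))
    hsps <- hsp_table(query_id = sprintf("q%d", seq_len(n_hsps)),
                      subject_id = sprintf("s%d", seq_len(n_hsps)),
                      q_start = 0, q_end = hsp_len,
                      s_start = 0, s_end = hsp_len, s_strand = "+",
                      aligned_query = q, aligned_subject = s)
    list(hsps = hsps, truth = truth[order(truth$hsp), , drop = FALSE])
  })
}

#' Generate an ATAC peak set with a controlled distance law
#'
#' Places each peak at a signed exponential offset from a uniformly
#' chosen gene boundary (start or end), so the true nearest-gene
#' distance follows approximately Exp(`mean_distance`).  Peaks that
#' would overlap a gene or fall outside the chromosome are resampled;
#' all returned peaks are disjoint from all genes.
#'
#' @param annotation a [genome_annotation()] with intergenic space.
#' @param n_peaks number of peaks.
#' @param distance_law only `"exponential"` is implemented.
#' @param mean_distance mean peak-edge-to-gene-edge distance in bp.
#' @param seed RNG seed.
#' @param peak_width peak width in bp.
#' @return object of class `atac_peaks`: data.frame `chrom`, `start`,
#'   `end`, `name`, `true_distance`, with attribute `species_id`.
#' @export
generate_atac_dataset <- function(annotation, n_peaks,
                                  distance_law = "exponential",
                                  mean_distance, seed = 1L,
                                  peak_width = 200L) {
  distance_law <- match.arg(distance_law)
  g <- annotation$genes
  if (!nrow(g)) kg_stop("annotation has no genes")
  if (genome_size(annotation) <= sum(g$end - g$start) + peak_width)
    kg_stop("annotation has no intergenic space")
  chrom_len <- stats::setNames(annotation$chromosomes$length,
                               annotation$chromosomes$chrom)
  out <- with_seed(derive_seed(seed, "atac"), {
    rows <- vector("list", n_peaks)
    for (p in seq_len(n_peaks)) {
      for (try in seq_len(1000L)) {
        k <- sample.int(nrow(g), 1)
        d <- max(1, round(stats::rexp(1, 1 / mean_distance)))
        right <- stats::runif(1) < 0.5
        if (right) {
          start <- g$end[k] + d
        } else {
          start <- g$start[k] - d - peak_width
        }
        end <- start + peak_width
        if (start < 0 || end > chrom_len[[g$chrom[k]]]) next
        same <- g$chrom == g$chrom[k]
        if (any(g$start[same] < end & g$end[same] > start)) next
        # keep a 1 bp gap so distances stay >= 1
        if (any(g$end[same] == start | g$start[same] == end)) next
        rows[[p]] <- data.frame(chrom = g$chrom[k], start = start,
                                end = end,
                                name = sprintf("peak%05d", p),
                                true_distance = d,
                                stringsAsFactors = FALSE)
        break
      }
      if (is.null(rows[[p]]))
        kg_stop("could not place peak %d: no intergenic space", p)
    }
    if (n_peaks == 0)
      data.frame(chrom = character(0), start = numeric(0),
                 end = numeric(0), name = character(0),
                 true_distance = numeric(0))
    else do.call(rbind, rows)
  })
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "species_id") <- annotation$species_id
  class(out) <- c("atac_peaks", "data.frame")
  out
}
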