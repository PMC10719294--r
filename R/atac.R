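#' Peak-to-nearest-gene distances for one species
#'
#' Peaks overlapping any repeat interval are removed, then peaks
#' overlapping (or directly abutting) any gene are removed, and the
#' remaining peaks are assigned the gap in bp between their closest edge
#' and the nearest gene edge (transcript start or end) on the same
#' chromosome.  Peaks on gene-free chromosomes are dropped.
#'
#' @param peaks data.frame (`chrom`, `start`, `end`) or `atac_peaks`.
#' @param annotation a [genome_annotation()] on the same assembly.
#' @param repeats optional repeat intervals (`chrom`, `start`, `end`).
#' @return object of class `distance_summary`: list with `distances`,
#'   `n`, `median`, `mean`, `sem`, `genome_size`, `species_id` and
#'   bookkeeping counts of removed peaks.
#' @export
peak_gene_distances <- function(peaks, annotation, repeats = NULL) {
  g <- annotation$genes
  known <- annotation$chromosomes$chrom
  bad <- setdiff(unique(peaks$chrom), known)
  if (length(bad))
    kg_stop("peak chromosomes absent from annotation: %s",
            paste(bad, collapse = ", "))
  if (!is.null(repeats)) {
    badr <- setdiff(unique(repeats$chrom), known)
    if (length(badr))
      kg_stop("repeat chromosomes absent from annotation: %s",
              paste(badr, collapse = ", "))
  }
  pk <- IRanges::IRanges(peaks$start + 1, peaks$end)
  n0 <- length(pk)
  in_repeat <- rep(FALSE, n0)
  if (!is.null(repeats) && nrow(repeats)) {
    for (ch in unique(repeats$chrom)) {
      same <- peaks$chrom == ch
      rr <- repeats[repeats$chrom == ch, ]
      hit <- IRanges::overlapsAny(pk[same],
                                  IRanges::IRanges(rr$start + 1, rr$end))
      in_repeat[same][hit] <- TRUE
    }
  }
  dist <- rep(NA_real_, n0)
  on_gene <- rep(FALSE, n0)
  for (ch in unique(peaks$chrom)) {
    same <- which(peaks$chrom == ch)
    gg <- g[g$chrom == ch, ]
    if (!nrow(gg)) next   # gene-free chromosome: stays NA, dropped
    gr <- IRanges::IRanges(gg$start + 1, gg$end)
    hits <- IRanges::distanceToNearest(pk[same], gr)
    d <- rep(NA_real_, length(same))
    d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
    on_gene[same][!is.na(d) & d == 0] <- TRUE
    dist[same] <- d
  }
  keep <- !in_repeat & !on_gene & !is.na(dist)
  distances <- dist[keep]
  structure(list(distances = distances, n = length(distances),
                 median = stats::median(distances),
                 mean = mean(distances),
                 sem = stats::sd(distances) / sqrt(length(distances)),
                 genome_size = genome_size(annotation),
                 species_id = annotation$species_id,
                 n_peaks = n0, n_repeat_removed = sum(in_repeat),
                 n_gene_overlap = sum(!in_repeat & on_gene)),
            class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, ...) {
  cat(sprintf(
    "<distance_summary> %s: n = %d, median = %g bp, mean = %.1f bp, SEM = %.2f\n",
    x$species_id, x$n, x$median, x$mean, x$sem))
  invisible(x)
}

#' Remove 1.5 x IQR outliers
#'
#' Keeps values within `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, with quartiles by
#' linear interpolation (quantile type 7).
#'
#' @param values numeric vector; fewer than 4 values pass through with a
#'   warning.
#' @return filtered numeric vector.
#' @export
iqr_filter <- function(values) {
  if (length(values) < 4) {
    warning("fewer than 4 values: returning input unchanged")
    return(values)
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  values[values >= q[1] - 1.5 * iqr & values <= q[2] + 1.5 * iqr]
}

#' Regress mean peak-to-gene distance on genome size
#'
#' Per-species distances are outlier-filtered with [iqr_filter()], their
#' means are regressed on genome size by ordinary least squares, and the
#' pointwise 95% confidence band of the fitted line is reported
#' alongside the Pearson correlation.
#'
#' @param summaries list of [peak_gene_distances()] results (>= 3
#'   species).
#' @param apply_iqr apply the outlier filter before taking means.
#' @return object of class `size_regression`: list with `slope`,
#'   `intercept`, `r`, `data` (per-species size / mean / n), `band`
#'   (fit and 95% CI at each species), `model` (the `lm` fit).
#' @export
size_regression <- function(summaries, apply_iqr = TRUE) {
  if (length(summaries) < 3) kg_stop("need >= 3 species for regression")
  df <- do.call(rbind, lapply(summaries, function(s) {
    d <- if (apply_iqr) iqr_filter(s$distances) else s$distances
    data.frame(species = s$species_id, genome_size = s$genome_size,
               mean_distance = mean(d), n = length(d),
               stringsAsFactors = FALSE)
  }))
  fit <- stats::lm(mean_distance ~ genome_size, data = df)
  band <- as.data.frame(stats::predict(fit, interval = "confidence",
                                       level = 0.95))
  r <- if (stats::sd(df$mean_distance) == 0 ||
           stats::sd(df$genome_size) == 0) 0
       else stats::cor(df$genome_size, df$mean_distance)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = r, data = df,
                 band = cbind(df["species"], band),
                 model = fit),
            class = "size_regression")
}

#' @export
print.size_regression <- function(x, ...) {
  cat(sprintf(
    "<size_regression> slope = %.4g bp/bp, intercept = %.4g bp, r = %.3f (%d species)\n",
    x$slope, x$intercept, x$r, nrow(x$data)))
  invisible(x)
}

#' 95% confidence interval of the regression slope
#'
#' @param regression a [size_regression()] result.
#' @return numeric length-2 vector (lower, upper).
#' @export
slope_confint <- function(regression) {
  ci <- stats::confint(regression$model, "genome_size", level = 0.95)
  c(lower = ci[1], upper = ci[2])
}
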