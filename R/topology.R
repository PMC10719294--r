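#' Insulation track of a contact matrix
#'
#' Crane-style insulation: `raw(i)` is the mean contact in the
#' `window_bins x window_bins` square spanning bins `i-w .. i-1` against
#' `i+1 .. i+w` (the diagonal bin itself is excluded); the score is
#' `log2(raw / mean(raw))` with the mean taken over defined bins, so the
#' track is invariant to global matrix scaling and mean-centred in
#' ratio space.  Bins closer than `window_bins` to either chromosome
#' end, and bins whose square contains only zeros, are undefined (`NA`).
#'
#' @param matrix a [contact_matrix()].
#' @param window_bins half-window in bins (default 10, i.e. 1 Mb at
#'   100 kb bins).
#' @return object of class `insulation_track`: data.frame `bin`
#'   (0-based), `raw`, `score`, with attributes `chrom`, `bin_size`,
#'   `window_bins`.
#' @export
insulation_track <- function(matrix, window_bins = 10L) {
  m <- matrix$values
  n <- nrow(m)
  w <- as.integer(window_bins)
  if (w < 1) kg_stop("window_bins must be >= 1")
  if (n <= 2 * w) kg_stop("matrix too small for window_bins = %d", w)
  raw <- rep(NA_real_, n)
  for (i in (w + 1):(n - w)) {
    sq <- m[(i - w):(i - 1), (i + 1):(i + w), drop = FALSE]
    raw[i] <- if (all(sq == 0)) NA_real_ else mean(sq)
  }
  mu <- mean(raw, na.rm = TRUE)
  score <- log2(raw / mu)
  out <- data.frame(bin = seq_len(n) - 1L, raw = raw, score = score)
  attr(out, "chrom") <- matrix$chrom
  attr(out, "bin_size") <- matrix$bin_size
  attr(out, "window_bins") <- w
  class(out) <- c("insulation_track", "data.frame")
  out
}

#' Call peaks and valleys of an insulation track
#'
#' Local extrema over the defined bins (undefined bins are skipped, and
#' the first and last defined bins are never extrema).  Plateaus
#' collapse to their centre bin.  Extrema with topographic prominence
#' below `min_prominence` are discarded.
#'
#' @param track an [insulation_track()] (or numeric vector of scores).
#' @param min_prominence minimum prominence in score (log2) units.
#' @return list with `peaks` and `valleys`: data.frames `bin`, `value`,
#'   `prominence`.
#' @export
call_extrema <- function(track, min_prominence = 0.1) {
  if (inherits(track, "insulation_track")) {
    bins <- track$bin; v <- track$score
  } else {
    bins <- seq_along(track) - 1L; v <- as.numeric(track)
  }
  def <- !is.na(v)
  bins <- bins[def]; v <- v[def]
  n <- length(v)
  if (n < 3) return(list(peaks = empty_extrema(), valleys = empty_extrema()))
  find <- function(x) {
    # runs of equal value; a run is a peak of x if both neighbours lower
    r <- rle(x)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    out <- integer(0)
    for (k in seq_along(r$values)) {
      if (k == 1L || k == length(r$values)) next
      if (r$values[k] > r$values[k - 1] && r$values[k] > r$values[k + 1])
        out <- c(out, (starts[k] + ends[k]) %/% 2L)
    }
    out
  }
  prominence <- function(x, i) {
    # min of the drops to the highest saddle on each side, bounded by
    # the track ends
    side <- function(idx_seq) {
      lo <- x[i]
      for (j in idx_seq) {
        if (x[j] > x[i]) break
        lo <- min(lo, x[j])
      }
      x[i] - lo
    }
    l <- side(rev(seq_len(i - 1L)))
    r <- side(seq(i + 1L, n))
    min(l, r)
  }
  pk <- find(v)
  vl <- find(-v)
  mk <- function(idx, sign) {
    if (!length(idx)) return(empty_extrema())
    prom <- vapply(idx, function(i) prominence(sign * v, i), 0)
    df <- data.frame(bin = bins[idx], value = v[idx], prominence = prom)
    df[df$prominence >= min_prominence, , drop = FALSE]
  }
  list(peaks = mk(pk, 1), valleys = mk(vl, -1))
}

empty_extrema <- function() {
  data.frame(bin = integer(0), value = numeric(0), prominence = numeric(0))
}

#' Boundary strength deltas from insulation extrema
#'
#' For each insulation valley (candidate topological boundary), the
#' delta is the drop from the flanking peaks: the nearest peak on each
#' side contributes `peak value - valley value`, and the per-valley
#' delta aggregates the existing flanks by `method` (mean by default;
#' min available).  Valleys with no flanking peak on either side are
#' dropped.
#'
#' @param extrema a [call_extrema()] result.
#' @param method `"mean"` or `"min"` over the flanking drops.
#' @return data.frame of class `boundary_deltas`: `valley_bin`,
#'   `valley_value`, `delta`.
#' @export
boundary_deltas <- function(extrema, method = c("mean", "min")) {
  method <- match.arg(method)
  pk <- extrema$peaks; vl <- extrema$valleys
  rows <- lapply(seq_len(nrow(vl)), function(k) {
    b <- vl$bin[k]
    left <- pk$value[pk$bin < b]
    right <- pk$value[pk$bin > b]
    drops <- c(if (length(left)) left[length(left)] - vl$value[k],
               if (length(right)) right[1] - vl$value[k])
    if (!length(drops)) return(NULL)
    data.frame(valley_bin = b, valley_value = vl$value[k],
               delta = if (method == "mean") mean(drops) else min(drops))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(valley_bin = integer(0), valley_value = numeric(0),
                      delta = numeric(0))
  class(out) <- c("boundary_deltas", "data.frame")
  out
}

#' Two-sided Mann-Whitney U comparison of boundary strengths
#'
#' Reports the U statistic for sample `a` and a two-sided p-value: by
#' full enumeration of all assignments of the pooled values (tie-aware,
#' via midranks) when `choose(n + m, n)` is small, otherwise by normal
#' approximation with tie and continuity corrections.
#'
#' @param a,b numeric vectors or [boundary_deltas()] results.
#' @param enum_limit largest number of enumerated combinations for the
#'   exact branch.
#' @return list with `U`, `p.value`, `method`.
#' @export
compare_boundary_strength <- function(a, b, enum_limit = 20000) {
  if (inherits(a, "boundary_deltas")) a <- a$delta
  if (inherits(b, "boundary_deltas")) b <- b$delta
  a <- as.numeric(a); b <- as.numeric(b)
  n <- length(a); m <- length(b)
  if (n == 0 || m == 0) kg_stop("both samples must be non-empty")
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (choose(n + m, n) <= enum_limit) {
    combs <- utils::combn(n + m, n)
    us <- colSums(matrix(r[combs], nrow = n)) - n * (n + 1) / 2
    eps <- 1e-9
    p <- 2 * min(mean(us <= U + eps), mean(us >= U - eps))
    return(list(U = U, p.value = min(1, p), method = "exact enumeration"))
  }
  mu <- n * m / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / ((n + m) * (n + m - 1))
  sigma <- sqrt(n * m / 12 * (n + m + 1 - tie_term))
  if (sigma == 0) return(list(U = U, p.value = 1,
                              method = "normal approximation"))
  z <- (U - mu - sign(U - mu) * 0.5) / sigma
  list(U = U, p.value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal approximation")
}

#' Contact decay profile of a matrix
#'
#' `P(s)` is the mean contact over all bin pairs at distance `s`; the
#' log-log slope over `fit_range` summarizes the decay (about `-1` for
#' a smooth power-law genome without topological domains).  The fit
#' regresses `log10 P` on `log10 (1 + s)` -- the same offset that keeps
#' the law finite at distance 0 -- so on a noise-free
#' `c (1 + s)^(-a)` matrix the slope recovers `-a` exactly.
#'
#' @param matrix a [contact_matrix()].
#' @param fit_range inclusive bin-distance range for the slope fit.
#' @return list with `profile` (data.frame `s`, `mean_contact`) and
#'   `slope`.
#' @export
contact_decay <- function(matrix, fit_range = c(1, 50)) {
  m <- matrix$values
  n <- nrow(m)
  if (n < 2) kg_stop("matrix must have >= 2 bins")
  s <- seq_len(n - 1)
  p <- vapply(s, function(d)
    mean(m[cbind(seq_len(n - d) + d, seq_len(n - d))]), 0)
  prof <- data.frame(s = s, mean_contact = p)
  infit <- prof$s >= fit_range[1] & prof$s <= min(fit_range[2], n - 1) &
    prof$mean_contact > 0
  slope <- if (sum(infit) >= 2 &&
               stats::var(log10(prof$mean_contact[infit])) > 0)
    unname(stats::coef(stats::lm(log10(mean_contact) ~ log10(1 + s),
                                 data = prof[infit, ]))[2])
  else 0
  list(profile = prof, slope = slope)
}
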