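#' Find microsyntenic blocks between two genomes
#'
#' A block is a chain of orthologous gene pairs on one chromosome pair,
#' with strictly increasing gene ordinals in species A, strictly
#' monotone (increasing or decreasing) ordinals in species B, and at
#' most `max_intervening` non-member genes between consecutive members
#' in either species.  A gene whose orthogroup is absent from the
#' partner species still counts as intervening.  Blocks are extracted
#' greedily, longest first (ties to the leftmost ordinal in A, then in
#' B), and every gene instance is used in at most one block, so no
#' reported block can be extended with unused genes.  Strand is ignored.
#'
#' @param ann_a,ann_b [genome_annotation()] of the two species.
#' @param table an [orthogroup_table()] containing both species.
#' @param max_intervening intervening-gene budget (>= 0).
#' @param min_len minimum number of gene pairs per block (>= 2).
#' @return data.frame of class `synteny_blocks`, one row per block:
#'   `block`, `n_genes`, `chrom_a`, `chrom_b`, `a_start`, `a_end`,
#'   `b_start`, `b_end` (ordinal spans, inclusive), `direction`,
#'   `orthogroups`, `genes_a`, `genes_b`.
#' @export
find_blocks <- function(ann_a, ann_b, table, max_intervening,
                        min_len = 2L) {
  if (max_intervening < 0) kg_stop("max_intervening must be >= 0")
  if (min_len < 2) kg_stop("min_len must be >= 2")
  pr <- ortholog_pairs(ann_a, ann_b, table)
  blocks <- extract_chains(pr, max_intervening, min_len)
  blocks_to_df(blocks, pr, ann_a$species_id, ann_b$species_id,
               max_intervening)
}

# all (gene_a, gene_b) pairs whose orthogroup occurs in both species
ortholog_pairs <- function(ann_a, ann_b, table) {
  sa <- ann_a$species_id; sb <- ann_b$species_id
  if (!all(c(sa, sb) %in% table$species))
    kg_stop("orthogroup table lacks species %s / %s", sa, sb)
  ga <- ann_a$genes; gb <- ann_b$genes
  rows <- lapply(names(table$entries), function(og) {
    a <- table$entries[[og]][[sa]]; b <- table$entries[[og]][[sb]]
    if (!length(a) || !length(b)) return(NULL)
    expand.grid(gene_a = a, gene_b = b, orthogroup = og,
                stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      orthogroup = character(0), chrom_a = character(0),
                      ord_a = integer(0), chrom_b = character(0),
                      ord_b = integer(0)))
  ia <- match(df$gene_a, ga$gene_id); ib <- match(df$gene_b, gb$gene_id)
  if (anyNA(ia)) kg_stop("gene %s missing from annotation of %s",
                         df$gene_a[is.na(ia)][1], sa)
  if (anyNA(ib)) kg_stop("gene %s missing from annotation of %s",
                         df$gene_b[is.na(ib)][1], sb)
  df$chrom_a <- ga$chrom[ia]; df$ord_a <- ga$ordinal[ia]
  df$chrom_b <- gb$chrom[ib]; df$ord_b <- gb$ordinal[ib]
  df <- df[order(df$chrom_a, df$ord_a, df$chrom_b, df$ord_b), ]
  rownames(df) <- NULL
  df
}

# indices (into cand) of pairs that may precede pair p in direction dir
chain_preds <- function(pr, cand, p, dir, max_intervening) {
  da <- pr$ord_a[p] - pr$ord_a[cand]
  db <- dir * (pr$ord_b[p] - pr$ord_b[cand])
  cand[pr$chrom_a[cand] == pr$chrom_a[p] &
       pr$chrom_b[cand] == pr$chrom_b[p] &
       da >= 1 & da - 1 <= max_intervening &
       db >= 1 & db - 1 <= max_intervening]
}


# compare two chains (index vectors into pr): TRUE if x is preferred
# over y under (longer first, then lexicographically smaller
# (ord_a, ord_b) sequence, then increasing direction first)
chain_better <- function(pr, x, dirx, y, diry) {
  if (is.null(y)) return(TRUE)
  if (length(x) != length(y)) return(length(x) > length(y))
  kx <- rbind(pr$ord_a[x], pr$ord_b[x])
  ky <- rbind(pr$ord_a[y], pr$ord_b[y])
  d <- which(kx != ky)
  if (length(d)) return(kx[d[1]] < ky[d[1]])
  dirx > diry
}

# greedy longest-first chain extraction
extract_chains <- function(pr, max_intervening, min_len) {
  blocks <- list()
  avail <- rep(TRUE, nrow(pr))
  used_a <- character(0); used_b <- character(0)
  repeat {
    idx <- which(avail)
    if (length(idx) < min_len) break
    best <- best_chain_dp(pr, idx, max_intervening)
    if (is.null(best) || length(best$chain) < min_len) break
    blocks[[length(blocks) + 1L]] <- best
    used_a <- c(used_a, pr$gene_a[best$chain])
    used_b <- c(used_b, pr$gene_b[best$chain])
    avail <- avail & !(pr$gene_a %in% used_a) & !(pr$gene_b %in% used_b)
  }
  blocks
}

best_chain_dp <- function(pr, idx, max_intervening) {
  # pairs in idx are already sorted by (chrom_a, ord_a, chrom_b, ord_b)
  n <- length(idx)
  best <- NULL; best_dir <- NULL
  for (dir in c(1L, -1L)) {
    chains <- vector("list", n)   # best chain ending at idx[k]
    for (k in seq_len(n)) {
      p <- idx[k]
      ch <- p
      preds <- chain_preds(pr, idx[seq_len(k - 1L)], p, dir,
                           max_intervening)
      for (q in preds) {
        cand <- c(chains[[match(q, idx)]], p)
        if (chain_better(pr, cand, dir, ch, dir)) ch <- cand
      }
      chains[[k]] <- ch
      if (chain_better(pr, ch, dir, best, best_dir)) {
        best <- ch; best_dir <- dir
      }
    }
  }
  if (is.null(best)) NULL else list(chain = best, dir = best_dir)
}


blocks_to_df <- function(blocks, pr, species_a, species_b,
                         max_intervening) {
  rows <- lapply(seq_along(blocks), function(i) {
    ch <- blocks[[i]]$chain
    data.frame(block = i, n_genes = length(ch),
               chrom_a = pr$chrom_a[ch[1]], chrom_b = pr$chrom_b[ch[1]],
               a_start = min(pr$ord_a[ch]), a_end = max(pr$ord_a[ch]),
               b_start = min(pr$ord_b[ch]), b_end = max(pr$ord_b[ch]),
               direction = if (blocks[[i]]$dir > 0) "+" else "-",
               orthogroups = paste(pr$orthogroup[ch], collapse = ","),
               genes_a = paste(pr$gene_a[ch], collapse = ","),
               genes_b = paste(pr$gene_b[ch], collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(block = integer(0), n_genes = integer(0),
                         chrom_a = character(0), chrom_b = character(0),
                         a_start = integer(0), a_end = integer(0),
                         b_start = integer(0), b_end = integer(0),
                         direction = character(0),
                         orthogroups = character(0),
                         genes_a = character(0), genes_b = character(0))
  attr(out, "species") <- c(species_a, species_b)
  attr(out, "max_intervening") <- max_intervening
  class(out) <- c("synteny_blocks", "data.frame")
  out
}

#' Remove blocks composed of paralogous genes
#'
#' Drops blocks dominated by a single orthogroup (tandem-array
#' self-synteny): a block is removed when its most frequent orthogroup
#' id occurs at least twice and accounts for at least half of the
#' members.
#'
#' @param blocks a [find_blocks()] result.
#' @return filtered `synteny_blocks` data.frame.
#' @export
filter_paralog_blocks <- function(blocks) {
  if (!nrow(blocks)) return(blocks)
  keep <- vapply(strsplit(blocks$orthogroups, ",", fixed = TRUE),
                 function(ogs) {
    tb <- table(ogs)
    !(max(tb) >= 2 && max(tb) >= 0.5 * length(ogs))
  }, NA)
  out <- blocks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Census of microsyntenic blocks across clades
#'
#' For every within-clade species pair and every combination of
#' intervening-gene budget and minimum block length, counts paralog-
#' filtered blocks; the orthogroup table is first restricted to
#' clade-complete orthogroups (at least one gene in every clade member)
#' so missing annotations do not break blocks.
#'
#' @param clades named list: clade -> character vector of species ids
#'   (each of length >= 2).
#' @param annotations named list species -> [genome_annotation()].
#' @param table an [orthogroup_table()] covering all species.
#' @param max_intervening intervening-gene budgets to evaluate.
#' @param min_lens minimum block lengths to evaluate.
#' @return list with `counts` (data.frame `clade`, `species_a`,
#'   `species_b`, `max_intervening`, `min_len`, `n_blocks`) and
#'   `medians` (per-clade median over species pairs).
#' @export
block_census <- function(clades, annotations, table,
                         max_intervening = c(0L, 5L),
                         min_lens = c(2L, 3L, 4L)) {
  rows <- list()
  for (clade in names(clades)) {
    sp <- clades[[clade]]
    if (length(sp) < 2) kg_stop("clade %s has < 2 species", clade)
    sub <- filter_clade_complete(table, sp)
    for (i in seq_len(length(sp) - 1L)) for (j in (i + 1L):length(sp)) {
      for (mi in max_intervening) {
        found <- find_blocks(annotations[[sp[i]]], annotations[[sp[j]]],
                             sub, max_intervening = mi, min_len = 2L)
        found <- filter_paralog_blocks(found)
        for (ml in min_lens) {
          rows[[length(rows) + 1L]] <- data.frame(
            clade = clade, species_a = sp[i], species_b = sp[j],
            max_intervening = mi, min_len = ml,
            n_blocks = sum(found$n_genes >= ml),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  counts <- do.call(rbind, rows)
  medians <- stats::aggregate(n_blocks ~ clade + max_intervening + min_len,
                              counts, stats::median)
  names(medians)[names(medians) == "n_blocks"] <- "median_blocks"
  list(counts = counts, medians = medians)
}
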