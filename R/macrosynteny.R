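#' Oxford (dot-plot) table for a species pair
#'
#' One row per orthologous gene pair with the chromosome and the rank
#' position (ordinal) of both genes, ready for dot plotting.  From an
#' orthogroup table, only single-copy orthogroups (exactly one member in
#' each of the two species) are used unless `expand_multi = TRUE`, in
#' which case multi-copy orthogroups contribute all cross products.
#'
#' @param pairs a [reciprocal_best_hits()] result (columns `gene_a`,
#'   `gene_b`) or an [orthogroup_table()].
#' @param ann_a,ann_b [genome_annotation()] of the two species; for an
#'   orthogroup table their `species_id` must name columns of the table.
#' @param partition optional `alg_partition`; adds an `alg` column by
#'   orthogroup membership.
#' @param expand_multi expand multi-copy orthogroups (default: skip).
#' @return data.frame of class `oxford_table`: `gene_a`, `gene_b`,
#'   `chrom_a`, `ordinal_a`, `chrom_b`, `ordinal_b`, `orthogroup`
#'   (NA for plain hit pairs), `alg` (when `partition` given).
#' @export
oxford_table <- function(pairs, ann_a, ann_b, partition = NULL,
                         expand_multi = FALSE) {
  if (inherits(pairs, "orthogroup_table")) {
    sa <- ann_a$species_id; sb <- ann_b$species_id
    if (!all(c(sa, sb) %in% pairs$species))
      kg_stop("annotations name species absent from the orthogroup table")
    rows <- lapply(names(pairs$entries), function(og) {
      ga <- pairs$entries[[og]][[sa]]
      gb <- pairs$entries[[og]][[sb]]
      if (!length(ga) || !length(gb)) return(NULL)
      if (!expand_multi && (length(ga) > 1 || length(gb) > 1)) return(NULL)
      expand.grid(gene_a = ga, gene_b = gb, orthogroup = og,
                  stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    if (is.null(df))
      df <- data.frame(gene_a = character(0), gene_b = character(0),
                       orthogroup = character(0))
  } else {
    df <- data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                     orthogroup = if (is.null(pairs$orthogroup))
                       NA_character_ else pairs$orthogroup,
                     stringsAsFactors = FALSE)
  }
  ga <- ann_a$genes; gb <- ann_b$genes
  ia <- match(df$gene_a, ga$gene_id)
  ib <- match(df$gene_b, gb$gene_id)
  if (anyNA(ia)) kg_stop("gene %s not in annotation of %s",
                         df$gene_a[is.na(ia)][1], ann_a$species_id)
  if (anyNA(ib)) kg_stop("gene %s not in annotation of %s",
                         df$gene_b[is.na(ib)][1], ann_b$species_id)
  out <- data.frame(gene_a = df$gene_a, gene_b = df$gene_b,
                    chrom_a = ga$chrom[ia], ordinal_a = ga$ordinal[ia],
                    chrom_b = gb$chrom[ib], ordinal_b = gb$ordinal[ib],
                    orthogroup = df$orthogroup, stringsAsFactors = FALSE)
  if (!is.null(partition)) {
    mem <- if (inherits(partition, "alg_partition")) partition$membership
           else partition
    out$alg <- unname(mem[out$orthogroup])
  }
  out <- out[order(out$chrom_a, out$ordinal_a, out$chrom_b, out$ordinal_b), ]
  rownames(out) <- NULL
  attr(out, "species") <- c(ann_a$species_id, ann_b$species_id)
  class(out) <- c("oxford_table", "data.frame")
  out
}

#' Chromosome-to-chromosome correspondence from an Oxford table
#'
#' Builds the contingency matrix of shared orthologs and classifies each
#' chromosome as `1-to-m`, where `m` counts partner chromosomes whose
#' shared-gene count passes both an absolute (`min_count`) and a
#' relative (`min_fraction` of the chromosome's orthologs) threshold.
#' Classification is computed for both species (rows use row totals,
#' columns use column totals).
#'
#' @param table an [oxford_table()].
#' @param min_fraction minimum fraction of a chromosome's orthologs.
#' @param min_count minimum absolute shared-gene count.
#' @return object of class `correspondence_map`: list with
#'   `contingency` (matrix), `classification_a` and `classification_b`
#'   (data.frames `chrom`, `n_partners`, `partners`, `label`).
#' @export
chromosome_correspondence <- function(table, min_fraction = 0.05,
                                      min_count = 5L) {
  if (!nrow(table)) kg_stop("empty oxford table")
  tab <- table(table$chrom_a, table$chrom_b)
  tab <- unclass(tab)
  classify <- function(counts_mat, totals) {
    partners <- lapply(seq_len(nrow(counts_mat)), function(i) {
      cnt <- counts_mat[i, ]
      ok <- cnt >= min_count & cnt >= min_fraction * totals[i]
      colnames(counts_mat)[ok]
    })
    data.frame(chrom = rownames(counts_mat),
               n_partners = lengths(partners),
               partners = vapply(partners, paste, "", collapse = ","),
               label = sprintf("1-to-%d", lengths(partners)),
               stringsAsFactors = FALSE)
  }
  structure(list(
    contingency = tab,
    classification_a = classify(tab, rowSums(tab)),
    classification_b = classify(t(tab), colSums(tab))),
    class = "correspondence_map")
}

#' @export
print.correspondence_map <- function(x, ...) {
  cat("<correspondence_map>\n")
  print(table(x$classification_a$label))
  invisible(x)
}

#' Project ancestral linkage groups onto extant chromosomes
#'
#' For one species, tabulates the ALG composition of every chromosome
#' (counts and fractions of placed orthogroups) and calls derived
#' events: a chromosome carrying two or more ALGs above threshold is a
#' fusion; an ALG above threshold on two or more chromosomes is a
#' fission.
#'
#' @param partition an `alg_partition` (or named orthogroup -> ALG
#'   vector).
#' @param placements a [place_orthogroups()] result.
#' @param species species column of `placements` to project onto.
#' @param fraction_threshold,count_threshold significance thresholds for
#'   an ALG's presence on a chromosome.
#' @return object of class `alg_projection`: list with `composition`
#'   (data.frame `chrom`, `alg`, `count`, `fraction`), `fusions`
#'   (data.frame `chrom`, `algs`), `fissions` (data.frame `alg`,
#'   `chroms`).
#' @export
project_algs <- function(partition, placements, species,
                         fraction_threshold = 0.1, count_threshold = 10L) {
  if (!species %in% colnames(placements))
    kg_stop("species %s absent from placements", species)
  mem <- if (inherits(partition, "alg_partition")) partition$membership
         else partition
  chrom <- placements[[species]]
  ogs <- rownames(placements)
  keep <- !is.na(chrom)
  alg <- as.character(mem[ogs[keep]])
  alg[is.na(alg)] <- "unassigned"
  comp <- as.data.frame(table(chrom = chrom[keep], alg = alg),
                        stringsAsFactors = FALSE)
  comp <- comp[comp$Freq > 0, ]
  names(comp)[3] <- "count"
  tot <- tapply(comp$count, comp$chrom, sum)
  comp$fraction <- comp$count / unname(tot[comp$chrom])
  comp <- comp[order(comp$chrom, -comp$count, comp$alg), ]
  rownames(comp) <- NULL
  sig <- comp[comp$alg != "unassigned" &
                comp$count >= count_threshold &
                comp$fraction >= fraction_threshold, ]
  fus <- sig[stats::ave(seq_len(nrow(sig)), sig$chrom, FUN = length) >= 2, ]
  fusions <- if (nrow(fus))
    data.frame(chrom = unique(fus$chrom),
               algs = vapply(split(fus$alg, fus$chrom)[unique(fus$chrom)],
                             paste, "", collapse = ","))
  else data.frame(chrom = character(0), algs = character(0))
  fis <- sig[stats::ave(seq_len(nrow(sig)), sig$alg, FUN = length) >= 2, ]
  fissions <- if (nrow(fis))
    data.frame(alg = unique(fis$alg),
               chroms = vapply(split(fis$chrom, fis$alg)[unique(fis$alg)],
                               paste, "", collapse = ","))
  else data.frame(alg = character(0), chroms = character(0))
  structure(list(composition = comp, fusions = fusions,
                 fissions = fissions, species = species),
            class = "alg_projection")
}

#' Ancestor-to-ancestor (or ancestor-to-genome) ALG mapping graph
#'
#' For each parent ALG `P_i` and child ALG `C_j`, draws an edge weighted
#' by the fraction of `P_i`'s orthogroups found in `C_j` (over the
#' shared orthogroup universe).  Edges with weight strictly above
#' `faded_threshold` are flagged as near one-to-one relationships.
#'
#' @param partition_parent,partition_child `alg_partition` objects or
#'   named orthogroup -> label vectors.
#' @param faded_threshold strict lower bound for the near one-to-one
#'   flag.
#' @return data.frame of class `ancestor_mapping`: `parent_alg`,
#'   `child_alg`, `n_shared`, `weight`, `near_one_to_one`.
#' @export
ancestor_mapping <- function(partition_parent, partition_child,
                             faded_threshold = 0.8) {
  getmem <- function(p) {
    m <- if (inherits(p, "alg_partition")) p$membership else p
    stats::setNames(as.character(m), names(m))
  }
  mp <- getmem(partition_parent)
  mc <- getmem(partition_child)
  shared <- intersect(names(mp), names(mc))
  mp <- mp[shared]; mc <- mc[shared]
  psize <- table(mp)
  if (any(psize == 0) || !length(shared)) kg_stop("empty parent ALG")
  tab <- as.data.frame(table(parent_alg = mp, child_alg = mc),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, ]
  out <- data.frame(parent_alg = tab$parent_alg,
                    child_alg = tab$child_alg,
                    n_shared = tab$Freq,
                    weight = tab$Freq / as.numeric(psize[tab$parent_alg]),
                    stringsAsFactors = FALSE)
  out$near_one_to_one <- out$weight > faded_threshold
  out <- out[order(out$parent_alg, -out$weight, out$child_alg), ]
  rownames(out) <- NULL
  class(out) <- c("ancestor_mapping", "data.frame")
  out
}
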