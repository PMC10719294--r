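#' Configuration for a karyotype evolution simulation
#'
#' Rates are expected event counts per unit branch length; actual counts
#' are drawn Poisson(rate x branch length), with branch lengths
#' defaulting to 1 when the tree has none.  The defaults describe a
#' regime of moderate inter-chromosomal rearrangement with heavy
#' intra-chromosomal gene shuffling, so that gene order decays while
#' gene-to-chromosome assignment stays informative.
#'
#' @param seed integer root seed; all randomness derives from it.
#' @param tree newick string or `ape::phylo`; the default is a
#'   six-leaf star (hard polytomy) with unit branch lengths, so every
#'   rearrangement is private to one terminal lineage and the ancestral
#'   state stays identifiable.
#' @param n_ancestral_chromosomes ancestral karyotype size.
#' @param genes_per_chromosome genes per ancestral chromosome.
#' @param fusion_rate,fission_rate,translocation_rate expected
#'   inter-chromosomal events per branch.
#' @param transposition_rate expected intra-chromosomal gene moves per
#'   branch.
#' @param gene_loss_rate,gene_dup_rate expected gene losses /
#'   duplications per branch.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              tree = "(s1:1,s2:1,s3:1,s4:1,s5:1,s6:1);",
                              n_ancestral_chromosomes = 18L,
                              genes_per_chromosome = 150L,
                              fusion_rate = 2, fission_rate = 2,
                              translocation_rate = 0,
                              transposition_rate = 100,
                              gene_loss_rate = 0, gene_dup_rate = 0) {
  rates <- c(fusion = fusion_rate, fission = fission_rate,
             translocation = translocation_rate,
             transposition = transposition_rate,
             loss = gene_loss_rate, duplication = gene_dup_rate)
  if (any(rates < 0)) kg_stop("event rates must be >= 0")
  if (n_ancestral_chromosomes < 1) kg_stop("need >= 1 ancestral chromosome")
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (is.null(tree$edge.length)) tree$edge.length <- rep(1, nrow(tree$edge))
  structure(list(seed = as.integer(seed), tree = tree,
                 n_ancestral_chromosomes = as.integer(n_ancestral_chromosomes),
                 genes_per_chromosome = as.integer(genes_per_chromosome),
                 rates = rates),
            class = "simulation_config")
}

# -- event machinery ---------------------------------------------------
# a genome during simulation is a list of character vectors of
# orthogroup ids, one vector per chromosome, in gene order

draw_event_params <- function(genome, type) {
  k <- length(genome)
  sizes <- lengths(genome)
  switch(type,
    fusion = {
      if (k < 2) return(NULL)
      ij <- sample.int(k, 2)
      list(first = ij[1], second = ij[2])
    },
    fission = {
      elig <- which(sizes >= 2)
      if (!length(elig)) return(NULL)
      i <- elig[sample.int(length(elig), 1)]
      list(chrom = i, cut = sample.int(sizes[i] - 1L, 1))
    },
    translocation = {
      if (k < 2) return(NULL)
      ij <- sample.int(k, 2)
      list(first = ij[1], second = ij[2],
           cut_first = sample.int(sizes[ij[1]] + 1L, 1) - 1L,
           cut_second = sample.int(sizes[ij[2]] + 1L, 1) - 1L)
    },
    transposition = {
      if (sum(sizes) < 1) return(NULL)
      g <- sample.int(sum(sizes), 1)
      i <- findInterval(g, cumsum(sizes), left.open = TRUE) + 1L
      pos <- g - c(0, cumsum(sizes))[i]
      list(chrom = i, from = pos, to = sample.int(sizes[i], 1))
    },
    loss = {
      if (sum(sizes) < 2) return(NULL)
      g <- sample.int(sum(sizes), 1)
      i <- findInterval(g, cumsum(sizes), left.open = TRUE) + 1L
      list(chrom = i, pos = g - c(0, cumsum(sizes))[i])
    },
    duplication = {
      if (sum(sizes) < 1) return(NULL)
      g <- sample.int(sum(sizes), 1)
      i <- findInterval(g, cumsum(sizes), left.open = TRUE) + 1L
      dst <- sample.int(k, 1)
      list(src_chrom = i, src_pos = g - c(0, cumsum(sizes))[i],
           dst_chrom = dst, dst_pos = sample.int(sizes[dst] + 1L, 1) - 1L)
    })
}

apply_event <- function(genome, type, params) {
  switch(type,
    fusion = {
      merged <- c(genome[[params$first]], genome[[params$second]])
      genome[[params$first]] <- merged
      genome[params$second] <- NULL
      genome
    },
    fission = {
      v <- genome[[params$chrom]]
      genome[[params$chrom]] <- v[seq_len(params$cut)]
      genome[[length(genome) + 1L]] <- v[(params$cut + 1L):length(v)]
      genome
    },
    translocation = {
      a <- genome[[params$first]]; b <- genome[[params$second]]
      ca <- params$cut_first; cb <- params$cut_second
      na_ <- c(a[seq_len(ca)], if (cb < length(b)) b[(cb + 1L):length(b)])
      nb <- c(b[seq_len(cb)], if (ca < length(a)) a[(ca + 1L):length(a)])
      genome[[params$first]] <- na_
      genome[[params$second]] <- nb
      genome[lengths(genome) == 0L] <- NULL
      genome
    },
    transposition = {
      v <- genome[[params$chrom]]
      g <- v[params$from]
      v <- v[-params$from]
      genome[[params$chrom]] <- append(v, g, after = params$to - 1L)
      genome
    },
    loss = {
      genome[[params$chrom]] <- genome[[params$chrom]][-params$pos]
      genome[lengths(genome) == 0L] <- NULL
      genome
    },
    duplication = {
      g <- genome[[params$src_chrom]][params$src_pos]
      genome[[params$dst_chrom]] <- append(genome[[params$dst_chrom]], g,
                                           after = params$dst_pos)
      genome
    })
}

simulate_branch <- function(genome, branch_label, cfg) {
  rates <- cfg$rates * attr(branch_label, "length")
  counts <- integer(length(rates))
  names(counts) <- names(rates)
  for (ty in names(rates)) {
    with_seed(derive_seed(cfg$seed, "count", branch_label, ty),
              counts[ty] <- stats::rpois(1, rates[ty]))
  }
  types <- rep(names(counts), counts)
  if (length(types) > 1) {
    ord <- with_seed(derive_seed(cfg$seed, "order", branch_label),
                     sample.int(length(types)))
    types <- types[ord]
  }
  log <- vector("list", length(types))
  for (e in seq_along(types)) {
    params <- with_seed(derive_seed(cfg$seed, "event", branch_label, e),
                        draw_event_params(genome, types[e]))
    if (is.null(params)) {
      log[[e]] <- list(branch = branch_label, event = e, type = types[e],
                       skipped = TRUE, params = list())
      next
    }
    genome <- apply_event(genome, types[e], params)
    log[[e]] <- list(branch = branch_label, event = e, type = types[e],
                     skipped = FALSE, params = params)
  }
  list(genome = genome, log = log)
}

#' Simulate a clade of genomes under karyotype evolution
#'
#' Starting from an ancestral karyotype of
#' `n_ancestral_chromosomes x genes_per_chromosome` single-copy genes,
#' evolves a genome down each branch of the species tree by chromosome
#' fusion, fission, reciprocal translocation, intra-chromosomal gene
#' transposition, gene loss and gene duplication.  Every extant gene
#' traces to its ancestral gene (orthogroup), giving downstream stages
#' exact ground truth: the true ancestral linkage group of every
#' orthogroup, a truth orthology table, and a replayable event log.
#'
#' @param config a [simulation_config()].
#' @return an object of class `synthetic_clade`: list with elements
#'   `ancestor` (a [genome_annotation()]), `alg_truth` (named vector
#'   orthogroup -> ancestral chromosome), `extant` (named list of
#'   [genome_annotation()]), `truth` (an [orthogroup_table()]),
#'   `event_log` (data.frame with a `params` list column), `tree`,
#'   `config`.
#' @export
simulate_clade <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  tree <- ape::reorder.phylo(config$tree, "cladewise")
  nc <- config$n_ancestral_chromosomes
  ng <- config$genes_per_chromosome
  og_ids <- sprintf("og%05d", seq_len(nc * ng))
  ancestor <- split(og_ids, rep(seq_len(nc), each = ng))
  names(ancestor) <- NULL
  anc_chroms <- sprintf("anc%02d", seq_len(nc))

  ntip <- length(tree$tip.label)
  genomes <- vector("list", ntip + tree$Nnode)
  genomes[[ntip + 1L]] <- ancestor
  logs <- list()
  for (r in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[r, 1]; child <- tree$edge[r, 2]
    label <- if (child <= ntip) tree$tip.label[child]
             else paste0("node", child)
    attr(label, "length") <- tree$edge.length[r]
    res <- simulate_branch(genomes[[parent]], label, config)
    genomes[[child]] <- res$genome
    logs <- c(logs, res$log)
  }

  extant <- list()
  truth_entries <- stats::setNames(
    lapply(og_ids, function(o) list()), og_ids)
  for (tip in seq_len(ntip)) {
    sp <- tree$tip.label[tip]
    ann <- genome_from_gene_lists(genomes[[tip]], sp)
    extant[[sp]] <- ann
    for (k in seq_len(nrow(ann$genes))) {
      og <- sub(sprintf("^%s_", sp), "", ann$genes$gene_id[k])
      og <- sub("_[0-9]+$", "", og)
      truth_entries[[og]][[sp]] <-
        c(truth_entries[[og]][[sp]], ann$genes$gene_id[k])
    }
  }

  event_log <- data.frame(
    branch = vapply(logs, function(l) as.character(l$branch), ""),
    event = vapply(logs, function(l) l$event, 0L),
    type = vapply(logs, function(l) l$type, ""),
    skipped = vapply(logs, function(l) l$skipped, NA),
    stringsAsFactors = FALSE)
  event_log$params <- lapply(logs, `[[`, "params")

  anc_ann <- genome_from_gene_lists(ancestor, "ancestor",
                                    chrom_names = anc_chroms,
                                    plain_ids = TRUE)
  structure(list(
    ancestor = anc_ann,
    alg_truth = stats::setNames(rep(anc_chroms, each = ng), og_ids),
    extant = extant,
    truth = orthogroup_table(truth_entries, tree$tip.label),
    event_log = event_log,
    tree = tree,
    config = config), class = "synthetic_clade")
}

# lay out a gene-list genome on coordinates: 1 kb genes, 500 bp flanks
genome_from_gene_lists <- function(genome, species_id, chrom_names = NULL,
                                   plain_ids = FALSE) {
  if (is.null(chrom_names)) chrom_names <- sprintf("chr%d", seq_along(genome))
  copy_count <- new.env(parent = emptyenv())
  genes <- list()
  for (i in seq_along(genome)) {
    ogs <- genome[[i]]
    if (!length(ogs)) next
    ids <- character(length(ogs))
    for (k in seq_along(ogs)) {
      n <- (if (is.null(copy_count[[ogs[k]]])) 0L else copy_count[[ogs[k]]]) + 1L
      copy_count[[ogs[k]]] <- n
      ids[k] <- if (plain_ids) ogs[k]
                else sprintf("%s_%s_%d", species_id, ogs[k], n)
    }
    start <- 250 + (seq_along(ogs) - 1) * 1500
    genes[[i]] <- data.frame(gene_id = ids, chrom = chrom_names[i],
                             start = start, end = start + 1000,
                             strand = "+", stringsAsFactors = FALSE)
  }
  genome_annotation(
    species_id,
    data.frame(chrom = chrom_names, length = pmax(lengths(genome), 1L) * 1500),
    do.call(rbind, genes))
}

#' @export
print.synthetic_clade <- function(x, ...) {
  cat(sprintf(
    "<synthetic_clade> %d species from %d ancestral chromosomes, %d events\n",
    length(x$extant), nrow(x$ancestor$chromosomes), nrow(x$event_log)))
  invisible(x)
}

#' Replay a clade's event log over its ancestor
#'
#' Deterministically re-applies the logged events branch by branch,
#' without consulting the RNG.  Used to verify that the simulation is a
#' pure function of its log: the replayed leaf genomes must equal the
#' simulated ones gene-for-gene.
#'
#' @param clade a [synthetic_clade()].
#' @return named list species -> list of chromosome gene-id vectors
#'   (orthogroup ids in gene order).
#' @export
replay_event_log <- function(clade) {
  tree <- clade$tree
  ntip <- length(tree$tip.label)
  nc <- nrow(clade$ancestor$chromosomes)
  ng <- clade$config$genes_per_chromosome
  ancestor <- split(names(clade$alg_truth), rep(seq_len(nc), each = ng))
  names(ancestor) <- NULL
  genomes <- vector("list", ntip + tree$Nnode)
  genomes[[ntip + 1L]] <- ancestor
  for (r in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[r, 1]; child <- tree$edge[r, 2]
    label <- if (child <= ntip) tree$tip.label[child]
             else paste0("node", child)
    g <- genomes[[parent]]
    rows <- which(clade$event_log$branch == label)
    for (k in rows) {
      if (clade$event_log$skipped[k]) next
      g <- apply_event(g, clade$event_log$type[k],
                       clade$event_log$params[[k]])
    }
    genomes[[child]] <- g
  }
  out <- genomes[seq_len(ntip)]
  names(out) <- tree$tip.label
  out
}

#' Write a synthetic clade as pipeline input files
#'
#' Emits, under `dir`: one BED and chrom.sizes per species, the truth
#' orthogroup table, the species tree, the true ancestral linkage of
#' each orthogroup, and the event log (without operand detail).
#'
#' @param clade a [synthetic_clade()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_clade <- function(clade, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(clade$extant)) {
    ann <- clade$extant[[sp]]
    write_annotation(ann, file.path(dir, paste0(sp, ".bed")), "bed")
    writeLines(sprintf("%s\t%d", ann$chromosomes$chrom,
                       as.integer(ann$chromosomes$length)),
               file.path(dir, paste0(sp, ".chrom.sizes")))
  }
  write_orthogroups(clade$truth, file.path(dir, "orthogroups.tsv"))
  ape::write.tree(clade$tree, file.path(dir, "tree.nwk"))
  write_tsv(data.frame(orthogroup = names(clade$alg_truth),
                       ancestral_chromosome = unname(clade$alg_truth)),
            file.path(dir, "alg_truth.tsv"))
  write_tsv(clade$event_log[c("branch", "event", "type", "skipped")],
            file.path(dir, "event_log.tsv"))
  invisible(dir)
}
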