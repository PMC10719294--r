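#' Place orthogroups on chromosomes per species
#'
#' An orthogroup is assigned, in each species where it has members, to
#' the chromosome holding a strict plurality of its member genes; a
#' plurality tie leaves it unplaced (`NA`) in that species.
#'
#' @param table an [orthogroup_table()].
#' @param annotations named list species -> [genome_annotation()],
#'   covering every species of `table` that should contribute.
#' @return object of class `gene_placements`: data.frame with rownames
#'   orthogroup ids and one character column per species (chromosome or
#'   `NA`).
#' @export
place_orthogroups <- function(table, annotations) {
  species <- intersect(table$species, names(annotations))
  if (length(species) < 1) kg_stop("no species shared with annotations")
  long <- orthogroup_long(table)
  long <- long[long$species %in% species, , drop = FALSE]
  ogs <- names(table$entries)
  out <- data.frame(row.names = ogs)
  for (sp in species) {
    ls <- long[long$species == sp, , drop = FALSE]
    g <- annotations[[sp]]$genes
    hit <- match(ls$gene_id, g$gene_id)
    if (anyNA(hit))
      kg_stop("gene %s not in annotation of %s",
              ls$gene_id[is.na(hit)][1], sp)
    chrom <- g$chrom[hit]
    plur <- vapply(split(chrom, ls$orthogroup), function(ch) {
      tb <- table(ch)
      top <- names(tb)[tb == max(tb)]
      if (length(top) == 1L) top else NA_character_
    }, "")
    out[[sp]] <- unname(plur[ogs])
  }
  class(out) <- c("gene_placements", "data.frame")
  out
}

#' Build the orthogroup co-linkage graph
#'
#' Nodes are orthogroups; the weight of edge `(u, v)` counts the species
#' in which `u` and `v` are placed on the same chromosome.  Edges below
#' `min_support` species are dropped (the default of 2 ensures every
#' edge reflects cross-species agreement); orthogroups placed in at
#' least one species are retained as nodes even if isolated.
#'
#' @param placements a [place_orthogroups()] result.
#' @param min_support minimum supporting species per edge.
#' @return weighted undirected `igraph` graph.
#' @export
build_linkage_graph <- function(placements, min_support = 2L) {
  if (ncol(placements) < 2) kg_stop("need placements for >= 2 species")
  ogs <- rownames(placements)
  placed <- rowSums(!is.na(placements)) > 0
  edges <- vector("list", ncol(placements))
  for (s in seq_len(ncol(placements))) {
    chrom <- placements[[s]]
    idx <- which(!is.na(chrom))
    by_chrom <- split(idx, chrom[idx])
    pairs <- lapply(by_chrom, function(i) {
      if (length(i) < 2) return(NULL)
      t(utils::combn(sort(i), 2L))
    })
    edges[[s]] <- do.call(rbind, pairs)
  }
  edges <- do.call(rbind, edges)
  if (is.null(edges)) {
    g <- igraph::make_empty_graph(n = sum(placed), directed = FALSE)
    igraph::V(g)$name <- ogs[placed]
    return(g)
  }
  dt <- data.table::data.table(i = edges[, 1], j = edges[, 2])
  dt <- dt[, list(weight = .N), by = c("i", "j")]
  dt <- dt[dt$weight >= min_support, ]
  data.table::setorderv(dt, c("i", "j"))
  g <- igraph::graph_from_data_frame(
    data.frame(from = ogs[dt$i], to = ogs[dt$j], weight = dt$weight),
    directed = FALSE,
    vertices = data.frame(name = ogs[placed]))
  g
}

#' Weighted Newman modularity of a partition
#'
#' `Q = sum_c [ W_c / W - resolution * (S_c / 2W)^2 ]` with `W` the total
#' edge weight, `W_c` the intra-community weight and `S_c` the summed
#' weighted degree of community `c`.
#'
#' @param graph weighted undirected `igraph` graph.
#' @param membership named vector (orthogroup -> community label)
#'   covering every vertex, or an `alg_partition`.
#' @param resolution resolution multiplier on the null-model term
#'   (1 = standard modularity).
#' @return numeric modularity score.
#' @export
modularity_score <- function(graph, membership, resolution = 1) {
  if (inherits(membership, "alg_partition"))
    membership <- membership$membership
  vn <- igraph::V(graph)$name
  if (is.null(names(membership))) {
    if (length(membership) != length(vn))
      kg_stop("membership length does not match vertex count")
    names(membership) <- vn
  }
  if (!all(vn %in% names(membership)))
    kg_stop("vertex %s missing from partition",
            setdiff(vn, names(membership))[1])
  m <- stats::setNames(as.character(membership[vn]), vn)
  el <- igraph::as_data_frame(graph, what = "edges")
  w <- if (is.null(el$weight)) rep(1, nrow(el)) else el$weight
  W <- sum(w)
  if (W == 0) return(0)
  ca <- m[el$from]; cb <- m[el$to]
  same <- ca == cb
  Wc <- if (any(same)) tapply(w[same], ca[same], sum) else numeric(0)
  deg <- tapply(c(w, w), c(ca, cb), sum)
  comms <- unique(m)
  intra <- unname(Wc[comms]); intra[is.na(intra)] <- 0
  degc <- unname(deg[comms]); degc[is.na(degc)] <- 0
  sum(intra / W - resolution * (degc / (2 * W))^2)
}

run_leiden <- function(graph, resolution, seed) {
  w <- igraph::E(graph)$weight
  with_seed(seed, igraph::cluster_leiden(
    graph, objective_function = "modularity", weights = w,
    resolution = resolution, n_iterations = 5))
}

#' Consensus Leiden community detection
#'
#' Runs `n_runs` Leiden optimizations of (resolution-scaled) modularity
#' from distinct derived seeds, builds the co-assignment frequency
#' matrix, thresholds it at `co_threshold` to obtain a consensus graph,
#' and re-applies the procedure iteratively until all runs agree
#' (Lancichinetti-Fortunato consensus clustering).  Reported modularity
#' is the standard (resolution 1) score on the input graph; stability is
#' the mean pairwise run-agreement over node pairs in the first round.
#'
#' Communities smaller than 1% of nodes are reported in the assignment
#' but excluded from the headline `n_algs` count.
#'
#' @param graph weighted undirected `igraph` graph.
#' @param resolution Leiden resolution parameter.
#' @param n_runs independent runs per consensus round (>= 2).
#' @param co_threshold co-assignment frequency below which node pairs
#'   are disconnected in the consensus graph.
#' @param seed root seed.
#' @param max_iter maximum consensus rounds before aborting.
#' @return object of class `alg_partition`: list with `membership`
#'   (named integer vector), `n_algs`, `n_communities`, `modularity`,
#'   `resolution`, `stability`, `sizes`.
#' @export
consensus_communities <- function(graph, resolution = 1, n_runs = 100L,
                                  co_threshold = 0.5, seed = 1L,
                                  max_iter = 50L) {
  if (igraph::vcount(graph) == 0) kg_stop("empty graph")
  if (n_runs < 2) kg_stop("n_runs must be >= 2")
  vn <- igraph::V(graph)$name
  n <- length(vn)
  cur <- graph
  stability <- NA_real_
  membership <- NULL
  best_run <- NULL
  best_run_q <- -Inf
  for (iter in seq_len(max_iter)) {
    runs <- matrix(0L, n, n_runs)
    for (r in seq_len(n_runs)) {
      cl <- run_leiden(cur, resolution,
                       derive_seed(seed, "leiden", iter, r))
      runs[, r] <- igraph::membership(cl)[vn]
      if (iter == 1L) {
        q <- modularity_score(graph, stats::setNames(runs[, r], vn),
                              resolution)
        if (q > best_run_q) {
          best_run_q <- q
          best_run <- runs[, r]
        }
      }
    }
    co <- matrix(0, n, n)
    for (r in seq_len(n_runs)) {
      mr <- runs[, r]
      co <- co + outer(mr, mr, "==")
    }
    co <- co / n_runs
    if (iter == 1L) {
      ut <- co[upper.tri(co)]
      stability <- if (length(ut)) mean(ut^2 + (1 - ut)^2) else 1
    }
    identical_runs <- all(apply(runs, 2, function(x)
      all(x == runs[, 1]) ||
        adjusted_rand_index(x, runs[, 1]) == 1))
    if (identical_runs) {
      membership <- stats::setNames(match(runs[, 1], unique(runs[, 1])), vn)
      break
    }
    adj <- co
    adj[adj < co_threshold] <- 0
    diag(adj) <- 0
    cur <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                               weighted = TRUE)
    igraph::V(cur)$name <- vn
  }
  if (is.null(membership))
    kg_stop("consensus did not converge after %d iterations", max_iter)
  # quality guarantee: the co-assignment majority can settle on a worse
  # local optimum than the best constituent run; never return less than
  # the best run achieved under the same objective
  if (!is.null(best_run) &&
      best_run_q > modularity_score(graph, membership, resolution) + 1e-12) {
    membership <- stats::setNames(match(best_run, unique(best_run)), vn)
  }
  sizes <- table(membership)
  min_major <- max(1, ceiling(0.01 * n))
  structure(list(membership = membership,
                 n_algs = sum(sizes >= min_major),
                 n_communities = length(sizes),
                 modularity = modularity_score(graph, membership),
                 resolution = resolution,
                 stability = stability,
                 sizes = as.integer(sizes)),
            class = "alg_partition")
}

#' @export
print.alg_partition <- function(x, ...) {
  cat(sprintf(
    "<alg_partition> %d ALGs (%d communities) at resolution %g; Q = %.4f, stability = %.3f\n",
    x$n_algs, x$n_communities, x$resolution, x$modularity, x$stability))
  invisible(x)
}

#' Sweep consensus clustering over a resolution grid
#'
#' Evaluates one consensus partition per resolution ("scenario") and
#' ranks scenarios by standard modularity on the input graph; ties break
#' toward fewer ALGs.
#'
#' @param graph weighted undirected `igraph` graph.
#' @param resolutions numeric grid of Leiden resolutions.
#' @param n_runs,seed,co_threshold passed to [consensus_communities()].
#' @return object of class `alg_scenarios`: list with `partitions` (one
#'   [consensus_communities()] result per resolution), `summary`
#'   (data.frame resolution / n_algs / modularity / stability) and
#'   `best` (the selected partition).
#' @export
scenario_sweep <- function(graph, resolutions, n_runs = 100L, seed = 1L,
                           co_threshold = 0.5) {
  if (!length(resolutions)) kg_stop("empty resolution grid")
  partitions <- lapply(seq_along(resolutions), function(i) {
    consensus_communities(graph, resolution = resolutions[i],
                          n_runs = n_runs, co_threshold = co_threshold,
                          seed = derive_seed(seed, "scenario", i))
  })
  summary <- data.frame(
    resolution = resolutions,
    n_algs = vapply(partitions, `[[`, 0L, "n_algs"),
    n_communities = vapply(partitions, `[[`, 0L, "n_communities"),
    modularity = vapply(partitions, `[[`, 0, "modularity"),
    stability = vapply(partitions, `[[`, 0, "stability"))
  best <- order(-summary$modularity, summary$n_algs)[1]
  structure(list(partitions = partitions, summary = summary,
                 best = partitions[[best]]),
            class = "alg_scenarios")
}

#' @export
print.alg_scenarios <- function(x, ...) {
  cat("<alg_scenarios>\n")
  print(x$summary)
  invisible(x)
}

#' Write an ALG partition as two-column TSV
#'
#' @param partition an `alg_partition`.
#' @param path output file.
#' @export
write_partition <- function(partition, path) {
  df <- data.frame(orthogroup = names(partition$membership),
                   alg = sprintf("ALG%02d", unname(partition$membership)))
  write_tsv(df[order(df$orthogroup), ], path)
}
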