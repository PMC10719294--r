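#' Validate a pipeline configuration file
#'
#' Reads a YAML configuration, rejects unknown keys, checks types and
#' referenced paths, and fills stage defaults.  All problems are
#' aggregated into a single error report.
#'
#' @param path YAML file.
#' @return a validated `pipeline_config` list.
#' @export
validate_config <- function(path) {
  problems <- character(0)
  if (!file.exists(path)) {
    prob <- sprintf("config file not found: %s", path)
    stop(structure(class = c("kg_validation_error", "error", "condition"),
                   list(message = prob, call = NULL)))
  }
  cfg <- yaml::read_yaml(path)
  top_allowed <- c("seed", "out_dir", "species", "clades", "params",
                   "orthogroups", "hsps", "matrices")
  unknown <- setdiff(names(cfg), top_allowed)
  if (length(unknown))
    problems <- c(problems, sprintf("unknown top-level key: %s", unknown))
  defaults <- list(
    simulate = list(tree = "(s1:1,s2:1,s3:1,s4:1,s5:1,s6:1);",
                    n_ancestral_chromosomes = 18L,
                    genes_per_chromosome = 150L, fusion_rate = 2,
                    fission_rate = 2, translocation_rate = 0,
                    transposition_rate = 100, gene_loss_rate = 0,
                    gene_dup_rate = 0),
    alg = list(resolutions = c(0.5, 1, 2), n_runs = 10L,
               min_support = 2L, co_threshold = 0.5),
    micro = list(max_intervening = c(0L, 5L), min_lens = c(2L, 3L, 4L)),
    uce = list(min_identity = 0.95, window = 20L),
    topology = list(window_bins = 10L, min_prominence = 0.1,
                    delta_method = "mean"),
    atac = list(apply_iqr = TRUE))
  params <- if (is.null(cfg$params)) list() else cfg$params
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    problems <- c(problems, sprintf("unknown params block: %s", unknown))
  for (blk in names(defaults)) {
    given <- if (is.null(params[[blk]])) list() else params[[blk]]
    extra <- setdiff(names(given), names(defaults[[blk]]))
    if (length(extra))
      problems <- c(problems,
                    sprintf("unknown key in params.%s: %s", blk, extra))
    defaults[[blk]][names(given)] <- given
  }
  cfg$params <- defaults
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed))
    problems <- c(problems, "seed must be an integer")
  sp_allowed <- c("id", "annotation", "format", "chrom_sizes",
                  "genome_size", "peaks", "repeats")
  for (sp in cfg$species) {
    extra <- setdiff(names(sp), sp_allowed)
    if (length(extra))
      problems <- c(problems, sprintf("unknown key in species %s: %s",
                                      if (is.null(sp$id)) "?" else sp$id,
                                      extra))
    if (is.null(sp$id))
      problems <- c(problems, "species entry without id")
    for (f in intersect(c("annotation", "chrom_sizes", "peaks", "repeats"),
                        names(sp))) {
      if (!file.exists(sp[[f]]))
        problems <- c(problems, sprintf("species %s: missing file %s",
                                        sp$id, sp[[f]]))
    }
  }
  for (f in intersect(c("orthogroups", "hsps"), names(cfg))) {
    if (!file.exists(cfg[[f]]))
      problems <- c(problems, sprintf("missing file for %s: %s", f,
                                      cfg[[f]]))
  }
  for (mx in cfg$matrices) {
    if (is.null(mx$path) || !file.exists(mx$path))
      problems <- c(problems, sprintf("matrix entry with missing file: %s",
                                      if (is.null(mx$path)) "(no path)"
                                      else mx$path))
  }
  if (length(problems)) {
    stop(structure(class = c("kg_validation_error", "error", "condition"),
                   list(message = paste(problems, collapse = "\n"),
                        call = NULL)))
  }
  class(cfg) <- "pipeline_config"
  cfg
}

load_config_annotations <- function(cfg) {
  anns <- list()
  for (sp in cfg$species) {
    fmt <- if (is.null(sp$format)) "bed" else sp$format
    anns[[sp$id]] <- read_annotation(sp$annotation, format = fmt,
                                     species_id = sp$id,
                                     chrom_sizes = sp$chrom_sizes)
  }
  anns
}

run_simulate <- function(cfg, out) {
  p <- cfg$params$simulate
  sim <- simulation_config(seed = cfg$seed, tree = p$tree,
                           n_ancestral_chromosomes = p$n_ancestral_chromosomes,
                           genes_per_chromosome = p$genes_per_chromosome,
                           fusion_rate = p$fusion_rate,
                           fission_rate = p$fission_rate,
                           translocation_rate = p$translocation_rate,
                           transposition_rate = p$transposition_rate,
                           gene_loss_rate = p$gene_loss_rate,
                           gene_dup_rate = p$gene_dup_rate)
  write_clade(simulate_clade(sim), out)
}

run_alg <- function(cfg, out) {
  table <- read_orthogroups(cfg$orthogroups)
  anns <- load_config_annotations(cfg)
  p <- cfg$params$alg
  placements <- place_orthogroups(table, anns)
  graph <- build_linkage_graph(placements, min_support = p$min_support)
  sweep <- scenario_sweep(graph, resolutions = p$resolutions,
                          n_runs = p$n_runs, seed = cfg$seed,
                          co_threshold = p$co_threshold)
  write_partition(sweep$best, file.path(out, "alg_partition.tsv"))
  write_tsv(sweep$summary, file.path(out, "alg_scenarios.tsv"))
  el <- igraph::as_data_frame(graph, what = "edges")
  write_tsv(el[order(el$from, el$to), ],
            file.path(out, "linkage_graph.tsv"))
}

run_macro <- function(cfg, out) {
  table <- read_orthogroups(cfg$orthogroups)
  anns <- load_config_annotations(cfg)
  ids <- names(anns)
  for (i in seq_len(length(ids) - 1L)) for (j in (i + 1L):length(ids)) {
    ox <- oxford_table(table, anns[[ids[i]]], anns[[ids[j]]])
    write_tsv(ox, file.path(out, sprintf("oxford_%s_%s.tsv",
                                         ids[i], ids[j])))
    if (nrow(ox)) {
      cm <- chromosome_correspondence(ox)
      write_tsv(cm$classification_a,
                file.path(out, sprintf("correspondence_%s_vs_%s.tsv",
                                       ids[i], ids[j])))
    }
  }
}

run_micro <- function(cfg, out) {
  table <- read_orthogroups(cfg$orthogroups)
  anns <- load_config_annotations(cfg)
  p <- cfg$params$micro
  census <- block_census(cfg$clades, anns, table,
                         max_intervening = p$max_intervening,
                         min_lens = p$min_lens)
  write_tsv(census$counts, file.path(out, "microsynteny_counts.tsv"))
  write_tsv(census$medians, file.path(out, "microsynteny_medians.tsv"))
}

run_uce <- function(cfg, out) {
  hsps <- read_hsp_table(cfg$hsps)
  p <- cfg$params$uce
  el <- window_scan(hsps, min_identity = p$min_identity,
                    window = p$window)
  el <- resolve_multimapping(el)
  write_tsv(el, file.path(out, "uce_elements.tsv"))
  writeLines(sprintf("%s\t%d\t%d\t%s", el$query_id,
                     as.integer(el$q_start), as.integer(el$q_end),
                     el$element_id),
             file.path(out, "uce_query.bed"))
  writeLines(sprintf("%s\t%d\t%d\t%s", el$subject_id,
                     as.integer(el$s_start), as.integer(el$s_end),
                     el$element_id),
             file.path(out, "uce_subject.bed"))
}

run_topology <- function(cfg, out) {
  p <- cfg$params$topology
  deltas <- list()
  for (mx in cfg$matrices) {
    fmt <- if (is.null(mx$format)) "coo" else mx$format
    cm <- read_contact_matrix(mx$path, format = fmt,
                              chrom = if (is.null(mx$chrom)) "chr"
                                      else mx$chrom,
                              bin_size = if (is.null(mx$bin_size)) 1e5
                                         else mx$bin_size)
    tr <- insulation_track(cm, window_bins = p$window_bins)
    ex <- call_extrema(tr, min_prominence = p$min_prominence)
    bd <- boundary_deltas(ex, method = p$delta_method)
    tag <- sub("\\.[^.]*$", "", basename(mx$path))
    write_tsv(tr, file.path(out, sprintf("insulation_%s.tsv", tag)))
    write_tsv(bd, file.path(out, sprintf("deltas_%s.tsv", tag)))
    deltas[[tag]] <- bd$delta
  }
  if (length(deltas) >= 2) {
    mwu <- compare_boundary_strength(deltas[[1]], deltas[[2]])
    write_tsv(data.frame(a = names(deltas)[1], b = names(deltas)[2],
                         U = mwu$U, p_value = mwu$p.value,
                         method = mwu$method),
              file.path(out, "boundary_mwu.tsv"))
  }
}

run_atacdist <- function(cfg, out) {
  anns <- load_config_annotations(cfg)
  summaries <- list()
  for (sp in cfg$species) {
    if (is.null(sp$peaks)) next
    peaks <- read_bed_intervals(sp$peaks)
    repeats <- if (is.null(sp$repeats)) NULL
               else read_bed_intervals(sp$repeats)
    s <- peak_gene_distances(peaks, anns[[sp$id]], repeats)
    if (!is.null(sp$genome_size)) s$genome_size <- sp$genome_size
    summaries[[sp$id]] <- s
  }
  df <- do.call(rbind, lapply(summaries, function(s)
    data.frame(species = s$species_id, n = s$n, median = s$median,
               mean = s$mean, sem = s$sem, genome_size = s$genome_size)))
  write_tsv(df, file.path(out, "atac_distance_summary.tsv"))
  if (length(summaries) >= 3) {
    reg <- size_regression(summaries,
                           apply_iqr = cfg$params$atac$apply_iqr)
    write_tsv(data.frame(slope = reg$slope, intercept = reg$intercept,
                         r = reg$r), file.path(out, "atac_regression.tsv"))
  }
}

#' Command-line entry point
#'
#' Dispatches `karyograph <subcommand> --config cfg.yaml [--out dir]
#' [--seed n]`, plus `karyograph rbh --a-hits x.tsv --b-hits y.tsv --out
#' dir`.  Subcommands: `simulate`, `rbh`, `alg`, `macro`, `micro`,
#' `uce`, `topology`, `atacdist`, `all` (runs every stage whose inputs
#' are configured).  All outputs are plain TSV/BED written
#' deterministically, so stages compose through files and identical
#' config plus seed reproduce outputs byte for byte.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status: 0 ok, 1 validation error, 2 runtime
#'   error.
#' @export
kg_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    message("usage: karyograph <simulate|rbh|alg|macro|micro|uce|topology|atacdist|all> --config cfg.yaml [--out dir] [--seed n]")
    1L
  }
  if (!length(args)) return(usage())
  sub <- args[1]
  opts <- list()
  rest <- args[-1]
  while (length(rest)) {
    if (!startsWith(rest[1], "--") || length(rest) < 2) return(usage())
    opts[[substring(rest[1], 3)]] <- rest[2]
    rest <- rest[-(1:2)]
  }
  tryCatch({
    if (sub == "rbh") {
      if (is.null(opts[["a-hits"]]) || is.null(opts[["b-hits"]]) ||
          is.null(opts$out))
        return(usage())
      dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
      rbh <- reciprocal_best_hits(read_blast_hits(opts[["a-hits"]]),
                                  read_blast_hits(opts[["b-hits"]]))
      write_tsv(rbh, file.path(opts$out, "rbh.tsv"))
      return(0L)
    }
    runner <- switch(sub, simulate = run_simulate, alg = run_alg,
                     macro = run_macro, micro = run_micro, uce = run_uce,
                     topology = run_topology, atacdist = run_atacdist,
                     all = NULL)
    if (is.null(runner) && sub != "all") return(usage())
    if (is.null(opts$config)) return(usage())
    cfg <- validate_config(opts$config)
    if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
    out <- if (!is.null(opts$out)) opts$out
           else if (!is.null(cfg$out_dir)) cfg$out_dir
           else "."
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(unclass(cfg), file.path(out, "config.echo.yaml"))
    message(sprintf("[karyograph] %s -> %s (seed %d)", sub, out,
                    cfg$seed))
    if (sub == "all") {
      if (!is.null(cfg$orthogroups) && length(cfg$species)) {
        run_alg(cfg, out); run_macro(cfg, out)
        if (length(cfg$clades)) run_micro(cfg, out)
      }
      if (!is.null(cfg$hsps)) run_uce(cfg, out)
      if (length(cfg$matrices)) run_topology(cfg, out)
      if (any(vapply(cfg$species, function(s) !is.null(s$peaks), NA)))
        run_atacdist(cfg, out)
    } else {
      runner(cfg, out)
    }
    0L
  }, kg_validation_error = function(e) {
    message("configuration errors:\n", conditionMessage(e))
    1L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
}
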