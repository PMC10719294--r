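#' Multi-species orthogroup table
#'
#' Maps each orthogroup to, per species, the (possibly empty) list of
#' member gene ids.  Orthogroups are the nodes of the co-linkage graph
#' used for ancestral linkage group inference.
#'
#' @param entries named list: orthogroup id -> named list species ->
#'   character vector of gene ids.
#' @param species character vector fixing species (column) order.
#' @return an object of class `orthogroup_table`.
#' @export
orthogroup_table <- function(entries, species) {
  stopifnot(is.list(entries), is.character(species), length(species) >= 1)
  if (anyDuplicated(names(entries)))
    kg_stop("duplicated orthogroup ids")
  entries <- lapply(entries, function(e) {
    e <- lapply(species, function(s) {
      g <- e[[s]]
      if (is.null(g)) character(0) else as.character(g)
    })
    names(e) <- species
    e
  })
  for (s in species) {
    genes <- unlist(lapply(entries, `[[`, s), use.names = FALSE)
    if (anyDuplicated(genes))
      kg_stop("gene %s of species %s listed in more than one orthogroup",
              genes[duplicated(genes)][1], s)
  }
  structure(list(entries = entries, species = species),
            class = "orthogroup_table")
}

#' @export
print.orthogroup_table <- function(x, ...) {
  cat(sprintf("<orthogroup_table> %d orthogroups x %d species (%s)\n",
              length(x$entries), length(x$species),
              paste(x$species, collapse = ", ")))
  invisible(x)
}

#' Long-format view of an orthogroup table
#'
#' @param table an [orthogroup_table()].
#' @return data.frame with columns `orthogroup`, `species`, `gene_id`,
#'   one row per gene.
#' @export
orthogroup_long <- function(table) {
  ogs <- names(table$entries)
  rows <- lapply(ogs, function(og) {
    e <- table$entries[[og]]
    n <- lengths(e)
    if (sum(n) == 0) return(NULL)
    data.frame(orthogroup = og,
               species = rep(names(e), n),
               gene_id = unlist(e, use.names = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(orthogroup = character(0), species = character(0),
                      gene_id = character(0))
  rownames(out) <- NULL
  out
}

#' Read an orthogroup table (OrthoFinder-style TSV)
#'
#' First column is the orthogroup id, one column per species, cells are
#' comma-separated gene lists; empty cells mean no member in that
#' species.
#'
#' @param path TSV file with a header line.
#' @return an [orthogroup_table()].
#' @export
read_orthogroups <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1) kg_stop("empty orthogroup file: %s", path)
  # count separators, not fields: strsplit drops trailing empty cells
  ntab <- lengths(gregexpr("\t", lines, fixed = TRUE))
  ntab[!grepl("\t", lines, fixed = TRUE)] <- 0L
  if (any(ntab != ntab[1]))
    kg_stop("ragged orthogroup table at line %d (expected %d columns)",
            which(ntab != ntab[1])[1], ntab[1] + 1L)
  ncol <- ntab[1] + 1L
  parts <- strsplit(lines, "\t", fixed = TRUE)
  parts <- lapply(parts, function(p) c(p, rep("", ncol - length(p))))
  species <- parts[[1]][-1]
  entries <- list()
  for (p in parts[-1]) {
    e <- lapply(p[-1], function(cell) {
      if (!nzchar(trimws(cell))) character(0)
      else trimws(strsplit(cell, ",", fixed = TRUE)[[1]])
    })
    names(e) <- species
    entries[[p[1]]] <- e
  }
  orthogroup_table(entries, species)
}

#' Write an orthogroup table as TSV
#'
#' Inverse of [read_orthogroups()]; rows in table order, cells
#' comma-joined, so write-then-read is the identity.
#'
#' @param table an [orthogroup_table()].
#' @param path output file.
#' @export
write_orthogroups <- function(table, path) {
  header <- paste(c("Orthogroup", table$species), collapse = "\t")
  rows <- vapply(names(table$entries), function(og) {
    cells <- vapply(table$entries[[og]],
                    function(g) paste(g, collapse = ","), "")
    paste(c(og, cells), collapse = "\t")
  }, "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Restrict an orthogroup table to clade-complete orthogroups
#'
#' Keeps orthogroups with at least one member gene in every listed
#' species, correcting the downstream microsynteny census for missing
#' gene annotations.
#'
#' @param table an [orthogroup_table()].
#' @param species species that must all be represented.
#' @return filtered [orthogroup_table()] with attributes `n_input` and
#'   `n_kept`.
#' @export
filter_clade_complete <- function(table, species) {
  if (length(species) < 1) kg_stop("empty species list")
  unknown <- setdiff(species, table$species)
  if (length(unknown))
    kg_stop("unknown species: %s", paste(unknown, collapse = ", "))
  keep <- vapply(table$entries, function(e) {
    all(vapply(e[species], length, 0L) >= 1L)
  }, NA)
  out <- orthogroup_table(table$entries[keep], table$species)
  attr(out, "n_input") <- length(table$entries)
  attr(out, "n_kept") <- sum(keep)
  out
}
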