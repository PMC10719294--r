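#' Genome annotation: chromosomes and gene intervals for one species
#'
#' The coordinate substrate for every synteny computation.  All internal
#' coordinates are 0-based half-open; GFF3 input is converted on read.
#' Genes are ranked per chromosome by `(start, end, gene_id)` and the
#' 0-based rank is stored in the `ordinal` column.
#'
#' @param species_id character scalar.
#' @param chromosomes data.frame with columns `chrom`, `length` (bp).
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`,
#'   `end`, `strand` (`+`, `-` or `.`).
#' @return an object of class `genome_annotation`.
#' @export
genome_annotation <- function(species_id, chromosomes, genes) {
  stopifnot(is.character(species_id), length(species_id) == 1L)
  chromosomes <- data.frame(chrom = as.character(chromosomes$chrom),
                            length = as.numeric(chromosomes$length),
                            stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = as.character(genes$gene_id),
                      chrom = as.character(genes$chrom),
                      start = as.numeric(genes$start),
                      end = as.numeric(genes$end),
                      strand = if (is.null(genes$strand)) "."
                               else as.character(genes$strand),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(chromosomes$chrom))
    kg_stop("duplicated chromosome names in %s", species_id)
  if (anyDuplicated(genes$gene_id))
    kg_stop("duplicated gene ids in %s: %s", species_id,
            paste(unique(genes$gene_id[duplicated(genes$gene_id)]),
                  collapse = ", "))
  bad <- setdiff(genes$chrom, chromosomes$chrom)
  if (length(bad))
    kg_stop("genes on unknown chromosomes: %s", paste(bad, collapse = ", "))
  if (any(genes$start < 0) || any(genes$start >= genes$end))
    kg_stop("gene intervals must satisfy 0 <= start < end")
  len <- chromosomes$length[match(genes$chrom, chromosomes$chrom)]
  if (any(genes$end > len))
    kg_stop("gene end beyond chromosome length for: %s",
            paste(utils::head(genes$gene_id[genes$end > len], 5),
                  collapse = ", "))
  ord <- order(match(genes$chrom, chromosomes$chrom),
               genes$start, genes$end, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  genes$ordinal <- stats::ave(seq_len(nrow(genes)), genes$chrom,
                              FUN = seq_along) - 1L
  rownames(genes) <- NULL
  structure(list(species_id = species_id, chromosomes = chromosomes,
                 genes = genes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %s: %d chromosomes, %d genes, %.2f Mb\n",
              x$species_id, nrow(x$chromosomes), nrow(x$genes),
              sum(x$chromosomes$length) / 1e6))
  invisible(x)
}

#' Total genome size of an annotation
#'
#' @param annotation a [genome_annotation()].
#' @return sum of chromosome lengths in bp.
#' @export
genome_size <- function(annotation) sum(annotation$chromosomes$length)

#' Read a genome annotation from BED6 or GFF3
#'
#' BED intervals are taken as-is (already 0-based half-open); GFF3 `gene`
#' features are converted from 1-based closed coordinates.  Chromosome
#' lengths come from, in order of preference: the `chrom_sizes` argument,
#' GFF3 `##sequence-region` pragmas, or the maximum gene end observed.
#'
#' @param path input file.
#' @param format `"bed"` or `"gff3"`.
#' @param species_id species label; defaults to the file base name.
#' @param chrom_sizes optional two-column file (`chrom`, `length`) or
#'   data.frame.
#' @return a [genome_annotation()].
#' @export
read_annotation <- function(path, format = c("bed", "gff3"),
                            species_id = NULL, chrom_sizes = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) kg_stop("no such file: %s", path)
  if (is.null(species_id))
    species_id <- sub("\\.[^.]*$", "", basename(path))
  if (format == "bed") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 4))
      kg_stop("malformed BED line %d: expected >= 4 fields",
              which(nf < 4)[1])
    genes <- data.frame(
      gene_id = vapply(parts, `[`, "", 4),
      chrom = vapply(parts, `[`, "", 1),
      start = as.numeric(vapply(parts, `[`, "", 2)),
      end = as.numeric(vapply(parts, `[`, "", 3)),
      strand = vapply(parts, function(p) if (length(p) >= 6) p[6] else ".",
                      ""),
      stringsAsFactors = FALSE)
    if (anyNA(genes$start) || anyNA(genes$end))
      kg_stop("malformed BED line %d: non-numeric coordinates",
              which(is.na(genes$start) | is.na(genes$end))[1])
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "gene"]
    df <- as.data.frame(gr)
    if (!nrow(df)) kg_stop("no gene features in %s", path)
    ids <- if (!is.null(df$ID)) df$ID else df$Name
    if (is.null(ids) || anyNA(ids))
      kg_stop("GFF3 gene feature without ID attribute in %s", path)
    genes <- data.frame(gene_id = as.character(ids),
                        chrom = as.character(df$seqnames),
                        start = df$start - 1, end = as.numeric(df$end),
                        strand = as.character(df$strand),
                        stringsAsFactors = FALSE)
    genes$strand[!genes$strand %in% c("+", "-")] <- "."
    if (is.null(chrom_sizes)) {
      sl <- GenomeInfoDb::seqlengths(gr)
      if (!all(is.na(sl))) {
        chrom_sizes <- data.frame(chrom = names(sl), length = as.numeric(sl))
      } else {
        # fall back to ##sequence-region pragmas
        prag <- grep("^##sequence-region", readLines(path), value = TRUE)
        if (length(prag)) {
          f <- strsplit(prag, "[ \t]+")
          chrom_sizes <- data.frame(
            chrom = vapply(f, `[`, "", 2),
            length = as.numeric(vapply(f, `[`, "", 4)))
        }
      }
    }
  }
  if (is.null(chrom_sizes)) {
    chrom_sizes <- stats::aggregate(end ~ chrom, genes, max)
    names(chrom_sizes) <- c("chrom", "length")
  } else if (is.character(chrom_sizes)) {
    chrom_sizes <- read_chrom_sizes(chrom_sizes)
  }
  genome_annotation(species_id, chrom_sizes, genes)
}

#' Write a genome annotation to BED6 or GFF3
#'
#' Writers emit genes in annotation order (deterministic); GFF3 output
#' includes `##sequence-region` pragmas so chromosome lengths round-trip.
#'
#' @param annotation a [genome_annotation()].
#' @param path output file.
#' @param format `"bed"` or `"gff3"`.
#' @export
write_annotation <- function(annotation, path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  g <- annotation$genes
  if (format == "bed") {
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", g$chrom, as.integer(g$start),
                     as.integer(g$end), g$gene_id, g$strand)
  } else {
    ch <- annotation$chromosomes
    lines <- c("##gff-version 3",
               sprintf("##sequence-region %s 1 %d", ch$chrom,
                       as.integer(ch$length)),
               sprintf("%s\t.\tgene\t%d\t%d\t.\t%s\t.\tID=%s", g$chrom,
                       as.integer(g$start) + 1L, as.integer(g$end),
                       ifelse(g$strand %in% c("+", "-"), g$strand, "."),
                       g$gene_id))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column chromosome sizes table
#'
#' @param path chrom.sizes file (chromosome, length in bp).
#' @return data.frame with columns `chrom`, `length`.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  df
}

#' Read a BED file of plain intervals (peaks, repeats, CDS, introns)
#'
#' @param path BED file with at least 3 columns.
#' @return data.frame with columns `chrom`, `start`, `end` and, when
#'   present, `name`.
#' @export
read_bed_intervals <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (length(parts) && any(lengths(parts) < 3))
    kg_stop("malformed BED line %d", which(lengths(parts) < 3)[1])
  df <- data.frame(
    chrom = vapply(parts, `[`, "", 1),
    start = as.numeric(vapply(parts, `[`, "", 2)),
    end = as.numeric(vapply(parts, `[`, "", 3)),
    stringsAsFactors = FALSE)
  if (length(parts) && all(lengths(parts) >= 4))
    df$name <- vapply(parts, `[`, "", 4)
  df
}
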