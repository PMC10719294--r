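# annotation with one chromosome per element of ogs_by_chrom; gene ids
# are "<sp>_<og>" so the matching orthogroup table is derivable
make_annotation <- function(sp, ogs_by_chrom, gene_len = 1000,
                            spacing = 1500, margin = 250) {
  genes <- do.call(rbind, lapply(seq_along(ogs_by_chrom), function(i) {
    ogs <- ogs_by_chrom[[i]]
    start <- margin + (seq_along(ogs) - 1) * spacing
    data.frame(gene_id = paste0(sp, "_", ogs), chrom = paste0("chr", i),
               start = start, end = start + gene_len, strand = "+",
               stringsAsFactors = FALSE)
  }))
  genome_annotation(
    sp,
    data.frame(chrom = paste0("chr", seq_along(ogs_by_chrom)),
               length = lengths(ogs_by_chrom) * spacing + margin),
    genes)
}

# orthogroup table linking make_annotation() genomes by shared og labels
make_og_table <- function(annotations) {
  sps <- names(annotations)
  ogs <- unique(unlist(lapply(annotations, function(a)
    sub("^[^_]*_", "", a$genes$gene_id))))
  entries <- lapply(ogs, function(og) {
    e <- lapply(sps, function(sp) {
      g <- annotations[[sp]]$genes$gene_id
      g[sub("^[^_]*_", "", g) == og]
    })
    names(e) <- sps
    e
  })
  names(entries) <- ogs
  orthogroup_table(entries, sps)
}

# random single-chromosome genome pair sharing n_shared orthogroups in
# shuffled order, with optional private genes and duplicated ogs
random_genome_pair <- function(n_shared, n_private = 4, n_dup = 0,
                               seed = 1) {
  set.seed(seed)
  shared <- sprintf("og%03d", seq_len(n_shared))
  a_order <- sample(c(shared, sprintf("pa%02d", seq_len(n_private))))
  b_extra <- if (n_dup > 0) sample(shared, n_dup) else character(0)
  b_order <- sample(c(shared, b_extra, sprintf("pb%02d", seq_len(n_private))))
  a_ids <- paste0("A_", a_order)
  b_ids <- paste0("B_", b_order)
  b_ids <- make.unique(b_ids, sep = ".")
  ann_a <- make_annotation("A", list(a_order))
  ann_b <- genome_annotation(
    "B",
    data.frame(chrom = "chr1", length = length(b_order) * 1500 + 250),
    data.frame(gene_id = b_ids, chrom = "chr1",
               start = 250 + (seq_along(b_order) - 1) * 1500,
               end = 1250 + (seq_along(b_order) - 1) * 1500,
               strand = "+", stringsAsFactors = FALSE))
  ogs <- unique(c(a_order, b_order))
  entries <- lapply(ogs, function(og) {
    list(A = a_ids[a_order == og],
         B = b_ids[b_order == og])
  })
  names(entries) <- ogs
  list(ann_a = ann_a, ann_b = ann_b,
       table = orthogroup_table(entries, c("A", "B")))
}
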