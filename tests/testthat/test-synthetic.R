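test_that("a zero-rate clade is a clone set with single-copy truth", {
  cl <- simulate_clade(simulation_config(
    seed = 1, n_ancestral_chromosomes = 4, genes_per_chromosome = 10,
    fusion_rate = 0, fission_rate = 0, transposition_rate = 0))
  expect_equal(nrow(cl$event_log), 0)
  for (sp in names(cl$extant)) {
    ann <- cl$extant[[sp]]
    expect_equal(nrow(ann$chromosomes), 4)
    expect_equal(sub("_[0-9]+$", "", sub(paste0("^", sp, "_"), "",
                                         ann$genes$gene_id)),
                 cl$ancestor$genes$gene_id)
  }
  expect_true(all(lengths(lapply(cl$truth$entries, unlist)) ==
                    length(cl$extant)))
})

test_that("replaying the event log reproduces every extant genome", {
  cl <- simulate_clade(simulation_config(
    seed = 11, n_ancestral_chromosomes = 5, genes_per_chromosome = 20,
    translocation_rate = 1, gene_loss_rate = 2, gene_dup_rate = 2))
  replayed <- replay_event_log(cl)
  for (sp in names(replayed)) {
    ann <- cl$extant[[sp]]
    simulated <- lapply(ann$chromosomes$chrom, function(ch) {
      g <- ann$genes[ann$genes$chrom == ch, ]
      sub("_[0-9]+$", "", sub(paste0("^", sp, "_"), "",
                              g$gene_id[order(g$start)]))
    })
    expect_identical(unname(simulated), lapply(replayed[[sp]], unname))
  }
})

test_that("event counts move chromosome and gene numbers as logged", {
  cl <- simulate_clade(simulation_config(
    seed = 5, n_ancestral_chromosomes = 6, genes_per_chromosome = 15,
    tree = "(x:1,y:1);", fusion_rate = 1, fission_rate = 0,
    transposition_rate = 0))
  for (sp in c("x", "y")) {
    log <- cl$event_log[cl$event_log$branch == sp & !cl$event_log$skipped, ]
    n_fus <- sum(log$type == "fusion")
    expect_equal(nrow(cl$extant[[sp]]$chromosomes), 6 - n_fus)
  }
  # duplications only: extant gene count = ancestral + logged events
  cl2 <- simulate_clade(simulation_config(
    seed = 9, n_ancestral_chromosomes = 3, genes_per_chromosome = 10,
    tree = "(x:1,y:1);", fusion_rate = 0, fission_rate = 0,
    transposition_rate = 0, gene_dup_rate = 3))
  for (sp in c("x", "y")) {
    n_dup <- sum(cl2$event_log$branch == sp & !cl2$event_log$skipped &
                   cl2$event_log$type == "duplication")
    expect_equal(nrow(cl2$extant[[sp]]$genes), 30 + n_dup)
  }
})

test_that("the simulator is a pure function of config and seed", {
  cfg <- simulation_config(seed = 21, n_ancestral_chromosomes = 5,
                           genes_per_chromosome = 12, gene_dup_rate = 1)
  a <- simulate_clade(cfg)
  b <- simulate_clade(cfg)
  expect_identical(lapply(a$extant, `[[`, "genes"),
                   lapply(b$extant, `[[`, "genes"))
  expect_identical(a$event_log$type, b$event_log$type)
})

test_that("contact map generator matches its closed form", {
  m <- generate_contact_map(20, "decay_only", decay_exponent = 1,
                            noise_sd = 0, c0 = 100)
  s <- abs(outer(1:20, 1:20, "-"))
  expect_equal(m$values, 100 / (1 + s))
  # tads mode: within/cross ratio at equal distance is the enrichment
  mt <- generate_contact_map(100, "tads", decay_exponent = 1,
                             tad_boundaries = 50, tad_enrichment = 3,
                             noise_sd = 0)
  within <- mt$values[10, 30]    # both in block 1, distance 20
  cross <- mt$values[40, 60]     # across the boundary, distance 20
  expect_equal(within / cross, 3)
  expect_identical(generate_contact_map(15, "decay_only", noise_sd = 0.5,
                                        seed = 8)$values,
                   generate_contact_map(15, "decay_only", noise_sd = 0.5,
                                        seed = 8)$values)
  expect_error(generate_contact_map(100, "tads", tad_boundaries = 150,
                                    tad_enrichment = 2), "boundaries")
})

test_that("planted alignments have exact truth coordinates", {
  # zero background: matching columns are exactly the planted element
  pl <- plant_conserved_alignments(3, 100, 1, 30,
                                   background_identity = 0, seed = 2)
  h <- pl$truth$hsp[1]
  qa <- strsplit(pl$hsps$aligned_query[h], "")[[1]]
  sa <- strsplit(pl$hsps$aligned_subject[h], "")[[1]]
  expect_equal(sum(qa == sa), 30)
  expect_equal(which(qa == sa),
               (pl$truth$col_start[1] + 1):pl$truth$col_end[1])

  expect_equal(nrow(plant_conserved_alignments(3, 100, 0, 30, 0.5,
                                               seed = 1)$truth), 0)
  expect_identical(plant_conserved_alignments(5, 200, 2, 20, 0.6,
                                              seed = 3)$hsps,
                   plant_conserved_alignments(5, 200, 2, 20, 0.6,
                                              seed = 3)$hsps)
  expect_error(plant_conserved_alignments(2, 100, 3, 20, 0.5),
               "n_elements")
})

test_that("ATAC generator controls the distance law and avoids genes", {
  ann <- make_annotation("S", list(sprintf("g%02d", 1:40)),
                         gene_len = 2000, spacing = 12000, margin = 3000)
  pk <- generate_atac_dataset(ann, 2000, mean_distance = 100, seed = 6)
  expect_equal(nrow(pk), 2000)
  expect_lt(abs(mean(pk$true_distance) - 100) / 100, 0.1)
  # all peaks disjoint from all genes
  g <- ann$genes
  for (k in seq_len(nrow(pk))) {
    same <- g$chrom == pk$chrom[k]
    expect_false(any(g$start[same] < pk$end[k] & g$end[same] > pk$start[k]))
  }
  expect_equal(nrow(generate_atac_dataset(ann, 0, mean_distance = 50,
                                          seed = 1)), 0)
})
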