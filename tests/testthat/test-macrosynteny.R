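test_that("oxford tables use single-copy orthogroups and carry ALG labels", {
  anns <- list(A = make_annotation("A", list(c("og1", "og2"))),
               B = make_annotation("B", list(c("og1", "og2"))))
  tab <- make_og_table(anns)
  ox <- oxford_table(tab, anns$A, anns$B)
  expect_equal(ox$ordinal_a, c(0, 1))
  expect_equal(ox$ordinal_b, c(0, 1))
  # multi-copy orthogroup contributes no row by default
  anns2 <- list(A = make_annotation("A", list(c("og1a", "og1b", "og2"))))
  tab2 <- orthogroup_table(list(
    og1 = list(A = c("A_og1a", "A_og1b"), B = "B_og1"),
    og2 = list(A = "A_og2", B = "B_og2")), c("A", "B"))
  ox2 <- oxford_table(tab2, anns2$A, make_annotation("B", list(c("og1", "og2"))))
  expect_equal(nrow(ox2), 1)
  expect_equal(nrow(oxford_table(tab2, anns2$A,
                                 make_annotation("B", list(c("og1", "og2"))),
                                 expand_multi = TRUE)), 3)
  # partition join
  part <- stats::setNames(c(7, 9), c("og1", "og2"))
  ox3 <- oxford_table(tab, anns$A, anns$B, partition = part)
  expect_equal(ox3$alg, c(7, 9))
})

test_that("oxford tables transpose under species swap", {
  pr <- random_genome_pair(20, n_private = 3, seed = 8)
  ab <- oxford_table(pr$table, pr$ann_a, pr$ann_b)
  ba <- oxford_table(pr$table, pr$ann_b, pr$ann_a)
  expect_setequal(paste(ab$gene_a, ab$gene_b, ab$ordinal_a, ab$ordinal_b),
                  paste(ba$gene_b, ba$gene_a, ba$ordinal_b, ba$ordinal_a))
})

test_that("chromosome correspondence classifies by joint thresholds", {
  ox <- data.frame(
    chrom_a = c(rep("a1", 52), rep("a2", 60)),
    chrom_b = c(rep("b1", 50), rep("b2", 2),
                rep("b2", 30), rep("b3", 30)))
  ox$ordinal_a <- seq_len(nrow(ox)); ox$ordinal_b <- seq_len(nrow(ox))
  cm <- chromosome_correspondence(ox)
  cls <- cm$classification_a
  expect_equal(cls$label[cls$chrom == "a1"], "1-to-1")
  expect_equal(cls$partners[cls$chrom == "a1"], "b1")
  expect_equal(cls$label[cls$chrom == "a2"], "1-to-2")
  expect_equal(sum(cm$contingency), nrow(ox))
})

test_that("a zero-event clade is entirely one-to-one", {
  cl <- simulate_clade(simulation_config(
    seed = 2, n_ancestral_chromosomes = 4, genes_per_chromosome = 20,
    tree = "(p:1,q:1);", fusion_rate = 0, fission_rate = 0,
    transposition_rate = 0))
  ox <- oxford_table(cl$truth, cl$extant$p, cl$extant$q)
  cm <- chromosome_correspondence(ox)
  expect_true(all(cm$classification_a$label == "1-to-1"))
  expect_true(all(cm$classification_b$label == "1-to-1"))
  # ancestor mapping of the truth onto itself has all weights 1
  am <- ancestor_mapping(cl$alg_truth, cl$alg_truth)
  expect_true(all(am$weight == 1))
  expect_true(all(am$near_one_to_one))
})

test_that("ALG projection calls fusions and fissions by thresholds", {
  # chr1 carries ALG1 (40) + ALG2 (35): fusion; ALG3 split 60/45: fission;
  # chr4 has 95 ALG4 + 3 ALG5: pure (ALG5 below count threshold)
  ogs <- c(sprintf("a%03d", 1:40), sprintf("b%03d", 1:35),
           sprintf("c%03d", 1:105), sprintf("d%03d", 1:95),
           sprintf("e%03d", 1:3))
  chrom <- c(rep("chr1", 75), rep("chr2", 60), rep("chr3", 45),
             rep("chr4", 98))
  placements <- data.frame(S = chrom, row.names = ogs)
  class(placements) <- c("gene_placements", "data.frame")
  alg <- stats::setNames(
    c(rep("ALG1", 40), rep("ALG2", 35), rep("ALG3", 105),
      rep("ALG4", 95), rep("ALG5", 3)), ogs)
  proj <- project_algs(alg, placements, "S")
  expect_equal(proj$fusions$chrom, "chr1")
  expect_setequal(strsplit(proj$fusions$algs, ",")[[1]], c("ALG1", "ALG2"))
  expect_equal(proj$fissions$alg, "ALG3")
  expect_setequal(strsplit(proj$fissions$chroms, ",")[[1]],
                  c("chr2", "chr3"))
  comp4 <- proj$composition[proj$composition$chrom == "chr4", ]
  sig4 <- comp4[comp4$count >= 10 & comp4$fraction >= 0.1, ]
  expect_equal(sig4$alg, "ALG4")
})

test_that("ancestor mapping weights are parent-content fractions", {
  parent <- stats::setNames(rep("P1", 10), sprintf("og%02d", 1:10))
  child <- stats::setNames(c(rep("C1", 8), rep("C2", 2)),
                           sprintf("og%02d", 1:10))
  am <- ancestor_mapping(parent, child)
  expect_equal(am$weight[am$child_alg == "C1"], 0.8)
  expect_equal(am$weight[am$child_alg == "C2"], 0.2)
  expect_false(any(am$near_one_to_one))  # 0.8 is not > 0.8
  ident <- ancestor_mapping(parent, stats::setNames(rep("C1", 10),
                                                    names(parent)))
  expect_equal(ident$weight, 1)
  expect_true(ident$near_one_to_one)
})
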