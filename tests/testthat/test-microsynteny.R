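test_that("intervening-gene budget controls block splitting", {
  ann_a <- make_annotation("A", list(c("g1", "g2", "g3", "g4")))
  ann_b <- make_annotation("B", list(c("g1", "g2", "gx", "g3", "g4")))
  tab <- make_og_table(list(A = ann_a, B = ann_b))
  b0 <- find_blocks(ann_a, ann_b, tab, max_intervening = 0)
  expect_equal(sort(b0$orthogroups), c("g1,g2", "g3,g4"))
  b1 <- find_blocks(ann_a, ann_b, tab, max_intervening = 1)
  expect_equal(b1$orthogroups, "g1,g2,g3,g4")
  # reversed partner order: one monotone-decreasing block
  ann_r <- make_annotation("B", list(c("g4", "g3", "g2", "g1")))
  tab_r <- make_og_table(list(A = ann_a, B = ann_r))
  br <- find_blocks(ann_a, ann_r, tab_r, max_intervening = 0)
  expect_equal(br$orthogroups, "g1,g2,g3,g4")
  expect_equal(br$direction, "-")
  expect_error(find_blocks(ann_a, ann_b, tab, max_intervening = -1),
               "max_intervening")
})

test_that("paralog-dominated blocks are removed", {
  mk <- function(ogs) {
    df <- data.frame(block = 1, n_genes = length(ogs), chrom_a = "c",
                     chrom_b = "c", a_start = 0, a_end = 1, b_start = 0,
                     b_end = 1, direction = "+",
                     orthogroups = paste(ogs, collapse = ","),
                     genes_a = "", genes_b = "")
    class(df) <- c("synteny_blocks", "data.frame")
    df
  }
  expect_equal(nrow(filter_paralog_blocks(mk(c("OG7", "OG7", "OG7")))), 0)
  expect_equal(nrow(filter_paralog_blocks(mk(c("OG1", "OG2", "OG3")))), 1)
  expect_equal(nrow(filter_paralog_blocks(
    mk(c("OG1", "OG1", "OG2", "OG1")))), 0)
  # a two-gene block of two distinct orthogroups survives
  expect_equal(nrow(filter_paralog_blocks(mk(c("OG1", "OG2")))), 1)
})

test_that("greedy blocks match the exhaustive oracle on random genomes", {
  cases <- 0
  for (seed in 1:12) {
    pr <- random_genome_pair(n_shared = 14 + (seed %% 5), n_private = 4,
                             n_dup = seed %% 3, seed = seed)
    for (mi in c(0, 1, 5)) {
      got <- find_blocks(pr$ann_a, pr$ann_b, pr$table,
                         max_intervening = mi, min_len = 2)
      want <- oracle_blocks(pr$ann_a, pr$ann_b, pr$table, mi, 2)
      expect_equal(nrow(got), length(want),
                   info = sprintf("seed %d mi %d", seed, mi))
      got_sig <- sort(got$genes_a)
      want_sig <- sort(vapply(want, function(b)
        paste(b$genes_a, collapse = ","), ""))
      expect_equal(got_sig, want_sig,
                   info = sprintf("seed %d mi %d", seed, mi))
      cases <- cases + 1
    }
  }
  expect_gte(cases, 36)
})

test_that("block counts are monotone in min_len and, in aggregate, in the budget", {
  totals <- c(`0` = 0, `5` = 0)
  for (seed in 21:32) {
    pr <- random_genome_pair(n_shared = 18, n_private = 5, seed = seed)
    counts <- sapply(c(0, 5), function(mi) {
      b <- find_blocks(pr$ann_a, pr$ann_b, pr$table, max_intervening = mi)
      sapply(c(2, 3, 4), function(ml) sum(b$n_genes >= ml))
    })
    expect_true(all(diff(counts[, 1]) <= 0))   # longer blocks are rarer
    expect_true(all(diff(counts[, 2]) <= 0))
    totals <- totals + counts[2, ]             # min_len = 3 column sums
  }
  # a wider budget can merge two blocks into one on a single instance,
  # so the budget effect is asserted over the collection
  expect_gte(totals[2], totals[1])
})

test_that("the census is symmetric and complete on a clone clade", {
  cl <- simulate_clade(simulation_config(
    seed = 3, n_ancestral_chromosomes = 2, genes_per_chromosome = 50,
    tree = "(x:1,y:1,z:1);", fusion_rate = 0, fission_rate = 0,
    transposition_rate = 0))
  census <- block_census(list(clade = c("x", "y", "z")), cl$extant,
                         cl$truth, max_intervening = 0,
                         min_lens = c(2, 4))
  # identical gene orders: every pair yields one block per chromosome
  expect_true(all(census$counts$n_blocks == 2))
  expect_true(all(census$medians$median_blocks == 2))
  # symmetry of a single pair census
  b_xy <- find_blocks(cl$extant$x, cl$extant$y, cl$truth, 0)
  b_yx <- find_blocks(cl$extant$y, cl$extant$x, cl$truth, 0)
  expect_equal(nrow(b_xy), nrow(b_yx))
  expect_error(block_census(list(c = "x"), cl$extant, cl$truth),
               "< 2 species")
})

test_that("an empty orthogroup table yields no blocks", {
  ann <- make_annotation("A", list(c("g1", "g2")))
  ann_b <- make_annotation("B", list(c("h1", "h2")))
  tab <- make_og_table(list(A = ann, B = ann_b))  # no shared orthogroups
  expect_equal(nrow(find_blocks(ann, ann_b, tab, 0)), 0)
})
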