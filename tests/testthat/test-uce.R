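mk_hsp <- function(q, s, q_start = 0, s_start = 0, strand = "+") {
  qlen <- nchar(gsub("-", "", q)); slen <- nchar(gsub("-", "", s))
  hsp_table("q", "s", q_start, q_start + qlen, s_start, s_start + slen,
            strand, aligned_query = q, aligned_subject = s)
}

test_that("window scan finds the identical core with exact columns", {
  h <- mk_hsp(strrep("A", 40),
              paste0(strrep("C", 6), strrep("A", 25), strrep("C", 9)))
  el <- window_scan(h)
  expect_equal(nrow(el), 1)
  expect_equal(el$col_start, 6)
  expect_equal(el$col_end, 31)
  expect_equal(el$identity, 1)
  expect_equal(el$q_start, 6); expect_equal(el$q_end, 31)
})

test_that("uniform sub-threshold identity yields nothing; exact window passes", {
  # 80% identity, mismatches evenly spread: every 20-window has 4
  q <- strrep("A", 100)
  s <- paste(rep(c("A", "A", "A", "A", "C"), 20), collapse = "")
  expect_equal(nrow(window_scan(mk_hsp(q, s))), 0)
  # exactly 20 identical columns spanning the whole HSP
  el <- window_scan(mk_hsp(strrep("G", 20), strrep("G", 20)))
  expect_equal(el$col_start, 0)
  expect_equal(el$col_end, 20)
})

test_that("gap columns count as mismatches and shift coordinates", {
  # 24 matched columns interrupted by a gap: gap breaks identity run
  q <- paste0(strrep("A", 12), "-", strrep("A", 12))
  s <- strrep("A", 25)
  el <- window_scan(mk_hsp(q, s), min_identity = 0.95, window = 10)
  expect_true(all(el$identity >= 0.95))
  # subject coordinates skip nothing, query skips the gap
  expect_true(all(el$q_end - el$q_start <= 12))
  # an element after a gap has query coordinates shifted by the gap
  q2 <- paste0(strrep("C", 5), "-----", strrep("T", 20))
  s2 <- paste0(strrep("G", 10), strrep("T", 20))
  el2 <- window_scan(mk_hsp(q2, s2))
  expect_equal(el2$col_start, 10)
  expect_equal(el2$q_start, 5)    # 5 ungapped query chars before col 10
  expect_equal(el2$s_start, 10)
})

test_that("minus-strand subject coordinates map from the interval end", {
  el <- window_scan(mk_hsp(strrep("A", 30), strrep("A", 30),
                           q_start = 100, s_start = 200, strand = "-"))
  expect_equal(el$q_start, 100); expect_equal(el$q_end, 130)
  expect_equal(el$s_start, 200); expect_equal(el$s_end, 230)
})

test_that("scan output is invariant to HSP input order", {
  pl <- plant_conserved_alignments(8, 400, 4, 30, 0.6, seed = 12)
  fwd <- window_scan(pl$hsps)
  shuf <- pl$hsps[c(5, 2, 8, 1, 7, 3, 6, 4), ]
  class(shuf) <- class(pl$hsps)
  rev <- window_scan(shuf)
  cols <- c("query_id", "q_start", "q_end", "subject_id", "s_start",
            "s_end", "identity")
  expect_equal(fwd[cols], rev[cols])
})

test_that("every reported element re-validates at 95% identity", {
  pl <- plant_conserved_alignments(10, 1000, 6, 40, 0.7, seed = 9)
  el <- window_scan(pl$hsps)
  for (k in seq_len(nrow(el))) {
    qa <- strsplit(pl$hsps$aligned_query[el$hsp[k]], "")[[1]]
    sa <- strsplit(pl$hsps$aligned_subject[el$hsp[k]], "")[[1]]
    cols <- (el$col_start[k] + 1):el$col_end[k]
    expect_gte(mean(qa[cols] == sa[cols] & qa[cols] != "-"), 0.95)
  }
  # at low background the planted elements are the only survivors
  pl2 <- plant_conserved_alignments(10, 1000, 6, 40, 0.5, seed = 10)
  el2 <- window_scan(pl2$hsps)
  expect_equal(nrow(el2), 6)
  m <- merge(pl2$truth, el2, by = "hsp")
  expect_equal(m$col_start.x, m$col_start.y)
  expect_equal(m$col_end.x, m$col_end.y)
})

test_that("multi-mapping elements reduce to the longest locus pair", {
  el <- data.frame(
    element_id = c("e1", "e2", "e3"),
    query_id = c("chrA", "chrA", "chrA"),
    q_start = c(100, 105, 500), q_end = c(200, 195, 600),
    subject_id = c("s1", "s2", "s3"),
    s_start = c(0, 0, 0), s_end = c(50, 80, 60))
  out <- resolve_multimapping(el)
  expect_setequal(out$element_id, c("e2", "e3"))  # 90+80 beats 100+50
  # 10% overlap: distinct loci, both kept
  el2 <- data.frame(element_id = c("e1", "e2"), query_id = "chrA",
                    q_start = c(0, 90), q_end = c(100, 190),
                    subject_id = c("s1", "s2"), s_start = 0,
                    s_end = c(100, 100))
  expect_equal(nrow(resolve_multimapping(el2)), 2)
  expect_equal(nrow(resolve_multimapping(el2[1, ])), 1)
})

test_that("elements classify against CDS and introns by majority overlap", {
  el <- data.frame(element_id = c("e1", "e2", "e3"),
                   query_id = "chr1",
                   q_start = c(100, 300, 700), q_end = c(200, 400, 800),
                   subject_id = "s", s_start = 0, s_end = 100)
  cds <- data.frame(chrom = "chr1", start = 100, end = 160)  # 60% of e1
  introns <- data.frame(chrom = "chr1", start = 250, end = 450)
  out <- classify_elements(el, cds, introns)
  expect_false("e1" %in% out$element_id)
  expect_equal(out$class[out$element_id == "e2"], "intronic")
  expect_equal(out$class[out$element_id == "e3"], "non_coding")
  all3 <- classify_elements(el, cds, introns, drop_coding = FALSE)
  expect_equal(all3$class[all3$element_id == "e1"], "coding_removed")
})

test_that("recurrence clustering is single linkage on coverage", {
  el <- data.frame(element_id = c("E1", "E2", "E3"),
                   query_id = "c", q_start = c(0, 1000, 2000),
                   q_end = c(100, 1100, 2100),
                   subject_id = "s", s_start = 0, s_end = 100)
  hits <- data.frame(query = "E1", subject = "E2", length = 95)
  cl <- cluster_recurrent(el, hits)
  expect_equal(cl$cluster[cl$element_id == "E1"],
               cl$cluster[cl$element_id == "E2"])
  expect_true(all(cl$recurrent[cl$element_id %in% c("E1", "E2")]))
  expect_false(cl$recurrent[cl$element_id == "E3"])
  # chain E1-E2, E2-E3 joins all three
  hits2 <- rbind(hits, data.frame(query = "E2", subject = "E3",
                                  length = 95))
  expect_equal(length(unique(cluster_recurrent(el, hits2)$cluster)), 1)
  # short hits below coverage do not link
  weak <- data.frame(query = "E1", subject = "E2", length = 50)
  expect_false(any(cluster_recurrent(el, weak)$recurrent))
  none <- cluster_recurrent(el, NULL)
  expect_equal(length(unique(none$cluster)), 3)
})
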