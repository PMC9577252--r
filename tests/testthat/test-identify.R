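ann_hk <- make_ann(list(
  list(id = "rrna1", biotype = "rRNA", strand = "+", starts = 1000, ends = 1200),
  list(id = "lncg1", biotype = "lncRNA", strand = "+", starts = c(5000, 5500),
       ends = c(5200, 5700)),
  list(id = "pc1", biotype = "protein_coding", strand = "+",
       starts = c(9000, 9600), ends = c(9400, 9900))
))

test_that("housekeeping overlap removes, abutting does not", {
  ts <- make_ts(list(
    # last exon ends exactly where the rRNA exon starts minus 1: abutting
    list(id = "abut", strand = "+", starts = 800, ends = 999),
    list(id = "inside", strand = "-", starts = 1050, ends = 1100),
    list(id = "far", strand = "+", starts = 3000, ends = 3400)
  ))
  res <- filter_housekeeping(ts, ann_hk)
  expect_setequal(res$removed_ids, "inside")
  expect_setequal(res$kept$transcripts$transcript_id, c("abut", "far"))
})

test_that("exon-count filter keeps two-exon, drops single-exon transcripts", {
  ts <- make_ts(list(
    list(id = "one", strand = "+", starts = 100, ends = 400),
    list(id = "two", strand = "+", starts = c(100, 600), ends = c(300, 800))
  ))
  res <- filter_exon_count(ts, 2)
  expect_equal(res$removed_ids, "one")
  expect_equal(res$kept$transcripts$transcript_id, "two")
})

test_that("coding-hit exclusion requires all three strict inequalities", {
  ts <- make_ts(list(
    list(id = "t1", strand = "+", starts = 1, ends = 500),
    list(id = "t2", strand = "+", starts = 1000, ends = 1500),
    list(id = "t3", strand = "+", starts = 2000, ends = 2500)
  ))
  hits <- data.frame(
    transcript_id = c("t1", "t2", "t3", "t3"),
    subject_id = "p",
    identity_pct = c(90.0, 95, 95, 85),   # t1 at the boundary: not excluded
    coverage_pct = c(95, 85, 79, 95),     # t3 first hit fails coverage
    p_value = c(1e-20, 1e-20, 1e-20, 1e-20),
    stringsAsFactors = FALSE)
  res <- filter_coding_hits(ts, hits)
  expect_setequal(res$removed_ids, "t2")
  # boundary p-value: 1e-10 exactly is not < 1e-10
  hits2 <- data.frame(transcript_id = "t1", subject_id = "p",
                      identity_pct = 95, coverage_pct = 95, p_value = 1e-10)
  expect_length(filter_coding_hits(ts, hits2)$removed_ids, 0)
})

test_that("annotated split requires same-strand exonic overlap", {
  ts <- make_ts(list(
    list(id = "same", strand = "+", starts = c(5100, 5600),
         ends = c(5300, 5800)),
    list(id = "opp", strand = "-", starts = c(5100, 5600),
         ends = c(5300, 5800)),
    list(id = "off", strand = "+", starts = 7000, ends = 7400)
  ))
  res <- split_annotated(ts, ann_hk)
  expect_equal(res$annotated_ids, "same")
  expect_setequal(res$unannotated$transcripts$transcript_id, c("opp", "off"))
})

test_that("length/ORF filter applies both boundaries", {
  withr::local_seed(3)
  s199 <- plant_orf_free_sequence(199, 100)
  s200 <- plant_orf_free_sequence(200, 100)
  long_orf <- paste0("ATG", paste(rep("GCT", 120), collapse = ""), "TAA")
  long_orf <- paste0(long_orf,
                     paste(rep("C", 500 - nchar(long_orf)), collapse = ""))
  ts <- make_ts(list(
    list(id = "short", strand = "+", starts = 1, ends = 199, seq = s199),
    list(id = "ok", strand = "+", starts = 300, ends = 499, seq = s200),
    list(id = "coding_like", strand = "+", starts = 1000, ends = 1499,
         seq = long_orf)
  ))
  res <- filter_length_orf(ts)
  expect_setequal(res$removed_ids, c("short", "coding_like"))
  expect_equal(res$kept$transcripts$transcript_id, "ok")
  expect_setequal(res$reasons$reason[res$reasons$transcript_id == "short"],
                  "too_short")
  expect_setequal(res$reasons$reason[
    res$reasons$transcript_id == "coding_like"], "orf_too_long")
})

test_that("missing sequences are removed with reason no_sequence", {
  withr::local_seed(4)
  ts <- make_ts(list(
    list(id = "with", strand = "+", starts = 1, ends = 300,
         seq = plant_orf_free_sequence(300, 100)),
    list(id = "without", strand = "+", starts = 1000, ends = 1299)
  ))
  expect_warning(res <- filter_length_orf(ts), "without sequence")
  expect_equal(res$reasons$reason[res$reasons$transcript_id == "without"],
               "no_sequence")
  expect_equal(res$kept$transcripts$transcript_id, "with")
})

test_that("coding-potential gate: Pfam dominates, external scores take precedence", {
  withr::local_seed(6)
  seqs <- list(a = plant_orf_free_sequence(400, 50),
               b = plant_orf_free_sequence(400, 50),
               c = plant_orf_free_sequence(400, 50))
  ts <- make_ts(list(
    list(id = "a", strand = "+", starts = 1, ends = 400, seq = seqs$a),
    list(id = "b", strand = "+", starts = 1000, ends = 1399, seq = seqs$b),
    list(id = "c", strand = "+", starts = 2000, ends = 2399, seq = seqs$c)
  ))
  ext <- data.frame(transcript_id = c("a", "b"), score = c(-1.2, 0.8))
  pfam <- data.frame(transcript_id = "c", evalue = 1e-6)
  res <- coding_potential_gate(ts, ext, pfam)
  # a kept (score < 0); b removed (score >= 0); c removed by the domain hit
  expect_equal(res$kept$transcripts$transcript_id, "a")
  expect_setequal(res$removed_ids, c("b", "c"))
  # without evidence tables, the built-in heuristic takes over
  res2 <- coding_potential_gate(ts)
  expect_equal(unique(res2$scores$source), "builtin_heuristic")
  # a Pfam hit at exactly the threshold still removes
  res3 <- coding_potential_gate(ts, ext,
                                data.frame(transcript_id = "a", evalue = 1e-5))
  expect_true("a" %in% res3$removed_ids)
})

test_that("cascade on empty input reports zero everywhere", {
  empty <- make_ts(list())
  cr <- run_cascade(empty, ann_hk, data.frame(
    transcript_id = character(), subject_id = character(),
    identity_pct = numeric(), coverage_pct = numeric(), p_value = numeric()))
  expect_true(all(cr$report$n_input == 0))
  expect_true(all(cr$report$n_removed == 0))
  expect_length(cr$lnc_ids, 0)
})

test_that("cascade accounting holds and re-running is deterministic", {
  sim <- shared_sim()
  cr <- run_cascade(sim$transcripts, sim$annotation, sim$hits,
                    external_scores = sim$cpc, pfam_hits = sim$pfam)
  expect_equal(cr$report$n_surviving, cr$report$n_input - cr$report$n_removed)
  # each stage's survivors feed the next stage (annotated split diverts)
  expect_equal(cr$report$n_input[-1], cr$report$n_surviving[-6])
  expect_length(intersect(cr$annotated_ids, cr$novel_ids), 0)
  cr2 <- run_cascade(sim$transcripts, sim$annotation, sim$hits,
                     external_scores = sim$cpc, pfam_hits = sim$pfam)
  expect_identical(cr$report, cr2$report)
  expect_identical(cr$lnc_ids, cr2$lnc_ids)
})

test_that("every final lncRNA satisfies the filter invariants", {
  sim <- shared_sim()
  cr <- run_cascade(sim$transcripts, sim$annotation, sim$hits,
                    external_scores = sim$cpc, pfam_hits = sim$pfam)
  novel <- subset_transcripts(sim$transcripts, cr$novel_ids)
  expect_true(all(novel$transcripts$length >= 200))
  expect_true(all(novel$transcripts$n_exons >= 2))
  aa <- longest_orf_lengths(novel$sequences[novel$transcripts$transcript_id])
  expect_true(all(aa < 100))
})

test_that("decoys planted to fail single gates are caught there", {
  sim <- shared_sim()
  man <- sim$manifest$transcripts
  cr <- run_cascade(sim$transcripts, sim$annotation, sim$hits,
                    external_scores = sim$cpc, pfam_hits = sim$pfam)
  # hit decoys and coding transcripts are gone; near-miss hits never exclude
  expect_length(intersect(cr$lnc_ids,
                          man$transcript_id[man$category %in%
                                              c("decoy_hit", "decoy_pfam",
                                                "coding", "noise",
                                                "housekeeping")]), 0)
  # the built-in heuristic flags planted coding-like sequences as coding
  decoy_ids <- man$transcript_id[man$category %in% c("decoy_hit", "decoy_pfam",
                                                     "coding")]
  sc <- coding_potential_score(sim$transcripts$sequences[decoy_ids])
  expect_gte(mean(sc$score > 0), 0.9)
})
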