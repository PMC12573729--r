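mk_hit <- function(family = "cifA", s_start = 1000, s_end = 2199,
                   e_value = 1e-30, qcov = 80, contig = "c1") {
  data.frame(query_id = paste0(family, "_query"), subject_id = contig,
             percent_identity = 85, align_length = 400, mismatches = 10,
             gap_opens = 0, q_start = 1, q_end = 400,
             s_start = s_start, s_end = s_end, e_value = e_value,
             bit_score = 300, query_coverage = qcov,
             stringsAsFactors = FALSE)
}

mk_features <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(contig = r$contig %||% "c1", start = r$start, end = r$end,
               strand = r$strand %||% "+",
               feature_id = r$id %||% sprintf("g%02d", i),
               product = "x", stringsAsFactors = FALSE)
  }))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("hit filtering applies both strict thresholds", {
  hits <- rbind(mk_hit(e_value = 1e-30, qcov = 80),   # kept
                mk_hit(e_value = 1e-10, qcov = 80),   # e-value fails
                mk_hit(e_value = 1e-30, qcov = 60),   # coverage boundary fails
                mk_hit(e_value = 1e-20, qcov = 80))   # e-value boundary fails
  kept <- filter_hits(hits)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$e_value, 1e-30)
  # idempotent
  expect_equal(filter_hits(kept), kept)
  # monotone in the thresholds
  relaxed <- filter_hits(hits, screen_config(e_value_max = 1e-5,
                                             query_coverage_min = 50))
  expect_gte(nrow(relaxed), nrow(kept))
})

test_that("malformed hit rows are reported with their row number", {
  hits <- rbind(mk_hit(), mk_hit())
  hits$e_value[2] <- NA
  expect_error(filter_hits(hits), "row 2")
  hits2 <- rbind(mk_hit(), mk_hit(), mk_hit())
  hits2$query_coverage[3] <- 140
  expect_error(filter_hits(hits2), "row 3")
})

test_that("reciprocal confirmation uses the declared top-hit tie rules", {
  fam_map <- c(cifA_ref = "cifA", cifB_ref = "cifB", wmk_ref = "wmk")
  rh <- data.frame(candidate_id = "c1:1-100",
                   subject_id = c("cifA_ref", "cifB_ref"),
                   e_value = c(1e-50, 1e-30), bit_score = c(400, 300))
  expect_true(reciprocal_confirm("c1:1-100", rh, fam_map, "cifA"))
  expect_false(reciprocal_confirm("c1:1-100", rh, fam_map, "cifB"))
  # ties on e-value resolved by higher bit score
  rh2 <- data.frame(candidate_id = "c1:1-100",
                    subject_id = c("cifB_ref", "cifA_ref"),
                    e_value = c(1e-50, 1e-50), bit_score = c(300, 400))
  expect_true(reciprocal_confirm("c1:1-100", rh2, fam_map, "cifA"))
  # no reciprocal hits: unconfirmed, not an error
  expect_false(reciprocal_confirm("c1:9-99", rh, fam_map, "cifA"))
})

test_that("annotation concordance requires a same-strand majority overlap", {
  feats <- mk_features(list(start = 1000, end = 2199, strand = "+", id = "gA"),
                       list(start = 5000, end = 6199, strand = "-", id = "gB"))
  # fully inside a same-strand gene: kept
  h1 <- annotation_concordance(mk_hit(s_start = 1100, s_end = 2000), feats)
  expect_true(h1$kept)
  expect_equal(h1$feature_id, "gA")
  # opposite strand of the only overlapping gene: dropped
  h2 <- annotation_concordance(mk_hit(s_start = 5100, s_end = 6000), feats)
  expect_false(h2$kept)
  # 40% overlap misses the 50% default
  h3 <- annotation_concordance(mk_hit(s_start = 1800, s_end = 2799), feats)
  expect_false(h3$kept)
})

test_that("operon detection uses gene adjacency on the same strand", {
  # adjacent cifA + cifB: one operon
  f1 <- mk_features(list(start = 100, end = 1099, id = "gA"),
                    list(start = 1200, end = 2199, id = "gB"))
  a1 <- data.frame(feature_id = c("gA", "gB"), family = c("cifA", "cifB"))
  op1 <- detect_operons(a1, f1)
  expect_equal(op1$n_operons, 1)
  expect_equal(nrow(op1$orphans), 0)
  # lone cifA: one orphan
  op2 <- detect_operons(data.frame(feature_id = "gA", family = "cifA"), f1)
  expect_equal(op2$n_operons, 0)
  expect_equal(op2$orphans$family, "cifA")
  # an intervening gene breaks adjacency
  f3 <- mk_features(list(start = 100, end = 1099, id = "gA"),
                    list(start = 1200, end = 2199, id = "gX"),
                    list(start = 2300, end = 3299, id = "gB"))
  op3 <- detect_operons(data.frame(feature_id = c("gA", "gB"),
                                   family = c("cifA", "cifB")), f3)
  expect_equal(op3$n_operons, 0)
  expect_equal(nrow(op3$orphans), 2)
  # strand mismatch also breaks the operon
  f4 <- mk_features(list(start = 100, end = 1099, id = "gA", strand = "+"),
                    list(start = 1200, end = 2199, id = "gB", strand = "-"))
  op4 <- detect_operons(a1, f4)
  expect_equal(op4$n_operons, 0)
})

test_that("the full screen keeps every planted locus and kills every decoy", {
  plan <- locus_plan(n_operons = 2, n_orphan_cifA = 1, n_orphan_cifB = 1,
                     n_wmk = 3,
                     decoys = c("evalue", "qcov", "reciprocal", "annotation",
                                "strand"))
  tabs <- simulate_hit_tables(plan, seed = 5)
  call <- suppressMessages(
    screen_genome("genome_1", tabs$hits, tabs$reciprocal, tabs$family_map,
                  tabs$features))
  expect_equal(call$n_cif_operons, 2)
  expect_equal(call$n_orphan_cifA, 1)
  expect_equal(call$n_orphan_cifB, 1)
  expect_equal(call$n_wmk, 3)
  # conservation per cif family: confirmed = 2 x operons + orphans
  n_cif_confirmed <- sum(tabs$truth$expected_kept &
                           tabs$truth$family %in% c("cifA", "cifB"))
  expect_equal(n_cif_confirmed,
               2 * call$n_cif_operons + call$n_orphan_cifA +
                 call$n_orphan_cifB)
})

test_that("locus calls tabulate one row per genome", {
  calls <- lapply(1:3, function(i) {
    tabs <- simulate_hit_tables(locus_plan(genome_id = paste0("g", i),
                                           n_operons = 1, n_wmk = i - 1),
                                seed = i)
    suppressMessages(
      screen_genome(paste0("g", i), tabs$hits, tabs$reciprocal,
                    tabs$family_map, tabs$features))
  })
  tab <- tabulate_locus_calls(calls)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$n_wmk, c(0, 1, 2))
  expect_equal(tab$n_cif_operons, rep(1, 3))
  expect_equal(names(tab), c("genome_id", "n_cif_operons", "n_orphan_cifA",
                             "n_orphan_cifB", "n_wmk"))
})

test_that("hit tables and features round-trip through their file formats", {
  tabs <- simulate_hit_tables(locus_plan(n_operons = 1, n_wmk = 1), seed = 9)
  f <- tempfile(fileext = ".tsv")
  write_blast_tab(tabs$hits, f)
  hits2 <- read_blast_tab(f)
  expect_equal(hits2$query_id, tabs$hits$query_id)
  expect_equal(hits2$e_value, tabs$hits$e_value)
  skip_if_not_installed("rtracklayer")
  g <- tempfile(fileext = ".gff3")
  write_gff3(tabs$features, g)
  feats2 <- read_gff3(g)
  expect_equal(feats2$start, tabs$features$start)
  expect_equal(feats2$feature_id, tabs$features$feature_id)
  expect_equal(feats2$strand, tabs$features$strand)
})
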