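test_that("a read maps exactly where it came from", {
  ref1 <- random_genome(2000, 1)
  ref2 <- random_genome(2000, 2)
  rd <- c(r1 = substr(ref1, 501, 650))
  aln <- competitive_map(rd, c(ref1 = ref1, ref2 = ref2))
  expect_equal(aln$ref_id, "ref1")
  expect_equal(aln$ref_start, 500)
  expect_equal(aln$edit_distance, 0)
  expect_true(aln$mapped)
})

test_that("ties go to the first reference in input order", {
  ref1 <- random_genome(2000, 3)
  ref2 <- ref1  # identical: every placement is equidistant
  rd <- c(r1 = substr(ref1, 101, 250))
  aln <- competitive_map(rd, c(refA = ref1, refB = ref2))
  expect_equal(aln$ref_id, "refA")
})

test_that("empty read sets map to an empty alignment table", {
  aln <- competitive_map(setNames(character(0), character(0)),
                         c(ref = random_genome(2000, 4)))
  expect_equal(nrow(aln), 0)
})

test_that("reads sort to their true source at 3% reference divergence", {
  ev <- evolve_strains(sim_strain_config(seed = 19, genome_length = 20000,
                                         n_strains = 2,
                                         target_distances = 0.03))
  rs <- simulate_reads(ev$genomes,
                       sim_read_config(c(strain_01 = 0.5, strain_02 = 0.5),
                                       coverage = 7.5, read_length = 150,
                                       error_rate = 0, seed = 20))
  expect_gte(length(rs$reads), 500)
  aln <- competitive_map(rs$reads, ev$genomes)
  correct <- mean(aln$ref_id == rs$truth$strain, na.rm = TRUE)
  expect_gte(correct, 0.95)
  # competitive exclusivity: one row per read
  expect_equal(nrow(aln), length(rs$reads))
  expect_false(any(duplicated(aln$read_id)))
})

test_that("pure error-free coverage gives full breadth and zero het", {
  ev <- evolve_strains(sim_strain_config(seed = 5, genome_length = 10000,
                                         n_strains = 1,
                                         target_distances = 0))
  rs <- simulate_reads(ev$genomes,
                       sim_read_config(c(strain_01 = 1), coverage = 30,
                                       error_rate = 0, seed = 6))
  ms <- wolbshift:::map_and_stats(rs$reads, ev$genomes, detection_config())
  expect_gt(ms$stats$breadth, 0.999)
  expect_equal(ms$stats$het_sites, 0)
  expect_lt(abs(ms$stats$mean_depth - 30), 2)
})

test_that("a 50/50 mixture mapped to one reference shows the divergence as het density", {
  ev <- evolve_strains(sim_strain_config(seed = 29, genome_length = 20000,
                                         n_strains = 2,
                                         target_distances = 0.02))
  rs <- simulate_reads(ev$genomes,
                       sim_read_config(c(strain_01 = 0.5, strain_02 = 0.5),
                                       coverage = 30, error_rate = 0,
                                       seed = 30))
  ms <- wolbshift:::map_and_stats(rs$reads, ev$genomes["strain_01"],
                                  detection_config())
  # expected het density ~ realized divergence (sites/kb)
  expected <- 1000 * ev$realized_distances[1, 2]
  expect_lt(abs(ms$stats$het_per_kb - expected) / expected, 0.30)
})

test_that("zero coverage yields zero breadth and het density", {
  m <- matrix(0L, 4, 100, dimnames = list(c("A", "C", "G", "T"), NULL))
  st <- coverage_stats(m, "ref")
  expect_equal(st$breadth, 0)
  expect_equal(st$het_per_kb, 0)
})

test_that("low error rates do not push het density over the threshold", {
  ev <- evolve_strains(sim_strain_config(seed = 41, genome_length = 10000,
                                         n_strains = 1,
                                         target_distances = 0))
  rs <- simulate_reads(ev$genomes,
                       sim_read_config(c(strain_01 = 1), coverage = 25,
                                       error_rate = 0.005, seed = 42))
  ms <- wolbshift:::map_and_stats(rs$reads, ev$genomes, detection_config())
  expect_lt(ms$stats$het_per_kb, 10)
})

test_that("screening classifies empty and on-panel samples correctly", {
  ev <- evolve_strains(sim_strain_config(seed = 8, genome_length = 20000,
                                         n_strains = 3,
                                         target_distances = 0.04))
  # zero reads: uninfected
  scr0 <- screen_sample(setNames(character(0), character(0)), ev$genomes)
  expect_equal(scr0$preliminary_status, "uninfected")
  # single-strain sample at 25x: its strain ranks first with breadth > 0.90
  rs <- simulate_reads(ev$genomes,
                       sim_read_config(c(strain_02 = 1), coverage = 25,
                                       seed = 9))
  scr <- screen_sample(rs$reads, ev$genomes)
  expect_equal(scr$ranking$ref_id[1], "strain_02")
  expect_gt(scr$ranking$breadth[1], 0.90)
})

test_that("a strain 8% diverged from the whole panel stays below the infection breadth", {
  ev <- evolve_strains(sim_strain_config(seed = 33, genome_length = 20000,
                                         n_strains = 2,
                                         target_distances = 0.08))
  panel <- ev$genomes["strain_01"]
  rs <- simulate_reads(ev$genomes,
                       sim_read_config(c(strain_02 = 1), coverage = 25,
                                       seed = 34))
  scr <- screen_sample(rs$reads, panel)
  expect_lt(max(scr$ranking$breadth), 0.90)
  if (scr$preliminary_status == "candidate_infected")
    expect_true("ambiguous_breadth" %in% scr$flags)
})

test_that("iterative assignment recovers single and dual infections", {
  ev <- evolve_strains(sim_strain_config(seed = 10, genome_length = 20000,
                                         n_strains = 4,
                                         target_distances = 0.04))
  single <- simulate_reads(ev$genomes,
                           sim_read_config(c(strain_03 = 1), coverage = 25,
                                           seed = 11))
  call1 <- detect_sample(single$reads, ev$genomes)
  expect_equal(call1$status, "infected")
  expect_equal(call1$strain_ids, "strain_03")
  expect_length(call1$iteration_log, 1)

  dual <- simulate_reads(ev$genomes,
                         sim_read_config(c(strain_01 = 0.5, strain_04 = 0.5),
                                         coverage = 25, seed = 12))
  call2 <- detect_sample(dual$reads, ev$genomes)
  expect_equal(call2$status, "infected")
  expect_setequal(call2$strain_ids, c("strain_01", "strain_04"))
  # the log reconstructs every decision and never exceeds the ranking
  expect_lte(max(lengths(lapply(call2$iteration_log, `[[`, "genomes"))),
             length(ev$genomes))
})

test_that("dual-infection recovery holds across seeds", {
  hits <- 0
  n_seeds <- 20
  for (seed in seq_len(n_seeds)) {
    ev <- evolve_strains(sim_strain_config(seed = 100 + seed,
                                           genome_length = 20000,
                                           n_strains = 4,
                                           target_distances = 0.03))
    rs <- simulate_reads(ev$genomes,
                         sim_read_config(c(strain_01 = 0.5, strain_02 = 0.5),
                                         coverage = 25, seed = 200 + seed))
    call <- detect_sample(rs$reads, ev$genomes)
    if (setequal(call$strain_ids, c("strain_01", "strain_02"))) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("the default decision thresholds are 90% breadth and 10 het/kb", {
  cfg <- detection_config()
  expect_equal(cfg$breadth_infected, 0.90)
  expect_equal(cfg$het_max_per_kb, 10)
})

test_that("consensus calling recovers the true strain over a related reference", {
  ev <- evolve_strains(sim_strain_config(seed = 14, genome_length = 10000,
                                         n_strains = 2,
                                         target_distances = 0.02))
  refA <- ev$genomes["strain_01"]
  # error-free reads from the reference itself reproduce it
  rsA <- simulate_reads(ev$genomes,
                        sim_read_config(c(strain_01 = 1), coverage = 30,
                                        error_rate = 0, seed = 15))
  msA <- wolbshift:::map_and_stats(rsA$reads, refA, detection_config())
  expect_identical(call_consensus(msA$piles[[1]], refA[[1]]), refA[[1]])

  # reads from strain B mapped onto ref A: consensus closer to B than to A
  rsB <- simulate_reads(ev$genomes,
                        sim_read_config(c(strain_02 = 1), coverage = 30,
                                        error_rate = 0, seed = 16))
  msB <- wolbshift:::map_and_stats(rsB$reads, refA, detection_config())
  cons <- call_consensus(msB$piles[[1]], refA[[1]])
  expect_lt(p_distance(cons, ev$genomes[["strain_02"]]),
            p_distance(cons, ev$genomes[["strain_01"]]))

  # all-zero coverage falls back to the reference with a warning
  empty <- matrix(0L, 4, nchar(refA[[1]]))
  expect_warning(cons0 <- call_consensus(empty, refA[[1]]), "no coverage")
  expect_identical(cons0, refA[[1]])
})
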