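test_that("zero target distance gives identical genomes", {
  ev <- evolve_strains(sim_strain_config(seed = 1, genome_length = 5000,
                                         n_strains = 3, target_distances = 0))
  expect_length(ev$genomes, 3)
  expect_true(all(nchar(ev$genomes) == 5000))
  expect_identical(unname(ev$genomes[1]), unname(ev$genomes[2]))
  expect_identical(unname(ev$genomes[1]), unname(ev$genomes[3]))
  expect_true(all(ev$realized_distances == 0))
})

test_that("realized p-distance tracks the multiple-hit expectation", {
  # two lineages, total 0.02 subs/site: expected p ~ d (1 - d/2)
  d <- 0.02
  L <- 20000
  ev <- evolve_strains(sim_strain_config(seed = 42, genome_length = L,
                                         n_strains = 2, target_distances = d))
  expected <- d * (1 - d / 2)
  se <- sqrt(expected * (1 - expected) / L)
  expect_lt(abs(ev$realized_distances[1, 2] - expected), 3 * se)
})

test_that("realized distances never exceed targets by more than 3 SE", {
  for (seed in 1:5) {
    d <- 0.05
    L <- 10000
    ev <- evolve_strains(sim_strain_config(seed = seed, genome_length = L,
                                           n_strains = 4,
                                           target_distances = d))
    se <- sqrt(d * (1 - d) / L)
    off <- ev$realized_distances[upper.tri(ev$realized_distances)]
    expect_true(all(off <= d + 3 * se))
  }
})

test_that("strain evolution is byte-identical under the same seed", {
  cfg <- sim_strain_config(seed = 9, genome_length = 4000, n_strains = 2,
                           target_distances = 0.03)
  ev1 <- evolve_strains(cfg)
  ev2 <- evolve_strains(cfg)
  expect_identical(ev1$genomes, ev2$genomes)
  f1 <- tempfile(fileext = ".fasta")
  f2 <- tempfile(fileext = ".fasta")
  write_genomes_fasta(ev1$genomes, f1)
  write_genomes_fasta(ev2$genomes, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("saturated target distances are rejected", {
  expect_error(sim_strain_config(seed = 1, target_distances = 0.75),
               "0.70")
})

test_that("error-free single-strain reads are exact substrings", {
  ev <- evolve_strains(sim_strain_config(seed = 2, genome_length = 3000,
                                         n_strains = 1, target_distances = 0))
  rs <- simulate_reads(ev$genomes,
                       sim_read_config(c(strain_01 = 1), coverage = 5,
                                       read_length = 100, error_rate = 0,
                                       seed = 3))
  g <- ev$genomes[["strain_01"]]
  ok <- mapply(function(rd, st) substr(g, st + 1, st + 100) == rd,
               rs$reads, rs$truth$start)
  expect_true(all(ok))
})

test_that("read counts follow the coverage formula and mixture weights", {
  ev <- evolve_strains(sim_strain_config(seed = 4, genome_length = 20000,
                                         n_strains = 2,
                                         target_distances = 0.02))
  rs <- simulate_reads(ev$genomes,
                       sim_read_config(c(strain_01 = 1), coverage = 30,
                                       read_length = 150, seed = 5))
  expect_equal(length(rs$reads), 4000)          # 30 x 20000 / 150
  expect_equal(nrow(rs$truth), length(rs$reads))  # label conservation
  mix <- simulate_reads(ev$genomes,
                        sim_read_config(c(strain_01 = 0.5, strain_02 = 0.5),
                                        coverage = 30, read_length = 150,
                                        seed = 6))
  n <- table(mix$truth$strain)
  # per-strain counts are fixed by rounding the expectation, so equal here
  expect_lt(abs(n[["strain_01"]] - n[["strain_02"]]),
            3 * sqrt(sum(n) * 0.25) + 1)
})

test_that("read-set configuration is validated", {
  g <- c(strain_01 = random_genome(1000, 1))
  expect_error(sim_read_config(c(strain_01 = 1), coverage = 0), "coverage")
  expect_error(sim_read_config(c(strain_01 = 1), error_rate = 0.2),
               "error_rate")
  expect_error(sim_read_config(c(strain_01 = 0.6, strain_02 = 0.6)),
               "sum to 1")
  expect_error(simulate_reads(g, sim_read_config(c(nope = 1))), "unknown")
})

test_that("an all-uninfected host system has an empty occurrence matrix", {
  w <- c(codivergence = 0, horizontal = 0, introgressive = 0, loss = 0,
         uninfected = 1)
  hs <- simulate_host_system(host_system_config(n_pairs = 4,
                                                scenario_weights = w,
                                                seed = 3))
  expect_true(all(hs$occurrence$counts == 0))
  expect_length(infected_species(hs$occurrence), 0)
})

test_that("introgressive pairs have mito distance matching the clock", {
  w <- c(codivergence = 0, horizontal = 0, introgressive = 1, loss = 0,
         uninfected = 0)
  cfg <- host_system_config(n_pairs = 6, scenario_weights = w,
                            mito_length = 20000, seed = 8)
  hs <- simulate_host_system(cfg)
  for (i in seq_len(6)) {
    t_mito_my <- hs$truth$mito_split_gen[i] / (cfg$generations_per_year * 1e6)
    d_target <- cfg$mito_rate / 100 * t_mito_my
    p_exp <- jc_expected_distance(d_target)
    p_obs <- p_distance(hs$mito_seqs[[hs$pair_table$species_a[i]]],
                        hs$mito_seqs[[hs$pair_table$species_b[i]]])
    se <- sqrt(p_exp * (1 - p_exp) / cfg$mito_length)
    expect_lt(abs(p_obs - p_exp), 4 * se + 1e-4)
    # introgression: symbiont split equals mito split, younger than host
    expect_equal(hs$truth$wolb_split_gen[i], hs$truth$mito_split_gen[i])
    expect_lt(hs$truth$wolb_split_gen[i], hs$truth$split_gen[i])
  }
})

test_that("planted hit tables honour their truth bookkeeping", {
  # one adjacent cifA+cifB pair, nothing else
  tabs <- simulate_hit_tables(locus_plan(n_operons = 1), seed = 1)
  call <- suppressMessages(
    screen_genome("genome_1", tabs$hits, tabs$reciprocal, tabs$family_map,
                  tabs$features))
  expect_equal(call$n_cif_operons, 1)
  expect_equal(call$n_orphan_cifA + call$n_orphan_cifB, 0)

  # a low-significance decoy never survives the e-value filter
  tabs2 <- simulate_hit_tables(locus_plan(n_operons = 0, n_wmk = 1,
                                          decoys = "evalue"), seed = 2)
  kept <- filter_hits(tabs2$hits)
  decoy_cand <- tabs2$truth$candidate_id[tabs2$truth$kind == "decoy"]
  span <- with(kept, paste0(subject_id, ":", pmin(s_start, s_end), "-",
                            pmax(s_start, s_end)))
  expect_false(decoy_cand %in% span)

  # six wmk copies tabulate as six
  tabs3 <- simulate_hit_tables(locus_plan(n_operons = 0, n_wmk = 6), seed = 3)
  call3 <- suppressMessages(
    screen_genome("genome_1", tabs3$hits, tabs3$reciprocal, tabs3$family_map,
                  tabs3$features))
  expect_equal(call3$n_wmk, 6)
})

test_that("turnover histories carry one set difference per event", {
  ti <- simulate_turnover_history(n_pairs = 10, rate = 0.3,
                                  split_gen = 5e7, seed = 4)
  expect_length(ti$pairs, 10)
  for (p in ti$pairs) {
    shared <- intersect(p$strains_a, p$strains_b)
    expect_length(shared, 1)  # the shared ancestral strain
  }
})
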