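#' Published assembly quality metrics of twelve butterfly Wolbachia genomes
#'
#' The quality-metric table of the twelve Wolbachia genomes assembled from
#' European butterfly hosts, shipped as a worked example for
#' [summarize_assemblies()].
#'
#' @return data.frame with one row per genome (span, N50, GC, BUSCO, CDS
#'   counts, ...).
#' @export
assembly_metrics <- function() {
  read.delim(system.file("extdata", "assembly_metrics.tsv",
                         package = "wolbshift"), check.names = TRUE)
}

#' Published CI/MK locus counts of the same twelve genomes
#'
#' Counts of consecutive cifA+cifB operons, orphan cifA/cifB and wmk
#' candidates per genome, shipped as a reference shape for
#' [tabulate_locus_calls()] output.
#'
#' @return data.frame with one row per genome.
#' @export
ci_mk_locus_counts <- function() {
  read.delim(system.file("extdata", "ci_mk_locus_counts.tsv",
                         package = "wolbshift"), check.names = TRUE)
}

#' Summaries of assembly quality metrics
#'
#' Per numeric column: minimum, maximum and arithmetic mean. Base-pair and
#' count means (span, N50, longest, contigs, CDS, rRNA, tRNA) are rounded to
#' integers, GC to 3 decimals, everything else to 2.
#'
#' @param metrics data.frame of assembly metrics (>= 1 row), e.g.
#'   [assembly_metrics()].
#' @return data.frame: metric, min, max, mean.
#' @export
summarize_assemblies <- function(metrics) {
  stopifnot(nrow(metrics) >= 1)
  num <- names(metrics)[vapply(metrics, is.numeric, logical(1))]
  int_cols <- c("n_contigs", "span", "n50", "longest", "n_cds", "n_rrna",
                "n_trna")
  out <- do.call(rbind, lapply(num, function(cl) {
    x <- metrics[[cl]]
    m <- mean(x)
    m <- if (cl %in% int_cols) round(m) else if (cl == "gc") round(m, 3) else
      round(m, 2)
    data.frame(metric = cl, min = min(x), max = max(x), mean = m,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

preflight <- function(ok, what) {
  if (!ok) stop("missing input for requested stage: ", what, call. = FALSE)
}

log_line <- function(log_path, ...) {
  cat(paste0(..., "\n"), file = log_path, append = TRUE)
}

#' Run the full pipeline end to end
#'
#' Executes simulate -> dereplicate -> detect -> share-test -> date ->
#' turnover -> screen, as configured, writing every stage's TSV/JSON outputs
#' plus a plain-text log of seeds and thresholds into `out_dir`. Re-running
#' with the same config reproduces the outputs. Missing inputs for a
#' requested stage are reported before any stage runs.
#'
#' @param config Named list (or path to a YAML file with the same keys):
#'   \describe{
#'     \item{seed}{master RNG seed (required).}
#'     \item{simulate}{list(n_strains, genome_length, distance, coverage,
#'       read_length, error_rate, n_pairs): generates the strain panel,
#'       one single-infection read set per strain, and a host pair system.
#'       When absent, occurrence/pairs must be given as files.}
#'     \item{occurrence_tsv, pairs_tsv}{file inputs for the share test when
#'       not simulating.}
#'     \item{stages}{character vector among simulate, derep, detect,
#'       share_test, date, turnover, screen, summarize.}
#'   }
#' @param out_dir Output directory (created if needed).
#' @return Named list of stage results, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML config requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$seed))
  stages <- config$stages %||% c("simulate", "derep", "detect", "share_test",
                                 "date", "turnover", "screen", "summarize")
  sim_requested <- "simulate" %in% stages && !is.null(config$simulate)
  # pre-flight: every requested stage must have its inputs
  if (!sim_requested) {
    for (st in intersect(stages, c("derep", "detect", "date", "turnover",
                                   "screen")))
      preflight(FALSE, paste0(st, " requires the simulate stage in this ",
                              "configuration"))
    if ("share_test" %in% stages) {
      preflight(!is.null(config$occurrence_tsv), "occurrence_tsv")
      preflight(!is.null(config$pairs_tsv), "pairs_tsv")
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  cat("", file = log_path)
  log_line(log_path, "seed\t", config$seed)
  results <- list()
  seed <- as.integer(config$seed)

  if (sim_requested) {
    sc <- config$simulate
    n_strains <- sc$n_strains %||% 4L
    gl <- sc$genome_length %||% 20000L
    dist <- sc$distance %||% 0.04
    ev <- evolve_strains(sim_strain_config(seed, gl, n_strains, dist))
    write_genomes_fasta(ev$genomes, file.path(out_dir, "strain_panel.fasta"))
    samples <- list()
    for (i in seq_along(ev$genomes)) {
      rc <- sim_read_config(setNames(1, names(ev$genomes)[i]),
                            coverage = sc$coverage %||% 25,
                            read_length = sc$read_length %||% 150L,
                            error_rate = sc$error_rate %||% 0.002,
                            seed = seed + i)
      samples[[names(ev$genomes)[i]]] <- simulate_reads(ev$genomes, rc)
      write_reads_fastq(samples[[i]]$reads,
                        file.path(out_dir, sprintf("sample_%02d.fastq", i)))
    }
    host <- simulate_host_system(host_system_config(
      n_pairs = sc$n_pairs %||% 10L, seed = seed + 100L))
    write_occurrence_tsv(host$occurrence,
                         file.path(out_dir, "occurrence.tsv"))
    write.table(host$pair_table, file.path(out_dir, "pairs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    log_line(log_path, "simulate\tn_strains=", n_strains, " distance=", dist)
    results$simulate <- list(strains = ev, samples = samples, host = host)
  }

  if ("derep" %in% stages) {
    dcfg <- derep_config()
    cs <- dereplicate(results$simulate$strains$genomes, dcfg)
    write.table(data.frame(genome = names(cs$membership),
                           representative = cs$membership),
                file.path(out_dir, "clusters.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    log_line(log_path, "derep\tani_threshold=", dcfg$ani_threshold,
             " maf_threshold=", dcfg$maf_threshold)
    results$derep <- cs
  }

  if ("detect" %in% stages) {
    cfg <- detection_config()
    panel <- results$simulate$strains$genomes
    if (!is.null(results$derep))
      panel <- panel[vapply(results$derep$clusters,
                            function(cl) cl$representative_id, character(1))]
    calls <- lapply(results$simulate$samples, function(s)
      detect_sample(s$reads, panel, cfg))
    tab <- data.frame(sample = names(calls),
                      status = vapply(calls, function(x) x$status,
                                      character(1)),
                      strains = vapply(calls, function(x)
                        paste(x$strain_ids, collapse = ","), character(1)))
    write.table(tab, file.path(out_dir, "detection.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    log_line(log_path, "detect\tbreadth_infected=", cfg$breadth_infected,
             " het_max_per_kb=", cfg$het_max_per_kb)
    results$detect <- calls
  }

  if ("share_test" %in% stages) {
    if (sim_requested) {
      occ <- results$simulate$host$occurrence
      pt <- results$simulate$host$pair_table
    } else {
      occ <- read_occurrence_tsv(config$occurrence_tsv)
      pt <- read.delim(config$pairs_tsv)
    }
    st <- sharing_permutation_test(occ, pt, statistic = "shared_count",
                                   filter = "both_infected",
                                   n_reps = config$n_reps %||% 30000L,
                                   seed = seed + 200L)
    jsonlite::write_json(
      list(statistic = st$statistic_name, observed = st$observed,
           p_emp = st$p_emp, n_reps = st$n_reps, filter = st$filter,
           seed = st$seed),
      file.path(out_dir, "share_test.json"), auto_unbox = TRUE, digits = NA)
    log_line(log_path, "share_test\tn_reps=", st$n_reps, " seed=", st$seed)
    results$share_test <- st
  }

  if ("date" %in% stages) {
    clock <- clock_config()
    host <- results$simulate$host
    both <- host$pair_table$scenario %in% c("codivergence", "horizontal",
                                            "introgressive")
    rows <- list()
    for (i in which(both)) {
      a <- host$pair_table$species_a[i]; b <- host$pair_table$species_b[i]
      d <- p_distance(host$wolb_seqs[[a]], host$wolb_seqs[[b]])
      rng <- wolb_split_range(jc_correct(d), clock)$generations
      host_rng <- time_range(host$pair_table$split_gen[i] * 0.9,
                             host$pair_table$split_gen[i] * 1.1,
                             "generations")
      rows[[length(rows) + 1L]] <- data.frame(
        species_a = a, species_b = b, wolb_lo = rng$lo, wolb_hi = rng$hi,
        verdict = classify_congruence(rng, host_rng))
    }
    dt <- if (length(rows)) do.call(rbind, rows) else NULL
    if (!is.null(dt))
      write.table(dt, file.path(out_dir, "dating.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    log_line(log_path, "date\twolb_rate=[", clock$wolb_rate_min, ",",
             clock$wolb_rate_max, "] divergence_factor=",
             clock$divergence_factor)
    results$date <- dt
  }

  if ("turnover" %in% stages) {
    host <- results$simulate$host
    occ <- host$occurrence
    pairs <- lapply(seq_len(nrow(host$pair_table)), function(i) {
      list(strains_a = species_strains(occ, host$pair_table$species_a[i]),
           strains_b = species_strains(occ, host$pair_table$species_b[i]),
           split_gen = host$pair_table$split_gen[i])
    })
    rate <- turnover_rate(structure(list(pairs = pairs),
                                    class = "turnover_input"))
    jsonlite::write_json(list(rate_per_million_generations = rate),
                         file.path(out_dir, "turnover.json"),
                         auto_unbox = TRUE, digits = NA)
    log_line(log_path, "turnover\trate=", rate)
    results$turnover <- rate
  }

  if ("screen" %in% stages) {
    plan <- locus_plan(genome_id = "sim_genome", n_operons = 1L, n_wmk = 2L,
                       decoys = c("evalue", "reciprocal"))
    tabs <- simulate_hit_tables(plan, seed = seed + 300L)
    call <- screen_genome("sim_genome", tabs$hits, tabs$reciprocal,
                          tabs$family_map, tabs$features)
    write.table(tabulate_locus_calls(list(call)),
                file.path(out_dir, "locus_screen.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    log_line(log_path, "screen\te_value_max=1e-20 query_coverage_min=60")
    results$screen <- call
  }

  if ("summarize" %in% stages) {
    summ <- summarize_assemblies(assembly_metrics())
    write.table(summ, file.path(out_dir, "assembly_summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    log_line(log_path, "summarize\trows=", nrow(summ))
    results$summarize <- summ
  }
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
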