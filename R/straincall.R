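#' Strain-detection configuration
#'
#' Decision thresholds for infection calling: a sample is confirmed infected
#' when breadth of coverage on a reference exceeds `breadth_infected`;
#' coinfection with a second strain is suspected when the density of
#' "heterozygous" sites (positions where competitively mapped reads support
#' two or more alleles) exceeds `het_max_per_kb` -- 10 sites/kb is
#' equivalent to an ANI below 99% between the mixed strains.
#'
#' @param breadth_infected Breadth above which a sample is called infected.
#' @param het_max_per_kb Heterozygous-site density (sites/kb) above which
#'   coinfection is suspected.
#' @param min_allele_support Minimum reads per allele for a site to count as
#'   heterozygous.
#' @param max_read_divergence Maximum edit distance for a read to map, as a
#'   fraction of read length.
#' @param uninfected_breadth Breadth below which (for every reference) a
#'   sample is preliminarily uninfected.
#' @param consensus_min_depth Minimum depth for the consensus caller to use
#'   the majority allele rather than the reference base.
#' @param seed_length,n_seeds,min_seed_hits Mapper seeding policy: k-mer
#'   length, number of seeds sampled evenly along each read, and the minimum
#'   number of concordant seed hits required to evaluate a placement.
#' @return Object of class `detection_config`.
#' @export
detection_config <- function(breadth_infected = 0.90, het_max_per_kb = 10,
                             min_allele_support = 2L,
                             max_read_divergence = 0.10,
                             uninfected_breadth = 0.10,
                             consensus_min_depth = 3L,
                             seed_length = 25L, n_seeds = 7L,
                             min_seed_hits = 3L) {
  if (!(uninfected_breadth > 0 && uninfected_breadth < breadth_infected &&
        breadth_infected <= 1))
    stop("need 0 < uninfected_breadth < breadth_infected <= 1")
  if (het_max_per_kb <= 0) stop("het_max_per_kb must be positive")
  structure(list(breadth_infected = breadth_infected,
                 het_max_per_kb = het_max_per_kb,
                 min_allele_support = as.integer(min_allele_support),
                 max_read_divergence = max_read_divergence,
                 uninfected_breadth = uninfected_breadth,
                 consensus_min_depth = as.integer(consensus_min_depth),
                 seed_length = as.integer(seed_length),
                 n_seeds = as.integer(n_seeds),
                 min_seed_hits = as.integer(min_seed_hits)),
            class = "detection_config")
}

#' Heterozygous-site density implied by an ANI, and vice versa
#'
#' `het_rate_to_ani(10)` is 99: 10 heterozygous sites per kilobase between
#' two mixed strains corresponds to 99% nucleotide identity between them.
#'
#' @param het_per_kb Heterozygous sites per kilobase.
#' @return Equivalent ANI in percent.
#' @export
het_rate_to_ani <- function(het_per_kb) 100 * (1 - het_per_kb / 1000)

#' Competitive read mapping against a reference panel
#'
#' Each read is assigned to its single lowest-edit-distance placement across
#' all references (ungapped, substitution-only model); ties are broken by
#' reference input order, then leftmost position. A read is unmapped when
#' its best edit distance exceeds `max_read_divergence x read length` or no
#' placement gathers `min_seed_hits` concordant seed-k-mer hits.
#'
#' @param reads Named character vector of read sequences (may be empty).
#' @param references Named character vector of reference sequences (>= 1).
#' @param config A [detection_config()].
#' @return data.frame: read_id, ref_id (NA if unmapped), ref_start (0-based),
#'   edit_distance, mapped.
#' @export
competitive_map <- function(reads, references, config = detection_config()) {
  stopifnot(length(references) >= 1, !is.null(names(references)))
  if (length(reads) == 0)
    return(data.frame(read_id = character(0), ref_id = character(0),
                      ref_start = integer(0), edit_distance = integer(0),
                      mapped = logical(0)))
  res <- cpp_map_reads(unname(reads), unname(references),
                       config$seed_length, config$n_seeds,
                       config$min_seed_hits, config$max_read_divergence)
  data.frame(read_id = names(reads),
             ref_id = names(references)[res$ref],
             ref_start = res$pos, edit_distance = res$dist,
             mapped = res$mapped, stringsAsFactors = FALSE)
}

#' Allele-count pileup over a reference panel
#'
#' @param reads Named character vector of read sequences.
#' @param alignments Alignments from [competitive_map()] over these reads.
#' @param references Named character vector of reference sequences.
#' @return Named list (one per reference) of 4 x L integer matrices with
#'   rows A, C, G, T.
#' @export
pileup <- function(reads, alignments, references) {
  stopifnot(all(stats::na.omit(alignments$ref_id) %in% names(references)))
  ridx <- match(alignments$ref_id, names(references))
  mats <- cpp_pileup(unname(reads[alignments$read_id]),
                     ifelse(is.na(ridx), NA_integer_, ridx),
                     alignments$ref_start, alignments$mapped,
                     nchar(unname(references)))
  names(mats) <- names(references)
  mats
}

#' Per-reference coverage and heterozygosity statistics
#'
#' A site is heterozygous when at least two distinct bases each have
#' `min_allele_support` supporting reads. Breadth is the fraction of
#' reference positions with depth >= 1; het density is per kilobase of
#' covered bases (0 when nothing is covered).
#'
#' @param columns Pileup matrix for one reference (4 x L).
#' @param ref_id Reference identifier to report.
#' @param config A [detection_config()].
#' @return One-row data.frame: ref_id, breadth, mean_depth, covered_bases,
#'   het_sites, het_per_kb.
#' @export
coverage_stats <- function(columns, ref_id, config = detection_config()) {
  depth <- colSums(columns)
  covered <- sum(depth >= 1L)
  het <- sum(colSums(columns >= config$min_allele_support) >= 2L)
  data.frame(ref_id = ref_id,
             breadth = covered / ncol(columns),
             mean_depth = mean(depth),
             covered_bases = covered,
             het_sites = het,
             het_per_kb = if (covered == 0) 0 else 1000 * het / covered,
             stringsAsFactors = FALSE)
}

# map + pileup + stats for a set of references, in one pass
map_and_stats <- function(reads, references, config) {
  aln <- competitive_map(reads, references, config)
  piles <- pileup(reads, aln, references)
  stats <- do.call(rbind, Map(coverage_stats, piles, names(piles),
                              MoreArgs = list(config = config)))
  rownames(stats) <- NULL
  list(alignments = aln, piles = piles, stats = stats)
}

#' Initial screen of a sample against the dereplicated panel
#'
#' Competitively maps the sample reads against all panel representatives and
#' ranks them by breadth of coverage (descending; ties keep panel order).
#' The sample is preliminarily uninfected when no reference reaches
#' `uninfected_breadth` ("almost no mapped reads"). A best breadth between
#' `uninfected_breadth` and `breadth_infected` is flagged ambiguous (e.g. a
#' strain diverged from everything in the panel).
#'
#' @param reads Named character vector of sample reads.
#' @param references Named character vector of panel representatives.
#' @param config A [detection_config()].
#' @return List: `ranking` (stats data.frame sorted by breadth),
#'   `preliminary_status` ("uninfected" or "candidate_infected") and
#'   `flags`.
#' @export
screen_sample <- function(reads, references, config = detection_config()) {
  stopifnot(length(references) >= 1)
  ms <- map_and_stats(reads, references, config)
  ord <- order(-ms$stats$breadth)
  ranking <- ms$stats[ord, , drop = FALSE]
  rownames(ranking) <- NULL
  best <- if (nrow(ranking)) ranking$breadth[1] else 0
  status <- if (best < config$uninfected_breadth) "uninfected" else
    "candidate_infected"
  flags <- character(0)
  if (status == "candidate_infected" && best <= config$breadth_infected)
    flags <- "ambiguous_breadth"
  list(ranking = ranking, preliminary_status = status, flags = flags)
}

#' Iterative strain assignment for one sample
#'
#' Starting from the best-screening reference, the read set is competitively
#' remapped against a growing genome set: while any reference in the current
#' set shows a heterozygous-site density above `het_max_per_kb` (evidence of
#' an unexplained second strain), the next reference in the screening
#' ranking is added. When three or more genomes accumulate, an extra mapping
#' against only the first and last added genomes is tried; if both then
#' satisfy the het threshold, the intermediate genomes are dropped (they were
#' soaking up reads from a single strain they resemble). The sample is
#' infected when any final reference exceeds `breadth_infected`, and the
#' strains assigned are the final references above that breadth.
#'
#' @param reads Named character vector of sample reads.
#' @param references Named character vector of all panel representatives.
#' @param ranking Character vector of reference ids in screening order
#'   (e.g. `screen_sample(...)$ranking$ref_id`).
#' @param config A [detection_config()].
#' @return List of class `infection_call`: status ("infected"/"uninfected"),
#'   strain_ids, final_stats, flags, iteration_log (one entry per mapping
#'   round: genome set and per-reference stats).
#' @export
iterate_strains <- function(reads, references, ranking,
                            config = detection_config()) {
  stopifnot(all(ranking %in% names(references)), length(ranking) >= 1)
  G <- ranking[1]
  log <- list()
  flags <- character(0)
  repeat {
    ms <- map_and_stats(reads, references[G], config)
    log[[length(log) + 1L]] <- list(genomes = G, stats = ms$stats)
    if (all(ms$stats$het_per_kb <= config$het_max_per_kb)) break
    nxt <- setdiff(ranking, G)
    if (!length(nxt)) {
      flags <- c(flags, "unresolved_coinfection")
      break
    }
    G <- c(G, nxt[1])
  }
  final_stats <- log[[length(log)]]$stats
  if (length(G) >= 3) {
    pair <- c(G[1], G[length(G)])
    ms2 <- map_and_stats(reads, references[pair], config)
    log[[length(log) + 1L]] <- list(genomes = pair, stats = ms2$stats,
                                    shortcut = TRUE)
    if (all(ms2$stats$het_per_kb <= config$het_max_per_kb)) {
      G <- pair
      final_stats <- ms2$stats
      flags <- setdiff(flags, "unresolved_coinfection")
    }
  }
  infected <- any(final_stats$breadth > config$breadth_infected)
  strains <- final_stats$ref_id[final_stats$breadth > config$breadth_infected]
  if ("unresolved_coinfection" %in% flags) infected <- TRUE
  structure(list(status = if (infected) "infected" else "uninfected",
                 strain_ids = if (infected) strains else character(0),
                 final_stats = final_stats, flags = flags,
                 iteration_log = log),
            class = "infection_call")
}

#' Screen and iterate: full detection of one sample
#'
#' Runs [screen_sample()] and, unless the sample is preliminarily
#' uninfected, [iterate_strains()].
#'
#' @inheritParams screen_sample
#' @return An `infection_call` (see [iterate_strains()]); uninfected screens
#'   short-circuit with an empty strain list.
#' @export
detect_sample <- function(reads, references, config = detection_config()) {
  scr <- screen_sample(reads, references, config)
  if (scr$preliminary_status == "uninfected")
    return(structure(list(status = "uninfected", strain_ids = character(0),
                          final_stats = scr$ranking, flags = scr$flags,
                          iteration_log = list()),
                     class = "infection_call"))
  call <- iterate_strains(reads, references, scr$ranking$ref_id, config)
  call$flags <- union(call$flags, scr$flags)
  call
}

#' Majority-rule consensus from a pileup
#'
#' Per position: the majority allele where depth reaches
#' `consensus_min_depth`, otherwise the reference base. Ties go to the
#' reference base when it is among the tied alleles, otherwise to the
#' alphabetically first base. With no coverage at all the reference is
#' returned with a warning.
#'
#' @param columns Pileup matrix for the reference (4 x L).
#' @param ref Reference sequence (character scalar).
#' @param config A [detection_config()].
#' @return Consensus sequence of the same length as `ref`.
#' @export
call_consensus <- function(columns, ref, config = detection_config()) {
  L <- nchar(ref)
  stopifnot(ncol(columns) == L)
  depth <- colSums(columns)
  if (all(depth == 0)) {
    warning("no coverage at all; consensus equals the reference")
    return(ref)
  }
  ref_int <- dna_to_int(ref)
  maj <- max.col(t(columns), ties.method = "first")
  maxcnt <- columns[cbind(maj, seq_len(L))]
  ref_cnt <- columns[cbind(ref_int, seq_len(L))]
  maj[!is.na(ref_int) & ref_cnt == maxcnt] <-
    ref_int[!is.na(ref_int) & ref_cnt == maxcnt]
  out <- ifelse(depth >= config$consensus_min_depth,
                c("A", "C", "G", "T")[maj],
                strsplit(ref, "", fixed = TRUE)[[1]])
  paste(out, collapse = "")
}
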