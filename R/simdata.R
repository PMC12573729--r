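#' Configuration for simulating a set of related strain genomes
#'
#' Pairwise divergence targets are expected substitutions per site
#' accumulated between the two lineages (multiple hits allowed, so the
#' realized proportion of differing sites is at most the target).
#'
#' @param seed Integer RNG seed.
#' @param genome_length Genome length in bp.
#' @param n_strains Number of strains.
#' @param target_distances Symmetric `n_strains x n_strains` matrix of target
#'   substitutions/site with zero diagonal; entries must lie in [0, 0.70]
#'   (the Jukes-Cantor correction used downstream degenerates near
#'   saturation). A single scalar is recycled to all off-diagonal entries.
#' @return Object of class `sim_strain_config`.
#' @export
sim_strain_config <- function(seed, genome_length = 20000L, n_strains = 2L,
                              target_distances = 0.02) {
  n <- as.integer(n_strains)
  if (is.matrix(target_distances)) {
    D <- target_distances
  } else {
    stopifnot(length(target_distances) == 1)
    D <- matrix(target_distances, n, n)
    diag(D) <- 0
  }
  if (nrow(D) != n || ncol(D) != n) stop("target_distances must be n_strains x n_strains")
  if (any(abs(D - t(D)) > 1e-12)) stop("target_distances must be symmetric")
  if (any(diag(D) != 0)) stop("target_distances must have a zero diagonal")
  if (any(D < 0) || any(D > 0.70))
    stop("target distances must lie in [0, 0.70]; larger values are rejected ",
         "(Jukes-Cantor correction breaks near saturation)")
  structure(list(seed = as.integer(seed), genome_length = as.integer(genome_length),
                 n_strains = n, target_distances = D,
                 alphabet = c("A", "C", "G", "T")),
            class = "sim_strain_config")
}

# Decompose a symmetric pairwise distance matrix into per-lineage branch
# lengths on a star tree (d_ij ~ r_i + r_j), by least squares with negative
# solutions clamped to zero. Exact for star-additive matrices.
star_branch_lengths <- function(D) {
  n <- nrow(D)
  if (n == 1) return(0)
  if (n == 2) return(rep(D[1, 2] / 2, 2))
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  A <- matrix(0, nrow(pairs), n)
  A[cbind(seq_len(nrow(pairs)), pairs[, 1])] <- 1
  A[cbind(seq_len(nrow(pairs)), pairs[, 2])] <- 1
  d <- D[upper.tri(D)]
  r <- as.vector(qr.solve(crossprod(A), crossprod(A, d)))
  r <- pmax(r, 0)
  resid <- max(abs(A %*% r - d))
  if (resid > 1e-8)
    warning("target_distances is not star-additive; realized distances will ",
            "approximate the targets only up to a residual of ",
            signif(resid, 3))
  r
}

# Apply n_mut substitutions at uniform positions (with replacement) to an
# integer-coded sequence; each hit moves the base to a uniform other base,
# so multiple hits can revert (Jukes-Cantor-like).
mutate_lineage <- function(seq_int, n_mut) {
  if (n_mut == 0) return(seq_int)
  pos <- sample.int(length(seq_int), n_mut, replace = TRUE)
  step <- sample.int(3L, n_mut, replace = TRUE)
  for (m in seq_len(n_mut)) {
    p <- pos[m]
    seq_int[p] <- ((seq_int[p] - 1L + step[m]) %% 4L) + 1L
  }
  seq_int
}

int_to_dna <- function(x) paste(c("A", "C", "G", "T")[x], collapse = "")
dna_to_int <- function(s) {
  match(strsplit(s, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
}

#' Evolve a set of strain genomes with controlled pairwise divergence
#'
#' A random ancestor is drawn and each strain accumulates
#' `Poisson(branch_length x L)` substitutions at uniform positions (with
#' replacement), where per-lineage branch lengths are the star-tree
#' decomposition of the target distance matrix. The realized
#' proportion-of-differing-sites matrix is returned as ground truth.
#'
#' @param config A [sim_strain_config()].
#' @return List with `genomes` (named character vector, ids `strain_01`,
#'   ...), `realized_distances` (p-distance matrix) and `branch_lengths`.
#' @export
evolve_strains <- function(config) {
  stopifnot(inherits(config, "sim_strain_config"))
  set.seed(config$seed)
  L <- config$genome_length
  n <- config$n_strains
  anc <- sample.int(4L, L, replace = TRUE)
  r <- star_branch_lengths(config$target_distances)
  genomes_int <- vector("list", n)
  for (i in seq_len(n)) {
    n_mut <- rpois(1, r[i] * L)
    genomes_int[[i]] <- mutate_lineage(anc, n_mut)
  }
  ids <- sprintf("strain_%02d", seq_len(n))
  genomes <- setNames(vapply(genomes_int, int_to_dna, character(1)), ids)
  P <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    cnt <- cpp_pdist_counts(genomes[[i]], genomes[[j]])
    P[i, j] <- P[j, i] <- cnt[["diff"]] / cnt[["comparable"]]
  }
  list(genomes = genomes, realized_distances = P, branch_lengths = r)
}

#' Configuration for simulating a (possibly mixed) read set
#'
#' @param mixture Named numeric vector of positive strain weights summing
#'   to 1 (names are strain ids).
#' @param coverage Total fold coverage across the mixture (> 0).
#' @param read_length Read length in bp.
#' @param error_rate Per-base substitution probability, in [0, 0.05].
#' @param seed Integer RNG seed.
#' @return Object of class `sim_read_config`.
#' @export
sim_read_config <- function(mixture, coverage = 25, read_length = 150L,
                            error_rate = 0.002, seed = 1L) {
  stopifnot(!is.null(names(mixture)), all(mixture > 0))
  if (abs(sum(mixture) - 1) > 1e-9) stop("mixture weights must sum to 1")
  if (coverage <= 0) stop("coverage must be positive")
  if (error_rate < 0 || error_rate > 0.05)
    stop("error_rate must lie in [0, 0.05]")
  structure(list(mixture = mixture, coverage = coverage,
                 read_length = as.integer(read_length),
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "sim_read_config")
}

#' Simulate single-end reads from a strain mixture, with truth labels
#'
#' Expected read count per strain is `weight x coverage x L / read_length`
#' (rounded); start positions are uniform on `[0, L - read_length]` (0-based,
#' linear genome); errors are substitutions only.
#'
#' @param genomes Named character vector of strain genomes.
#' @param config A [sim_read_config()]; every mixture id must name a genome.
#' @return List with `reads` (named character vector) and `truth`
#'   (data.frame read_id, strain, start).
#' @export
simulate_reads <- function(genomes, config) {
  stopifnot(inherits(config, "sim_read_config"))
  miss <- setdiff(names(config$mixture), names(genomes))
  if (length(miss)) stop("mixture names unknown strain(s): ",
                         paste(miss, collapse = ", "))
  rl <- config$read_length
  if (any(nchar(genomes[names(config$mixture)]) < rl))
    stop("read_length exceeds a mixture genome length")
  set.seed(config$seed)
  all_reads <- character(0)
  truth <- list()
  for (sid in names(config$mixture)) {
    g <- genomes[[sid]]
    L <- nchar(g)
    n <- round(config$mixture[[sid]] * config$coverage * L / rl)
    if (n == 0) next
    starts <- sample.int(L - rl + 1L, n, replace = TRUE) - 1L
    reads <- substring(g, starts + 1L, starts + rl)
    if (config$error_rate > 0) {
      n_err <- rbinom(1, n * rl, config$error_rate)
      if (n_err > 0) {
        flat <- sample.int(n * rl, n_err, replace = FALSE)
        ridx <- ((flat - 1L) %/% rl) + 1L
        off <- ((flat - 1L) %% rl) + 1L
        step <- sample.int(3L, n_err, replace = TRUE)
        bases <- c("A", "C", "G", "T")
        for (e in seq_len(n_err)) {
          old <- match(substr(reads[ridx[e]], off[e], off[e]), bases)
          substr(reads[ridx[e]], off[e], off[e]) <-
            bases[((old - 1L + step[e]) %% 4L) + 1L]
        }
      }
    }
    ids <- sprintf("%s_read_%06d", sid, seq_len(n))
    names(reads) <- ids
    all_reads <- c(all_reads, reads)
    truth[[sid]] <- data.frame(read_id = ids, strain = sid, start = starts,
                               stringsAsFactors = FALSE)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(read_id = character(0), strain = character(0),
               start = integer(0))
  rownames(truth) <- NULL
  list(reads = all_reads, truth = truth)
}

#' Configuration for simulating host sister-pair histories
#'
#' Scenarios: `codivergence` (symbiont split = host split), `horizontal`
#' (symbiont split independent of host split, older or younger),
#' `introgressive` (symbiont and mitochondrial splits equal and younger than
#' the host nuclear split), `loss` (one species uninfected), `uninfected`
#' (both uninfected).
#'
#' @param n_pairs Number of sister-species pairs.
#' @param split_time_range Host nuclear split times (generations), drawn
#'   uniformly from this range.
#' @param sympatry_range Range for the degree of sympatry, within [0, 1].
#' @param scenario_weights Named probabilities over the five scenarios,
#'   summing to 1.
#' @param wolb_rate Symbiont substitution rate (subs/site/host generation,
#'   per lineage). Default sits between the slow and fast clock bounds
#'   used for dating.
#' @param mito_rate Mitochondrial divergence rate (% uncorrected distance
#'   per My between the two lineages).
#' @param generations_per_year Host generations per year, in [1, 3].
#' @param wolb_genome_length,mito_length Simulated sequence lengths (bp).
#' @param n_specimens Specimens sampled per species.
#' @param seed Integer RNG seed.
#' @return Object of class `host_system_config`.
#' @export
host_system_config <- function(n_pairs = 10L,
                               split_time_range = c(5e5, 4e6),
                               sympatry_range = c(0, 1),
                               scenario_weights = c(codivergence = 0.3,
                                                    horizontal = 0.25,
                                                    introgressive = 0.15,
                                                    loss = 0.15,
                                                    uninfected = 0.15),
                               wolb_rate = 6.4e-10,
                               mito_rate = 1.9,
                               generations_per_year = 2,
                               wolb_genome_length = 20000L,
                               mito_length = 12000L,
                               n_specimens = 3L,
                               seed = 1L) {
  want <- c("codivergence", "horizontal", "introgressive", "loss", "uninfected")
  stopifnot(setequal(names(scenario_weights), want))
  scenario_weights <- scenario_weights[want]
  if (abs(sum(scenario_weights) - 1) > 1e-9)
    stop("scenario_weights must sum to 1")
  if (wolb_rate <= 0 || mito_rate <= 0)
    stop("rates must be strictly positive")
  if (generations_per_year < 1 || generations_per_year > 3)
    stop("generations_per_year must lie in [1, 3]")
  stopifnot(sympatry_range[1] >= 0, sympatry_range[2] <= 1)
  structure(list(n_pairs = as.integer(n_pairs),
                 split_time_range = split_time_range,
                 sympatry_range = sympatry_range,
                 scenario_weights = scenario_weights,
                 wolb_rate = wolb_rate, mito_rate = mito_rate,
                 generations_per_year = generations_per_year,
                 wolb_genome_length = as.integer(wolb_genome_length),
                 mito_length = as.integer(mito_length),
                 n_specimens = as.integer(n_specimens),
                 seed = as.integer(seed)),
            class = "host_system_config")
}

# Evolve a pair of sequences from a fresh random ancestor so that the two
# lineages together accumulate d_total expected substitutions per site.
evolve_pair <- function(L, d_total) {
  anc <- sample.int(4L, L, replace = TRUE)
  a <- mutate_lineage(anc, rpois(1, d_total / 2 * L))
  b <- mutate_lineage(anc, rpois(1, d_total / 2 * L))
  c(int_to_dna(a), int_to_dna(b))
}

#' Simulate a host sister-pair system with known transfer scenarios
#'
#' @param config A [host_system_config()].
#' @return List with `pair_table` (species_a, species_b, split_gen, split_my,
#'   sympatry, scenario), `occurrence` (an [occurrence_matrix]),
#'   `wolb_seqs` / `mito_seqs` (named character vectors per species;
#'   symbiont sequences only for infected species) and `truth`
#'   (per-pair symbiont/mito split times and sharing flags).
#' @export
simulate_host_system <- function(config) {
  stopifnot(inherits(config, "host_system_config"))
  set.seed(config$seed)
  gpy <- config$generations_per_year
  np <- config$n_pairs
  scen <- sample(names(config$scenario_weights), np, replace = TRUE,
                 prob = config$scenario_weights)
  split_gen <- runif(np, config$split_time_range[1], config$split_time_range[2])
  sympatry <- runif(np, config$sympatry_range[1], config$sympatry_range[2])
  species_a <- sprintf("species_%02da", seq_len(np))
  species_b <- sprintf("species_%02db", seq_len(np))
  wolb_seqs <- character(0)
  mito_seqs <- character(0)
  strain_of <- list()  # species -> strain id
  truth <- data.frame(pair = seq_len(np), scenario = scen,
                      split_gen = split_gen,
                      wolb_split_gen = NA_real_, mito_split_gen = split_gen,
                      shares_strain = FALSE)
  for (i in seq_len(np)) {
    T_host <- split_gen[i]
    T_wolb <- switch(scen[i],
      codivergence = T_host,
      horizontal = runif(1, config$split_time_range[1],
                         config$split_time_range[2]),
      introgressive = runif(1, 0.05, 0.5) * T_host,
      loss = T_host,
      uninfected = NA_real_)
    T_mito <- if (scen[i] == "introgressive") T_wolb else T_host
    truth$mito_split_gen[i] <- T_mito
    # mitochondria always present
    d_mito <- config$mito_rate / 100 * (T_mito / (gpy * 1e6))
    mp <- evolve_pair(config$mito_length, d_mito)
    mito_seqs[species_a[i]] <- mp[1]
    mito_seqs[species_b[i]] <- mp[2]
    if (scen[i] == "uninfected") next
    if (scen[i] == "loss") {
      # species_a retains an isolated strain; species_b lost it
      g <- int_to_dna(sample.int(4L, config$wolb_genome_length, TRUE))
      wolb_seqs[species_a[i]] <- g
      strain_of[[species_a[i]]] <- sprintf("strain_p%02d_a", i)
      next
    }
    truth$wolb_split_gen[i] <- T_wolb
    d_wolb <- 2 * config$wolb_rate * T_wolb
    wp <- evolve_pair(config$wolb_genome_length, d_wolb)
    wolb_seqs[species_a[i]] <- wp[1]
    wolb_seqs[species_b[i]] <- wp[2]
    shared <- d_wolb < 0.01  # below the 99%-ANI dereplication radius
    truth$shares_strain[i] <- shared
    if (shared) {
      sid <- sprintf("strain_p%02d", i)
      strain_of[[species_a[i]]] <- sid
      strain_of[[species_b[i]]] <- sid
    } else {
      strain_of[[species_a[i]]] <- sprintf("strain_p%02d_a", i)
      strain_of[[species_b[i]]] <- sprintf("strain_p%02d_b", i)
    }
  }
  species <- c(rbind(species_a, species_b))
  strains <- unique(unlist(strain_of))
  counts <- matrix(0L, length(species), max(1L, length(strains)),
                   dimnames = list(species,
                                   if (length(strains)) strains else "none"))
  for (sp in names(strain_of))
    counts[sp, strain_of[[sp]]] <- config$n_specimens
  occ <- occurrence_matrix(counts,
                           n_specimens = setNames(rep(config$n_specimens,
                                                      length(species)),
                                                  species))
  pair_table <- data.frame(species_a = species_a, species_b = species_b,
                           split_gen = split_gen,
                           split_my = split_gen / (gpy * 1e6),
                           sympatry = sympatry, scenario = scen,
                           stringsAsFactors = FALSE)
  list(pair_table = pair_table, occurrence = occ,
       wolb_seqs = wolb_seqs, mito_seqs = mito_seqs, truth = truth)
}

#' Simulate gain/loss histories for the turnover-rate estimator
#'
#' Events occur as a Poisson process at `rate` per million host generations
#' along the `divergence_factor x split_gen` branch length of each pair;
#' every event adds a distinct private strain to one species
#' (infinite-strains model), so each event contributes exactly one
#' strain-set difference.
#'
#' @param n_pairs Number of sister pairs.
#' @param rate True turnover rate (events per million host generations).
#' @param split_gen Host split time(s) in generations (recycled).
#' @param divergence_factor Branch-length multiplier (2 = both lineages).
#' @param seed Integer RNG seed.
#' @return A `turnover_input` list (see [turnover_rate()]) with the true
#'   rate attached as attribute `true_rate`.
#' @export
simulate_turnover_history <- function(n_pairs, rate, split_gen,
                                      divergence_factor = 2, seed = 1L) {
  stopifnot(n_pairs >= 1, rate > 0, all(split_gen > 0))
  set.seed(as.integer(seed))
  split_gen <- rep_len(split_gen, n_pairs)
  pairs <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    n_ev <- rpois(1, rate * divergence_factor * split_gen[i] / 1e6)
    base <- sprintf("anc_%02d", i)
    a <- base
    b <- base
    if (n_ev > 0) {
      to_a <- as.logical(rbinom(n_ev, 1, 0.5))
      ev <- sprintf("ev_%02d_%03d", i, seq_len(n_ev))
      a <- c(a, ev[to_a])
      b <- c(b, ev[!to_a])
    }
    pairs[[i]] <- list(strains_a = a, strains_b = b, split_gen = split_gen[i])
  }
  structure(list(pairs = pairs), class = "turnover_input",
            true_rate = rate)
}

#' Plan planted CI/MK loci and decoys for a synthetic hit table
#'
#' @param genome_id Genome (and contig) identifier.
#' @param n_operons Number of adjacent cifA+cifB pairs to plant.
#' @param n_orphan_cifA,n_orphan_cifB Lone cif genes to plant.
#' @param n_wmk Number of wmk candidates to plant.
#' @param decoys Character vector of decoy violations, each one of
#'   `"evalue"`, `"qcov"`, `"reciprocal"`, `"annotation"`, `"strand"`;
#'   each decoy violates exactly that one screening criterion.
#' @return Object of class `locus_plan`.
#' @export
locus_plan <- function(genome_id = "genome_1", n_operons = 1L,
                       n_orphan_cifA = 0L, n_orphan_cifB = 0L, n_wmk = 0L,
                       decoys = character()) {
  ok <- c("evalue", "qcov", "reciprocal", "annotation", "strand")
  if (length(decoys) && !all(decoys %in% ok))
    stop("unknown decoy violation(s): ",
         paste(setdiff(decoys, ok), collapse = ", "))
  structure(list(genome_id = genome_id, n_operons = as.integer(n_operons),
                 n_orphan_cifA = as.integer(n_orphan_cifA),
                 n_orphan_cifB = as.integer(n_orphan_cifB),
                 n_wmk = as.integer(n_wmk), decoys = decoys),
            class = "locus_plan")
}

# internal: canonical candidate region id shared with the locus screen
candidate_region_id <- function(subject_id, s_start, s_end) {
  paste0(subject_id, ":", pmin(s_start, s_end), "-", pmax(s_start, s_end))
}

#' Simulate a homology hit table with planted loci and decoys
#'
#' Planted true loci receive e-values < 1e-20, query coverage > 60%,
#' concordant top reciprocal hits and an overlapping same-strand gene
#' feature; a filler gene is inserted between planted elements so operon
#' partners are adjacent and nothing else is. Each decoy violates exactly
#' one screening criterion, recorded in the truth table.
#'
#' @param plan A [locus_plan()].
#' @param seed Integer RNG seed.
#' @return List with `hits` (13-column hit table), `reciprocal` (candidate_id,
#'   subject_id, e_value, bit_score), `family_map` (subject protein ->
#'   family), `features` (gene table, GFF3 convention) and `truth`.
#' @export
simulate_hit_tables <- function(plan, seed = 1L) {
  stopifnot(inherits(plan, "locus_plan"))
  set.seed(as.integer(seed))
  contig <- plan$genome_id
  fams <- c("cifA", "cifB", "wmk")
  elements <- c(rep("operon", plan$n_operons),
                rep("orphan_cifA", plan$n_orphan_cifA),
                rep("orphan_cifB", plan$n_orphan_cifB),
                rep("wmk", plan$n_wmk),
                if (length(plan$decoys)) paste0("decoy_", plan$decoys))
  cursor <- 500L
  feat <- list(); hits <- list(); recip <- list(); truth <- list()
  fid <- 0L
  add_gene <- function(len, strand, product) {
    fid <<- fid + 1L
    g <- data.frame(contig = contig, start = cursor, end = cursor + len - 1L,
                    strand = strand,
                    feature_id = sprintf("%s_gene_%03d", contig, fid),
                    product = product, stringsAsFactors = FALSE)
    cursor <<- cursor + len + sample(150:400, 1)
    g
  }
  gene_len <- function() 3L * sample(300:500, 1)
  add_hit <- function(family, s_start, s_end, e_value = 10^-runif(1, 25, 60),
                      qcov = runif(1, 70, 95)) {
    qlen <- sample(300:500, 1)
    qs <- 1L
    qe <- as.integer(ceiling(qcov / 100 * qlen))
    data.frame(query_id = paste0(family, "_query"), subject_id = contig,
               percent_identity = round(runif(1, 70, 95), 2),
               align_length = qe - qs + 1L, mismatches = sample(5:40, 1),
               gap_opens = 0L, q_start = qs, q_end = qe,
               s_start = s_start, s_end = s_end,
               e_value = signif(e_value, 3), bit_score = round(runif(1, 200, 600), 1),
               query_coverage = round(qcov, 1), stringsAsFactors = FALSE)
  }
  add_recip <- function(cand_id, top_family, origin_family) {
    # top hit (lowest e-value) from top_family, plus a worse off-family hit
    other <- setdiff(fams, top_family)[1]
    data.frame(candidate_id = cand_id,
               subject_id = c(paste0(top_family, "_prot_ref"),
                              paste0(other, "_prot_ref")),
               e_value = c(1e-80, 1e-40),
               bit_score = c(500, 250), stringsAsFactors = FALSE)
  }
  el_id <- 0L
  for (el in elements) {
    el_id <- el_id + 1L
    if (el == "operon") {
      strand <- sample(c("+", "-"), 1)
      gA <- add_gene(gene_len(), strand, "cifA candidate")
      # adjacent: no filler between the operon partners
      gB <- add_gene(gene_len(), strand, "cifB candidate")
      for (g in list(gA, gB)) feat[[length(feat) + 1L]] <- g
      for (fg in list(list("cifA", gA), list("cifB", gB))) {
        fam <- fg[[1]]; g <- fg[[2]]
        ss <- if (g$strand == "+") c(g$start, g$end) else c(g$end, g$start)
        h <- add_hit(fam, ss[1], ss[2])
        hits[[length(hits) + 1L]] <- h
        cid <- candidate_region_id(contig, h$s_start, h$s_end)
        recip[[length(recip) + 1L]] <- add_recip(cid, fam, fam)
        truth[[length(truth) + 1L]] <- data.frame(
          element = el_id, kind = "operon", family = fam, violation = NA,
          feature_id = g$feature_id, candidate_id = cid, expected_kept = TRUE,
          stringsAsFactors = FALSE)
      }
    } else if (el %in% c("orphan_cifA", "orphan_cifB", "wmk")) {
      fam <- if (el == "wmk") "wmk" else sub("orphan_", "", el)
      strand <- sample(c("+", "-"), 1)
      g <- add_gene(gene_len(), strand, paste(fam, "candidate"))
      feat[[length(feat) + 1L]] <- g
      ss <- if (strand == "+") c(g$start, g$end) else c(g$end, g$start)
      h <- add_hit(fam, ss[1], ss[2])
      hits[[length(hits) + 1L]] <- h
      cid <- candidate_region_id(contig, h$s_start, h$s_end)
      recip[[length(recip) + 1L]] <- add_recip(cid, fam, fam)
      truth[[length(truth) + 1L]] <- data.frame(
        element = el_id, kind = sub("orphan_.*", "orphan", el), family = fam,
        violation = NA, feature_id = g$feature_id, candidate_id = cid,
        expected_kept = TRUE, stringsAsFactors = FALSE)
    } else {  # decoy
      violation <- sub("decoy_", "", el)
      fam <- sample(fams, 1)
      strand <- "+"
      if (violation == "annotation") {
        # hit in an intergenic gap: no gene feature planted
        span <- 600L
        s0 <- cursor
        cursor <- cursor + span + sample(400:800, 1)
        h <- add_hit(fam, s0, s0 + span - 1L)
        g_id <- NA_character_
      } else {
        g <- add_gene(gene_len(), strand, "decoy gene")
        feat[[length(feat) + 1L]] <- g
        g_id <- g$feature_id
        hs <- c(g$start, g$end)
        if (violation == "strand") hs <- rev(hs)  # hit on minus, gene on plus
        h <- switch(violation,
          evalue = add_hit(fam, hs[1], hs[2], e_value = 1e-10),
          qcov = add_hit(fam, hs[1], hs[2], qcov = 50),
          add_hit(fam, hs[1], hs[2]))
      }
      hits[[length(hits) + 1L]] <- h
      cid <- candidate_region_id(contig, h$s_start, h$s_end)
      recip_fam <- if (violation == "reciprocal") setdiff(fams, fam)[1] else fam
      recip[[length(recip) + 1L]] <- add_recip(cid, recip_fam, fam)
      truth[[length(truth) + 1L]] <- data.frame(
        element = el_id, kind = "decoy", family = fam, violation = violation,
        feature_id = g_id, candidate_id = cid, expected_kept = FALSE,
        stringsAsFactors = FALSE)
    }
    # filler gene separating consecutive planted elements
    feat[[length(feat) + 1L]] <- add_gene(gene_len(), sample(c("+", "-"), 1),
                                          "hypothetical protein")
  }
  features <- if (length(feat)) do.call(rbind, feat) else
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               strand = character(0), feature_id = character(0),
               product = character(0))
  if (nrow(features) > 1) {
    o <- order(features$start)
    if (any(features$start[o][-1] <= features$end[o][-nrow(features)]))
      stop("planted loci overlap; adjust the plan")
  }
  hits <- if (length(hits)) do.call(rbind, hits) else NULL
  recip <- if (length(recip)) do.call(rbind, recip) else NULL
  truth <- if (length(truth)) do.call(rbind, truth) else NULL
  family_map <- setNames(fams, paste0(fams, "_prot_ref"))
  list(hits = hits, reciprocal = recip, family_map = family_map,
       features = features, truth = truth)
}

#' Simulate a multi-sample infection panel study with known truth
#'
#' Builds a panel of diverged strains and a set of samples spanning
#' uninfected specimens (reads from an unrelated genome), single infections
#' and dual 50/50 coinfections, the composition the strain caller has to
#' recover end to end.
#'
#' @param seed Integer RNG seed.
#' @param n_strains Panel size.
#' @param genome_length Strain genome length (bp).
#' @param distance Target pairwise divergence between panel strains
#'   (substitutions/site).
#' @param n_uninfected,n_single,n_dual Sample composition.
#' @param coverage,read_length,error_rate Read-simulation settings.
#' @return List with `panel` (named genomes), `samples` (list of read sets)
#'   and `truth` (list of true strain-id vectors per sample, empty for
#'   uninfected).
#' @export
simulate_panel_study <- function(seed, n_strains = 6L, genome_length = 20000L,
                                 distance = 0.04, n_uninfected = 4L,
                                 n_single = 8L, n_dual = 8L, coverage = 25,
                                 read_length = 150L, error_rate = 0.002) {
  ev <- evolve_strains(sim_strain_config(seed, genome_length, n_strains,
                                         distance))
  panel <- ev$genomes
  ids <- names(panel)
  set.seed(seed + 1L)
  outsider <- int_to_dna(sample.int(4L, genome_length, replace = TRUE))
  samples <- list()
  truth <- list()
  k <- 0L
  add <- function(mixture, genomes, true_strains) {
    k <<- k + 1L
    sid <- sprintf("sample_%02d", k)
    rc <- sim_read_config(mixture, coverage = coverage,
                          read_length = read_length,
                          error_rate = error_rate, seed = seed + 10L + k)
    samples[[sid]] <<- simulate_reads(genomes, rc)$reads
    truth[[sid]] <<- true_strains
  }
  for (i in seq_len(n_uninfected))
    add(c(outsider = 1), c(outsider = outsider), character(0))
  for (i in seq_len(n_single)) {
    s <- ids[(i - 1L) %% n_strains + 1L]
    add(setNames(1, s), panel, s)
  }
  for (i in seq_len(n_dual)) {
    a <- ids[(i - 1L) %% n_strains + 1L]
    b <- ids[i %% n_strains + 1L]
    add(setNames(c(0.5, 0.5), c(a, b)), panel, c(a, b))
  }
  list(panel = panel, samples = samples, truth = truth,
       realized_distances = ev$realized_distances)
}

#' Precision and recall of strain assignment over a panel study
#'
#' Runs [detect_sample()] on every sample of a [simulate_panel_study()] and
#' scores the called strain sets against the truth at the
#' sample-strain-assignment level.
#'
#' @param study A [simulate_panel_study()] result.
#' @param config A [detection_config()].
#' @return List: precision, recall, calls (per-sample strain vectors).
#' @export
evaluate_strain_recovery <- function(study, config = detection_config()) {
  calls <- lapply(study$samples, function(r)
    detect_sample(r, study$panel, config)$strain_ids)
  tp <- fp <- fn <- 0L
  for (sid in names(calls)) {
    called <- calls[[sid]]
    true <- study$truth[[sid]]
    tp <- tp + length(intersect(called, true))
    fp <- fp + length(setdiff(called, true))
    fn <- fn + length(setdiff(true, called))
  }
  list(precision = if (tp + fp == 0) 1 else tp / (tp + fp),
       recall = if (tp + fn == 0) 1 else tp / (tp + fn),
       calls = calls)
}
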