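# Independent oracles used across test files.

# Full dynamic-programming ANI: align every query fragment globally (query
# ends free in the reference) with Biostrings and average identities of
# fragments above the floor. Independent of the seed-anchored implementation.
dp_fragment_ani <- function(query, ref, fragment_length = 1000,
                            identity_floor = 80) {
  n_frag <- nchar(query) %/% fragment_length
  starts <- (seq_len(n_frag) - 1L) * fragment_length + 1L
  fragments <- substring(query, starts, starts + fragment_length - 1L)
  ident <- vapply(fragments, function(fr) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(fr), Biostrings::DNAString(ref),
      type = "global-local")
    Biostrings::nmatch(al) / fragment_length
  }, numeric(1))
  aligned <- ident * 100 >= identity_floor
  list(ani = if (any(aligned)) mean(ident[aligned]) * 100 else NA_real_,
       aligned_fraction = mean(aligned), n_fragments = n_frag)
}

# Exhaustive dereplication oracle: full-DP ANI both ways, thresholds applied
# by hand with the same greedy order (length desc, id asc).
dp_dereplicate <- function(genomes, ani_threshold = 99, maf_threshold = 0.90) {
  ord <- order(-nchar(genomes), names(genomes))
  genomes <- genomes[ord]
  reps <- character(0)
  members <- list()
  for (id in names(genomes)) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      r <- reps[ci]
      a1 <- dp_fragment_ani(genomes[[id]], genomes[[r]])
      a2 <- dp_fragment_ani(genomes[[r]], genomes[[id]])
      if (!is.na(a1$ani) && !is.na(a2$ani) &&
          a1$ani > ani_threshold && a2$ani > ani_threshold &&
          min(a1$aligned_fraction, a2$aligned_fraction) >= maf_threshold) {
        members[[ci]] <- c(members[[ci]], id)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      members[[length(reps)]] <- id
    }
  }
  setNames(rep(reps, lengths(members)), unlist(members))
}

# All perfect matchings of an even-sized set (for exhaustive permutation
# p-values at tiny n).
all_matchings <- function(items) {
  if (length(items) == 2) return(list(list(items)))
  first <- items[1]
  out <- list()
  for (j in 2:length(items)) {
    rest <- items[-c(1, j)]
    for (m in all_matchings(rest))
      out[[length(out) + 1L]] <- c(list(c(first, items[j])), m)
  }
  out
}

random_genome <- function(L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# occurrence matrix + arbitrary fixed pairing with no pairing signal, for
# permutation-test calibration (every species infected by 1-3 of n_strains)
random_null_dataset <- function(n_species = 16, n_strains = 24) {
  counts <- matrix(0L, n_species, n_strains,
                   dimnames = list(sprintf("sp%02d", seq_len(n_species)),
                                   sprintf("st%02d", seq_len(n_strains))))
  for (i in seq_len(n_species))
    counts[i, sample.int(n_strains, sample(1:3, 1))] <- 1L
  occ <- occurrence_matrix(counts)
  pairs <- data.frame(species_a = rownames(counts)[seq(1, n_species, 2)],
                      species_b = rownames(counts)[seq(2, n_species, 2)])
  ani <- matrix(runif(n_strains^2, 85, 99), n_strains, n_strains,
                dimnames = list(colnames(counts), colnames(counts)))
  diag(ani) <- 100
  list(occ = occ, pairs = pairs, ani = ani)
}
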