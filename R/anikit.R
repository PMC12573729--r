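#' Dereplication / ANI configuration
#'
#' Defaults mirror the usual strain-level dereplication settings: genomes
#' with ANI above 99% over a minimum aligned fraction of 90% collapse into
#' one representative strain.
#'
#' @param ani_threshold ANI threshold in percent (50-100).
#' @param maf_threshold Minimum aligned fraction, in (0, 1].
#' @param fragment_length Query fragment length in bp.
#' @param seed_kmer Seed k-mer length for fragment anchoring.
#' @param fragment_identity_floor Minimum percent identity for a fragment to
#'   count as aligned.
#' @return Object of class `derep_config`.
#' @export
derep_config <- function(ani_threshold = 99, maf_threshold = 0.90,
                         fragment_length = 1000L, seed_kmer = 15L,
                         fragment_identity_floor = 80) {
  if (maf_threshold <= 0 || maf_threshold > 1)
    stop("maf_threshold must lie in (0, 1]")
  if (ani_threshold < 50 || ani_threshold > 100)
    stop("ani_threshold must lie in [50, 100]")
  structure(list(ani_threshold = ani_threshold,
                 maf_threshold = maf_threshold,
                 fragment_length = as.integer(fragment_length),
                 seed_kmer = as.integer(seed_kmer),
                 fragment_identity_floor = fragment_identity_floor),
            class = "derep_config")
}

#' Fragment-based average nucleotide identity (one direction)
#'
#' The query is cut into consecutive non-overlapping fragments of
#' `fragment_length` (a final partial fragment is dropped); each fragment is
#' placed at its best-identity ungapped location in the reference, anchored
#' by shared seed k-mers. A fragment counts as aligned when its best
#' identity reaches `fragment_identity_floor`. ANI is the mean identity over
#' aligned fragments (x 100); the aligned fraction is aligned / total
#' fragments. ANI is asymmetric: swap the arguments for the other direction.
#'
#' @param query,ref Nucleotide sequences (character scalars).
#' @param config A [derep_config()].
#' @return List with query_id/ref_id (if the inputs were named), `ani`
#'   (percent, NA when no fragment aligns), `aligned_fraction` and
#'   `n_fragments`.
#' @export
fragment_ani <- function(query, ref, config = derep_config()) {
  stopifnot(inherits(config, "derep_config"))
  q <- as.character(query)[1]
  r <- as.character(ref)[1]
  if (!nzchar(q) || !nzchar(r)) stop("sequences must be non-empty")
  fl <- config$fragment_length
  n_frag <- nchar(q) %/% fl
  if (n_frag == 0) stop("query too short: fewer than one fragment of ", fl, " bp")
  starts <- (seq_len(n_frag) - 1L) * fl + 1L
  fragments <- substring(q, starts, starts + fl - 1L)
  ident <- cpp_fragment_identity(fragments, r, config$seed_kmer)
  aligned <- !is.na(ident) & ident * 100 >= config$fragment_identity_floor
  list(query_id = if (!is.null(names(query))) names(query)[1] else NA,
       ref_id = if (!is.null(names(ref))) names(ref)[1] else NA,
       ani = if (any(aligned)) mean(ident[aligned]) * 100 else NA_real_,
       aligned_fraction = sum(aligned) / n_frag,
       n_fragments = n_frag)
}

#' All-pairs ANI matrices
#'
#' Computes [fragment_ani()] in both directions for every ordered pair
#' (ANI is asymmetric); the diagonal is 100% ANI with aligned fraction 1.
#'
#' @param genomes Named character vector of genome sequences.
#' @param config A [derep_config()].
#' @return List of two matrices, `ani` (percent; rows = query) and
#'   `aligned_fraction`.
#' @export
pairwise_ani_matrix <- function(genomes, config = derep_config()) {
  n <- length(genomes)
  ids <- names(genomes)
  stopifnot(!is.null(ids))
  ani <- matrix(100, n, n, dimnames = list(ids, ids))
  af <- matrix(1, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    res <- fragment_ani(genomes[i], genomes[j], config)
    ani[i, j] <- res$ani
    af[i, j] <- res$aligned_fraction
  }
  list(ani = ani, aligned_fraction = af)
}

#' Greedy genome dereplication into strain clusters
#'
#' Genomes are processed in decreasing length order (ids ascending on ties);
#' each genome joins the first existing cluster whose representative it
#' matches at ANI above the threshold in both directions with
#' min(aligned fraction both ways) at or above the MAF threshold, otherwise
#' it founds a new cluster. The representative is the longest member (the
#' founder, by the processing order). The result is independent of the
#' input order of `genomes`.
#'
#' @param genomes Named character vector of genome sequences (>= 1).
#' @param config A [derep_config()].
#' @return Object of class `cluster_set`: list with `clusters` (list of
#'   `representative_id`, `member_ids`) and a `membership` named vector.
#' @export
dereplicate <- function(genomes, config = derep_config()) {
  stopifnot(length(genomes) >= 1, !is.null(names(genomes)))
  ord <- order(-nchar(genomes), names(genomes))
  genomes <- genomes[ord]
  reps <- character(0)
  members <- list()
  for (id in names(genomes)) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      r <- reps[ci]
      a1 <- fragment_ani(genomes[id], genomes[r], config)
      a2 <- fragment_ani(genomes[r], genomes[id], config)
      ok <- !is.na(a1$ani) && !is.na(a2$ani) &&
        a1$ani > config$ani_threshold && a2$ani > config$ani_threshold &&
        min(a1$aligned_fraction, a2$aligned_fraction) >= config$maf_threshold
      if (ok) {
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
  clusters <- Map(function(r, m) list(representative_id = r, member_ids = m),
                  reps, members)
  names(clusters) <- reps
  membership <- setNames(rep(reps, lengths(members)), unlist(members))
  structure(list(clusters = clusters, membership = membership,
                 config = config[c("ani_threshold", "maf_threshold")]),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(length(x$clusters), "cluster(s) at ANI >", x$config$ani_threshold,
      "/ MAF >=", x$config$maf_threshold, "\n")
  for (cl in x$clusters)
    cat(" ", cl$representative_id, "<-",
        paste(cl$member_ids, collapse = ", "), "\n")
  invisible(x)
}
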