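#' Locus-screen configuration
#'
#' Both homology thresholds are strict inequalities: hits are kept when
#' e-value < 1e-20 AND query coverage > 60%.
#'
#' @param e_value_max E-value threshold (strict).
#' @param query_coverage_min Query coverage threshold in percent (strict).
#' @param gene_overlap_min Minimum fraction of the hit span that an
#'   annotated gene must overlap.
#' @return Object of class `screen_config`.
#' @export
screen_config <- function(e_value_max = 1e-20, query_coverage_min = 60,
                          gene_overlap_min = 0.5) {
  structure(list(e_value_max = e_value_max,
                 query_coverage_min = query_coverage_min,
                 gene_overlap_min = gene_overlap_min),
            class = "screen_config")
}

# locus family encoded in the query id (cifA|cifB|wmk prefix)
hit_family <- function(query_id) {
  fam <- sub("^(cifA|cifB|wmk).*$", "\\1", query_id)
  if (any(!fam %in% c("cifA", "cifB", "wmk")))
    stop("query id(s) without a cifA/cifB/wmk family tag: ",
         paste(head(query_id[!fam %in% c("cifA", "cifB", "wmk")]),
               collapse = ", "))
  fam
}

# strand and 1-based inclusive span encoded by s_start/s_end
hit_span <- function(hits) {
  data.frame(lo = pmin(hits$s_start, hits$s_end),
             hi = pmax(hits$s_start, hits$s_end),
             strand = ifelse(hits$s_start <= hits$s_end, "+", "-"))
}

#' Filter homology hits on e-value and query coverage
#'
#' @param hits Hit table (see [read_blast_tab()] for columns).
#' @param config A [screen_config()].
#' @return The kept rows. Malformed rows (non-finite e-value or coverage,
#'   coverage outside [0, 100]) raise an error naming the row.
#' @export
filter_hits <- function(hits, config = screen_config()) {
  bad <- which(!is.finite(hits$e_value) | hits$e_value < 0 |
                 !is.finite(hits$query_coverage) |
                 hits$query_coverage < 0 | hits$query_coverage > 100)
  if (length(bad))
    stop("malformed hit record at row ", bad[1])
  keep <- hits$e_value < config$e_value_max &
    hits$query_coverage > config$query_coverage_min
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reciprocal confirmation of a candidate hit
#'
#' A candidate is confirmed when the top reciprocal hit (lowest e-value;
#' ties by highest bit score, then subject id lexicographic) belongs to the
#' same locus family as the query that produced the candidate. A candidate
#' with no reciprocal hits is unconfirmed (not an error).
#'
#' @param candidate_id Candidate region id (`contig:lo-hi`).
#' @param reciprocal_hits data.frame: candidate_id, subject_id, e_value,
#'   bit_score.
#' @param family_map Named character vector mapping reciprocal subject ids
#'   to locus families.
#' @param origin_family Family of the query that produced the candidate.
#' @return TRUE when confirmed.
#' @export
reciprocal_confirm <- function(candidate_id, reciprocal_hits, family_map,
                               origin_family) {
  rh <- reciprocal_hits[reciprocal_hits$candidate_id == candidate_id, ,
                        drop = FALSE]
  if (!nrow(rh)) return(FALSE)
  rh <- rh[order(rh$e_value, -rh$bit_score, rh$subject_id), , drop = FALSE]
  top_fam <- family_map[[rh$subject_id[1]]]
  if (is.null(top_fam)) return(FALSE)
  identical(top_fam, origin_family)
}

#' Concordance of a candidate hit with the structural annotation
#'
#' A candidate is kept when some annotated gene on the same contig and
#' strand overlaps at least `gene_overlap_min` of the hit span; the
#' best-overlapping feature id is recorded.
#'
#' @param hits Filtered hit table.
#' @param features Gene feature table (see [read_gff3()]).
#' @param config A [screen_config()].
#' @return `hits` with added columns kept (logical) and feature_id.
#' @export
annotation_concordance <- function(hits, features,
                                   config = screen_config()) {
  span <- hit_span(hits)
  kept <- logical(nrow(hits))
  fid <- rep(NA_character_, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    f <- features[features$contig == hits$subject_id[i] &
                    features$strand == span$strand[i], , drop = FALSE]
    if (!nrow(f)) next
    ov <- pmax(0, pmin(f$end, span$hi[i]) - pmax(f$start, span$lo[i]) + 1)
    frac <- ov / (span$hi[i] - span$lo[i] + 1)
    j <- which.max(frac)
    if (frac[j] >= config$gene_overlap_min) {
      kept[i] <- TRUE
      fid[i] <- f$feature_id[j]
    }
  }
  hits$kept <- kept
  hits$feature_id <- fid
  hits
}

#' Detect cif operons among confirmed gene assignments
#'
#' A cifA-assigned gene and a cifB-assigned gene form one operon when their
#' features are adjacent in genomic order on the same contig and strand (no
#' intervening predicted gene, whatever its strand). Each gene joins at most
#' one operon (greedy, left to right); remaining assignments are orphans.
#'
#' @param assignments data.frame with columns feature_id, family (cifA/cifB).
#' @param features Gene feature table covering those features.
#' @return List: n_operons, operons (data.frame feature_a, feature_b),
#'   orphans (data.frame feature_id, family).
#' @export
detect_operons <- function(assignments, features) {
  assignments <- unique(assignments[, c("feature_id", "family")])
  stopifnot(all(assignments$family %in% c("cifA", "cifB")))
  fidx <- match(assignments$feature_id, features$feature_id)
  if (anyNA(fidx)) stop("assignment to unknown feature")
  df <- cbind(assignments, features[fidx, c("contig", "start", "strand")])
  # genomic rank of every feature within its contig
  features$rank <- ave(features$start, features$contig,
                       FUN = function(x) rank(x, ties.method = "first"))
  df$rank <- features$rank[fidx]
  df <- df[order(df$contig, df$rank), , drop = FALSE]
  used <- rep(FALSE, nrow(df))
  operons <- list()
  for (i in seq_len(nrow(df))) {
    if (used[i]) next
    j <- which(!used & df$contig == df$contig[i] &
                 df$strand == df$strand[i] &
                 abs(df$rank - df$rank[i]) == 1 &
                 df$family != df$family[i])
    j <- j[df$feature_id[j] != df$feature_id[i]]
    if (length(j)) {
      j <- j[order(df$rank[j])][1]
      used[c(i, j)] <- TRUE
      ab <- if (df$family[i] == "cifA") c(i, j) else c(j, i)
      operons[[length(operons) + 1L]] <-
        data.frame(feature_a = df$feature_id[ab[1]],
                   feature_b = df$feature_id[ab[2]],
                   stringsAsFactors = FALSE)
    }
  }
  orphans <- df[!used, c("feature_id", "family"), drop = FALSE]
  rownames(orphans) <- NULL
  list(n_operons = length(operons),
       operons = if (length(operons)) do.call(rbind, operons) else
         data.frame(feature_a = character(0), feature_b = character(0)),
       orphans = orphans)
}

#' Full CI/MK locus screen of one genome
#'
#' Chains [filter_hits()], [reciprocal_confirm()],
#' [annotation_concordance()] and, when the genome sequence is provided, an
#' open-reading-frame integrity check (no internal stop codon in the
#' assigned gene), then counts cif operons, orphan cifA/cifB and wmk
#' candidates.
#'
#' @param genome_id Genome identifier for the report row.
#' @param hits Raw hit table (13-column tabular dialect).
#' @param reciprocal Reciprocal hit table (candidate_id, subject_id,
#'   e_value, bit_score).
#' @param family_map Named vector: reciprocal subject id -> family.
#' @param features Gene feature table.
#' @param config A [screen_config()].
#' @param genome_seq Optional named character vector of contig sequences;
#'   when absent the ORF check is skipped with a message.
#' @return One-row data.frame of class `locus_call`: genome_id,
#'   n_cif_operons, n_orphan_cifA, n_orphan_cifB, n_wmk.
#' @export
screen_genome <- function(genome_id, hits, reciprocal, family_map, features,
                          config = screen_config(), genome_seq = NULL) {
  kept <- filter_hits(hits, config)
  if (nrow(kept)) {
    span <- hit_span(kept)
    kept$candidate_id <- candidate_region_id(kept$subject_id, span$lo, span$hi)
    kept$family <- hit_family(kept$query_id)
    conf <- vapply(seq_len(nrow(kept)), function(i)
      reciprocal_confirm(kept$candidate_id[i], reciprocal, family_map,
                         kept$family[i]), logical(1))
    kept <- kept[conf, , drop = FALSE]
  }
  if (nrow(kept)) {
    kept <- annotation_concordance(kept, features, config)
    kept <- kept[kept$kept, , drop = FALSE]
  }
  if (nrow(kept) && !is.null(genome_seq)) {
    ok <- vapply(seq_len(nrow(kept)), function(i) {
      f <- features[features$feature_id == kept$feature_id[i], ]
      orf_intact(genome_seq[[f$contig]], f$start, f$end, f$strand)
    }, logical(1))
    kept <- kept[ok, , drop = FALSE]
  } else if (is.null(genome_seq)) {
    message("no genome sequence provided; ORF-integrity check skipped")
  }
  cif <- kept[kept$family %in% c("cifA", "cifB"),
              c("feature_id", "family"), drop = FALSE]
  op <- if (nrow(cif)) detect_operons(cif, features) else
    list(n_operons = 0L,
         orphans = data.frame(feature_id = character(0),
                              family = character(0)))
  n_wmk <- length(unique(kept$feature_id[kept$family == "wmk"]))
  structure(data.frame(genome_id = genome_id,
                       n_cif_operons = op$n_operons,
                       n_orphan_cifA = sum(op$orphans$family == "cifA"),
                       n_orphan_cifB = sum(op$orphans$family == "cifB"),
                       n_wmk = n_wmk, stringsAsFactors = FALSE),
            class = c("locus_call", "data.frame"))
}

# no internal stop codon in the reading frame of [start, end] on strand
orf_intact <- function(contig_seq, start, end, strand) {
  s <- substr(contig_seq, start, end)
  dna <- Biostrings::DNAString(s)
  if (strand == "-") dna <- Biostrings::reverseComplement(dna)
  len <- 3 * (length(dna) %/% 3)
  if (len < 3) return(FALSE)
  aa <- as.character(Biostrings::translate(dna[seq_len(len)],
                                           if.fuzzy.codon = "X"))
  !grepl("\\*", substr(aa, 1, nchar(aa) - 1))
}

#' Combine per-genome locus calls into a summary table
#'
#' One row per genome with the counts of consecutive cifA+cifB operons,
#' non-consecutive (orphan) cifA and cifB, and wmk candidates.
#'
#' @param calls List of `locus_call` rows from [screen_genome()].
#' @return data.frame with one row per genome.
#' @export
tabulate_locus_calls <- function(calls) {
  out <- do.call(rbind, lapply(calls, as.data.frame))
  rownames(out) <- NULL
  out
}
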