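#' Read genome sequences from a FASTA file
#'
#' @param path Path to a (possibly multi-record) FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_genomes_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write genome sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genomes_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Write reads to FASTQ with a constant dummy quality
#'
#' All bases receive quality "I" (Phred 40); the simulator does not model
#' quality scores.
#'
#' @param reads Named character vector of read sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  stopifnot(!is.null(names(reads)))
  x <- Biostrings::DNAStringSet(reads)
  quals <- Biostrings::BStringSet(strrep("I", nchar(reads)))
  Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                              qualities = quals)
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#'
#' @param path Path to a FASTQ file.
#' @return Named character vector of read sequences.
#' @export
read_reads_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write an occurrence matrix to TSV
#'
#' Species in rows, strains in columns, plus a final `n_specimens` column.
#'
#' @param occ An [occurrence_matrix] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_occurrence_tsv <- function(occ, path) {
  stopifnot(inherits(occ, "occurrence_matrix"))
  df <- data.frame(species = rownames(occ$counts), occ$counts,
                   n_specimens = occ$n_specimens, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an occurrence matrix from TSV
#'
#' @param path Path to a TSV written by [write_occurrence_tsv()].
#' @return An [occurrence_matrix].
#' @export
read_occurrence_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  counts <- as.matrix(df[, setdiff(colnames(df), c("species", "n_specimens")),
                         drop = FALSE])
  rownames(counts) <- df$species
  occurrence_matrix(counts, n_specimens = setNames(df$n_specimens, df$species))
}

#' Read a BLAST tabular hit file (12 standard columns + qcovs)
#'
#' @param path Path to a headerless tab-separated hit table in the
#'   `-outfmt "6 std qcovs"` dialect.
#' @return data.frame with named columns.
#' @export
read_blast_tab <- function(path) {
  cols <- c("query_id", "subject_id", "percent_identity", "align_length",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start", "s_end",
            "e_value", "bit_score", "query_coverage")
  df <- read.delim(path, header = FALSE, col.names = cols)
  df
}

#' Write a hit table in BLAST tabular form
#'
#' @param hits data.frame with the 13 columns produced by [read_blast_tab()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene features from a GFF3 file
#'
#' Thin wrapper around `rtracklayer::import()` that flattens the result to
#' the feature table the locus screen consumes.
#'
#' @param path Path to a GFF3 file.
#' @return data.frame with columns contig, start, end, strand, feature_id,
#'   product (1-based inclusive coordinates).
#' @export
read_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GFF3 requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gff3")
  md <- as.data.frame(gr)
  data.frame(
    contig = as.character(md$seqnames),
    start = md$start, end = md$end,
    strand = as.character(md$strand),
    feature_id = if ("ID" %in% names(md)) as.character(md$ID) else
      paste0("feature_", seq_len(nrow(md))),
    product = if ("product" %in% names(md)) as.character(md$product) else NA,
    stringsAsFactors = FALSE
  )
}

#' Write gene features to a GFF3 file
#'
#' @param features Feature data.frame (see [read_gff3()] for columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE) ||
      !requireNamespace("GenomicRanges", quietly = TRUE))
    stop("writing GFF3 requires the rtracklayer and GenomicRanges packages")
  gr <- GenomicRanges::GRanges(
    seqnames = features$contig,
    ranges = IRanges::IRanges(start = features$start, end = features$end),
    strand = features$strand
  )
  gr$ID <- features$feature_id
  gr$type <- "gene"
  gr$product <- features$product
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
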