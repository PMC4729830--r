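# Interchange formats: BED6 for integration coordinates, FASTA/FASTQ via
# Biostrings, headered TSV. BED is strictly 0-based half-open; FASTQ is
# strict four-line records.

#' Write an integration table as BED6
#'
#' One width-1 interval per integration; the name field encodes
#' `sample_id:replicate:group`, score is 1. Records are sorted by
#' (chrom, start).
#'
#' @param tab integration table.
#' @param path output file.
#' @export
write_integrations_bed <- function(tab, path) {
  check_integration_table(tab)
  o <- order(tab$chrom, tab$position)
  bed <- data.frame(
    chrom = tab$chrom[o],
    start = format(tab$position[o], scientific = FALSE, trim = TRUE),
    end = format(tab$position[o] + 1, scientific = FALSE, trim = TRUE),
    name = paste(tab$sample_id[o], tab$replicate[o], tab$group[o], sep = ":"),
    score = 1L,
    strand = tab$strand[o]
  )
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file of integrations
#'
#' @param path BED6 file written by [write_integrations_bed()] (or
#'   compatible: name field `sample:replicate:group`).
#' @return integration table.
#' @export
read_integrations_bed <- function(path) {
  bed <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (!nrow(bed)) return(empty_integration_table())
  if (ncol(bed) < 6L) stopf("expected BED6, got %d columns", ncol(bed))
  meta <- strsplit(bed[[4]], ":", fixed = TRUE)
  bad <- lengths(meta) != 3L
  if (any(bad)) stopf("BED name field must be sample:replicate:group (row %d)", which(bad)[1])
  tab <- data.frame(
    chrom = bed[[1]], position = bed[[2]], strand = bed[[6]],
    sample_id = vapply(meta, `[`, "", 1L),
    replicate = as.integer(vapply(meta, `[`, "", 2L)),
    group = vapply(meta, `[`, "", 3L),
    stringsAsFactors = FALSE
  )
  check_integration_table(tab)
  tab
}

#' Write reads as FASTQ
#'
#' @param reads character vector of sequences.
#' @param path output file.
#' @param ids read identifiers (default read1..readN).
#' @export
write_reads_fastq <- function(reads, path, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("read%d", seq_along(reads))
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- ids
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(strrep("I", nchar(reads)))
  )
  invisible(path)
}

#' Read a FASTQ file as a character vector of sequences
#' @param path FASTQ file.
#' @return named character vector.
#' @export
read_reads_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), names(x))
}

#' Write a genome as FASTA
#' @param genome named [Biostrings::DNAStringSet] or named character vector.
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  if (!methods::is(genome, "DNAStringSet")) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a genome FASTA
#' @param path FASTA file.
#' @return [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write a headered TSV
#' @param df data.frame.
#' @param path output file.
#' @export
write_tsv <- function(df, path) {
  is_list <- vapply(df, is.list, TRUE)
  if (any(is_list)) df <- df[!is_list] # list-columns are in-memory only
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a headered TSV
#' @param path TSV file; lines starting with '#' are comments.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
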