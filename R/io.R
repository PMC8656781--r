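# Plain-text readers/writers for the pipeline's tabular artifacts.
# All matrices travel as TSV with a probe_id first column and a header row
# of sample ids; genomes travel as FASTA via Biostrings.

#' @rdname methseas_io
#' @param sequence,chrom,path,matrix,df See details per function.
#' @name methseas_io
#' @title Read and write pipeline artifacts
#' @description `write_genome_fasta()`/`read_genome_fasta()` handle the
#' genome; `write_matrix_tsv()`/`read_matrix_tsv()` handle intensity and
#' beta matrices; `write_table_tsv()`/`read_table_tsv()` handle manifests,
#' gene models, truth tables, site results and pairing maps.
NULL

#' @rdname methseas_io
#' @export
write_genome_fasta <- function(sequence, chrom, path) {
  x <- Biostrings::DNAStringSet(stats::setNames(sequence, chrom))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname methseas_io
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname methseas_io
#' @export
write_matrix_tsv <- function(matrix, path) {
  df <- data.frame(probe_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname methseas_io
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname methseas_io
#' @export
write_table_tsv <- function(df, path) {
  drop <- vapply(df, is.list, logical(1))   # list-columns are in-memory only
  utils::write.table(df[, !drop, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname methseas_io
#' @export
read_table_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
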