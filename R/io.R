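#' Read a FASTQ file
#'
#' Reads a (possibly gzip-compressed) Phred+33 FASTQ file into a tibble of
#' reads. Malformed records (quality and sequence length mismatch) raise an
#' error naming the record.
#'
#' @param path path to a `.fastq` or `.fastq.gz` file.
#' @return tibble with columns `read_id`, `bases`, `qual_string` (Phred+33
#'   encoded quality string, same length as `bases`).
#' @export
read_fastq <- function(path) {
  # the mcols-dropping warnings from the internal XStringSet conversions are
  # expected here: FASTQ metadata beyond the id is not carried
  qs <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  bases <- suppressWarnings(as.character(qs))
  quals <- suppressWarnings(as.character(Biostrings::quality(qs)))
  bad <- nchar(bases) != nchar(quals)
  assert_that(!any(bad), "FASTQ record %s: sequence/quality length mismatch",
              paste(names(qs)[bad], collapse = ", "))
  tibble(read_id = names(qs), bases = unname(bases), qual_string = unname(quals))
}

#' Write a FASTQ file
#'
#' @param reads tibble as returned by [read_fastq()].
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @export
write_fastq <- function(reads, path) {
  assert_that(all(nchar(reads$qual_string) == nchar(reads$bases)),
              "sequence/quality length mismatch")
  x <- Biostrings::DNAStringSet(reads$bases)
  names(x) <- reads$read_id
  qs <- Biostrings::QualityScaledDNAStringSet(
    x, Biostrings::PhredQuality(reads$qual_string))
  Biostrings::writeQualityScaledXStringSet(qs, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTA file into a tibble
#'
#' @param path path to a FASTA file.
#' @return tibble with columns `name`, `sequence`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(name = names(x), sequence = unname(as.character(x)))
}

#' Write sequences to FASTA
#'
#' @param x tibble with columns `name` and `sequence`.
#' @param path output path.
#' @export
write_fasta <- function(x, path) {
  s <- Biostrings::DNAStringSet(x$sequence)
  names(s) <- x$name
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

# provenance comment line written at the top of every output table
provenance_line <- function(params = NULL) {
  ver <- as.character(utils::packageVersion("igflow"))
  extra <- if (length(params)) {
    paste0(" ", paste(names(params), unlist(params), sep = "=", collapse = " "))
  } else ""
  sprintf("# igflow %s%s", ver, extra)
}

#' Write a rearrangement table as AIRR-style TSV
#'
#' Writes a tab-separated table using AIRR Rearrangement column names, with a
#' leading `#` provenance comment line (tool version and any parameters
#' supplied). `NA` values are written as empty strings, the AIRR convention.
#'
#' @param df rearrangement tibble.
#' @param path output path.
#' @param params optional named list recorded on the provenance line.
#' @export
write_airr <- function(df, path, params = NULL) {
  df <- as.data.frame(df)
  listcols <- vapply(df, is.list, TRUE)
  for (nm in names(df)[listcols]) {
    df[[nm]] <- vapply(df[[nm]], function(v) paste(v, collapse = ";"), "")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_line(params), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an AIRR-style TSV written by [write_airr()]
#'
#' @param path input path.
#' @return tibble; empty strings in character columns become `NA`.
#' @export
read_airr <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          na.strings = "", check.names = FALSE)
  as_tibble(df)
}

#' Read a primer set table
#'
#' The primer set is tab-separated with columns `name`, `end` (`5` or `3`),
#' `sequence` (the anchor matched at the read start) and `umi_length`
#' (8 or 12; the UMI immediately follows the primer on the read).
#'
#' @param path path to the primer TSV.
#' @return tibble of primers.
#' @export
read_primer_set <- function(path) {
  pr <- as_tibble(utils::read.delim(path, stringsAsFactors = FALSE,
                                    colClasses = c(end = "character")))
  assert_that(all(c("name", "end", "sequence", "umi_length") %in% names(pr)),
              "primer set needs name/end/sequence/umi_length columns")
  assert_that(all(pr$umi_length %in% c(8L, 12L)), "UMI lengths must be 8 or 12")
  pr
}

#' Bundled synthetic primer set
#' @return tibble of the primers used by the simulator.
#' @export
builtin_primer_set <- function() {
  read_primer_set(system.file("extdata", "primers_synthetic.tsv", package = "igflow"))
}

#' Write a machine-readable run report
#'
#' @param report named list or tibble of per-stage counts/parameters.
#' @param path output `.json` path.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
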