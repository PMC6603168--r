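#' Read a germline gene reference
#'
#' Loads a V/D/J/constant germline reference from a FASTA file plus a
#' tab-separated region sidecar. The sidecar assigns each gene to a segment
#' class (`V`, `D`, `J`, `C`, `L`) and gives 0-based half-open region
#' intervals on the gene: framework/CDR bounds for V genes, the conserved
#' 2nd-CYS codon (`CYS`) marking the junction 5' boundary, the conserved
#' J-TRP/PHE codon (`JWF`) marking the junction 3' boundary, `FWR4`, and the
#' codons of Kabat positions 12 (`KABAT12`, on V) and 136 (`KABAT136`, on J)
#' used for core-region trimming.
#'
#' @param fasta_path path to a FASTA file of germline gene sequences.
#' @param regions_path path to the tab-separated sidecar with columns
#'   `gene`, `segment`, `region`, `start`, `end`.
#' @return an object of class `germline_reference`: a list with tibbles
#'   `v_genes`, `d_genes`, `j_genes`, `constant_stubs`, the `regions` table,
#'   and the `leader` anchor sequence (or `NA`).
#' @export
read_germline_reference <- function(fasta_path, regions_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  genes <- tibble(name = names(seqs), sequence = unname(as.character(seqs)))
  assert_that(!anyDuplicated(genes$name), "duplicate gene names in %s", fasta_path)
  assert_that(all(grepl("^[ACGT]+$", genes$sequence)),
              "germline sequences must be uppercase A/C/G/T only")
  regions <- as_tibble(utils::read.delim(regions_path, stringsAsFactors = FALSE))
  assert_that(all(c("gene", "segment", "region", "start", "end") %in% names(regions)),
              "region sidecar must have gene/segment/region/start/end columns")
  assert_that(all(regions$gene %in% genes$name),
              "region sidecar names a gene absent from the FASTA")
  seg <- regions[regions$region == "GENE", c("gene", "segment")]
  genes <- left_join(genes, seg, by = c(name = "gene"))
  assert_that(!anyNA(genes$segment), "every gene needs a GENE row in the sidecar")

  # validate region intervals
  lens <- stats::setNames(nchar(genes$sequence), genes$name)
  bad <- regions$start < 0 | regions$end > lens[regions$gene] | regions$start >= regions$end
  assert_that(!any(bad), "region bounds out of range for: %s",
              paste(unique(regions$gene[bad]), collapse = ", "))

  pick <- function(s) genes[genes$segment == s, c("name", "sequence")]
  ref <- structure(list(
    v_genes = pick("V"),
    d_genes = pick("D"),
    j_genes = pick("J"),
    constant_stubs = {
      cs <- pick("C")
      names(cs) <- c("isotype", "sequence")
      cs
    },
    leader = if (any(genes$segment == "L")) genes$sequence[genes$segment == "L"][1] else NA_character_,
    regions = regions
  ), class = "germline_reference")
  assert_that(nrow(ref$v_genes) >= 1 && nrow(ref$j_genes) >= 1,
              "reference must contain at least one V and one J gene")
  assert_that(all(nchar(ref$constant_stubs$sequence) >= 20),
              "constant stubs must be at least 20 nt")
  ref
}

#' Bundled synthetic germline reference
#'
#' Returns the small synthetic germline reference shipped with the package:
#' 8 V genes (288 nt, conserved 2nd-CYS codon at position 279), 4 D genes,
#' 6 J genes (conserved TRP codon at position 9) and 7 heavy-chain constant
#' region stubs (IgM, IgG1-4, IgA1-2). Gene names follow IMGT-style
#' nomenclature but the sequences are synthetic; the fixture stands in for a
#' full germline database so that annotation and SHM are exactly testable
#' against simulation ground truth.
#'
#' @return a `germline_reference` object.
#' @export
builtin_germline_reference <- function() {
  read_germline_reference(
    system.file("extdata", "germline_synthetic.fasta", package = "igflow"),
    system.file("extdata", "germline_synthetic_regions.tsv", package = "igflow")
  )
}

#' @export
print.germline_reference <- function(x, ...) {
  cat(sprintf(
    "germline_reference: %d V, %d D, %d J genes; %d constant stubs\n",
    nrow(x$v_genes), nrow(x$d_genes), nrow(x$j_genes), nrow(x$constant_stubs)))
  invisible(x)
}

# internal: region interval c(start, end) (0-based half-open) for gene
gene_region <- function(ref, gene, region) {
  r <- ref$regions[ref$regions$gene == gene & ref$regions$region == region, ]
  if (nrow(r) == 0) return(NULL)
  c(r$start[1], r$end[1])
}

# internal: germline sequence string for a gene name
gene_sequence <- function(ref, gene) {
  all_genes <- rbind(ref$v_genes, ref$d_genes, ref$j_genes,
                     stats::setNames(ref$constant_stubs, c("name", "sequence")))
  s <- all_genes$sequence[all_genes$name == gene]
  assert_that(length(s) == 1, "unknown gene: %s", gene)
  s
}

# internal: isotype class from a constant-stub / subtype name
isotype_class <- function(subtype) {
  out <- rep(NA_character_, length(subtype))
  out[grepl("^IGHM|^IgM", subtype)] <- "IgM"
  out[grepl("^IGHG|^IgG", subtype)] <- "IgG"
  out[grepl("^IGHA|^IgA", subtype)] <- "IgA"
  out
}
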