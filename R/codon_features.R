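# Codon and di-codon relative-frequency featurization of coding-sequence
# FASTA files, producing the 64 + 64^2 = 4160-column predictor table.

.codonAlphabet <- c("A", "C", "G", "T")

# Fixed column order: 64 codons then 4096 di-codons, both lexicographic
# over A < C < G < T (first codon major, second minor).
.codonColumnNames <- function() {
  b <- .codonAlphabet
  codons <- sort(as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0)))
  dicodons <- sort(as.vector(outer(codons, codons, paste0)))
  list(codons = codons, dicodons = dicodons)
}

#' Count codons and di-codons over a set of genes
#'
#' Codons are read in frame from position 1 in steps of 3; di-codons are
#' overlapping pairs of consecutive in-frame codons (step one codon) and
#' never span genes. A trailing partial codon is ignored, and any codon
#' containing a non-ACGT symbol is skipped, as is every di-codon touching
#' it (counting is delegated to
#' [Biostrings::oligonucleotideFrequency()], whose windowed word counts
#' implement exactly these rules).
#'
#' @param cdsRecords coding sequences: a [Biostrings::DNAStringSet] or a
#'   character vector (case-insensitive).
#' @return list with `codons` (named length-64 integer vector, lexicographic
#'   order) and `dicodons` (named length-4096 integer vector).
#' @examples
#' countCodons(c("ATGAAATTT"))
#' @export
countCodons <- function(cdsRecords) {
  if (is.character(cdsRecords))
    cdsRecords <- Biostrings::DNAStringSet(toupper(cdsRecords))
  if (!length(cdsRecords)) stop("empty record set")
  c3 <- Biostrings::oligonucleotideFrequency(cdsRecords, width = 3L,
                                             step = 3L)
  c6 <- Biostrings::oligonucleotideFrequency(cdsRecords, width = 6L,
                                             step = 3L)
  cols <- .codonColumnNames()
  codons <- colSums(c3)[cols$codons]
  dicodons <- colSums(c6)[cols$dicodons]
  list(codons = codons, dicodons = dicodons)
}

#' Build the codon/di-codon predictor table for a set of genomes
#'
#' Converts per-genome coding-sequence FASTA files (or in-memory sequence
#' sets) into relative frequencies: within each genome, codon counts are
#' normalized by the total codon count and di-codon counts by the total
#' di-codon count, giving 64 + 64^2 = 4160 predictor columns in a fixed
#' lexicographic order.
#'
#' @param genomes a named character vector of FASTA file paths, or a named
#'   list of [Biostrings::DNAStringSet] / character sequence sets; names
#'   are the genome ids (file base names are used for unnamed paths).
#' @return numeric matrix, genomes x 4160, rows named by genome id; the
#'   codon block of every row sums to 1, as does the di-codon block when
#'   at least one di-codon exists.
#' @seealso [countCodons()], [writePredictorTable()]
#' @export
featurizeGenomes <- function(genomes) {
  if (!length(genomes)) stop("no genomes given")
  if (is.character(genomes)) {
    ids <- if (!is.null(names(genomes))) names(genomes)
           else sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(genomes))
    seqs <- lapply(genomes, Biostrings::readDNAStringSet)
  } else {
    ids <- names(genomes)
    if (is.null(ids)) stop("genome list must be named")
    seqs <- genomes
  }
  cols <- .codonColumnNames()
  out <- matrix(0, length(seqs), 4160L,
                dimnames = list(ids, c(cols$codons, cols$dicodons)))
  for (i in seq_along(seqs)) {
    ct <- countCodons(seqs[[i]])
    nCod <- sum(ct$codons)
    if (nCod == 0)
      stop("genome '", ids[i], "' contains no valid codons")
    nDi <- sum(ct$dicodons)
    out[i, ] <- c(ct$codons / nCod,
                  if (nDi > 0) ct$dicodons / nDi else ct$dicodons)
  }
  out
}
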