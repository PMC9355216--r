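#' Read a FASTA file of nucleotide sequences
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()]: sequences are
#' upper-cased, description lines preserved as names, and empty or malformed
#' files rejected with a diagnostic.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] with one element per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                   error = function(e)
                     stop("malformed FASTA in '", path, "': ",
                          conditionMessage(e), call. = FALSE))
  if (length(seqs) == 0L)
    stop("no sequence records in '", path, "'")
  if (any(Biostrings::width(seqs) == 0L))
    stop("empty sequence record in '", path, "'")
  Biostrings::DNAStringSet(toupper(as.character(seqs)))
}

#' Count candidate protospacers by PAM-motif occurrences
#'
#' Counts the occurrences of a protospacer-adjacent motif (PAM) on a genome.
#' Each PAM position flags a distinct adjacent protospacer, so overlapping
#' occurrences are counted (sliding-window semantics). With
#' `strands = "both"`, the reverse strand is scanned as reverse-complement
#' matches on the given sequence and added to the forward count. Ambiguity
#' codes (`N`) never match.
#'
#' @param genome A [Biostrings::DNAStringSet]/`DNAString` or a plain
#'   nucleotide string.
#' @param pam Motif over `A`, `C`, `G`, `T` (e.g. `"AGAA"`, the
#'   *S. thermophilus* CR1 PAM).
#' @param strands `"both"` (default) or `"forward"`.
#' @return Integer count of candidate protospacers.
#' @examples
#' count_pam_sites("AGAAAGAA", "AGAA", strands = "forward")  # 2
#' count_pam_sites("TTCT", "AGAA")                           # 1 (reverse)
#' @export
count_pam_sites <- function(genome, pam, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  if (!grepl("^[ACGT]+$", toupper(pam)))
    stop("PAM motif must use only A, C, G, T; got '", pam, "'")
  if (is.character(genome))
    genome <- Biostrings::DNAStringSet(toupper(genome))
  if (methods::is(genome, "DNAString"))
    genome <- Biostrings::DNAStringSet(genome)
  if (any(Biostrings::width(genome) < nchar(pam)))
    stop("motif is longer than the genome")
  pat <- Biostrings::DNAString(toupper(pam))
  fwd <- sum(Biostrings::vcountPattern(pat, genome, fixed = TRUE))
  if (strands == "forward") return(fwd)
  rev <- sum(Biostrings::vcountPattern(pat,
                                       Biostrings::reverseComplement(genome),
                                       fixed = TRUE))
  fwd + rev
}
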