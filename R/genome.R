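## Genome I/O. A genome is a named Biostrings::DNAStringSet restricted to
## the alphabet {A,C,G,T,N}; names are chromosome names and must be unique.

#' Read a genome from FASTA
#'
#' Sequences are uppercased on input and restricted to A/C/G/T/N.
#'
#' @param path FASTA file.
#' @return a named `DNAStringSet`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_txbench("no such file: ", path)
  seqs <- withCallingHandlers(
    tryCatch(Biostrings::readDNAStringSet(path),
             error = function(e)
               stop_txbench("malformed FASTA '", path, "': ",
                            conditionMessage(e))),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        stop_txbench("malformed FASTA '", path, "': ",
                     conditionMessage(w))
    })
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  validate_genome(seqs)
  seqs
}

validate_genome <- function(genome) {
  if (!length(genome)) stop_txbench("genome has no sequences")
  if (anyDuplicated(names(genome)))
    stop_txbench("duplicate chromosome names in genome")
  if (any(Biostrings::width(genome) == 0L))
    stop_txbench("empty sequence in genome")
  freq <- Biostrings::letterFrequency(genome, c("A", "C", "G", "T", "N"))
  if (any(rowSums(freq) != Biostrings::width(genome)))
    stop_txbench("genome alphabet must be restricted to A/C/G/T/N")
  invisible(genome)
}

#' Write a genome to FASTA
#'
#' @param genome named `DNAStringSet`.
#' @param path output file.
#' @param width line width.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  validate_genome(genome)
  Biostrings::writeXStringSet(genome, path, width = width)
  invisible(path)
}
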