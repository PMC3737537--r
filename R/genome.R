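#' Read a genome FASTA file
#'
#' Sequence names are truncated at the first whitespace, matching the
#' chromosome names used in BAM/BED records.
#'
#' @param path Path to a (plain-text) FASTA file.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

# Extract the sense-strand sequence of [start, end) (0-based half-open),
# clipped at the chromosome ends. strand "-" returns the reverse complement.
genome_slice <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome))
    stop_("unknown chromosome '", chrom, "' (not present in the genome)")
  len <- Biostrings::width(genome[chrom])
  start <- max(0L, as.integer(start))
  end <- min(len, as.integer(end))
  if (end <= start) return("")
  s <- as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end))
  if (strand == "-") s <- revcomp(s)
  s
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Fill in read sequences from a genome
#'
#' Reads on the minus strand receive the reverse complement of the reference
#' slice, i.e. the sequence as it was read off the RNA.
#'
#' @param reads A read table as returned by [read_alignments()].
#' @param genome A [Biostrings::DNAStringSet] from [read_genome()].
#' @return `reads` with the `seq` column populated.
#' @export
hydrate_reads <- function(reads, genome) {
  if (nrow(reads) == 0L) return(reads)
  seqs <- character(nrow(reads))
  for (chrom in unique(reads$chrom)) {
    if (!chrom %in% names(genome))
      stop_("unknown chromosome '", chrom, "' (not present in the genome)")
    i <- which(reads$chrom == chrom)
    clen <- Biostrings::width(genome[chrom])
    if (any(reads$end[i] > clen) || any(reads$start[i] < 0L))
      stop_("read coordinates outside chromosome '", chrom, "' (length ", clen, ")")
    cstr <- as.character(genome[[chrom]])
    seqs[i] <- substring(cstr, reads$start[i] + 1L, reads$end[i])
  }
  minus <- reads$strand == "-"
  if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
  reads$seq <- seqs
  reads
}
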