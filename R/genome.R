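#' Simulate a random genome
#'
#' Draws i.i.d. bases at a stated GC content.  Contigs are named
#' `contig1`, `contig2`, ... and contain only A/C/G/T (the simulator
#' never emits N).
#'
#' @param n_contigs number of contigs.
#' @param length length of each contig in nt.
#' @param gc target G+C fraction, strictly between 0 and 1.
#' @param seed integer seed; the same seed reproduces the genome exactly.
#' @return A [Biostrings::DNAStringSet] with one entry per contig.
#' @examples
#' g <- simulate_genome(1, 1000, gc = 0.5, seed = 7)
#' Biostrings::letterFrequency(g, "GC", as.prob = TRUE)
#' @export
simulate_genome <- function(n_contigs, length, gc = 0.5, seed = 1L) {
  if (!is.numeric(length) || length(length) != 1L || length < 1)
    stop("'length' must be a positive integer")
  if (!is.numeric(n_contigs) || n_contigs < 1)
    stop("'n_contigs' must be a positive integer")
  if (gc <= 0 || gc >= 1)
    stop("'gc' must be strictly between 0 and 1")
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_contigs), function(i) {
      paste(sample(names(probs), length, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1))
  })
  names(seqs) <- sprintf("contig%d", seq_len(n_contigs))
  Biostrings::DNAStringSet(seqs)
}

#' Construct the synthetic oligo duplex genome
#'
#' Builds a one-contig genome emulating a synthetic double-stranded oligo
#' carrying a single 6mA on the plus strand, together with the matching
#' methylation truth.  The sequence around the methylated adenine is
#' random (seeded); the adenine itself is fixed.  This is the worked
#' example used to check the cleavage and stop geometry: an endonuclease
#' cut immediately 3' of the 6mA at the 25th position of a 59-nt duplex
#' yields a 25-nt upstream and a 34-nt downstream fragment.
#'
#' @param length duplex length in nt (default 59).
#' @param methyl_pos 1-based position of the methylated adenine on the
#'   plus strand (default 25).
#' @param seed seed for the flanking sequence.
#' @return list with elements `genome` (DNAStringSet) and `truth`
#'   (a methylation-truth data frame, see [plant_methylation()]).
#' @export
synthetic_duplex <- function(length = 59L, methyl_pos = 25L, seed = 1L) {
  stopifnot(methyl_pos >= 1L, methyl_pos <= length)
  g <- simulate_genome(1L, length, gc = 0.5, seed = seed)
  s <- as.character(g[[1]])
  substr(s, methyl_pos, methyl_pos) <- "A"
  g <- Biostrings::DNAStringSet(stats::setNames(s, "oligo"))
  truth <- data.frame(
    contig = "oligo", pos = methyl_pos - 1L, strand = "+",
    methyl_fraction = 1, motif = "6mA",
    stringsAsFactors = FALSE
  )
  list(genome = g, truth = truth)
}

contig_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

# per-contig character vector of plus-strand bases
contig_chars <- function(genome, contig) {
  strsplit(as.character(genome[[contig]]), "", fixed = TRUE)[[1]]
}

complement_chars <- function(x) chartr("ACGTN", "TGCAN", x)

#' Read a genome from FASTA
#'
#' Sequences are uppercased on read.  Duplicate headers are an error.
#'
#' @param path FASTA file.
#' @return DNAStringSet.
#' @export
read_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  # keep only the first word of each header, as aligners do
  names(g) <- sub("\\s.*$", "", names(g))
  if (anyDuplicated(names(g)))
    stop("duplicate FASTA headers: ",
         paste(unique(names(g)[duplicated(names(g))]), collapse = ", "))
  if (any(!nzchar(names(g)))) stop("empty FASTA header")
  Biostrings::DNAStringSet(toupper(as.character(g)))
}

#' Write a genome to FASTA
#'
#' @param genome DNAStringSet.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}
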