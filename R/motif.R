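#' Define a methylation motif rule
#'
#' A motif rule names an IUPAC pattern, the offset of the methylated
#' adenine within it, and whether both strands are scanned.  The pattern
#' must contain exactly one literal `A`, at `methyl_offset`.  Allowed
#' IUPAC codes are A, C, G, T, V (= A/C/G), B (= C/G/T) and N.
#'
#' @param name short label, e.g. `"GATC"`.
#' @param pattern IUPAC string, e.g. `"GATC"` or `"VATB"`.
#' @param methyl_offset 0-based offset of the methylated A in `pattern`.
#' @param both_strands scan both strands of the duplex?
#' @return an object of class `motif_rule`.
#' @examples
#' rule_gatc()
#' motif_rule("VATB", "VATB", 1L)
#' @export
motif_rule <- function(name, pattern, methyl_offset, both_strands = TRUE) {
  pattern <- toupper(pattern)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  if (!all(chars %in% c("A", "C", "G", "T", "V", "B", "N")))
    stop("pattern may only use IUPAC codes A, C, G, T, V, B, N")
  methyl_offset <- as.integer(methyl_offset)
  if (methyl_offset < 0L || methyl_offset >= length(chars) ||
      chars[methyl_offset + 1L] != "A")
    stop("pattern must have the methylated 'A' at methyl_offset")
  if (sum(chars == "A") != 1L)
    stop("pattern must contain exactly one literal 'A'")
  structure(
    list(name = name, pattern = pattern, methyl_offset = methyl_offset,
         both_strands = isTRUE(both_strands)),
    class = "motif_rule"
  )
}

#' @rdname motif_rule
#' @export
rule_gatc <- function(both_strands = TRUE)
  motif_rule("GATC", "GATC", 1L, both_strands)

#' @rdname motif_rule
#' @export
rule_vatb <- function(both_strands = TRUE)
  motif_rule("VATB", "VATB", 1L, both_strands)

iupac_to_regex <- function(pattern) {
  map <- c(A = "A", C = "C", G = "G", T = "T",
           V = "[ACG]", B = "[CGT]", N = "[ACGT]")
  paste(map[strsplit(pattern, "", fixed = TRUE)[[1]]], collapse = "")
}

rc_pattern <- function(pattern) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(pattern)))
}

is_palindromic <- function(pattern) identical(pattern, rc_pattern(pattern))

# 0-based start positions of IUPAC pattern matches on the plus strand
motif_starts <- function(genome, pattern) {
  pat <- Biostrings::DNAString(pattern)
  out <- lapply(names(genome), function(ct) {
    m <- Biostrings::matchPattern(pat, genome[[ct]], fixed = FALSE)
    data.frame(contig = rep(ct, length(m)),
               start = BiocGenerics::start(m) - 1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

empty_truth <- function() {
  data.frame(contig = character(), pos = integer(), strand = character(),
             methyl_fraction = numeric(), motif = character(),
             stringsAsFactors = FALSE)
}

#' Plant 6mA sites in a genome
#'
#' Scans the genome for a motif and marks matching adenines as
#' methylated, each independently with probability `fraction`.  With a
#' palindromic pattern and `both_strands = TRUE` (the fully-methylated
#' case, e.g. Dam GATC), the plus- and minus-strand adenines of one
#' duplex occurrence are included or excluded jointly, so the truth is
#' symmetric per duplex.  Hemi-methylated truths are produced with a
#' rule whose `both_strands = FALSE` (plus strand only).
#'
#' @param genome DNAStringSet.
#' @param rule a [motif_rule()].
#' @param fraction per-occurrence methylation probability, in \[0, 1\].
#' @param seed integer seed.
#' @param methyl_fraction per-site stoichiometry recorded in the truth
#'   (multiplies `capture_prob` in the fragment simulators).
#' @return data frame with columns `contig`, `pos` (0-based position of
#'   the methylated A), `strand`, `methyl_fraction`, `motif`.
#' @export
plant_methylation <- function(genome, rule, fraction, seed = 1L,
                              methyl_fraction = 1) {
  if (!inherits(rule, "motif_rule")) stop("'rule' must be a motif_rule")
  if (fraction < 0 || fraction > 1) stop("'fraction' must be in [0, 1]")
  L <- nchar(rule$pattern)
  mo <- rule$methyl_offset
  plus <- motif_starts(genome, rule$pattern)
  plus_sites <- data.frame(contig = plus$contig, pos = plus$start + mo,
                           strand = rep("+", nrow(plus)),
                           stringsAsFactors = FALSE)
  pal <- is_palindromic(rule$pattern)
  minus_sites <- NULL
  if (rule$both_strands) {
    rcm <- if (pal) plus else motif_starts(genome, rc_pattern(rule$pattern))
    minus_sites <- data.frame(contig = rcm$contig,
                              pos = rcm$start + (L - 1L - mo),
                              strand = rep("-", nrow(rcm)),
                              stringsAsFactors = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    if (rule$both_strands && pal) {
      keep <- runif(nrow(plus_sites)) < fraction
      sites <- rbind(plus_sites[keep, , drop = FALSE],
                     minus_sites[keep, , drop = FALSE])
    } else {
      sites <- rbind(plus_sites, minus_sites)
      sites <- sites[runif(nrow(sites)) < fraction, , drop = FALSE]
    }
    sites
  }) -> sites
  if (nrow(sites) == 0L) return(empty_truth())
  sites$methyl_fraction <- methyl_fraction
  sites$motif <- rule$name
  sites <- sites[order(sites$contig, sites$pos, sites$strand), ]
  rownames(sites) <- NULL
  validate_truth(sites, genome)
  sites
}

validate_truth <- function(truth, genome) {
  if (nrow(truth) == 0L) return(invisible(TRUE))
  lens <- contig_lengths(genome)
  if (!all(truth$contig %in% names(lens)))
    stop("truth refers to contigs absent from the genome")
  if (any(truth$pos < 0L) || any(truth$pos >= lens[truth$contig]))
    stop("truth positions outside contig bounds")
  for (ct in unique(truth$contig)) {
    sel <- truth$contig == ct
    b <- contig_chars(genome, ct)[truth$pos[sel] + 1L]
    onstrand <- ifelse(truth$strand[sel] == "+", b, complement_chars(b))
    if (any(onstrand != "A"))
      stop("truth site base is not 'A' on its strand (contig ", ct, ")")
  }
  invisible(TRUE)
}
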