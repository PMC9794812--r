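#' Collapse exact coordinate duplicates
#'
#' Records identical in (`contig`, `start`, `end`, `strand`) are
#' collapsed to their first occurrence; order is preserved and the
#' operation is idempotent.  This is the simplified stand-in for an
#' upstream duplicate-marking step on real libraries; simulator output
#' is already duplicate-free in the PCR sense and should normally not
#' be collapsed (coordinate-identical stop fragments are real signal).
#'
#' @param aln alignment data frame.
#' @return alignment data frame without coordinate duplicates.
#' @export
dedup_alignments <- function(aln) {
  key <- paste(aln$contig, aln$start, aln$end, aln$strand, sep = "\r")
  aln[!duplicated(key), , drop = FALSE]
}

# candidate-site events implied by alignment termini.
# exo: the 5'-terminal base itself.
# endo: both termini; a 3' terminus maps to its own position, a 5'
# terminus to the position immediately 5' of it on the same strand --
# the inverse of the cut-immediately-3'-of-the-A rule, so both pieces
# flanking a cut vote for the same adenine.
terminal_events <- function(aln, mode) {
  plus <- aln$strand == "+"
  if (mode == "exo") {
    data.table(contig = aln$contig,
               pos = ifelse(plus, aln$start, aln$end - 1L),
               strand = aln$strand)
  } else {
    data.table(
      contig = rep(aln$contig, 2L),
      pos = c(ifelse(plus, aln$start - 1L, aln$end),      # 5' termini
              ifelse(plus, aln$end - 1L, aln$start)),     # 3' termini
      strand = rep(aln$strand, 2L)
    )
  }
}

#' Count terminal events and coverage per position and strand
#'
#' Converts alignments into the per-position statistics of the binomial
#' site test: `k`, the number of terminal events assigned to the
#' candidate site, and `n`, the number of fragments whose span covers
#' the position (strand-blind span coverage).  In `exo` mode each
#' alignment contributes one event at its strand-specific 5'-terminal
#' base; in `endo` mode both termini contribute, mapped to candidate
#' adenines by the inverse of the cut rule (see the package vignette).
#' Candidate positions whose strand base is not A are counted too and
#' flagged by the `base` column; they carry the background stratum used
#' by [estimate_background()].
#'
#' @param aln alignment data frame.
#' @param mode `"endo"` or `"exo"`.
#' @param genome DNAStringSet sharing contigs with `aln`.
#' @return data frame (`contig`, `pos`, `strand`, `base`, `k`, `n`) over
#'   all covered positions, with attributes `mode`, `n_alignments` and
#'   `dropped_events` (events falling outside contig bounds).
#' @export
count_terminals <- function(aln, mode = c("endo", "exo"), genome) {
  mode <- match.arg(mode)
  validate_alignments(aln, genome)
  lens <- contig_lengths(genome)
  ev <- terminal_events(aln, mode)
  inb <- ev$pos >= 0L & ev$pos < lens[ev$contig]
  dropped <- sum(!inb)
  ev <- ev[inb]
  kt <- ev[, .(k = .N), by = .(contig, pos, strand)]
  out <- vector("list", length(lens))
  adt <- as.data.table(aln)
  for (i in seq_along(lens)) {
    ct <- names(lens)[i]
    sel <- adt[contig == ct]
    if (nrow(sel) == 0L) next
    cov <- IRanges::coverage(IRanges::IRanges(sel$start + 1L, sel$end),
                             width = lens[ct])
    covv <- as.integer(cov)
    covered <- which(covv > 0L) - 1L
    chars <- contig_chars(genome, ct)[covered + 1L]
    out[[i]] <- data.table(
      contig = ct,
      pos = rep(covered, 2L),
      strand = rep(c("+", "-"), each = length(covered)),
      base = c(chars, complement_chars(chars)),
      n = rep(covv[covered + 1L], 2L)
    )
  }
  tab <- rbindlist(out)
  tab <- merge(tab, kt, by = c("contig", "pos", "strand"), all.x = TRUE)
  tab[is.na(k), k := 0L]
  # events at positions no fragment covers are untestable; count them
  # with the out-of-bounds ones
  dropped <- dropped + (sum(kt$k) - sum(tab$k))
  setorder(tab, contig, pos, strand)
  res <- as.data.frame(tab[, .(contig, pos, strand, base, k, n)])
  attr(res, "mode") <- mode
  attr(res, "n_alignments") <- nrow(aln)
  attr(res, "dropped_events") <- dropped
  res
}

#' Estimate the background terminal rate
#'
#' Under random shearing every covered position receives terminal events
#' at a common per-fragment rate `p0`.  The estimator uses only
#' positions whose strand base is not adenine -- positions where true
#' 6mA signal cannot occur -- making it robust even when nearly every
#' motif adenine in the genome is methylated.  If the non-A stratum is
#' empty the global rate is used.
#'
#' @param counts terminal counts from [count_terminals()].
#' @return object of class `background_model` with element `p0`.
#' @export
estimate_background <- function(counts) {
  if (nrow(counts) == 0L || sum(counts$n) == 0) stop("no covered positions")
  if (sum(counts$k) == 0)
    stop("degenerate input: no terminal events observed")
  nonA <- counts$base != "A"
  p0 <- NA_real_
  stratum <- "non-A"
  if (any(nonA) && sum(counts$n[nonA]) > 0)
    p0 <- sum(counts$k[nonA]) / sum(counts$n[nonA])
  if (is.na(p0) || p0 <= 0) {
    p0 <- sum(counts$k) / sum(counts$n)
    stratum <- "global"
  }
  if (p0 <= 0 || p0 >= 1) stop("background rate estimate outside (0, 1)")
  structure(list(p0 = p0, stratum = stratum), class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("background terminal rate p0 = %.3g (%s stratum)\n",
              x$p0, x$stratum))
  invisible(x)
}
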