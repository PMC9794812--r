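#' Simulation configuration
#'
#' Parameters of the fragment simulators.  Fragment lengths are drawn
#' from a truncated normal (minimum 20 nt) and fragments are placed
#' uniformly so that they lie fully inside their contig.
#' `capture_prob` is the probability that an existing 6mA produces a
#' cleavage (endonuclease) or stop (exonuclease) event on a fragment
#' copy that covers it; it multiplies the per-site `methyl_fraction` of
#' the truth.  `endo_cut_offset` shifts the cut away from its default
#' position immediately 3' of the methylated adenine.
#'
#' @param n_fragments number of fragments to draw.
#' @param capture_prob per-covering-fragment event probability, in \[0, 1\].
#' @param frag_len_mean,frag_len_sd fragment length distribution (nt).
#' @param endo_cut_offset cut placement offset (nt, default 0 = the
#'   phosphodiester bond immediately 3' of the methylated A).
#' @param seed integer seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_fragments, capture_prob = 0.5,
                       frag_len_mean = 200L, frag_len_sd = 50L,
                       endo_cut_offset = 0L, seed = 1L) {
  if (n_fragments < 1) stop("'n_fragments' must be positive")
  if (capture_prob < 0 || capture_prob > 1)
    stop("'capture_prob' must be in [0, 1]")
  if (frag_len_mean < 20) stop("'frag_len_mean' must be at least 20")
  if (frag_len_sd < 0) stop("'frag_len_sd' must be non-negative")
  structure(
    list(n_fragments = as.integer(n_fragments),
         capture_prob = capture_prob,
         frag_len_mean = as.integer(frag_len_mean),
         frag_len_sd = as.integer(frag_len_sd),
         endo_cut_offset = as.integer(endo_cut_offset),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Fragment count for a target span coverage
#'
#' Convenience arithmetic: `round(depth * genome_length / frag_len_mean)`.
#'
#' @param depth target mean span coverage.
#' @param genome DNAStringSet.
#' @param frag_len_mean mean fragment length (nt).
#' @return integer fragment count.
#' @export
fragments_for_depth <- function(depth, genome, frag_len_mean = 200L) {
  as.integer(round(depth * sum(Biostrings::width(genome)) / frag_len_mean))
}

# Draw fragments uniformly inside contigs.  Assumes the RNG state is set.
sample_fragments <- function(genome, cfg) {
  lens <- contig_lengths(genome)
  nfrag <- cfg$n_fragments
  ci <- if (length(lens) == 1L) rep(1L, nfrag) else
    sample(length(lens), nfrag, replace = TRUE, prob = lens)
  L <- pmax(20L, as.integer(round(rnorm(nfrag, cfg$frag_len_mean,
                                        cfg$frag_len_sd))))
  clen <- unname(lens[ci])
  L <- pmin(L, clen)
  start <- as.integer(floor(runif(nfrag) * (clen - L + 1)))
  data.table(frag_id = seq_len(nfrag), contig = names(lens)[ci],
             start = start, end = start + L)
}

aln_df <- function(contig = character(), start = integer(),
                   end = integer(), strand = character(),
                   source_tag = character()) {
  data.frame(contig = contig, start = as.integer(start),
             end = as.integer(end), strand = strand,
             source_tag = source_tag, stringsAsFactors = FALSE)
}

# (site, fragment) pairs where the fragment span covers the site
truth_fragment_pairs <- function(frags, truth) {
  if (is.null(truth) || nrow(truth) == 0L) {
    return(data.table(frag_id = integer(), pos = integer(),
                      strand = character(), methyl_fraction = numeric(),
                      fstart = integer(), fend = integer()))
  }
  out <- vector("list", 0L)
  for (ct in unique(truth$contig)) {
    tsel <- truth[truth$contig == ct, , drop = FALSE]
    fsel <- frags[frags$contig == ct]
    if (nrow(fsel) == 0L) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(tsel$pos + 1L, width = 1L),
      IRanges::IRanges(fsel$start + 1L, fsel$end)
    )
    if (length(hits) == 0L) next
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    out[[length(out) + 1L]] <- data.table(
      frag_id = fsel$frag_id[si], pos = tsel$pos[qi],
      strand = tsel$strand[qi],
      methyl_fraction = tsel$methyl_fraction[qi],
      fstart = fsel$start[si], fend = fsel$end[si]
    )
  }
  if (length(out) == 0L) {
    return(data.table(frag_id = integer(), pos = integer(),
                      strand = character(), methyl_fraction = numeric(),
                      fstart = integer(), fend = integer()))
  }
  rbindlist(out)
}

#' Simulate endonuclease-mode fragments
#'
#' Fragments are drawn by random shearing; for every planted 6mA whose
#' duplex a fragment covers, with probability
#' `capture_prob * methyl_fraction` the fragment is cut on the
#' methylated strand between the adenine and the next base 3' of it
#' (shifted by `endo_cut_offset`), replacing the fragment with two
#' pieces whose abutting termini flank the cut.  Multiple captured sites
#' on one fragment yield multiple pieces that partition its span.  Each
#' emitted alignment's strand (the sequencing orientation that defines
#' its 5' terminal) is drawn uniformly.
#'
#' @param genome DNAStringSet.
#' @param truth methylation truth from [plant_methylation()]; may be
#'   empty (pure-shear background).
#' @param cfg a [sim_config()].
#' @return alignment data frame (`contig`, `start`, `end`, `strand`,
#'   `source_tag`), 0-based half-open.
#' @export
simulate_fragments_endo <- function(genome, truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(truth)) validate_truth(truth, genome)
  withr::with_seed(cfg$seed, {
    frags <- sample_fragments(genome, cfg)
    label <- ifelse(runif(nrow(frags)) < 0.5, "+", "-")
    pairs <- truth_fragment_pairs(frags, truth)
    setorder(pairs, frag_id, pos, strand)
    if (nrow(pairs) > 0L) {
      pairs[, captured := runif(.N) < cfg$capture_prob * methyl_fraction]
      off <- cfg$endo_cut_offset
      # cut coordinate c: pieces are [start, c) and [c, end)
      pairs[, cutpos := ifelse(strand == "+", pos + 1L + off, pos - off)]
      cuts <- pairs[captured & cutpos > fstart & cutpos < fend,
                    .(frag_id, cutpos)]
      cuts <- unique(cuts)
    } else {
      cuts <- data.table(frag_id = integer(), cutpos = integer())
    }
    cut_ids <- unique(cuts$frag_id)
    uncut <- frags[!frag_id %in% cut_ids]
    out_uncut <- data.table(
      frag_id = uncut$frag_id, contig = uncut$contig,
      start = uncut$start, end = uncut$end, piece = 1L,
      source_tag = "shear"
    )
    if (nrow(cuts) > 0L) {
      cuts <- merge(cuts, frags[, .(frag_id, contig, fstart = start,
                                    fend = end)], by = "frag_id")
      setorder(cuts, frag_id, cutpos)
      pieces <- cuts[, {
        b <- c(fstart[1L], cutpos, fend[1L])
        list(contig = contig[1L], start = b[-length(b)], end = b[-1L],
             piece = seq_len(length(b) - 1L),
             source_tag = c(rep("endo_up", length(cutpos)), "endo_down"))
      }, by = frag_id]
      out <- rbind(out_uncut, pieces)
    } else {
      out <- out_uncut
    }
    setorder(out, frag_id, piece)
    # sequencing orientation: first piece inherits the fragment's label,
    # additional pieces draw their own
    out[, strand := label[frag_id]]
    extra <- out$piece > 1L
    if (any(extra))
      out$strand[extra] <- ifelse(runif(sum(extra)) < 0.5, "+", "-")
    aln_df(out$contig, out$start, out$end, out$strand, out$source_tag)
  })
}

#' Simulate exonuclease-mode fragments
#'
#' Fragments are drawn by random shearing; each strand of every fragment
#' is then digested 5'->3' independently.  Walking 5'->3' along the
#' strand, each planted 6mA inside the fragment stalls the digestion
#' with probability `capture_prob * methyl_fraction`; the first stall
#' wins (the exonuclease cannot pass a block), and the strand is trimmed
#' so the methylated adenine becomes its 5'-terminal base.  A strand
#' with no stall is emitted with its native shear 5' end.  Every
#' fragment therefore emits one plus-strand and one minus-strand
#' alignment.
#'
#' @inheritParams simulate_fragments_endo
#' @return alignment data frame, 0-based half-open.
#' @export
simulate_fragments_exo <- function(genome, truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(truth)) validate_truth(truth, genome)
  withr::with_seed(cfg$seed, {
    frags <- sample_fragments(genome, cfg)
    pairs <- truth_fragment_pairs(frags, truth)
    stops <- NULL
    if (nrow(pairs) > 0L) {
      # encounter order along the digested strand
      pairs[, ord := ifelse(strand == "+", pos, -pos)]
      setorder(pairs, frag_id, strand, ord)
      pairs[, captured := runif(.N) < cfg$capture_prob * methyl_fraction]
      stops <- pairs[captured == TRUE,
                     .(stop_pos = pos[1L]), by = .(frag_id, strand)]
    }
    plus <- data.table(frag_id = frags$frag_id, contig = frags$contig,
                       start = frags$start, end = frags$end,
                       strand = "+", source_tag = "shear")
    minus <- data.table(frag_id = frags$frag_id, contig = frags$contig,
                        start = frags$start, end = frags$end,
                        strand = "-", source_tag = "shear")
    if (!is.null(stops) && nrow(stops) > 0L) {
      sp <- stops[strand == "+"]
      if (nrow(sp) > 0L) {
        idx <- match(sp$frag_id, plus$frag_id)
        plus$start[idx] <- sp$stop_pos
        plus$source_tag[idx] <- "exo_stop"
      }
      sm <- stops[strand == "-"]
      if (nrow(sm) > 0L) {
        idx <- match(sm$frag_id, minus$frag_id)
        minus$end[idx] <- sm$stop_pos + 1L
        minus$source_tag[idx] <- "exo_stop"
      }
    }
    out <- rbind(plus, minus)
    setorder(out, frag_id, strand)
    aln_df(out$contig, out$start, out$end, out$strand, out$source_tag)
  })
}

#' Simulate the whole-genome-amplified (WGA) null
#'
#' Pure random shearing with no cleavage or stop events: the
#' modification-free negative control used to measure familywise error
#' control.  Structurally identical to [simulate_fragments_endo()] with
#' an empty truth, but tagged `"wga"`.
#'
#' @inheritParams simulate_fragments_endo
#' @return alignment data frame.
#' @export
simulate_wga <- function(genome, cfg) {
  out <- simulate_fragments_endo(genome, empty_truth(), cfg)
  out$source_tag <- "wga"
  out
}

#' Mix spike-in alignments into a host sample
#'
#' Renames contigs with disjoint prefixes and returns the union; the
#' partition is recoverable exactly with [partition_by_namespace()].
#'
#' @param host,spike alignment data frames on disjoint genomes.
#' @param host_prefix,spike_prefix contig name prefixes; neither may be
#'   a prefix of the other.
#' @return combined alignment data frame with prefixed contig names.
#' @export
mix_spikein <- function(host, spike, host_prefix = "host_",
                        spike_prefix = "spike_") {
  if (startsWith(host_prefix, spike_prefix) ||
      startsWith(spike_prefix, host_prefix))
    stop("prefix collision: '", host_prefix, "' vs '", spike_prefix, "'")
  host$contig <- paste0(host_prefix, host$contig)
  spike$contig <- paste0(spike_prefix, spike$contig)
  rbind(host, spike)
}
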