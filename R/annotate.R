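passed_only <- function(calls) {
  if ("passed" %in% names(calls)) calls[calls$passed, , drop = FALSE]
  else calls
}

site_key <- function(df) paste(df$contig, df$pos, df$strand, sep = "\r")

# strand-oriented flank sequences (minus-strand sites reverse
# complemented so the methylated strand reads 5'->3'); sites without a
# full flank are excluded.
flank_sequences <- function(sites, genome, flank) {
  lens <- contig_lengths(genome)
  ok <- sites$pos - flank >= 0L & sites$pos + flank < lens[sites$contig]
  kept <- sites[ok, , drop = FALSE]
  if (nrow(kept) == 0L)
    return(list(seqs = Biostrings::DNAStringSet(), excluded = sum(!ok)))
  views <- Biostrings::DNAStringSet(vapply(seq_len(nrow(kept)), function(i) {
    as.character(Biostrings::subseq(genome[[kept$contig[i]]],
                                    start = kept$pos[i] - flank + 1L,
                                    end = kept$pos[i] + flank + 1L))
  }, character(1)))
  minus <- kept$strand == "-"
  if (any(minus))
    views[minus] <- Biostrings::reverseComplement(views[minus])
  list(seqs = views, excluded = sum(!ok))
}

#' Sequence-context summary of called sites
#'
#' Extracts strand-oriented flanks around each site, computes the base
#' frequency matrix over positions `-flank..+flank` (columns sum to 1),
#' and the fraction of sites matching each motif rule with the rule's
#' adenine aligned on the site.
#'
#' @param calls site calls (only passing sites are used when a `passed`
#'   column is present).
#' @param genome DNAStringSet.
#' @param rules list of [motif_rule()] objects.
#' @param flank flank width in nt (default 5; must cover each rule's
#'   pattern around its adenine).
#' @return list with `total_sites`, `excluded_edge`, `fraction_matching`
#'   (named per rule), `base_freq` (4 x (2 flank + 1) matrix), and
#'   `match_matrix` (site x rule logical).
#' @export
motif_summary <- function(calls, genome, rules, flank = 5L) {
  if (flank < 1L) stop("'flank' must be >= 1")
  if (inherits(rules, "motif_rule")) rules <- list(rules)
  sites <- passed_only(calls)
  fl <- flank_sequences(sites, genome, flank)
  seqs <- as.character(fl$seqs)
  nseq <- length(seqs)
  freq <- matrix(NA_real_, 4L, 2L * flank + 1L,
                 dimnames = list(c("A", "C", "G", "T"), -flank:flank))
  if (nseq > 0L) {
    cm <- Biostrings::consensusMatrix(fl$seqs, as.prob = TRUE,
                                      baseOnly = TRUE)
    freq[] <- cm[c("A", "C", "G", "T"), ]
  }
  match_matrix <- matrix(logical(), nseq, length(rules))
  frac <- stats::setNames(rep(NA_real_, length(rules)),
                          vapply(rules, `[[`, character(1), "name"))
  for (j in seq_along(rules)) {
    r <- rules[[j]]
    L <- nchar(r$pattern)
    from <- flank + 1L - r$methyl_offset
    to <- from + L - 1L
    if (from < 1L || to > 2L * flank + 1L)
      stop("flank too small for rule '", r$name, "'")
    if (nseq > 0L) {
      window <- substr(seqs, from, to)
      hits <- grepl(paste0("^", iupac_to_regex(r$pattern), "$"), window)
      match_matrix[, j] <- hits
      frac[j] <- mean(hits)
    }
  }
  colnames(match_matrix) <- names(frac)
  list(total_sites = nseq, excluded_edge = fl$excluded,
       fraction_matching = frac, base_freq = freq,
       match_matrix = match_matrix)
}

#' Classify duplex motif occurrences as fully or hemi methylated
#'
#' For a palindromic motif (e.g. GATC) each duplex occurrence carries
#' one candidate adenine per strand.  An occurrence is `full` when both
#' strand adenines are called, `hemi_plus`/`hemi_minus` when only one
#' is, `unmethylated` when neither is.  Strand-resolved calls (the
#' exonuclease readout) are required for this distinction to be
#' meaningful: endonuclease cleavage between the two adenines of a
#' palindrome does not reveal which strand was modified.
#'
#' @param calls site calls (passing sites used).
#' @param genome DNAStringSet.
#' @param rule palindromic [motif_rule()].
#' @return data frame with `contig`, `start` (0-based occurrence
#'   start), `plus_pos`, `minus_pos`, `status`.
#' @export
classify_symmetry <- function(calls, genome, rule) {
  if (!inherits(rule, "motif_rule")) stop("'rule' must be a motif_rule")
  if (!is_palindromic(rule$pattern))
    stop("symmetry classification needs a palindromic pattern")
  occ <- motif_starts(genome, rule$pattern)
  L <- nchar(rule$pattern)
  mo <- rule$methyl_offset
  plus_pos <- occ$start + mo
  minus_pos <- occ$start + (L - 1L - mo)
  called <- site_key(passed_only(calls))
  pk <- paste(occ$contig, plus_pos, "+", sep = "\r") %in% called
  mk <- paste(occ$contig, minus_pos, "-", sep = "\r") %in% called
  status <- ifelse(pk & mk, "full",
            ifelse(pk, "hemi_plus",
            ifelse(mk, "hemi_minus", "unmethylated")))
  data.frame(contig = occ$contig, start = occ$start,
             plus_pos = plus_pos, minus_pos = minus_pos,
             status = status, stringsAsFactors = FALSE)
}

#' TSS distance profile and periodicity
#'
#' For each site, the signed distance to its nearest transcription
#' start site, oriented by the TSS strand (downstream of transcription
#' positive).  The histogram of distances within `[-window, window]` is
#' autocorrelated and the dominant period reported as the lag of the
#' autocorrelation peak searched within `period_range`.
#'
#' @param calls site calls (passing sites used).
#' @param tss data frame from [read_tss()] (`contig`, `pos`, `strand`).
#' @param window histogram half-width in nt (>= 100).
#' @param period_range lag range searched for the period, in nt.
#' @return list with `distances`, `histogram` (data frame `distance`,
#'   `count`), `dominant_period`, `period_score` (normalised
#'   autocorrelation at the peak), `n_sites_unassigned`.
#' @export
tss_profile <- function(calls, tss, window = 2000L,
                        period_range = c(50L, 300L)) {
  if (is.null(tss) || nrow(tss) == 0L) stop("empty TSS list")
  if (window < 100L) stop("'window' must be >= 100")
  sites <- passed_only(calls)
  dists <- integer()
  unassigned <- 0L
  for (ct in unique(sites$contig)) {
    s <- sites[sites$contig == ct, , drop = FALSE]
    t <- tss[tss$contig == ct, , drop = FALSE]
    if (nrow(t) == 0L) { unassigned <- unassigned + nrow(s); next }
    o <- order(t$pos)
    tp <- t$pos[o]; tstr <- t$strand[o]
    idx <- findInterval(s$pos, tp)
    lo <- pmax(idx, 1L)
    hi <- pmin(idx + 1L, length(tp))
    pick <- ifelse(abs(s$pos - tp[lo]) <= abs(s$pos - tp[hi]), lo, hi)
    d <- s$pos - tp[pick]
    d <- ifelse(tstr[pick] == "-", -d, d)
    dists <- c(dists, as.integer(d))
  }
  h <- tabulate(dists + window + 1L, nbins = 2L * window + 1L)
  hist_df <- data.frame(distance = -window:window, count = h)
  dominant_period <- NA_real_
  period_score <- NA_real_
  lag_max <- min(period_range[2], length(h) - 1L)
  if (sum(h) > 0L && stats::var(h) > 0 && lag_max >= period_range[1]) {
    ac <- acf(h, lag.max = lag_max, plot = FALSE,
              demean = TRUE)$acf[, 1, 1]
    lags <- seq.int(period_range[1], lag_max)
    vals <- ac[lags + 1L]
    best <- which.max(vals)
    dominant_period <- lags[best]
    period_score <- vals[best]
  }
  list(distances = dists, histogram = hist_df,
       dominant_period = dominant_period, period_score = period_score,
       n_sites_unassigned = unassigned)
}

#' Overlap between two site sets
#'
#' Intersection by exact (`contig`, `pos`, `strand`) match, with the
#' Jaccard index.
#'
#' @param a,b site calls (passing sites used).
#' @return list with `n_a`, `n_b`, `n_both`, `jaccard`.
#' @export
overlap_sites <- function(a, b) {
  ka <- unique(site_key(passed_only(a)))
  kb <- unique(site_key(passed_only(b)))
  nboth <- length(intersect(ka, kb))
  nunion <- length(union(ka, kb))
  list(n_a = length(ka), n_b = length(kb), n_both = nboth,
       jaccard = if (nunion == 0L) NA_real_ else nboth / nunion)
}

#' Fraction of sites inside regions
#'
#' Counts calls whose position lies inside at least one 0-based
#' half-open region (strand ignored).
#'
#' @param calls site calls (passing sites used).
#' @param regions region data frame (`contig`, `start`, `end`).
#' @return list with `n_sites`, `n_inside`, `fraction`.
#' @export
sites_in_regions <- function(calls, regions) {
  sites <- passed_only(calls)
  if (nrow(sites) == 0L)
    return(list(n_sites = 0L, n_inside = 0L, fraction = NA_real_))
  if (is.null(regions) || nrow(regions) == 0L)
    return(list(n_sites = nrow(sites), n_inside = 0L, fraction = 0))
  q <- GenomicRanges::GRanges(sites$contig,
                              IRanges::IRanges(sites$pos + 1L, width = 1L))
  s <- GenomicRanges::GRanges(regions$contig,
                              IRanges::IRanges(regions$start + 1L,
                                               regions$end))
  inside <- GenomicRanges::countOverlaps(q, s, ignore.strand = TRUE) > 0L
  list(n_sites = nrow(sites), n_inside = sum(inside),
       fraction = mean(inside))
}

#' Partition spike-in alignments from a mixed sample
#'
#' The inverse of [mix_spikein()]: records on contigs carrying
#' `spike_prefix` are the spike-in, the rest the host; prefixes are
#' stripped so the round trip recovers both sets exactly.  An empty
#' `spike_prefix` matches nothing.  When `host_prefix` is given, any
#' contig matching neither prefix is an error.
#'
#' @param aln mixed alignment data frame.
#' @param spike_prefix contig prefix of the spike-in genome.
#' @param host_prefix optional contig prefix of the host genome.
#' @return list with elements `host` and `spike`.
#' @export
partition_by_namespace <- function(aln, spike_prefix,
                                   host_prefix = NULL) {
  is_spike <- nzchar(spike_prefix) & startsWith(aln$contig, spike_prefix)
  host <- aln[!is_spike, , drop = FALSE]
  spike <- aln[is_spike, , drop = FALSE]
  spike$contig <- substring(spike$contig, nchar(spike_prefix) + 1L)
  if (!is.null(host_prefix)) {
    bad <- !startsWith(host$contig, host_prefix)
    if (any(bad))
      stop("contigs match neither prefix: ",
           paste(head(unique(host$contig[bad]), 5), collapse = ", "))
    host$contig <- substring(host$contig, nchar(host_prefix) + 1L)
  }
  rownames(host) <- NULL
  rownames(spike) <- NULL
  list(host = host, spike = spike)
}
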