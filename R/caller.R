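#' Site-caller configuration
#'
#' Defaults follow the published analysis: Bonferroni-corrected p-values
#' at or below 0.01 under a fragment-coverage cutoff of 5, testing
#' adenines only.  `correction = "bh"` switches to Benjamini-Hochberg,
#' the alternative reading of an "FDR" threshold.  `require_A = FALSE`
#' is the damage-detection mode in which any base may carry a terminal
#' excess.  `edge_exclude` masks positions within that many nt of a
#' contig end, where shear termini are constrained by the boundary and
#' the binomial null's proportionality assumption fails (see vignette).
#'
#' @param coverage_cutoff minimum fragment coverage to test (default 5).
#' @param alpha adjusted-p threshold (default 0.01); equality passes.
#' @param correction `"bonferroni"` (default) or `"bh"`.
#' @param require_A only test positions whose strand base is adenine.
#' @param edge_exclude contig-end mask width in nt (default 500).
#' @return object of class `caller_config`.
#' @export
caller_config <- function(coverage_cutoff = 5L, alpha = 0.01,
                          correction = c("bonferroni", "bh"),
                          require_A = TRUE, edge_exclude = 500L) {
  correction <- match.arg(correction)
  if (coverage_cutoff < 1) stop("'coverage_cutoff' must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  if (edge_exclude < 0) stop("'edge_exclude' must be >= 0")
  structure(
    list(coverage_cutoff = as.integer(coverage_cutoff), alpha = alpha,
         correction = correction, require_A = isTRUE(require_A),
         edge_exclude = as.integer(edge_exclude)),
    class = "caller_config"
  )
}

#' One-sided binomial tail probability
#'
#' Exact upper-tail probability `P(X >= k)` for `X ~ Binomial(n, p0)`:
#' the chance that random shearing alone places at least `k` terminal
#' events among `n` covering fragments.  One-sided because only a
#' terminal excess is evidence of cleavage or stalling.
#'
#' @param k observed terminal events (vectorised).
#' @param n fragment coverage (vectorised).
#' @param p0 background terminal rate, in (0, 1).
#' @return numeric vector of p-values.
#' @examples
#' binomial_pvalue(5, 5, 0.01)  # 1e-10
#' @export
binomial_pvalue <- function(k, n, p0) {
  if (any(k < 0) || any(k > n)) stop("need 0 <= k <= n")
  if (p0 <= 0 || p0 >= 1) stop("'p0' must be in (0, 1)")
  pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Multiple-testing correction
#'
#' Bonferroni (`min(1, m p)`) or Benjamini-Hochberg step-up, with `m`
#' the number of tested hypotheses (defaults to `length(p)`).  Order is
#' preserved.
#'
#' @param p raw p-values in \[0, 1\].
#' @param method `"bonferroni"` or `"bh"`.
#' @param m number of tests.
#' @return adjusted p-values in the input order.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh"),
                           m = length(p)) {
  method <- match.arg(method)
  if (length(p) == 0L) return(numeric())
  if (any(p < 0) || any(p > 1)) stop("p-values must be in [0, 1]")
  p.adjust(p, method = if (method == "bh") "BH" else "bonferroni", n = m)
}

#' Call 6mA sites from terminal counts
#'
#' Tests exactly the positions passing the coverage cutoff (and, by
#' default, carrying an adenine on the tested strand, outside the
#' contig-end mask) against the binomial shear null; corrects over the
#' number of tested positions; flags sites whose adjusted p-value is at
#' or below `alpha`.  All tested positions are returned so the caller's
#' decisions are auditable.
#'
#' @param counts terminal counts from [count_terminals()].
#' @param bg background model from [estimate_background()].
#' @param genome DNAStringSet (for contig lengths).
#' @param cfg a [caller_config()].
#' @return data frame of tested positions, sorted by contig, position,
#'   strand: `contig`, `pos`, `strand`, `base`, `k`, `n`, `p_raw`,
#'   `p_adj`, `passed`; attribute `m` records the number of tests.
#' @export
call_sites <- function(counts, bg, genome, cfg = caller_config()) {
  if (!inherits(bg, "background_model") || is.null(bg$p0))
    stop("'bg' must be a background_model with p0")
  stopifnot(inherits(cfg, "caller_config"))
  if (!all(counts$contig %in% names(genome)))
    stop("counts and genome do not share contigs")
  lens <- contig_lengths(genome)
  tested <- counts$n >= cfg$coverage_cutoff
  if (cfg$require_A) tested <- tested & counts$base == "A"
  if (cfg$edge_exclude > 0L) {
    tested <- tested & counts$pos >= cfg$edge_exclude &
      counts$pos < lens[counts$contig] - cfg$edge_exclude
  }
  res <- counts[tested, c("contig", "pos", "strand", "base", "k", "n"),
                drop = FALSE]
  # endo counting can assign both termini of one fragment to the same
  # candidate, so k may locally exceed span coverage; clamp to the
  # maximal-evidence tail p0^n rather than reject the row
  res$p_raw <- binomial_pvalue(pmin(res$k, res$n), res$n, bg$p0)
  res$p_adj <- adjust_pvalues(res$p_raw, cfg$correction, m = nrow(res))
  res$passed <- res$p_adj <= cfg$alpha
  res <- res[order(res$contig, res$pos, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "m") <- nrow(res)
  attr(res, "mode") <- attr(counts, "mode")
  attr(res, "p0") <- bg$p0
  res
}

#' Remove calls falling in blacklist regions
#'
#' A call at position `pos` is removed when `pos` lies inside any
#' 0-based half-open region; strand is ignored.
#'
#' @param calls site-call data frame.
#' @param blacklist region data frame (`contig`, `start`, `end`).
#' @return filtered calls.
#' @export
filter_blacklist <- function(calls, blacklist) {
  if (is.null(blacklist) || nrow(blacklist) == 0L || nrow(calls) == 0L)
    return(calls)
  q <- GenomicRanges::GRanges(calls$contig,
                              IRanges::IRanges(calls$pos + 1L, width = 1L))
  s <- GenomicRanges::GRanges(blacklist$contig,
                              IRanges::IRanges(blacklist$start + 1L,
                                               blacklist$end))
  hit <- GenomicRanges::countOverlaps(q, s, ignore.strand = TRUE) > 0L
  out <- calls[!hit, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("m", "mode", "p0")) attr(out, a) <- attr(calls, a)
  out
}
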