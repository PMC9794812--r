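# shared helpers: tiny deterministic fixtures built in code

make_genome <- function(seqs) {
  Biostrings::DNAStringSet(seqs)
}

site_keys <- function(df) paste(df$contig, df$pos, df$strand)

# simulate -> count -> call in one step
run_caller <- function(genome, truth, n_fragments, mode = "exo",
                       capture_prob = 0.5, seed = 1L,
                       cfg = caller_config(), ...) {
  scfg <- sim_config(n_fragments, capture_prob = capture_prob,
                     seed = seed, ...)
  aln <- if (mode == "endo") simulate_fragments_endo(genome, truth, scfg)
         else simulate_fragments_exo(genome, truth, scfg)
  counts <- count_terminals(aln, mode, genome)
  call_sites(counts, estimate_background(counts), genome, cfg)
}

# truth positions away from contig ends (the caller's edge mask)
interior_truth <- function(truth, genome, margin = 500L) {
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  truth[truth$pos >= margin & truth$pos < lens[truth$contig] - margin, ,
        drop = FALSE]
}

strand_5prime_base <- function(aln, genome) {
  p <- ifelse(aln$strand == "+", aln$start, aln$end - 1L)
  out <- character(nrow(aln))
  for (ct in unique(aln$contig)) {
    sel <- aln$contig == ct
    ch <- strsplit(as.character(genome[[ct]]), "", fixed = TRUE)[[1]]
    b <- ch[p[sel] + 1L]
    out[sel] <- ifelse(aln$strand[sel] == "+", b, chartr("ACGT", "TGCA", b))
  }
  out
}
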