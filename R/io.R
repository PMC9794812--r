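#' Read genomic regions from BED
#'
#' BED3+ with optional name, score, strand columns.  Coordinates are
#' kept verbatim in the 0-based half-open frame.  A line with
#' `start >= end` is an error reported with its line number.
#'
#' @param path BED file.
#' @return data frame with columns `contig`, `start`, `end`, `name`,
#'   `strand` (missing columns filled with `"."`).
#' @export
read_regions_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0L)
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), name = character(),
                      strand = character(), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- vapply(fields, length, integer(1))
  bad <- which(ncol < 3L)
  if (length(bad) > 0L)
    stop("malformed BED: ", length(bad), " line(s) with fewer than 3 ",
         "fields (first at line ", bad[1], ")")
  contig <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  if (anyNA(start) || anyNA(end))
    stop("malformed BED: non-numeric coordinate at line ",
         which(is.na(start) | is.na(end))[1])
  bad <- which(start >= end)
  if (length(bad) > 0L)
    stop("invalid BED interval (start >= end) at line ", bad[1])
  name <- vapply(fields, function(f)
    if (length(f) >= 4L) f[[4L]] else ".", character(1))
  strand <- vapply(fields, function(f)
    if (length(f) >= 6L) f[[6L]] else ".", character(1))
  if (!all(strand %in% c("+", "-", ".")))
    stop("invalid strand value in BED (must be '+', '-' or '.')")
  data.frame(contig = contig, start = start, end = end, name = name,
             strand = strand, stringsAsFactors = FALSE)
}

#' Write regions to BED6
#'
#' @param regions data frame with `contig`, `start`, `end` and optional
#'   `name`, `score`, `strand`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_regions_bed <- function(regions, path) {
  name <- if ("name" %in% names(regions)) regions$name else "."
  score <- if ("score" %in% names(regions)) regions$score else 0L
  strand <- if ("strand" %in% names(regions)) regions$strand else "."
  out <- data.frame(regions$contig, regions$start, regions$end,
                    name, score, strand)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a methylation truth to BED6
#'
#' name = motif, score = `round(1000 * methyl_fraction)`.
#'
#' @param truth truth data frame from [plant_methylation()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_truth_bed <- function(truth, path) {
  out <- data.frame(truth$contig, truth$pos, truth$pos + 1L,
                    truth$motif, round(1000 * truth$methyl_fraction),
                    truth$strand)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read fragment alignments from TSV
#'
#' Expects tab-separated columns `contig`, `start`, `end`, `strand` and
#' optionally `source_tag`, with or without a header line.  Coordinates
#' are 0-based half-open.  If a genome is supplied, records are
#' validated against contig bounds.
#'
#' @param path TSV file.
#' @param genome optional DNAStringSet for validation.
#' @return alignment data frame.
#' @export
read_alignments <- function(path, genome = NULL) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) return(aln_df())
  has_header <- startsWith(first, "contig")
  df <- read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (!has_header) {
    cols <- c("contig", "start", "end", "strand", "source_tag")
    names(df) <- cols[seq_len(ncol(df))]
  }
  if (!"source_tag" %in% names(df)) df$source_tag <- "unknown"
  df <- df[, c("contig", "start", "end", "strand", "source_tag")]
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  validate_alignments(df, genome)
  df
}

validate_alignments <- function(aln, genome = NULL) {
  if (nrow(aln) == 0L) return(invisible(TRUE))
  if (anyNA(aln$start) || anyNA(aln$end))
    stop("non-numeric alignment coordinates")
  if (any(aln$start < 0L) || any(aln$start >= aln$end))
    stop("invalid alignment span (need 0 <= start < end)")
  if (!all(aln$strand %in% c("+", "-")))
    stop("alignment strand must be '+' or '-'")
  if (!is.null(genome)) {
    lens <- contig_lengths(genome)
    if (!all(aln$contig %in% names(lens)))
      stop("alignment contigs absent from genome: ",
           paste(head(setdiff(aln$contig, names(lens)), 5), collapse = ", "))
    if (any(aln$end > lens[aln$contig]))
      stop("alignment end exceeds contig length")
  }
  invisible(TRUE)
}

#' Write fragment alignments to TSV
#'
#' @param aln alignment data frame.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_alignments <- function(aln, path) {
  write.table(aln, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read transcription start sites
#'
#' GFF3/GTF input is 1-based inclusive and converted at the boundary:
#' the TSS of a plus-strand feature is `start - 1` in the 0-based frame,
#' and of a minus-strand feature `end - 1` (the feature's last base).
#' TSV input is three 0-based columns `contig`, `position`, `strand`
#' without a header.
#'
#' @param path input file.
#' @param format `"gff"` or `"tsv"`.
#' @param feature_type GFF feature type to use (default `"gene"`; set
#'   to `NULL` to keep all features).
#' @return data frame with columns `contig`, `pos` (0-based), `strand`.
#' @export
read_tss <- function(path, format = c("gff", "tsv"), feature_type = "gene") {
  format <- match.arg(format)
  if (format == "gff") {
    gr <- rtracklayer::import(path)
    if (!is.null(feature_type) && "type" %in% names(S4Vectors::mcols(gr)))
      gr <- gr[as.character(gr$type) %in% feature_type]
    strand <- as.character(BiocGenerics::strand(gr))
    if (any(strand == "*"))
      stop("GFF feature without strand; TSS undefined")
    pos <- ifelse(strand == "+",
                  BiocGenerics::start(gr) - 1L,
                  BiocGenerics::end(gr) - 1L)
    out <- data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
                      pos = as.integer(pos), strand = strand,
                      stringsAsFactors = FALSE)
  } else {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 3L) stop("TSS TSV needs columns contig, position, strand")
    out <- data.frame(contig = as.character(df[[1]]),
                      pos = as.integer(df[[2]]),
                      strand = as.character(df[[3]]),
                      stringsAsFactors = FALSE)
    if (!all(out$strand %in% c("+", "-")))
      stop("TSS strand must be '+' or '-'")
  }
  out
}

#' Write terminal counts to TSV
#'
#' A bedGraph-like table (`contig`, `pos`, `strand`, `base`, `k`, `n`)
#' with the counting mode recorded in a `# mode=` header line.
#'
#' @param counts terminal counts from [count_terminals()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_counts <- function(counts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mode=%s", attr(counts, "mode")), con)
  write.table(counts, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read terminal counts written by [write_counts()]
#'
#' @param path TSV file with a `# mode=` header.
#' @return terminal-counts data frame with a `mode` attribute.
#' @export
read_counts <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "# mode="))
    stop("counts file lacks '# mode=' header")
  mode <- sub("^# mode=", "", first)
  df <- read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  attr(df, "mode") <- mode
  df
}

#' Write site calls
#'
#' `write_calls_tsv()` writes the full table; `write_calls_bed()` writes
#' BED6 with name = base, score = `min(1000, round(-10 log10 p_adj))`.
#'
#' @param calls site-call data frame from [call_sites()].
#' @param path output file.
#' @param passed_only write only passing sites (default TRUE for BED).
#' @return invisibly, `path`.
#' @export
write_calls_bed <- function(calls, path, passed_only = TRUE) {
  if (passed_only) calls <- calls[calls$passed, , drop = FALSE]
  score <- ifelse(calls$p_adj <= 0, 1000L,
                  pmin(1000L, as.integer(round(-10 * log10(calls$p_adj)))))
  out <- data.frame(calls$contig, calls$pos, calls$pos + 1L,
                    calls$base, score, calls$strand)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_calls_bed
#' @export
write_calls_tsv <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
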