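#' Split a scaffold into contigs at long N runs
#'
#' Contigs are the maximal intervals left after removing runs of `N` of
#' length at least `min_gap_run`; shorter N runs (captured bases) stay
#' inside their contig, the usual assembler convention.
#'
#' @param sequence scaffold sequence (A, C, G, T, N).
#' @param min_gap_run minimum N-run length that splits a contig.
#' @return data frame of 0-based half-open contig intervals
#'   (`start`, `end`), sorted and non-overlapping.
#' @export
split_contigs <- function(sequence, min_gap_run = 10L) {
  stopifnot(min_gap_run >= 1L)
  n <- nchar(sequence)
  empty <- data.frame(start = integer(0), end = integer(0))
  if (n == 0L) return(empty)
  m <- gregexpr(sprintf("N{%d,}", min_gap_run), sequence)[[1]]
  if (m[1] == -1L)
    return(data.frame(start = 0L, end = n))
  gs <- as.integer(m) - 1L                       # 0-based gap starts
  ge <- gs + attr(m, "match.length")
  starts <- c(0L, ge)
  ends <- c(gs, n)
  keep <- ends > starts
  data.frame(start = starts[keep], end = ends[keep])
}

#' N50 / L50 of a set of lengths
#'
#' Following the convention of karyotype-era assembly tables: sort lengths
#' descending; `n50` is the smallest k whose cumulative sum reaches half the
#' total, and `l50` is the k-th length in that order.
#'
#' @param lengths positive numeric vector of scaffold (or contig) lengths.
#' @return list with `n50` (count) and `l50` (length).
#' @export
nl50 <- function(lengths) {
  if (length(lengths) == 0L) stop("empty length vector")
  stopifnot(all(lengths > 0))
  s <- sort(unname(lengths), decreasing = TRUE)
  k <- which(cumsum(s) >= sum(s) / 2)[1]
  list(n50 = k, l50 = s[k])
}

#' Cumulative assembly size table
#'
#' For each size threshold, aggregates the scaffolds at least that long:
#' counts of scaffolds and contigs, total span, non-gap (non-N) bases, and
#' the non-gap percentage rounded to two decimals (round-half-even).
#'
#' @param scaffolds named character vector of scaffold sequences.
#' @param thresholds size thresholds in bp, sorted descending.
#' @param min_gap_run N-run length that splits contigs.
#' @return data frame with one row per threshold.
#' @export
cumulative_size_table <- function(scaffolds, thresholds, min_gap_run = 10L) {
  if (is.unsorted(rev(thresholds))) stop("thresholds must be sorted descending")
  lens <- nchar(scaffolds)
  n_counts <- vapply(scaffolds, function(s)
    nchar(gsub("[^N]", "", s)), integer(1))
  contig_n <- vapply(scaffolds, function(s)
    nrow(split_contigs(s, min_gap_run)), integer(1))
  rows <- lapply(thresholds, function(th) {
    sel <- lens >= th
    span <- sum(lens[sel])
    nongap <- span - sum(n_counts[sel])
    data.frame(threshold = th,
               n_scaffolds = sum(sel),
               n_contigs = sum(contig_n[sel]),
               span_bp = span,
               nongap_bp = nongap,
               pct_nongap = if (span > 0) nongap_percent(nongap, span) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Non-gap percentage of a span
#'
#' `100 * nongap / span`, rounded to two decimals (round-half-even) — the
#' per-row percentage of a cumulative size table.
#'
#' @param nongap_bp non-N bases.
#' @param span_bp total bases.
#' @return percentage.
#' @export
nongap_percent <- function(nongap_bp, span_bp) {
  if (span_bp == 0) stop("span is zero")
  round(100 * nongap_bp / span_bp, 2)
}

#' Gap fraction of an assembly
#'
#' `100 * (scaffold span - contig span) / scaffold span`, rounded to one
#' decimal (round-half-even), as printed in assembly summary tables.
#'
#' @param scaffold_span total scaffold bp.
#' @param contig_span total contig bp.
#' @return percentage gap.
#' @export
gap_fraction <- function(scaffold_span, contig_span) {
  if (scaffold_span == 0) stop("scaffold span is zero")
  stopifnot(contig_span <= scaffold_span)
  round(100 * (scaffold_span - contig_span) / scaffold_span, 1)
}

#' Alignment discrepancy rate
#'
#' `100 * discrepant / total`, rounded to two decimals; used to express
#' assembly error rates from independent clone alignments.
#'
#' @param discrepant_bp discrepant base count.
#' @param total_bp total aligned base count.
#' @return percentage error.
#' @export
discrepancy_rate <- function(discrepant_bp, total_bp) {
  if (total_bp == 0) stop("total aligned bp is zero")
  stopifnot(discrepant_bp <= total_bp)
  round(100 * discrepant_bp / total_bp, 2)
}
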