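#' Simulate a bimodal ortholog-identity distribution
#'
#' Draws pairwise protein identities from a two-component truncated-normal
#' mixture on \[0, 1\], emulating the bimodal best-hit identity distribution
#' seen when a proteome is compared against a close relative (high mode) and
#' a distant outgroup (low mode). The true component of every pair is
#' recorded.
#'
#' @param config a [sim_config()]; uses `identity_modes`, `identity_sds`,
#'   `mixture_weight` and `seed`.
#' @param n_pairs number of pairs to draw.
#' @return data frame with `pair_id`, `identity`, `component` (1 = first
#'   mode, 2 = second).
#' @export
simulate_ortholog_identities <- function(config, n_pairs) {
  validate_sim_config(config)
  m <- config$identity_modes; s <- config$identity_sds
  if (m[1] == m[2]) stop("identity modes must be distinct")
  if (abs(m[1] - m[2]) < 2 * max(s))
    warning("identity modes overlap (|m1 - m2| < 2 max sd); mixture may not be bimodal")
  set.seed(config$seed + 3L)
  if (n_pairs == 0L)
    return(data.frame(pair_id = character(0), identity = numeric(0),
                      component = integer(0)))
  comp <- ifelse(stats::runif(n_pairs) < config$mixture_weight, 1L, 2L)
  identity <- rtruncnorm01(n_pairs, m[comp], s[comp])
  data.frame(pair_id = sprintf("p%06d", seq_len(n_pairs) - 1L),
             identity = identity, component = comp,
             stringsAsFactors = FALSE)
}

# truncated normal on [0,1] by rejection (vectorised over mean/sd)
rtruncnorm01 <- function(n, mean, sd) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < 0 | out > 1)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[out[bad] < 0 | out[bad] > 1]
  }
  out
}

#' Simulate coding sequences with controlled codon-usage bias
#'
#' Generates genes whose codons are drawn either uniformly over synonymous
#' codons ("uniform") or proportionally to per-codon relative adaptiveness
#' under the supplied tRNA pool ("adapted"), with the per-gene flag recorded.
#' Every sequence starts with ATG, ends with a single stop codon, and has
#' length divisible by 3.
#'
#' @param config a [sim_config()].
#' @param trna_pool data frame (anticodon, copies), e.g.
#'   [default_trna_pool()].
#' @param n_genes number of genes.
#' @param length_range range of internal codon counts per gene.
#' @return list with `sequences` (named character vector) and `truth`
#'   (data frame gene_id, bias, n_codons).
#' @export
simulate_codon_genes <- function(config, trna_pool, n_genes,
                                 length_range = c(100L, 300L)) {
  validate_sim_config(config)
  if (nrow(trna_pool) == 0L || all(trna_pool$copies == 0))
    stop("tRNA pool is empty")
  set.seed(config$seed + 4L)
  prof <- tai_profile(trna_pool)
  # adapted genes draw synonymous codons proportionally to relative
  # adaptiveness; codons no tRNA recognises (W = 0) are excluded rather
  # than given the zero-replacement w, so an adapted gene only ever uses
  # codons the pool can decode
  w <- ifelse(prof$W > 0, prof$w, 0)
  names(w) <- names(prof$w)
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  by_aa <- split(sense, code[sense])
  aas <- names(by_aa)
  bias <- sample(rep(c("adapted", "uniform"), length.out = n_genes))
  lrng <- seq(length_range[1], length_range[2])
  lens <- lrng[sample.int(length(lrng), n_genes, replace = TRUE)]
  seqs <- character(n_genes)
  for (i in seq_len(n_genes)) {
    aa_seq <- sample(aas, lens[i], replace = TRUE)
    codons <- vapply(aa_seq, function(a) {
      syn <- by_aa[[a]]
      if (length(syn) == 1L) return(syn)
      if (bias[i] == "adapted" && any(w[syn] > 0))
        sample(syn, 1L, prob = w[syn])
      else sample(syn, 1L)
    }, character(1))
    seqs[i] <- paste(c("ATG", codons, "TAA"), collapse = "")
  }
  names(seqs) <- sprintf("cds%04d", seq_len(n_genes) - 1L)
  list(sequences = seqs,
       truth = data.frame(gene_id = names(seqs), bias = bias,
                          n_codons = lens + 2L, stringsAsFactors = FALSE))
}

#' A deterministic default tRNA pool
#'
#' One tRNA species per sense codon (the Watson-Crick anticodon), with gene
#' copy numbers cycling over a fixed pattern so that relative adaptiveness
#' varies across synonymous codons. Purely a reproducible stand-in for a
#' genome-scanned pool; real pools (e.g. from tRNAscan-SE) are supplied as a
#' two-column table in the same shape.
#'
#' @return data frame with columns `anticodon`, `copies`.
#' @export
default_trna_pool <- function() {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  anticodons <- revcomp(sense)
  copies <- rep(c(9L, 2L, 12L, 4L, 7L, 1L, 10L, 3L, 6L, 8L, 5L, 11L),
                length.out = length(anticodons))
  data.frame(anticodon = anticodons, copies = copies,
             stringsAsFactors = FALSE)
}
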