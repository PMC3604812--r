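#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-genome generator. The defaults
#' describe the study system this package targets: a crucifer genome whose
#' gene order derives from 24 conserved ancestral blocks (A-X) rearranged
#' into an n = 7 karyotype, fragmented into scaffolds with N-gap runs,
#' carrying AT-rich 177-bp centromeric satellite arrays at pericentromeric
#' scaffold termini, and whose cross-species protein identities form a
#' bimodal mixture with modes near 85% and 35%.
#'
#' @param seed integer RNG seed; a fixed seed makes every generator output
#'   byte-identical across runs.
#' @param n_blocks number of ancestral blocks (single-letter labels, max 26).
#' @param genes_per_block length-2 integer range; per-block gene counts are
#'   drawn uniformly from it.
#' @param n_chromosomes number of chromosomes in the karyotype.
#' @param n_scaffolds total number of scaffolds the genome is fragmented
#'   into; must be at least `n_chromosomes`.
#' @param gene_length length of each simulated gene, bp.
#' @param intergenic_length length of intergenic spacers, bp.
#' @param gap_rate per-spacer probability of carrying an N-gap run.
#' @param gap_run_length length of each planted N run, bp.
#' @param satellite_period satellite repeat-unit length, bp.
#' @param satellite_copies length-2 integer range of tandem copies per array.
#' @param satellite_at_fraction target AT fraction of the satellite unit.
#' @param satellite_mutation per-base per-copy mutation probability applied
#'   to each tandem copy, so arrays are detectable but not literal repeats.
#' @param identity_modes modes of the two ortholog-identity components
#'   (high-homology ingroup, low-homology outgroup), as fractions.
#' @param identity_sds standard deviations of the two components.
#' @param mixture_weight weight of the first (high-identity) component.
#' @param pericentromere_fraction fraction of chromosome length on either
#'   side of the centromere treated as pericentromeric when deciding which
#'   scaffold termini receive satellite arrays. The real extent of
#'   pericentromeric heterochromatin varies widely between chromosomes, so
#'   this is exposed as a knob rather than fixed.
#' @param mislabel_rate fraction of genes whose block label is corrupted in
#'   the emitted block table (painting noise); ground truth keeps the true
#'   labels.
#' @return object of class `"sim_config"` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_blocks = 24L,
                       genes_per_block = c(30L, 60L),
                       n_chromosomes = 7L,
                       n_scaffolds = 40L,
                       gene_length = 300L,
                       intergenic_length = 200L,
                       gap_rate = 0.1,
                       gap_run_length = 50L,
                       satellite_period = 177L,
                       satellite_copies = c(30L, 60L),
                       satellite_at_fraction = 0.7,
                       satellite_mutation = 0.01,
                       identity_modes = c(0.85, 0.35),
                       identity_sds = c(0.05, 0.10),
                       mixture_weight = 0.6,
                       pericentromere_fraction = 0.05,
                       mislabel_rate = 0) {
  cfg <- list(seed = as.integer(seed),
              n_blocks = as.integer(n_blocks),
              genes_per_block = as.integer(rep(genes_per_block, length.out = 2)),
              n_chromosomes = as.integer(n_chromosomes),
              n_scaffolds = as.integer(n_scaffolds),
              gene_length = as.integer(gene_length),
              intergenic_length = as.integer(intergenic_length),
              gap_rate = gap_rate,
              gap_run_length = as.integer(gap_run_length),
              satellite_period = as.integer(satellite_period),
              satellite_copies = as.integer(rep(satellite_copies, length.out = 2)),
              satellite_at_fraction = satellite_at_fraction,
              satellite_mutation = satellite_mutation,
              identity_modes = identity_modes,
              identity_sds = identity_sds,
              mixture_weight = mixture_weight,
              pericentromere_fraction = pericentromere_fraction,
              mislabel_rate = mislabel_rate)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$seed) == 1, !is.na(cfg$seed))
  if (cfg$n_blocks > 26L)
    stop("n_blocks > 26: single-letter block labels exhausted")
  if (cfg$n_blocks < 1L) stop("n_blocks must be >= 1")
  if (cfg$n_blocks < cfg$n_chromosomes)
    stop("n_blocks must be >= n_chromosomes")
  if (cfg$n_scaffolds < cfg$n_chromosomes)
    stop("n_scaffolds must be >= n_chromosomes")
  if (cfg$satellite_period < 2L) stop("satellite_period must be >= 2")
  fr <- c(cfg$gap_rate, cfg$satellite_at_fraction, cfg$satellite_mutation,
          cfg$identity_modes, cfg$identity_sds, cfg$mixture_weight,
          cfg$pericentromere_fraction, cfg$mislabel_rate)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  if (any(cfg$genes_per_block < 1L)) stop("genes_per_block must be >= 1")
  if (diff(cfg$genes_per_block) < 0) stop("genes_per_block range reversed")
  if (diff(cfg$satellite_copies) < 0) stop("satellite_copies range reversed")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic genome configuration\n")
  cat(sprintf("  %d blocks (%s..%s), %d-%d genes/block, %d chromosomes, %d scaffolds\n",
              x$n_blocks, "A", LETTERS[x$n_blocks],
              x$genes_per_block[1], x$genes_per_block[2],
              x$n_chromosomes, x$n_scaffolds))
  cat(sprintf("  satellite: %d bp unit, %d-%d copies, AT %.2f\n",
              x$satellite_period, x$satellite_copies[1], x$satellite_copies[2],
              x$satellite_at_fraction))
  cat(sprintf("  identity mixture: modes %.2f/%.2f, weight %.2f\n",
              x$identity_modes[1], x$identity_modes[2], x$mixture_weight))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}
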