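# small, fast simulation configurations used across tests
tiny_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_blocks = 6L, genes_per_block = c(15L, 25L),
             n_chromosomes = 2L, n_scaffolds = 6L, gene_length = 60L,
             intergenic_length = 40L, satellite_copies = c(20L, 30L),
             satellite_period = 80L, ...)
}

study_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, ...)
}

# plant `n_copies` tandem copies of a random unit (with per-base mutation)
# inside random flanking sequence; returns sequence plus truth interval
plant_array <- function(period, n_copies, flank = 3000L, at = 0.7,
                        mutation = 0.01) {
  unit <- sample(c("A", "T", "C", "G"), period, replace = TRUE,
                 prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2))
  bases <- c("A", "C", "G", "T")
  arr <- unlist(lapply(seq_len(n_copies), function(i) {
    cp <- unit
    mut <- which(runif(period) < mutation)
    for (j in mut) cp[j] <- sample(setdiff(bases, cp[j]), 1L)
    cp
  }))
  left <- paste(sample(bases, flank, replace = TRUE), collapse = "")
  right <- paste(sample(bases, flank, replace = TRUE), collapse = "")
  list(sequence = paste0(left, paste(arr, collapse = ""), right),
       start = flank, end = flank + period * n_copies,
       period = period, copies = n_copies)
}

# fraction of scaffolds placed on their true chromosome with the true
# orientation, over one simulated genome
placement_accuracy <- function(sim, plan) {
  truth <- sim$truth$scaffolds
  ok <- 0L
  for (kn in names(plan$chromosomes)) {
    df <- plan$chromosomes[[kn]]
    for (r in seq_len(nrow(df))) {
      t <- truth[truth$scaffold == df$scaffold[r], , drop = FALSE]
      if (t$chrom == kn && t$orientation == df$orientation[r]) ok <- ok + 1L
    }
  }
  ok / nrow(truth)
}

run_assembly <- function(sim) {
  segs <- paint_scaffolds(sim$placements, sim$block_table)
  match_scaffolds(sim$karyotype, segs, sim$truth$satellites,
                  nchar(sim$scaffolds))
}
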