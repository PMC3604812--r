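#' Simulate an ancestral gene order partitioned into blocks
#'
#' Genes are numbered `0..G-1` in ancestral order; each gene belongs to one
#' block (labels `A`, `B`, ... up to `n_blocks` letters) and carries a
#' strictly increasing ancestral index within its block.
#'
#' @param config a [sim_config()].
#' @return data frame with columns `gene_id`, `block`, `anc_index`
#'   (0-based rank within block).
#' @export
simulate_ancestral_genome <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  rng <- seq(config$genes_per_block[1], config$genes_per_block[2])
  counts <- rng[sample.int(length(rng), config$n_blocks, replace = TRUE)]
  block <- rep(LETTERS[seq_len(config$n_blocks)], counts)
  anc_index <- unlist(lapply(counts, function(k) seq_len(k) - 1L),
                      use.names = FALSE)
  g <- length(block)
  data.frame(gene_id = sprintf("g%05d", seq_len(g) - 1L),
             block = block,
             anc_index = anc_index,
             stringsAsFactors = FALSE)
}

#' Rearrange ancestral blocks into a karyotype
#'
#' Blocks are partitioned over `n_chromosomes` chromosomes (each receives at
#' least one), given a random order and a random sign; a chromosome's gene
#' order is the concatenation of its blocks, each block reversed when its
#' sign is `-`. A centromere is placed between two adjacent blocks of each
#' chromosome.
#'
#' @param config a [sim_config()].
#' @param ancestral output of [simulate_ancestral_genome()].
#' @return list with elements
#'   `karyotype` (per-chromosome list of `name`, signed `blocks`,
#'   `centromere_after`) and `genes` (data frame of the chromosome-ordered
#'   genes with `chrom`, `chrom_order`, `strand`).
#' @export
simulate_karyotype <- function(config, ancestral) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  labels <- LETTERS[seq_len(config$n_blocks)]
  perm <- sample(labels)
  # random composition of n_blocks into n_chromosomes parts, each >= 1
  nc <- config$n_chromosomes
  cuts <- sort(sample(seq_len(config$n_blocks - 1L), nc - 1L))
  sizes <- diff(c(0L, cuts, config$n_blocks))
  signs <- sample(c("+", "-"), config$n_blocks, replace = TRUE)
  names(signs) <- perm

  idx <- split(perm, rep(seq_len(nc), sizes))
  karyotype <- vector("list", nc)
  gene_rows <- vector("list", nc)
  for (ci in seq_len(nc)) {
    blocks <- idx[[ci]]
    signed <- paste0(signs[blocks], blocks)
    cen_after <- if (length(blocks) >= 2L)
      sample(seq_len(length(blocks) - 1L), 1L) else 1L
    ord <- lapply(blocks, function(b) {
      bg <- ancestral[ancestral$block == b, , drop = FALSE]
      bg <- bg[order(bg$anc_index), , drop = FALSE]
      if (signs[[b]] == "-") {
        bg <- bg[rev(seq_len(nrow(bg))), , drop = FALSE]
        bg$strand <- "-"
      } else bg$strand <- "+"
      bg
    })
    genes <- do.call(rbind, ord)
    genes$chrom <- sprintf("Chr%d", ci)
    genes$chrom_order <- seq_len(nrow(genes)) - 1L
    rownames(genes) <- NULL
    karyotype[[ci]] <- list(name = sprintf("Chr%d", ci),
                            blocks = signed,
                            centromere_after = cen_after)
    gene_rows[[ci]] <- genes
  }
  list(karyotype = karyotype, genes = do.call(rbind, gene_rows))
}

# internal: one satellite array sequence plus its unit, from the config RNG
make_satellite_array <- function(config) {
  at <- config$satellite_at_fraction
  unit <- sample(c("A", "T", "C", "G"), config$satellite_period,
                 replace = TRUE,
                 prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2))
  crng <- seq(config$satellite_copies[1], config$satellite_copies[2])
  copies <- crng[sample.int(length(crng), 1L)]
  bases <- c("A", "C", "G", "T")
  arr <- unlist(lapply(seq_len(copies), function(i) {
    cp <- unit
    mut <- which(stats::runif(length(cp)) < config$satellite_mutation)
    for (j in mut) cp[j] <- sample(setdiff(bases, cp[j]), 1L)
    cp
  }), use.names = FALSE)
  list(seq = paste(arr, collapse = ""),
       unit = paste(unit, collapse = ""),
       copies = copies)
}

#' Fragment chromosomes into scaffolds and emit sequences with ground truth
#'
#' Builds each chromosome's sequence (genes separated by intergenic spacers,
#' some carrying N-gap runs), cuts it at inter-gene breakpoints into
#' scaffolds — one breakpoint is forced at the centromere whenever the
#' chromosome receives more than one scaffold — flips each scaffold with
#' probability 0.5, and plants a tandem satellite array at the
#' centromere-facing terminus of every pericentromeric scaffold. All
#' coordinates in the returned tables are 0-based, half-open, on the emitted
#' (post-flip) scaffold.
#'
#' @param config a [sim_config()].
#' @param karyo output of [simulate_karyotype()].
#' @return list with `scaffolds` (named character vector), `placements`
#'   (BED-like data frame: scaffold, start, end, gene_id, score, strand),
#'   `block_table` (gene_id, block, anc_index; with `mislabel_rate` noise
#'   applied if configured) and `truth` (lists `genes`, `scaffolds`,
#'   `satellites` of ground-truth records).
#' @export
emit_scaffolds <- function(config, karyo) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  genes <- karyo$genes
  chroms <- vapply(karyo$karyotype, function(k) k$name, character(1))
  n_genes_per_chrom <- vapply(chroms, function(ch) sum(genes$chrom == ch),
                              integer(1))

  # allocate scaffolds to chromosomes: one each, remainder by gene share
  extra <- config$n_scaffolds - length(chroms)
  alloc <- rep(1L, length(chroms))
  if (extra > 0L) {
    share <- n_genes_per_chrom / sum(n_genes_per_chrom) * extra
    add <- floor(share)
    rem <- extra - sum(add)
    if (rem > 0L) {
      ord <- order(share - add, decreasing = TRUE)
      add[ord[seq_len(rem)]] <- add[ord[seq_len(rem)]] + 1L
    }
    alloc <- alloc + as.integer(add)
  }

  scaffold_seqs <- list()
  placement_rows <- list()
  truth_genes <- list()
  truth_scaffolds <- list()
  truth_sats <- list()
  scf_counter <- 0L

  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    kchrom <- karyo$karyotype[[ci]]
    cg <- genes[genes$chrom == ch, , drop = FALSE]
    cg <- cg[order(cg$chrom_order), , drop = FALSE]
    n <- nrow(cg)

    # chromosome sequence: spacer, gene, spacer, gene, ..., spacer
    spacers <- character(n + 1L)
    for (j in seq_len(n + 1L)) {
      sp <- random_dna(config$intergenic_length)
      if (stats::runif(1) < config$gap_rate) {
        half <- config$intergenic_length %/% 2L
        sp <- paste0(substr(sp, 1L, half),
                     strrep("N", config$gap_run_length),
                     substr(sp, half + 1L, config$intergenic_length))
      }
      spacers[j] <- sp
    }
    gene_seqs <- vapply(seq_len(n), function(j) random_dna(config$gene_length),
                        character(1))
    parts <- character(2L * n + 1L)
    parts[seq(1L, 2L * n + 1L, by = 2L)] <- spacers
    parts[seq(2L, 2L * n, by = 2L)] <- gene_seqs
    part_len <- nchar(parts)
    part_end <- cumsum(part_len)
    gene_start <- part_end[seq(2L, 2L * n, by = 2L)] - config$gene_length
    gene_end <- part_end[seq(2L, 2L * n, by = 2L)]
    chrom_seq <- paste(parts, collapse = "")
    chrom_len <- nchar(chrom_seq)

    # centromere: boundary after the genes of blocks 1..centromere_after
    blocks_here <- sub("^[+-]", "", kchrom$blocks)
    genes_per_block_here <- vapply(blocks_here,
                                   function(b) sum(cg$block == b), integer(1))
    cen_gene <- sum(genes_per_block_here[seq_len(kchrom$centromere_after)])
    cen_bp <- if (cen_gene >= n) chrom_len
      else part_end[2L * cen_gene + 1L] - part_len[2L * cen_gene + 1L] %/% 2L

    # cut sites: inter-gene boundaries (site j = middle of spacer j+1,
    # i.e. between gene j and gene j+1)
    # breakpoints are spaced at least 6 genes apart (and from the
    # chromosome ends) so every scaffold carries enough genes to paint:
    # a scaffold can straddle at most one block boundary, leaving at
    # least one run of >= 3 genes
    k <- alloc[ci]
    sites <- integer(0)
    if (k > 1L) {
      min_sp <- 6L
      cand <- setdiff(seq.int(min_sp, max(min_sp, n - min_sp)), cen_gene)
      cand <- cand[cand >= 1L & cand <= n - 1L]
      chosen <- if (cen_gene >= 1L && cen_gene <= n - 1L) cen_gene else integer(0)
      need <- k - 1L - length(chosen)
      if (need > 0L) {
        pool <- cand[sample.int(length(cand))]
        for (s in pool) {
          if (length(chosen) >= k - 1L) break
          if (length(chosen) == 0L || all(abs(s - chosen) >= min_sp))
            chosen <- c(chosen, s)
        }
        # fallback if spacing left too few sites
        if (length(chosen) < k - 1L) {
          left <- setdiff(pool, chosen)
          chosen <- c(chosen, left[seq_len(min(length(left), k - 1L - length(chosen)))])
        }
      }
      sites <- sort(chosen)
    }
    cut_bp <- vapply(sites, function(s)
      part_end[2L * s + 1L] - part_len[2L * s + 1L] %/% 2L, numeric(1))
    bounds <- c(0, cut_bp, chrom_len)

    peri <- config$pericentromere_fraction * chrom_len

    gene_cuts <- c(0L, sites, n)
    for (si in seq_len(length(bounds) - 1L)) {
      scf_counter <- scf_counter + 1L
      sname <- sprintf("scf%03d", scf_counter)
      s0 <- bounds[si]; s1 <- bounds[si + 1L]
      sseq <- substr(chrom_seq, s0 + 1L, s1)
      gidx <- seq(gene_cuts[si] + 1L, gene_cuts[si + 1L])
      gs <- gene_start[gidx] - s0
      ge <- gene_end[gidx] - s0
      slen <- s1 - s0

      # satellite planting at the centromere-facing terminus
      sat <- NULL
      dist_left <- abs(s0 - cen_bp)
      dist_right <- abs(s1 - cen_bp)
      if (min(dist_left, dist_right) <= peri) {
        arr <- make_satellite_array(config)
        alen <- nchar(arr$seq)
        if (dist_right <= dist_left) {      # plant at right end
          sseq <- paste0(sseq, arr$seq)
          sat <- list(start = slen, end = slen + alen)
        } else {                            # plant at left end
          sseq <- paste0(arr$seq, sseq)
          sat <- list(start = 0L, end = alen)
          gs <- gs + alen; ge <- ge + alen
        }
        sat$period <- config$satellite_period
        sat$copies <- arr$copies
        slen <- slen + alen
      }

      flip <- stats::runif(1) < 0.5
      strand <- cg$strand[gidx]
      if (flip) {
        sseq <- revcomp(sseq)
        tmp <- gs
        gs <- slen - ge
        ge <- slen - tmp
        ord <- rev(seq_along(gidx))
        gs <- gs[ord]; ge <- ge[ord]; gidx <- gidx[ord]
        strand <- ifelse(strand[ord] == "+", "-", "+")
        if (!is.null(sat)) {
          tmp <- sat$start
          sat$start <- slen - sat$end
          sat$end <- slen - tmp
        }
      }

      scaffold_seqs[[sname]] <- sseq
      placement_rows[[sname]] <- data.frame(
        scaffold = sname, start = as.integer(gs), end = as.integer(ge),
        gene_id = cg$gene_id[gidx], score = ".", strand = strand,
        stringsAsFactors = FALSE)
      truth_genes[[sname]] <- data.frame(
        gene_id = cg$gene_id[gidx], block = cg$block[gidx],
        anc_index = cg$anc_index[gidx], chrom = ch,
        scaffold = sname, start = as.integer(gs), end = as.integer(ge),
        strand = strand, stringsAsFactors = FALSE)
      truth_scaffolds[[sname]] <- data.frame(
        scaffold = sname, chrom = ch, rank = si - 1L,
        orientation = if (flip) "-" else "+",
        length = as.integer(slen), stringsAsFactors = FALSE)
      if (!is.null(sat))
        truth_sats[[sname]] <- data.frame(
          scaffold = sname, start = as.integer(sat$start),
          end = as.integer(sat$end), period = sat$period,
          copies = sat$copies, stringsAsFactors = FALSE)
    }
  }

  placements <- do.call(rbind, placement_rows)
  placements <- placements[order(placements$scaffold, placements$start), ,
                           drop = FALSE]
  rownames(placements) <- NULL

  block_table <- genes[order(genes$gene_id),
                       c("gene_id", "block", "anc_index")]
  rownames(block_table) <- NULL
  if (config$mislabel_rate > 0)
    block_table <- mislabel_block_table(block_table, config$mislabel_rate,
                                        config$n_blocks)

  sats <- if (length(truth_sats)) do.call(rbind, truth_sats) else
    data.frame(scaffold = character(0), start = integer(0), end = integer(0),
               period = integer(0), copies = integer(0))
  rownames(sats) <- NULL

  list(scaffolds = unlist(scaffold_seqs),
       placements = placements,
       block_table = block_table,
       truth = list(genes = do.call(rbind, truth_genes),
                    scaffolds = do.call(rbind, truth_scaffolds),
                    satellites = sats))
}

#' Corrupt a fraction of block labels (painting noise)
#'
#' Reassigns a random fraction of genes to a different, random block label
#' while keeping their ancestral index. Used to test robustness of painting
#' and karyotype matching to mismapped reference genes.
#'
#' @param block_table data frame (gene_id, block, anc_index).
#' @param rate fraction of genes to mislabel.
#' @param n_blocks size of the block alphabet to draw wrong labels from.
#' @return the perturbed block table.
#' @export
mislabel_block_table <- function(block_table, rate, n_blocks = 24L) {
  n <- nrow(block_table)
  bad <- which(stats::runif(n) < rate)
  labels <- LETTERS[seq_len(n_blocks)]
  for (i in bad)
    block_table$block[i] <- sample(setdiff(labels, block_table$block[i]), 1L)
  block_table
}

#' Run the full synthetic-genome generator
#'
#' Convenience wrapper chaining [simulate_ancestral_genome()],
#' [simulate_karyotype()] and [emit_scaffolds()].
#'
#' @param config a [sim_config()].
#' @return list with `ancestral`, `karyotype`, `genes` (chromosome order),
#'   `scaffolds`, `placements`, `block_table` and `truth`.
#' @export
simulate_genome <- function(config = sim_config()) {
  anc <- simulate_ancestral_genome(config)
  kar <- simulate_karyotype(config, anc)
  emit <- emit_scaffolds(config, kar)
  c(list(ancestral = anc, karyotype = kar$karyotype, genes = kar$genes),
    emit)
}
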