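test_that("ancestral genome respects block structure and determinism", {
  # degenerate single block
  cfg1 <- sim_config(seed = 1, n_blocks = 1, genes_per_block = c(5, 5),
                     n_chromosomes = 1, n_scaffolds = 1)
  anc1 <- simulate_ancestral_genome(cfg1)
  expect_equal(anc1$block, rep("A", 5))
  expect_equal(anc1$anc_index, 0:4)

  # determinism: same config twice is identical
  cfg <- study_config(seed = 1)
  expect_identical(simulate_ancestral_genome(cfg),
                   simulate_ancestral_genome(cfg))

  # independent recount: total genes = sum of per-block counts
  anc <- simulate_ancestral_genome(cfg)
  per_block <- table(anc$block)
  expect_equal(nrow(anc), sum(per_block))
  expect_true(all(per_block >= 30 & per_block <= 60))
  # ancestral indices strictly increasing within each block
  for (b in names(per_block)) {
    idx <- anc$anc_index[anc$block == b]
    expect_true(all(diff(idx) > 0))
  }

  # label alphabet exhaustion
  expect_error(sim_config(n_blocks = 27), "exhausted")
})

test_that("karyotype rearrangement conserves gene content", {
  cfg <- study_config(seed = 2)
  anc <- simulate_ancestral_genome(cfg)
  kar <- simulate_karyotype(cfg, anc)

  # 24 blocks over 7 chromosomes, each chromosome non-empty
  nb <- vapply(kar$karyotype, function(ch) length(ch$blocks), integer(1))
  expect_length(nb, 7)
  expect_true(all(nb >= 1))
  expect_equal(sum(nb), 24)

  # multiset of (gene, block) identical before and after rearrangement
  expect_setequal(paste(anc$gene_id, anc$block),
                  paste(kar$genes$gene_id, kar$genes$block))
  expect_equal(nrow(kar$genes), nrow(anc))

  # per chromosome, gene order is the signed block concatenation
  for (ch in kar$karyotype) {
    g <- kar$genes[kar$genes$chrom == ch$name, ]
    g <- g[order(g$chrom_order), ]
    expect_equal(rle(g$block)$values, sub("^[+-]", "", ch$blocks))
    for (sb in ch$blocks) {
      b <- sub("^[+-]", "", sb)
      idx <- g$anc_index[g$block == b]
      if (substr(sb, 1, 1) == "+") expect_true(all(diff(idx) > 0))
      else expect_true(all(diff(idx) < 0))
    }
    expect_gte(ch$centromere_after, 1)
    expect_lte(ch$centromere_after, max(1, length(ch$blocks) - 1))
  }
})

test_that("scaffold emission preserves genes, plants satellites, records flips", {
  cfg <- tiny_config(seed = 3)
  sim <- simulate_genome(cfg)

  # every gene appears exactly once in placements and ground truth
  expect_setequal(sim$placements$gene_id, sim$ancestral$gene_id)
  expect_false(any(duplicated(sim$placements$gene_id)))
  expect_setequal(sim$truth$scaffolds$scaffold, names(sim$scaffolds))

  # placements lie inside their scaffold and gene length is exact
  lens <- nchar(sim$scaffolds)
  expect_true(all(sim$placements$start >= 0))
  expect_true(all(sim$placements$end <= lens[sim$placements$scaffold]))
  expect_true(all(sim$placements$end - sim$placements$start ==
                    cfg$gene_length))

  # satellite truth intervals have length period * copies
  sat <- sim$truth$satellites
  expect_gt(nrow(sat), 0)
  expect_equal(sat$end - sat$start, sat$period * sat$copies)

  # a planted 40 x 177 array has interval length 7080
  expect_equal(40 * 177, 7080)

  # flip recorded "-" means ancestral indices decrease along a
  # single-block scaffold
  merged <- merge(sim$placements, sim$truth$genes[, c("gene_id", "block",
                                                      "anc_index")],
                  by = "gene_id")
  for (scf in unique(merged$scaffold)) {
    m <- merged[merged$scaffold == scf, ]
    m <- m[order(m$start), ]
    ori <- sim$truth$scaffolds$orientation[
      sim$truth$scaffolds$scaffold == scf]
    for (b in unique(m$block)) {
      idx <- m$anc_index[m$block == b]
      if (length(idx) < 2) next
      ksign <- NULL
      for (ch in sim$karyotype) {
        hit <- grep(paste0("^[+-]", b, "$"), ch$blocks, value = TRUE)
        if (length(hit)) ksign <- substr(hit, 1, 1)
      }
      expected_up <- (ksign == "+") == (ori == "+")
      if (expected_up) expect_true(all(diff(idx) > 0))
      else expect_true(all(diff(idx) < 0))
    }
  }

  # byte-identical reruns
  sim2 <- simulate_genome(cfg)
  expect_identical(sim$scaffolds, sim2$scaffolds)
  expect_identical(sim$placements, sim2$placements)

  expect_error(sim_config(n_scaffolds = 3, n_chromosomes = 7),
               "n_scaffolds")
})

test_that("ortholog identity mixture has the configured modes and labels", {
  # degenerate mixture
  all1 <- simulate_ortholog_identities(tiny_config(mixture_weight = 1), 200)
  expect_true(all(all1$component == 1))
  # empty table
  none <- simulate_ortholog_identities(tiny_config(), 0)
  expect_equal(nrow(none), 0)

  # Monte-Carlo: labelled component means within 3 SE of their modes
  cfg <- study_config(seed = 11)
  tab <- simulate_ortholog_identities(cfg, 10000)
  for (k in 1:2) {
    x <- tab$identity[tab$component == k]
    se <- cfg$identity_sds[k] / sqrt(length(x))
    expect_lt(abs(mean(x) - cfg$identity_modes[k]), 3 * se + 0.005)
  }
  expect_true(all(tab$identity >= 0 & tab$identity <= 1))

  expect_warning(
    simulate_ortholog_identities(
      tiny_config(identity_modes = c(0.5, 0.45), identity_sds = c(0.1, 0.1)),
      10),
    "overlap")
})

test_that("codon-gene simulator produces valid ORFs with controlled bias", {
  pool <- default_trna_pool()
  g <- simulate_codon_genes(study_config(seed = 5), pool, 60)
  seqs <- g$sequences
  expect_true(all(nchar(seqs) %% 3 == 0))
  expect_true(all(substr(seqs, 1, 3) == "ATG"))
  stops <- substring(seqs, nchar(seqs) - 2, nchar(seqs))
  expect_true(all(stops %in% c("TAA", "TAG", "TGA")))
  # no internal stops: gene_tai would error otherwise
  prof <- tai_profile(pool)
  tais <- vapply(seqs, gene_tai, numeric(1), w = prof$w)
  expect_true(all(tais > 0 & tais <= 1))

  # downstream recovery: adapted genes have higher mean tAI
  expect_gt(mean(tais[g$truth$bias == "adapted"]),
            mean(tais[g$truth$bias == "uniform"]))

  # forced support: one tRNA per amino acid restricts adapted genes to
  # codons the pool can decode
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  one_per_aa <- vapply(split(sense, code[sense]), `[`, character(1), 1)
  small_pool <- data.frame(anticodon = revcomp(unname(one_per_aa)),
                           copies = 4L)
  gp <- simulate_codon_genes(study_config(seed = 6), small_pool, 10)
  profp <- tai_profile(small_pool)
  decodable <- names(profp$W)[profp$W > 0]
  for (i in which(gp$truth$bias == "adapted")) {
    s <- gp$sequences[i]
    codons <- substring(s, seq(1, nchar(s) - 3, 3), seq(3, nchar(s) - 3, 3))
    expect_true(all(codons %in% decodable))
  }
})
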