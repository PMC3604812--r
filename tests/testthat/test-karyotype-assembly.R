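simple_karyotype <- function() {
  list(list(name = "Chr1", blocks = c("+A", "-B", "+C"),
            centromere_after = 1L),
       list(name = "Chr2", blocks = c("+D"), centromere_after = 1L))
}

seg_row <- function(scaffold, block, start, end, orientation = "+",
                    n_genes = 5, mean_index = 2) {
  data.frame(scaffold = scaffold, start = start, end = end, block = block,
             n_genes = n_genes, orientation = orientation,
             mean_index = mean_index, stringsAsFactors = FALSE)
}

test_that("a scaffold painted as a chromosome's block order matches identically", {
  segs <- rbind(seg_row("s1", "A", 0, 100, "+"),
                seg_row("s1", "B", 100, 200, "-"),
                seg_row("s1", "C", 200, 300, "+"))
  plan <- match_scaffolds(simple_karyotype(), segs)
  df <- plan$chromosomes$Chr1
  expect_equal(df$scaffold, "s1")
  expect_equal(df$orientation, "+")
  expect_length(plan$unplaced, 0)

  # the reversed painting matches with orientation "-"
  rsegs <- rbind(seg_row("s2", "C", 0, 100, "-"),
                 seg_row("s2", "B", 100, 200, "+"),
                 seg_row("s2", "A", 200, 300, "-"))
  plan2 <- match_scaffolds(simple_karyotype(), rsegs)
  expect_equal(plan2$chromosomes$Chr1$orientation, "-")

  # a scaffold matching nothing is binned unplaced
  off <- seg_row("s3", "Z", 0, 100, "+")
  plan3 <- match_scaffolds(simple_karyotype(), off)
  expect_equal(plan3$unplaced, "s3")
  expect_true("unplaced_scaffold" %in% plan3$conflicts$kind)
})

test_that("simulated genomes are fully recovered without noise", {
  sim <- simulate_genome(study_config(seed = 31))
  plan <- run_assembly(sim)
  expect_equal(placement_accuracy(sim, plan), 1)
  # order along each chromosome equals ground-truth rank order
  for (kn in names(plan$chromosomes)) {
    df <- plan$chromosomes[[kn]]
    tr <- sim$truth$scaffolds[sim$truth$scaffolds$chrom == kn, ]
    tr <- tr[order(tr$rank), ]
    expect_equal(df$scaffold, tr$scaffold)
  }
  # sequence conservation: placed + unplaced = input scaffold set
  placed <- unlist(lapply(plan$chromosomes, function(df) df$scaffold))
  expect_setequal(c(placed, plan$unplaced), names(sim$scaffolds))
  expect_false(any(duplicated(placed)))
})

test_that("satellite-terminal evidence overrides orientation", {
  # single-block scaffold left of the centromere with ambiguous tau and a
  # left-terminal satellite: the satellite must face the centromere
  # (to the scaffold's right on the chromosome), forcing orientation "-"
  segs <- seg_row("s1", "A", 1000, 9000, "?")
  sat <- data.frame(scaffold = "s1", start = 0, end = 500)
  plan <- match_scaffolds(simple_karyotype(), segs, sat,
                          c(s1 = 10000))
  expect_equal(plan$chromosomes$Chr1$orientation[1], "-")
  expect_true("orientation_conflict" %in% plan$conflicts$kind)

  # same scaffold with a right-terminal satellite keeps "+"
  sat2 <- data.frame(scaffold = "s1", start = 9500, end = 10000)
  plan2 <- match_scaffolds(simple_karyotype(), segs, sat2,
                           c(s1 = 10000))
  expect_equal(plan2$chromosomes$Chr1$orientation[1], "+")
  expect_false("orientation_conflict" %in% plan2$conflicts$kind)
})

test_that("pseudomolecule construction emits exact AGP arithmetic", {
  karyotype <- list(list(name = "Chr1", blocks = c("+A", "+B"),
                         centromere_after = 1L))
  segs <- rbind(seg_row("s1", "A", 0, 900),
                seg_row("s2", "B", 0, 1900))
  plan <- match_scaffolds(karyotype, segs)
  set.seed(1)
  scaffolds <- c(s1 = paste(sample(c("A", "C", "G", "T"), 1000,
                                   replace = TRUE), collapse = ""),
                 s2 = paste(sample(c("A", "C", "G", "T"), 2000,
                                   replace = TRUE), collapse = ""))
  pm <- build_pseudomolecules(plan, scaffolds, inter_scaffold_gap = 100)
  expect_equal(nchar(pm$sequences[["Chr1"]]), 3100)
  expect_equal(pm$agp$object_end, c(1000, 1100, 3100))
  expect_equal(pm$agp$component_type, c("W", "U", "W"))

  # single-scaffold chromosome equals the scaffold sequence
  k1 <- list(list(name = "Chr1", blocks = "+A", centromere_after = 1L))
  p1 <- match_scaffolds(k1, seg_row("s1", "A", 0, 900))
  pm1 <- build_pseudomolecules(p1, scaffolds["s1"])
  expect_identical(pm1$sequences[["Chr1"]], scaffolds[["s1"]])
  expect_equal(nrow(pm1$agp), 1)

  # minus-orientation scaffold is reverse-complemented
  rsegs <- rbind(seg_row("s1", "B", 0, 900, "+"),
                 seg_row("s1", "A", 900, 1800, "+"))
  karyo2 <- list(list(name = "Chr1", blocks = c("+A", "+B"),
                      centromere_after = 1L))
  pr <- match_scaffolds(karyo2, rsegs)
  expect_equal(pr$chromosomes$Chr1$orientation, "-")
  pmr <- build_pseudomolecules(pr, c(s1 = "AACG"))
  expect_equal(pmr$sequences[["Chr1"]], "CGTT")

  # scaffold named in the plan but missing from the FASTA errors
  expect_error(build_pseudomolecules(plan, scaffolds["s1"]), "absent")
})

test_that("AGP round-trips the input scaffolds byte-identically", {
  for (s in c(41, 42)) {
    sim <- simulate_genome(tiny_config(seed = s))
    plan <- run_assembly(sim)
    pm <- build_pseudomolecules(plan, sim$scaffolds)
    back <- extract_agp_components(pm$agp, pm$sequences)
    expect_identical(back[sort(names(back))],
                     sim$scaffolds[sort(names(back))])
    # file round trip preserves the table
    f <- tempfile(fileext = ".agp")
    write_agp(pm$agp, f)
    agp2 <- read_agp(f)
    expect_equal(agp2$object_end, pm$agp$object_end)
    back2 <- extract_agp_components(agp2, pm$sequences)
    expect_identical(back2, back)
  }
})

test_that("discrepancy reporting covers missing and split blocks", {
  sim <- simulate_genome(study_config(seed = 33))
  plan <- run_assembly(sim)
  expect_equal(nrow(discrepancy_report(plan)), 0)

  # a karyotype block never painted is reported missing
  karyotype <- simple_karyotype()
  segs <- rbind(seg_row("s1", "A", 0, 100),
                seg_row("s2", "D", 0, 100))
  rep1 <- discrepancy_report(match_scaffolds(karyotype, segs))
  expect_setequal(rep1$entities[rep1$kind == "missing_block"], c("B", "C"))

  # a block placed on two chromosomes is flagged split
  karyo_split <- list(
    list(name = "Chr1", blocks = c("+A", "+B"), centromere_after = 1L),
    list(name = "Chr2", blocks = c("+C", "+A"), centromere_after = 1L))
  segs2 <- rbind(seg_row("s1", "A", 0, 100),
                 seg_row("s2", "B", 0, 100),
                 seg_row("s3", "C", 0, 100, n_genes = 8),
                 seg_row("s3", "A", 100, 200, n_genes = 8))
  rep2 <- discrepancy_report(match_scaffolds(karyo_split, segs2))
  expect_equal(sum(rep2$kind == "split_block"), 1)
  expect_equal(rep2$entities[rep2$kind == "split_block"], "A")
})

test_that("digital karyotype rendering is deterministic and complete", {
  sim <- simulate_genome(tiny_config(seed = 44))
  plan <- run_assembly(sim)
  svg1 <- render_digital_karyotype(plan)
  svg2 <- render_digital_karyotype(plan)
  expect_identical(svg1, svg2)
  n_blocks_drawn <- sum(vapply(plan$chromosomes, function(df)
    length(unlist(strsplit(df$blocks, ","))), integer(1)))
  expect_equal(lengths(regmatches(svg1, gregexpr("<rect", svg1))),
               n_blocks_drawn)

  # empty plan renders a header-only document
  empty_plan <- structure(list(chromosomes = list(), unplaced = character(0),
                               conflicts = data.frame(), karyotype = list()),
                          class = "placement_plan")
  svg0 <- render_digital_karyotype(empty_plan)
  expect_match(svg0, "^<svg")
  expect_false(grepl("<rect", svg0))
})
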