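mk_catalog <- function(n, species = "sp1", scaffold = "c1",
                       family = NA, cluster = NA) {
  data.frame(gene = sprintf("%s_g%03d", species, seq_len(n)),
             species = species, scaffold = scaffold,
             order_index = seq_len(n), family = family, cluster = cluster,
             stringsAsFactors = FALSE)
}

test_that("tandem calls follow the less-than-20-genes rule", {
  cat <- mk_catalog(40)
  cat$family[c(5, 6, 30)] <- "F"
  res <- tandem_pairs(cat, "F")
  # adjacent members at indices 5 and 6: intervening 0, tandem
  adj <- res$calls[res$calls$gene_a == "sp1_g005", ]
  expect_equal(adj$intervening, 0)
  expect_true(adj$is_tandem)
  # indices 6 and 30: difference 24, not tandem
  far <- res$calls[res$calls$gene_a == "sp1_g006", ]
  expect_false(far$is_tandem)
  # boundary: exactly max_distance apart is non-tandem
  cat2 <- mk_catalog(40)
  cat2$family[c(5, 25)] <- "F"          # difference exactly 20
  expect_false(tandem_pairs(cat2, "F")$calls$is_tandem)
  cat3 <- mk_catalog(40)
  cat3$family[c(5, 24)] <- "F"          # difference 19 < 20
  expect_true(tandem_pairs(cat3, "F")$calls$is_tandem)

  # tandem proportion counts members in >= 1 tandem call
  expect_equal(res$proportion$members, 3)
  expect_equal(res$proportion$tandem_members, 2)

  # absent family: empty result
  expect_equal(nrow(tandem_pairs(cat, "nope")$calls), 0)
})

test_that("tandem calls match a brute-force oracle and ignore row order", {
  set.seed(10)
  for (i in 1:25) {
    cat <- mk_catalog(200, scaffold = sample(c("c1", "c2"), 200,
                                             replace = TRUE))
    cat$order_index <- ave(seq_len(200), cat$scaffold, FUN = seq_along)
    fam_genes <- sample(200, 25)
    cat$family[fam_genes] <- "F"
    res <- tandem_pairs(cat, "F")

    # oracle: all same-scaffold pairs with no intervening family member
    fam <- cat[!is.na(cat$family), ]
    oracle <- list()
    for (sc in unique(fam$scaffold)) {
      sub <- fam[fam$scaffold == sc, ]
      sub <- sub[order(sub$order_index), ]
      if (nrow(sub) < 2) next
      for (a in seq_len(nrow(sub) - 1)) {
        b <- a + 1
        oracle[[length(oracle) + 1]] <- data.frame(
          gene_a = sub$gene[a], gene_b = sub$gene[b],
          is_tandem = (sub$order_index[b] - sub$order_index[a]) < 20)
      }
    }
    oracle <- do.call(rbind, oracle)
    got <- res$calls[order(res$calls$gene_a, res$calls$gene_b), ]
    oracle <- oracle[order(oracle$gene_a, oracle$gene_b), ]
    expect_equal(got$gene_b, oracle$gene_b)
    expect_equal(got$is_tandem, oracle$is_tandem)

    # row-order invariance
    shuf <- cat[sample(nrow(cat)), ]
    res2 <- tandem_pairs(shuf, "F")
    expect_equal(res2$calls[order(res2$calls$gene_a, res2$calls$gene_b),
                            "is_tandem"],
                 got$is_tandem)
  }
})

test_that("lineage-specific clusters are counted per species", {
  cat <- rbind(
    within(mk_catalog(11, "esal"), cluster <- "grp1"),   # 11 + 0 others
    within(mk_catalog(3, "athal"), cluster <- "grp2"),
    within(mk_catalog(2, "esal"), cluster <- "grp2"),    # mixed
    within(mk_catalog(1, "athal"), cluster <- "grp3"))   # singleton
  res <- lineage_specific_clusters(cat)
  expect_equal(unname(res$counts["esal"]), 1)
  expect_equal(unname(res$counts["athal"]), 0)
  expect_equal(nrow(res$matrix), 2)   # singleton cluster ignored

  # planted single-species clusters are all recovered
  set.seed(3)
  k <- 7
  planted <- do.call(rbind, lapply(seq_len(k), function(i)
    within(mk_catalog(sample(2:6, 1), "spX"), cluster <- paste0("p", i))))
  mixed <- rbind(within(mk_catalog(2, "spX"), cluster <- "m1"),
                 within(mk_catalog(2, "spY"), cluster <- "m1"))
  res2 <- lineage_specific_clusters(rbind(planted, mixed))
  expect_equal(unname(res2$counts["spX"]), k)
  # summed counts never exceed clusters of size >= 2
  expect_lte(sum(res2$counts), nrow(res2$matrix))
})

test_that("copy-number comparison uses Fisher's exact test with BH", {
  cat_a <- mk_catalog(1000, "A")
  cat_b <- mk_catalog(1000, "B")
  cat_a$family[1:10] <- "F"
  cat_b$family[1:10] <- "F"
  res <- copy_number_compare(rbind(cat_a, cat_b),
                             species_pair = c("A", "B"))
  expect_equal(res$p, 1)

  # p equals the exact hypergeometric enumeration
  cat_a$family[1:20] <- "F"
  cat_b$family[1:10] <- NA
  cat_b$family[1:5] <- "F"
  res2 <- copy_number_compare(rbind(cat_a, cat_b),
                              species_pair = c("A", "B"))
  # oracle: two-sided Fisher p by enumerating the hypergeometric tail
  m <- 20 + 5; tot <- 2000
  probs <- dhyper(0:m, 1000, 1000, m)
  p_oracle <- sum(probs[probs <= dhyper(20, 1000, 1000, m) * (1 + 1e-7)])
  expect_equal(res2$p, p_oracle, tolerance = 1e-10)

  # a strongly enriched family is flagged at large n
  cat_a$family[1:60] <- "G"
  cat_b$family <- NA
  cat_b$family[1:20] <- "G"
  res3 <- copy_number_compare(rbind(cat_a, cat_b),
                              species_pair = c("A", "B"))
  expect_true(res3$enriched[res3$family == "G"])

  # BH adjustment is monotone in the raw p-values
  set.seed(8)
  cat_a$family <- sample(c("f1", "f2", "f3", NA), 1000, replace = TRUE)
  cat_b$family <- sample(c("f1", "f2", "f3", NA), 1000, replace = TRUE,
                         prob = c(0.4, 0.2, 0.1, 0.3))
  res4 <- copy_number_compare(rbind(cat_a, cat_b),
                              species_pair = c("A", "B"))
  ord <- order(res4$p)
  expect_true(all(diff(res4$p_adj[ord]) >= -1e-12))

  expect_error(copy_number_compare(cat_a, species_pair = c("A", "Z")),
               "zero")
})
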