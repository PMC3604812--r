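#' Tandem-duplication calls within a gene family
#'
#' Consecutive same-family genes along each scaffold form a candidate pair;
#' the pair is tandem when their gene-order index difference is strictly
#' below `max_distance` (the "less than 20 genes apart" rule). A family
#' member counts as tandemly duplicated when it participates in at least
#' one tandem call. With `all_pairs = TRUE` every same-scaffold pair within
#' the window is called, not only consecutive members.
#'
#' @param catalog data frame with columns `gene`, `species`, `scaffold`,
#'   `order_index`, `family` (and optionally `cluster`).
#' @param family family id to analyse.
#' @param max_distance tandem window in gene-order units (exclusive).
#' @param all_pairs call all within-window pairs instead of consecutive
#'   members only.
#' @return list with `calls` (data frame `gene_a`, `gene_b`, `species`,
#'   `scaffold`, `intervening`, `is_tandem`) and `proportion` (data frame
#'   `species`, `members`, `tandem_members`, `proportion`).
#' @export
tandem_pairs <- function(catalog, family, max_distance = 20L,
                         all_pairs = FALSE) {
  fam <- catalog[!is.na(catalog$family) & catalog$family == family, ,
                 drop = FALSE]
  empty_calls <- data.frame(gene_a = character(0), gene_b = character(0),
                            species = character(0), scaffold = character(0),
                            intervening = integer(0), is_tandem = logical(0))
  if (nrow(fam) == 0L)
    return(list(calls = empty_calls,
                proportion = data.frame(species = character(0),
                                        members = integer(0),
                                        tandem_members = integer(0),
                                        proportion = numeric(0))))
  fam <- fam[order(fam$species, fam$scaffold, fam$order_index), ,
             drop = FALSE]
  calls <- list()
  for (key in unique(paste(fam$species, fam$scaffold, sep = "\r"))) {
    parts <- strsplit(key, "\r")[[1]]
    sub <- fam[fam$species == parts[1] & fam$scaffold == parts[2], ,
               drop = FALSE]
    n <- nrow(sub)
    if (n < 2L) next
    pairs <- if (all_pairs) utils::combn(n, 2L) else
      rbind(seq_len(n - 1L), seq(2L, n))
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1L, k]; j <- pairs[2L, k]
      d <- sub$order_index[j] - sub$order_index[i]
      if (all_pairs && d >= max_distance) next
      calls[[length(calls) + 1L]] <- data.frame(
        gene_a = sub$gene[i], gene_b = sub$gene[j],
        species = parts[1], scaffold = parts[2],
        intervening = d - 1L, is_tandem = d < max_distance,
        stringsAsFactors = FALSE)
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else empty_calls
  tandem_genes <- unique(c(calls$gene_a[calls$is_tandem],
                           calls$gene_b[calls$is_tandem]))
  prop <- do.call(rbind, lapply(split(fam, fam$species), function(sp)
    data.frame(species = sp$species[1], members = nrow(sp),
               tandem_members = sum(sp$gene %in% tandem_genes),
               proportion = sum(sp$gene %in% tandem_genes) / nrow(sp),
               stringsAsFactors = FALSE)))
  rownames(prop) <- NULL
  list(calls = calls, proportion = prop)
}

#' Count lineage-specific homology clusters per species
#'
#' Clusters of size at least two whose members all come from one species
#' are lineage-specific to that species (e.g. a cluster of 11 genes from
#' one genome and none from the others). Returns per-species counts and
#' the full cluster-by-species membership matrix.
#'
#' @param catalog data frame with `gene`, `species`, `cluster`.
#' @return list with `counts` (named integer vector per species) and
#'   `matrix` (clusters x species member counts, clusters of size >= 2).
#' @export
lineage_specific_clusters <- function(catalog) {
  cl <- catalog[!is.na(catalog$cluster), , drop = FALSE]
  species <- sort(unique(catalog$species))
  counts <- stats::setNames(integer(length(species)), species)
  if (nrow(cl) == 0L)
    return(list(counts = counts,
                matrix = matrix(0L, 0L, length(species),
                                dimnames = list(NULL, species))))
  tab <- table(cl$cluster, cl$species)
  tab <- tab[rowSums(tab) >= 2L, , drop = FALSE]
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  one_species <- rowSums(m > 0L) == 1L
  for (r in which(one_species)) {
    sp <- colnames(m)[m[r, ] > 0L]
    counts[sp] <- counts[sp] + 1L
  }
  list(counts = counts, matrix = m)
}

#' Compare family copy numbers between two species
#'
#' For every family, builds the 2x2 table (family members vs all other
#' genes, species A vs species B), applies Fisher's exact test (two-sided)
#' and Benjamini-Hochberg adjustment across families, and flags families
#' with adjusted p below `alpha`.
#'
#' @param catalog gene catalog data frame (`gene`, `species`, `family`).
#' @param families families to test; default all families present in
#'   either species.
#' @param species_pair length-2 character vector of species names.
#' @param alpha significance threshold on the adjusted p-value.
#' @return data frame with `family`, `count_a`, `count_b`, `total_a`,
#'   `total_b`, `odds_ratio`, `p`, `p_adj`, `enriched`.
#' @export
copy_number_compare <- function(catalog, families = NULL, species_pair,
                                alpha = 0.05) {
  stopifnot(length(species_pair) == 2L)
  a <- catalog[catalog$species == species_pair[1], , drop = FALSE]
  b <- catalog[catalog$species == species_pair[2], , drop = FALSE]
  total_a <- nrow(a); total_b <- nrow(b)
  if (total_a == 0L || total_b == 0L) stop("zero genome totals")
  families <- families %||%
    sort(unique(stats::na.omit(c(a$family, b$family))))
  rows <- lapply(families, function(f) {
    ca <- sum(!is.na(a$family) & a$family == f)
    cb <- sum(!is.na(b$family) & b$family == f)
    ft <- stats::fisher.test(matrix(c(ca, total_a - ca, cb, total_b - cb),
                                    nrow = 2L))
    data.frame(family = f, count_a = ca, count_b = cb,
               total_a = total_a, total_b = total_b,
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$enriched <- out$p_adj < alpha
  out
}
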