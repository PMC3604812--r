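#' Wobble pairing rules for tAI
#'
#' The selective constraints `s` penalising non-Watson-Crick codon:anticodon
#' pairings at the codon third position, in the standard tAI
#' parameterisation: Watson-Crick pairs have s = 0; wobble pairs are
#' anticodon G : codon U (s = 0.41), inosine (from anticodon A) : codon C
#' (s = 0.28), inosine : codon A (s = 0.9999), anticodon U : codon G
#' (s = 0.68); and the lysidine-class pairing of anticodon CAU reading AUA
#' (s = 0.89). All values are overridable.
#'
#' @return list with `pairs` (data frame: codon third base, anticodon wobble
#'   base, s) and `special` (data frame: codon, anticodon, s).
#' @export
wobble_rules <- function() {
  list(
    pairs = data.frame(
      codon3 = c("T", "T", "C", "C", "A", "A", "G", "G"),
      anti1  = c("A", "G", "G", "A", "T", "A", "C", "T"),
      s      = c(0,   0.41, 0,  0.28, 0,  0.9999, 0, 0.68),
      stringsAsFactors = FALSE),
    special = data.frame(
      codon = "ATA", anticodon = "CAT", s = 0.89,
      stringsAsFactors = FALSE))
}

stop_codons <- function() c("TAA", "TAG", "TGA")

#' Absolute adaptiveness W of a codon
#'
#' `W = sum over recognising anticodons j of (1 - s_j) * tGCN_j`, where
#' recognition is determined by the wobble rules at the codon third
#' position (the anticodon's last two bases must Watson-Crick pair the
#' codon's first two).
#'
#' @param codon a sense codon (DNA alphabet).
#' @param pool data frame (anticodon, copies).
#' @param rules wobble rules, see [wobble_rules()].
#' @return numeric W (possibly 0 when no tRNA recognises the codon).
#' @export
absolute_adaptiveness <- function(codon, pool, rules = wobble_rules()) {
  codon <- toupper(codon)
  if (codon %in% stop_codons()) stop("stop codon has no adaptiveness: ", codon)
  tgcn <- stats::setNames(pool$copies, pool$anticodon)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  b <- strsplit(codon, "")[[1]]
  tail2 <- paste0(comp[b[2]], comp[b[1]])   # anticodon positions 2-3
  rel <- rules$pairs[rules$pairs$codon3 == b[3], , drop = FALSE]
  W <- 0
  for (i in seq_len(nrow(rel))) {
    anti <- paste0(rel$anti1[i], tail2)
    if (anti %in% names(tgcn)) W <- W + (1 - rel$s[i]) * tgcn[[anti]]
  }
  sp <- rules$special[rules$special$codon == codon, , drop = FALSE]
  for (i in seq_len(nrow(sp)))
    if (sp$anticodon[i] %in% names(tgcn))
      W <- W + (1 - sp$s[i]) * tgcn[[sp$anticodon[i]]]
  W
}

#' Relative adaptiveness w from absolute W values
#'
#' `w = W / max(W)`; codons with w = 0 (no recognising tRNA) are replaced by
#' the geometric mean of the nonzero w values, the standard tAI convention.
#'
#' @param W named numeric vector of absolute adaptiveness values.
#' @return named numeric vector `w` in (0, 1].
#' @export
relative_adaptiveness <- function(W) {
  if (all(W == 0)) stop("all W are zero: empty tRNA pool?")
  w <- W / max(W)
  zero <- w == 0
  if (any(zero)) w[zero] <- exp(mean(log(w[!zero])))
  w
}

#' Per-codon tAI profile for a tRNA pool
#'
#' @param pool data frame (anticodon, copies).
#' @param rules wobble rules.
#' @return list with named vectors `W` and `w` over all 61 sense codons.
#' @export
tai_profile <- function(pool, rules = wobble_rules()) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  W <- vapply(sense, absolute_adaptiveness, numeric(1),
              pool = pool, rules = rules)
  list(W = W, w = relative_adaptiveness(W))
}

#' tAI of a coding sequence
#'
#' Geometric mean of the per-codon relative adaptiveness values over the
#' gene's codons; a single terminal stop codon is excluded, and the
#' initiator codon can optionally be excluded too.
#'
#' @param cds coding sequence (length divisible by 3).
#' @param w named per-codon relative adaptiveness (see [tai_profile()]).
#' @param exclude_initiator drop the first codon from the mean.
#' @return tAI in (0, 1].
#' @export
gene_tai <- function(cds, w, exclude_initiator = FALSE) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n == 0L || n %% 3L != 0L) stop("coding sequence length not divisible by 3")
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  if (codons[length(codons)] %in% stop_codons())
    codons <- codons[-length(codons)]
  if (exclude_initiator && length(codons) > 1L) codons <- codons[-1L]
  if (any(codons %in% stop_codons())) stop("premature stop codon")
  if (!all(codons %in% names(w))) stop("codon missing from w table")
  exp(mean(log(w[codons])))
}

#' Compare tAI distributions of a gene family between two species
#'
#' Wilcoxon rank-sum (Mann-Whitney) test: for combined sample sizes up to
#' `exact_max` the null distribution is obtained by full enumeration of all
#' assignments of the pooled ranks (correct under ties); larger samples use
#' the normal approximation with continuity correction. The reported
#' direction is the sign of `median(a) - median(b)`.
#'
#' @param a,b numeric tAI values of family members in the two species.
#' @param exact_max largest combined n for the exact enumeration.
#' @return list with `statistic` (rank sum of sample `a`), `p` (two-sided),
#'   `direction` (-1, 0, 1) and `method`.
#' @export
family_tai_compare <- function(a, b, exact_max = 20L) {
  if (length(a) == 0L && length(b) == 0L) stop("both samples empty")
  if (length(a) == 0L || length(b) == 0L)
    stop("rank-sum test needs both samples non-empty")
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))
  W <- sum(r[seq_len(n1)])
  if (n <= exact_max) {
    sums <- utils::combn(r, n1, sum)
    p <- min(1, 2 * min(mean(sums <= W), mean(sums >= W)))
    method <- "exact enumeration"
  } else {
    mu <- n1 * (n + 1) / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(statistic = W, p = p,
       direction = sign(stats::median(a) - stats::median(b)),
       method = method)
}

#' Cross-species tAI density summary
#'
#' Builds the 2-D kernel density over ortholog-paired tAI values plus the
#' marginal summaries used for the cross-species comparison plot.
#'
#' @param tai_a,tai_b ortholog-paired tAI vectors, equal length.
#' @param n grid size per axis.
#' @return list with `density` ([MASS::kde2d()] result), `mean_a`, `mean_b`,
#'   `quantiles_a`, `quantiles_b` and `frac_b_higher` (fraction of pairs
#'   with tAI_b > tAI_a).
#' @export
genome_tai_density <- function(tai_a, tai_b, n = 100L) {
  if (length(tai_a) != length(tai_b)) stop("paired tAI vectors differ in length")
  qs <- c(0.25, 0.5, 0.75)
  list(density = MASS::kde2d(tai_a, tai_b, n = n),
       mean_a = mean(tai_a), mean_b = mean(tai_b),
       quantiles_a = stats::quantile(tai_a, qs),
       quantiles_b = stats::quantile(tai_b, qs),
       frac_b_higher = mean(tai_b > tai_a))
}
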