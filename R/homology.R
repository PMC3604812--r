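#' Overall tiled identity of one query-subject pair
#'
#' Merges the multiple alignment fragments (HSPs) of a protein pair into a
#' single non-redundant alignment on the query axis: fragments are tiled
#' greedily in descending matched-position order, and columns already
#' claimed by a stronger fragment are truncated away (a truncated fragment
#' keeps matches in proportion to its surviving columns). The overall
#' identity is the surviving matched positions divided by the total tiled
#' columns.
#'
#' @param fragments data frame with columns `qstart`, `qend` (0-based
#'   half-open, aa) and `matched`; all rows must belong to one
#'   query-subject pair.
#' @param query_length optional query length (bounds checking only).
#' @return list with `identity` and `columns` (tiled column count).
#' @export
tiled_identity <- function(fragments, query_length = NULL) {
  if (nrow(fragments) == 0L) stop("empty fragment list")
  len <- fragments$qend - fragments$qstart
  stopifnot(all(len > 0), all(fragments$matched <= len))
  qmax <- query_length %||% max(fragments$qend)
  stopifnot(max(fragments$qend) <= qmax)
  ord <- order(-fragments$matched, fragments$qstart, fragments$qend)
  covered <- logical(qmax)
  matched <- 0
  for (i in ord) {
    idx <- seq(fragments$qstart[i] + 1L, fragments$qend[i])
    new <- !covered[idx]
    if (!any(new)) next
    matched <- matched + fragments$matched[i] * sum(new) / length(idx)
    covered[idx[new]] <- TRUE
  }
  cols <- sum(covered)
  list(identity = matched / cols, columns = cols)
}

#' Best hit per query from tiled identities
#'
#' Selects, for every query, the subject with the highest overall tiled
#' identity; ties are broken by larger tiled column count, then by
#' lexicographically smaller subject id.
#'
#' @param hits data frame with columns `query`, `subject`, `identity` and
#'   optionally `columns`.
#' @return data frame with one row per query (`query`, `subject`,
#'   `identity`, `columns`).
#' @export
best_hits <- function(hits) {
  stopifnot(all(hits$identity >= 0 & hits$identity <= 1))
  if (is.null(hits$columns)) hits$columns <- 0
  ord <- order(hits$query, -hits$identity, -hits$columns, hits$subject)
  h <- hits[ord, , drop = FALSE]
  h <- h[!duplicated(h$query), , drop = FALSE]
  rownames(h) <- NULL
  h[, c("query", "subject", "identity", "columns")]
}

#' Modes of a smoothed identity distribution
#'
#' Gaussian-kernel density on a 512-point grid over \[0, 1\]; the modes are
#' the interior local maxima whose density reaches at least 10% of the
#' global maximum, sorted by density (highest first).
#'
#' @param identities numeric vector of identities in \[0, 1\]; at least 50
#'   values are required for a stable density.
#' @param bandwidth kernel bandwidth; default Silverman's rule (`bw.nrd0`).
#' @return data frame with `mode` (identity) and `density`.
#' @export
identity_modes <- function(identities, bandwidth = NULL) {
  if (length(identities) < 50L)
    stop("need at least 50 values for a stable density")
  d <- identity_density(identities, bandwidth)
  y <- d$y
  i <- seq(2L, length(y) - 1L)
  is_max <- y[i] > y[i - 1L] & y[i] >= y[i + 1L] & y[i] >= 0.1 * max(y)
  mi <- i[is_max]
  out <- data.frame(mode = d$x[mi], density = y[mi])
  out[order(-out$density), , drop = FALSE]
}

# shared density grid so two samples are directly comparable
identity_density <- function(identities, bandwidth = NULL) {
  bw <- bandwidth %||% stats::bw.nrd0(identities)
  stats::density(identities, bw = bw, n = 512L, from = 0, to = 1)
}

#' Crossing point of two identity densities
#'
#' Finds the identity at which two smoothed densities intersect between
#' their principal modes — the natural homology cutoff between an ingroup
#' and an outgroup distribution. With several sign changes the one nearest
#' the midpoint of the two modes wins; within it, the grid point minimising
#' the density difference is returned.
#'
#' @param density_a,density_b density objects on the same grid
#'   (see [identity_density()] via [identity_modes()]), or numeric samples
#'   (densities are then computed internally with a shared default
#'   bandwidth).
#' @return list with `crossing`, `mode_a`, `mode_b`.
#' @export
crossing_point <- function(density_a, density_b) {
  if (is.numeric(density_a)) density_a <- identity_density(density_a)
  if (is.numeric(density_b)) density_b <- identity_density(density_b)
  stopifnot(isTRUE(all.equal(density_a$x, density_b$x)))
  x <- density_a$x; ya <- density_a$y; yb <- density_b$y
  ma <- which.max(ya); mb <- which.max(yb)
  if (ma == mb) stop("distributions do not cross: principal modes coincide")
  lo <- min(ma, mb); hi <- max(ma, mb)
  d <- ya[lo:hi] - yb[lo:hi]
  sc <- which(d[-length(d)] * d[-1L] < 0 |
                (d[-length(d)] != 0 & d[-1L] == 0))
  if (length(sc) == 0L) stop("distributions do not cross")
  mid <- (lo + hi) / 2
  best <- sc[which.min(abs((lo + sc) - mid))]
  pair <- c(best, best + 1L)
  gi <- lo - 1L + pair[which.min(abs(d[pair]))]
  list(crossing = x[gi], mode_a = x[ma], mode_b = x[mb])
}

#' Classify best hits by homology cutoffs
#'
#' `identity < low` is `no_homolog`; `low <= identity < high` is `low`
#' (homology); `identity >= high` is `high`. Bins are half-open at the
#' upper edge.
#'
#' @param identity numeric vector of best-hit identities.
#' @param low_cutoff,high_cutoff homology cutoffs (defaults 0.30 / 0.60).
#' @return factor with levels `no_homolog`, `low`, `high`.
#' @export
classify_orthologs <- function(identity, low_cutoff = 0.30,
                               high_cutoff = 0.60) {
  stopifnot(low_cutoff < high_cutoff)
  cut(identity, breaks = c(-Inf, low_cutoff, high_cutoff, Inf),
      labels = c("no_homolog", "low", "high"), right = FALSE)
}

#' Derive homology cutoffs from two identity samples
#'
#' Computes the principal modes of an ingroup and an outgroup identity
#' sample, their crossing point, and the derived cutoffs: the high-homology
#' cutoff is the crossing identity and the low-homology cutoff is half of
#' it (mirroring the 30/60% convention obtained from distributions crossing
#' near 60%).
#'
#' @param ingroup,outgroup identity samples (high- and low-identity
#'   distributions).
#' @param bandwidth optional shared kernel bandwidth.
#' @return list with `mode_high`, `mode_low`, `crossing`, `low_cutoff`,
#'   `high_cutoff`.
#' @export
derive_cutoffs <- function(ingroup, outgroup, bandwidth = NULL) {
  da <- identity_density(ingroup, bandwidth)
  db <- identity_density(outgroup, bandwidth)
  cr <- crossing_point(da, db)
  mode_high <- max(cr$mode_a, cr$mode_b)
  mode_low <- min(cr$mode_a, cr$mode_b)
  if (!(mode_low < cr$crossing && cr$crossing < mode_high))
    stop("crossing does not lie between the modes")
  list(mode_high = mode_high, mode_low = mode_low, crossing = cr$crossing,
       low_cutoff = cr$crossing / 2, high_cutoff = cr$crossing)
}
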