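# sequence as integer codes; N mapped to NA so it can never match
seq_codes <- function(sequence) {
  r <- utf8ToInt(toupper(sequence))
  r[r == utf8ToInt("N")] <- NA_integer_
  r
}

# per-offset base-match indicator: m[i] = (s[i] == s[i+p]), N never matches
period_matches <- function(codes, p) {
  L <- length(codes)
  a <- codes[seq_len(L - p)]
  b <- codes[seq(p + 1L, L)]
  m <- a == b
  m[is.na(m)] <- FALSE
  m
}

#' Estimate the tandem-repeat period of a window
#'
#' Base-match autocorrelation: for each candidate period p the score is the
#' fraction of positions i with `base(i) == base(i + p)` (N never counts as
#' a match). The best period is the smallest p whose score is within
#' `harmonic_tol` of the maximum, provided the maximum reaches
#' `match_threshold` — the smallest-period rule suppresses harmonics
#' (multiples of the true period score equally well).
#'
#' @param sequence window sequence; must be at least `3 * max_period` long.
#' @param min_period,max_period candidate period range, bp.
#' @param match_threshold minimum score to call periodicity.
#' @param harmonic_tol score slack within which the smallest period wins.
#' @return list with `period` and `score`, or `NULL` when no candidate
#'   reaches the threshold.
#' @export
estimate_period <- function(sequence, min_period = 50L, max_period = 500L,
                            match_threshold = 0.8, harmonic_tol = 0.01) {
  codes <- seq_codes(sequence)
  L <- length(codes)
  if (L < 3L * max_period)
    stop("window shorter than 3 * max_period")
  periods <- seq(min_period, max_period)
  scores <- vapply(periods, function(p) mean(period_matches(codes, p)),
                   numeric(1))
  top <- max(scores)
  if (top < match_threshold) return(NULL)
  eligible <- which(scores >= top - harmonic_tol & scores >= match_threshold)
  best <- eligible[1]
  list(period = periods[best], score = scores[best])
}

#' Find tandem satellite arrays on a scaffold
#'
#' Slides windows of length `3 * max_period` with 50% overlap, estimates a
#' period per window, merges runs of adjacent windows reporting the same
#' period (within 2 bp), refines each merged region's boundaries outward
#' and inward in period-sized steps while the local match score stays at or
#' above `match_threshold`, and reports each surviving region as an array
#' with copy count, phase-aligned majority consensus and consensus AT
#' fraction.
#'
#' @param sequence scaffold sequence.
#' @param scaffold scaffold name recorded in the output.
#' @param min_period,max_period candidate period range, bp.
#' @param match_threshold minimum autocorrelation score.
#' @param harmonic_tol score slack for the smallest-period rule.
#' @param min_copies arrays with fewer tandem copies are dropped.
#' @return data frame (possibly empty) with columns `scaffold`, `start`,
#'   `end` (0-based half-open), `period`, `copies`, `consensus`,
#'   `at_fraction`, sorted by `start`.
#' @export
find_arrays <- function(sequence, scaffold = "scaffold",
                        min_period = 50L, max_period = 500L,
                        match_threshold = 0.8, harmonic_tol = 0.01,
                        min_copies = 5) {
  empty <- data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), period = integer(0),
                      copies = numeric(0), consensus = character(0),
                      at_fraction = numeric(0))
  codes <- seq_codes(sequence)
  L <- length(codes)
  W <- 3L * max_period
  if (L < W) return(empty)
  step <- W %/% 2L
  starts <- seq(1L, L - W + 1L, by = step)
  periods <- seq(min_period, max_period)

  # score matrix windows x periods via one cumsum per period
  S <- matrix(0, nrow = length(starts), ncol = length(periods))
  for (j in seq_along(periods)) {
    p <- periods[j]
    cs <- c(0, cumsum(period_matches(codes, p)))
    e <- pmin(starts + W - p - 1L, L - p)
    S[, j] <- (cs[e + 1L] - cs[starts]) / (e - starts + 1L)
  }
  win_period <- rep(NA_integer_, length(starts))
  for (i in seq_along(starts)) {
    top <- max(S[i, ])
    if (top < match_threshold) next
    eligible <- which(S[i, ] >= top - harmonic_tol &
                        S[i, ] >= match_threshold)
    win_period[i] <- periods[eligible[1]]
  }

  hit <- which(!is.na(win_period))
  if (length(hit) == 0L) return(empty)
  # group consecutive hit windows with compatible periods
  grp <- cumsum(c(1L, diff(hit) > 1L |
                    abs(diff(win_period[hit])) > 2L))
  out <- list()
  for (g in unique(grp)) {
    wi <- hit[grp == g]
    p <- as.integer(round(stats::median(win_period[wi])))
    seed_start <- starts[wi[1]]
    seed_end <- min(starts[wi[length(wi)]] + W - 1L, L)
    m <- period_matches(codes, p)
    chunk_ok <- function(a, b) {               # positions a..b of m
      a <- max(1L, a); b <- min(length(m), b)
      b >= a && mean(m[a:b]) >= match_threshold
    }
    # extend outward, then trim inward, in period-sized steps
    a <- seed_start
    while (a - p >= 1L && chunk_ok(a - p, a - 1L)) a <- a - p
    while (a + p <= seed_end && !chunk_ok(a, a + p - 1L)) a <- a + p
    b <- seed_end - p                           # last compared position
    while (b + p <= length(m) && chunk_ok(b + 1L, b + p)) b <- b + p
    while (b - p >= a && !chunk_ok(b - p + 1L, b)) b <- b - p
    arr_start <- a - 1L                         # 0-based
    arr_end <- min(b + p, L)                    # half-open
    len <- arr_end - arr_start
    copies <- len / p
    if (copies < min_copies) next
    cons <- array_consensus(sequence, arr_start, arr_end, p)
    out[[length(out) + 1L]] <- data.frame(
      scaffold = scaffold, start = arr_start, end = arr_end,
      period = p, copies = copies, consensus = cons,
      at_fraction = at_fraction(cons), stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# majority-vote consensus over phase-aligned full copies
array_consensus <- function(sequence, start, end, period) {
  n_full <- (end - start) %/% period
  if (n_full == 0L) return("")
  off <- start + (seq_len(n_full) - 1L) * period
  mat <- vapply(seq_len(period), function(j) {
    substring(sequence, off + j, off + j)
  }, character(n_full))
  if (n_full == 1L) mat <- matrix(mat, nrow = 1L)
  cons <- apply(mat, 2L, function(col) {
    col <- col[col %in% c("A", "C", "G", "T")]
    if (length(col) == 0L) return("N")
    tb <- table(col)
    names(tb)[which.max(tb)]
  })
  paste(cons, collapse = "")
}

at_fraction <- function(x) {
  n <- nchar(x)
  if (n == 0L) return(NA_real_)
  nchar(gsub("[^AT]", "", x)) / n
}

#' Classify an array as scaffold-terminal or internal
#'
#' An array is terminal when it lies within `margin` of the scaffold
#' length from an end; when it qualifies at both ends the nearer terminus
#' wins (ties go left). Terminal satellite arrays mark the centromeric end
#' of a scaffold and are the orientation evidence used at assembly time.
#'
#' @param start,end array interval (0-based half-open).
#' @param scaffold_length scaffold length, bp.
#' @param margin fraction of the scaffold length counted as terminal.
#' @return one of `"left_terminal"`, `"right_terminal"`, `"internal"`.
#' @export
terminal_classification <- function(start, end, scaffold_length,
                                    margin = 0.1) {
  stopifnot(start >= 0, end <= scaffold_length)
  left <- start < margin * scaffold_length
  right <- end > (1 - margin) * scaffold_length
  if (left && right) {
    if (start <= scaffold_length - end) "left_terminal" else "right_terminal"
  } else if (left) "left_terminal"
  else if (right) "right_terminal"
  else "internal"
}

#' Genome-wide satellite summary
#'
#' @param arrays data frame of arrays as returned by [find_arrays()]
#'   (rows from several scaffolds may be concatenated).
#' @return list with `total_copies`, `n_arrays`, `arrays_per_scaffold`
#'   (named count vector, scaffold order), and `at_summary`
#'   (min/mean/max consensus AT fraction), computed over the input sorted
#'   by scaffold then start.
#' @export
genome_satellite_summary <- function(arrays) {
  if (nrow(arrays) == 0L)
    return(list(total_copies = 0, n_arrays = 0L,
                arrays_per_scaffold = integer(0),
                at_summary = c(min = NA_real_, mean = NA_real_,
                               max = NA_real_)))
  arrays <- arrays[order(arrays$scaffold, arrays$start), , drop = FALSE]
  list(total_copies = sum(arrays$copies),
       n_arrays = nrow(arrays),
       arrays_per_scaffold = table(arrays$scaffold),
       at_summary = c(min = min(arrays$at_fraction),
                      mean = mean(arrays$at_fraction),
                      max = max(arrays$at_fraction)))
}
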