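#' Paint one scaffold with ancestral-block segments
#'
#' Walks the reference genes placed on a scaffold (in scaffold order) and
#' segments them into maximal runs of one block label, tolerating up to
#' `max_interleave` consecutive foreign-label genes inside a run (absorbed
#' and counted, not made members). Runs with fewer than `min_run` member
#' genes are discarded. Segment orientation is the sign of Kendall's tau
#' between scaffold order and ancestral index over the member genes, with
#' `"?"` when `|tau| < 0.5` (or a single member).
#'
#' @param placements data frame of one scaffold's gene placements
#'   (`gene_id`, `start`, `end`, optionally `scaffold`), 0-based half-open.
#' @param block_table data frame `gene_id`, `block`, `anc_index`.
#' @param min_run minimum member genes per reported segment.
#' @param max_interleave maximum run of foreign genes absorbed into a
#'   segment.
#' @return data frame of segments (`scaffold`, `start`, `end`, `block`,
#'   `n_genes`, `orientation`, `mean_index`) ordered along the scaffold,
#'   with attribute `counts` (named vector: `placed`, `skipped` genes
#'   missing from the block table, `absorbed`, `discarded`).
#' @export
paint_scaffold <- function(placements, block_table, min_run = 3L,
                           max_interleave = 2L) {
  scf <- if (!is.null(placements$scaffold) && nrow(placements))
    placements$scaffold[1] else "scaffold"
  empty <- data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), block = character(0),
                      n_genes = integer(0), orientation = character(0),
                      mean_index = numeric(0))
  placed <- nrow(placements)
  pl <- placements[order(placements$start), , drop = FALSE]
  idx <- match(pl$gene_id, block_table$gene_id)
  skipped <- sum(is.na(idx))
  pl <- pl[!is.na(idx), , drop = FALSE]
  bt <- block_table[idx[!is.na(idx)], , drop = FALSE]
  counts <- c(placed = placed, skipped = skipped, absorbed = 0L,
              discarded = 0L)
  if (nrow(pl) == 0L) {
    attr(empty, "counts") <- counts
    return(empty)
  }

  # runs of identical labels, then absorb short foreign runs flanked by the
  # same label on both sides (left-to-right, repeated until stable)
  r <- rle(bt$block)
  ends <- cumsum(r$lengths)
  runs <- Map(function(s, e, lab) list(label = lab, members = s:e,
                                       absorbed = integer(0)),
              ends - r$lengths + 1L, ends, r$values)
  repeat {
    merged <- FALSE
    i <- 2L
    while (i <= length(runs) - 1L) {
      if (runs[[i - 1L]]$label == runs[[i + 1L]]$label &&
          runs[[i]]$label != runs[[i - 1L]]$label &&
          length(runs[[i]]$members) <= max_interleave) {
        runs[[i - 1L]] <- list(
          label = runs[[i - 1L]]$label,
          members = c(runs[[i - 1L]]$members, runs[[i + 1L]]$members),
          absorbed = c(runs[[i - 1L]]$absorbed, runs[[i]]$members,
                       runs[[i]]$absorbed, runs[[i + 1L]]$absorbed))
        runs <- runs[-c(i, i + 1L)]
        merged <- TRUE
      } else i <- i + 1L
    }
    if (!merged) break
  }

  segs <- list()
  for (run in runs) {
    n <- length(run$members)
    if (n < min_run) {
      counts["discarded"] <- counts["discarded"] + n
      counts["absorbed"] <- counts["absorbed"] + length(run$absorbed)
      next
    }
    counts["absorbed"] <- counts["absorbed"] + length(run$absorbed)
    m <- run$members
    anc <- bt$anc_index[m]
    orientation <- "?"
    if (n >= 2L) {
      tau <- suppressWarnings(
        stats::cor(seq_len(n), anc, method = "kendall"))
      if (!is.na(tau) && abs(tau) >= 0.5)
        orientation <- if (tau > 0) "+" else "-"
    }
    segs[[length(segs) + 1L]] <- data.frame(
      scaffold = scf, start = min(pl$start[m]), end = max(pl$end[m]),
      block = run$label, n_genes = n, orientation = orientation,
      mean_index = mean(anc), stringsAsFactors = FALSE)
  }
  out <- if (length(segs)) do.call(rbind, segs) else empty
  rownames(out) <- NULL
  attr(out, "counts") <- counts
  out
}

#' Paint every scaffold of a placement track
#'
#' @param placements data frame of gene placements for many scaffolds.
#' @inheritParams paint_scaffold
#' @return data frame of all segments, ordered by scaffold then start.
#' @export
paint_scaffolds <- function(placements, block_table, min_run = 3L,
                            max_interleave = 2L) {
  parts <- lapply(split(placements, placements$scaffold), paint_scaffold,
                  block_table = block_table, min_run = min_run,
                  max_interleave = max_interleave)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Inventory of painted blocks across scaffolds
#'
#' Lists every block's segments; a block whose segments lie on more than
#' one scaffold (or, when a scaffold-to-chromosome map is given, more than
#' one chromosome) is flagged as split.
#'
#' @param segments data frame of segments from [paint_scaffolds()].
#' @param chromosome_of optional named vector mapping scaffold to
#'   chromosome; split status is then judged at chromosome level.
#' @return data frame with one row per block: `block`, `n_segments`,
#'   `scaffolds` (comma-joined), `split`.
#' @export
block_inventory <- function(segments, chromosome_of = NULL) {
  if (nrow(segments) == 0L)
    return(data.frame(block = character(0), n_segments = integer(0),
                      scaffolds = character(0), split = logical(0)))
  rows <- lapply(split(segments, segments$block), function(sg) {
    unit <- if (is.null(chromosome_of)) unique(sg$scaffold)
      else unique(chromosome_of[sg$scaffold])
    data.frame(block = sg$block[1], n_segments = nrow(sg),
               scaffolds = paste(sort(unique(sg$scaffold)), collapse = ","),
               split = length(unit) > 1L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$block), , drop = FALSE]
  rownames(out) <- NULL
  out
}
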