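flip_sign <- function(x) ifelse(x == "+", "-", ifelse(x == "-", "+", x))

# all (chromosome, position, reversed) matches of a label run
match_label_run <- function(lab, karyotype) {
  hits <- list()
  for (ci in seq_along(karyotype)) {
    kb <- sub("^[+-]", "", karyotype[[ci]]$blocks)
    for (rev_match in c(FALSE, TRUE)) {
      v <- if (rev_match) rev(lab) else lab
      k <- length(v)
      if (k > length(kb)) next
      for (i in seq_len(length(kb) - k + 1L)) {
        if (all(kb[i:(i + k - 1L)] == v))
          hits[[length(hits) + 1L]] <- list(chrom = ci, start = i,
                                            end = i + k - 1L,
                                            reversed = rev_match)
      }
    }
  }
  hits
}

#' Match painted scaffolds to a karyotype
#'
#' Arranges and orients scaffolds into chromosomes: scaffolds are processed
#' in descending painted-gene-count order; each scaffold's ordered block
#' labels are matched, forward or reversed, to the longest exact contiguous
#' run of one chromosome's block order. Orientation comes from the match
#' direction (multi-block scaffolds) or from agreement between segment
#' orientation and the karyotype block sign (single-block scaffolds);
#' satellite-terminal evidence overrides both — a satellite-bearing
#' terminus must face the centromere — with overridden sign evidence logged
#' as an orientation conflict. Scaffolds are never split; those matching no
#' chromosome, or colliding with an already-claimed block interval, go to
#' the unplaced bin.
#'
#' @param karyotype karyotype definition (see [read_karyotype_json()]).
#' @param segments painted segments from [paint_scaffolds()].
#' @param satellites optional data frame of satellite arrays (`scaffold`,
#'   `start`, `end`).
#' @param scaffold_lengths named vector of scaffold lengths (needed for
#'   terminal classification of satellite evidence).
#' @param margin terminal margin passed to [terminal_classification()].
#' @return object of class `"placement_plan"`: list with `chromosomes`
#'   (named list of ordered placement data frames), `unplaced` (character),
#'   `conflicts` (data frame `kind`, `entities`, `description`) and the
#'   `karyotype`.
#' @export
match_scaffolds <- function(karyotype, segments, satellites = NULL,
                            scaffold_lengths = NULL, margin = 0.1) {
  ksigns <- lapply(karyotype, function(ch) substr(ch$blocks, 1L, 1L))
  conflicts <- list()
  note <- function(kind, entities, description)
    conflicts[[length(conflicts) + 1L]] <<- data.frame(
      kind = kind, entities = entities, description = description,
      stringsAsFactors = FALSE)

  by_scf <- split(segments, segments$scaffold)
  gene_totals <- vapply(by_scf, function(sg) sum(sg$n_genes), numeric(1))
  order_scf <- names(by_scf)[order(-gene_totals, names(by_scf))]

  placed <- lapply(karyotype, function(ch)
    data.frame(scaffold = character(0), orientation = character(0),
               start_pos = integer(0), end_pos = integer(0),
               blocks = character(0), n_genes = integer(0),
               anchor = numeric(0), stringsAsFactors = FALSE))
  names(placed) <- vapply(karyotype, `[[`, character(1), "name")
  unplaced <- character(0)

  for (scf in order_scf) {
    sg <- by_scf[[scf]]
    sg <- sg[order(sg$start), , drop = FALSE]
    lab <- sg$block
    # longest matching sub-run: shrink from full length, preferring longer
    # runs, dropping from the scaffold's ends symmetrically
    hit <- NULL; used <- NULL
    for (len in seq(length(lab), 1L)) {
      for (off in seq_len(length(lab) - len + 1L)) {
        sub <- seq(off, off + len - 1L)
        hits <- match_label_run(lab[sub], karyotype)
        if (length(hits)) { hit <- hits[[1]]; used <- sub; break }
      }
      if (!is.null(hit)) break
    }
    if (is.null(hit)) {
      unplaced <- c(unplaced, scf)
      note("unplaced_scaffold", scf, "no block run matches any chromosome")
      next
    }
    ci <- hit$chrom
    kname <- karyotype[[ci]]$name
    msg <- sg[used, , drop = FALSE]

    # orientation from match direction, else from sign agreement
    if (nrow(msg) >= 2L) {
      orientation <- if (hit$reversed) "-" else "+"
    } else {
      sig <- ksigns[[ci]][hit$start]
      so <- msg$orientation[1]
      orientation <- if (so == "?") "+" else if (so == sig) "+" else "-"
    }

    # satellite-terminal override
    if (!is.null(satellites) && !is.null(scaffold_lengths) &&
        scf %in% satellites$scaffold) {
      sat <- satellites[satellites$scaffold == scf, , drop = FALSE][1, ]
      term <- terminal_classification(sat$start, sat$end,
                                      scaffold_lengths[[scf]], margin)
      cen <- karyotype[[ci]]$centromere_after
      side <- if (hit$end <= cen) "left" else if (hit$start > cen) "right"
        else NA_character_
      if (term != "internal" && !is.na(side)) {
        required <- if (side == "left") {
          if (term == "right_terminal") "+" else "-"
        } else {
          if (term == "left_terminal") "+" else "-"
        }
        if (required != orientation) {
          note("orientation_conflict", scf,
               sprintf("satellite terminus evidence (%s, %s of centromere) overrode sign-based orientation %s",
                       term, side, orientation))
          orientation <- required
        }
      }
    }

    # sign-agreement check for the chosen orientation
    kpos <- seq(hit$start, hit$end)
    omsg <- if (orientation == "-") msg[rev(seq_len(nrow(msg))), , drop = FALSE]
      else msg
    oriented_signs <- if (orientation == "-") flip_sign(omsg$orientation)
      else omsg$orientation
    disagree <- which(oriented_signs != "?" &
                        oriented_signs != ksigns[[ci]][kpos])
    for (d in disagree)
      note("orientation_conflict",
           paste(scf, omsg$block[d], sep = ":"),
           sprintf("segment sign %s disagrees with karyotype sign %s for block %s",
                   oriented_signs[d], ksigns[[ci]][kpos[d]], omsg$block[d]))

    # claim check: overlap of >=2 positions, or one position interior to
    # either range, means two scaffolds claim the same unique position
    clash <- FALSE
    for (r in seq_len(nrow(placed[[kname]]))) {
      pr <- placed[[kname]][r, ]
      ov <- intersect(kpos, seq(pr$start_pos, pr$end_pos))
      if (length(ov) >= 2L ||
          (length(ov) == 1L &&
           ((ov > hit$start && ov < hit$end) ||
            (ov > pr$start_pos && ov < pr$end_pos)))) {
        clash <- TRUE
        note("order_conflict", paste(scf, pr$scaffold, sep = ","),
             sprintf("scaffolds %s and %s claim the same block position(s) %s on %s",
                     scf, pr$scaffold,
                     paste(ov, collapse = ","), kname))
        break
      }
    }
    if (clash) { unplaced <- c(unplaced, scf); next }

    # anchor: oriented first segment's mean ancestral index, signed so that
    # ascending anchor follows the karyotype's reading direction
    first_seg <- omsg[1L, ]
    sig1 <- ksigns[[ci]][hit$start]
    anchor <- if (sig1 == "-") -first_seg$mean_index else first_seg$mean_index
    placed[[kname]] <- rbind(placed[[kname]], data.frame(
      scaffold = scf, orientation = orientation,
      start_pos = hit$start, end_pos = hit$end,
      blocks = paste(omsg$block, collapse = ","),
      n_genes = sum(msg$n_genes), anchor = anchor,
      stringsAsFactors = FALSE))
  }

  placed <- lapply(placed, function(df) {
    df <- df[order(df$start_pos, df$anchor), , drop = FALSE]
    rownames(df) <- NULL
    df
  })
  conf <- if (length(conflicts)) do.call(rbind, conflicts) else
    data.frame(kind = character(0), entities = character(0),
               description = character(0))
  structure(list(chromosomes = placed, unplaced = unplaced,
                 conflicts = conf, karyotype = karyotype),
            class = "placement_plan")
}

#' @export
print.placement_plan <- function(x, ...) {
  cat("Placement plan:", length(x$chromosomes), "chromosomes,",
      sum(vapply(x$chromosomes, nrow, integer(1))), "scaffolds placed,",
      length(x$unplaced), "unplaced,",
      nrow(x$conflicts), "conflicts\n")
  invisible(x)
}

#' Build pseudomolecule sequences and AGP from a placement plan
#'
#' Joins each chromosome's scaffolds in plan order (reverse-complemented
#' when oriented `-`) with runs of N of length `inter_scaffold_gap`, and
#' emits AGP v2.0 rows (1-based inclusive; component type `W` for
#' scaffolds, `U` for gaps of unknown size with `scaffold`/`no`/`na`
#' annotations).
#'
#' @param plan a `placement_plan` from [match_scaffolds()].
#' @param scaffolds named character vector of scaffold sequences.
#' @param inter_scaffold_gap gap length between consecutive scaffolds, bp.
#' @return list with `sequences` (named character vector of chromosome
#'   sequences) and `agp` (data frame of AGP rows).
#' @export
build_pseudomolecules <- function(plan, scaffolds, inter_scaffold_gap = 100L) {
  seqs <- character(0)
  agp <- list()
  for (kname in names(plan$chromosomes)) {
    df <- plan$chromosomes[[kname]]
    if (nrow(df) == 0L) next
    missing <- setdiff(df$scaffold, names(scaffolds))
    if (length(missing))
      stop("scaffolds in plan but absent from FASTA: ",
           paste(missing, collapse = ", "))
    pos <- 0L; part <- 0L
    parts <- character(0)
    for (r in seq_len(nrow(df))) {
      if (r > 1L) {
        part <- part + 1L
        agp[[length(agp) + 1L]] <- data.frame(
          object = kname, object_beg = pos + 1L,
          object_end = pos + inter_scaffold_gap, part_number = part,
          component_type = "U", component_id = inter_scaffold_gap,
          component_beg = "scaffold", component_end = "no",
          orientation = "na", stringsAsFactors = FALSE)
        parts <- c(parts, strrep("N", inter_scaffold_gap))
        pos <- pos + inter_scaffold_gap
      }
      s <- scaffolds[[df$scaffold[r]]]
      if (df$orientation[r] == "-") s <- revcomp(s)
      part <- part + 1L
      agp[[length(agp) + 1L]] <- data.frame(
        object = kname, object_beg = pos + 1L,
        object_end = pos + nchar(s), part_number = part,
        component_type = "W", component_id = df$scaffold[r],
        component_beg = "1", component_end = as.character(nchar(s)),
        orientation = df$orientation[r], stringsAsFactors = FALSE)
      parts <- c(parts, s)
      pos <- pos + nchar(s)
    }
    seqs[[kname]] <- paste(parts, collapse = "")
  }
  list(sequences = seqs, agp = do.call(rbind, agp))
}

#' Discrepancy report for an assembled karyotype
#'
#' Collects every conflict between the karyotype template and the
#' assembled placement: karyotype blocks with no placed segment
#' (`missing_block`), blocks whose placements land on more than one
#' chromosome (`split_block`), the order and orientation conflicts logged
#' during matching, and the unplaced scaffold bin. Scaffolds are never
#' broken to resolve a conflict; discrepancies are reported for review.
#'
#' @param plan a `placement_plan`.
#' @return data frame with `kind`, `entities`, `description`.
#' @export
discrepancy_report <- function(plan) {
  rows <- list()
  add <- function(kind, entities, description)
    rows[[length(rows) + 1L]] <<- data.frame(
      kind = kind, entities = entities, description = description,
      stringsAsFactors = FALSE)

  block_chrom <- list()
  for (kname in names(plan$chromosomes)) {
    df <- plan$chromosomes[[kname]]
    for (bl in unlist(strsplit(df$blocks, ",")))
      block_chrom[[bl]] <- union(block_chrom[[bl]], kname)
  }
  all_blocks <- unique(unlist(lapply(plan$karyotype, function(ch)
    sub("^[+-]", "", ch$blocks))))
  for (b in sort(setdiff(all_blocks, names(block_chrom))))
    add("missing_block", b, sprintf("karyotype block %s has no placed segment", b))
  for (b in sort(names(block_chrom)))
    if (length(block_chrom[[b]]) > 1L)
      add("split_block", b,
          sprintf("block %s placed on chromosomes %s", b,
                  paste(sort(block_chrom[[b]]), collapse = ",")))
  if (nrow(plan$conflicts))
    for (r in seq_len(nrow(plan$conflicts)))
      add(plan$conflicts$kind[r], plan$conflicts$entities[r],
          plan$conflicts$description[r])
  for (s in plan$unplaced)
    if (!s %in% plan$conflicts$entities[plan$conflicts$kind == "unplaced_scaffold"])
      add("unplaced_scaffold", s, "scaffold left unplaced after matching")
  if (length(rows) == 0L)
    return(data.frame(kind = character(0), entities = character(0),
                      description = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fixed 24-colour palette keyed by block letter
#'
#' @param n number of colours (block letters A..).
#' @return named character vector of hex colours.
#' @export
block_palette <- function(n = 24L) {
  cols <- c("#e6194b", "#3cb44b", "#ffe119", "#4363d8", "#f58231",
            "#911eb4", "#46f0f0", "#f032e6", "#bcf60c", "#fabebe",
            "#008080", "#e6beff", "#9a6324", "#fffac8", "#800000",
            "#aaffc3", "#808000", "#ffd8b1", "#000075", "#808080",
            "#5a2a6e", "#2f4f4f", "#d2691e", "#1e90ff")
  stats::setNames(cols[seq_len(n)], LETTERS[seq_len(n)])
}

#' Render a digital karyotype as an SVG ideogram document
#'
#' One ideogram per chromosome: the placed scaffolds' blocks drawn in plan
#' order as stacked rectangles coloured by the fixed block palette, letter
#' labels inside, and the centromere marked by a filled circle at its
#' between-block position. Output is a deterministic SVG string.
#'
#' @param plan a `placement_plan`.
#' @param path optional file to write the SVG to.
#' @return the SVG document as a single character string (invisibly when
#'   `path` is given).
#' @export
render_digital_karyotype <- function(plan, path = NULL) {
  pal <- block_palette()
  bar_w <- 40; block_h <- 22; gap_x <- 70; top <- 40
  nch <- length(plan$chromosomes)
  max_blocks <- max(c(1L, vapply(plan$karyotype, function(ch)
    length(ch$blocks), integer(1))))
  width <- 40 + nch * gap_x
  height <- top + max_blocks * block_h + 40
  out <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
                   width, height))
  for (ci in seq_along(plan$karyotype)) {
    kname <- plan$karyotype[[ci]]$name
    x <- 20 + (ci - 1) * gap_x
    out <- c(out, sprintf('<text x="%.1f" y="%.1f" font-size="13" text-anchor="middle">%s</text>',
                          x + bar_w / 2, top - 12, kname))
    df <- plan$chromosomes[[kname]]
    y <- top
    drawn <- 0L
    if (!is.null(df) && nrow(df)) {
      for (r in seq_len(nrow(df))) {
        for (bl in strsplit(df$blocks[r], ",")[[1]]) {
          out <- c(out, sprintf(
            '<rect x="%.1f" y="%.1f" width="%.1f" height="%.1f" fill="%s" stroke="black" stroke-width="0.5"/>',
            x, y, bar_w, block_h, pal[[bl]]),
            sprintf('<text x="%.1f" y="%.1f" font-size="11" text-anchor="middle">%s</text>',
                    x + bar_w / 2, y + block_h / 2 + 4, bl))
          y <- y + block_h
          drawn <- drawn + 1L
        }
      }
    }
    cen <- plan$karyotype[[ci]]$centromere_after
    cy <- top + min(cen, drawn) * block_h
    out <- c(out, sprintf(
      '<circle cx="%.1f" cy="%.1f" r="5" fill="black"/>',
      x + bar_w / 2, cy))
  }
  out <- c(out, "</svg>")
  svg <- paste(out, collapse = "\n")
  if (!is.null(path)) {
    writeLines(svg, path)
    return(invisible(svg))
  }
  svg
}
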