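#' Read a FASTA file into a named character vector
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()]; sequences are returned
#' as plain uppercase character strings named by the first word of each
#' header, which is the representation the rest of the package works on.
#'
#' @param path path to a (possibly multi-record) FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write a named character vector of sequences to FASTA
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  stopifnot(!is.null(names(seqs)), !anyNA(seqs))
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Reverse-complement a DNA string
#'
#' @param x character vector of DNA strings (A, C, G, T, N).
#' @return reverse complement of each element.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read / write a karyotype definition as JSON
#'
#' The on-disk format is
#' `{"chromosomes": [{"name": "Chr1", "blocks": ["+A","-B"], "centromere_after": 2}, ...]}`,
#' where `centromere_after = k` places the centromere between the k-th and
#' (k+1)-th block of that chromosome.
#'
#' @param path file path.
#' @return `read_karyotype_json`: a karyotype, i.e. an unnamed list with one
#'   element per chromosome, each a list with `name`, `blocks` (signed labels)
#'   and `centromere_after`.
#' @export
read_karyotype_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(obj$chromosomes, function(ch) {
    list(name = ch$name,
         blocks = vapply(ch$blocks, identity, character(1)),
         centromere_after = as.integer(ch$centromere_after))
  })
}

#' @rdname read_karyotype_json
#' @param karyotype a karyotype list as returned by [simulate_karyotype()].
#' @export
write_karyotype_json <- function(karyotype, path) {
  obj <- list(chromosomes = lapply(karyotype, function(ch) {
    list(name = ch$name, blocks = as.list(ch$blocks),
         centromere_after = ch$centromere_after)
  }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write / read AGP v2.0
#'
#' Components are written with 1-based inclusive coordinates, component type
#' `W` for placed scaffolds and `U` for gaps of unknown size.
#'
#' @param agp data frame of AGP rows as produced by [build_pseudomolecules()].
#' @param path file path.
#' @export
write_agp <- function(agp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.0", con)
  utils::write.table(agp, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_agp
#' @return `read_agp`: data frame with the nine AGP columns.
#' @export
read_agp <- function(path) {
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = c("object", "object_beg", "object_end",
                                        "part_number", "component_type",
                                        "component_id", "component_beg",
                                        "component_end", "orientation"))
  df
}

#' Re-extract component sequences from an AGP and its object sequences
#'
#' Inverts [build_pseudomolecules()]: every `W` row is cut out of its object
#' sequence and reverse-complemented when placed on the minus strand, so a
#' faithful AGP round-trips the input scaffolds byte-identically.
#'
#' @param agp AGP data frame (see [read_agp()]).
#' @param objects named character vector of object (chromosome) sequences.
#' @return named character vector of component sequences.
#' @export
extract_agp_components <- function(agp, objects) {
  w <- agp[agp$component_type == "W", , drop = FALSE]
  out <- character(nrow(w))
  names(out) <- w$component_id
  for (i in seq_len(nrow(w))) {
    seq <- substr(objects[[w$object[i]]], w$object_beg[i], w$object_end[i])
    if (w$orientation[i] == "-") seq <- revcomp(seq)
    out[i] <- seq
  }
  out
}

#' Write all outputs of a simulated genome to a directory
#'
#' Emits the full external file set: scaffold FASTA, BED-like placements TSV
#' (0-based half-open), block table TSV, karyotype JSON and ground-truth JSON.
#'
#' @param sim result of [simulate_genome()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- function(df, file, col.names = TRUE) {
    utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = col.names)
  }
  write_fasta(sim$scaffolds, file.path(dir, "scaffolds.fa"))
  tsv(sim$placements, "placements.bed", col.names = FALSE)
  tsv(sim$block_table, "blocks.tsv")
  write_karyotype_json(sim$karyotype, file.path(dir, "karyotype.json"))
  jsonlite::write_json(sim$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

# internal: random DNA of length n with uniform base composition
random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
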