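#' Read FASTA sequences as circular_sequence objects
#'
#' Sequences are uppercased; characters outside A/C/G/T/N are rejected.
#' Circularity can be forced via the `circular` argument or declared per
#' record with a `circular=true` token in the description line.
#'
#' @param path path to a FASTA file.
#' @param circular force all records circular (default: honour the
#'   description token).
#' @return A named list of [circular_sequence] objects, in file order.
#' @export
read_fasta <- function(path, circular = NULL) {
  ss <- Biostrings::readBStringSet(path)
  if (!length(ss)) stopf("empty FASTA file: %s", path)
  out <- lapply(seq_along(ss), function(i) {
    desc <- names(ss)[i]
    id <- strsplit(desc, "\\s+")[[1L]][1L]
    circ <- if (!is.null(circular)) isTRUE(circular) else
      grepl("circular=true", desc, fixed = TRUE)
    circular_sequence(as.character(ss[[i]]), id = id, circular = circ)
  })
  names(out) <- vapply(out, function(s) s$id, character(1L))
  out
}

#' Write circular_sequence objects as FASTA
#'
#' Circular records carry a `circular=true` token in the description line
#' so that [read_fasta()] round-trips the flag.
#'
#' @param seqs a [circular_sequence] or list of them.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "circular_sequence")) seqs <- list(seqs)
  ss <- Biostrings::BStringSet(vapply(seqs, function(s) s$bases,
                                      character(1L)))
  names(ss) <- vapply(seqs, function(s) {
    if (s$circular) paste(s$id, "circular=true") else s$id
  }, character(1L))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' @param path path to the GMT file.
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t")
  stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                  vapply(parts, `[`, character(1L), 1L))
}
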