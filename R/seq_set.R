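#' Sequence record sets
#'
#' A `seq_set` is the package's light-weight carrier for DNA sequences: a
#' named character vector of sequences over `A/C/G/T/N` (lower case allowed,
#' meaning soft-masked) with an optional `descriptions` attribute. Names are
#' record ids and must be unique.
#'
#' @param sequences named character vector of DNA sequences.
#' @param descriptions optional character vector of descriptions, recycled to
#'   the number of records.
#' @return a `seq_set` object.
#' @examples
#' s <- seq_set(c(a = "ACGT", b = "GGGTTT"))
#' seq_lengths(s)
#' @export
seq_set <- function(sequences, descriptions = NULL) {
  if (length(sequences) == 0) {
    out <- character(0)
    attr(out, "descriptions") <- character(0)
    class(out) <- "seq_set"
    return(out)
  }
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("seq_set: all records must be named", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("seq_set: duplicate record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(sequences))) {
    stop("seq_set: empty sequence for record(s): ",
         paste(ids[!nzchar(sequences)], collapse = ", "), call. = FALSE)
  }
  bad <- grepl("[^ACGTNacgtn]", sequences)
  if (any(bad)) {
    stop("seq_set: non-IUPAC character in record(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sequences))
  descriptions <- rep_len(as.character(descriptions), length(sequences))
  out <- as.character(sequences)
  names(out) <- ids
  attr(out, "descriptions") <- descriptions
  class(out) <- "seq_set"
  out
}

#' @export
print.seq_set <- function(x, ...) {
  cat("seq_set with", length(x), "record(s)\n")
  n <- min(length(x), 6L)
  for (i in seq_len(n)) {
    s <- unclass(x)[[i]]
    cat(sprintf("  %s (%d bp) %s\n", names(x)[i], nchar(s),
                if (nchar(s) > 40) paste0(substr(s, 1, 40), "...") else s))
  }
  if (length(x) > n) cat("  ...\n")
  invisible(x)
}

#' @export
`[.seq_set` <- function(x, i) {
  d <- attr(x, "descriptions")
  y <- unclass(x)[i]
  seq_set(y, descriptions = if (is.null(d)) NULL else d[i])
}

#' Record lengths of a seq_set
#' @param x a `seq_set`.
#' @return named integer vector of sequence lengths.
#' @export
seq_lengths <- function(x) {
  setNames(nchar(unclass(x)), names(x))
}

#' Reverse complement
#'
#' Complement is case-preserving so soft-masking survives.
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTacgtNn", "TGCAtgcaNn",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Uppercase (unmask) sequences of a seq_set
#' @param x a `seq_set`.
#' @return a `seq_set` with all bases upper case.
#' @export
unmask <- function(x) {
  seq_set(setNames(toupper(unclass(x)), names(x)),
          descriptions = attr(x, "descriptions"))
}

subseq_chr <- function(s, start, end) substr(s, start, end)

#' Extract a CDS from a genome sequence
#'
#' Concatenates exon intervals (1-based inclusive) in genomic order and
#' reverse-complements the result for minus-strand genes.
#'
#' @param seqs a `seq_set` (or named character vector) of genome sequences.
#' @param chrom sequence id.
#' @param exon_starts,exon_ends integer vectors of exon coordinates.
#' @param strand `"+"` or `"-"`.
#' @return a single CDS string (upper case).
#' @export
extract_cds <- function(seqs, chrom, exon_starts, exon_ends, strand = "+") {
  s <- unclass(seqs)[[chrom]]
  if (is.null(s)) stop("extract_cds: unknown sequence id: ", chrom, call. = FALSE)
  o <- order(exon_starts)
  parts <- mapply(subseq_chr, MoreArgs = list(s = s),
                  start = exon_starts[o], end = exon_ends[o])
  cds <- toupper(paste(parts, collapse = ""))
  if (identical(strand, "-")) cds <- revcomp(cds)
  cds
}

random_dna <- function(n, gc = 0.44) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
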