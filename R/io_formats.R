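#' Read a FASTA file into a seq_set
#'
#' Thin validating wrapper over [Biostrings::readBStringSet()]. Sequences are
#' uppercased on read (FASTA input is treated as unmasked primary data); ids
#' must be unique; only `A/C/G/T/N` are accepted (`U` is rejected: this is a
#' DNA pipeline).
#'
#' @param path path to a FASTA file.
#' @param keep_case keep soft-masking case instead of uppercasing.
#' @return a [seq_set].
#' @export
read_fasta <- function(path, keep_case = FALSE) {
  if (!file.exists(path)) stop("read_fasta: no such file: ", path, call. = FALSE)
  bs <- Biostrings::readBStringSet(path, format = "fasta")
  seqs <- as.character(bs)
  full <- names(seqs)
  ids <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  if (anyDuplicated(ids)) {
    stop("read_fasta: duplicate id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (!keep_case) seqs <- toupper(seqs)
  names(seqs) <- ids
  seq_set(seqs, descriptions = desc)
}

#' Write a seq_set to FASTA
#'
#' @param x a [seq_set].
#' @param path output path.
#' @param width line wrap width.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(x, path, width = 70L) {
  stopifnot(inherits(x, "seq_set"))
  desc <- attr(x, "descriptions")
  hdr <- ifelse(nzchar(desc), paste(names(x), desc), names(x))
  bs <- Biostrings::BStringSet(setNames(unclass(x), hdr))
  Biostrings::writeXStringSet(bs, filepath = path, width = width)
  invisible(path)
}

#' Construct / validate a feature table
#'
#' The in-memory form of GFF3-style annotations: a data.frame with columns
#' `seqid, source, type, start, end, strand` plus any number of attribute
#' columns (e.g. `ID`, `Parent`, `family`). Coordinates are 1-based inclusive.
#'
#' @param df a data.frame with at least the six core columns.
#' @param seqs optional [seq_set] to validate `seqid`/coordinates against.
#' @return the validated data.frame with class `feature_table`.
#' @export
feature_table <- function(df, seqs = NULL) {
  need <- c("seqid", "source", "type", "start", "end", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("feature_table: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$start > df$end)) {
    stop("feature_table: start > end for ", sum(df$start > df$end),
         " feature(s)", call. = FALSE)
  }
  if (!all(df$strand %in% c("+", "-", "."))) {
    stop("feature_table: strand must be one of '+', '-', '.'", call. = FALSE)
  }
  if (!is.null(seqs)) {
    lens <- seq_lengths(seqs)
    unknown <- setdiff(unique(df$seqid), names(lens))
    if (length(unknown)) {
      stop("feature_table: unknown seqid(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    over <- df$end > lens[df$seqid]
    if (any(over)) stop("feature_table: feature(s) beyond sequence end",
                        call. = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Read GFF3 annotations
#'
#' Uses [rtracklayer::import.gff3()] and flattens the result to a
#' [feature_table] data.frame. Attribute values (including percent-escaped
#' characters) are decoded by rtracklayer.
#'
#' @param path path to a GFF3 file.
#' @return a [feature_table].
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("read_gff3: no such file: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    source = as.character(gr$source),
    type = as.character(gr$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))),
    stringsAsFactors = FALSE)
  mc <- as.data.frame(S4Vectors::mcols(gr))
  extra <- setdiff(names(mc), c("source", "type", "score", "phase"))
  for (nm in extra) {
    v <- mc[[nm]]
    if (methods::is(v, "List") || is.list(v)) {
      v <- vapply(v, function(e) if (length(e)) paste(e, collapse = ",") else NA_character_,
                  character(1))
    }
    df[[nm]] <- as.character(v)
  }
  feature_table(df)
}

#' Write GFF3 annotations
#'
#' @param features a [feature_table].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gff3 <- function(features, path) {
  features <- feature_table(features)
  gr <- GenomicRanges::GRanges(
    seqnames = features$seqid,
    ranges = IRanges::IRanges(features$start, features$end),
    strand = sub("^\\.$", "*", features$strand))
  gr$source <- features$source
  gr$type <- features$type
  if (!"phase" %in% names(features) && any(features$type == "CDS")) {
    gr$phase <- ifelse(features$type == "CDS", 0L, NA_integer_)
  }
  extra <- setdiff(names(features),
                   c("seqid", "source", "type", "start", "end", "strand"))
  for (nm in extra) S4Vectors::mcols(gr)[[nm]] <- features[[nm]]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write a contig layout as AGP v2.1
#'
#' Serializes the ordered/oriented contigs of a clone layout (see
#' [order_contigs()]) as AGP v2.1: `W` rows for contigs and `N` rows for the
#' template-estimated gaps between them. A negative gap estimate (overlapping
#' projections) is emitted as a 1 bp `N` gap with an `overlap_suspected`
#' trailing comment field, so no information is silently dropped.
#'
#' @param layout a `contig_layout` from [order_contigs()] (gaps filled by
#'   [estimate_gaps()]; missing gaps are written as length-100 `U` gaps).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_layout_agp <- function(layout, path) {
  if (!inherits(layout, "contig_layout")) {
    stop("write_layout_agp: need a validated contig_layout", call. = FALSE)
  }
  pl <- layout$placed
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  if (nrow(pl) == 0) return(invisible(path))
  pos <- 1L
  part <- 1L
  for (i in seq_len(nrow(pl))) {
    len <- pl$length[i]
    row <- c(layout$clone_id, pos, pos + len - 1L, part, "W",
             pl$contig_id[i], 1L, len, pl$orientation[i])
    writeLines(paste(row, collapse = "\t"), con)
    pos <- pos + len
    part <- part + 1L
    if (i < nrow(pl)) {
      g <- pl$gap_after[i]
      comment <- NULL
      if (is.na(g)) {
        gtype <- "U"; glen <- 100L
      } else if (g < 0) {
        gtype <- "N"; glen <- 1L; comment <- "# overlap_suspected"
      } else {
        gtype <- "N"; glen <- max(1L, as.integer(g))
      }
      row <- c(layout$clone_id, pos, pos + glen - 1L, part, gtype,
               glen, "scaffold", "yes", "align_genus")
      if (!is.null(comment)) row <- c(row, comment)
      writeLines(paste(row, collapse = "\t"), con)
      pos <- pos + glen
      part <- part + 1L
    }
  }
  invisible(path)
}

#' Read an AGP v2.1 layout file
#'
#' Inverse of [write_layout_agp()] for files this package writes: returns a
#' list with the object id, the placed-contig table (contig id, length,
#' orientation, gap after, overlap flag) and the raw AGP rows.
#'
#' @param path path to an AGP file.
#' @return a list with elements `object_id`, `placed`, `rows`.
#' @export
read_layout_agp <- function(path) {
  if (!file.exists(path)) stop("read_layout_agp: no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  if (!length(lines)) {
    return(list(object_id = NA_character_,
                placed = data.frame(contig_id = character(0),
                                    length = integer(0),
                                    orientation = character(0),
                                    gap_after = integer(0),
                                    overlap_suspected = logical(0)),
                rows = NULL))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  object_id <- parts[[1]][1]
  contig_id <- character(0); len <- integer(0); ori <- character(0)
  gap_after <- integer(0); overlap <- logical(0)
  for (p in parts) {
    if (p[5] == "W") {
      contig_id <- c(contig_id, p[6])
      len <- c(len, as.integer(p[8]) - as.integer(p[7]) + 1L)
      ori <- c(ori, p[9])
      gap_after <- c(gap_after, NA_integer_)
      overlap <- c(overlap, FALSE)
    } else {
      k <- length(contig_id)
      if (k > 0) {
        gap_after[k] <- as.integer(p[6])
        overlap[k] <- length(p) >= 10 && grepl("overlap_suspected", p[10])
      }
    }
  }
  list(object_id = object_id,
       placed = data.frame(contig_id = contig_id, length = len,
                           orientation = ori, gap_after = gap_after,
                           overlap_suspected = overlap,
                           stringsAsFactors = FALSE),
       rows = parts)
}

#' Read / write TSV report tables
#'
#' Plain tab-separated tables with a header row; used for probe tables, truth
#' tables and the report tables. Percent columns are formatted to one decimal
#' by the reporting layer, not here.
#'
#' @param path file path.
#' @return `read_tsv_report`: a data.frame.
#' @export
read_tsv_report <- function(path) {
  if (!file.exists(path)) stop("read_tsv_report: no such file: ", path, call. = FALSE)
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' @param x a data.frame.
#' @rdname read_tsv_report
#' @export
write_tsv_report <- function(x, path) {
  if (any(vapply(x, function(col) is.numeric(col) && anyNA(col) &&
                 all(is.na(col)), logical(1)))) {
    # all-NA numeric columns round-trip as logical; write as empty strings
  }
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}
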