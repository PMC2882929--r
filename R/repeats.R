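#' Library-based repeat masking with family accounting
#'
#' Aligns every library consensus against the sequences with the anchor
#' aligner (default threshold 50 bits, permissive enough for diverged
#' copies), soft-masks hit intervals, resolves overlapping family claims by
#' the higher bit score, and tallies masked bp per family of the fixed
#' taxonomy plus perfect simple repeats ([detect_ssrs()]) and low-complexity
#' sequence (Shannon entropy below `entropy_threshold` bits/base over 64 bp
#' windows). Masking is idempotent: soft-masked bases are never re-seeded.
#'
#' @param seqs a [seq_set].
#' @param library a repeat [seq_set] whose names are family labels; labels
#'   outside the taxonomy are counted as `Unclassified`.
#' @param min_bit_repeat bit-score threshold for repeat hits.
#' @param entropy_threshold low-complexity entropy cutoff (bits/base).
#' @param params an [align_params] (its `min_bit` is replaced by
#'   `min_bit_repeat`).
#' @return list with `seqs` (soft-masked [seq_set]), `summary` (a
#'   `repeat_summary` data.frame: family, masked_bp, fraction), and
#'   `intervals` (per-hit masked intervals with families).
#' @export
mask_repeats <- function(seqs, library, min_bit_repeat = 50,
                         entropy_threshold = 1.5,
                         params = align_params()) {
  params$min_bit <- min_bit_repeat
  total_bp <- sum(seq_lengths(seqs))
  tax <- repeat_taxonomy()
  fam_bp <- setNames(numeric(length(tax)), tax)
  intervals <- list()
  masked <- unclass(seqs)
  if (length(library)) {
    hits <- seed_extend_align(library, seqs, params)
    if (nrow(hits)) {
      hits$family <- ifelse(hits$query_id %in% tax, hits$query_id,
                            "Unclassified")
      for (sid in unique(hits$template_id)) {
        h <- hits[hits$template_id == sid, , drop = FALSE]
        h <- h[order(-h$bit_score), , drop = FALSE]
        L <- nchar(masked[[sid]])
        owner <- integer(L) # 0 = unclaimed, else row index into h
        for (r in seq_len(nrow(h))) {
          sl <- h$template_start[r]:h$template_end[r]
          free <- sl[owner[sl] == 0L]
          owner[free] <- r
        }
        x <- strsplit(masked[[sid]], "", fixed = TRUE)[[1]]
        claimed <- which(owner > 0L)
        x[claimed] <- tolower(x[claimed])
        masked[[sid]] <- paste(x, collapse = "")
        for (r in seq_len(nrow(h))) {
          bp <- sum(owner == r)
          if (bp == 0) next
          fam_bp[h$family[r]] <- fam_bp[h$family[r]] + bp
          intervals[[length(intervals) + 1]] <- data.frame(
            seqid = sid, start = h$template_start[r],
            end = h$template_end[r], family = h$family[r], masked_bp = bp,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  mset <- seq_set(masked, descriptions = attr(seqs, "descriptions"))
  ssrs <- detect_ssrs(mset)
  simple_bp <- sum(ssrs$end - ssrs$start + 1)
  low_bp <- 0
  for (sid in names(masked)) {
    lc <- low_complexity_intervals(masked[[sid]], entropy_threshold)
    if (nrow(lc)) low_bp <- low_bp + sum(lc$end - lc$start + 1)
  }
  summary <- data.frame(
    family = c(tax, "Simple repeats", "Low complexity"),
    masked_bp = c(unname(fam_bp), simple_bp, low_bp),
    stringsAsFactors = FALSE)
  summary$fraction <- summary$masked_bp / total_bp
  tot <- data.frame(family = "Total", masked_bp = sum(summary$masked_bp),
                    fraction = sum(summary$masked_bp) / total_bp)
  summary <- rbind(summary, tot)
  class(summary) <- c("repeat_summary", "data.frame")
  list(seqs = mset, summary = summary,
       intervals = if (length(intervals)) do.call(rbind, intervals) else NULL)
}

# merged intervals of 64-bp windows with Shannon entropy below the threshold
low_complexity_intervals <- function(seq, threshold = 1.5, window = 64L,
                                     step = 32L) {
  n <- nchar(seq)
  if (n < window) return(data.frame(start = integer(0), end = integer(0)))
  starts <- seq(1L, n - window + 1L, by = step)
  x <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  low <- logical(length(starts))
  for (i in seq_along(starts)) {
    sl <- x[starts[i]:(starts[i] + window - 1L)]
    p <- table(sl[sl %in% c("A", "C", "G", "T")]) / sum(sl %in% c("A", "C", "G", "T"))
    H <- -sum(p * log2(p))
    low[i] <- is.finite(H) && H < threshold
  }
  if (!any(low)) return(data.frame(start = integer(0), end = integer(0)))
  s <- starts[low]; e <- s + window - 1L
  o <- order(s)
  s <- s[o]; e <- e[o]
  ms <- s[1]; me <- e[1]; out <- list()
  for (i in seq_along(s)[-1]) {
    if (s[i] <= me + 1L) me <- max(me, e[i]) else {
      out[[length(out) + 1]] <- c(ms, me); ms <- s[i]; me <- e[i]
    }
  }
  out[[length(out) + 1]] <- c(ms, me)
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2])
}

#' Detect perfect microsatellites (SSRs)
#'
#' Maximal perfect tandem runs of primitive 1-6 bp motifs, with per-motif-
#' length copy thresholds (mono >= 12, di >= 6, tri >= 4, tetra-hexa >= 3 by
#' default). Overlapping candidates are resolved to the longest run, then
#' the shortest motif. Motifs are canonicalized to the lexicographically
#' smallest rotation over both strands, so the locus set is strand-
#' symmetric. Flanking sequence of up to `flank_len` bp is attached
#' (truncated at sequence ends, with a flag).
#'
#' @param seqs a [seq_set].
#' @param min_copies copy thresholds for motif lengths 1-6.
#' @param flank_len flank length (bp).
#' @return data.frame `seq_id, start, end, motif, motif_len, copy_number,
#'   left_flank, right_flank, flank_truncated`.
#' @export
detect_ssrs <- function(seqs, min_copies = c(12, 6, 4, 3, 3, 3),
                        flank_len = 200L) {
  rows <- list()
  for (sid in names(seqs)) {
    s <- unclass(seqs)[[sid]]
    cand <- cpp_ssr_scan(s, as.numeric(min_copies))
    if (!nrow(cand)) next
    cand <- cand[order(-(cand$end - cand$start + 1), cand$motif_len,
                       cand$start), , drop = FALSE]
    keep <- logical(nrow(cand))
    taken_s <- integer(0); taken_e <- integer(0)
    for (i in seq_len(nrow(cand))) {
      if (!length(taken_s) ||
          all(cand$end[i] < taken_s | cand$start[i] > taken_e)) {
        keep[i] <- TRUE
        taken_s <- c(taken_s, cand$start[i]); taken_e <- c(taken_e, cand$end[i])
      }
    }
    cand <- cand[keep, , drop = FALSE]
    if (!nrow(cand)) next
    n <- nchar(s)
    ls <- pmax(1L, cand$start - flank_len)
    re <- pmin(n, cand$end + flank_len)
    rows[[length(rows) + 1]] <- data.frame(
      seq_id = sid, start = cand$start, end = cand$end,
      motif = vapply(cand$motif, canonical_motif, character(1)),
      motif_len = cand$motif_len, copy_number = cand$copy_number,
      left_flank = toupper(substring(s, ls, cand$start - 1)),
      right_flank = toupper(substring(s, cand$end + 1, re)),
      flank_truncated = (cand$start - flank_len < 1) | (cand$end + flank_len > n),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), motif = character(0),
                      motif_len = integer(0), copy_number = numeric(0),
                      left_flank = character(0), right_flank = character(0),
                      flank_truncated = logical(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$seq_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Soft-mask sequences from annotated repeat features
#'
#' Lower-cases the bases of annotated repeat intervals (feature types
#' `repeat_region` and `microsatellite` by default), e.g. to mask a template
#' genome from its own annotation before anchoring.
#'
#' @param seqs a [seq_set].
#' @param features a [feature_table].
#' @param types feature types to mask.
#' @return a soft-masked [seq_set].
#' @export
mask_from_features <- function(seqs, features,
                               types = c("repeat_region", "microsatellite")) {
  f <- features[features$type %in% types, , drop = FALSE]
  out <- unclass(seqs)
  for (sid in unique(f$seqid)) {
    if (is.null(out[[sid]])) next
    x <- strsplit(out[[sid]], "", fixed = TRUE)[[1]]
    fs <- f[f$seqid == sid, , drop = FALSE]
    for (r in seq_len(nrow(fs))) {
      sl <- fs$start[r]:fs$end[r]
      x[sl] <- tolower(x[sl])
    }
    out[[sid]] <- paste(x, collapse = "")
  }
  seq_set(out, descriptions = attr(seqs, "descriptions"))
}

#' Canonical motif of a tandem repeat
#'
#' Lexicographically smallest rotation over the motif and its reverse
#' complement, so a locus reports the same motif from either strand.
#'
#' @param motif a 1-6 bp motif.
#' @return the canonical motif string.
#' @export
canonical_motif <- function(motif) {
  motif <- toupper(motif)
  rots <- function(m) {
    n <- nchar(m)
    vapply(seq_len(n), function(i)
      paste0(substr(m, i, n), substr(m, 1, i - 1)), character(1))
  }
  min(c(rots(motif), rots(revcomp(motif))))
}
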