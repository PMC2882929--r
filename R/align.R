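#' Alignment parameters
#'
#' Scoring and seeding parameters for the seed-and-extend anchor aligner.
#' Bit scores follow Karlin-Altschul: `bit = (lambda * raw - ln K) / ln 2`;
#' the default `(lambda, K)` pair matches the +1/-2 match/mismatch scores.
#' Gap cost convention: a gap of length L costs `gap_open + L * gap_extend`.
#'
#' @param seed_k exact seed length.
#' @param match,mismatch,gap_open,gap_extend scores (match positive,
#'   mismatch negative; gap penalties given as positive costs).
#' @param x_drop extension margin control: the banded extension window pads
#'   `8 * x_drop` bases beyond the outermost seeds.
#' @param lambda,K Karlin-Altschul constants for the score system.
#' @param min_bit minimum bit score for a reported hit.
#' @param max_occ seeds occurring more often than this in the target are
#'   skipped (repeat protection).
#' @param max_seed_gap,max_diag_drift seed clustering: maximum query gap and
#'   diagonal drift between consecutive seeds of one cluster.
#' @param band_pad extra diagonals added around a cluster's seed diagonals.
#' @return an `align_params` list.
#' @export
align_params <- function(seed_k = 13L, match = 1, mismatch = -2,
                         gap_open = 5, gap_extend = 2, x_drop = 50,
                         lambda = 1.28, K = 0.46, min_bit = 200,
                         max_occ = 64L, max_seed_gap = 300L,
                         max_diag_drift = 60L, band_pad = 50L) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend > 0,
            min_bit >= 0, seed_k >= 4, seed_k <= 15)
  structure(list(seed_k = as.integer(seed_k), match = match,
                 mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, x_drop = x_drop, lambda = lambda,
                 K = K, min_bit = min_bit, max_occ = as.integer(max_occ),
                 max_seed_gap = as.integer(max_seed_gap),
                 max_diag_drift = as.integer(max_diag_drift),
                 band_pad = as.integer(band_pad)),
            class = "align_params")
}

#' Bit score of a raw alignment score
#' @param raw raw alignment score(s).
#' @param params an [align_params].
#' @return bit score(s).
#' @export
bit_score <- function(raw, params = align_params()) {
  (params$lambda * raw - log(params$K)) / log(2)
}

empty_hits <- function() {
  data.frame(query_id = character(0), query_start = integer(0),
             query_end = integer(0), template_id = character(0),
             template_start = integer(0), template_end = integer(0),
             strand = character(0), raw_score = numeric(0),
             bit_score = numeric(0), identity = numeric(0),
             stringsAsFactors = FALSE)
}

#' Seed-and-extend local alignment anchors
#'
#' Finds local alignments between every query and every target sequence on
#' both strands: exact `seed_k`-mer seeds (soft-masked regions excluded from
#' seeding, still available to extension), diagonal clustering, banded
#' affine-gap local extension, bit-score filtering, and removal of hits whose
#' query and template intervals are both covered by a stronger hit. Output is
#' deterministically ordered by template position then query position.
#'
#' @param query,template [seq_set] objects (or named character vectors).
#' @param params an [align_params].
#' @return a data.frame of hits: `query_id, query_start, query_end,
#'   template_id, template_start, template_end, strand, raw_score, bit_score,
#'   identity` (coordinates 1-based inclusive; query coordinates always on
#'   the forward query).
#' @export
seed_extend_align <- function(query, template, params = align_params()) {
  q <- unclass(query); t <- unclass(template)
  if (!length(q) || !length(t)) return(empty_hits())
  if (all(nchar(q) < params$seed_k)) {
    warning("seed_extend_align: all query sequences shorter than seed_k")
    return(empty_hits())
  }
  pad <- as.integer(max(50, 8 * params$x_drop))
  hits <- cpp_seed_extend(as.character(q), names(q), as.character(t), names(t),
                          params$seed_k, params$match, params$mismatch,
                          params$gap_open, params$gap_extend,
                          params$max_occ, params$max_seed_gap,
                          params$max_diag_drift, pad, params$band_pad, TRUE)
  if (!nrow(hits)) return(empty_hits())
  hits$bit_score <- bit_score(hits$raw_score, params)
  hits <- hits[hits$bit_score >= params$min_bit, , drop = FALSE]
  if (!nrow(hits)) return(empty_hits())
  hits <- dedupe_hits(hits)
  hits <- hits[order(hits$template_id, hits$template_start, hits$query_id,
                     hits$query_start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits[, c("query_id", "query_start", "query_end", "template_id",
           "template_start", "template_end", "strand", "raw_score",
           "bit_score", "identity")]
}

# drop hits whose query AND template intervals are >= 90% covered by a single
# stronger hit of the same (query, template, strand)
dedupe_hits <- function(hits, frac = 0.9) {
  o <- order(-hits$raw_score)
  hits <- hits[o, , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    if (i == 1) next
    for (j in seq_len(i - 1)) {
      if (!keep[j]) next
      if (hits$query_id[j] != hits$query_id[i] ||
          hits$template_id[j] != hits$template_id[i] ||
          hits$strand[j] != hits$strand[i]) next
      qov <- min(hits$query_end[i], hits$query_end[j]) -
        max(hits$query_start[i], hits$query_start[j]) + 1
      tov <- min(hits$template_end[i], hits$template_end[j]) -
        max(hits$template_start[i], hits$template_start[j]) + 1
      qlen <- hits$query_end[i] - hits$query_start[i] + 1
      tlen <- hits$template_end[i] - hits$template_start[i] + 1
      if (qov >= frac * qlen && tov >= frac * tlen) { keep[i] <- FALSE; break }
    }
  }
  hits[keep, , drop = FALSE]
}

#' Chain collinear anchors
#'
#' Maximum-bit-weight collinear chain per `(template_id, strand)` group by
#' longest-increasing-subsequence-style dynamic programming: within a group,
#' hits are sorted by template start and may be chained when template and
#' query coordinates both advance in the strand's direction with gaps of at
#' most `max_gap` on either genome (overlaps between adjacent chained hits
#' are allowed; duplications show up as such overlaps). Ties are broken
#' toward the leftmost template coordinate.
#'
#' @param hits a hit data.frame from [seed_extend_align()] for one query.
#' @param max_gap maximum collinear gap in bp.
#' @return a list with `chains` (list of integer row-index vectors into
#'   `hits`, one per group, ordered by decreasing weight), `weights`,
#'   `main` (row indices of the best chain), and `off_chain` (row indices in
#'   no position of the best chain).
#' @export
chain_anchors <- function(hits, max_gap = 20000) {
  if (!nrow(hits)) {
    return(list(chains = list(), weights = numeric(0),
                main = integer(0), off_chain = integer(0)))
  }
  grp <- paste(hits$template_id, hits$strand)
  chains <- list(); weights <- numeric(0)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    h <- hits[idx, , drop = FALSE]
    ord <- order(h$template_start, h$template_end)
    idx <- idx[ord]; h <- h[ord, , drop = FALSE]
    n <- nrow(h)
    minus <- h$strand[1] == "-"
    score <- h$bit_score
    best <- score
    prev <- rep(0L, n)
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        if (h$template_end[j] > h$template_end[i]) next
        tgap <- h$template_start[i] - h$template_end[j] - 1
        if (tgap > max_gap) next
        if (!minus) {
          if (h$query_start[j] >= h$query_start[i] ||
              h$query_end[j] > h$query_end[i]) next
          qgap <- h$query_start[i] - h$query_end[j] - 1
        } else {
          # minus strand: query runs backwards along the template
          if (h$query_start[j] <= h$query_start[i] ||
              h$query_end[j] < h$query_end[i]) next
          qgap <- h$query_start[j] - h$query_end[i] - 1
        }
        if (qgap > max_gap) next
        cand <- best[j] + score[i]
        if (cand > best[i]) { best[i] <- cand; prev[i] <- j }
      }
    }
    end <- which.max(best)
    chain <- integer(0)
    while (end != 0L) { chain <- c(end, chain); end <- prev[end] }
    chains[[length(chains) + 1]] <- idx[chain]
    weights <- c(weights, max(best))
  }
  o <- order(-weights,
             vapply(chains, function(ix) min(hits$template_start[ix]), numeric(1)))
  chains <- chains[o]; weights <- weights[o]
  main <- chains[[1]]
  list(chains = chains, weights = weights, main = main,
       off_chain = setdiff(seq_len(nrow(hits)), main))
}

#' Write anchor hits as BED6
#'
#' One record per hit; the BED score column is the bit score clipped to
#' 0-1000; full precision is preserved in the name field companion TSV
#' written alongside when `tsv = TRUE`.
#'
#' @param hits a hit data.frame.
#' @param path output BED path.
#' @param tsv also write `<path>.tsv` with full precision.
#' @return invisibly, `path`.
#' @export
write_hits_bed <- function(hits, path, tsv = TRUE) {
  bed <- data.frame(chrom = hits$template_id,
                    start = hits$template_start - 1L,
                    end = hits$template_end,
                    name = paste0(hits$query_id, ":", hits$query_start, "-",
                                  hits$query_end),
                    score = pmin(1000L, as.integer(round(hits$bit_score))),
                    strand = hits$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  if (tsv) write_tsv_report(hits, paste0(path, ".tsv"))
  invisible(path)
}
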