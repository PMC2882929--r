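#' Remove ambiguous (contained/duplicated) contigs
#'
#' Contig-vs-contig screening with the anchor aligner: a contig is dropped
#' when at least `min_containment` of its length is covered by
#' identity-weighted alignment to a single longer contig (sequence
#' duplication, overlap or embedding among redundant assemblies); the longer
#' contig is kept.
#'
#' @param contigs a [seq_set].
#' @param min_containment identity-weighted coverage fraction (default 0.9).
#' @param params an [align_params]; the default lowers `min_bit` to 100 so
#'   that moderate-sized contained fragments are seen.
#' @return a [seq_set] of unambiguous contigs (attribute `removed` lists the
#'   dropped ids and which contig contains them).
#' @export
dedupe_contigs <- function(contigs, min_containment = 0.9,
                           params = align_params(min_bit = 100)) {
  ids <- names(contigs)
  if (length(ids) < 2) return(contigs)
  lens <- seq_lengths(contigs)
  hits <- seed_extend_align(contigs, contigs, params)
  hits <- hits[hits$query_id != hits$template_id, , drop = FALSE]
  ord <- ids[order(-lens, ids)]
  removed <- character(0); container <- character(0)
  for (cid in rev(ord)) { # shortest first
    h <- hits[hits$query_id == cid &
                !(hits$template_id %in% removed), , drop = FALSE]
    if (!nrow(h)) next
    h <- h[lens[h$template_id] >= lens[cid] &
             h$template_id != cid, , drop = FALSE]
    if (!nrow(h)) next
    for (tid in unique(h$template_id)) {
      ht <- h[h$template_id == tid, , drop = FALSE]
      cov <- rep(0, lens[cid])
      for (r in seq_len(nrow(ht))) {
        sl <- ht$query_start[r]:ht$query_end[r]
        cov[sl] <- pmax(cov[sl], ht$identity[r])
      }
      if (sum(cov) / lens[cid] >= min_containment) {
        removed <- c(removed, cid); container <- c(container, tid)
        break
      }
    }
  }
  out <- contigs[setdiff(ids, removed)]
  attr(out, "removed") <- data.frame(contig_id = removed,
                                     contained_in = container,
                                     stringsAsFactors = FALSE)
  out
}

#' Order and orient contigs against the template
#'
#' Each contig's anchors are chained per template locus; the dominant chain
#' determines chromosome, strand and projected template interval. Contigs
#' whose best and second-best locus chain weights differ by less than
#' `ambiguity_ratio` are left unplaced (`multi_locus`), contigs without
#' anchors are `no_anchor`, and contigs whose projection is swallowed by a
#' stronger contig's projection are `conflict` (overlaps are otherwise
#' resolved by trimming the weaker projection). Placed contigs are sorted by
#' projected template start; minus-strand chains flip the contig
#' orientation.
#'
#' @param contigs a [seq_set] (deduplicated).
#' @param template a [seq_set] of template chromosomes (soft-masked regions
#'   are not seeded).
#' @param params an [align_params].
#' @param max_gap chaining gap (bp).
#' @param ambiguity_ratio best/second-best locus bit-weight ratio below
#'   which a contig is considered multi-locus.
#' @param clone_id object id used in AGP output.
#' @return a `contig_layout`: list with `clone_id`, `placed` (data.frame
#'   `contig_id, length, orientation, chrom, t_start, t_end, weight,
#'   gap_after, gap_flag`), `unplaced` (data.frame `contig_id, reason`), and
#'   `spans` (`spanned_query_bp`, `spanned_template_bp`).
#' @export
order_contigs <- function(contigs, template, params = align_params(),
                          max_gap = 20000, ambiguity_ratio = 2,
                          clone_id = "clone") {
  placed <- list(); unplaced <- list()
  lens <- seq_lengths(contigs)
  for (cid in names(contigs)) {
    hits <- seed_extend_align(contigs[cid], template, params)
    if (!nrow(hits)) {
      unplaced[[length(unplaced) + 1]] <- data.frame(contig_id = cid,
                                                     reason = "no_anchor")
      next
    }
    ch <- chain_anchors(hits, max_gap)
    w1 <- ch$weights[1]
    main <- hits[ch$main, , drop = FALSE]
    span1 <- c(main$template_id[1], min(main$template_start),
               max(main$template_end))
    # second-best chain at a different locus (other chromosome or >50 kb away)
    w2 <- 0
    if (length(ch$chains) > 1) {
      for (j in seq(2, length(ch$chains))) {
        hj <- hits[ch$chains[[j]], , drop = FALSE]
        other <- hj$template_id[1] != span1[1] ||
          min(hj$template_start) > as.numeric(span1[3]) + 50000 ||
          max(hj$template_end) < as.numeric(span1[2]) - 50000
        if (other) { w2 <- ch$weights[j]; break }
      }
    }
    if (w2 > 0 && w1 / w2 < ambiguity_ratio) {
      unplaced[[length(unplaced) + 1]] <- data.frame(contig_id = cid,
                                                     reason = "multi_locus")
      next
    }
    qlo <- min(main$query_start); qhi <- max(main$query_end)
    placed[[length(placed) + 1]] <- data.frame(
      contig_id = cid, length = unname(lens[cid]),
      orientation = main$strand[1], chrom = main$template_id[1],
      t_start = min(main$template_start), t_end = max(main$template_end),
      weight = w1, q_aligned = qhi - qlo + 1L, stringsAsFactors = FALSE)
  }
  pl <- if (length(placed)) do.call(rbind, placed) else
    data.frame(contig_id = character(0), length = integer(0),
               orientation = character(0), chrom = character(0),
               t_start = integer(0), t_end = integer(0), weight = numeric(0),
               q_aligned = integer(0), stringsAsFactors = FALSE)
  up <- if (length(unplaced)) do.call(rbind, unplaced) else
    data.frame(contig_id = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  if (nrow(pl)) {
    pl <- pl[order(pl$chrom, pl$t_start, pl$t_end), , drop = FALSE]
    # resolve overlapping projections: trim the weaker projection
    drop <- logical(nrow(pl))
    for (i in seq_len(nrow(pl))[-1]) {
      j <- i - 1
      while (j >= 1 && drop[j]) j <- j - 1
      if (j < 1 || pl$chrom[i] != pl$chrom[j]) next
      if (pl$t_start[i] <= pl$t_end[j]) {
        if (pl$weight[i] >= pl$weight[j]) {
          pl$t_end[j] <- pl$t_start[i] - 1L
          if (pl$t_end[j] < pl$t_start[j]) drop[j] <- TRUE
        } else {
          pl$t_start[i] <- pl$t_end[j] + 1L
          if (pl$t_start[i] > pl$t_end[i]) drop[i] <- TRUE
        }
      }
    }
    if (any(drop)) {
      up <- rbind(up, data.frame(contig_id = pl$contig_id[drop],
                                 reason = "conflict"))
      pl <- pl[!drop, , drop = FALSE]
    }
    pl$gap_after <- NA_integer_
    pl$gap_flag <- NA_character_
    rownames(pl) <- NULL
  }
  spans <- c(spanned_query_bp = sum(pl$q_aligned),
             spanned_template_bp = if (nrow(pl))
               sum(vapply(split(pl, pl$chrom), function(d)
                 max(d$t_end) - min(d$t_start) + 1L, numeric(1))) else 0)
  structure(list(clone_id = clone_id, placed = pl, unplaced = up,
                 spans = spans),
            class = "contig_layout")
}

#' @export
print.contig_layout <- function(x, ...) {
  cat(sprintf("contig_layout %s: %d placed, %d unplaced (%d bp query span, %d bp template span)\n",
              x$clone_id, nrow(x$placed), nrow(x$unplaced),
              x$spans["spanned_query_bp"], x$spans["spanned_template_bp"]))
  invisible(x)
}

#' Estimate inter-contig gaps from the template
#'
#' The gap after each placed contig is the template distance between its
#' projected end and the next contig's projected start (the template is
#' gapless, so this projection is the best available physical estimate).
#' Negative estimates are flagged `overlap_suspected`; gaps of less than
#' 2 kb are flagged `closable` (small enough to close by PCR walking).
#'
#' @param layout a `contig_layout`.
#' @param closable_below gap size strictly below which a gap is closable.
#' @return the layout with `gap_after`/`gap_flag` filled.
#' @export
estimate_gaps <- function(layout, closable_below = 2000L) {
  pl <- layout$placed
  if (!nrow(pl)) stop("estimate_gaps: empty layout", call. = FALSE)
  for (i in seq_len(nrow(pl) - 1L)) {
    if (pl$chrom[i] != pl$chrom[i + 1]) next
    g <- pl$t_start[i + 1] - pl$t_end[i] - 1L
    pl$gap_after[i] <- g
    pl$gap_flag[i] <- if (g < 0) "overlap_suspected" else
      if (g < closable_below) "closable" else "ok"
  }
  layout$placed <- pl
  layout
}

#' Synteny summary over clone layouts
#'
#' The headline fractions of a template-guided assembly:
#' `ordered_fraction = sum(ordered bp) / sum(insert bp)`,
#' `aligned_fraction = sum(spanned query bp) / sum(insert bp)`, and
#' `expansion_fraction = (sum(spanned template) - sum(spanned query)) /
#' sum(spanned query)`. Accepts either computed layouts or pre-tabulated
#' per-clone numbers, so published summary tables can be fed straight in.
#'
#' @param layouts list of `contig_layout` objects, or a data.frame with
#'   columns `assembled_bp, unambiguous_bp, ordered_bp, spanned_query_bp,
#'   spanned_template_bp`.
#' @param insert_bp per-clone insert sizes (bp), recycled as needed.
#' @param denominator `"insert"` (default) or `"unambiguous"`: denominator
#'   of the ordered/aligned fractions.
#' @return a `synteny_summary` list with totals and fractions (percentages
#'   rounded to one decimal in `as.data.frame`/report output).
#' @export
summarize_layouts <- function(layouts, insert_bp, denominator = c("insert", "unambiguous")) {
  denominator <- match.arg(denominator)
  if (is.data.frame(layouts)) {
    tab <- layouts
  } else {
    tab <- do.call(rbind, lapply(layouts, function(ly) {
      data.frame(assembled_bp = sum(ly$placed$length) +
                   0L, # unplaced contig lengths unknown here; caller may pass a table
                 unambiguous_bp = sum(ly$placed$length),
                 ordered_bp = sum(ly$placed$length),
                 spanned_query_bp = unname(ly$spans["spanned_query_bp"]),
                 spanned_template_bp = unname(ly$spans["spanned_template_bp"]))
    }))
  }
  tot_insert <- sum(insert_bp)
  if (tot_insert <= 0) stop("summarize_layouts: zero insert total", call. = FALSE)
  denom <- if (denominator == "insert") tot_insert else sum(tab$unambiguous_bp)
  sq <- sum(tab$spanned_query_bp); st <- sum(tab$spanned_template_bp)
  structure(list(
    n_clones = nrow(tab),
    assembled_bp = sum(tab$assembled_bp),
    unambiguous_bp = sum(tab$unambiguous_bp),
    ordered_bp = sum(tab$ordered_bp),
    insert_bp = tot_insert,
    spanned_query_bp = sq,
    spanned_template_bp = st,
    ordered_fraction = sum(tab$ordered_bp) / denom,
    aligned_fraction = sq / denom,
    expansion_fraction = if (sq > 0) (st - sq) / sq else NA_real_),
    class = "synteny_summary")
}

#' @export
print.synteny_summary <- function(x, ...) {
  cat(sprintf(paste0("synteny_summary: %d clones, %s bp inserts; ordered %.1f%%, ",
                     "aligned %.1f%%, template expansion %.1f%%\n"),
              x$n_clones, format(x$insert_bp, big.mark = ","),
              100 * x$ordered_fraction, 100 * x$aligned_fraction,
              100 * x$expansion_fraction))
  invisible(x)
}
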