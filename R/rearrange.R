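#' Classify micro-rearrangements from anchor alignments
#'
#' The maximum-weight collinear chain of a clone's anchors defines its
#' syntenic frame; rearrangements are read off two complementary signals:
#'
#' * adjacent chained anchors that overlap on one genome but not the other
#'   (the aligner extends through a tandem copy): query-side overlap with
#'   disjoint template intervals is a duplication in the template
#'   (`duplication_template`), template-side overlap with disjoint query
#'   intervals is a duplication in the query (`duplication_query`);
#' * off-chain anchors: an anchor whose query (template) interval is
#'   already covered by the frame is the extra copy of a template (query)
#'   duplication; an opposite-strand anchor sitting where the frame expects
#'   it is an `inversion`; a same-strand anchor at an unexpected template
#'   position (other chromosome, outside the frame span, or violating
#'   collinear order beyond `max_collinear_gap`) is a `translocation`,
#'   opposite-strand and out-of-place is an `inverted_translocation`.
#'   Off-chain anchors that fit the frame within `max_collinear_gap`
#'   are collinear leftovers, not events.
#'
#' Every off-chain anchor is assigned to at most one class; indels are not
#' called (they are visible only as unaligned sequence).
#'
#' @param hits anchor data.frame from [seed_extend_align()] for one clone
#'   (already bit-score filtered).
#' @param max_collinear_gap placement tolerance in bp.
#' @param min_event_len minimum event size in bp.
#' @param cov_frac coverage fraction for the duplication rules (reciprocal
#'   overlap threshold).
#' @return data.frame `class, q_start, q_end, t_chrom, t_start, t_end,
#'   length, bit_score, strand`.
#' @export
classify_rearrangements <- function(hits, max_collinear_gap = 20000,
                                    min_event_len = 100, cov_frac = 0.5) {
  empty <- data.frame(class = character(0), q_start = integer(0),
                      q_end = integer(0), t_chrom = character(0),
                      t_start = integer(0), t_end = integer(0),
                      length = integer(0), bit_score = numeric(0),
                      strand = character(0), stringsAsFactors = FALSE)
  if (is.null(hits) || !nrow(hits)) return(empty)
  ch <- chain_anchors(hits, max_collinear_gap)
  main <- hits[ch$main, , drop = FALSE]
  main <- main[order(main$template_start), , drop = FALSE]
  frame_chrom <- main$template_id[1]
  frame_strand <- main$strand[1]
  frame_t <- c(min(main$template_start), max(main$template_end))
  frame_q <- c(min(main$query_start), max(main$query_end))
  events <- list()
  add <- function(class, qs, qe, tch, ts, te, len, bit, strand) {
    events[[length(events) + 1]] <<- data.frame(
      class = class, q_start = qs, q_end = qe, t_chrom = tch, t_start = ts,
      t_end = te, length = as.integer(len), bit_score = bit, strand = strand,
      stringsAsFactors = FALSE)
  }
  # --- chain-adjacency overlaps (duplications the aligner extended through)
  if (nrow(main) > 1) {
    for (i in seq_len(nrow(main) - 1)) {
      a <- main[i, ]; b <- main[i + 1, ]
      tov <- min(a$template_end, b$template_end) -
        max(a$template_start, b$template_start) + 1
      qov <- min(a$query_end, b$query_end) -
        max(a$query_start, b$query_start) + 1
      if (qov >= min_event_len && tov < min_event_len) {
        qs <- max(a$query_start, b$query_start)
        add("duplication_template", qs, qs + qov - 1, frame_chrom,
            a$template_end - qov + 1, b$template_start + qov - 1, qov,
            min(a$bit_score, b$bit_score), frame_strand)
      } else if (tov >= min_event_len && qov < min_event_len) {
        ts <- max(a$template_start, b$template_start)
        add("duplication_query",
            b$query_start, b$query_start + tov - 1, frame_chrom,
            ts, ts + tov - 1, tov, min(a$bit_score, b$bit_score), frame_strand)
      }
    }
  }
  # --- off-chain anchors
  if (length(ch$off_chain)) {
    # frame coverage and expected-position interpolation
    tq_map_t <- as.numeric((main$template_start + main$template_end) / 2)
    tq_map_q <- as.numeric((main$query_start + main$query_end) / 2)
    cover_frac <- function(s, e, ss, ee) {
      ov <- pmin(e, ee) - pmax(s, ss) + 1
      sum(pmax(ov, 0)) / (e - s + 1)
    }
    for (ix in ch$off_chain) {
      h <- hits[ix, , drop = FALSE]
      hlen <- h$query_end - h$query_start + 1
      if (hlen < min_event_len) next
      on_frame_chrom <- h$template_id == frame_chrom
      qcov <- cover_frac(h$query_start, h$query_end,
                         main$query_start, main$query_end)
      tcov <- if (on_frame_chrom)
        cover_frac(h$template_start, h$template_end,
                   main$template_start, main$template_end) else 0
      if (qcov >= cov_frac && tcov < cov_frac) {
        add("duplication_template", h$query_start, h$query_end,
            h$template_id, h$template_start, h$template_end, hlen,
            h$bit_score, h$strand)
        next
      }
      if (tcov >= cov_frac && qcov < cov_frac) {
        add("duplication_query", h$query_start, h$query_end,
            h$template_id, h$template_start, h$template_end, hlen,
            h$bit_score, h$strand)
        next
      }
      in_span <- on_frame_chrom &&
        h$template_start >= frame_t[1] - max_collinear_gap &&
        h$template_end <= frame_t[2] + max_collinear_gap
      in_place <- FALSE
      if (in_span && length(tq_map_t) >= 2) {
        expq <- approx(tq_map_t, tq_map_q,
                       xout = (h$template_start + h$template_end) / 2,
                       rule = 2)$y
        in_place <- abs(expq - (h$query_start + h$query_end) / 2) <=
          max_collinear_gap
      } else if (in_span) {
        in_place <- TRUE
      }
      if (h$strand == frame_strand) {
        if (in_place) next # collinear leftover, not an event
        add("translocation", h$query_start, h$query_end, h$template_id,
            h$template_start, h$template_end, hlen, h$bit_score, h$strand)
      } else {
        if (in_place) {
          add("inversion", h$query_start, h$query_end, h$template_id,
              h$template_start, h$template_end, hlen, h$bit_score, h$strand)
        } else {
          add("inverted_translocation", h$query_start, h$query_end,
              h$template_id, h$template_start, h$template_end, hlen,
              h$bit_score, h$strand)
        }
      }
    }
  }
  if (!length(events)) return(empty)
  out <- do.call(rbind, events)
  out[order(out$q_start), , drop = FALSE]
}

rearrangement_classes <- function() {
  c("translocation", "inverted_translocation", "inversion",
    "duplication_query", "duplication_template")
}

#' Summarize rearrangement events
#'
#' Per-class totals, event counts and integer-rounded mean lengths, plus
#' grand totals; classes without events are reported with `n = 0`. The
#' polarity caveat applies: without an outgroup, which genome an event
#' occurred in cannot be inferred; classes are reported relative to the
#' template.
#'
#' @param events data.frame from [classify_rearrangements()] (rows from
#'   several clones may be concatenated).
#' @return a `rearrangement_summary` data.frame `class, total_bp, n_events,
#'   mean_bp` with a final `Total` row.
#' @export
summarize_events <- function(events) {
  cls <- rearrangement_classes()
  rows <- lapply(cls, function(cl) {
    e <- events[events$class == cl, , drop = FALSE]
    data.frame(class = cl, total_bp = sum(e$length), n_events = nrow(e),
               mean_bp = if (nrow(e)) as.integer(round(sum(e$length) / nrow(e)))
               else 0L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  tot <- data.frame(class = "Total", total_bp = sum(out$total_bp),
                    n_events = sum(out$n_events),
                    mean_bp = if (sum(out$n_events))
                      as.integer(round(sum(out$total_bp) / sum(out$n_events)))
                    else 0L, stringsAsFactors = FALSE)
  out <- rbind(out, tot)
  class(out) <- c("rearrangement_summary", "data.frame")
  out
}

#' Detect tandem gene duplications from ortholog maps
#'
#' Groups genes mapping to a common counterpart locus: adjacent same-strand
#' copies within `max_tandem_gap` of each other on one genome that share one
#' ortholog on the other genome form a tandem array. Arrays whose copy
#' numbers differ between the genomes are reported.
#'
#' @param genes_query,genes_template data.frames `gene_id, seqid, start,
#'   end, strand`.
#' @param ortholog_map data.frame `gene_id_query, gene_id_template`
#'   (many-to-one in either direction marks the extra copies).
#' @param max_tandem_gap maximum distance between adjacent copies (bp).
#' @return data.frame `family, copies_query, copies_template`.
#' @export
detect_tandem_duplications <- function(genes_query, genes_template,
                                       ortholog_map, max_tandem_gap = 20000) {
  count_adjacent <- function(genes, ids) {
    g <- genes[genes$gene_id %in% ids, , drop = FALSE]
    if (!nrow(g)) return(0L)
    g <- g[order(g$seqid, g$start), , drop = FALSE]
    best <- run <- 1L
    for (i in seq_len(nrow(g))[-1]) {
      adjacent <- g$seqid[i] == g$seqid[i - 1] &&
        g$strand[i] == g$strand[i - 1] &&
        g$start[i] - g$end[i - 1] <= max_tandem_gap
      run <- if (adjacent) run + 1L else 1L
      best <- max(best, run)
    }
    best
  }
  rows <- list()
  # query-side arrays: several query genes to one template gene
  for (tid in unique(ortholog_map$gene_id_template)) {
    qids <- ortholog_map$gene_id_query[ortholog_map$gene_id_template == tid]
    cq <- count_adjacent(genes_query, qids)
    tq <- count_adjacent(genes_template, tid)
    if (cq != tq) {
      rows[[length(rows) + 1]] <- data.frame(
        family = tid, copies_query = cq, copies_template = tq,
        stringsAsFactors = FALSE)
    }
  }
  # template-side arrays: several template genes to one query gene
  for (qid in unique(ortholog_map$gene_id_query)) {
    tids <- ortholog_map$gene_id_template[ortholog_map$gene_id_query == qid]
    if (length(tids) < 2) next
    ct <- count_adjacent(genes_template, tids)
    cq <- count_adjacent(genes_query, qid)
    if (ct != cq) {
      rows[[length(rows) + 1]] <- data.frame(
        family = qid, copies_query = cq, copies_template = ct,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(family = character(0), copies_query = integer(0),
                      copies_template = integer(0), stringsAsFactors = FALSE))
  }
  out <- unique(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Score recovery of implanted rearrangements
#'
#' Matches called events against truth events of the same clone by class
#' and clone-coordinate overlap (reciprocal fraction `min_overlap` of the
#' shorter interval).
#'
#' @param called data.frame of called events with a `clone_id` column.
#' @param truth truth events data.frame (from the simulator).
#' @param min_overlap minimum overlap fraction of the shorter interval.
#' @return list `precision`, `recall`, `n_called`, `n_truth`, `matched`.
#' @export
score_event_recovery <- function(called, truth, min_overlap = 0.5) {
  match_one <- function(ev, tt) {
    cand <- which(tt$class == ev$class & tt$clone_id == ev$clone_id)
    for (j in cand) {
      ov <- min(ev$q_end, tt$end[j]) - max(ev$q_start, tt$start[j]) + 1
      short <- min(ev$q_end - ev$q_start, tt$end[j] - tt$start[j]) + 1
      if (ov >= min_overlap * short) return(j)
    }
    NA_integer_
  }
  matched_truth <- integer(0)
  n_matched_called <- 0L
  for (i in seq_len(nrow(called))) {
    j <- match_one(called[i, ], truth)
    if (!is.na(j)) {
      n_matched_called <- n_matched_called + 1L
      matched_truth <- union(matched_truth, j)
    }
  }
  list(precision = if (nrow(called)) n_matched_called / nrow(called) else NA,
       recall = if (nrow(truth)) length(matched_truth) / nrow(truth) else NA,
       n_called = nrow(called), n_truth = nrow(truth),
       matched = length(matched_truth))
}
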