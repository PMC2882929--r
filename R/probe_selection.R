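#' Probe selection parameters
#'
#' Screening thresholds for selecting clones from overgo hybridization data:
#' probes must have exactly one template hit with at least `min_identical`
#' identical bases, a polyploid library hit count within `copy_count_range`
#' (the expected homolog count band), and candidate clones must be supported
#' by at least two retained probes within `max_pair_distance` on the
#' template.
#'
#' @param min_identical minimum identical stretch on the template (bp).
#' @param copy_count_range inclusive band of polyploid hit counts.
#' @param max_pair_distance maximum template distance between supporting
#'   probes (bp, inclusive).
#' @param one_clone_per_region report a single clone per template window.
#' @return a `selection_params` list.
#' @export
selection_params <- function(min_identical = 35L,
                             copy_count_range = c(4L, 20L),
                             max_pair_distance = 50000L,
                             one_clone_per_region = FALSE) {
  stopifnot(min_identical > 0, copy_count_range[1] <= copy_count_range[2])
  structure(list(min_identical = min_identical,
                 copy_count_range = as.integer(copy_count_range),
                 max_pair_distance = max_pair_distance,
                 one_clone_per_region = one_clone_per_region),
            class = "selection_params")
}

#' Single-copy probe filter
#'
#' Keeps probes with exactly one template hit whose identical stretch is at
#' least `min_identical` bp. Output is sorted by probe id, so it is
#' independent of input row order.
#'
#' @param table a `probe_hit_table` (or list with `template_hits`).
#' @param params a [selection_params].
#' @return character vector of probe ids.
#' @export
filter_single_copy <- function(table, params = selection_params()) {
  th <- table$template_hits
  if (is.null(th) || !nrow(th)) return(character(0))
  cnt <- table(th$probe_id)
  single <- names(cnt)[cnt == 1]
  th1 <- th[th$probe_id %in% single & th$identical_length >= params$min_identical, ]
  sort(unique(th1$probe_id))
}

#' Copy-number band filter
#'
#' Keeps probes whose polyploid library hit count falls inside
#' `copy_count_range` (inclusive).
#'
#' @param probe_ids candidate probe ids (subset of the table's probes).
#' @param table a `probe_hit_table`.
#' @param params a [selection_params].
#' @return character vector of probe ids.
#' @export
filter_copy_number <- function(probe_ids, table, params = selection_params()) {
  if (!length(probe_ids)) return(character(0))
  pc <- table$polyploid_counts
  cnt <- table(factor(pc$probe_id, levels = probe_ids))
  keep <- names(cnt)[cnt >= params$copy_count_range[1] &
                       cnt <= params$copy_count_range[2]]
  sort(keep)
}

#' Candidate clone selection from probe pairs
#'
#' A clone is a candidate when at least two retained probes hybridize it and
#' their template positions are within `max_pair_distance` (inclusive) on
#' the same chromosome. With `one_clone_per_region`, overlapping template
#' windows report a single clone (tie-break: most probe support, then
#' smallest pair distance, then lexicographic clone id).
#'
#' @param probe_ids retained probe ids (after both filters).
#' @param table a `probe_hit_table`.
#' @param params a [selection_params].
#' @return data.frame `clone_id, probe_a, probe_b, chrom, template_distance`.
#' @export
select_candidate_clones <- function(probe_ids, table,
                                    params = selection_params()) {
  empty <- data.frame(clone_id = character(0), probe_a = character(0),
                      probe_b = character(0), chrom = character(0),
                      template_distance = numeric(0), stringsAsFactors = FALSE)
  if (length(probe_ids) < 2) return(empty)
  th <- table$template_hits
  th <- th[th$probe_id %in% probe_ids, , drop = FALSE]
  pc <- table$polyploid_counts
  pc <- pc[pc$probe_id %in% probe_ids, , drop = FALSE]
  rows <- list()
  for (clone in sort(unique(pc$clone_id))) {
    probes <- sort(unique(pc$probe_id[pc$clone_id == clone]))
    if (length(probes) < 2) next
    hp <- th[th$probe_id %in% probes, , drop = FALSE]
    if (nrow(hp) < 2) next
    best <- NULL
    for (ai in seq_len(nrow(hp) - 1)) {
      for (bi in seq(ai + 1, nrow(hp))) {
        if (hp$chrom[ai] != hp$chrom[bi]) next
        d <- abs(hp$position[ai] - hp$position[bi])
        if (d > params$max_pair_distance) next
        if (is.null(best) || d < best$template_distance) {
          pr <- sort(c(hp$probe_id[ai], hp$probe_id[bi]))
          best <- data.frame(clone_id = clone, probe_a = pr[1],
                             probe_b = pr[2], chrom = hp$chrom[ai],
                             template_distance = d, n_support = length(probes),
                             stringsAsFactors = FALSE)
        }
      }
    }
    if (!is.null(best)) rows[[length(rows) + 1]] <- best
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  if (params$one_clone_per_region) {
    # cluster candidate windows per chromosome; keep one clone per cluster
    pos <- vapply(seq_len(nrow(out)), function(i) {
      hp <- th[th$probe_id %in% c(out$probe_a[i], out$probe_b[i]), ]
      mean(hp$position)
    }, numeric(1))
    out$.pos <- pos
    keep <- logical(nrow(out))
    for (ch in unique(out$chrom)) {
      ix <- which(out$chrom == ch)
      ix <- ix[order(out$.pos[ix])]
      grp <- cumsum(c(1, diff(out$.pos[ix]) > params$max_pair_distance))
      for (g in unique(grp)) {
        cand <- ix[grp == g]
        o <- cand[order(-out$n_support[cand], out$template_distance[cand],
                        out$clone_id[cand])]
        keep[o[1]] <- TRUE
      }
    }
    out <- out[keep, , drop = FALSE]
    out$.pos <- NULL
  }
  out <- out[order(out$clone_id), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("clone_id", "probe_a", "probe_b", "chrom", "template_distance")]
}
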