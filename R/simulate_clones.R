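# Clone construction works on a copy of the template interval and applies
# three coordinate-changing passes (structural edits, small indels, tandem
# duplications) through a single edit engine that rebuilds the sequence and
# shifts every tracked coordinate table in one sweep.

# edits: data.frame(pos, del_len, ins) on the current sequence, sorted and
# non-overlapping; deletion covers [pos, pos + del_len - 1], the insertion
# string replaces it. tracked: named list of data.frames with start/end
# columns. Rows overlapping a deleted span are dropped.
apply_edits <- function(x, edits, tracked = list()) {
  if (is.null(edits) || nrow(edits) == 0) {
    nil <- data.frame(new_start = integer(0), new_end = integer(0))
    return(list(x = x, tracked = tracked, edit_new = nil))
  }
  edits <- edits[order(edits$pos), , drop = FALSE]
  spans_end <- edits$pos + edits$del_len # first position NOT deleted
  if (any(edits$pos[-1] < spans_end[-nrow(edits)])) {
    stop("apply_edits: overlapping edits", call. = FALSE)
  }
  ins_len <- nchar(edits$ins)
  delta <- ins_len - edits$del_len
  cum <- cumsum(delta)
  shift_of <- function(v) {
    # shift for original coordinates at/after each edit's replaced span
    i <- findInterval(v, spans_end)
    ifelse(i > 0, cum[pmax(i, 1)], 0) * (i > 0)
  }
  inside_del <- function(v) {
    j <- findInterval(v, edits$pos)
    j > 0 & v <= (edits$pos[pmax(j, 1)] + edits$del_len[pmax(j, 1)] - 1) &
      edits$del_len[pmax(j, 1)] > 0
  }
  # rebuild sequence
  pieces <- list()
  prev <- 1L
  for (i in seq_len(nrow(edits))) {
    if (edits$pos[i] > prev) pieces[[length(pieces) + 1]] <- x[prev:(edits$pos[i] - 1L)]
    if (ins_len[i] > 0) {
      pieces[[length(pieces) + 1]] <- strsplit(edits$ins[i], "", fixed = TRUE)[[1]]
    }
    prev <- edits$pos[i] + edits$del_len[i]
  }
  if (prev <= length(x)) pieces[[length(pieces) + 1]] <- x[prev:length(x)]
  newx <- unlist(pieces, use.names = FALSE)
  # shift tracked tables
  out_tracked <- lapply(tracked, function(df) {
    if (is.null(df) || nrow(df) == 0) return(df)
    bad <- inside_del(df$start) | inside_del(df$end)
    df <- df[!bad, , drop = FALSE]
    if (nrow(df)) {
      df$start <- df$start + shift_of(df$start)
      df$end <- df$end + shift_of(df$end)
    }
    df
  })
  # new coordinates of each edit's inserted span
  before <- c(0, cum[-length(cum)])
  new_start <- edits$pos + before
  new_end <- new_start + ins_len - 1L
  list(x = newx, tracked = out_tracked,
       edit_new = data.frame(new_start = as.integer(new_start),
                             new_end = as.integer(new_end)))
}

rel_window <- function(df, a, b, cols = c("start", "end")) {
  if (is.null(df) || !nrow(df)) return(df)
  keep <- df[[cols[1]]] >= a & df[[cols[2]]] <= b
  df <- df[keep, , drop = FALSE]
  for (cl in cols) df[[cl]] <- df[[cl]] - a + 1L
  df
}

sample_free_point <- function(free, margin = 100L) {
  a <- alloc_block(free, 1L, margin = margin)
  if (is.null(a)) return(NULL)
  a
}

#' Simulate diverged polyploid clones from a template
#'
#' Each clone copies an interval of its assigned chromosome arm, then
#' diverges: substitutions calibrated so the realized NG86 Ks of embedded
#' genes matches `target_ks` (purifying selection on coding sequence),
#' deletion of part of the inherited repeat complement (template-side
#' expansion), clone-specific repeat insertions up to the query repeat
#' fraction, clone-specific genes, implanted rearrangements per the
#' configured spectrum (inversions, translocations, inverted translocations,
#' tandem query duplications, and collapse of template donor pairs =
#' template duplications), and small intergenic indels. All events, genes
#' and repeats are recorded with clone coordinates in the truth set.
#'
#' @param template a `template_genome` from [simulate_template()].
#' @param cfg a [sim_config] (defaults to the template's).
#' @return list with `clones` (list of `bac_clone`: `clone_id, seq, chrom,
#'   t_start, t_end, row, col, genes, events, repeats`), and `truth`
#'   (data.frames `clones`, `events`, `orthologs`, `genes`).
#' @export
simulate_polyploid_clones <- function(template, cfg = template$cfg) {
  stopifnot(inherits(template, "template_genome"))
  L <- cfg$chrom_length
  if (max(cfg$insert_size_range) > L) {
    stop("simulate_polyploid_clones: insert_size_range exceeds chromosome length",
         call. = FALSE)
  }
  p_sub <- calibrate_substitution_rate(cfg$target_ks, cfg$omega, cfg$ts_tv)
  n_clones <- cfg$n_clones
  n_arms <- 2L * cfg$n_chromosomes
  lib <- template$library
  fam_w <- .family_weights("query")
  tg <- template$truth

  # assign clone-local event quotas
  quotas <- list()
  for (cls in c("translocation", "inverted_translocation", "inversion",
                "duplication_query")) {
    spec <- cfg$rearrangement_spectrum[[cls]]
    n <- if (is.null(spec)) 0L else spec$n
    quotas[[cls]] <- if (n > 0) sample(rep_len(seq_len(n_clones), n)) else integer(0)
  }
  cells <- expand.grid(row = seq_len(cfg$grid[1]), col = seq_len(cfg$grid[2]))
  clones <- list()
  ev_all <- list(); orth_all <- list(); cl_rows <- list(); gene_all <- list()

  for (i in seq_len(n_clones)) {
    clone_id <- sprintf("BAC%02d", i)
    arm_index <- ((i - 1L) %% n_arms) + 1L
    chrom_i <- ceiling(arm_index / 2)
    arm <- ((arm_index - 1L) %% 2L) + 1L
    chrom <- sprintf("chr%02d", chrom_i)
    insert_len <- as.integer(round(runif(1, cfg$insert_size_range[1],
                                         cfg$insert_size_range[2])))
    center <- if (arm == 1) round(L / 4) else round(3 * L / 4)
    a <- max(1L, min(L - insert_len + 1L, as.integer(round(center - insert_len / 2))))
    b <- a + insert_len - 1L
    x <- strsplit(substr(unclass(template$seqs)[[chrom]], a, b), "",
                  fixed = TRUE)[[1]]
    n0 <- length(x)

    genes <- tg$genes[tg$genes$chrom == chrom, , drop = FALSE]
    genes <- rel_window(genes, a, b)
    exons <- tg$exons[tg$exons$chrom == chrom & tg$exons$gene_id %in% genes$gene_id, , drop = FALSE]
    for (cl in c("start", "end")) exons[[cl]] <- exons[[cl]] - a + 1L
    reps <- rel_window(tg$repeats[tg$repeats$chrom == chrom, , drop = FALSE], a, b)
    donors <- tg$donors[tg$donors$chrom == chrom & tg$donors$arm == arm &
                          tg$donors$x1_start >= a & tg$donors$x2_end <= b, , drop = FALSE]
    if (nrow(donors)) {
      for (cl in c("x1_start", "x1_end", "x2_start", "x2_end")) {
        donors[[cl]] <- donors[[cl]] - a + 1L
      }
    }

    # --- substitutions -------------------------------------------------
    cds_mask <- rep(FALSE, n0)
    for (r in seq_len(nrow(exons))) cds_mask[exons$start[r]:exons$end[r]] <- TRUE
    if (p_sub > 0) {
      idx <- which(runif(n0) < p_sub & !cds_mask & x %in% c("A", "C", "G", "T"))
      for (j in idx) x[j] <- propose_base(x[j], cfg$ts_tv)
    }
    orths <- list()
    for (r in seq_len(nrow(genes))) {
      gexp <- exons[exons$gene_id == genes$gene_id[r], , drop = FALSE]
      gexp <- gexp[order(gexp$start), , drop = FALSE]
      cds_chars <- unlist(lapply(seq_len(nrow(gexp)), function(e)
        x[gexp$start[e]:gexp$end[e]]))
      if (genes$strand[r] == "-") {
        cds_chars <- rev(chartr("ACGT", "TGCA", cds_chars))
      }
      cds_chars <- mutate_cds_chars(cds_chars, p_sub, cfg$omega, cfg$ts_tv)
      back <- cds_chars
      if (genes$strand[r] == "-") back <- rev(chartr("ACGT", "TGCA", back))
      off <- 0L
      for (e in seq_len(nrow(gexp))) {
        w <- gexp$end[e] - gexp$start[e] + 1L
        x[gexp$start[e]:gexp$end[e]] <- back[(off + 1L):(off + w)]
        off <- off + w
      }
      orths[[r]] <- data.frame(clone_id = clone_id,
                               gene_id = genes$gene_id[r],
                               cds_template = genes$cds[r],
                               cds_clone = paste(cds_chars, collapse = ""),
                               stringsAsFactors = FALSE)
    }

    # --- structural edits ----------------------------------------------
    blocked <- rbind(
      if (nrow(genes)) data.frame(start = pmax(1L, genes$start - 100L),
                                  end = pmin(n0, genes$end + 100L)),
      if (nrow(reps)) reps[, c("start", "end")],
      if (nrow(donors)) data.frame(start = donors$x1_start, end = donors$x2_end))
    free <- if (is.null(blocked) || !nrow(blocked)) {
      data.frame(start = 1L, end = n0)
    } else {
      o <- order(blocked$start)
      complement_intervals(blocked$start[o], blocked$end[o], n0)
    }
    free <- free[free$start > 200 & free$end < n0 - 200, , drop = FALSE]

    edits <- list(); meta <- list()
    add_edit <- function(pos, del_len, ins, kind, info = NULL) {
      edits[[length(edits) + 1]] <<- data.frame(pos = as.integer(pos),
                                                del_len = as.integer(del_len),
                                                ins = ins,
                                                stringsAsFactors = FALSE)
      meta[[length(meta) + 1]] <<- c(list(kind = kind), info)
    }
    # donor collapse -> template-side duplications
    dup_t_x1 <- data.frame(start = integer(0), end = integer(0),
                           t_start = integer(0), t_end = integer(0))
    for (d in seq_len(nrow(donors))) {
      add_edit(donors$x2_start[d], donors$x2_end[d] - donors$x2_start[d] + 1L,
               "", "collapse")
      dup_t_x1 <- rbind(dup_t_x1, data.frame(
        start = donors$x1_start[d], end = donors$x1_end[d],
        t_start = donors$x1_start[d] + a - 1L,
        t_end = donors$x2_end[d] + a - 1L))
    }
    # expansion: delete part of the inherited repeat complement
    target_del <- round(cfg$expansion_bias * n0 / 1000)
    del_bp <- 0L
    reps$kept <- rep(TRUE, nrow(reps))
    if (nrow(reps) && target_del > 0) {
      for (r in sample(seq_len(nrow(reps)))) {
        if (del_bp >= target_del) break
        w <- reps$end[r] - reps$start[r] + 1L
        add_edit(reps$start[r], w, "", "rep_del")
        reps$kept[r] <- FALSE
        del_bp <- del_bp + w
      }
    }
    reps_kept <- reps[reps$kept, c("start", "end", "family"), drop = FALSE]
    # clone-specific repeat insertions toward the query repeat fraction
    r_keep <- sum(reps_kept$end - reps_kept$start + 1L)
    rf <- cfg$repeat_fraction_query
    ins_target <- max(0, round((rf * (n0 - del_bp) - r_keep) / (1 - rf)))
    ins_bp <- 0L
    new_reps <- list()
    while (ins_bp < ins_target) {
      fam <- sample(names(fam_w), 1, prob = fam_w)
      cons <- unclass(lib)[[fam]]
      keep <- round(nchar(cons) * runif(1, 0.6, 1))
      copy <- mutate_dna(substr(cons, nchar(cons) - keep + 1, nchar(cons)),
                         runif(1, 0.05, 0.15), cfg$ts_tv)
      pt <- sample_free_point(free)
      if (is.null(pt)) break
      free <- pt$free
      add_edit(pt$pos, 0L, copy, "rep_ins", list(family = fam))
      ins_bp <- ins_bp + nchar(copy)
    }
    # clone-specific genes
    n_spec <- round(cfg$specific_gene_rate * nrow(genes))
    for (s in seq_len(n_spec)) {
      g <- make_gene()
      pt <- sample_free_point(free)
      if (is.null(pt)) break
      free <- pt$free
      strand <- sample(c("+", "-"), 1)
      gseq <- if (strand == "+") g$seq else revcomp(g$seq)
      add_edit(pt$pos, 0L, gseq, "spec_gene",
               list(strand = strand, cds = g$cds))
    }
    # translocations (blocks copied in from a distant template location)
    for (cls in c("translocation", "inverted_translocation")) {
      n_here <- sum(quotas[[cls]] == i)
      for (s in seq_len(n_here)) {
        src_chrom_i <- if (cfg$n_chromosomes > 1) {
          sample(setdiff(seq_len(cfg$n_chromosomes), chrom_i), 1)
        } else chrom_i
        src_chrom <- sprintf("chr%02d", src_chrom_i)
        len <- event_len(1, cfg$rearrangement_spectrum[[cls]]$mean_bp,
                         cfg$min_event_bp)
        src <- NULL
        feats_src <- template$features[template$features$seqid == src_chrom, ]
        for (try in 1:50) {
          p0 <- sample.int(L - len - 200L, 1) + 100L
          hit <- any(feats_src$start <= p0 + len - 1 & feats_src$end >= p0)
          near_self <- src_chrom_i == chrom_i && p0 + len >= a - 1000 && p0 <= b + 1000
          if (!hit && !near_self) { src <- p0; break }
        }
        if (is.null(src)) next
        block <- mutate_dna(substr(unclass(template$seqs)[[src_chrom]], src,
                                   src + len - 1L), p_sub, cfg$ts_tv)
        if (cls == "inverted_translocation") block <- revcomp(block)
        pt <- sample_free_point(free)
        if (is.null(pt)) next
        free <- pt$free
        add_edit(pt$pos, 0L, block, cls,
                 list(t_chrom = src_chrom, t_start = src, t_end = src + len - 1L))
      }
    }
    # inversions (in-place reverse complement of clone backbone)
    n_inv <- sum(quotas$inversion == i)
    for (s in seq_len(n_inv)) {
      len <- event_len(1, cfg$rearrangement_spectrum$inversion$mean_bp,
                       cfg$min_event_bp)
      al <- alloc_block(free, len, margin = 100L)
      if (is.null(al)) next
      free <- al$free
      seg <- paste(x[al$pos:(al$pos + len - 1L)], collapse = "")
      add_edit(al$pos, len, revcomp(seg), "inversion",
               list(t_chrom = chrom, t_start = al$pos + a - 1L,
                    t_end = al$pos + a + len - 2L))
    }

    edf <- if (length(edits)) do.call(rbind, edits) else NULL
    keep_meta <- meta
    if (!is.null(edf)) {
      # drop overlapping edits (later-placed ones), keeping deterministic order
      o <- order(edf$pos)
      edf <- edf[o, , drop = FALSE]; keep_meta <- keep_meta[o]
      ok <- rep(TRUE, nrow(edf))
      last_end <- -1
      for (r in seq_len(nrow(edf))) {
        span_end <- edf$pos[r] + max(edf$del_len[r] - 1L, 0L)
        if (edf$pos[r] <= last_end) ok[r] <- FALSE else last_end <- span_end
      }
      edf <- edf[ok, , drop = FALSE]; keep_meta <- keep_meta[ok]
    }
    tracked <- list(genes = genes, exons = exons, reps = reps_kept,
                    dup_t = dup_t_x1)
    ap <- apply_edits(x, edf, tracked)
    x <- ap$x
    genes <- ap$tracked$genes; exons <- ap$tracked$exons
    reps_kept <- ap$tracked$reps; dup_t_x1 <- ap$tracked$dup_t

    events <- list()
    add_event <- function(class, qs, qe, t_chrom, t_start, t_end) {
      events[[length(events) + 1]] <<- data.frame(
        clone_id = clone_id, class = class, start = as.integer(qs),
        end = as.integer(qe), length = as.integer(qe - qs + 1L),
        t_chrom = t_chrom, t_start = t_start, t_end = t_end,
        stringsAsFactors = FALSE)
    }
    spec_genes <- list()
    new_rep_rows <- list()
    if (!is.null(edf)) {
      for (r in seq_len(nrow(edf))) {
        m <- keep_meta[[r]]
        ns <- ap$edit_new$new_start[r]; ne <- ap$edit_new$new_end[r]
        if (m$kind %in% c("translocation", "inverted_translocation", "inversion")) {
          add_event(m$kind, ns, ne, m$t_chrom, m$t_start, m$t_end)
        } else if (m$kind == "spec_gene") {
          spec_genes[[length(spec_genes) + 1]] <- data.frame(
            gene_id = sprintf("%s_SG%02d", clone_id, length(spec_genes) + 1L),
            chrom = chrom, start = ns, end = ne, strand = m$strand,
            cds = m$cds, stringsAsFactors = FALSE)
        } else if (m$kind == "rep_ins") {
          new_rep_rows[[length(new_rep_rows) + 1]] <- data.frame(
            start = ns, end = ne, family = m$family, stringsAsFactors = FALSE)
        }
      }
    }
    for (r in seq_len(nrow(dup_t_x1))) {
      add_event("duplication_template", dup_t_x1$start[r], dup_t_x1$end[r],
                chrom, dup_t_x1$t_start[r], dup_t_x1$t_end[r])
    }
    rep_tab <- rbind(
      if (nrow(reps_kept)) cbind(reps_kept[, c("start", "end", "family")],
                                 origin = "inherited"),
      if (length(new_rep_rows)) cbind(do.call(rbind, new_rep_rows),
                                      origin = "inserted"))

    # --- small intergenic indels ---------------------------------------
    n1 <- length(x)
    ev_now <- if (length(events)) do.call(rbind, events) else NULL
    blocked2 <- rbind(
      if (nrow(genes)) data.frame(start = pmax(1L, genes$start - 30L),
                                  end = pmin(n1, genes$end + 30L)),
      if (!is.null(ev_now)) data.frame(start = pmax(1L, ev_now$start - 30L),
                                       end = pmin(n1, ev_now$end + 30L)))
    free2 <- if (is.null(blocked2) || !nrow(blocked2)) {
      data.frame(start = 1L, end = n1)
    } else {
      o <- order(blocked2$start)
      complement_intervals(blocked2$start[o], blocked2$end[o], n1)
    }
    n_ind <- rpois(1, cfg$indel_rate * n1)
    ind_edits <- NULL
    if (n_ind > 0) {
      rows <- list()
      for (s in seq_len(n_ind)) {
        al <- alloc_block(free2, 25L, margin = 10L)
        if (is.null(al)) break
        free2 <- al$free
        w <- 1L + min(as.integer(rgeom(1, 1 / 3)), 19L)
        if (runif(1) < 0.5) {
          rows[[length(rows) + 1]] <- data.frame(pos = al$pos, del_len = w,
                                                 ins = "", stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1]] <- data.frame(pos = al$pos, del_len = 0L,
                                                 ins = random_dna(w),
                                                 stringsAsFactors = FALSE)
        }
      }
      if (length(rows)) ind_edits <- do.call(rbind, rows)
    }
    ev_df <- ev_now
    tracked <- list(genes = genes, exons = exons, reps = rep_tab, events = ev_df)
    ap <- apply_edits(x, ind_edits, tracked)
    x <- ap$x
    genes <- ap$tracked$genes; exons <- ap$tracked$exons
    rep_tab <- ap$tracked$reps; ev_df <- ap$tracked$events

    # --- tandem duplications in the clone ------------------------------
    n2 <- length(x)
    n_dupq <- sum(quotas$duplication_query == i)
    if (n_dupq > 0) {
      blocked3 <- rbind(
        if (nrow(genes)) genes[, c("start", "end")],
        if (!is.null(ev_df) && nrow(ev_df)) ev_df[, c("start", "end")],
        if (!is.null(rep_tab) && nrow(rep_tab)) rep_tab[, c("start", "end")])
      free3 <- if (is.null(blocked3) || !nrow(blocked3)) {
        data.frame(start = 1L, end = n2)
      } else {
        o <- order(blocked3$start)
        complement_intervals(blocked3$start[o], blocked3$end[o], n2)
      }
      free3 <- free3[free3$start > 200 & free3$end < n2 - 200, , drop = FALSE]
      dq_edits <- list(); dq_len <- integer(0)
      for (s in seq_len(n_dupq)) {
        len <- event_len(1, cfg$rearrangement_spectrum$duplication_query$mean_bp,
                         cfg$min_event_bp)
        al <- alloc_block(free3, len, margin = 100L)
        if (is.null(al)) next
        free3 <- al$free
        blk <- paste(x[al$pos:(al$pos + len - 1L)], collapse = "")
        dq_edits[[length(dq_edits) + 1]] <- data.frame(
          pos = al$pos + len, del_len = 0L, ins = blk, stringsAsFactors = FALSE)
        dq_len <- c(dq_len, len)
      }
      if (length(dq_edits)) {
        dqe <- do.call(rbind, dq_edits)
        tracked <- list(genes = genes, exons = exons, reps = rep_tab,
                        events = ev_df)
        ap <- apply_edits(x, dqe, tracked)
        x <- ap$x
        genes <- ap$tracked$genes; exons <- ap$tracked$exons
        rep_tab <- ap$tracked$reps; ev_df <- ap$tracked$events
        for (r in seq_len(nrow(ap$edit_new))) {
          row <- data.frame(clone_id = clone_id, class = "duplication_query",
                            start = ap$edit_new$new_start[r],
                            end = ap$edit_new$new_end[r],
                            length = dq_len[r], t_chrom = chrom,
                            t_start = NA_integer_, t_end = NA_integer_,
                            stringsAsFactors = FALSE)
          ev_df <- rbind(ev_df, row)
        }
      }
    }

    spec_df <- if (length(spec_genes)) do.call(rbind, spec_genes) else NULL
    gene_tab <- rbind(
      if (nrow(genes)) data.frame(gene_id = genes$gene_id, start = genes$start,
                                  end = genes$end, strand = genes$strand,
                                  specific = FALSE, stringsAsFactors = FALSE),
      if (!is.null(spec_df)) data.frame(gene_id = spec_df$gene_id,
                                        start = spec_df$start,
                                        end = spec_df$end,
                                        strand = spec_df$strand,
                                        specific = TRUE,
                                        stringsAsFactors = FALSE))
    if (is.null(gene_tab)) {
      gene_tab <- data.frame(gene_id = character(0), start = integer(0),
                             end = integer(0), strand = character(0),
                             specific = logical(0), stringsAsFactors = FALSE)
    }
    if (is.null(ev_df)) {
      ev_df <- data.frame(clone_id = character(0), class = character(0),
                          start = integer(0), end = integer(0),
                          length = integer(0), t_chrom = character(0),
                          t_start = integer(0), t_end = integer(0),
                          stringsAsFactors = FALSE)
    }
    clone <- structure(list(clone_id = clone_id,
                            seq = paste(x, collapse = ""),
                            chrom = chrom, t_start = a, t_end = b,
                            row = cells$row[i], col = cells$col[i],
                            genes = gene_tab, exons = exons,
                            events = ev_df, repeats = rep_tab),
                       class = "bac_clone")
    clones[[clone_id]] <- clone
    ev_all[[i]] <- ev_df
    if (length(orths)) orth_all[[i]] <- do.call(rbind, orths)
    if (nrow(gene_tab)) gene_all[[i]] <- cbind(clone_id = clone_id, gene_tab)
    cl_rows[[i]] <- data.frame(clone_id = clone_id, chrom = chrom,
                               t_start = a, t_end = b, insert_bp = n0,
                               final_bp = length(x), row = cells$row[i],
                               col = cells$col[i], stringsAsFactors = FALSE)
  }
  truth <- list(clones = do.call(rbind, cl_rows),
                events = do.call(rbind, ev_all),
                orthologs = if (length(orth_all)) do.call(rbind, orth_all) else NULL,
                genes = do.call(rbind, gene_all))
  list(clones = clones, truth = truth)
}

#' @export
print.bac_clone <- function(x, ...) {
  cat(sprintf("bac_clone %s: %d bp from %s:%d-%d (cell r%d c%d), %d genes, %d events\n",
              x$clone_id, nchar(x$seq), x$chrom, x$t_start, x$t_end,
              x$row, x$col, nrow(x$genes), nrow(x$events)))
  invisible(x)
}
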