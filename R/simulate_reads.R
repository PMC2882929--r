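#' Shear clones into row/column pooled shotgun reads
#'
#' Clone-array pooled shotgun sequencing: every clone sits in one cell of a
#' row x column grid; its reads are sampled uniformly at the configured
#' total coverage and each read is placed in either the clone's row pool or
#' its column pool (never both). With the default 4x5 grid of 20 clones this
#' yields 9 pools.
#'
#' @param clones result of [simulate_polyploid_clones()] (the full list) or
#'   its `clones` element.
#' @param cfg a [sim_config].
#' @return list with `pools` (list of `pooled_read_set`: `pool_id, axis,
#'   index, reads` named character vector) and `truth` (data.frame
#'   `read_id, clone_id, row, col, start`).
#' @export
shear_and_pool <- function(clones, cfg) {
  if (!is.null(clones$clones)) clones <- clones$clones
  rl <- cfg$read_length
  lens <- vapply(clones, function(cl) nchar(cl$seq), numeric(1))
  if (rl > min(lens)) {
    stop("shear_and_pool: read_length exceeds the smallest insert", call. = FALSE)
  }
  cellkey <- vapply(clones, function(cl) paste(cl$row, cl$col), character(1))
  if (anyDuplicated(cellkey)) {
    stop("shear_and_pool: grid must assign each clone a unique cell", call. = FALSE)
  }
  pools <- list()
  get_pool <- function(axis, index) {
    id <- sprintf("%s%02d", if (axis == "row") "R" else "C", index)
    if (is.null(pools[[id]])) {
      pools[[id]] <<- list(pool_id = id, axis = axis, index = index,
                           reads = character(0))
    }
    id
  }
  for (cl in clones) {
    get_pool("row", cl$row); get_pool("col", cl$col)
  }
  truth <- list()
  for (cl in clones) {
    n_reads <- max(1L, as.integer(round(cfg$coverage * nchar(cl$seq) / rl)))
    starts <- sample.int(nchar(cl$seq) - rl + 1L, n_reads, replace = TRUE)
    seqs <- substring(cl$seq, starts, starts + rl - 1L)
    ids <- sprintf("%s_r%05d", cl$clone_id, seq_len(n_reads))
    to_row <- runif(n_reads) < 0.5
    rid <- get_pool("row", cl$row); cid <- get_pool("col", cl$col)
    r1 <- setNames(seqs[to_row], ids[to_row])
    r2 <- setNames(seqs[!to_row], ids[!to_row])
    pools[[rid]]$reads <- c(pools[[rid]]$reads, r1)
    pools[[cid]]$reads <- c(pools[[cid]]$reads, r2)
    truth[[cl$clone_id]] <- data.frame(read_id = ids, clone_id = cl$clone_id,
                                       row = cl$row, col = cl$col,
                                       start = starts, stringsAsFactors = FALSE)
  }
  pools <- lapply(pools, function(p) structure(p, class = "pooled_read_set"))
  list(pools = pools, truth = do.call(rbind, truth))
}

#' @export
print.pooled_read_set <- function(x, ...) {
  cat(sprintf("pooled_read_set %s (%s %d): %d reads\n", x$pool_id, x$axis,
              x$index, length(x$reads)))
  invisible(x)
}

#' Simulate an overgo probe hit table
#'
#' Emulates hybridization screening data: ~40 bp probes located on the
#' template (with the length of their identical stretch) and their hit
#' counts against a large polyploid clone library. Planted structure per
#' candidate clone: a pair of single-copy probes within `max_pair_distance`
#' on the template, each hybridizing the candidate plus 9-11 library
#' homologs (the expected 10-12 homologous copies in a ~12x polyploid).
#' Noise probes carry multiple template hits, sub-threshold identical
#' stretches, or out-of-band copy numbers.
#'
#' @param template a `template_genome`.
#' @param clones result of [simulate_polyploid_clones()].
#' @param n_probes total number of probes (must cover the planted structure).
#' @param cfg a [sim_config].
#' @param max_pair_distance template distance between the planted probe pair.
#' @return a `probe_hit_table`: list with data.frames `template_hits`
#'   (`probe_id, chrom, position, identical_length`), `polyploid_counts`
#'   (`probe_id, clone_id`), and `truth` (`probe_id, class, clone_id`).
#' @export
simulate_probe_table <- function(template, clones, n_probes = 200L,
                                 cfg = template$cfg,
                                 max_pair_distance = 50000L) {
  if (!is.null(clones$clones)) clones <- clones$clones
  n_planted <- 2L * length(clones)
  if (n_probes < n_planted + 10L) {
    stop("simulate_probe_table: n_probes smaller than the planted structure",
         call. = FALSE)
  }
  th <- list(); pc <- list(); tr <- list()
  pid <- 0L
  next_id <- function() { pid <<- pid + 1L; sprintf("OV%04d", pid) }
  hom <- 0L
  add_homs <- function(p, n) {
    ids <- sprintf("HOM%05d", hom + seq_len(n)); hom <<- hom + n
    pc[[length(pc) + 1]] <<- data.frame(probe_id = p, clone_id = ids,
                                        stringsAsFactors = FALSE)
  }
  L <- cfg$chrom_length
  for (cl in clones) {
    span <- cl$t_end - cl$t_start - max_pair_distance
    pos_a <- cl$t_start + sample.int(max(1L, cl$t_end - cl$t_start - 60000L), 1)
    gap <- sample(5000:(max_pair_distance - 1000L), 1)
    pos_b <- min(pos_a + gap, cl$t_end - 100L)
    for (pos in c(pos_a, pos_b)) {
      p <- next_id()
      th[[length(th) + 1]] <- data.frame(probe_id = p, chrom = cl$chrom,
                                         position = pos,
                                         identical_length = sample(38:40, 1),
                                         stringsAsFactors = FALSE)
      pc[[length(pc) + 1]] <- data.frame(probe_id = p, clone_id = cl$clone_id,
                                         stringsAsFactors = FALSE)
      add_homs(p, sample(9:11, 1))
      tr[[length(tr) + 1]] <- data.frame(probe_id = p, class = "planted_pair",
                                         clone_id = cl$clone_id,
                                         stringsAsFactors = FALSE)
    }
  }
  n_noise <- n_probes - pid
  kinds <- sample(c("multi_template", "short_identity", "out_of_band",
                    "isolated_single"), n_noise, replace = TRUE)
  for (kind in kinds) {
    p <- next_id()
    chrom <- sprintf("chr%02d", sample.int(cfg$n_chromosomes, 1))
    pos <- sample.int(L - 100L, 1)
    if (kind == "multi_template") {
      k <- sample(2:4, 1)
      for (j in seq_len(k)) {
        th[[length(th) + 1]] <- data.frame(probe_id = p,
                                           chrom = sprintf("chr%02d", sample.int(cfg$n_chromosomes, 1)),
                                           position = sample.int(L - 100L, 1),
                                           identical_length = sample(36:40, 1),
                                           stringsAsFactors = FALSE)
      }
      add_homs(p, sample(4:20, 1))
    } else if (kind == "short_identity") {
      th[[length(th) + 1]] <- data.frame(probe_id = p, chrom = chrom,
                                         position = pos,
                                         identical_length = sample(25:34, 1),
                                         stringsAsFactors = FALSE)
      add_homs(p, sample(4:20, 1))
    } else if (kind == "out_of_band") {
      th[[length(th) + 1]] <- data.frame(probe_id = p, chrom = chrom,
                                         position = pos,
                                         identical_length = sample(36:40, 1),
                                         stringsAsFactors = FALSE)
      add_homs(p, sample(c(1:3, 21:30), 1))
    } else {
      th[[length(th) + 1]] <- data.frame(probe_id = p, chrom = chrom,
                                         position = pos,
                                         identical_length = sample(36:40, 1),
                                         stringsAsFactors = FALSE)
      add_homs(p, sample(4:20, 1))
    }
    tr[[length(tr) + 1]] <- data.frame(probe_id = p, class = kind,
                                       clone_id = NA_character_,
                                       stringsAsFactors = FALSE)
  }
  structure(list(template_hits = do.call(rbind, th),
                 polyploid_counts = do.call(rbind, pc),
                 truth = do.call(rbind, tr)),
            class = "probe_hit_table")
}

#' Fragment a clone into contigs
#'
#' Emulates the contig structure of a shotgun assembly: cuts the clone into
#' `n_frags` pieces at intergenic points (optionally guaranteeing at least
#' one gene per fragment), reverse-complements a fraction of them, shuffles
#' their order, and returns the pieces with ground truth.
#'
#' @param clone a `bac_clone`.
#' @param n_frags number of fragments.
#' @param revcomp_frac fraction of fragments stored reverse-complemented.
#' @param ensure_gene cut only between genes so every fragment keeps at
#'   least one gene anchor (requires `n_frags <=` number of genes).
#' @return list with `contigs` (a [seq_set], shuffled) and `truth`
#'   (data.frame `contig_id, start, end, rc, rank`).
#' @export
fragment_clone <- function(clone, n_frags, revcomp_frac = 0.1,
                           ensure_gene = TRUE) {
  n <- nchar(clone$seq)
  if (ensure_gene) {
    g <- clone$genes[order(clone$genes$start), , drop = FALSE]
    if (n_frags > nrow(g)) {
      stop("fragment_clone: need at least one gene per fragment", call. = FALSE)
    }
    # choose n_frags-1 distinct inter-gene gaps and cut at their midpoints
    gaps <- data.frame(lo = head(g$end, -1) + 1L, hi = tail(g$start, -1) - 1L)
    gaps <- gaps[gaps$hi - gaps$lo > 10, , drop = FALSE]
    pick <- sort(sample(seq_len(nrow(gaps)), n_frags - 1L))
    cuts <- as.integer(round((gaps$lo[pick] + gaps$hi[pick]) / 2))
  } else {
    cuts <- sort(sample(seq(1000L, n - 1000L), n_frags - 1L))
  }
  bounds <- c(0L, cuts, n)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  ids <- sprintf("%s_ctg%02d", clone$clone_id, seq_along(starts))
  rc <- runif(length(ids)) < revcomp_frac
  seqs <- substring(clone$seq, starts, ends)
  seqs[rc] <- revcomp(seqs[rc])
  ord <- sample(seq_along(ids))
  contigs <- seq_set(setNames(seqs[ord], ids[ord]))
  truth <- data.frame(contig_id = ids, start = starts, end = ends, rc = rc,
                      rank = seq_along(ids), stringsAsFactors = FALSE)
  list(contigs = contigs, truth = truth)
}
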