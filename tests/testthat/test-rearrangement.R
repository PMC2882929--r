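test_that("a reverse-complemented middle block is called as one inversion", {
  set.seed(61)
  tpl <- random_seqs(1, 30000, "chr")
  s <- unclass(tpl)[[1]]
  inv <- revcomp(substr(s, 12001, 12600))
  clone <- paste0(substr(s, 5000, 12000), inv, substr(s, 12601, 25000))
  hits <- seed_extend_align(seq_set(c(q = clone)), tpl)
  ev <- classify_rearrangements(hits)
  expect_identical(ev$class, "inversion")
  expect_lt(abs(ev$length - 600), 60)
  expect_identical(ev$strand, "-")
})

test_that("a block imported from another chromosome is a translocation", {
  set.seed(62)
  tpl <- random_seqs(2, 30000, "chr")
  s1 <- unclass(tpl)[[1]]; s2 <- unclass(tpl)[[2]]
  block <- substr(s2, 10000, 10500)
  clone <- paste0(substr(s1, 5000, 15000), block, substr(s1, 15001, 25000))
  hits <- seed_extend_align(seq_set(c(q = clone)), tpl)
  ev <- classify_rearrangements(hits)
  expect_identical(ev$class, "translocation")
  expect_identical(ev$t_chrom, "chr2")
  # the same block reverse-complemented is an inverted translocation
  clone2 <- paste0(substr(s1, 5000, 15000), revcomp(block),
                   substr(s1, 15001, 25000))
  ev2 <- classify_rearrangements(seed_extend_align(seq_set(c(q = clone2)), tpl))
  expect_identical(ev2$class, "inverted_translocation")
})

test_that("tandem copies are read as duplications with the correct polarity", {
  set.seed(63)
  tpl <- random_seqs(1, 30000, "chr")
  s <- unclass(tpl)[[1]]
  blk <- substr(s, 12001, 12500)
  # extra copy in the query
  cloneQ <- paste0(substr(s, 5000, 12500), blk, substr(s, 12501, 25000))
  evQ <- classify_rearrangements(seed_extend_align(seq_set(c(q = cloneQ)), tpl))
  expect_identical(evQ$class, "duplication_query")
  expect_lt(abs(evQ$length - 500), 60)
  # clone carries one copy where the template carries two
  tpl2 <- seq_set(c(chr = paste0(substr(s, 1, 12500), blk,
                                 substr(s, 12501, 30000))))
  cloneT <- substr(s, 5000, 25000)
  evT <- classify_rearrangements(seed_extend_align(seq_set(c(q = cloneT)), tpl2))
  expect_identical(evT$class, "duplication_template")
  expect_lt(abs(evT$length - 500), 60)
})

test_that("an implanted spectrum is recovered and classes partition the evidence", {
  set.seed(64)
  cfg <- sim_config(n_chromosomes = 5L, chrom_length = 150000L,
                    insert_size_range = c(40000L, 55000L), grid = c(2L, 5L),
                    n_clones = 10L, coverage = 8, seed = 64)
  tpl <- simulate_template(cfg)
  cl <- simulate_polyploid_clones(tpl, cfg)
  tmasked <- mask_from_features(tpl$seqs, tpl$features)
  called <- list()
  for (clone in cl$clones) {
    mk <- mask_repeats(seq_set(setNames(clone$seq, clone$clone_id)),
                       tpl$library)
    hits <- seed_extend_align(mk$seqs, tmasked)
    ev <- classify_rearrangements(hits)
    if (nrow(ev)) {
      ev$clone_id <- clone$clone_id
      called[[length(called) + 1]] <- ev
    }
  }
  called <- do.call(rbind, called)
  sc <- score_event_recovery(called, cl$truth$events)
  expect_gte(sc$precision, 0.9)
  expect_gte(sc$recall, 0.9)
  # classification is a partition: no called interval assigned twice
  for (cid in unique(called$clone_id)) {
    e <- called[called$clone_id == cid, ]
    if (nrow(e) < 2) next
    o <- order(e$q_start)
    overlap <- e$q_start[o][-1] <= e$q_end[o][-nrow(e)] - 50
    expect_false(any(overlap))
  }
})

test_that("class counts survive a global reverse-complement of the clone", {
  set.seed(65)
  tpl <- random_seqs(1, 30000, "chr")
  s <- unclass(tpl)[[1]]
  inv <- revcomp(substr(s, 12001, 12600))
  clone <- paste0(substr(s, 5000, 12000), inv, substr(s, 12601, 25000))
  ev1 <- classify_rearrangements(seed_extend_align(seq_set(c(q = clone)), tpl))
  ev2 <- classify_rearrangements(seed_extend_align(seq_set(c(q = revcomp(clone))), tpl))
  expect_identical(table(ev1$class), table(ev2$class))
})

test_that("event summaries reproduce the published per-class arithmetic", {
  lens <- function(total, n) {
    base <- total %/% n
    out <- rep(base, n)
    out[1] <- out[1] + total - sum(out)
    out
  }
  events <- rbind(
    data.frame(class = "translocation", length = lens(1925, 7)),
    data.frame(class = "inverted_translocation", length = lens(1566, 4)),
    data.frame(class = "inversion", length = lens(842, 3)),
    data.frame(class = "duplication_query", length = lens(12150, 26)),
    data.frame(class = "duplication_template", length = lens(4595, 14)))
  s <- summarize_events(events)
  expect_identical(s$mean_bp[s$class == "translocation"], 275L)
  expect_identical(s$mean_bp[s$class == "inverted_translocation"], 392L)
  expect_identical(s$mean_bp[s$class == "inversion"], 281L)
  expect_identical(s$mean_bp[s$class == "duplication_query"], 467L)
  expect_identical(s$mean_bp[s$class == "duplication_template"], 328L)
  tot <- s[s$class == "Total", ]
  expect_equal(tot$total_bp, 21078)
  expect_equal(tot$n_events, 54L)
  expect_identical(tot$mean_bp, 390L)
  # single event: mean equals its length; empty classes report n = 0
  s1 <- summarize_events(data.frame(class = "inversion", length = 123L))
  expect_identical(s1$mean_bp[s1$class == "inversion"], 123L)
  expect_identical(s1$n_events[s1$class == "translocation"], 0L)
})

test_that("tandem gene arrays are detected with per-genome copy numbers", {
  gq <- data.frame(gene_id = c("q1", "q2", "q3"), seqid = "ctg",
                   start = c(100, 6000, 90000), end = c(500, 6400, 90400),
                   strand = "+", stringsAsFactors = FALSE)
  gt <- data.frame(gene_id = c("t1", "t2", "t3", "t4"), seqid = "chr7",
                   start = c(100, 1200, 2500, 50000),
                   end = c(500, 1600, 2900, 50400),
                   strand = "+", stringsAsFactors = FALSE)
  # three adjacent template copies of q1's gene, one copy in the query
  om <- data.frame(gene_id_query = c("q1", "q1", "q1", "q3"),
                   gene_id_template = c("t1", "t2", "t3", "t4"),
                   stringsAsFactors = FALSE)
  td <- detect_tandem_duplications(gq, gt, om)
  expect_identical(nrow(td), 1L)
  expect_identical(td$copies_query, 1L)
  expect_identical(td$copies_template, 3L)
  # equal single copies produce no row
  om2 <- data.frame(gene_id_query = "q3", gene_id_template = "t4")
  expect_identical(nrow(detect_tandem_duplications(gq, gt, om2)), 0L)
  # adjacent query copies mapping to one template gene
  om3 <- data.frame(gene_id_query = c("q1", "q2"), gene_id_template = "t4")
  td3 <- detect_tandem_duplications(gq, gt, om3)
  expect_identical(td3$copies_query, 2L)
  expect_identical(td3$copies_template, 1L)
})
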