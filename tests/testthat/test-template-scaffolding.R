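test_that("contained and duplicated contigs are removed, disjoint ones kept", {
  set.seed(51)
  A <- paste(sample(c("A", "C", "G", "T"), 8000, TRUE), collapse = "")
  C <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  s <- seq_set(c(A = A, B = substr(A, 2000, 4500), C = C))
  dd <- dedupe_contigs(s)
  expect_setequal(names(dd), c("A", "C"))
  expect_identical(attr(dd, "removed")$contig_id, "B")
  expect_identical(attr(dd, "removed")$contained_in, "A")
})

test_that("planted redundancy is removed exactly on a synthetic clone", {
  cfg <- tiny_cfg(rearrangement_spectrum = zero_spectrum(), seed = 52)
  tpl <- simulate_template(cfg)
  cl <- simulate_polyploid_clones(tpl, cfg)
  ngenes <- vapply(cl$clones, function(x) nrow(x$genes), numeric(1))
  clone <- cl$clones[[which.max(ngenes)]]
  fr <- fragment_clone(clone, min(4L, nrow(clone$genes)), revcomp_frac = 0)
  contigs <- unclass(fr$contigs)
  # add redundant assemblies: a contained piece and a near-duplicate
  tr <- fr$truth[order(fr$truth$start), ]
  big <- contigs[[tr$contig_id[1]]]
  contigs[["redundant1"]] <- substr(big, 200, round(nchar(big) * 0.8))
  contigs[["redundant2"]] <- mutated_copy(contigs[[tr$contig_id[2]]], 0.01)
  dd <- dedupe_contigs(seq_set(contigs))
  expect_setequal(names(dd), fr$truth$contig_id)
})

test_that("shuffled, partly reverse-complemented fragments are re-ordered exactly", {
  cfg <- tiny_cfg(rearrangement_spectrum = zero_spectrum(), seed = 53)
  tpl <- simulate_template(cfg)
  cl <- simulate_polyploid_clones(tpl, cfg)
  tmasked <- mask_from_features(tpl$seqs, tpl$features)
  for (clone in cl$clones) {
    n <- min(5L, nrow(clone$genes))
    if (n < 2) next
    fr <- fragment_clone(clone, n, revcomp_frac = 0.3)
    mk <- mask_repeats(fr$contigs, tpl$library)
    lay <- order_contigs(mk$seqs, tmasked, clone_id = clone$clone_id)
    tr <- fr$truth[order(fr$truth$start), ]
    expect_identical(lay$placed$contig_id, tr$contig_id)
    expect_identical(lay$placed$orientation, ifelse(tr$rc, "-", "+"))
    # layout invariant to contig input order
    lay2 <- order_contigs(mk$seqs[rev(seq_along(mk$seqs))], tmasked,
                          clone_id = clone$clone_id)
    expect_identical(lay2$placed$contig_id, lay$placed$contig_id)
  }
})

test_that("anchorless and two-locus contigs are left unplaced with reasons", {
  set.seed(54)
  tpl <- random_seqs(2, 30000, "chr")
  s1 <- unclass(tpl)[[1]]; s2 <- unclass(tpl)[[2]]
  contigs <- seq_set(c(
    good = substr(s1, 5000, 12000),
    alien = paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = ""),
    both = paste0(substr(s1, 20000, 22000), substr(s2, 10000, 12000))))
  lay <- order_contigs(contigs, tpl)
  expect_identical(lay$placed$contig_id, "good")
  expect_identical(lay$unplaced$reason[lay$unplaced$contig_id == "alien"],
                   "no_anchor")
  expect_identical(lay$unplaced$reason[lay$unplaced$contig_id == "both"],
                   "multi_locus")
})

test_that("gap estimation uses template projections with the 2 kb boundary", {
  lay <- structure(list(
    clone_id = "x",
    placed = data.frame(contig_id = c("a", "b", "c", "d"),
                        length = c(10000L, 8000L, 6000L, 5000L),
                        orientation = "+", chrom = "chr01",
                        t_start = c(1L, 12001L, 22000L, 26000L),
                        t_end = c(10000L, 19999L, 27000L, 30000L),
                        weight = 1, q_aligned = 1L,
                        gap_after = NA_integer_, gap_flag = NA_character_,
                        stringsAsFactors = FALSE),
    unplaced = data.frame(), spans = c(spanned_query_bp = 1,
                                       spanned_template_bp = 1)),
    class = "contig_layout")
  lay <- estimate_gaps(lay)
  expect_identical(lay$placed$gap_after[1:3], c(2000L, 2000L, -1001L))
  # exactly 2000 is NOT closable (strictly less than 2 kb); overlaps flagged
  expect_identical(lay$placed$gap_flag[1:3],
                   c("ok", "ok", "overlap_suspected"))
  lay$placed$t_start[2] <- 11000L
  lay$placed$gap_after[] <- NA_integer_
  lay <- estimate_gaps(lay)
  expect_identical(lay$placed$gap_after[1], 999L)
  expect_identical(lay$placed$gap_flag[1], "closable")
  expect_error(estimate_gaps(structure(list(placed = data.frame()),
                                       class = "contig_layout")), "empty")
})

test_that("estimated gaps match the truth on synthetic fragmentation", {
  cfg <- tiny_cfg(rearrangement_spectrum = zero_spectrum(), target_ks = 0,
                  indel_rate = 0, expansion_bias = 0,
                  repeat_fraction_query = 0, specific_gene_rate = 0,
                  seed = 55)
  tpl <- simulate_template(cfg)
  cl <- simulate_polyploid_clones(tpl, cfg)
  clone <- cl$clones[[1]]
  # drop the middle fragment: the remaining gap must equal its length
  fr <- fragment_clone(clone, 3L, revcomp_frac = 0)
  tr <- fr$truth[order(fr$truth$start), ]
  keep <- fr$contigs[c(tr$contig_id[1], tr$contig_id[3])]
  tmasked <- mask_from_features(tpl$seqs, tpl$features)
  mk <- mask_repeats(keep, tpl$library)
  lay <- estimate_gaps(order_contigs(mk$seqs, tmasked))
  true_gap <- tr$end[2] - tr$start[2] + 1L
  expect_lt(abs(lay$placed$gap_after[1] - true_gap), 50)
})

test_that("summary fractions reproduce the published arithmetic", {
  tab <- data.frame(assembled_bp = 2609910, unambiguous_bp = 1989000,
                    ordered_bp = 1451000, spanned_query_bp = 985845,
                    spanned_template_bp = 1189649)
  s <- summarize_layouts(tab, insert_bp = 1855000)
  expect_identical(round(100 * s$ordered_fraction, 1), 78.2)
  expect_identical(round(100 * s$aligned_fraction, 1), 53.1)
  expect_identical(round(100 * s$expansion_fraction, 1), 20.7)
  expect_error(summarize_layouts(tab, insert_bp = 0), "zero insert")
})
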