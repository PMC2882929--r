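test_that("a planted full-length element is masked under its family", {
  set.seed(71)
  lib <- repeat_library()
  copia <- unclass(lib)[["LTR/Copia"]]
  backbone <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
  s <- seq_set(c(x = paste0(substr(backbone, 1, 4000), copia,
                            substr(backbone, 4001, 10000))))
  mk <- mask_repeats(s, lib)
  row <- mk$summary[mk$summary$family == "LTR/Copia", ]
  expect_gte(row$masked_bp, nchar(copia) - 20)
  expect_equal(row$fraction, row$masked_bp / (10000 + nchar(copia)))
  masked_run <- regmatches(unclass(mk$seqs)[[1]],
                           regexpr("[acgt]+", unclass(mk$seqs)[[1]]))
  expect_gte(nchar(masked_run), nchar(copia) - 20)
})

test_that("an empty library masks nothing beyond simple/low-complexity scans", {
  set.seed(72)
  s <- random_seqs(1, 5000)
  mk <- mask_repeats(s, seq_set(character(0)))
  fams <- repeat_taxonomy()
  expect_true(all(mk$summary$masked_bp[mk$summary$family %in% fams] == 0))
  expect_identical(unclass(mk$seqs)[[1]], unclass(s)[[1]])
})

test_that("masking is idempotent and families never double-claim bases", {
  cfg <- tiny_cfg(seed = 73)
  tpl <- simulate_template(cfg)
  s <- tpl$seqs[1]
  mk1 <- mask_repeats(s, tpl$library)
  mk2 <- mask_repeats(mk1$seqs, tpl$library)
  expect_identical(unclass(mk2$seqs), unclass(mk1$seqs))
  fams <- repeat_taxonomy()
  fam_total <- sum(mk1$summary$masked_bp[mk1$summary$family %in% fams])
  masked_bases <- sum(strsplit(unclass(mk1$seqs)[[1]], "")[[1]] %in%
                        c("a", "c", "g", "t"))
  expect_identical(as.integer(fam_total), as.integer(masked_bases))
  expect_lte(fam_total, sum(seq_lengths(s)))
})

test_that("an implanted family mixture is recovered within 2 points per category", {
  cfg <- sim_config(n_chromosomes = 2L, chrom_length = 200000L,
                    insert_size_range = c(30000L, 40000L), grid = c(1L, 2L),
                    n_clones = 2L, seed = 74)
  tpl <- simulate_template(cfg)
  mk <- mask_repeats(tpl$seqs, tpl$library)
  total <- sum(seq_lengths(tpl$seqs))
  tr <- tpl$truth$repeats
  tr$bp <- tr$end - tr$start + 1
  for (fam in repeat_taxonomy()) {
    truth_frac <- sum(tr$bp[tr$family == fam]) / total
    got_frac <- mk$summary$fraction[mk$summary$family == fam]
    expect_lt(abs(got_frac - truth_frac), 0.02)
  }
  tot_truth <- sum(tr$bp) / total
  fams <- repeat_taxonomy()
  tot_got <- sum(mk$summary$fraction[mk$summary$family %in% fams])
  expect_lt(abs(tot_got - tot_truth), 0.02)
})

test_that("SSR detection thresholds and flanks behave as specified", {
  set.seed(75)
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  s <- seq_set(c(x = paste0(pad(300), "G", strrep("AC", 6), "G", pad(300),
                            "C", strrep("A", 11), "C", pad(300))))
  out <- detect_ssrs(s)
  expect_identical(nrow(out), 1L) # 11 x A is below the mono threshold of 12
  expect_identical(out$motif, "AC")
  expect_equal(out$copy_number, 6)
  expect_equal(out$copy_number * out$motif_len, out$end - out$start + 1)
  expect_identical(nchar(out$left_flank), 200L)
  expect_false(out$flank_truncated)
  # flank truncation at a sequence end is flagged
  s2 <- seq_set(c(y = paste0(strrep("AG", 8), pad(400))))
  out2 <- detect_ssrs(s2)
  expect_true(out2$flank_truncated[1])
  expect_identical(out2$left_flank[1], "")
})

test_that("SSR scan agrees with brute-force enumeration on random sequence", {
  set.seed(76)
  for (rep in 1:3) {
    base <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
    # implant a few runs so there is signal
    base <- paste0(substr(base, 1, 3000), strrep("AGC", 5),
                   substr(base, 3001, 6000), strrep("AT", 7),
                   substr(base, 6001, 10000))
    got <- detect_ssrs(seq_set(c(x = base)))
    brute <- brute_ssrs(base)
    # every brute maximal run must be covered by a reported locus
    # (after overlap resolution) and vice versa
    for (i in seq_len(nrow(brute))) {
      expect_true(any(got$start <= brute$start[i] & got$end >= brute$start[i]))
    }
    for (i in seq_len(nrow(got))) {
      expect_true(any(brute$start == got$start[i] & brute$end == got$end[i]))
    }
  }
})

test_that("SSR loci are strand-symmetric up to coordinate reflection", {
  set.seed(77)
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  s <- paste0(pad(500), strrep("AAG", 6), pad(500))
  f <- detect_ssrs(seq_set(c(x = s)))
  r <- detect_ssrs(seq_set(c(x = revcomp(s))))
  expect_identical(nrow(f), nrow(r))
  expect_identical(f$motif, r$motif) # canonical motif
  n <- nchar(s)
  expect_identical(sort(n - f$end + 1L), sort(r$start))
})

test_that("motif canonicalization picks the smallest rotation over strands", {
  expect_identical(canonical_motif("GA"), "AG")
  expect_identical(canonical_motif("CT"), "AG") # reverse complement of AG
  expect_identical(canonical_motif("TTA"), "AAT")
})
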