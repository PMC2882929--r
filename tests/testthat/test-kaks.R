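test_that("codon alignment handles identity, deletions and rejects stops", {
  set.seed(81)
  cds <- polysynt:::random_sense_cds(80)
  al <- align_codons(cds, cds)
  expect_false(grepl("-", al$a, fixed = TRUE))
  expect_false(grepl("-", al$b, fixed = TRUE))
  k <- ng86(al)
  expect_identical(k$Ks, 0)
  expect_identical(k$Ka, 0)
  # one deleted codon: a single in-frame triplet gap
  cds2 <- paste0(substr(cds, 1, 120), substr(cds, 124, nchar(cds)))
  al2 <- align_codons(cds, cds2)
  expect_identical(nchar(al2$b), nchar(al2$a))
  expect_true(grepl("---", al2$b, fixed = TRUE))
  expect_identical(nchar(gsub("[^-]", "", al2$b)), 3L)
  # an internal stop rejects the pair
  bad <- paste0(substr(cds, 1, 30), "TAA", substr(cds, 34, nchar(cds)))
  expect_error(align_codons(cds, bad), "internal stop")
})

test_that("back-mapped DNA alignments reproduce the protein alignment", {
  set.seed(82)
  for (rep in 1:5) {
    a <- polysynt:::random_sense_cds(60)
    x <- strsplit(a, "")[[1]]
    b <- paste(polysynt:::mutate_cds_chars(x, 0.05, 0.5), collapse = "")
    if (sample(2, 1) == 1) b <- paste0(substr(b, 1, 90), substr(b, 94, nchar(b)))
    al <- align_codons(a, b)
    retrans <- function(dna) {
      n <- nchar(dna)
      cods <- substring(dna, seq(1, n, 3), seq(3, n, 3))
      paste(ifelse(cods == "---", "-",
                   vapply(cods, function(cc) translate_cds(cc), character(1))),
            collapse = "")
    }
    expect_identical(retrans(al$a), sub("\\*$", "", al$protein_a))
    expect_identical(retrans(al$b), sub("\\*$", "", al$protein_b))
  }
})

test_that("NG86 is symmetric and conserves site totals", {
  set.seed(83)
  for (rep in 1:10) {
    a <- polysynt:::random_sense_cds(50)
    b <- paste(polysynt:::mutate_cds_chars(strsplit(a, "")[[1]], 0.08, 0.6),
               collapse = "")
    k1 <- ng86(list(a = a, b = b))
    k2 <- ng86(list(a = b, b = a))
    expect_equal(k1$Ks, k2$Ks, tolerance = 1e-12)
    expect_equal(k1$Ka, k2$Ka, tolerance = 1e-12)
    expect_equal(k1$S + k1$N, 3 * k1$n_codons_used, tolerance = 1e-9)
  }
})

test_that("NG86 matches the exhaustive pathway oracle", {
  set.seed(84)
  for (rep in 1:50) {
    a <- polysynt:::random_sense_cds(40)
    b <- paste(polysynt:::mutate_cds_chars(strsplit(a, "")[[1]],
                                           runif(1, 0.02, 0.25), 0.7),
               collapse = "")
    got <- ng86(list(a = a, b = b))
    want <- oracle_ng86(toupper(a), toupper(b))
    expect_equal(got$Ks, want$Ks, tolerance = 1e-9)
    expect_equal(got$Ka, want$Ka, tolerance = 1e-9)
    expect_equal(got$Sd, want$Sd, tolerance = 1e-9)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-9)
  }
})

test_that("saturated or degenerate alignments raise informative errors", {
  expect_error(ng86(list(a = "ATG", b = "ATGATG")), "equal length")
  expect_error(estimate_divergence(numeric(0)), "empty")
})

test_that("the molecular clock reproduces published datings and is linear", {
  expect_identical(estimate_divergence(0.10)$time_mya, 7.7)
  expect_identical(estimate_divergence(0.53)$time_mya, 40.8)
  expect_identical(estimate_divergence(0.58)$time_mya, 44.6)
  expect_identical(estimate_divergence(0)$time_mya, 0)
  set.seed(85)
  ks <- runif(21, 0.01, 0.6)
  for (c in c(0.5, 2)) {
    e1 <- estimate_divergence(ks)
    e2 <- estimate_divergence(c * ks)
    expect_equal(e2$time_years, c * e1$time_years, tolerance = 1e-12)
  }
  # lower-median convention for even counts
  expect_identical(estimate_divergence(c(0.1, 0.2))$median_ks, 0.1)
  expect_identical(estimate_divergence(c(0.2, 0.1, 0.4, 0.3))$median_ks, 0.2)
})

test_that("unreliable pairs are discarded with reasons", {
  set.seed(86)
  good <- polysynt:::random_sense_cds(80)
  short <- polysynt:::random_sense_cds(20)
  pairs <- data.frame(
    gene_id_query = c("g1", "g2"), gene_id_template = c("g1", "g2"),
    cds_query = c(good, short), cds_template = c(good, short),
    stringsAsFactors = FALSE)
  out <- kaks_pairs(pairs)
  expect_identical(out$gene_id_query, "g1")
  rej <- attr(out, "rejected")
  expect_identical(rej$gene_id_query, "g2")
  expect_match(rej$reason, "aligned residues")
})
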