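test_that("identity and reverse-complement anchoring behave as expected", {
  set.seed(2)
  tpl <- random_seqs(1, 50000, "chr")
  s <- unclass(tpl)[[1]]
  q <- seq_set(c(fwd = substr(s, 20001, 30000),
                 rev = revcomp(substr(s, 5001, 6000))))
  hits <- seed_extend_align(q, tpl)
  hf <- hits[hits$query_id == "fwd", ]
  expect_identical(nrow(hf), 1L)
  expect_identical(c(hf$template_start, hf$template_end), c(20001L, 30000L))
  expect_identical(c(hf$query_start, hf$query_end), c(1L, 10000L))
  expect_identical(hf$strand, "+")
  expect_equal(hf$identity, 1.0)
  hr <- hits[hits$query_id == "rev", ]
  expect_identical(c(hr$template_start, hr$template_end), c(5001L, 6000L))
  expect_identical(hr$strand, "-")
  expect_equal(hr$identity, 1.0)
})

test_that("bit scores follow the Karlin-Altschul form and filtering is monotone", {
  p <- align_params()
  expect_equal(bit_score(200, p), (p$lambda * 200 - log(p$K)) / log(2))
  set.seed(3)
  tpl <- random_seqs(1, 30000, "chr")
  s <- unclass(tpl)[[1]]
  q <- seq_set(c(a = mutated_copy(substr(s, 1000, 3000), 0.05),
                 b = mutated_copy(substr(s, 10000, 10400), 0.05)))
  lo <- seed_extend_align(q, tpl, align_params(min_bit = 100))
  hi <- seed_extend_align(q, tpl, align_params(min_bit = 400))
  expect_true(nrow(hi) <= nrow(lo))
  key <- function(h) paste(h$query_id, h$query_start, h$template_start)
  expect_true(all(key(hi) %in% key(lo)))
})

test_that("reported raw scores equal full Smith-Waterman on the hit intervals", {
  set.seed(4)
  for (rep in 1:5) {
    tpl <- random_seqs(1, 2000, "t")
    s <- unclass(tpl)[[1]]
    a <- sample(1:500, 1)
    b <- a + sample(800:1400, 1)
    q <- seq_set(setNames(mutated_copy(substr(s, a, b), runif(1, 0.01, 0.08)), "q"))
    hits <- seed_extend_align(q, tpl, align_params(min_bit = 100))
    expect_gt(nrow(hits), 0)
    for (i in seq_len(nrow(hits))) {
      qs <- substr(unclass(q)[[1]], hits$query_start[i], hits$query_end[i])
      ts <- substr(s, hits$template_start[i], hits$template_end[i])
      if (hits$strand[i] == "-") qs <- revcomp(qs)
      expect_equal(hits$raw_score[i], sw_score_oracle(qs, ts))
    }
  }
})

test_that("alignment is symmetric under joint reverse-complement", {
  set.seed(5)
  tpl <- random_seqs(1, 20000, "t")
  s <- unclass(tpl)[[1]]
  q <- seq_set(c(q = mutated_copy(substr(s, 3000, 8000), 0.04)))
  h1 <- seed_extend_align(q, tpl)
  q2 <- seq_set(c(q = revcomp(unclass(q)[[1]])))
  t2 <- seq_set(c(t = revcomp(s)))
  h2 <- seed_extend_align(q2, t2)
  expect_identical(nrow(h1), nrow(h2))
  L <- nchar(s); Lq <- nchar(unclass(q)[[1]])
  # coordinates reflect: start' = L - end + 1
  expect_setequal(L - h1$template_end + 1, h2$template_start)
  expect_setequal(Lq - h1$query_end + 1, h2$query_start)
  expect_equal(sort(h1$raw_score), sort(h2$raw_score))
})

test_that("soft-masked regions are not seeded", {
  set.seed(6)
  tpl <- random_seqs(1, 20000, "t")
  s <- unclass(tpl)[[1]]
  q <- seq_set(c(q = substr(s, 5001, 7000)))
  masked_q <- seq_set(c(q = tolower(unclass(q)[[1]])))
  expect_gt(nrow(seed_extend_align(q, tpl)), 0)
  expect_identical(nrow(seed_extend_align(masked_q, tpl)), 0L)
})

test_that("chaining matches the exhaustive best chain on small hit sets", {
  # independent brute force over all increasing subsequences
  chainable <- function(h, j, i, max_gap) {
    if (h$template_end[j] > h$template_end[i]) return(FALSE)
    if (h$template_start[i] - h$template_end[j] - 1 > max_gap) return(FALSE)
    if (h$strand[1] == "+") {
      if (h$query_start[j] >= h$query_start[i] ||
          h$query_end[j] > h$query_end[i]) return(FALSE)
      gap <- h$query_start[i] - h$query_end[j] - 1
    } else {
      if (h$query_start[j] <= h$query_start[i] ||
          h$query_end[j] < h$query_end[i]) return(FALSE)
      gap <- h$query_start[j] - h$query_end[i] - 1
    }
    gap <= max_gap
  }
  brute_best <- function(h, max_gap) {
    h <- h[order(h$template_start, h$template_end), ]
    n <- nrow(h)
    best <- 0
    recurse <- function(last, weight, rest) {
      best <<- max(best, weight)
      for (i in rest) {
        if (is.na(last) || chainable(h, last, i, max_gap)) {
          recurse(i, weight + h$bit_score[i], rest[rest > i])
        }
      }
    }
    recurse(NA, 0, seq_len(n))
    best
  }
  set.seed(8)
  for (rep in 1:6) {
    n <- sample(5:10, 1)
    ts <- sort(sample.int(50000, n))
    h <- data.frame(query_id = "q", query_start = sample.int(50000, n),
                    template_id = "t", template_start = ts,
                    strand = sample(c("+", "-"), 1), bit_score = runif(n, 10, 100))
    h$query_end <- h$query_start + sample.int(2000, n)
    h$template_end <- h$template_start + sample.int(2000, n)
    ch <- chain_anchors(h, max_gap = 20000)
    expect_equal(max(ch$weights), brute_best(h, 20000), tolerance = 1e-9)
  }
})

test_that("an inverted hit among collinear hits is excluded from the chain", {
  h <- data.frame(query_id = "q",
                  query_start = c(1L, 1001L, 2001L),
                  query_end = c(1000L, 2000L, 3000L),
                  template_id = "t",
                  template_start = c(1L, 1001L, 2001L),
                  template_end = c(1000L, 2000L, 3000L),
                  strand = c("+", "-", "+"),
                  bit_score = c(100, 100, 100), stringsAsFactors = FALSE)
  ch <- chain_anchors(h)
  expect_setequal(ch$main, c(1L, 3L))
  expect_identical(ch$off_chain, 2L)
})
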