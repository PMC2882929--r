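make_table <- function(template_hits, polyploid_counts) {
  structure(list(template_hits = template_hits,
                 polyploid_counts = polyploid_counts),
            class = "probe_hit_table")
}

test_that("single-copy filtering enforces hit count and identity boundary", {
  th <- data.frame(probe_id = c("p1", "p2", "p2", "p3", "p4"),
                   chrom = "chr01", position = c(100, 200, 300, 400, 500),
                   identical_length = c(40, 40, 40, 34, 35),
                   stringsAsFactors = FALSE)
  tab <- make_table(th, data.frame(probe_id = character(0),
                                   clone_id = character(0)))
  kept <- filter_single_copy(tab)
  expect_setequal(kept, c("p1", "p4")) # p2 multi-hit, p3 under 35 bp
  expect_identical(filter_single_copy(make_table(th[0, ], NULL)), character(0))
})

test_that("copy-number band boundaries are inclusive", {
  pc <- do.call(rbind, lapply(c(p3 = 3, p4 = 4, p20 = 20, p21 = 21),
                              function(n) NULL))
  rows <- list()
  for (nm in c("p3", "p4", "p20", "p21")) {
    n <- as.integer(sub("p", "", nm))
    rows[[nm]] <- data.frame(probe_id = nm, clone_id = sprintf("c%03d", 1:n))
  }
  tab <- make_table(NULL, do.call(rbind, rows))
  kept <- filter_copy_number(c("p3", "p4", "p20", "p21"), tab)
  expect_setequal(kept, c("p4", "p20"))
  expect_identical(filter_copy_number(character(0), tab), character(0))
})

test_that("copy-number filter agrees with brute-force counting", {
  set.seed(31)
  for (rep in 1:5) {
    probes <- paste0("p", 1:30)
    pc <- data.frame(probe_id = sample(probes, 300, replace = TRUE),
                     clone_id = paste0("c", sample.int(500, 300)),
                     stringsAsFactors = FALSE)
    pc <- unique(pc)
    tab <- make_table(NULL, pc)
    kept <- filter_copy_number(probes, tab, selection_params())
    brute <- sort(Filter(function(p) {
      n <- sum(pc$probe_id == p)
      n >= 4 && n <= 20
    }, probes))
    expect_identical(kept, brute)
  }
})

test_that("candidate clones need two probes within the distance cap", {
  th <- data.frame(probe_id = c("a", "b", "c", "d"), chrom = "chr01",
                   position = c(0, 49000, 200000, 251000),
                   identical_length = 40, stringsAsFactors = FALSE)
  pc <- data.frame(probe_id = c("a", "b", "c", "d", "a"),
                   clone_id = c("near", "near", "far", "far", "lonely"),
                   stringsAsFactors = FALSE)
  tab <- make_table(th, pc)
  sel <- select_candidate_clones(c("a", "b", "c", "d"), tab)
  expect_identical(sel$clone_id, "near") # 49 kb in, 51 kb out, 1 probe out
  expect_identical(sel$template_distance, 49000)
})

test_that("selection output is independent of row order and monotone in thresholds", {
  set.seed(32)
  cfg <- tiny_cfg(seed = 33)
  tpl <- simulate_template(cfg)
  cl <- simulate_polyploid_clones(tpl, cfg)
  pt <- simulate_probe_table(tpl, cl, n_probes = 60)
  run <- function(tab, params = selection_params()) {
    p <- filter_copy_number(filter_single_copy(tab, params), tab, params)
    select_candidate_clones(p, tab, params)
  }
  sel1 <- run(pt)
  expect_setequal(sel1$clone_id, names(cl$clones)) # planted truth recovered
  shuf <- pt
  shuf$template_hits <- shuf$template_hits[sample(nrow(shuf$template_hits)), ]
  shuf$polyploid_counts <- shuf$polyploid_counts[sample(nrow(shuf$polyploid_counts)), ]
  expect_identical(run(shuf), sel1)
  # relaxing thresholds never shrinks the probe set
  strict <- filter_single_copy(pt, selection_params(min_identical = 38))
  loose <- filter_single_copy(pt, selection_params(min_identical = 30))
  expect_true(all(strict %in% loose))
  narrow <- filter_copy_number(loose, pt, selection_params(copy_count_range = c(8, 12)))
  wide <- filter_copy_number(loose, pt, selection_params(copy_count_range = c(2, 30)))
  expect_true(all(narrow %in% wide))
})
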