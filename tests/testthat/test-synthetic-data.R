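test_that("sim_config validates proportions, grid and feasibility", {
  expect_error(sim_config(repeat_fraction_template = 1.2), "not in")
  expect_error(sim_config(coverage = 0), "coverage")
  expect_error(sim_config(grid = c(2L, 2L), n_clones = 5L), "grid")
  expect_error(sim_config(gene_density = 1 / 1600,
                          repeat_fraction_template = 0.5), "infeasible")
})

test_that("a repeat-free template contains only gene features with clean ORFs", {
  cfg <- sim_config(n_chromosomes = 1L, chrom_length = 100000L,
                    repeat_fraction_template = 0, n_ssr_per_chrom = 0L,
                    insert_size_range = c(20000L, 30000L), grid = c(1L, 1L),
                    n_clones = 1L, seed = 101)
  tpl <- simulate_template(cfg)
  expect_setequal(unique(tpl$features$type), c("gene", "CDS"))
  for (i in seq_len(nrow(tpl$truth$genes))) {
    g <- tpl$truth$genes[i, ]
    ex <- tpl$truth$exons[tpl$truth$exons$gene_id == g$gene_id, ]
    cds <- extract_cds(tpl$seqs, g$chrom, ex$start, ex$end, g$strand)
    expect_identical(cds, g$cds)
    aa <- translate_cds(cds)
    expect_false(grepl("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE))
    expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
  }
})

test_that("realized repeat fraction is close to the configured target", {
  cfg <- sim_config(n_chromosomes = 2L, chrom_length = 200000L,
                    repeat_fraction_template = 0.276, grid = c(1L, 2L),
                    n_clones = 2L, insert_size_range = c(30000L, 40000L),
                    seed = 102)
  tpl <- simulate_template(cfg)
  frac <- sum(tpl$truth$repeats$end - tpl$truth$repeats$start + 1) /
    sum(seq_lengths(tpl$seqs))
  expect_gt(frac, 0.276 - 0.03)
  expect_lt(frac, 0.276 + 0.03)
})

test_that("realized gene counts follow the configured density", {
  # distributional check: aggregate count over many seeds inside the
  # 99% band of a Poisson with the configured mean
  cfg_base <- function(seed) {
    sim_config(n_chromosomes = 1L, chrom_length = 100000L,
               repeat_fraction_template = 0, n_ssr_per_chrom = 0L,
               insert_size_range = c(20000L, 30000L), grid = c(1L, 1L),
               n_clones = 1L, seed = seed)
  }
  counts <- vapply(1:100, function(s)
    nrow(simulate_template(cfg_base(s))$truth$genes), numeric(1))
  lambda <- 100 * 100000 / 10100
  expect_gt(sum(counts), qpois(0.005, lambda))
  expect_lt(sum(counts), qpois(0.995, lambda))
})

test_that("the zero-divergence limit reproduces the template interval", {
  cfg <- tiny_cfg(target_ks = 0, indel_rate = 0, expansion_bias = 0,
                  specific_gene_rate = 0, repeat_fraction_query = 0,
                  rearrangement_spectrum = zero_spectrum(), seed = 103)
  tpl <- simulate_template(cfg)
  cl <- simulate_polyploid_clones(tpl, cfg)
  for (clone in cl$clones) {
    expect_identical(clone$seq,
                     substr(unclass(tpl$seqs)[[clone$chrom]], clone$t_start,
                            clone$t_end))
  }
})

test_that("implanted event counts match the truth bookkeeping", {
  cfg <- tiny_cfg(seed = 104)
  tpl <- simulate_template(cfg)
  cl <- simulate_polyploid_clones(tpl, cfg)
  per_clone <- table(cl$truth$events$clone_id)
  by_clone <- vapply(cl$clones, function(x) nrow(x$events), numeric(1))
  for (nm in names(per_clone)) {
    expect_identical(as.integer(per_clone[[nm]]), as.integer(by_clone[[nm]]))
  }
  # realized spectrum equals the configured counts (all implants landed)
  spec <- cfg$rearrangement_spectrum
  cnt <- table(cl$truth$events$class)
  for (cls in names(spec)) {
    expect_lte(as.integer(cnt[cls]), spec[[cls]]$n)
  }
  expect_gte(sum(cnt), 0.8 * sum(vapply(spec, `[[`, numeric(1), "n")))
})

test_that("the generator is deterministic given a seed", {
  cfg <- tiny_cfg(seed = 105)
  t1 <- simulate_template(cfg); c1 <- simulate_polyploid_clones(t1, cfg)
  t2 <- simulate_template(cfg); c2 <- simulate_polyploid_clones(t2, cfg)
  expect_identical(unclass(t1$seqs), unclass(t2$seqs))
  expect_identical(vapply(c1$clones, `[[`, character(1), "seq"),
                   vapply(c2$clones, `[[`, character(1), "seq"))
  expect_identical(c1$truth$events, c2$truth$events)
})

test_that("pooling covers the grid, conserves reads and hits target coverage", {
  cfg <- sim_config(n_chromosomes = 10L, chrom_length = 30000L,
                    insert_size_range = c(8000L, 10000L), grid = c(4L, 5L),
                    n_clones = 20L, coverage = 6, read_length = 500L,
                    repeat_fraction_template = 0.1,
                    repeat_fraction_query = 0.1,
                    rearrangement_spectrum = zero_spectrum(), seed = 106)
  tpl <- simulate_template(cfg)
  cl <- simulate_polyploid_clones(tpl, cfg)
  sp <- shear_and_pool(cl, cfg)
  expect_identical(length(sp$pools), 9L) # 4 row + 5 column pools
  n_in_pools <- sum(vapply(sp$pools, function(p) length(p$reads), numeric(1)))
  expect_identical(as.integer(n_in_pools), nrow(sp$truth)) # each read in exactly one pool
  all_ids <- unlist(lapply(sp$pools, function(p) names(p$reads)))
  expect_false(anyDuplicated(all_ids) > 0)
  expect_setequal(all_ids, sp$truth$read_id)
  # realized per-clone coverage within 15% of nominal
  for (clone in cl$clones) {
    n_reads <- sum(sp$truth$clone_id == clone$clone_id)
    cov <- n_reads * cfg$read_length / nchar(clone$seq)
    expect_gt(cov, cfg$coverage * 0.85)
    expect_lt(cov, cfg$coverage * 1.15)
  }
  expect_error(shear_and_pool(cl, sim_config(read_length = 20000L)),
               "read_length")
})

test_that("probe tables carry the planted structure", {
  cfg <- tiny_cfg(seed = 107)
  tpl <- simulate_template(cfg)
  cl <- simulate_polyploid_clones(tpl, cfg)
  pt <- simulate_probe_table(tpl, cl, n_probes = 60)
  planted <- pt$truth$probe_id[pt$truth$class == "planted_pair"]
  th_counts <- table(pt$template_hits$probe_id)
  expect_true(all(th_counts[planted] == 1)) # planted probes are single copy
  pc_counts <- table(pt$polyploid_counts$probe_id)
  expect_true(all(pc_counts[planted] >= 10 & pc_counts[planted] <= 12))
  expect_error(simulate_probe_table(tpl, cl, n_probes = 3), "planted")
})

test_that("fragmented clones keep a gene in every fragment", {
  cfg <- tiny_cfg(rearrangement_spectrum = zero_spectrum(), seed = 108)
  tpl <- simulate_template(cfg)
  cl <- simulate_polyploid_clones(tpl, cfg)
  clone <- cl$clones[[1]]
  n <- min(4L, nrow(clone$genes))
  fr <- fragment_clone(clone, n)
  expect_identical(length(fr$contigs), n)
  expect_identical(sum(seq_lengths(fr$contigs)), nchar(clone$seq))
  for (i in seq_len(nrow(fr$truth))) {
    g <- clone$genes
    expect_true(any(g$start >= fr$truth$start[i] & g$end <= fr$truth$end[i]))
  }
})
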