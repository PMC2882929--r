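# small study configurations used across tests

zero_spectrum <- function() {
  list(translocation = list(n = 0L, mean_bp = 275),
       inverted_translocation = list(n = 0L, mean_bp = 392),
       inversion = list(n = 0L, mean_bp = 281),
       duplication_query = list(n = 0L, mean_bp = 467),
       duplication_template = list(n = 0L, mean_bp = 328))
}

tiny_cfg <- function(...) {
  defaults <- list(n_chromosomes = 2L, chrom_length = 100000L,
                   insert_size_range = c(25000L, 35000L), grid = c(2L, 2L),
                   n_clones = 4L, coverage = 8, read_length = 600L)
  over <- list(...)
  do.call(sim_config, utils::modifyList(defaults, over))
}

random_seqs <- function(n, len, prefix = "s") {
  seq_set(setNames(vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1)), paste0(prefix, seq_len(n))))
}

# a mutated copy of a sequence (substitutions only)
mutated_copy <- function(s, rate) {
  x <- strsplit(s, "", fixed = TRUE)[[1]]
  idx <- which(runif(length(x)) < rate)
  for (i in idx) x[i] <- sample(setdiff(c("A", "C", "G", "T"), x[i]), 1)
  paste(x, collapse = "")
}
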