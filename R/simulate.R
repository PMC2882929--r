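#' Simulation configuration
#'
#' Conditions for the synthetic study system: a diploid multi-chromosome
#' template ("sorghum" role) and a set of diverged polyploid large-insert
#' clones ("sugarcane BAC" role), sequenced as row/column pooled shotgun
#' reads. Defaults reproduce the study conditions: ~2 Mb of clones over 20
#' chromosome arms, insert sizes 40-165 kb, 64x pooled coverage on a 4x5
#' clone grid, template/query repeat fractions 27.6% / 25.5%, target
#' synonymous divergence Ks = 0.10, and a rearrangement spectrum of
#' 7 translocations, 4 inverted translocations, 3 inversions, 26 query
#' duplications and 14 template duplications with the per-class mean sizes
#' of the study (275/392/281/467/328 bp).
#'
#' @param n_chromosomes number of template chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param gene_density genes per bp (default one gene per 10.1 kb).
#' @param repeat_fraction_template,repeat_fraction_query target repeat
#'   fractions of template and clone sequence.
#' @param target_ks target synonymous divergence of clone genes vs template.
#' @param omega acceptance probability of nonsynonymous substitutions
#'   (purifying selection; 0.35 makes Ks 0.10 coexist with ~95% exon
#'   identity).
#' @param ts_tv transition:transversion ratio of the substitution process.
#' @param indel_rate small indels per bp (intergenic only, so gene models
#'   stay in frame).
#' @param rearrangement_spectrum named list per event class with elements
#'   `n` (events across the clone set) and `mean_bp`.
#' @param min_event_bp floor of the event length distribution
#'   (`min_event_bp + geometric` keeping `mean_bp`).
#' @param expansion_bias template-side repeat excess: bp of inherited repeat
#'   sequence deleted from the clone per kb of insert (creates the net
#'   template expansion seen in alignments).
#' @param specific_gene_rate clone-specific genes per inherited gene
#'   (default 17/209).
#' @param insert_size_range clone insert size range in bp.
#' @param read_length,coverage shotgun read length (bp) and total per-clone
#'   fold coverage (split between the clone's row and column pool).
#' @param grid `c(n_rows, n_cols)` of the clone pooling grid.
#' @param n_clones number of clones (default fills the grid).
#' @param n_ssr_per_chrom planted perfect microsatellites per chromosome.
#' @param seed optional RNG seed applied by [simulate_template()].
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 10L, chrom_length = 400000L,
                       gene_density = 1 / 10100,
                       repeat_fraction_template = 0.276,
                       repeat_fraction_query = 0.255,
                       target_ks = 0.10, omega = 0.35, ts_tv = 2,
                       indel_rate = 2e-4,
                       rearrangement_spectrum = list(
                         translocation = list(n = 7L, mean_bp = 275),
                         inverted_translocation = list(n = 4L, mean_bp = 392),
                         inversion = list(n = 3L, mean_bp = 281),
                         duplication_query = list(n = 26L, mean_bp = 467),
                         duplication_template = list(n = 14L, mean_bp = 328)),
                       min_event_bp = 150L,
                       expansion_bias = 120,
                       specific_gene_rate = 17 / 209,
                       insert_size_range = c(40000L, 165000L),
                       read_length = 700L, coverage = 64,
                       grid = c(4L, 5L), n_clones = NULL,
                       n_ssr_per_chrom = 2L, seed = NULL) {
  if (is.null(n_clones)) n_clones <- as.integer(prod(grid))
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.integer(chrom_length),
              gene_density = gene_density,
              repeat_fraction_template = repeat_fraction_template,
              repeat_fraction_query = repeat_fraction_query,
              target_ks = target_ks, omega = omega, ts_tv = ts_tv,
              indel_rate = indel_rate,
              rearrangement_spectrum = rearrangement_spectrum,
              min_event_bp = as.integer(min_event_bp),
              expansion_bias = expansion_bias,
              specific_gene_rate = specific_gene_rate,
              insert_size_range = as.integer(insert_size_range),
              read_length = as.integer(read_length), coverage = coverage,
              grid = as.integer(grid), n_clones = as.integer(n_clones),
              n_ssr_per_chrom = as.integer(n_ssr_per_chrom), seed = seed)
  for (p in c("repeat_fraction_template", "repeat_fraction_query")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop("sim_config: ", p, " not in [0,1]",
                                           call. = FALSE)
  }
  if (cfg$coverage <= 0) stop("sim_config: coverage must be > 0", call. = FALSE)
  if (prod(cfg$grid) < cfg$n_clones) {
    stop("sim_config: grid must have at least n_clones cells", call. = FALSE)
  }
  # joint feasibility of gene density and repeat fraction: genes occupy about
  # 1.4 kb each on average and repeats must fit in the intergenic remainder
  gene_frac <- cfg$gene_density * 1400
  if (gene_frac + cfg$repeat_fraction_template > 0.85) {
    stop("sim_config: gene density and template repeat fraction jointly ",
         "infeasible", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# ---- substitution machinery ------------------------------------------------

.tv_map <- list(A = c("G", "C", "T"), G = c("A", "C", "T"),
                C = c("T", "A", "G"), T = c("C", "A", "G")) # [1] = transition

propose_base <- function(base, ts_tv) {
  alt <- .tv_map[[base]]
  p <- c(ts_tv, 1, 1) / (ts_tv + 2)
  alt[sample.int(3, 1, prob = p)]
}

# uniform substitutions at per-site rate `rate` on a character vector
mutate_chars <- function(x, rate, ts_tv = 2) {
  if (rate <= 0) return(x)
  idx <- which(runif(length(x)) < rate & x %in% c("A", "C", "G", "T"))
  for (i in idx) x[i] <- propose_base(x[i], ts_tv)
  x
}

mutate_dna <- function(seq, rate, ts_tv = 2) {
  paste(mutate_chars(strsplit(seq, "", fixed = TRUE)[[1]], rate, ts_tv),
        collapse = "")
}

# substitutions in coding sequence under purifying selection: synonymous
# proposals always accepted, nonsynonymous with probability omega, proposals
# creating stop codons rejected
mutate_cds_chars <- function(x, rate, omega, ts_tv = 2) {
  if (rate <= 0) return(x)
  tab <- .codon_table()
  idx <- which(runif(length(x)) < rate)
  for (i in idx) {
    ci <- (i - 1) %/% 3
    cpos <- ci * 3 + 1
    cod <- paste(x[cpos:(cpos + 2)], collapse = "")
    b <- x[i]
    if (!b %in% c("A", "C", "G", "T")) next
    nb <- propose_base(b, ts_tv)
    new <- x[cpos:(cpos + 2)]
    new[i - cpos + 1] <- nb
    newcod <- paste(new, collapse = "")
    if (is.na(tab[newcod]) || tab[newcod] == "*") next
    if (tab[newcod] == tab[cod] || runif(1) < omega) x[i] <- nb
  }
  x
}

random_sense_cds <- function(n_codons) {
  tab <- .codon_table()
  sense <- names(tab)[tab != "*" & names(tab) != "ATG"]
  stops <- names(tab)[tab == "*"]
  paste0("ATG", paste(sample(sense, n_codons - 2, replace = TRUE), collapse = ""),
         sample(stops, 1))
}

#' Calibrate the substitution rate for a target synonymous divergence
#'
#' Closed-loop calibration: finds the per-site proposal rate whose realized
#' NG86 Ks (measured with this package's own [ng86()]) matches `target_ks`
#' on a large random CDS, by root finding.
#'
#' @param target_ks target synonymous substitutions per synonymous site.
#' @param omega nonsynonymous acceptance probability.
#' @param ts_tv transition:transversion ratio.
#' @param n_codons size of the calibration CDS.
#' @return the per-site proposal rate.
#' @export
calibrate_substitution_rate <- function(target_ks, omega = 0.35, ts_tv = 2,
                                        n_codons = 4000) {
  if (target_ks <= 0) return(0)
  cds <- random_sense_cds(n_codons)
  x0 <- strsplit(cds, "", fixed = TRUE)[[1]]
  f <- function(p) {
    x1 <- mutate_cds_chars(x0, p, omega, ts_tv)
    k <- ng86(list(a = cds, b = paste(x1, collapse = "")))
    k$Ks - target_ks
  }
  # realized Ks is close to the raw proposal rate; bracket around it
  p0 <- target_ks
  lo <- p0 / 3; hi <- min(0.75, p0 * 3)
  uniroot(f, c(lo, hi), tol = p0 * 0.02)$root
}

# event length: floor + geometric, keeping the requested mean
event_len <- function(n, mean_bp, min_bp) {
  if (mean_bp <= min_bp) return(rep(as.integer(mean_bp), n))
  min_bp + rgeom(n, 1 / (mean_bp - min_bp + 1))
}

# ---- repeat library --------------------------------------------------------

repeat_taxonomy <- function() {
  c("SINE", "LINE/L1-CIN4", "LTR/Copia", "LTR/Gypsy-DIRS1",
    "DNA/hobo-Activator", "DNA/Tc1-Pogo", "DNA/En-Spm", "DNA/MuDR",
    "DNA/Tourist-Harbinger", "Unclassified")
}

#' Generate a labelled repeat consensus library
#'
#' One random consensus per family of the fixed taxonomy (SINE, LINE,
#' LTR/Copia, LTR/Gypsy, four DNA transposon superfamilies, Tourist/Harbinger
#' MITEs, Unclassified), with field-typical consensus lengths.
#'
#' @return a [seq_set] whose names are family labels.
#' @export
repeat_library <- function() {
  lens <- c("SINE" = 300, "LINE/L1-CIN4" = 1200, "LTR/Copia" = 1500,
            "LTR/Gypsy-DIRS1" = 1500, "DNA/hobo-Activator" = 700,
            "DNA/Tc1-Pogo" = 800, "DNA/En-Spm" = 1000, "DNA/MuDR" = 900,
            "DNA/Tourist-Harbinger" = 400, "Unclassified" = 600)
  seq_set(setNames(vapply(lens, random_dna, character(1)), names(lens)))
}

# family weights approximating the per-family shares observed in each genome
# (template = Gypsy-rich diploid, query = Copia-rich polyploid)
.family_weights <- function(role) {
  w <- if (role == "template") {
    c(0.13, 0.38, 1.18, 4.82, 0.20, 0.28, 1.95, 0.23, 3.93, 1.21)
  } else {
    c(0.10, 0.75, 3.53, 1.18, 0.18, 0.23, 1.20, 0.28, 2.26, 1.86)
  }
  setNames(w / sum(w), repeat_taxonomy())
}

# ---- interval allocator ----------------------------------------------------

# free: data.frame(start, end); returns list(pos, free) or NULL
alloc_block <- function(free, len, lo = -Inf, hi = Inf, margin = 30L) {
  if (!nrow(free)) return(NULL)
  s <- pmax(free$start, lo) + margin
  e <- pmin(free$end, hi) - margin
  ok <- which(e - s + 1 >= len)
  if (!length(ok)) return(NULL)
  i <- if (length(ok) == 1) ok else sample(ok, 1, prob = (e - s + 1)[ok])
  pos <- s[i] + sample.int(e[i] - s[i] + 1 - len + 1, 1) - 1
  # split the chosen free interval
  row <- free[i, ]
  keep <- free[-i, , drop = FALSE]
  left <- data.frame(start = row$start, end = pos - 1)
  right <- data.frame(start = pos + len, end = row$end)
  add <- rbind(left, right)
  add <- add[add$end - add$start + 1 >= 2 * margin, , drop = FALSE]
  list(pos = pos, free = rbind(keep, add))
}

complement_intervals <- function(starts, ends, L) {
  if (!length(starts)) return(data.frame(start = 1L, end = L))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  fs <- c(1L, ends + 1L)
  fe <- c(starts - 1L, L)
  keep <- fe >= fs
  data.frame(start = fs[keep], end = fe[keep])
}

# ---- gene models -----------------------------------------------------------

make_gene <- function(min_codons = 100, max_codons = 400) {
  n_codons <- sample(min_codons:max_codons, 1)
  cds <- random_sense_cds(n_codons)
  n_exons <- sample(1:4, 1)
  L <- nchar(cds)
  cuts <- if (n_exons > 1) sort(sample(seq(30, L - 30), n_exons - 1)) else integer(0)
  bounds <- c(0, cuts, L)
  exon_seqs <- substring(cds, bounds[-length(bounds)] + 1, bounds[-1])
  introns <- if (n_exons > 1) {
    vapply(seq_len(n_exons - 1), function(i)
      paste0("GT", random_dna(sample(60:250, 1)), "AG"), character(1))
  } else character(0)
  pieces <- character(0)
  exon_rel <- data.frame(start = integer(0), end = integer(0))
  pos <- 1L
  for (i in seq_len(n_exons)) {
    el <- nchar(exon_seqs[i])
    exon_rel <- rbind(exon_rel, data.frame(start = pos, end = pos + el - 1L))
    pieces <- c(pieces, exon_seqs[i])
    pos <- pos + el
    if (i < n_exons) {
      il <- nchar(introns[i])
      pieces <- c(pieces, introns[i])
      pos <- pos + il
    }
  }
  list(seq = paste(pieces, collapse = ""), cds = cds, exon_rel = exon_rel,
       span = pos - 1L)
}

# ---- template simulation ---------------------------------------------------

#' Simulate a diploid template genome
#'
#' Generates chromosomes carrying non-overlapping multi-exon gene models
#' (valid ORFs, no internal stops), labelled repeat copies drawn from a
#' family library until the target repeat fraction is realized, planted
#' perfect microsatellites, and tandem duplication donor loci (adjacent
#' near-identical blocks later collapsed in clones to create template-side
#' duplications). Everything is recorded in a ground-truth set.
#'
#' @param cfg a [sim_config].
#' @return a `template_genome`: list with `seqs` ([seq_set]), `features`
#'   ([feature_table] of genes, CDS exons, repeats, SSRs), `truth` (lists of
#'   data.frames: `genes`, `exons`, `repeats`, `ssrs`, `donors`), `library`
#'   (the repeat [seq_set]) and `cfg`.
#' @export
simulate_template <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  lib <- repeat_library()
  fam_w <- .family_weights("template")
  L <- cfg$chrom_length
  n_arms <- 2L * cfg$n_chromosomes
  # distribute template-duplication donors over arms, round-robin
  n_donors <- cfg$rearrangement_spectrum$duplication_template$n
  donor_mean <- cfg$rearrangement_spectrum$duplication_template$mean_bp
  donor_arm <- if (n_donors > 0) (seq_len(n_donors) - 1L) %% n_arms + 1L else integer(0)
  min_insert <- cfg$insert_size_range[1]

  seqs <- list(); feats <- list()
  genes_tr <- list(); exons_tr <- list(); reps_tr <- list()
  ssrs_tr <- list(); donors_tr <- list()
  gid <- 0L
  for (ci in seq_len(cfg$n_chromosomes)) {
    chrom <- sprintf("chr%02d", ci)
    x <- strsplit(random_dna(L), "", fixed = TRUE)[[1]]
    # gene placement: renewal process with mean spacing 1/gene_density
    spacing <- 1 / cfg$gene_density
    pos <- 1L + as.integer(rexp(1, 1 / spacing))
    g_start <- integer(0); g_end <- integer(0)
    while (TRUE) {
      g <- make_gene()
      if (pos + g$span > L - 100) break
      gid <- gid + 1L
      gene_id <- sprintf("G%04d", gid)
      strand <- sample(c("+", "-"), 1)
      gseq <- if (strand == "+") g$seq else revcomp(g$seq)
      x[pos:(pos + g$span - 1L)] <- strsplit(gseq, "", fixed = TRUE)[[1]]
      # exon coordinates on the genome (strand-aware)
      er <- g$exon_rel
      if (strand == "+") {
        es <- pos + er$start - 1L; ee <- pos + er$end - 1L
      } else {
        es <- pos + g$span - er$end; ee <- pos + g$span - er$start
        o <- order(es); es <- es[o]; ee <- ee[o]
      }
      genes_tr[[length(genes_tr) + 1]] <- data.frame(
        gene_id = gene_id, chrom = chrom, start = pos,
        end = pos + g$span - 1L, strand = strand, cds = g$cds,
        stringsAsFactors = FALSE)
      exons_tr[[length(exons_tr) + 1]] <- data.frame(
        gene_id = gene_id, chrom = chrom, start = es, end = ee,
        strand = strand, stringsAsFactors = FALSE)
      g_start <- c(g_start, pos); g_end <- c(g_end, pos + g$span - 1L)
      # mean gene span is ~1000 bp; subtract it so the renewal interval mean
      # matches 1/gene_density and realized counts are unbiased
      gap <- as.integer(rexp(1, 1 / max(1, spacing - 1000)))
      pos <- pos + g$span + gap
    }
    free <- complement_intervals(g_start, g_end, L)
    # donors for this chromosome's arms, near arm centers so clones cover them
    for (d in which(donor_arm %in% c(2L * ci - 1L, 2L * ci))) {
      arm <- donor_arm[d] - 2L * (ci - 1L)
      center <- if (arm == 1) round(L / 4) else round(3 * L / 4)
      dl <- event_len(1, donor_mean, cfg$min_event_bp)
      win <- round(min_insert * 0.3)
      a <- alloc_block(free, 2L * dl, lo = center - win, hi = center + win)
      if (is.null(a)) a <- alloc_block(free, 2L * dl)
      if (is.null(a)) next
      free <- a$free
      p1 <- a$pos
      block <- x[p1:(p1 + dl - 1L)]
      copy2 <- mutate_chars(block, 0.02, cfg$ts_tv)
      x[(p1 + dl):(p1 + 2L * dl - 1L)] <- copy2
      donors_tr[[length(donors_tr) + 1]] <- data.frame(
        donor_id = sprintf("D%03d", d), chrom = chrom, arm = arm,
        x1_start = p1, x1_end = p1 + dl - 1L,
        x2_start = p1 + dl, x2_end = p1 + 2L * dl - 1L,
        stringsAsFactors = FALSE)
    }
    # repeats until the target masked fraction is reached
    target_bp <- round(cfg$repeat_fraction_template * L)
    placed <- 0L; rix <- 0L; fails <- 0L
    while (placed < target_bp && fails < 50) {
      fam <- sample(names(fam_w), 1, prob = fam_w)
      cons <- unclass(lib)[[fam]]
      keep <- round(nchar(cons) * runif(1, 0.6, 1))
      copy <- mutate_dna(substr(cons, nchar(cons) - keep + 1, nchar(cons)),
                         runif(1, 0.05, 0.15), cfg$ts_tv)
      a <- alloc_block(free, nchar(copy))
      if (is.null(a)) { fails <- fails + 1; next }
      free <- a$free
      rix <- rix + 1L
      x[a$pos:(a$pos + nchar(copy) - 1L)] <- strsplit(copy, "", fixed = TRUE)[[1]]
      reps_tr[[length(reps_tr) + 1]] <- data.frame(
        repeat_id = sprintf("%s_R%04d", chrom, rix), chrom = chrom,
        start = a$pos, end = a$pos + nchar(copy) - 1L, family = fam,
        stringsAsFactors = FALSE)
      placed <- placed + nchar(copy)
    }
    if (target_bp > 0 && placed < target_bp * 0.8) {
      stop("simulate_template: cannot reach target repeat fraction; gene ",
           "density and repeat fraction jointly infeasible for chrom_length",
           call. = FALSE)
    }
    # microsatellites
    motifs <- c("AC", "AG", "AT", "AAG", "AGC", "ACGT")
    for (si in seq_len(cfg$n_ssr_per_chrom)) {
      mo <- sample(motifs, 1)
      nc <- sample(8:15, 1)
      run <- strrep(mo, nc)
      a <- alloc_block(free, nchar(run))
      if (is.null(a)) next
      free <- a$free
      x[a$pos:(a$pos + nchar(run) - 1L)] <- strsplit(run, "", fixed = TRUE)[[1]]
      ssrs_tr[[length(ssrs_tr) + 1]] <- data.frame(
        chrom = chrom, start = a$pos, end = a$pos + nchar(run) - 1L,
        motif = mo, copy_number = nc, stringsAsFactors = FALSE)
    }
    seqs[[chrom]] <- paste(x, collapse = "")
  }
  bindl <- function(l, proto) if (length(l)) do.call(rbind, l) else proto
  genes <- bindl(genes_tr, data.frame(gene_id = character(0), chrom = character(0),
                                      start = integer(0), end = integer(0),
                                      strand = character(0), cds = character(0)))
  exons <- bindl(exons_tr, data.frame(gene_id = character(0), chrom = character(0),
                                      start = integer(0), end = integer(0),
                                      strand = character(0)))
  reps <- bindl(reps_tr, data.frame(repeat_id = character(0), chrom = character(0),
                                    start = integer(0), end = integer(0),
                                    family = character(0)))
  ssrs <- bindl(ssrs_tr, data.frame(chrom = character(0), start = integer(0),
                                    end = integer(0), motif = character(0),
                                    copy_number = numeric(0)))
  donors <- bindl(donors_tr, data.frame(donor_id = character(0), chrom = character(0),
                                        arm = integer(0), x1_start = integer(0),
                                        x1_end = integer(0), x2_start = integer(0),
                                        x2_end = integer(0)))
  sset <- seq_set(unlist(seqs))
  ft <- rbind(
    if (nrow(genes)) data.frame(seqid = genes$chrom, source = "polysynt_sim",
                                type = "gene", start = genes$start,
                                end = genes$end, strand = genes$strand,
                                ID = genes$gene_id, family = NA_character_),
    if (nrow(exons)) data.frame(seqid = exons$chrom, source = "polysynt_sim",
                                type = "CDS", start = exons$start,
                                end = exons$end, strand = exons$strand,
                                ID = paste0(exons$gene_id, ".cds"),
                                family = NA_character_),
    if (nrow(reps)) data.frame(seqid = reps$chrom, source = "polysynt_sim",
                               type = "repeat_region", start = reps$start,
                               end = reps$end, strand = ".",
                               ID = reps$repeat_id, family = reps$family),
    if (nrow(ssrs)) data.frame(seqid = ssrs$chrom, source = "polysynt_sim",
                               type = "microsatellite", start = ssrs$start,
                               end = ssrs$end, strand = ".",
                               ID = paste0("SSR_", seq_len(nrow(ssrs))),
                               family = NA_character_))
  structure(list(seqs = sset, features = feature_table(ft, sset),
                 truth = list(genes = genes, exons = exons, repeats = reps,
                              ssrs = ssrs, donors = donors),
                 library = lib, cfg = cfg),
            class = "template_genome")
}

#' @export
print.template_genome <- function(x, ...) {
  cat(sprintf("template_genome: %d chromosome(s), %d genes, %d repeat copies, %d SSRs\n",
              length(x$seqs), nrow(x$truth$genes), nrow(x$truth$repeats),
              nrow(x$truth$ssrs)))
  invisible(x)
}
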