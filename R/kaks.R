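#' Codon-aware alignment of two CDS
#'
#' Aligns the protein translations globally (Needleman-Wunsch through
#' [Biostrings::pairwiseAlignment()] with BLOSUM62 and affine gaps) and
#' expands every protein gap back to a codon-triplet gap in the DNA, the
#' PAL2NAL strategy. Columns containing gaps or ambiguous bases are flagged
#' so that substitution counting can skip them.
#'
#' @param cds_a,cds_b DNA coding sequences; length divisible by 3, no internal
#'   stop codons (a trailing stop codon is trimmed).
#' @param gap_opening,gap_extension affine gap penalties for the protein
#'   alignment (positive costs, Biostrings convention).
#' @return a `codon_alignment`: list with aligned DNA strings `a` and `b`
#'   (with `-` gaps), the aligned protein strings, and `n_codons` aligned
#'   codon columns.
#' @export
align_codons <- function(cds_a, cds_b, gap_opening = 10, gap_extension = 1) {
  prep <- function(cds, which) {
    cds <- toupper(cds)
    if (nchar(cds) %% 3 != 0) {
      stop("align_codons: CDS ", which, " length not divisible by 3", call. = FALSE)
    }
    aa <- translate_cds(cds)
    if (endsWith(aa, "*")) {
      aa <- substr(aa, 1, nchar(aa) - 1)
      cds <- substr(cds, 1, nchar(cds) - 3)
    }
    if (grepl("*", aa, fixed = TRUE)) {
      stop("align_codons: internal stop codon in CDS ", which,
           "; pair rejected as unreliable", call. = FALSE)
    }
    list(cds = cds, aa = aa)
  }
  a <- prep(cds_a, "a")
  b <- prep(cds_b, "b")
  data("BLOSUM62", package = "Biostrings", envir = environment())
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a$aa), Biostrings::AAString(b$aa),
    type = "global", substitutionMatrix = get("BLOSUM62"),
    gapOpening = gap_opening, gapExtension = gap_extension)
  pa <- as.character(Biostrings::alignedPattern(aln))
  pb <- as.character(Biostrings::alignedSubject(aln))
  expand <- function(aa_aln, cds) {
    cols <- strsplit(aa_aln, "")[[1]]
    n <- nchar(cds)
    codons <- substring(cds, seq(1, n, 3), seq(3, n, 3))
    out <- character(length(cols))
    j <- 0
    for (i in seq_along(cols)) {
      if (cols[i] == "-") out[i] <- "---" else { j <- j + 1; out[i] <- codons[j] }
    }
    paste(out, collapse = "")
  }
  structure(list(a = expand(pa, a$cds), b = expand(pb, b$cds),
                 protein_a = pa, protein_b = pb,
                 n_codons = nchar(pa)),
            class = "codon_alignment")
}

#' Nei-Gojobori (NG86) synonymous and nonsynonymous divergence
#'
#' Classic NG86 counting on a codon alignment: synonymous site fractions per
#' codon (averaged between the two sequences), pathway-averaged difference
#' counts for multi-hit codons with stop-codon pathways excluded, and
#' Jukes-Cantor correction `d = -(3/4) log(1 - (4/3) p)` applied to both
#' proportions. Columns with gaps, ambiguous bases or stop codons are
#' excluded; codon pairs whose substitution pathways all pass through stops
#' are excluded entirely.
#'
#' @param aln a `codon_alignment` from [align_codons()], or a list with
#'   aligned DNA strings `a` and `b`.
#' @return list with `Ks`, `Ka`, `S`, `N`, `Sd`, `Nd`, `pS`, `pN`,
#'   `n_codons_used`.
#' @export
ng86 <- function(aln) {
  a <- toupper(aln$a); b <- toupper(aln$b)
  if (nchar(a) != nchar(b) || nchar(a) %% 3 != 0) {
    stop("ng86: aligned sequences must have equal length divisible by 3",
         call. = FALSE)
  }
  n <- nchar(a)
  ca <- substring(a, seq(1, n, 3), seq(3, n, 3))
  cb <- substring(b, seq(1, n, 3), seq(3, n, 3))
  ok <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  syn <- .syn_sites_table()
  tab <- .codon_table()
  ok <- ok & !is.na(tab[ca]) & tab[ca] != "*" & !is.na(tab[cb]) & tab[cb] != "*"
  ca <- ca[ok]; cb <- cb[ok]
  if (!length(ca)) stop("ng86: no ungapped codon columns", call. = FALSE)
  S <- 0; N <- 0; Sd <- 0; Nd <- 0; used <- 0
  for (i in seq_along(ca)) {
    d <- codon_pair_diffs(ca[i], cb[i])
    if (is.null(d)) next # all pathways through stops: exclude column
    s_i <- (syn[ca[i]] + syn[cb[i]]) / 2
    S <- S + s_i
    N <- N + (3 - s_i)
    Sd <- Sd + d[["sd"]]
    Nd <- Nd + d[["nd"]]
    used <- used + 1
  }
  if (S <= 0) stop("ng86: zero synonymous sites", call. = FALSE)
  pS <- unname(Sd / S)
  pN <- unname(Nd / N)
  if (pS >= 3 / 4) stop("ng86: synonymous sites saturated (pS >= 3/4)", call. = FALSE)
  if (pN >= 3 / 4) stop("ng86: nonsynonymous sites saturated (pN >= 3/4)", call. = FALSE)
  jc <- function(p) -3 / 4 * log(1 - 4 / 3 * p)
  list(Ks = jc(pS), Ka = jc(pN), S = unname(S), N = unname(N),
       Sd = unname(Sd), Nd = unname(Nd), pS = unname(pS), pN = unname(pN),
       n_codons_used = used)
}

#' Ka/Ks for a set of ortholog CDS pairs
#'
#' Convenience pipeline: codon-align each pair, discard unreliable pairs
#' (internal stops, fewer than `min_residues` aligned residues, or protein
#' identity below `min_identity`), and run [ng86()] on the rest.
#'
#' @param pairs a data.frame with columns `gene_id_query`, `gene_id_template`,
#'   `cds_query`, `cds_template`.
#' @param min_residues minimum aligned protein length.
#' @param min_identity minimum protein identity over aligned residues.
#' @return a data.frame with one row per retained pair (Ks, Ka, S, N, Sd, Nd)
#'   and an attribute `rejected` listing discarded pairs with reasons.
#' @export
kaks_pairs <- function(pairs, min_residues = 50, min_identity = 0.5) {
  res <- list(); rej <- list()
  for (i in seq_len(nrow(pairs))) {
    out <- tryCatch({
      aln <- align_codons(pairs$cds_query[i], pairs$cds_template[i])
      pa <- strsplit(aln$protein_a, "")[[1]]
      pb <- strsplit(aln$protein_b, "")[[1]]
      both <- pa != "-" & pb != "-"
      nres <- sum(both)
      ident <- if (nres > 0) sum(pa[both] == pb[both]) / nres else 0
      if (nres < min_residues) stop("fewer than ", min_residues,
                                    " aligned residues")
      if (ident < min_identity) stop("protein identity below ", min_identity)
      k <- ng86(aln)
      data.frame(gene_id_query = pairs$gene_id_query[i],
                 gene_id_template = pairs$gene_id_template[i],
                 Ks = k$Ks, Ka = k$Ka, S = k$S, N = k$N, Sd = k$Sd, Nd = k$Nd,
                 stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(out, "error")) {
      rej[[length(rej) + 1]] <- data.frame(
        gene_id_query = pairs$gene_id_query[i],
        gene_id_template = pairs$gene_id_template[i],
        reason = conditionMessage(out), stringsAsFactors = FALSE)
    } else {
      res[[length(res) + 1]] <- out
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(gene_id_query = character(0), gene_id_template = character(0),
               Ks = numeric(0), Ka = numeric(0), S = numeric(0), N = numeric(0),
               Sd = numeric(0), Nd = numeric(0), stringsAsFactors = FALSE)
  attr(out, "rejected") <- if (length(rej)) do.call(rbind, rej) else NULL
  out
}

#' Molecular-clock divergence estimate from synonymous divergence
#'
#' `T = Ks / (2 r)` with the median Ks of the ortholog set (lower median for
#' even counts) and a default synonymous substitution rate of `6.5e-9`
#' substitutions per synonymous site per year (grass lineage).
#'
#' @param ks_values numeric vector of per-pair Ks values.
#' @param rate substitutions per synonymous site per year.
#' @return list with `n_pairs`, `median_ks`, `rate`, `time_years`, `time_mya`
#'   (million years, rounded to one decimal).
#' @examples
#' estimate_divergence(0.10)$time_mya # 7.7
#' @export
estimate_divergence <- function(ks_values, rate = 6.5e-9) {
  ks_values <- ks_values[!is.na(ks_values)]
  if (!length(ks_values)) stop("estimate_divergence: empty Ks list", call. = FALSE)
  if (rate <= 0) stop("estimate_divergence: rate must be positive", call. = FALSE)
  s <- sort(ks_values)
  n <- length(s)
  med <- if (n %% 2 == 1) s[(n + 1) / 2] else s[n / 2] # lower median
  ty <- med / (2 * rate)
  structure(list(n_pairs = n, median_ks = med, rate = rate,
                 time_years = ty, time_mya = round(ty / 1e6, 1)),
            class = "divergence_estimate")
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat(sprintf("Divergence estimate: median Ks = %.4g over %d pairs -> %.1f MYa (rate %.3g /site/yr)\n",
              x$median_ks, x$n_pairs, x$time_mya, x$rate))
  invisible(x)
}
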