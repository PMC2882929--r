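# Independent oracles used to cross-check the package implementations.

# --- Smith-Waterman score oracle via Biostrings (affine gaps, same cost
# convention: a gap of length L costs gap_open + L * gap_extend)
sw_score_oracle <- function(a, b, match = 1, mismatch = -2, gap_open = 5,
                            gap_extend = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(Biostrings::DNAString(toupper(a)),
                                Biostrings::DNAString(toupper(b)),
                                type = "local", substitutionMatrix = mat,
                                gapOpening = gap_open,
                                gapExtension = gap_extend,
                                scoreOnly = TRUE)
}

# --- NG86 oracle: direct per-codon enumeration, written independently of
# the package internals (genetic code taken from Biostrings).
.oracle_env <- new.env(parent = emptyenv())

oracle_codon_sites <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  key <- paste0("s_", codon)
  if (!is.null(.oracle_env[[key]])) return(.oracle_env[[key]])
  sp <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    for (alt in setdiff(c("A", "C", "G", "T"), sp[pos])) {
      mut <- sp; mut[pos] <- alt
      mc <- paste(mut, collapse = "")
      if (gc[[mc]] != "*" && gc[[mc]] == gc[[codon]]) s <- s + 1 / 3
    }
  }
  .oracle_env[[key]] <- s
  s
}

oracle_codon_paths <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  key <- paste0("p_", c1, c2)
  if (!is.null(.oracle_env[[key]])) return(.oracle_env[[key]])
  s1 <- strsplit(c1, "")[[1]]; s2 <- strsplit(c2, "")[[1]]
  diff <- which(s1 != s2)
  res <- if (!length(diff)) {
    c(0, 0, 1)
  } else {
    acc <- c(0, 0, 0) # sd, nd, n_valid
    recurse <- function(cur, remaining, sd, nd) {
      if (!length(remaining)) {
        acc <<- acc + c(sd, nd, 1)
        return(invisible(NULL))
      }
      for (pos in remaining) {
        nxt <- cur; nxt[pos] <- s2[pos]
        cn <- paste(nxt, collapse = "")
        if (gc[[cn]] == "*") next # pathway through a stop codon: excluded
        syn <- gc[[cn]] == gc[[paste(cur, collapse = "")]]
        recurse(nxt, setdiff(remaining, pos), sd + syn, nd + !syn)
      }
    }
    recurse(s1, diff, 0, 0)
    acc
  }
  .oracle_env[[key]] <- res
  res
}

oracle_ng86 <- function(a, b) {
  gc <- Biostrings::GENETIC_CODE
  n <- nchar(a)
  ca <- substring(a, seq(1, n, 3), seq(3, n, 3))
  cb <- substring(b, seq(1, n, 3), seq(3, n, 3))
  ok <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  ok <- ok & gc[ca] != "*" & gc[cb] != "*"
  ca <- ca[ok]; cb <- cb[ok]
  S <- N <- Sd <- Nd <- 0
  for (i in seq_along(ca)) {
    p <- oracle_codon_paths(ca[i], cb[i])
    if (p[3] == 0) next # every pathway blocked by stops: column excluded
    si <- (oracle_codon_sites(ca[i]) + oracle_codon_sites(cb[i])) / 2
    S <- S + si; N <- N + 3 - si
    Sd <- Sd + p[1] / p[3]; Nd <- Nd + p[2] / p[3]
  }
  jc <- function(p) -3 / 4 * log(1 - 4 / 3 * p)
  list(Ks = jc(Sd / S), Ka = jc(Nd / N), S = S, N = N, Sd = Sd, Nd = Nd)
}

# --- brute-force canonical minimizers
brute_minimizers <- function(s, k, w) {
  s <- toupper(s)
  n <- nchar(s)
  if (n < k) return(numeric(0))
  enc <- function(km) {
    v <- match(strsplit(km, "")[[1]], c("A", "C", "G", "T")) - 1
    sum(v * 4^(rev(seq_along(v)) - 1))
  }
  rc <- function(km) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", km), "")[[1]]), collapse = "")
  }
  kmers <- substring(s, 1:(n - k + 1), k:n)
  canon <- vapply(kmers, function(km) min(enc(km), enc(rc(km))), numeric(1))
  if (length(canon) >= w) {
    mins <- vapply(1:(length(canon) - w + 1), function(i)
      min(canon[i:(i + w - 1)]), numeric(1))
  } else {
    mins <- min(canon)
  }
  sort(unique(mins))
}

# --- brute-force perfect tandem runs (maximal, primitive motifs)
brute_ssrs <- function(s, min_copies = c(12, 6, 4, 3, 3, 3)) {
  s <- toupper(s)
  n <- nchar(s)
  x <- strsplit(s, "")[[1]]
  is_primitive <- function(m) {
    L <- nchar(m)
    for (p in seq_len(L - 1)) {
      if (L %% p == 0 &&
          m == paste(rep(substr(m, 1, p), L / p), collapse = "")) return(FALSE)
    }
    TRUE
  }
  out <- list()
  for (m in 1:6) {
    i <- 1
    while (i + m <= n) {
      j <- i
      while (j + m <= n && x[j + m] == x[j] &&
             all(x[c(j, j + m)] %in% c("A", "C", "G", "T"))) j <- j + 1
      run_len <- j + m - i
      copies <- run_len / m
      motif <- substr(s, i, i + m - 1)
      if (copies >= min_copies[m] && is_primitive(motif) &&
          all(strsplit(motif, "")[[1]] %in% c("A", "C", "G", "T"))) {
        out[[length(out) + 1]] <- data.frame(start = i, end = i + run_len - 1,
                                             motif = motif, motif_len = m,
                                             copy_number = copies)
      }
      i <- if (run_len >= 2 * m) j + 1 else i + 1
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}
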