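# Standard genetic code tables and per-codon synonymous-site arithmetic.
# Stop codons: a single-base change that creates a stop is counted as
# nonsynonymous in site counting; substitution pathways passing through a
# stop codon are excluded when averaging multi-hit codon differences.

.codon_table <- function() {
  if (!is.null(.ps_env$codons)) return(.ps_env$codons)
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  codons <- as.vector(outer(outer(bases, bases, function(a, b) paste0(a, b)),
                            bases, paste0))
  # outer ordering: first index varies fastest; rebuild explicitly
  codons <- character(64)
  k <- 0
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    k <- k + 1
    codons[k] <- paste0(b1, b2, b3)
  }
  tab <- setNames(aas, codons)
  .ps_env$codons <- tab
  tab
}

#' Translate a CDS
#'
#' Standard genetic code; `*` for stop, `X` for codons containing non-ACGT.
#' @param cds a DNA string with length divisible by 3.
#' @return amino-acid string.
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3 != 0) stop("translate_cds: length not divisible by 3", call. = FALSE)
  tab <- .codon_table()
  cod <- substring(cds, seq(1, n, 3), seq(3, n, 3))
  aa <- tab[cod]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

codon_is_stop <- function(codon) {
  tab <- .codon_table()
  !is.na(tab[codon]) & tab[codon] == "*"
}

# fraction of synonymous sites per codon (NG86): sum over the 3 positions of
# (# synonymous single-base changes)/3; changes to stop count as nonsynonymous.
.syn_sites_table <- function() {
  if (!is.null(.ps_env$syn_sites)) return(.ps_env$syn_sites)
  tab <- .codon_table()
  bases <- c("A", "C", "G", "T")
  out <- setNames(numeric(64), names(tab))
  for (cod in names(tab)) {
    if (tab[cod] == "*") { out[cod] <- NA_real_; next }
    s <- 0
    sp <- strsplit(cod, "")[[1]]
    for (pos in 1:3) {
      for (b in setdiff(bases, sp[pos])) {
        alt <- sp
        alt[pos] <- b
        alt <- paste(alt, collapse = "")
        if (tab[alt] != "*" && tab[alt] == tab[cod]) s <- s + 1 / 3
      }
    }
    out[cod] <- s
  }
  .ps_env$syn_sites <- out
  out
}

# pathway-averaged (Sd, Nd) between two sense codons, excluding pathways
# through stop codons; NULL if no valid pathway exists.
.codon_pair_diffs <- function(c1, c2) {
  key <- paste0(c1, c2)
  if (is.null(.ps_env$pair_cache)) .ps_env$pair_cache <- new.env(parent = emptyenv())
  hit <- .ps_env$pair_cache[[key]]
  if (!is.null(hit)) return(hit)
  tab <- .codon_table()
  s1 <- strsplit(c1, "")[[1]]
  s2 <- strsplit(c2, "")[[1]]
  diffpos <- which(s1 != s2)
  d <- length(diffpos)
  if (d == 0) {
    res <- c(sd = 0, nd = 0)
  } else {
    perms <- switch(as.character(d),
                    "1" = list(diffpos),
                    "2" = list(diffpos, rev(diffpos)),
                    "3" = {
                      p <- diffpos
                      list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
                           p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
                    })
    sd_tot <- 0; nd_tot <- 0; nvalid <- 0
    for (ord in perms) {
      cur <- s1
      sd <- 0; nd <- 0; ok <- TRUE
      for (pos in ord) {
        nxt <- cur
        nxt[pos] <- s2[pos]
        ccur <- paste(cur, collapse = "")
        cnxt <- paste(nxt, collapse = "")
        if (tab[cnxt] == "*" && cnxt != c2) { ok <- FALSE; break }
        if (tab[cnxt] == "*") { ok <- FALSE; break } # c2 is sense by contract
        if (tab[cnxt] == tab[ccur]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (ok) {
        sd_tot <- sd_tot + sd; nd_tot <- nd_tot + nd; nvalid <- nvalid + 1
      }
    }
    res <- if (nvalid == 0) NULL else c(sd = sd_tot / nvalid, nd = nd_tot / nvalid)
  }
  .ps_env$pair_cache[[key]] <- if (is.null(res)) list(NULL) else res
  if (is.null(res)) return(NULL)
  res
}

codon_pair_diffs <- function(c1, c2) {
  r <- .codon_pair_diffs(c1, c2)
  if (is.list(r)) return(NULL) # cached "no valid pathway"
  r
}
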