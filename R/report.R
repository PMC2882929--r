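#' Gene content statistics
#'
#' Counts and the derived headline numbers of a comparative annotation:
#' ortholog fraction (`n_orthologs / n_genes_query`), lineage-specific gene
#' counts (genes with no counterpart in the aligned counterpart region; a
#' whole-genome recheck may reduce the specific set and is reported
#' separately when given), and gene density in kb per validated gene. When
#' the validated count differs from the annotated count, density is
#' reported against the validated denominator and both raw counts are kept,
#' so inconsistent published percentages can be audited rather than
#' adopted.
#'
#' @param n_genes_query,n_genes_template annotated gene counts.
#' @param ortholog_map data.frame `gene_id_query, gene_id_template` of
#'   matched genes (or an integer count).
#' @param insert_kb total sequence analysed, in kb.
#' @param n_validated genes validated by expression evidence (defaults to
#'   all query genes).
#' @param n_query_specific,n_template_specific specific-gene counts
#'   (defaults derived from the counts and the map).
#' @return a `gene_stats` list with counts, `ortholog_fraction`,
#'   `gene_density_kb` (kb per validated gene, one decimal) and both
#'   density denominators.
#' @export
compute_gene_stats <- function(n_genes_query, n_genes_template, ortholog_map,
                               insert_kb, n_validated = n_genes_query,
                               n_query_specific = NULL,
                               n_template_specific = NULL) {
  n_orth <- if (is.data.frame(ortholog_map)) nrow(ortholog_map) else
    as.integer(ortholog_map)
  if (n_orth > min(n_genes_query, n_genes_template)) {
    stop("compute_gene_stats: more orthologs than genes", call. = FALSE)
  }
  if (n_validated <= 0) {
    stop("compute_gene_stats: zero validated genes; density undefined",
         call. = FALSE)
  }
  if (is.null(n_query_specific)) n_query_specific <- n_genes_query - n_orth
  if (is.null(n_template_specific)) n_template_specific <- n_genes_template - n_orth
  structure(list(
    n_genes_query = n_genes_query,
    n_genes_template = n_genes_template,
    n_orthologs = n_orth,
    n_query_specific = n_query_specific,
    n_template_specific = n_template_specific,
    n_validated = n_validated,
    ortholog_fraction = n_orth / n_genes_query,
    gene_density_kb = round(insert_kb / n_validated, 1),
    validated_fraction_of_annotated = n_validated / n_genes_query,
    insert_kb = insert_kb), class = "gene_stats")
}

#' Assemble a pipeline report
#'
#' Bundles the stage summaries (synteny, rearrangements, repeats for both
#' genomes, divergence, gene stats) into one object for [render_report()].
#' Any section may be `NULL` (rendered as an empty table).
#'
#' @param synteny a `synteny_summary`.
#' @param rearrangements a `rearrangement_summary`.
#' @param repeats_query,repeats_template `repeat_summary` data.frames.
#' @param divergence a `divergence_estimate`.
#' @param gene_stats a `gene_stats`.
#' @return a `pipeline_report` list.
#' @export
pipeline_report <- function(synteny = NULL, rearrangements = NULL,
                            repeats_query = NULL, repeats_template = NULL,
                            divergence = NULL, gene_stats = NULL) {
  structure(list(synteny = synteny, rearrangements = rearrangements,
                 repeats_query = repeats_query,
                 repeats_template = repeats_template,
                 divergence = divergence, gene_stats = gene_stats),
            class = "pipeline_report")
}

fmt_pct <- function(x) sprintf("%.1f%%", 100 * x)

#' Render a pipeline report to TSV tables and a summary
#'
#' Writes one TSV per section (ordering/alignment summary, rearrangement
#' classes, repeat families per genome, divergence dating, gene stats) plus
#' a human-readable `summary.md`. Identical inputs produce byte-identical
#' output; every percentage in the summary is recomputable from raw columns
#' present in the tables.
#'
#' @param report a `pipeline_report`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
render_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    write_tsv_report(df, p)
    files <<- c(files, p)
  }
  syn <- report$synteny
  syn_df <- if (is.null(syn)) {
    data.frame(metric = character(0), value = character(0))
  } else {
    data.frame(metric = c("n_clones", "assembled_bp", "unambiguous_bp",
                          "ordered_bp", "insert_bp", "spanned_query_bp",
                          "spanned_template_bp", "ordered_fraction",
                          "aligned_fraction", "expansion_fraction"),
               value = c(syn$n_clones, syn$assembled_bp, syn$unambiguous_bp,
                         syn$ordered_bp, syn$insert_bp, syn$spanned_query_bp,
                         syn$spanned_template_bp, fmt_pct(syn$ordered_fraction),
                         fmt_pct(syn$aligned_fraction),
                         fmt_pct(syn$expansion_fraction)),
               stringsAsFactors = FALSE)
  }
  wr(syn_df, "synteny_summary.tsv")
  re_df <- if (is.null(report$rearrangements)) {
    data.frame(class = character(0), total_bp = integer(0),
               n_events = integer(0), mean_bp = integer(0))
  } else as.data.frame(report$rearrangements)
  wr(re_df, "rearrangements.tsv")
  for (side in c("query", "template")) {
    rs <- report[[paste0("repeats_", side)]]
    df <- if (is.null(rs)) {
      data.frame(family = character(0), masked_bp = numeric(0),
                 fraction = character(0))
    } else {
      d <- as.data.frame(rs)
      d$fraction <- sprintf("%.2f", 100 * d$fraction)
      d
    }
    wr(df, paste0("repeats_", side, ".tsv"))
  }
  dv <- report$divergence
  dv_df <- if (is.null(dv)) {
    data.frame(metric = character(0), value = numeric(0))
  } else {
    data.frame(metric = c("n_pairs", "median_ks", "rate_per_site_per_year",
                          "time_mya"),
               value = c(dv$n_pairs, dv$median_ks, dv$rate, dv$time_mya),
               stringsAsFactors = FALSE)
  }
  wr(dv_df, "divergence.tsv")
  gs <- report$gene_stats
  gs_df <- if (is.null(gs)) {
    data.frame(metric = character(0), value = numeric(0))
  } else {
    data.frame(metric = c("n_genes_query", "n_genes_template", "n_orthologs",
                          "n_query_specific", "n_template_specific",
                          "n_validated", "ortholog_fraction",
                          "gene_density_kb_per_gene", "insert_kb"),
               value = c(gs$n_genes_query, gs$n_genes_template,
                         gs$n_orthologs, gs$n_query_specific,
                         gs$n_template_specific, gs$n_validated,
                         fmt_pct(gs$ortholog_fraction), gs$gene_density_kb,
                         gs$insert_kb),
               stringsAsFactors = FALSE)
  }
  wr(gs_df, "gene_stats.tsv")
  md <- c("# Microsynteny pipeline report", "",
          if (!is.null(syn)) c(
            sprintf("- Ordered contigs: %s bp of %s bp inserts (%s)",
                    format(syn$ordered_bp, big.mark = ","),
                    format(syn$insert_bp, big.mark = ","),
                    fmt_pct(syn$ordered_fraction)),
            sprintf("- Aligned to template: %s bp (%s); template span %s bp (expansion %s)",
                    format(syn$spanned_query_bp, big.mark = ","),
                    fmt_pct(syn$aligned_fraction),
                    format(syn$spanned_template_bp, big.mark = ","),
                    fmt_pct(syn$expansion_fraction))),
          if (!is.null(report$rearrangements)) {
            t <- report$rearrangements
            tr <- t[t$class == "Total", ]
            sprintf("- Rearrangements: %d events, %d bp, mean %d bp (polarity unresolved without an outgroup)",
                    tr$n_events, tr$total_bp, tr$mean_bp)
          },
          if (!is.null(dv)) sprintf(
            "- Divergence: median Ks %.3g over %d pairs -> %.1f MYa",
            dv$median_ks, dv$n_pairs, dv$time_mya),
          if (!is.null(gs)) sprintf(
            "- Genes: %d query / %d template; %d orthologs (%s); one gene per %.1f kb",
            gs$n_genes_query, gs$n_genes_template, gs$n_orthologs,
            fmt_pct(gs$ortholog_fraction), gs$gene_density_kb),
          "")
  p <- file.path(out_dir, "summary.md")
  writeLines(md, p)
  files <- c(files, p)
  invisible(files)
}
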