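#' Minimizer index of a read pool
#'
#' Canonical (strand-symmetric) minimizers: each window of `w` consecutive
#' k-mers contributes its smallest 2-bit-encoded canonical k-mer. Reads
#' shorter than `k` are indexed with zero minimizers (with a warning).
#'
#' @param pool a `pooled_read_set` (or named character vector of reads).
#' @param k k-mer size (default 21, must be <= 26).
#' @param w window size in k-mers (default 11).
#' @return a `data.table` with columns `minimizer` (numeric code) and
#'   `read_id`, one row per distinct minimizer per read; attribute `k`, `w`.
#' @export
build_minimizer_index <- function(pool, k = 21L, w = 11L) {
  reads <- if (inherits(pool, "pooled_read_set")) pool$reads else pool
  if (any(nchar(reads) < k)) {
    warning("build_minimizer_index: ", sum(nchar(reads) < k),
            " read(s) shorter than k indexed with zero minimizers")
  }
  mz <- cpp_minimizers(as.character(reads), as.integer(k), as.integer(w))
  n <- lengths(mz)
  dt <- data.table::data.table(
    minimizer = unlist(mz, use.names = FALSE),
    read_id = rep(names(reads), n))
  data.table::setattr(dt, "k", k)
  data.table::setattr(dt, "w", w)
  dt
}

#' Deconvolve row/column pooled reads to clone cells
#'
#' CAPSS-style intersection on shared sequence: a read from a row pool is
#' assigned to column `c` iff it shares at least `min_shared` distinct
#' canonical minimizers with the reads of exactly one column pool `c`
#' (symmetrically for column-pool reads). Reads sharing enough minimizers
#' with several opposite-axis pools are ambiguous; reads sharing enough with
#' none are unassigned. The three categories partition the input.
#'
#' @param pools list of `pooled_read_set` covering both axes of the grid.
#' @param grid data.frame `clone_id, row, col` (one row per clone).
#' @param k,w minimizer parameters.
#' @param min_shared minimum shared distinct minimizers.
#' @return a `deconvolution_result`: list with `assignments` (data.frame
#'   `read_id, row, col, clone_id, n_shared`), `ambiguous` (data.frame
#'   `read_id, candidates`), `unassigned` (character vector), and `bins`
#'   (list clone_id -> read ids).
#' @export
deconvolve <- function(pools, grid, k = 21L, w = 11L, min_shared = 3L) {
  axes <- vapply(pools, function(p) p$axis, character(1))
  idxs <- vapply(pools, function(p) p$index, numeric(1))
  rows_needed <- sort(unique(grid$row)); cols_needed <- sort(unique(grid$col))
  if (!all(rows_needed %in% idxs[axes == "row"]) ||
      !all(cols_needed %in% idxs[axes == "col"])) {
    stop("deconvolve: pools do not cover the grid axes", call. = FALSE)
  }
  cellmap <- grid
  key <- function(r, c) paste(r, c, sep = ":")
  cellkey <- setNames(cellmap$clone_id, key(cellmap$row, cellmap$col))

  index_of <- lapply(pools, build_minimizer_index, k = k, w = w)

  assign_axis <- function(from_axis) {
    to_axis <- if (from_axis == "row") "col" else "row"
    to_ix <- which(axes == to_axis)
    # opposite-axis index: minimizer -> opposite pool index (distinct)
    opp <- data.table::rbindlist(lapply(to_ix, function(i) {
      dt <- unique(index_of[[i]], by = "minimizer")
      dt <- dt[, c("minimizer")]
      dt$opp_index <- pools[[i]]$index
      dt
    }))
    res <- list()
    for (i in which(axes == from_axis)) {
      own <- pools[[i]]$index
      dt <- index_of[[i]]
      if (!nrow(dt)) next
      m <- merge(dt, opp, by = "minimizer", allow.cartesian = TRUE)
      counts <- m[, list(n_shared = .N), by = c("read_id", "opp_index")]
      counts <- counts[counts$n_shared >= min_shared, ]
      nhit <- counts[, list(k = .N), by = "read_id"]
      all_reads <- unique(dt$read_id)
      one <- nhit$read_id[nhit$k == 1L]
      multi <- nhit$read_id[nhit$k > 1L]
      a <- counts[counts$read_id %in% one, ]
      res[[length(res) + 1]] <- list(
        assigned = if (nrow(a)) data.frame(
          read_id = a$read_id,
          row = if (from_axis == "row") own else a$opp_index,
          col = if (from_axis == "row") a$opp_index else own,
          n_shared = a$n_shared, stringsAsFactors = FALSE) else NULL,
        ambiguous = if (length(multi)) data.frame(
          read_id = multi,
          candidates = vapply(multi, function(rd) {
            cc <- counts$opp_index[counts$read_id == rd]
            if (from_axis == "row") {
              paste(key(own, sort(cc)), collapse = ";")
            } else paste(key(sort(cc), own), collapse = ";")
          }, character(1)), stringsAsFactors = FALSE) else NULL,
        unassigned = setdiff(all_reads, c(one, multi)))
    }
    res
  }
  parts <- c(assign_axis("row"), assign_axis("col"))
  assigned <- do.call(rbind, Filter(Negate(is.null),
                                    lapply(parts, `[[`, "assigned")))
  ambiguous <- do.call(rbind, Filter(Negate(is.null),
                                     lapply(parts, `[[`, "ambiguous")))
  unassigned <- unlist(lapply(parts, `[[`, "unassigned"), use.names = FALSE)
  if (is.null(assigned)) {
    assigned <- data.frame(read_id = character(0), row = integer(0),
                           col = integer(0), n_shared = integer(0),
                           stringsAsFactors = FALSE)
  }
  if (is.null(ambiguous)) {
    ambiguous <- data.frame(read_id = character(0), candidates = character(0),
                            stringsAsFactors = FALSE)
  }
  assigned$clone_id <- unname(cellkey[key(assigned$row, assigned$col)])
  bins <- split(assigned$read_id, assigned$clone_id)
  structure(list(assignments = assigned, ambiguous = ambiguous,
                 unassigned = unassigned, bins = bins),
            class = "deconvolution_result")
}

#' @export
print.deconvolution_result <- function(x, ...) {
  total <- nrow(x$assignments) + nrow(x$ambiguous) + length(x$unassigned)
  cat(sprintf("deconvolution_result: %d reads (%d assigned, %d ambiguous, %d unassigned)\n",
              total, nrow(x$assignments), nrow(x$ambiguous),
              length(x$unassigned)))
  invisible(x)
}
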