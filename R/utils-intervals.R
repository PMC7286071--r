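# Interval primitives shared across modules. All coordinates are BED-native:
# 0-based, half-open [start, end). Interval tables are plain tibbles with at
# least chrom/start/end columns; extra columns are preserved where documented.

#' Merge overlapping and adjacent intervals
#'
#' Normalizes an interval table: within each chromosome (and each combination
#' of the optional grouping columns) intervals are sorted and overlapping or
#' book-ended intervals are merged. Adjacent intervals (`[10,20)` + `[20,30)`)
#' collapse to one because per-nucleotide ON/OFF status is the only semantics
#' the downstream encoding uses.
#'
#' @param x A data frame with columns `chrom`, `start`, `end`.
#' @param by Character vector of extra grouping columns (e.g. `sample_id`,
#'   `modification`) kept in the output.
#' @return A tibble with columns `by`, `chrom`, `start`, `end`, sorted, with
#'   pairwise disjoint non-adjacent intervals within each group.
#' @export
merge_intervals <- function(x, by = character()) {
  x <- tibble::as_tibble(x)
  if (nrow(x) == 0L) {
    return(tibble::as_tibble(x[, c(by, "chrom", "start", "end"), drop = FALSE]))
  }
  grp <- c(by, "chrom")
  x |>
    dplyr::select(dplyr::all_of(c(grp, "start", "end"))) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(grp)), .data$start, .data$end) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(
      .reach = cummax(dplyr::lag(.data$end, default = dplyr::first(.data$start))),
      .cluster = cumsum(.data$start > .data$.reach)
    ) |>
    dplyr::group_by(.data$.cluster, .add = TRUE) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") |>
    dplyr::select(-".cluster") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(grp)), .data$start)
}

# Covered-bp lookup for one chromosome: given disjoint sorted intervals
# (starts, ends), C(x) = number of covered nucleotides in [0, x).
coverage_fun <- function(starts, ends) {
  cum <- cumsum(ends - starts)
  function(x) {
    i <- findInterval(x, starts)
    out <- numeric(length(x))
    hit <- i > 0L
    out[hit] <- cum[i[hit]] - pmax(0, ends[i[hit]] - x[hit])
    out
  }
}

#' Total overlap between a query window set and a disjoint interval set
#'
#' @param q A data frame of query windows (`chrom`, `start`, `end`); windows
#'   may overlap each other (each is measured independently).
#' @param s A normalized (disjoint, sorted) interval table (`chrom`, `start`,
#'   `end`), e.g. output of [merge_intervals()].
#' @return Numeric vector: covered bp of each query window, in input order.
#' @export
overlap_bp <- function(q, s) {
  out <- numeric(nrow(q))
  if (nrow(q) == 0L || nrow(s) == 0L) return(out)
  for (ch in unique(q$chrom)) {
    qi <- which(q$chrom == ch)
    si <- s$chrom == ch
    if (!any(si)) next
    cf <- coverage_fun(s$start[si], s$end[si])
    out[qi] <- cf(q$end[qi]) - cf(q$start[qi])
  }
  out
}

#' Intersection size of two disjoint interval sets, in bp
#'
#' @param a,b Normalized interval tables (`chrom`, `start`, `end`).
#' @return Total bp present in both `a` and `b`.
#' @export
intersect_bp <- function(a, b) sum(overlap_bp(a, b))

# Midpoint of [start, end): the floor-median covered nucleotide.
interval_midpoint <- function(start, end) start + (end - start - 1L) %/% 2L
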