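# Peak-track input/output. A "track" is the ON-region set of one sample for
# one histone modification: a tibble of normalized intervals. Collections of
# tracks are long tibbles keyed by (sample_id, modification).

#' Read a BED3+ peak file as a normalized interval track
#'
#' Only the first three columns are used; extra columns are ignored. The
#' result is normalized with [merge_intervals()] (sorted, overlapping and
#' adjacent intervals merged), so a track is exactly the set of nucleotides
#' carrying the modification. Lines starting with `track`, `browser` or `#`
#' are skipped.
#'
#' @param path Path to a BED file (uncompressed text).
#' @param layout Optional [genome_layout()]. When supplied, intervals are
#'   checked against chromosome bounds, and records on chromosomes absent
#'   from the layout are skipped with a warning (default) or rejected
#'   (`strict = TRUE`).
#' @param strict Error on unknown chromosomes instead of skipping them.
#' @return A tibble with columns `chrom`, `start`, `end` (0-based half-open).
#' @export
read_bed <- function(path, layout = NULL, strict = FALSE) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  lines <- readr::read_lines(path, progress = FALSE)
  lineno <- seq_along(lines)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (length(lines) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer()))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop(sprintf("%s: line %d has fewer than 3 BED columns", path,
                 lineno[which(nf < 3L)[1]]), call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(!is.finite(start) | !is.finite(end) |
                 start != floor(start) | end != floor(end))
  if (length(bad)) {
    stop(sprintf("%s: line %d has non-integer coordinates", path,
                 lineno[bad[1]]), call. = FALSE)
  }
  bad <- which(start < 0 | start >= end)
  if (length(bad)) {
    stop(sprintf("%s: line %d violates 0 <= start < end", path,
                 lineno[bad[1]]), call. = FALSE)
  }
  x <- tibble::tibble(chrom = chrom, start = start, end = end)
  if (!is.null(layout)) {
    unknown <- !x$chrom %in% layout$chrom
    if (any(unknown)) {
      if (strict) {
        stop(sprintf("%s: line %d has unknown chromosome '%s'", path,
                     lineno[which(unknown)[1]], x$chrom[which(unknown)[1]]),
             call. = FALSE)
      }
      warning(sprintf("%s: skipped %d records on chromosomes absent from layout",
                      path, sum(unknown)), call. = FALSE)
      x <- x[!unknown, ]
    }
    over <- x$end > layout_length(layout, x$chrom)
    if (any(over)) {
      stop(sprintf("%s: interval beyond chromosome end (%s:%d-%d)", path,
                   x$chrom[which(over)[1]], x$start[which(over)[1]],
                   x$end[which(over)[1]]), call. = FALSE)
    }
  }
  merge_intervals(x)
}

#' Write a track as 3-column BED
#'
#' Records are sorted by the layout's chromosome order (alphabetically when
#' no layout is given), then by start. `read_bed(write_bed(x))` is the
#' identity on normalized tracks.
#'
#' @param track A normalized interval tibble (`chrom`, `start`, `end`).
#' @param path Output path.
#' @param layout Optional [genome_layout()] fixing chromosome order.
#' @return `path`, invisibly.
#' @export
write_bed <- function(track, path, layout = NULL) {
  ord <- if (is.null(layout)) {
    order(track$chrom, track$start)
  } else {
    order(match(track$chrom, layout$chrom), track$start)
  }
  track <- track[ord, c("chrom", "start", "end")]
  readr::write_tsv(dplyr::mutate(track,
                                 start = format(.data$start, scientific = FALSE, trim = TRUE),
                                 end = format(.data$end, scientific = FALSE, trim = TRUE)),
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' @param path TSV with header columns `sample_id`, `cell_type`, `tissue`,
#'   `individual`, `subtype`, `modification`, `bed_path`.
#' @return A tibble with those columns.
#' @export
read_sample_sheet <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  need <- c("sample_id", "cell_type", "tissue", "individual", "subtype",
            "modification", "bed_path")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("sample sheet missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dup <- x |>
    dplyr::count(.data$sample_id, .data$modification) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    stop("duplicate (sample_id, modification) in sample sheet: ",
         dup$sample_id[1], call. = FALSE)
  }
  x
}

#' Read all tracks listed in a sample sheet
#'
#' @param sheet A sample-sheet tibble ([read_sample_sheet()]); `bed_path`
#'   entries are resolved relative to `dir` when given.
#' @param layout A [genome_layout()].
#' @param dir Optional base directory for relative `bed_path`s.
#' @param strict Passed to [read_bed()].
#' @return A long tibble with columns `sample_id`, `cell_type`,
#'   `modification`, `chrom`, `start`, `end`.
#' @export
read_tracks <- function(sheet, layout, dir = NULL, strict = FALSE) {
  purrr::pmap(sheet[, c("sample_id", "cell_type", "modification", "bed_path")],
              function(sample_id, cell_type, modification, bed_path) {
                p <- if (!is.null(dir)) file.path(dir, bed_path) else bed_path
                dplyr::mutate(read_bed(p, layout, strict),
                              sample_id = sample_id, cell_type = cell_type,
                              modification = modification,
                              .before = 1L)
              }) |>
    purrr::list_rbind()
}

#' Exclude samples with peak-free chromosomes
#'
#' A track is excluded when it has zero intervals on at least one layout
#' chromosome outside the layout's excluded set (the Y chromosome by
#' default). This is the peak-level reading of the upstream per-chromosome
#' missing-data filter: peak files are the only evidence available here.
#'
#' @param tracks A long track tibble (see [read_tracks()]); the filter is
#'   applied per (`sample_id`, `modification`) track.
#' @param layout A [genome_layout()].
#' @param samples Optional tibble of expected (`sample_id`, `modification`)
#'   tracks, e.g. from the sample sheet. Needed to catch tracks with no
#'   intervals at all, which leave no rows in `tracks`. Defaults to the
#'   tracks present in `tracks`.
#' @return A list with `kept` (tracks tibble restricted to passing tracks)
#'   and `excluded` (one row per failing track: `sample_id`, `modification`,
#'   `missing_chroms` as a comma-separated string).
#' @export
qc_filter <- function(tracks, layout, samples = NULL) {
  required <- qc_required_chroms(layout)
  if (is.null(samples)) {
    samples <- dplyr::distinct(tracks, .data$sample_id, .data$modification)
  }
  empty <- tibble::tibble(sample_id = character(), modification = character(),
                          missing_chroms = character())
  if (nrow(samples) == 0L) {
    return(list(kept = tracks, excluded = empty))
  }
  status <- tracks |>
    dplyr::distinct(.data$sample_id, .data$modification, .data$chrom) |>
    dplyr::right_join(samples[, c("sample_id", "modification")],
                      by = c("sample_id", "modification")) |>
    dplyr::group_by(.data$sample_id, .data$modification) |>
    dplyr::summarise(
      missing_chroms = paste(setdiff(required, stats::na.omit(.data$chrom)),
                             collapse = ","),
      .groups = "drop"
    )
  bad <- dplyr::filter(status, nzchar(.data$missing_chroms))
  kept <- dplyr::anti_join(tracks, bad, by = c("sample_id", "modification"))
  list(kept = kept, excluded = bad)
}
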