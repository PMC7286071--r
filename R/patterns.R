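# Character encoding: every nucleotide of the genome is a binary ON/OFF
# character across samples. Maximal runs of nucleotides with an identical
# cross-sample pattern form atomic segments; unique patterns are collapsed
# with bp weights. Parsimony on weighted patterns is provably identical to
# per-nucleotide parsimony, at a tiny fraction of the cost.

#' Partition one modification's tracks into atomic segments
#'
#' Segment boundaries are exactly the union of all interval endpoints plus
#' chromosome bounds, so the per-sample ON/OFF state vector is constant
#' within each segment. The segments partition the genome. Computed one
#' chromosome at a time (bounded memory).
#'
#' @param tracks Long track tibble for a single modification (`sample_id`,
#'   `chrom`, `start`, `end`), all tracks normalized and QC-passed.
#' @param layout A [genome_layout()].
#' @param samples Optional character vector fixing sample order; defaults to
#'   the sorted unique `sample_id`s in `tracks`.
#' @return A list with `segments` (tibble `chrom`, `start`, `end`) and
#'   `states` (integer 0/1 matrix, segments x samples, colnames = samples).
#' @export
partition_segments <- function(tracks, layout, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(tracks$sample_id))
  if ("modification" %in% names(tracks) &&
      length(unique(tracks$modification)) > 1L) {
    stop("partition_segments() takes tracks of a single modification",
         call. = FALSE)
  }
  if (!all(tracks$chrom %in% layout$chrom)) {
    stop("track contains chromosome absent from layout", call. = FALSE)
  }
  per_chrom <- purrr::map2(layout$chrom, layout$length, function(ch, len) {
    iv <- tracks[tracks$chrom == ch, , drop = FALSE]
    bp <- sort(unique(c(0, len, iv$start, iv$end)))
    starts <- bp[-length(bp)]
    ends <- bp[-1L]
    st <- matrix(0L, nrow = length(starts), ncol = length(samples),
                 dimnames = list(NULL, samples))
    for (s in unique(iv$sample_id)) {
      si <- iv[iv$sample_id == s, , drop = FALSE]
      si <- si[order(si$start), , drop = FALSE]
      i <- findInterval(starts, si$start)
      on <- i > 0L & starts < si$end[pmax(i, 1L)]
      st[, s] <- as.integer(on)
    }
    list(segments = tibble::tibble(chrom = ch, start = starts, end = ends),
         states = st)
  })
  list(segments = purrr::list_rbind(purrr::map(per_chrom, "segments")),
       states = do.call(rbind, purrr::map(per_chrom, "states")))
}

#' Collapse atomic segments into a weighted site-pattern matrix
#'
#' @param partition Output of [partition_segments()].
#' @param modification Optional modification label carried in the result.
#' @return A `site_pattern_matrix`: list with `samples`, `states` (unique
#'   patterns x samples 0/1 matrix), `weight` (bp per pattern), `is_variable`
#'   (pattern holds both 0 and 1), and `segments` (tibble `chrom`, `start`,
#'   `end`, `pattern_id` mapping every atomic segment to its pattern).
#' @export
collapse_patterns <- function(partition, modification = NA_character_) {
  st <- partition$states
  key <- apply(st, 1L, paste0, collapse = "")
  ids <- match(key, unique(key))
  first <- !duplicated(ids)
  states <- st[first, , drop = FALSE]
  rownames(states) <- NULL
  seg <- partition$segments
  w <- seg$end - seg$start
  weight <- as.numeric(tapply(w, ids, sum))
  site_pattern_matrix(colnames(st), states, weight,
                      dplyr::mutate(seg, pattern_id = ids),
                      modification = modification)
}

#' Construct a site-pattern matrix directly
#'
#' Low-level constructor used by [collapse_patterns()] and by tests that
#' build matrices by hand (e.g. one character per nucleotide).
#'
#' @param samples Character vector of sample ids (column order of `states`).
#' @param states Integer 0/1 matrix, patterns x samples.
#' @param weight Numeric vector of bp weights, one per pattern.
#' @param segments Optional segment map tibble (`chrom`, `start`, `end`,
#'   `pattern_id`).
#' @param modification Optional modification label.
#' @return A `site_pattern_matrix`.
#' @export
site_pattern_matrix <- function(samples, states, weight, segments = NULL,
                                modification = NA_character_) {
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  colnames(states) <- samples
  stopifnot(nrow(states) == length(weight), all(states %in% 0:1),
            all(weight >= 1))
  structure(list(samples = as.character(samples), states = states,
                 weight = as.numeric(weight),
                 is_variable = matrixStats_any(states),
                 segments = segments, modification = modification),
            class = "site_pattern_matrix")
}

# variable iff row contains both 0 and 1
matrixStats_any <- function(states) {
  rs <- rowSums(states)
  rs > 0L & rs < ncol(states)
}

#' Encode tracks as a weighted site-pattern matrix
#'
#' Convenience wrapper: [partition_segments()] then [collapse_patterns()].
#'
#' @inheritParams partition_segments
#' @return A `site_pattern_matrix`.
#' @export
encode_patterns <- function(tracks, layout, samples = NULL) {
  modification <- if ("modification" %in% names(tracks)) {
    unique(tracks$modification)[1]
  } else NA_character_
  collapse_patterns(partition_segments(tracks, layout, samples), modification)
}

#' @export
print.site_pattern_matrix <- function(x, ...) {
  cat("<site_pattern_matrix> ", nrow(x$states), " patterns x ",
      length(x$samples), " samples",
      if (!is.na(x$modification)) paste0(" [", x$modification, "]"), "\n",
      "  total ", format(sum(x$weight), big.mark = ","), " bp; variable ",
      format(count_variable_sites(x), big.mark = ","), " bp in ",
      sum(x$is_variable), " patterns\n", sep = "")
  invisible(x)
}

#' Total variable sites (bp)
#'
#' A site (nucleotide) is variable when its pattern contains both ON and OFF
#' states; the count is the summed weight of variable patterns.
#'
#' @param spm A `site_pattern_matrix`.
#' @return Variable bp (numeric scalar).
#' @export
count_variable_sites <- function(spm) {
  sum(spm$weight[spm$is_variable])
}

#' @method tidy site_pattern_matrix
#' @export
tidy.site_pattern_matrix <- function(x, ...) {
  tibble::tibble(pattern_id = seq_len(nrow(x$states)),
                 weight = x$weight,
                 is_variable = x$is_variable,
                 pattern = apply(x$states, 1L, paste0, collapse = ""))
}

#' Expand a site-pattern matrix to one character per nucleotide
#'
#' Testing utility: undoes the lossless compression so results can be
#' compared against a brute-force per-nucleotide run. Memory scales with
#' genome size; intended for small genomes only.
#'
#' @param spm A `site_pattern_matrix` with a segment map.
#' @return A `site_pattern_matrix` whose patterns are unit-weight single
#'   nucleotides, uncollapsed.
#' @export
expand_to_nucleotides <- function(spm) {
  seg <- spm$segments
  stopifnot(!is.null(seg))
  n <- seg$end - seg$start
  idx <- rep.int(seq_len(nrow(seg)), n)
  pos <- seg$start[idx] + (sequence(n) - 1)
  states <- spm$states[seg$pattern_id[idx], , drop = FALSE]
  site_pattern_matrix(spm$samples, states, rep(1, length(idx)),
                      tibble::tibble(chrom = seg$chrom[idx], start = pos,
                                     end = pos + 1,
                                     pattern_id = seq_along(idx)),
                      modification = spm$modification)
}

#' Serialize / deserialize a site-pattern matrix as TSV
#'
#' Two plain-text files: `<stem>.patterns.tsv` (`pattern_id`, `weight`, one
#' 0/1 column per sample) and `<stem>.segments.bed.tsv` (`chrom`, `start`,
#' `end`, `pattern_id`).
#'
#' @param spm A `site_pattern_matrix`.
#' @param stem Output path stem.
#' @return `stem` (write) or a `site_pattern_matrix` (read).
#' @export
write_pattern_matrix <- function(spm, stem) {
  pat <- tibble::as_tibble(spm$states) |>
    dplyr::mutate(pattern_id = dplyr::row_number(),
                  weight = spm$weight, .before = 1L)
  readr::write_tsv(pat, paste0(stem, ".patterns.tsv"), progress = FALSE)
  readr::write_tsv(spm$segments, paste0(stem, ".segments.bed.tsv"),
                   progress = FALSE)
  invisible(stem)
}

#' @rdname write_pattern_matrix
#' @export
read_pattern_matrix <- function(stem) {
  pat <- readr::read_tsv(paste0(stem, ".patterns.tsv"),
                         col_types = readr::cols(), progress = FALSE)
  seg <- readr::read_tsv(paste0(stem, ".segments.bed.tsv"),
                         col_types = readr::cols(), progress = FALSE)
  samples <- setdiff(names(pat), c("pattern_id", "weight"))
  site_pattern_matrix(samples, as.matrix(pat[, samples]), pat$weight, seg)
}
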