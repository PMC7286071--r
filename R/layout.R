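#' Define the chromosome universe of an analysis
#'
#' A genome layout fixes the chromosome names and lengths every track is
#' validated against, plus the set of chromosomes the per-sample QC filter
#' ignores. The QC rule excludes any sample with no peaks on some chromosome,
#' with the Y chromosome exempted by default (samples from donors without a
#' Y must not be discarded).
#'
#' @param chrom_names Character vector of unique chromosome identifiers, in
#'   the order used for output sorting.
#' @param chrom_lengths Positive integer vector of chromosome lengths (bp).
#' @param excluded_chroms Chromosomes ignored by [qc_filter()]. Defaults to
#'   the Y chromosome under either common naming scheme.
#' @return A `genome_layout`: a tibble with columns `chrom` and `length` and
#'   an `excluded_chroms` attribute.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genome_layout <- function(chrom_names, chrom_lengths,
                          excluded_chroms = c("chrY", "Y")) {
  stopifnot(length(chrom_names) == length(chrom_lengths))
  if (anyDuplicated(chrom_names)) {
    stop("duplicate chromosome names in layout", call. = FALSE)
  }
  if (any(chrom_lengths <= 0)) {
    stop("chromosome lengths must be positive", call. = FALSE)
  }
  out <- tibble::tibble(chrom = as.character(chrom_names),
                        length = as.numeric(chrom_lengths))
  attr(out, "excluded_chroms") <- as.character(excluded_chroms)
  class(out) <- c("genome_layout", class(out))
  out
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("<genome_layout> ", nrow(x), " chromosomes, ",
      format(sum(x$length), big.mark = ","), " bp (QC-excluded: ",
      paste(attr(x, "excluded_chroms"), collapse = ", "), ")\n", sep = "")
  NextMethod()
}

#' Read a two-column chromosome-sizes file
#'
#' @param path Path to a TSV with columns name, length (no header).
#' @inheritParams genome_layout
#' @return A [genome_layout()].
#' @export
read_chrom_sizes <- function(path, excluded_chroms = c("chrY", "Y")) {
  x <- readr::read_tsv(path, col_names = c("chrom", "length"),
                       col_types = readr::cols(readr::col_character(),
                                               readr::col_double()),
                       progress = FALSE)
  genome_layout(x$chrom, x$length, excluded_chroms)
}

# Chromosomes the QC filter requires peaks on.
qc_required_chroms <- function(layout) {
  setdiff(layout$chrom, attr(layout, "excluded_chroms"))
}

layout_length <- function(layout, chrom) {
  layout$length[match(chrom, layout$chrom)]
}
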