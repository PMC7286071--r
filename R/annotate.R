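# Genomic annotation of inferred changes: branch-exclusivity classes,
# signed distance to the nearest transcription start site (TSS), the
# 12-category distance scheme, and a weighted two-sample
# Kolmogorov-Smirnov comparison of inter-only vs intra-only changes.

#' Gene model constructor
#'
#' @param gene_id Character gene identifiers (unique).
#' @param chrom,strand Chromosome and strand (`"+"`/`"-"`).
#' @param start,end Gene body, 0-based half-open.
#' @return Tibble (`gene_id`, `chrom`, `strand`, `start`, `end`, `tss`) with
#'   `tss` the 0-based position of the TSS nucleotide (body start on `+`,
#'   last body position on `-`).
#' @export
gene_model <- function(gene_id, chrom, strand, start, end) {
  stopifnot(!anyDuplicated(gene_id), all(strand %in% c("+", "-")),
            all(start < end))
  tibble::tibble(gene_id = as.character(gene_id), chrom = as.character(chrom),
                 strand = strand, start = as.numeric(start),
                 end = as.numeric(end),
                 tss = ifelse(strand == "+", as.numeric(start),
                              as.numeric(end) - 1))
}

#' Read gene models from a GTF file
#'
#' Uses rtracklayer to parse the GTF and keeps `gene` features (falling back
#' to the span of each `gene_id`'s features when no `gene` rows exist).
#'
#' @param path Path to an uncompressed GTF/GFF file.
#' @return A [gene_model()] tibble.
#' @export
read_gtf_genes <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_gtf_genes() needs the rtracklayer package; ",
         "use read_tss_bed() otherwise", call. = FALSE)
  }
  gr <- rtracklayer::import(path)
  df <- tibble::as_tibble(as.data.frame(gr))
  if ("type" %in% names(df) && any(df$type == "gene")) {
    df <- df[df$type == "gene", ]
  } else {
    df <- df |>
      dplyr::group_by(.data$gene_id, .data$seqnames, .data$strand) |>
      dplyr::summarise(start = min(.data$start), end = max(.data$end),
                       .groups = "drop")
  }
  gene_model(df$gene_id, as.character(df$seqnames), as.character(df$strand),
             df$start - 1, df$end)
}

#' Read gene models from a 6-column TSS BED file
#'
#' @param path BED6 (`chrom`, `start`, `end`, `name`, `score`, `strand`)
#'   where the interval is the gene body.
#' @return A [gene_model()] tibble.
#' @export
read_tss_bed <- function(path) {
  x <- readr::read_tsv(path,
                       col_names = c("chrom", "start", "end", "name",
                                     "score", "strand"),
                       col_types = "cddcdc", progress = FALSE)
  gene_model(x$name, x$chrom, x$strand, x$start, x$end)
}

#' Branch-exclusivity class of every pattern
#'
#' A pattern is `INTER_ONLY` when all its inferred changes lie on inter-type
#' branches (at least one change), `INTRA_ONLY` symmetrically, `MIXED` when
#' both branch classes carry changes, and `NO_CHANGE` for constant or
#' change-free patterns. Inter-only and intra-only sites are the two sets
#' whose genomic distributions are compared; mixed sites belong to neither.
#'
#' @param recon An `ancestral_recon`.
#' @return Tibble (`pattern_id`, `exclusivity`, `weight`) over all patterns.
#' @export
classify_exclusivity <- function(recon) {
  changes <- map_changes(recon)
  cls <- changes |>
    dplyr::group_by(.data$pattern_id) |>
    dplyr::summarise(inter = any(.data$class == "INTER"),
                     intra = any(.data$class == "INTRA"), .groups = "drop") |>
    dplyr::mutate(exclusivity = dplyr::case_when(
      .data$inter & .data$intra ~ "MIXED",
      .data$inter ~ "INTER_ONLY",
      .data$intra ~ "INTRA_ONLY"
    ))
  tibble::tibble(pattern_id = seq_along(recon$pattern_weight),
                 weight = recon$pattern_weight) |>
    dplyr::left_join(cls[, c("pattern_id", "exclusivity")], by = "pattern_id") |>
    dplyr::mutate(exclusivity = dplyr::coalesce(.data$exclusivity, "NO_CHANGE"))
}

#' Signed distance from segment midpoints to the nearest TSS
#'
#' Distance is measured from each segment's midpoint (or 5' end) to the
#' nearest TSS by absolute genomic distance; the sign is strand-aware:
#' negative = upstream of the assigned gene, positive = downstream.
#' Equidistant TSSs resolve to the lexicographically smallest `gene_id`.
#' Segments on chromosomes without genes get `NA` (unassigned).
#'
#' @param segments Tibble (`chrom`, `start`, `end`, ...).
#' @param genes A [gene_model()] tibble.
#' @param anchor `"midpoint"` (default) or `"start"`.
#' @return `segments` with `gene_id` and `tss_distance` columns appended.
#' @export
tss_distance <- function(segments, genes, anchor = c("midpoint", "start")) {
  anchor <- match.arg(anchor)
  pos <- if (anchor == "midpoint") {
    interval_midpoint(segments$start, segments$end)
  } else {
    segments$start
  }
  gene_id <- rep(NA_character_, nrow(segments))
  dist <- rep(NA_real_, nrow(segments))
  # one representative gene per distinct TSS position: the smallest gene_id
  reps <- genes |>
    dplyr::arrange(.data$chrom, .data$tss, .data$gene_id) |>
    dplyr::distinct(.data$chrom, .data$tss, .keep_all = TRUE)
  for (ch in unique(segments$chrom)) {
    gi <- reps[reps$chrom == ch, ]
    si <- which(segments$chrom == ch)
    if (nrow(gi) == 0L || length(si) == 0L) next
    p <- pos[si]
    i <- findInterval(p, gi$tss)
    lo <- pmax(i, 1L)
    hi <- pmin(i + 1L, nrow(gi))
    d_lo <- abs(p - gi$tss[lo])
    d_hi <- abs(p - gi$tss[hi])
    use_hi <- (i == 0L) | (d_hi < d_lo) |
      (d_hi == d_lo & gi$gene_id[hi] < gi$gene_id[lo])
    pick <- ifelse(use_hi, hi, lo)
    g <- p - gi$tss[pick]
    gene_id[si] <- gi$gene_id[pick]
    dist[si] <- ifelse(gi$strand[pick] == "+", g, -g)
  }
  dplyr::mutate(segments, gene_id = gene_id, tss_distance = dist)
}

tss_bin_levels <- function() {
  bands <- c("0-1 kb", "1-3 kb", "3-5 kb", "5-10 kb", "10-100 kb", ">100 kb")
  c(paste("upstream", rev(bands)), paste("downstream", bands))
}

#' Bin a signed TSS distance into the 12-category scheme
#'
#' Six absolute-distance bands (0-1, 1-3, 3-5, 5-10, 10-100, >100 kb) on
#' each side of the TSS. Boundaries are half-open toward larger distances:
#' |d| = 1000 falls in 1-3 kb. d = 0 counts as downstream.
#'
#' @param distance Signed distances in bp (negative = upstream).
#' @return Ordered factor with the 12 category levels (upstream >100 kb
#'   through downstream >100 kb); `NA` stays `NA`.
#' @export
bin_distance <- function(distance) {
  bands <- c("0-1 kb", "1-3 kb", "3-5 kb", "5-10 kb", "10-100 kb", ">100 kb")
  band <- bands[findInterval(abs(distance), c(0, 1e3, 3e3, 5e3, 1e4, 1e5))]
  side <- ifelse(distance < 0, "upstream", "downstream")
  factor(ifelse(is.na(distance), NA, paste(side, band)),
         levels = tss_bin_levels(), ordered = TRUE)
}

#' Per-category bp fractions of TSS distances
#'
#' The percentage analog: summed site weight per category divided by the
#' total assigned weight, optionally within groups.
#'
#' @param annotated Output of [tss_distance()] with a `weight` column (bp);
#'   unassigned rows (`NA` distance) are dropped with a message.
#' @param by Optional grouping column name (e.g. `"exclusivity"`).
#' @return A `tss_distribution` tibble (`by`..., `category`, `bp`,
#'   `fraction`) covering all 12 categories; fractions sum to 1 per group.
#' @export
tss_distribution <- function(annotated, by = NULL) {
  drop <- is.na(annotated$tss_distance)
  if (any(drop)) {
    message(sum(drop), " unassigned segments (no gene on chromosome) dropped")
    annotated <- annotated[!drop, ]
  }
  out <- annotated |>
    dplyr::mutate(category = bin_distance(.data$tss_distance)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "category"))),
                    .drop = FALSE) |>
    dplyr::summarise(bp = sum(.data$weight), .groups = "drop_last") |>
    dplyr::mutate(fraction = .data$bp / sum(.data$bp)) |>
    dplyr::ungroup()
  class(out) <- c("tss_distribution", class(out))
  out
}

#' Weighted two-sample Kolmogorov-Smirnov test
#'
#' D is the sup-distance between the bp-weighted empirical distribution
#' functions of the two signed-distance samples. The null distribution uses
#' effective sample sizes equal to the number of segments per group (not
#' bp), since bp-level counts would be wildly anti-conservative; for
#' unweighted tie-free small samples the exact Smirnov distribution is
#' used, otherwise the asymptotic Kolmogorov approximation.
#'
#' @param x,y Numeric samples (e.g. inter-only and intra-only distances).
#' @param w_x,w_y Optional positive weights (default 1).
#' @return Tibble: `statistic` (D), `p_value`, `n_x`, `n_y`, `method`.
#' @export
ks_two_sample <- function(x, y, w_x = NULL, w_y = NULL) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (is.null(w_x)) w_x <- rep(1, length(x))
  if (is.null(w_y)) w_y <- rep(1, length(y))
  ecdf_at <- function(v, w, at) {
    o <- order(v)
    cw <- cumsum(w[o]) / sum(w)
    i <- findInterval(at, v[o])
    c(0, cw)[i + 1L]
  }
  support <- sort(unique(c(x, y)))
  D <- max(abs(ecdf_at(x, w_x, support) - ecdf_at(y, w_y, support)))
  m <- length(x)
  n <- length(y)
  unweighted <- all(w_x == w_x[1L]) && all(w_y == w_y[1L])
  ties <- anyDuplicated(c(x, y)) > 0L
  if (unweighted && !ties && m * n <= 1e4) {
    p <- 1 - stats::psmirnov(D, sizes = c(m, n), two.sided = TRUE,
                             exact = TRUE)
    method <- "exact"
  } else {
    t <- sqrt(m * n / (m + n)) * D
    if (t < 0.2) {
      # Kolmogorov tail is 1 to machine precision; the alternating series
      # converges too slowly here
      p <- 1
    } else {
      k <- seq_len(100)
      p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
      p <- min(1, max(0, p))
    }
    method <- "asymptotic"
  }
  tibble::tibble(statistic = D, p_value = p, n_x = m, n_y = n,
                 method = method)
}

#' Compare inter-only vs intra-only TSS-distance distributions
#'
#' Runs [tss_distance()], keeps inter-only and intra-only changed patterns,
#' and returns the per-category distribution table plus the weighted KS
#' test between the two groups.
#'
#' @param recon An `ancestral_recon` with a segment map.
#' @param genes A [gene_model()] tibble.
#' @param anchor Passed to [tss_distance()].
#' @return List: `distribution` (a `tss_distribution` grouped by
#'   `exclusivity`) and `ks` (the [ks_two_sample()] row).
#' @export
compare_change_locations <- function(recon, genes,
                                     anchor = c("midpoint", "start")) {
  excl <- classify_exclusivity(recon)
  seg <- recon$segments |>
    dplyr::left_join(excl, by = "pattern_id") |>
    dplyr::filter(.data$exclusivity %in% c("INTER_ONLY", "INTRA_ONLY")) |>
    dplyr::mutate(weight = .data$end - .data$start)
  ann <- tss_distance(seg, genes, anchor)
  ok <- !is.na(ann$tss_distance)
  inter <- ann$exclusivity == "INTER_ONLY" & ok
  intra <- ann$exclusivity == "INTRA_ONLY" & ok
  ks <- ks_two_sample(ann$tss_distance[inter], ann$tss_distance[intra],
                      ann$weight[inter], ann$weight[intra])
  list(distribution = tss_distribution(ann, by = "exclusivity"), ks = ks)
}

#' Stacked-fraction plot of a TSS-distance distribution
#'
#' @param object A `tss_distribution`.
#' @param ... Unused.
#' @method autoplot tss_distribution
#' @export
autoplot.tss_distribution <- function(object, ...) {
  grp <- setdiff(names(object), c("category", "bp", "fraction"))
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = if (length(grp)) .data[[grp[1]]] else "all",
                                    y = .data$fraction, fill = .data$category)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_viridis_d(direction = -1) +
    ggplot2::labs(x = NULL, y = "fraction of changed bp",
                  fill = "distance to TSS") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
  p
}
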