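# Integration of the six reconstructed modification tracks at progenitor
# nodes: per-gene ON-bp tables over the gene body and the 5' upstream
# window, and combinatorial chromatin-state calls (active = H3K4me3 +
# H3K27ac, bivalent = H3K4me3 + H3K27me3 in the promoter region).

gene_regions <- function(genes, upstream_window) {
  body <- dplyr::transmute(genes, gene_id = .data$gene_id,
                           region = "GENE_BODY", chrom = .data$chrom,
                           start = .data$start, end = .data$end)
  up <- dplyr::transmute(
    genes, gene_id = .data$gene_id, region = "FIVE_PRIME_UPSTREAM",
    chrom = .data$chrom,
    start = ifelse(.data$strand == "+",
                   pmax(0, .data$tss - upstream_window), .data$tss + 1),
    end = ifelse(.data$strand == "+", .data$tss,
                 .data$tss + 1 + upstream_window))
  dplyr::bind_rows(body, up) |> dplyr::filter(.data$end > .data$start)
}

#' Per-gene ON bp of reconstructed node tracks
#'
#' Intersects each internal node's reconstructed ON track with every gene
#' body and 5' upstream window. Rows (gene, region, modification) where
#' every node is 0 are omitted, matching the convention that only
#' modifications present at some node are tabulated.
#'
#' @param node_tracks Tibble from [node_state_tracks()] (`node`,
#'   `modification`, `chrom`, `start`, `end`), possibly concatenated over
#'   modifications.
#' @param genes A [gene_model()] tibble.
#' @param upstream_window 5' upstream extent in bp (default 5000).
#' @return A `node_mark_table` tibble: `gene_id`, `region`, `modification`,
#'   `node`, `bp`.
#' @export
node_gene_bp <- function(node_tracks, genes, upstream_window = 5000) {
  regions <- gene_regions(genes, upstream_window)
  combos <- dplyr::distinct(node_tracks, .data$node, .data$modification)
  out <- purrr::pmap(combos, function(node, modification) {
    trk <- node_tracks[node_tracks$node == node &
                         node_tracks$modification == modification, ]
    bp <- overlap_bp(regions, trk)
    keep <- bp > 0
    if (!any(keep)) return(NULL)
    tibble::tibble(gene_id = regions$gene_id[keep],
                   region = regions$region[keep],
                   modification = modification, node = node, bp = bp[keep])
  }) |>
    purrr::compact() |>
    purrr::list_rbind()
  if (is.null(out) || nrow(out) == 0L) {
    out <- tibble::tibble(gene_id = character(), region = character(),
                          modification = character(), node = character(),
                          bp = numeric())
  }
  # complete the node grid within surviving (gene, region, modification) rows
  grid <- out |>
    dplyr::distinct(.data$gene_id, .data$region, .data$modification) |>
    tidyr::crossing(node = unique(node_tracks$node))
  out <- grid |>
    dplyr::left_join(out, by = c("gene_id", "region", "modification",
                                 "node")) |>
    dplyr::mutate(bp = dplyr::coalesce(.data$bp, 0)) |>
    dplyr::arrange(.data$gene_id, .data$region, .data$modification)
  class(out) <- c("node_mark_table", class(out))
  out
}

#' Call combinatorial chromatin states per gene and node
#'
#' ACTIVE: promoter-region H3K4me3 and H3K27ac both at or above the bp
#' threshold. BIVALENT: H3K4me3 and H3K27me3 both at or above it. The
#' promoter region is the union of the 5' upstream window and the gene
#' body; the threshold (default 200 bp, about one nucleosome footprint) is
#' a convenience layer over the raw bp table, which is always available.
#' Flags are not mutually exclusive and are monotone in the threshold.
#'
#' @param table A `node_mark_table`.
#' @param threshold Minimum ON bp per mark (default 200).
#' @return Tibble (`gene_id`, `node`, `active`, `bivalent`).
#' @export
call_marks <- function(table, threshold = 200) {
  bp <- table |>
    dplyr::group_by(.data$gene_id, .data$node, .data$modification) |>
    dplyr::summarise(bp = sum(.data$bp), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "modification", values_from = "bp",
                       values_fill = 0)
  for (m in c("H3K4me3", "H3K27ac", "H3K27me3")) {
    if (!m %in% names(bp)) bp[[m]] <- 0
  }
  dplyr::transmute(bp, gene_id = .data$gene_id, node = .data$node,
                   active = .data$H3K4me3 >= threshold &
                     .data$H3K27ac >= threshold,
                   bivalent = .data$H3K4me3 >= threshold &
                     .data$H3K27me3 >= threshold)
}

#' Export / import a node-mark table in wide per-node layout
#'
#' TSV with columns `gene_id`, `region`, `modification`, then one column
#' per internal node; round-trips through the reader.
#'
#' @param table A `node_mark_table`.
#' @param path Output path.
#' @export
write_node_mark_table <- function(table, path) {
  wide <- tidyr::pivot_wider(table, names_from = "node",
                             values_from = "bp", values_fill = 0)
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_node_mark_table
#' @export
read_node_mark_table <- function(path) {
  wide <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  out <- tidyr::pivot_longer(wide, -c("gene_id", "region", "modification"),
                             names_to = "node", values_to = "bp")
  class(out) <- c("node_mark_table", class(out))
  out
}
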