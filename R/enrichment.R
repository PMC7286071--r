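# Gene-set over-representation of inferred changes, per branch group:
# hypergeometric upper-tail tests against the annotation universe with
# Benjamini-Hochberg control, the dot-plot-table analog of a
# compareCluster analysis.

#' Read gene sets from a GMT file
#'
#' @param path GMT: one set per line, tab-separated `name`, `description`,
#'   gene ids.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])),
                  vapply(fields, `[[`, "", 1L))
}

#' Write gene sets as GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  readr::write_lines(vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, ""), path)
  invisible(path)
}

#' Harmonize gene sets against a universe
#'
#' Drops out-of-universe ids (with a warning) and discards sets outside the
#' size guards.
#'
#' @param sets Named list of gene-id vectors.
#' @param universe Character vector of all annotated gene ids.
#' @param min_size,max_size Post-harmonization size guards.
#' @return Filtered named list.
#' @export
harmonize_gene_sets <- function(sets, universe, min_size = 5L,
                                max_size = 500L) {
  trimmed <- lapply(sets, intersect, universe)
  lost <- sum(lengths(sets)) - sum(lengths(trimmed))
  if (lost > 0L) {
    warning(lost, " gene-set entries outside the universe dropped",
            call. = FALSE)
  }
  keep <- lengths(trimmed) >= min_size & lengths(trimmed) <= max_size
  trimmed[keep]
}

#' Genes associated with a set of changed segments
#'
#' A gene is assigned when at least one segment overlaps its body or its
#' promoter window (TSS +/- `promoter_window`). Optionally, segments
#' touching nothing are assigned to their nearest-TSS gene.
#'
#' @param segments Tibble (`chrom`, `start`, `end`).
#' @param genes A [gene_model()] tibble.
#' @param promoter_window Half-width of the promoter window in bp
#'   (default 3000).
#' @param fallback_nearest Assign orphan segments to the nearest TSS.
#' @return Character vector of assigned gene ids.
#' @export
assign_genes <- function(segments, genes, promoter_window = 3000,
                         fallback_nearest = FALSE) {
  if (nrow(segments) == 0L) return(character(0))
  seg <- merge_intervals(segments)
  win <- genes |>
    dplyr::mutate(w_start = pmin(.data$start,
                                 pmax(0, .data$tss - promoter_window)),
                  w_end = pmax(.data$end, .data$tss + promoter_window + 1))
  hit <- overlap_bp(dplyr::transmute(win, chrom = .data$chrom,
                                     start = .data$w_start,
                                     end = .data$w_end), seg) > 0
  out <- genes$gene_id[hit]
  if (fallback_nearest) {
    ann <- tss_distance(seg, genes)
    covered <- overlap_bp(seg, dplyr::transmute(win[hit, ],
                                                chrom = .data$chrom,
                                                start = .data$w_start,
                                                end = .data$w_end)) > 0
    out <- union(out, stats::na.omit(ann$gene_id[!covered]))
  }
  sort(unique(out))
}

#' Hypergeometric over-representation p-value
#'
#' Upper tail P(X >= k) for drawing `length(group_genes)` genes from the
#' universe, with the gene set as successes.
#'
#' @param group_genes Genes associated with a branch group (non-empty).
#' @param gene_set Genes of one set (subset of `universe`).
#' @param universe All annotated genes.
#' @return List: `k` (overlap), `p` (upper-tail probability).
#' @export
ora_test <- function(group_genes, gene_set, universe) {
  group_genes <- intersect(group_genes, universe)
  if (length(group_genes) == 0L) stop("empty group", call. = FALSE)
  gene_set <- unique(gene_set)
  if (length(setdiff(gene_set, universe))) {
    stop("gene set not contained in universe", call. = FALSE)
  }
  k <- length(intersect(group_genes, gene_set))
  p <- stats::phyper(k - 1L, length(gene_set),
                     length(universe) - length(gene_set),
                     length(group_genes), lower.tail = FALSE)
  list(k = k, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up control of the false discovery rate: sorted p-values
#' scaled by m/i with a cumulative minimum from the largest rank.
#'
#' @param p Raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Per-group gene-set over-representation table
#'
#' Tests every (group, set) pair and adjusts p-values across the whole
#' table, mirroring a compareCluster-style analysis.
#'
#' @param groups Named list of gene-id vectors (e.g. from
#'   [branch_change_groups()] + [assign_genes()]); empty groups are skipped.
#' @param sets Named list of gene sets (harmonized).
#' @param universe All annotated gene ids.
#' @param alpha Significance threshold on adjusted p (default 0.05).
#' @return A `branch_enrichment` tibble: `group`, `set`, `k`, `n_group`,
#'   `n_set`, `n_universe`, `gene_ratio`, `p`, `p_adj`, `significant`.
#' @export
enrich_groups <- function(groups, sets, universe, alpha = 0.05) {
  groups <- purrr::map(groups, intersect, universe)
  groups <- groups[lengths(groups) > 0L]
  grid <- tidyr::expand_grid(group = names(groups), set = names(sets))
  out <- grid |>
    dplyr::mutate(purrr::map2_dfr(.data$group, .data$set, function(g, s) {
      r <- ora_test(groups[[g]], sets[[s]], universe)
      tibble::tibble(k = r$k, n_group = length(groups[[g]]),
                     n_set = length(sets[[s]]),
                     n_universe = length(universe),
                     gene_ratio = r$k / length(groups[[g]]), p = r$p)
    })) |>
    dplyr::mutate(p_adj = bh_adjust(.data$p),
                  significant = .data$p_adj < alpha)
  class(out) <- c("branch_enrichment", class(out))
  out
}

#' Changed-segment groups for enrichment
#'
#' Builds the row scheme of the per-branch enrichment figure: `Inter (all)`
#' (patterns changing only on inter-type branches), one group per
#' inter-type branch (the inter-only patterns with a `direction` change on
#' that branch -- the "analyzed separately" rows), and one `Intra <type>`
#' group per cell type (patterns changing only on that type's intra
#' branches). Only patterns with at least one change in `direction` on the
#' qualifying branches contribute segments.
#'
#' @param recon An `ancestral_recon` with a segment map.
#' @param direction `"GAIN"` (changes to ON, the default reported
#'   direction) or `"LOSS"`.
#' @return Named list of segment tibbles (`chrom`, `start`, `end`).
#' @export
branch_change_groups <- function(recon, direction = c("GAIN", "LOSS")) {
  direction <- match.arg(direction)
  changes <- map_changes(recon)
  edges <- recon$tree$edges
  seg <- recon$segments
  seg_of <- function(ids) {
    seg[seg$pattern_id %in% ids, c("chrom", "start", "end")]
  }
  per_pattern <- changes |>
    dplyr::group_by(.data$pattern_id) |>
    dplyr::summarise(inter = any(.data$class == "INTER"),
                     intra = any(.data$class == "INTRA"),
                     branches = list(unique(.data$branch)),
                     dir_branches = list(unique(.data$branch[
                       .data$direction == direction])), .groups = "drop")
  has_dir <- lengths(per_pattern$dir_branches) > 0L
  groups <- list()
  inter_only <- per_pattern$inter & !per_pattern$intra
  groups[["Inter (all)"]] <- seg_of(per_pattern$pattern_id[inter_only & has_dir])
  for (br in unique(edges$branch[edges$class == "INTER"])) {
    on_br <- purrr::map_lgl(per_pattern$dir_branches, ~ br %in% .x)
    groups[[br]] <- seg_of(per_pattern$pattern_id[inter_only & on_br])
  }
  types <- unique(recon$tree$sample_map$cell_type)
  intra_branches <- split(edges$branch[edges$class == "INTRA"],
                          find_intra_type(recon$tree))
  for (ty in types) {
    brs <- intra_branches[[ty]]
    if (is.null(brs)) next
    only_ty <- purrr::map_lgl(per_pattern$branches,
                              ~ all(.x %in% brs) && length(.x) > 0L) & has_dir
    groups[[paste("Intra", ty)]] <- seg_of(per_pattern$pattern_id[only_ty])
  }
  groups
}

# cell type owning each INTRA edge (by containing type clade)
find_intra_type <- function(tree) {
  phylo <- tree$phylo
  n_tip <- length(phylo$tip.label)
  intra <- tree$edges[tree$edges$class == "INTRA", ]
  owner <- character(nrow(intra))
  for (ty in names(tree$type_nodes)) {
    nd <- tree$type_nodes[[ty]]
    if (nd <= n_tip) next
    inside <- c(nd, below_nodes(phylo, nd))
    owner[intra$parent %in% inside] <- ty
  }
  owner
}

#' Dot-plot of a branch-enrichment table
#'
#' @param object A `branch_enrichment` tibble.
#' @param ... Unused.
#' @method autoplot branch_enrichment
#' @export
autoplot.branch_enrichment <- function(object, ...) {
  sig_sets <- unique(object$set[object$significant])
  dat <- object[object$set %in% sig_sets & object$k > 0L, ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$group, y = .data$set,
                                    size = .data$gene_ratio,
                                    colour = .data$p_adj)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient(low = "red", high = "blue") +
    ggplot2::labs(x = NULL, y = NULL, size = "gene ratio",
                  colour = "adjusted p") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
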