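# End-to-end orchestration: QC -> encoding -> tree -> ancestral
# reconstruction -> change annotation -> enrichment -> mark integration,
# per modification, with a deterministic JSON manifest. This is the
# package's "run everything" entry point; each stage is equally usable on
# its own.

#' Run the full reconstruction pipeline
#'
#' @param x Either a `sim_epigenome` (all inputs taken from it) or a long
#'   track tibble; in the latter case `layout` and `sample_map` are
#'   required.
#' @param layout A [genome_layout()].
#' @param sample_map Tibble (`sample_id`, `cell_type`).
#' @param backbone Newick over cell types.
#' @param genes Optional [gene_model()] tibble; enables TSS annotation and
#'   mark integration.
#' @param gene_sets Optional named list of gene sets; enables enrichment.
#' @param algorithm `"ACCTRAN"` (default) or `"DELTRAN"`.
#' @param search Run [constrained_search()] for within-type topology
#'   instead of star clades (default FALSE).
#' @param seed Seed for the search's addition sequence.
#' @param promoter_window,upstream_window,bh_alpha,mark_threshold,anchor
#'   Stage thresholds (bp, bp, FDR, bp, TSS anchor).
#' @param direction Change direction used for enrichment grouping.
#' @param outdir Optional directory: per-stage TSV/JSON/BED outputs and a
#'   `manifest.json` recording the configuration are written there.
#' @return An `epitree_run` list: `per_modification` (spm summary, tree,
#'   reconstruction, change table, locations, enrichment), `marks`
#'   (node-mark table and active/bivalent calls), `qc`, `manifest`.
#' @export
run_pipeline <- function(x, layout = NULL, sample_map = NULL,
                         backbone = hematopoiesis_backbone(),
                         genes = NULL, gene_sets = NULL,
                         algorithm = c("ACCTRAN", "DELTRAN"),
                         search = FALSE, seed = 1L,
                         promoter_window = 3000, upstream_window = 5000,
                         bh_alpha = 0.05, mark_threshold = 200,
                         anchor = "midpoint", direction = "GAIN",
                         outdir = NULL) {
  algorithm <- match.arg(algorithm)
  if (inherits(x, "sim_epigenome")) {
    tracks <- x$tracks
    layout <- x$layout
    sample_map <- x$sample_map
    backbone <- x$config$backbone
    if (is.null(genes)) genes <- x$genes
    if (is.null(gene_sets)) gene_sets <- x$gene_sets
  } else {
    tracks <- x
    stopifnot(!is.null(layout), !is.null(sample_map))
  }
  qc <- qc_filter(tracks, layout)
  tracks <- qc$kept
  mods <- unique(tracks$modification)
  universe <- if (!is.null(genes)) genes$gene_id
  sets <- if (!is.null(gene_sets) && !is.null(universe)) {
    harmonize_gene_sets(gene_sets, universe)
  }
  per_mod <- purrr::map(mods, function(mod) {
    trk <- tracks[tracks$modification == mod, ]
    map_mod <- sample_map[sample_map$sample_id %in% trk$sample_id, ]
    spm <- encode_patterns(trk, layout)
    tree <- if (search) {
      constrained_search(spm, backbone, map_mod, seed = seed)
    } else {
      cell_type_tree(backbone, map_mod)
    }
    recon <- resolve_ancestral(tree, spm, algorithm)
    changes <- aggregate_changes(recon)
    locations <- if (!is.null(genes)) {
      tryCatch(compare_change_locations(recon, genes, anchor),
               error = function(e) NULL)
    }
    enrichment <- if (!is.null(sets) && length(sets)) {
      groups <- branch_change_groups(recon, direction)
      gene_groups <- purrr::map(groups, assign_genes, genes = genes,
                                promoter_window = promoter_window)
      enrich_groups(gene_groups, sets, universe, alpha = bh_alpha)
    }
    list(modification = mod, summary = glance(recon), tree = tree,
         recon = recon, changes = changes, locations = locations,
         enrichment = enrichment,
         node_tracks = node_state_tracks(recon))
  })
  names(per_mod) <- mods
  marks <- if (!is.null(genes)) {
    nt <- purrr::list_rbind(purrr::map(per_mod, "node_tracks"))
    tab <- node_gene_bp(nt, genes, upstream_window)
    list(table = tab, calls = call_marks(tab, mark_threshold))
  }
  manifest <- list(
    package = "epitree", version = as.character(utils::packageVersion("epitree")),
    algorithm = algorithm, search = search, seed = seed,
    promoter_window = promoter_window, upstream_window = upstream_window,
    bh_alpha = bh_alpha, mark_threshold = mark_threshold, anchor = anchor,
    direction = direction, modifications = mods,
    n_samples = length(unique(sample_map$sample_id)),
    n_excluded = nrow(qc$excluded))
  run <- structure(list(per_modification = per_mod, marks = marks, qc = qc,
                        manifest = manifest),
                   class = "epitree_run")
  if (!is.null(outdir)) write_run(run, outdir)
  run
}

#' @export
print.epitree_run <- function(x, ...) {
  cat("<epitree_run> ", length(x$per_modification), " modifications (",
      paste(names(x$per_modification), collapse = ", "), ")\n", sep = "")
  for (m in x$per_modification) {
    cat(sprintf("  %-9s score %s bp changes, %s variable bp\n",
                m$modification,
                format(m$summary$score, big.mark = ","),
                format(m$summary$variable_bp, big.mark = ",")))
  }
  invisible(x)
}

#' Inter-type change table in wide layout
#'
#' Rows (modification, change ON/OFF), one column per inter-type branch:
#' the per-branch gain/loss bp table.
#'
#' @param run An `epitree_run` (or an [aggregate_changes()] tibble).
#' @return A wide tibble.
#' @export
change_table <- function(run) {
  agg <- if (inherits(run, "epitree_run")) {
    purrr::list_rbind(purrr::map(run$per_modification, "changes"))
  } else run
  agg |>
    dplyr::filter(.data$class == "INTER") |>
    dplyr::select("modification", "change", "branch", "bp") |>
    tidyr::pivot_wider(names_from = "branch", values_from = "bp")
}

# write per-stage outputs + manifest (deterministic: no timestamps)
write_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(change_table(run), file.path(outdir, "change_table.tsv"),
                   progress = FALSE)
  for (m in run$per_modification) {
    stem <- file.path(outdir, m$modification)
    if (!is.null(m$locations)) {
      readr::write_tsv(m$locations$distribution,
                       paste0(stem, ".tss_distribution.tsv"),
                       progress = FALSE)
      jsonlite::write_json(as.list(m$locations$ks),
                           paste0(stem, ".ks.json"), auto_unbox = TRUE,
                           digits = NA)
    }
    if (!is.null(m$enrichment)) {
      readr::write_tsv(m$enrichment, paste0(stem, ".enrichment.tsv"),
                       progress = FALSE)
    }
    readr::write_lines(render_newick(m$tree), paste0(stem, ".tree.nwk"))
    readr::write_tsv(m$node_tracks, paste0(stem, ".node_states.bed.tsv"),
                     progress = FALSE)
    ch <- map_changes(m$recon)
    seg <- m$recon$segments
    changed <- dplyr::inner_join(ch, seg, by = "pattern_id",
                                 relationship = "many-to-many") |>
      dplyr::select("branch", "direction", "chrom", "start", "end") |>
      dplyr::arrange(.data$branch, .data$direction, .data$chrom, .data$start)
    readr::write_tsv(changed, paste0(stem, ".changes.bed.tsv"),
                     progress = FALSE)
  }
  if (!is.null(run$marks)) {
    write_node_mark_table(run$marks$table,
                          file.path(outdir, "node_marks.tsv"))
    readr::write_tsv(run$marks$calls, file.path(outdir, "mark_calls.tsv"),
                     progress = FALSE)
  }
  jsonlite::write_json(run$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
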