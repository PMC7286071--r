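# Synthetic-data generator: a fully specified world with the statistical
# structure the pipeline assumes. Heritable binary ON/OFF regions evolve
# along the fixed differentiation tree (gain only where the parent is OFF,
# loss only where it is ON), with region-level leaf noise standing in for
# tissue/individual variation, plus genes, gene sets and optionally planted
# functional enrichment on chosen branches. Ground truth (ancestral states
# and per-branch events) is returned for recovery scoring.

#' Simulation configuration
#'
#' Defaults are the stated world of the generator: the eight-type
#' hematopoiesis backbone with 3 samples per type, six modification tracks,
#' 3 x 1 Mb chromosomes, 300 modifiable regions per modification of
#' 500-2000 bp, root ON probability 0.3, per-region change probability 0.05
#' on inter-type and 0.01 on intra-type branches, and 0.01 region-flip leaf
#' noise.
#'
#' @param n_chrom,chrom_length Layout: number and length of chromosomes.
#' @param backbone Newick over cell types (default
#'   [hematopoiesis_backbone()]).
#' @param samples_per_type Samples per cell type (default 3).
#' @param modifications Modification names to simulate.
#' @param regions_per_mod Modifiable regions per modification (default 300).
#' @param region_length Length range (uniform, default 500-2000 bp).
#' @param p0 Root ON probability per region (default 0.3).
#' @param q_inter,q_intra Per-branch per-region gain and loss probability on
#'   inter-/intra-type branches (defaults 0.05 / 0.01).
#' @param noise Leaf region-flip probability (default 0.01).
#' @param n_genes,gene_length Gene count and body-length range.
#' @param n_gene_sets,genes_per_set Gene-set database shape.
#' @param planted Optional tibble (`modification`, `set`, `branch`,
#'   `multiplier`): multiply the gain probability for regions overlapping
#'   the set's gene promoters on that branch.
#' @param promoter_window Promoter half-width used for planting (bp).
#' @param seed Mandatory integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_chrom = 3L, chrom_length = 1e6,
                       backbone = hematopoiesis_backbone(),
                       samples_per_type = 3L,
                       modifications = c("H3K4me1", "H3K4me3", "H3K27ac",
                                         "H3K36me3", "H3K27me3", "H3K9me3"),
                       regions_per_mod = 300L,
                       region_length = c(500L, 2000L),
                       p0 = 0.3, q_inter = 0.05, q_intra = 0.01,
                       noise = 0.01,
                       n_genes = 200L, gene_length = c(2000L, 10000L),
                       n_gene_sets = 20L, genes_per_set = 15L,
                       planted = NULL, promoter_window = 3000L,
                       seed = 1L) {
  stopifnot(p0 >= 0, p0 <= 1, q_inter >= 0, q_inter <= 1,
            q_intra >= 0, q_intra <= 1, noise >= 0, noise <= 1,
            is.numeric(seed), length(seed) == 1L)
  structure(as.list(environment()), class = "sim_config")
}

# place n non-overlapping intervals of the given lengths uniformly on the
# layout (stick-breaking of the slack); returns chrom/start/end
place_regions <- function(layout, n, len_range) {
  lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  chrom <- sample(layout$chrom, n, replace = TRUE,
                  prob = layout$length / sum(layout$length))
  purrr::map2(layout$chrom, layout$length, function(ch, L) {
    l <- lens[chrom == ch]
    if (length(l) == 0L) return(NULL)
    slack <- L - sum(l)
    if (slack < 0) {
      stop("region model infeasible: regions exceed chromosome ", ch,
           call. = FALSE)
    }
    gaps <- diff(c(0, sort(stats::runif(length(l))), 1)) * slack
    starts <- floor(cumsum(gaps[-length(gaps)]) + cumsum(c(0, l[-length(l)])))
    tibble::tibble(chrom = ch, start = starts, end = starts + l)
  }) |>
    purrr::list_rbind()
}

#' Generate a synthetic multi-sample epigenome with ground truth
#'
#' @param config A [sim_config()].
#' @return A `sim_epigenome` list: `config`, `layout`, `sample_map`,
#'   `sample_sheet`, `tree` (a `cell_type_tree` with star within-type
#'   clades), `tracks` (long track tibble over all samples and
#'   modifications), `genes`, `gene_sets`, and `truth` (per-modification
#'   region table, node state matrices, per-branch event list, planted
#'   manifest).
#' @export
simulate_epigenomes <- function(config = sim_config()) {
  cfg <- config
  withr::with_seed(cfg$seed, {
    layout <- genome_layout(paste0("chr", seq_len(cfg$n_chrom)),
                            rep(cfg$chrom_length, cfg$n_chrom))
    bb <- read_newick(cfg$backbone)
    types <- bb$tip.label
    sample_map <- tibble::tibble(
      cell_type = rep(types, each = cfg$samples_per_type),
      sample_id = paste0(rep(types, each = cfg$samples_per_type), "_s",
                         rep(seq_len(cfg$samples_per_type), length(types)))
    )[, c("sample_id", "cell_type")]
    tree <- cell_type_tree(bb, sample_map)
    genes <- {
      g <- place_regions(layout, cfg$n_genes, cfg$gene_length)
      gene_model(sprintf("g%03d", seq_len(nrow(g))), g$chrom,
                 sample(c("+", "-"), nrow(g), replace = TRUE), g$start, g$end)
    }
    gene_sets <- stats::setNames(
      lapply(seq_len(cfg$n_gene_sets), function(i) {
        sort(sample(genes$gene_id, cfg$genes_per_set))
      }),
      sprintf("set%02d", seq_len(cfg$n_gene_sets)))
    # preorder edge order: each edge after the edge above its parent
    eng <- engine_tree(tree)
    preorder <- rev(eng$postorder)
    edges <- tree$edges[order(match(tree$edges$parent, preorder)), ]
    labs <- eng$labels
    promoters <- dplyr::transmute(
      genes, chrom = .data$chrom,
      start = pmax(0, .data$tss - cfg$promoter_window),
      end = .data$tss + cfg$promoter_window + 1)
    sims <- purrr::map(cfg$modifications, function(mod) {
      reg <- place_regions(layout, cfg$regions_per_mod, cfg$region_length)
      reg <- dplyr::mutate(reg, region_id = paste0(mod, "_r",
                                                   seq_len(nrow(reg))))
      states <- matrix(0L, nrow(reg), eng$n_node,
                       dimnames = list(reg$region_id, labs))
      states[, eng$root] <- stats::rbinom(nrow(reg), 1L, cfg$p0)
      events <- list()
      for (i in seq_len(nrow(edges))) {
        e <- edges[i, ]
        q <- if (e$class == "INTER") cfg$q_inter else cfg$q_intra
        q_gain <- rep(q, nrow(reg))
        if (!is.null(cfg$planted)) {
          pl <- cfg$planted[cfg$planted$modification == mod &
                              cfg$planted$branch == e$branch, ]
          if (nrow(pl)) {
            for (j in seq_len(nrow(pl))) {
              prom <- promoters[genes$gene_id %in% gene_sets[[pl$set[j]]], ]
              hot <- overlap_bp(reg, merge_intervals(prom)) > 0
              q_gain[hot] <- pmin(1, q_gain[hot] * pl$multiplier[j])
            }
          }
        }
        ps <- states[, e$parent]
        u <- stats::runif(nrow(reg))
        gain <- ps == 0L & u < q_gain
        loss <- ps == 1L & u < q
        states[, e$child] <- ps + gain - loss
        if (any(gain | loss)) {
          events[[length(events) + 1L]] <- tibble::tibble(
            modification = mod, branch = e$branch, class = e$class,
            region_id = reg$region_id[gain | loss],
            direction = ifelse(gain[gain | loss], "GAIN", "LOSS"))
        }
      }
      # leaf noise: whole-region flips
      leaf_states <- states[, seq_len(eng$n_tip), drop = FALSE]
      if (cfg$noise > 0) {
        flip <- matrix(stats::runif(length(leaf_states)) < cfg$noise,
                       nrow(leaf_states))
        leaf_states[flip] <- 1L - leaf_states[flip]
      }
      tracks <- purrr::map(seq_len(eng$n_tip), function(ti) {
        on <- leaf_states[, ti] == 1L
        if (!any(on)) return(NULL)
        merge_intervals(reg[on, c("chrom", "start", "end")]) |>
          dplyr::mutate(sample_id = eng$phylo$tip.label[ti],
                        modification = mod, .before = 1L)
      }) |> purrr::compact() |> purrr::list_rbind()
      ev <- purrr::list_rbind(events)
      if (nrow(ev) == 0L) {
        ev <- tibble::tibble(modification = character(), branch = character(),
                             class = character(), region_id = character(),
                             direction = character())
      }
      list(regions = reg, node_states = states,
           events = ev, tracks = tracks,
           leaf_states = leaf_states)
    })
    names(sims) <- cfg$modifications
    tracks <- purrr::list_rbind(purrr::map(sims, "tracks")) |>
      dplyr::left_join(sample_map, by = "sample_id") |>
      dplyr::select("sample_id", "cell_type", "modification", "chrom",
                    "start", "end")
    sheet <- sample_map |>
      tidyr::crossing(modification = cfg$modifications) |>
      dplyr::mutate(tissue = "synthetic", individual = .data$sample_id,
                    subtype = "none",
                    bed_path = paste0(.data$sample_id, ".",
                                      .data$modification, ".bed")) |>
      dplyr::select("sample_id", "cell_type", "tissue", "individual",
                    "subtype", "modification", "bed_path")
    structure(list(config = cfg, layout = layout, sample_map = sample_map,
                   sample_sheet = sheet, tree = tree, tracks = tracks,
                   genes = genes, gene_sets = gene_sets,
                   truth = list(regions = purrr::map(sims, "regions"),
                                node_states = purrr::map(sims, "node_states"),
                                events = purrr::list_rbind(
                                  purrr::map(sims, "events")),
                                planted = cfg$planted)),
              class = "sim_epigenome")
  })
}

#' Write a simulated dataset in the formats the pipeline consumes
#'
#' Emits per-sample BED files, a TSV sample sheet, a chromosome-sizes file,
#' the tree in newick, a GTF of gene features, the gene sets in GMT, and
#' the ground truth as JSON.
#'
#' @param sim A `sim_epigenome`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(sim$sample_sheet, file.path(dir, "sample_sheet.tsv"),
                   progress = FALSE)
  readr::write_tsv(tibble::tibble(chrom = sim$layout$chrom,
                                  length = sim$layout$length),
                   file.path(dir, "chrom.sizes"), col_names = FALSE,
                   progress = FALSE)
  for (i in seq_len(nrow(sim$sample_sheet))) {
    row <- sim$sample_sheet[i, ]
    trk <- sim$tracks[sim$tracks$sample_id == row$sample_id &
                        sim$tracks$modification == row$modification, ]
    write_bed(trk, file.path(dir, row$bed_path), sim$layout)
  }
  readr::write_lines(render_newick(sim$tree), file.path(dir, "tree.nwk"))
  gtf <- sprintf("%s\tepitree_sim\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
                 sim$genes$chrom, sim$genes$start + 1, sim$genes$end,
                 sim$genes$strand, sim$genes$gene_id)
  readr::write_lines(gtf, file.path(dir, "genes.gtf"))
  write_gmt(sim$gene_sets, file.path(dir, "gene_sets.gmt"))
  jsonlite::write_json(list(events = sim$truth$events,
                            planted = sim$truth$planted),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Plant clean synapomorphies on every edge of a tree
#'
#' Builds a site-pattern matrix in which each edge of the tree carries
#' `n_per_edge` identical noiseless synapomorphic sites (leaves below the
#' edge ON, all others OFF), collapsed into one weighted pattern per edge.
#' Used to test topology recovery under maximal signal.
#'
#' @param tree A `cell_type_tree`.
#' @param n_per_edge Sites per edge (pattern weight).
#' @return A `site_pattern_matrix` without a segment map.
#' @export
simulate_site_patterns <- function(tree, n_per_edge = 50L) {
  eng <- engine_tree(tree)
  tipsets <- descendant_tips(eng$phylo)
  samples <- eng$phylo$tip.label
  states <- purrr::map(tree$edges$child, function(nd) {
    v <- integer(length(samples))
    v[tipsets[[nd]]] <- 1L
    v
  })
  states <- do.call(rbind, states)
  keep <- rowSums(states) < length(samples)  # drop root-spanning patterns
  site_pattern_matrix(samples, states[keep, , drop = FALSE],
                      rep(n_per_edge, sum(keep)))
}

#' Random resolved within-type topologies
#'
#' @param sample_map Tibble (`sample_id`, `cell_type`).
#' @param seed Integer seed.
#' @return Named list of newick fragments (no trailing `;`), one per type
#'   with at least 3 samples, for [cell_type_tree()]'s `intra` argument.
#' @export
random_resolved_intra <- function(sample_map, seed = 1L) {
  withr::with_seed(seed, {
    types <- unique(sample_map$cell_type)
    out <- list()
    for (ty in types) {
      s <- sample_map$sample_id[sample_map$cell_type == ty]
      if (length(s) < 3L) next
      tr <- ape::rtree(length(s), tip.label = sample(s), br = NULL)
      out[[ty]] <- sub(";$", "", ape::write.tree(tr))
    }
    out
  })
}

#' Score a reconstruction against simulation truth
#'
#' Internal-node state accuracy is matching bp over all truth internal
#' nodes shared with the reconstruction (genome-wide, so constant regions
#' count); event precision and recall are over (branch, region, direction)
#' triples, where a region counts as changed when at least half of its bp
#' carries the change on that branch.
#'
#' @param recon An `ancestral_recon` for one modification.
#' @param sim The `sim_epigenome` it was computed from.
#' @return List: `state_accuracy`, `event_precision`, `event_recall`,
#'   `per_node` tibble.
#' @export
score_recovery <- function(recon, sim) {
  mod <- recon$modification
  stopifnot(mod %in% names(sim$truth$node_states))
  truth_states <- sim$truth$node_states[[mod]]
  reg <- sim$truth$regions[[mod]]
  genome <- sum(sim$layout$length)
  internal <- setdiff(colnames(truth_states), sim$sample_map$sample_id)
  internal <- intersect(internal, colnames(recon$states))
  recon_tracks <- node_state_tracks(recon, internal)
  per_node <- purrr::map(internal, function(nd) {
    tr_true <- merge_intervals(reg[truth_states[, nd] == 1L,
                                   c("chrom", "start", "end")])
    tr_rec <- recon_tracks[recon_tracks$node == nd,
                           c("chrom", "start", "end")]
    a <- sum(tr_true$end - tr_true$start)
    b <- sum(tr_rec$end - tr_rec$start)
    ab <- intersect_bp(tr_true, tr_rec)
    tibble::tibble(node = nd, accuracy = (genome - (a + b - 2 * ab)) / genome)
  }) |> purrr::list_rbind()
  # event triples
  tev <- sim$truth$events
  tev <- tev[tev$modification == mod, c("branch", "region_id", "direction")]
  changes <- map_changes(recon)
  seg <- recon$segments
  rec_triples <- changes |>
    dplyr::distinct(.data$branch, .data$direction) |>
    purrr::pmap(function(branch, direction) {
      ids <- changes$pattern_id[changes$branch == branch &
                                  changes$direction == direction]
      cs <- merge_intervals(seg[seg$pattern_id %in% ids,
                                c("chrom", "start", "end")])
      cov <- overlap_bp(reg, cs)
      hit <- cov >= 0.5 * (reg$end - reg$start)
      if (!any(hit)) return(NULL)
      tibble::tibble(branch = branch, region_id = reg$region_id[hit],
                     direction = direction)
    }) |> purrr::compact() |> purrr::list_rbind()
  if (is.null(rec_triples) || nrow(rec_triples) == 0L) {
    rec_triples <- tibble::tibble(branch = character(),
                                  region_id = character(),
                                  direction = character())
  }
  both <- dplyr::inner_join(tev, rec_triples,
                            by = c("branch", "region_id", "direction"))
  list(state_accuracy = mean(per_node$accuracy),
       event_precision = if (nrow(rec_triples)) nrow(both) / nrow(rec_triples)
                         else NA_real_,
       event_recall = if (nrow(tev)) nrow(both) / nrow(tev) else NA_real_,
       per_node = per_node)
}
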