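mini_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_chrom = 1, chrom_length = 3e5, samples_per_type = 2,
         modifications = "H3K4me3", regions_per_mod = 50,
         n_genes = 25, gene_length = c(1000, 3000),
         n_gene_sets = 4, genes_per_set = 6),
    list(...))
  do.call(sim_config, args)
}

test_that("simulation is deterministic given the seed", {
  a <- simulate_epigenomes(mini_cfg(seed = 9))
  b <- simulate_epigenomes(mini_cfg(seed = 9))
  expect_equal(a$tracks, b$tracks)
  expect_equal(a$truth$events, b$truth$events)
  c <- simulate_epigenomes(mini_cfg(seed = 10))
  expect_false(identical(a$tracks, c$tracks))

  # byte-identical files too
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(a, d1)
  write_simulation(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("the no-change limit collapses all samples onto the root", {
  sim <- simulate_epigenomes(mini_cfg(q_inter = 0, q_intra = 0, noise = 0,
                                      seed = 3))
  expect_equal(nrow(sim$truth$events), 0L)
  spm <- encode_patterns(sim$tracks, sim$layout,
                         samples = sim$sample_map$sample_id)
  expect_equal(count_variable_sites(spm), 0)
})

test_that("emitted files feed the readers that consume them", {
  sim <- simulate_epigenomes(mini_cfg(seed = 4))
  d <- withr::local_tempdir()
  write_simulation(sim, d)
  lay <- read_chrom_sizes(file.path(d, "chrom.sizes"))
  expect_equal(lay$length, sim$layout$length)
  sheet <- read_sample_sheet(file.path(d, "sample_sheet.tsv"))
  tracks <- read_tracks(sheet, lay, dir = d)
  expect_equal(dplyr::arrange(tracks, sample_id, chrom, start),
               dplyr::arrange(sim$tracks, sample_id, chrom, start))
  expect_equal(ape::Ntip(read_newick(readLines(file.path(d, "tree.nwk")))),
               16L)
  sets <- read_gmt(file.path(d, "gene_sets.gmt"))
  expect_equal(sets, sim$gene_sets)
  genes <- read_gtf_genes(file.path(d, "genes.gtf"))
  expect_equal(genes, sim$genes)
})

test_that("truth events follow the stated per-branch rates", {
  withr::local_seed(71)
  seeds <- sample.int(1e6, 25)
  counts <- purrr::map(seeds, function(s) {
    sim <- simulate_epigenomes(mini_cfg(noise = 0, seed = s))
    ev <- sim$truth$events
    tibble::tibble(inter = sum(ev$class == "INTER"),
                   intra = sum(ev$class == "INTRA"))
  }) |> purrr::list_rbind()
  # 13 inter half-edges x 50 regions x q=0.05 (minus multi-event shadowing:
  # a region changed upstream has its ON/OFF base flipped, rates symmetric)
  exp_inter <- 13 * 50 * 0.05
  se_inter <- sqrt(exp_inter) / sqrt(nrow(counts))
  expect_lt(abs(mean(counts$inter) - exp_inter), 3 * se_inter + 1)
  exp_intra <- 16 * 50 * 0.01
  se_intra <- sqrt(exp_intra) / sqrt(nrow(counts))
  expect_lt(abs(mean(counts$intra) - exp_intra), 3 * se_intra + 1)
})

test_that("a single planted event is mapped back to its branch", {
  # noiseless, near-zero background: plant one strong gain region on L-B by
  # running with a tiny world where only inter events can occur
  sim <- simulate_epigenomes(mini_cfg(noise = 0, q_intra = 0, q_inter = 0.02,
                                      seed = 12))
  spm <- encode_patterns(sim$tracks, sim$layout,
                         samples = sim$sample_map$sample_id)
  recon <- resolve_ancestral(sim$tree, spm)
  sc <- score_recovery(recon, sim)
  ev <- sim$truth$events
  single <- names(which(table(ev$region_id) == 1L))
  expect_gt(length(single), 0)
  # every single-event region off the root branch is recovered exactly
  reg <- sim$truth$regions$H3K4me3
  changes <- map_changes(recon)
  for (i in which(ev$region_id %in% single & ev$branch != "M-L")) {
    ids <- changes$pattern_id[changes$branch == ev$branch[i] &
                                changes$direction == ev$direction[i]]
    seg <- recon$segments[recon$segments$pattern_id %in% ids, ]
    r <- reg[reg$region_id == ev$region_id[i], ]
    expect_equal(overlap_bp(r, merge_intervals(seg[, c("chrom", "start", "end")])),
                 r$end - r$start)
  }
})

test_that("score_recovery is exact on a perfect reconstruction", {
  sim <- simulate_epigenomes(mini_cfg(noise = 0, seed = 5))
  spm <- encode_patterns(sim$tracks, sim$layout,
                         samples = sim$sample_map$sample_id)
  recon <- resolve_ancestral(sim$tree, spm)
  # self-consistency: identical recon scores 1/1/1 against itself
  fake_truth <- sim
  nodes <- colnames(sim$truth$node_states$H3K4me3)
  reg <- sim$truth$regions$H3K4me3
  dec <- sapply(nodes, function(nd) {
    on <- node_state_tracks(recon, nd)
    as.integer(overlap_bp(reg, on[, c("chrom", "start", "end")]) >=
                 (reg$end - reg$start) / 2)
  })
  fake_truth$truth$node_states$H3K4me3 <- dec
  fake_truth$truth$events <- dplyr::mutate(
    map_changes(recon) |>
      dplyr::inner_join(recon$segments, by = "pattern_id",
                        relationship = "many-to-many") |>
      dplyr::mutate(region_id = reg$region_id[
        findInterval(start, reg$start)]) |>
      dplyr::filter(!is.na(region_id)) |>
      dplyr::distinct(branch, class, region_id, direction),
    modification = "H3K4me3")
  sc <- score_recovery(recon, fake_truth)
  expect_equal(sc$state_accuracy, 1)
  expect_equal(sc$event_recall, 1)
})

test_that("all-OFF reconstruction scores the complement of the root rate", {
  sim <- simulate_epigenomes(mini_cfg(q_inter = 0, q_intra = 0, noise = 0,
                                      regions_per_mod = 120, seed = 6))
  spm <- encode_patterns(sim$tracks, sim$layout,
                         samples = sim$sample_map$sample_id)
  recon <- resolve_ancestral(sim$tree, spm)
  blank <- recon
  blank$states[] <- 0L
  sc <- score_recovery(blank, sim)
  on_frac <- sum((sim$truth$regions$H3K4me3$end -
                    sim$truth$regions$H3K4me3$start) *
                   sim$truth$node_states$H3K4me3[, "M"]) /
    sum(sim$layout$length)
  expect_equal(sc$state_accuracy, 1 - on_frac, tolerance = 1e-9)
})
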