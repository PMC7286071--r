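# Shared fixtures, all built in code.

quartet <- function() read_newick("((A,B)ab,(C,D)cd)root;")

tiny_layout <- function(len = 1000, n = 1) {
  genome_layout(paste0("chr", seq_len(n)), rep(len, n))
}

# random normalized track on a layout
random_track <- function(layout, n = 10) {
  chrom <- sample(layout$chrom, n, replace = TRUE)
  len <- layout$length[match(chrom, layout$chrom)]
  start <- floor(runif(n) * (len - 50))
  end <- pmin(len, start + 1 + floor(runif(n) * 200))
  merge_intervals(tibble::tibble(chrom = chrom, start = start, end = end))
}

# random rooted tree, possibly multifurcating, tips t1..tn
random_test_tree <- function(n_tips, p_collapse = 0.3) {
  tr <- ape::rtree(n_tips, tip.label = paste0("t", seq_len(n_tips)))
  tr$edge.length <- runif(nrow(tr$edge))
  internal <- tr$edge[, 2L] > ape::Ntip(tr)
  tr$edge.length[internal] <- ifelse(runif(sum(internal)) < p_collapse,
                                     1e-9, 1)
  tr <- ape::di2multi(tr, tol = 1e-6)
  tr$edge.length <- NULL
  tr
}

# number of changes implied by a full node labeling on a phylo
labeling_changes <- function(phylo, states) {
  sum(states[phylo$edge[, 1L]] != states[phylo$edge[, 2L]])
}

# sample map for the eight-type backbone
hema_samples <- function(per_type = 3) {
  types <- c("Er", "Me", "Eo", "Ne", "Mo", "Nk", "T", "B")
  tibble::tibble(
    sample_id = paste0(rep(types, each = per_type), "_s",
                       rep(seq_len(per_type), length(types))),
    cell_type = rep(types, each = per_type))
}

# per-nucleotide brute-force partition oracle: states of every position
per_bp_states <- function(tracks, layout, samples) {
  purrr::map(layout$chrom, function(ch) {
    L <- layout$length[layout$chrom == ch]
    st <- sapply(samples, function(s) {
      on <- rep(0L, L)
      iv <- tracks[tracks$sample_id == s & tracks$chrom == ch, ]
      for (i in seq_len(nrow(iv))) {
        on[(iv$start[i] + 1):iv$end[i]] <- 1L
      }
      on
    })
    colnames(st) <- samples
    st
  }) |> do.call(what = rbind)
}

# sorted split keys of a cell-type tree (topology comparison)
split_keys <- function(ctt) sort(epitree:::phylo_split_keys(ctt$phylo))
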