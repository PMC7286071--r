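# Constrained heuristic parsimony search. The between-type backbone and the
# monophyly of every cell type are fixed; what the search infers is the
# topology inside each type's clade (and any polytomy of the backbone, which
# a rearrangement may resolve). The search is random-addition-sequence
# stepwise insertion followed by tree bisection-reconnection (TBR) swapping
# with first-improvement acceptance, every proposal being checked against
# the constraints before it is scored.

# --- unrooted tree structure ------------------------------------------------
# ut: list(edges = E x 2 integer matrix of node ids, label = named character
# vector (leaf labels, indexed by node id as character), next_id)

ut_new <- function(edges, label, next_id) {
  list(edges = edges, label = label, next_id = next_id)
}

ut_from_phylo <- function(phylo) {
  n_tip <- length(phylo$tip.label)
  label <- stats::setNames(phylo$tip.label, as.character(seq_len(n_tip)))
  edges <- phylo$edge
  root <- n_tip + 1L
  kids <- edges[edges[, 1L] == root, 2L]
  if (length(kids) == 2L) {  # suppress the degree-2 root
    edges <- edges[edges[, 1L] != root, , drop = FALSE]
    edges <- rbind(edges, kids)
  }
  ut_new(unname(edges), label, n_tip + phylo$Nnode + 1L)
}

ut_leaves <- function(ut) as.integer(names(ut$label))

# adjacency list over node ids present in edges
ut_adj <- function(ut) {
  nodes <- unique(as.vector(ut$edges))
  adj <- vector("list", max(nodes))
  for (i in seq_len(nrow(ut$edges))) {
    a <- ut$edges[i, 1L]; b <- ut$edges[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# Root the unrooted tree into an ape-compatible phylo. root_edge: row index
# of ut$edges to subdivide with a degree-2 root; NULL roots at the neighbor
# of the first leaf.
ut_to_phylo <- function(ut, root_edge = NULL) {
  edges <- ut$edges
  next_id <- ut$next_id
  if (length(ut$label) == 1L) stop("tree with a single leaf", call. = FALSE)
  if (!is.null(root_edge)) {
    ab <- edges[root_edge, ]
    edges <- edges[-root_edge, , drop = FALSE]
    rootid <- next_id
    edges <- rbind(edges, c(rootid, ab[1L]), c(rootid, ab[2L]))
  } else {
    first <- as.integer(names(ut$label)[1L])
    nb <- c(edges[edges[, 1L] == first, 2L], edges[edges[, 2L] == first, 1L])
    rootid <- nb[1L]
  }
  # orient by DFS from rootid
  adj <- list2env(list(), hash = TRUE)
  for (i in seq_len(nrow(edges))) {
    a <- as.character(edges[i, 1L]); b <- as.character(edges[i, 2L])
    assign(a, c(mget(a, envir = adj, ifnotfound = list(integer(0)))[[1L]],
                edges[i, 2L]), envir = adj)
    assign(b, c(mget(b, envir = adj, ifnotfound = list(integer(0)))[[1L]],
                edges[i, 1L]), envir = adj)
  }
  parent <- integer(0)
  child <- integer(0)
  stack <- rootid
  seen <- as.character(rootid)
  order_nodes <- rootid
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (w in get(as.character(v), envir = adj)) {
      if (!as.character(w) %in% seen) {
        seen <- c(seen, as.character(w))
        parent <- c(parent, v)
        child <- c(child, w)
        stack <- c(stack, w)
        order_nodes <- c(order_nodes, w)
      }
    }
  }
  is_leaf <- as.character(order_nodes) %in% names(ut$label)
  tips <- order_nodes[is_leaf]
  internals <- order_nodes[!is_leaf]
  internals <- c(rootid, setdiff(internals, rootid))
  newid <- integer(max(c(order_nodes, 1L)))
  newid[tips] <- seq_along(tips)
  newid[internals] <- length(tips) + seq_along(internals)
  phylo <- structure(list(edge = cbind(newid[parent], newid[child]),
                          tip.label = unname(ut$label[as.character(tips)]),
                          Nnode = length(internals)),
                     class = "phylo")
  attr(phylo, "order") <- NULL
  phylo
}

# leaf-label set below each edge child, keyed for split comparison
phylo_split_keys <- function(phylo) {
  tipsets <- descendant_tips(phylo)
  kids <- phylo$edge[, 2L]
  vapply(kids, function(nd) {
    paste(sort(phylo$tip.label[tipsets[[nd]]]), collapse = "|")
  }, "")
}

set_key <- function(x) paste(sort(x), collapse = "|")

# required sample splits implied by backbone + monophyly
required_splits <- function(backbone, sample_map) {
  bb <- if (inherits(backbone, "phylo")) backbone else read_newick(backbone)
  tipsets <- descendant_tips(bb)
  n_tip <- length(bb$tip.label)
  all_samples <- sample_map$sample_id
  samples_of <- function(types) {
    sample_map$sample_id[sample_map$cell_type %in% types]
  }
  nodes <- setdiff(seq_len(n_tip + bb$Nnode), n_tip + 1L)  # all but root
  out <- purrr::map(nodes, function(nd) samples_of(bb$tip.label[tipsets[[nd]]]))
  sizes <- lengths(out)
  out <- out[sizes >= 2L & sizes <= length(all_samples) - 2L]
  unique(vapply(out, set_key, ""))
}

#' Check a sample tree against backbone and monophyly constraints
#'
#' Every cell type must be monophyletic and every backbone clade must appear
#' as a split of the sample tree (further resolution of backbone polytomies
#' is allowed).
#'
#' @param tree A `cell_type_tree`, [ape::phylo] over sample ids, or internal
#'   unrooted structure.
#' @param backbone Newick string or phylo over cell types.
#' @param sample_map Tibble (`sample_id`, `cell_type`).
#' @return `TRUE`/`FALSE`.
#' @export
satisfies_constraints <- function(tree, backbone, sample_map) {
  phylo <- if (inherits(tree, "cell_type_tree")) tree$phylo
           else if (inherits(tree, "phylo")) tree
           else ut_to_phylo(tree)
  req <- required_splits(backbone, sample_map)
  keys <- phylo_split_keys(phylo)
  all_s <- sort(sample_map$sample_id)
  comp <- function(k) set_key(setdiff(all_s, strsplit(k, "|", fixed = TRUE)[[1L]]))
  all(vapply(req, function(k) k %in% keys || comp(k) %in% keys, NA))
}

# subdivide edge row i with a new node; returns list(ut, node)
ut_subdivide <- function(ut, i) {
  ab <- ut$edges[i, ]
  p <- ut$next_id
  edges <- ut$edges[-i, , drop = FALSE]
  edges <- rbind(edges, c(ab[1L], p), c(p, ab[2L]))
  list(ut = ut_new(edges, ut$label, p + 1L), node = p)
}

# attach a new leaf with label lab on edge row i
ut_attach_leaf <- function(ut, i, lab) {
  sd <- ut_subdivide(ut, i)
  leaf <- sd$ut$next_id
  edges <- rbind(sd$ut$edges, c(sd$node, leaf))
  label <- c(sd$ut$label, stats::setNames(lab, as.character(leaf)))
  ut_new(edges, label, leaf + 1L)
}

# node sets of the two components after dropping edge row i
ut_components <- function(ut, i) {
  edges <- ut$edges[-i, , drop = FALSE]
  seeds <- ut$edges[i, ]
  comp <- function(seed) {
    seen <- seed
    frontier <- seed
    while (length(frontier)) {
      hit <- edges[, 1L] %in% frontier | edges[, 2L] %in% frontier
      nxt <- setdiff(unique(as.vector(edges[hit, , drop = FALSE])), seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    seen
  }
  list(a = comp(seeds[1L]), b = comp(seeds[2L]))
}

# remove edge row i and suppress the stranded degree-2 endpoints; returns
# list of two fragment uts (each edges may be empty when the fragment is a
# single node) plus their node sets
ut_bisect <- function(ut, i) {
  cps <- ut_components(ut, i)
  ends <- ut$edges[i, ]
  edges <- ut$edges[-i, , drop = FALSE]
  frag <- function(nodes, cut_end) {
    e <- edges[edges[, 1L] %in% nodes & edges[, 2L] %in% nodes, , drop = FALSE]
    # suppress cut_end if it is now degree 2 and unlabeled
    deg <- sum(e == cut_end)
    if (deg == 2L && !as.character(cut_end) %in% names(ut$label)) {
      nb <- c(e[e[, 1L] == cut_end, 2L], e[e[, 2L] == cut_end, 1L])
      e <- e[e[, 1L] != cut_end & e[, 2L] != cut_end, , drop = FALSE]
      e <- rbind(e, nb)
      nodes <- setdiff(nodes, cut_end)
    }
    list(edges = e, nodes = nodes)
  }
  list(a = frag(cps$a, ends[1L]), b = frag(cps$b, ends[2L]))
}

# reconnect two fragments at attachment options oa/ob (edge row index or 0 =
# the fragment's single node); returns a ut
ut_reconnect <- function(frag_a, frag_b, oa, ob, ut) {
  next_id <- ut$next_id
  pick <- function(frag, o) {
    if (o == 0L) {
      list(edges = frag$edges, node = frag$nodes[1L])
    } else {
      ab <- frag$edges[o, ]
      p <- next_id
      next_id <<- next_id + 1L
      list(edges = rbind(frag$edges[-o, , drop = FALSE],
                         c(ab[1L], p), c(p, ab[2L])),
           node = p)
    }
  }
  pa <- pick(frag_a, oa)
  pb <- pick(frag_b, ob)
  keep <- names(ut$label) %in% as.character(c(frag_a$nodes, frag_b$nodes,
                                              pa$node, pb$node))
  ut_new(rbind(pa$edges, pb$edges, c(pa$node, pb$node)),
         ut$label[keep], next_id)
}

# reduce a matrix to its variable patterns (constants never change the score)
variable_spm <- function(spm) {
  v <- spm$is_variable
  site_pattern_matrix(spm$samples, spm$states[v, , drop = FALSE],
                      spm$weight[v], modification = spm$modification)
}

ut_score <- function(ut, spm) {
  if (nrow(spm$states) == 0L) return(0)
  parsimony_score(ut_to_phylo(ut), spm)
}

#' Constrained parsimony tree search
#'
#' Infers the within-type topology of the cell-type tree by weighted
#' parsimony: random-addition-sequence stepwise insertion (each sample may
#' only join its own type's clade), then TBR branch swapping in which any
#' rearrangement violating monophyly or the backbone is rejected before
#' scoring. First-improvement acceptance, iterated to a local optimum;
#' deterministic for a given seed.
#'
#' @param spm A `site_pattern_matrix` over all samples.
#' @param backbone Newick string or phylo over cell types.
#' @param sample_map Tibble (`sample_id`, `cell_type`); every type needs at
#'   least one sample.
#' @param seed Integer seed for the addition sequence (default 1).
#' @param max_sweeps Upper bound on full TBR sweeps.
#' @return A `cell_type_tree` whose weighted parsimony score is less than or
#'   equal to the stepwise starting tree's.
#' @export
constrained_search <- function(spm, backbone, sample_map, seed = 1L,
                               max_sweeps = 20L) {
  bb <- if (inherits(backbone, "phylo")) backbone else read_newick(backbone)
  sample_map <- tibble::as_tibble(sample_map)
  if (!all(bb$tip.label %in% sample_map$cell_type)) {
    stop("backbone type without samples: ",
         setdiff(bb$tip.label, sample_map$cell_type)[1], call. = FALSE)
  }
  vspm <- variable_spm(spm)
  withr::with_seed(seed, {
    first <- sample_map |>
      dplyr::slice_sample(prop = 1) |>
      dplyr::distinct(.data$cell_type, .keep_all = TRUE)
    rest <- sample_map |>
      dplyr::anti_join(first, by = "sample_id") |>
      dplyr::slice_sample(prop = 1)
  })
  start <- bb
  start$tip.label <- first$sample_id[match(bb$tip.label, first$cell_type)]
  start$node.label <- NULL
  ut <- ut_from_phylo(start)
  type_of <- stats::setNames(sample_map$cell_type, sample_map$sample_id)
  # stepwise addition within the growing type clade
  if (nrow(rest)) {
    for (r in seq_len(nrow(rest))) {
      s <- rest$sample_id[r]
      ty <- rest$cell_type[r]
      members <- names(ut$label)[unname(ut$label) %in%
                                   sample_map$sample_id[sample_map$cell_type == ty]]
      member_ids <- as.integer(members)
      cand <- which(vapply(seq_len(nrow(ut$edges)), function(i) {
        cps <- ut_components(ut, i)
        leaves_a <- intersect(cps$a, ut_leaves(ut))
        leaves_b <- intersect(cps$b, ut_leaves(ut))
        all(leaves_a %in% member_ids) || all(leaves_b %in% member_ids)
      }, NA))
      best <- NULL
      best_score <- Inf
      for (i in cand) {
        trial <- ut_attach_leaf(ut, i, s)
        sc <- ut_score(trial, vspm)
        if (sc < best_score) {
          best <- trial
          best_score <- sc
        }
      }
      ut <- best
    }
  }
  score <- ut_score(ut, vspm)
  # TBR swapping
  if (nrow(vspm$states) > 0L) {
    req_check <- function(u) satisfies_constraints(u, bb, sample_map)
    sweep <- 0L
    repeat {
      sweep <- sweep + 1L
      improved <- FALSE
      for (i in seq_len(nrow(ut$edges))) {
        bis <- ut_bisect(ut, i)
        opts_a <- if (nrow(bis$a$edges)) seq_len(nrow(bis$a$edges)) else 0L
        opts_b <- if (nrow(bis$b$edges)) seq_len(nrow(bis$b$edges)) else 0L
        for (oa in opts_a) {
          for (ob in opts_b) {
            trial <- ut_reconnect(bis$a, bis$b, oa, ob, ut)
            if (!req_check(trial)) next
            sc <- ut_score(trial, vspm)
            if (sc < score) {
              ut <- trial
              score <- sc
              improved <- TRUE
              break
            }
          }
          if (improved) break
        }
        if (improved) break
      }
      if (!improved || sweep >= max_sweeps) break
    }
  }
  finalize_search_tree(ut, bb, sample_map)
}

# root the searched tree on the backbone root edge and transfer backbone
# node labels to the matching MRCAs
finalize_search_tree <- function(ut, bb, sample_map) {
  root_kids <- bb$edge[bb$edge[, 1L] == length(bb$tip.label) + 1L, 2L]
  tipsets <- descendant_tips(bb)
  side <- sample_map$sample_id[sample_map$cell_type %in%
                                 bb$tip.label[tipsets[[root_kids[1L]]]]]
  want <- set_key(side)
  all_s <- sort(sample_map$sample_id)
  want_c <- set_key(setdiff(all_s, strsplit(want, "|", fixed = TRUE)[[1L]]))
  hit <- NA_integer_
  for (i in seq_len(nrow(ut$edges))) {
    cps <- ut_components(ut, i)
    ka <- set_key(unname(ut$label[as.character(intersect(cps$a, ut_leaves(ut)))]))
    if (ka == want || ka == want_c) {
      hit <- i
      break
    }
  }
  if (is.na(hit)) stop("search result lost the backbone root split",
                       call. = FALSE)
  phylo <- ut_to_phylo(ut, root_edge = hit)
  phylo <- label_from_backbone(phylo, bb, sample_map)
  new_cell_type_tree(phylo, sample_map)
}

# assign backbone internal-node labels (and type labels) to their MRCAs
label_from_backbone <- function(phylo, bb, sample_map) {
  n_tip <- length(phylo$tip.label)
  labs <- rep("", phylo$Nnode)
  bb_labs <- node_labels(bb)
  tipsets <- descendant_tips(bb)
  for (nd in seq_len(length(bb$tip.label) + bb$Nnode)) {
    types <- bb$tip.label[tipsets[[nd]]]
    s <- sample_map$sample_id[sample_map$cell_type %in% types]
    tips <- match(s, phylo$tip.label)
    node <- if (length(tips) == 1L) next else ape::getMRCA(phylo, tips)
    labs[node - n_tip] <- bb_labs[nd]
  }
  phylo$node.label <- labs
  phylo
}
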