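# Cell-type trees: leaves are samples, internal nodes are progenitor states.
# Cell types are constrained to be monophyletic, and the between-type
# topology follows a fixed differentiation backbone. Edges are classified as
# INTER (separating cell types: type stems, lineage backbone, root edges) or
# INTRA (inside one type's clade: tissue/individual/subtype variation).

#' Parse a newick tree
#'
#' Thin wrapper over [ape::read.tree()] adding the validation this package
#' needs: a parse failure raises an error, duplicate leaf labels are
#' rejected, and multifurcations are preserved.
#'
#' @param text A newick string (terminal `;` optional).
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(text) {
  if (!grepl(";\\s*$", text)) text <- paste0(text, ";")
  tr <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("malformed newick: ", text, call. = FALSE)
  }
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf labels in newick: ",
         tr$tip.label[duplicated(tr$tip.label)][1], call. = FALSE)
  }
  tr
}

#' Render a tree as newick
#'
#' @param tree An [ape::phylo] or `cell_type_tree`.
#' @return A newick string (internal node labels preserved).
#' @export
render_newick <- function(tree) {
  if (inherits(tree, "cell_type_tree")) tree <- tree$phylo
  ape::write.tree(tree)
}

#' The fixed hematopoiesis backbone
#'
#' The traditional hierarchical differentiation model over the eight
#' profiled blood cell types: myeloid lineage M = ((Er,Me), ((Eo,Ne), Mo)),
#' lymphoid lineage L = (Nk, T, B) left unresolved, rooted between M and L
#' at the implied stem-cell position.
#'
#' @return A newick string over cell-type placeholders.
#' @export
hematopoiesis_backbone <- function() {
  "(((Er,Me)ErMe,((Eo,Ne)EoNe,Mo)EoNeMo)M,(Nk,T,B)L)root;"
}

# internal: all node labels (tips then internal), auto-filling blanks
node_labels <- function(phylo) {
  nl <- phylo$node.label
  if (is.null(nl)) nl <- rep("", phylo$Nnode)
  blank <- !nzchar(nl) | is.na(nl)
  nl[blank] <- paste0("n", which(blank) + length(phylo$tip.label))
  c(phylo$tip.label, nl)
}

#' Build a cell-type tree from a backbone and a sample map
#'
#' Each cell-type placeholder leaf of the backbone is replaced by a clade of
#' that type's samples. The within-type topology is a star (polytomy) unless
#' `intra` supplies a resolved newick subtree for a type; use
#' [constrained_search()] to infer within-type structure from data.
#'
#' @param backbone Newick string (or phylo) over cell-type names, rooted;
#'   the root's two child lineages define the reported merged root branch.
#' @param sample_map Tibble with columns `sample_id`, `cell_type`.
#' @param intra Optional named list of newick fragments (without trailing
#'   `;`), one per cell type, whose leaves are that type's sample ids.
#' @return A `cell_type_tree`: list with `phylo`, `sample_map`, and an edge
#'   table (`parent`, `child`, `parent_label`, `child_label`, `branch`,
#'   `class`) where the two root half-edges share one merged branch name.
#' @export
cell_type_tree <- function(backbone, sample_map, intra = NULL) {
  bb <- if (inherits(backbone, "phylo")) backbone else read_newick(backbone)
  sample_map <- tibble::as_tibble(sample_map)
  types <- unique(sample_map$cell_type)
  missing <- setdiff(types, bb$tip.label)
  if (length(missing)) {
    stop("cell types absent from backbone: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  empty <- setdiff(bb$tip.label, types)
  if (length(empty)) {
    stop("backbone types without samples: ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  frag <- function(type) {
    s <- sample_map$sample_id[sample_map$cell_type == type]
    if (!is.null(intra) && type %in% names(intra)) {
      paste0(intra[[type]], type)
    } else if (length(s) == 1L) {
      s
    } else {
      paste0("(", paste(s, collapse = ","), ")", type)
    }
  }
  labs <- node_labels(bb)
  render <- function(node) {
    if (node <= length(bb$tip.label)) return(frag(bb$tip.label[node]))
    kids <- bb$edge[bb$edge[, 1L] == node, 2L]
    paste0("(", paste(vapply(kids, render, ""), collapse = ","), ")",
           labs[node])
  }
  root <- length(bb$tip.label) + 1L
  phylo <- read_newick(paste0(render(root), ";"))
  new_cell_type_tree(phylo, sample_map)
}

# assemble the object + edge table from a rooted phylo whose tips are samples
new_cell_type_tree <- function(phylo, sample_map) {
  if (!setequal(phylo$tip.label, sample_map$sample_id)) {
    stop("tree leaves and sample map disagree", call. = FALSE)
  }
  labs <- node_labels(phylo)
  root <- length(phylo$tip.label) + 1L
  edges <- tibble::tibble(parent = phylo$edge[, 1L], child = phylo$edge[, 2L],
                          parent_label = labs[phylo$edge[, 1L]],
                          child_label = labs[phylo$edge[, 2L]])
  root_kids <- edges$child[edges$parent == root]
  merged <- paste(labs[root_kids], collapse = "-")
  edges$branch <- ifelse(edges$parent == root, merged,
                         paste0(edges$parent_label, "-", edges$child_label))
  edges$class <- NA_character_
  out <- structure(list(phylo = phylo, sample_map = sample_map,
                        edges = edges, labels = labs, root = root),
                   class = "cell_type_tree")
  classify_branches(out)
}

#' @export
print.cell_type_tree <- function(x, ...) {
  cat("<cell_type_tree> ", length(x$phylo$tip.label), " samples, ",
      length(unique(x$sample_map$cell_type)), " cell types; ",
      sum(x$edges$class == "INTER"), " inter-type / ",
      sum(x$edges$class == "INTRA"), " intra-type edges\n", sep = "")
  invisible(x)
}

# descendant tips of every node (list indexed by node id)
descendant_tips <- function(phylo) {
  n_tip <- length(phylo$tip.label)
  n_all <- n_tip + phylo$Nnode
  po <- ape::reorder.phylo(phylo, "postorder")
  tips <- vector("list", n_all)
  for (i in seq_len(n_tip)) tips[[i]] <- i
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]; c <- po$edge[k, 2L]
    tips[[p]] <- c(tips[[p]], tips[[c]])
  }
  tips
}

#' Classify edges as inter- or intra-type
#'
#' For each cell type, its "type node" is the MRCA of its samples (the leaf
#' itself for singleton types). Edges strictly inside a type clade (parent at
#' or below the type node) are INTRA; all other edges (type stems, lineage
#' backbone, root half-edges) are INTER. Errors when a type is not
#' monophyletic.
#'
#' @param tree A `cell_type_tree`.
#' @return The tree with its edge table's `class` column filled and a
#'   `type_nodes` named vector (node id per cell type).
#' @export
classify_branches <- function(tree) {
  phylo <- tree$phylo
  n_tip <- length(phylo$tip.label)
  tipsets <- descendant_tips(phylo)
  type_of <- tree$sample_map$cell_type[match(phylo$tip.label,
                                             tree$sample_map$sample_id)]
  types <- unique(tree$sample_map$cell_type)
  type_nodes <- integer(length(types))
  names(type_nodes) <- types
  intra_nodes <- integer(0)
  for (ty in types) {
    tips <- which(type_of == ty)
    node <- if (length(tips) == 1L) tips else ape::getMRCA(phylo, tips)
    if (!setequal(tipsets[[node]], tips)) {
      stop("cell type not monophyletic: ", ty, call. = FALSE)
    }
    type_nodes[ty] <- node
    if (node > n_tip) intra_nodes <- c(intra_nodes, node, below_nodes(phylo, node))
  }
  tree$edges$class <- ifelse(tree$edges$parent %in% intra_nodes,
                             "INTRA", "INTER")
  tree$type_nodes <- type_nodes
  tree
}

# all nodes strictly below `node`
below_nodes <- function(phylo, node) {
  out <- integer(0)
  frontier <- phylo$edge[phylo$edge[, 1L] == node, 2L]
  while (length(frontier)) {
    out <- c(out, frontier)
    frontier <- phylo$edge[phylo$edge[, 1L] %in% frontier, 2L]
  }
  out
}

# Rooted traversal structure for the parsimony engine. Accepts a phylo or a
# cell_type_tree; leaves keep their tip order, labels cover all nodes.
engine_tree <- function(tree) {
  phylo <- if (inherits(tree, "cell_type_tree")) tree$phylo else tree
  n_tip <- length(phylo$tip.label)
  po <- ape::reorder.phylo(phylo, "postorder")
  children <- split(po$edge[, 2L], factor(po$edge[, 1L],
                                          levels = seq_len(n_tip + phylo$Nnode)))
  parent <- integer(n_tip + phylo$Nnode)
  parent[po$edge[, 2L]] <- po$edge[, 1L]
  list(phylo = phylo, n_tip = n_tip, n_node = n_tip + phylo$Nnode,
       children = children,
       postorder = unique(po$edge[, 1L]),
       parent = parent, root = n_tip + 1L,
       labels = node_labels(phylo))
}
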