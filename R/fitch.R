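# Weighted binary Fitch parsimony and ancestral-state reconstruction.
#
# Characters are undirected with equal ON->OFF and OFF->ON costs. The up
# pass is Hartigan vote counting, which handles multifurcations exactly; a
# min-cost up/down dynamic program yields exact MPR state sets, and
# ACCTRAN/DELTRAN pick a single labeling by placing ambiguous changes as
# close to (ACCTRAN) or as far from (DELTRAN) the root as possible. All
# passes are vectorized across site patterns.

INF_COST <- 1e9

# tip state matrix in engine tip order (patterns x tips)
tip_states <- function(x, eng) {
  states <- if (inherits(x, "site_pattern_matrix")) x$states else as.matrix(x)
  idx <- match(eng$phylo$tip.label, colnames(states))
  if (anyNA(idx)) {
    stop("tree leaf without a state: ",
         eng$phylo$tip.label[which(is.na(idx))[1]], call. = FALSE)
  }
  states[, idx, drop = FALSE]
}

#' Fitch parsimony length of binary site patterns
#'
#' Minimum number of state changes on the tree explaining the leaf states,
#' per pattern. Multifurcations use the exact vote-counting recurrence; with
#' a degree-2 root the score equals the unrooted parsimony length.
#'
#' @param tree A `cell_type_tree` or [ape::phylo].
#' @param x A `site_pattern_matrix`, or a 0/1 matrix (patterns x samples,
#'   colnames = leaf labels), or a named 0/1 vector for a single pattern.
#' @return Integer vector of per-pattern lengths.
#' @export
fitch_score <- function(tree, x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L, dimnames = list(NULL, names(x)))
  eng <- engine_tree(tree)
  ts <- tip_states(x, eng)
  P <- nrow(ts)
  code <- matrix(0L, P, eng$n_node)
  code[, seq_len(eng$n_tip)] <- ts + 1L
  len <- integer(P)
  for (v in eng$postorder) {
    kids <- eng$children[[v]]
    v0 <- integer(P)
    v1 <- integer(P)
    for (k in kids) {
      v0 <- v0 + (code[, k] != 2L)
      v1 <- v1 + (code[, k] != 1L)
    }
    len <- len + length(kids) - pmax(v0, v1)
    code[, v] <- 1L * (v0 >= v1) + 2L * (v1 >= v0)
  }
  len
}

#' Weighted parsimony score of a site-pattern matrix
#'
#' @param tree A `cell_type_tree` or [ape::phylo].
#' @param spm A `site_pattern_matrix`.
#' @return Total bp-weighted changes: sum over patterns of weight x length.
#' @export
parsimony_score <- function(tree, spm) {
  len <- numeric(nrow(spm$states))
  v <- spm$is_variable
  if (any(v)) {
    len[v] <- fitch_score(tree, spm$states[v, , drop = FALSE])
  }
  sum(spm$weight * len)
}

# up/down min-cost DP. Returns list(U0,U1,D0,D1, minlen) matrices P x nodes.
mpr_dp <- function(eng, ts) {
  P <- nrow(ts)
  N <- eng$n_node
  U0 <- matrix(0, P, N)
  U1 <- matrix(0, P, N)
  U0[, seq_len(eng$n_tip)] <- ifelse(ts == 0L, 0, INF_COST)
  U1[, seq_len(eng$n_tip)] <- ifelse(ts == 1L, 0, INF_COST)
  for (v in eng$postorder) {
    a0 <- numeric(P)
    a1 <- numeric(P)
    for (k in eng$children[[v]]) {
      a0 <- a0 + pmin(U0[, k], U1[, k] + 1)
      a1 <- a1 + pmin(U1[, k], U0[, k] + 1)
    }
    U0[, v] <- a0
    U1[, v] <- a1
  }
  D0 <- matrix(0, P, N)
  D1 <- matrix(0, P, N)
  for (v in rev(eng$postorder)) {
    for (k in eng$children[[v]]) {
      ex0 <- U0[, v] - pmin(U0[, k], U1[, k] + 1) + D0[, v]
      ex1 <- U1[, v] - pmin(U1[, k], U0[, k] + 1) + D1[, v]
      D0[, k] <- pmin(ex0, ex1 + 1)
      D1[, k] <- pmin(ex1, ex0 + 1)
    }
  }
  list(U0 = U0, U1 = U1, D0 = D0, D1 = D1,
       minlen = pmin(U0[, eng$root], U1[, eng$root]))
}

#' MPR state sets at every node
#'
#' The set of states a node takes in at least one most-parsimonious
#' labeling of the rooted tree.
#'
#' @inheritParams fitch_score
#' @return Integer matrix (patterns x nodes) of set codes: 1 = \{OFF\},
#'   2 = \{ON\}, 3 = \{OFF, ON\}. Columns follow the tree's node numbering
#'   (tips first); leaf columns are their observed singletons.
#' @export
mpr_state_sets <- function(tree, x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L, dimnames = list(NULL, names(x)))
  eng <- engine_tree(tree)
  ts <- tip_states(x, eng)
  dp <- mpr_dp(eng, ts)
  in0 <- (dp$U0 + dp$D0) <= dp$minlen
  in1 <- (dp$U1 + dp$D1) <= dp$minlen
  sets <- 1L * in0 + 2L * in1
  colnames(sets) <- eng$labels
  sets
}

#' Reconstruct ancestral ON/OFF states
#'
#' Resolves every pattern to a single most-parsimonious labeling. ACCTRAN
#' prefers a state differing from the parent whenever both choices remain
#' minimal (changes accelerate toward the root); DELTRAN prefers the
#' parent's state (changes are delayed toward the tips). A root whose MPR
#' set is \{OFF, ON\} resolves to OFF, a fixed documented tie-break.
#' Constant patterns bypass the engine: every node takes the constant state.
#'
#' @param tree A `cell_type_tree`.
#' @param spm A `site_pattern_matrix` whose samples are the tree's leaves.
#' @param algorithm `"ACCTRAN"` (default, used for all reporting) or
#'   `"DELTRAN"`.
#' @return An `ancestral_recon` object: node state matrix (patterns x
#'   nodes), per-pattern lengths, pattern weights/segments, and the weighted
#'   parsimony score in bp x changes.
#' @export
resolve_ancestral <- function(tree, spm, algorithm = c("ACCTRAN", "DELTRAN")) {
  algorithm <- match.arg(algorithm)
  eng <- engine_tree(tree)
  ts_all <- tip_states(spm, eng)
  P <- nrow(ts_all)
  states <- matrix(0L, P, eng$n_node)
  colnames(states) <- eng$labels
  len <- numeric(P)
  # constant patterns: uniform labeling, zero changes
  const <- !spm$is_variable
  if (any(const)) {
    states[const, ] <- ts_all[const, 1L]
  }
  vi <- which(spm$is_variable)
  if (length(vi)) {
    ts <- ts_all[vi, , drop = FALSE]
    dp <- mpr_dp(eng, ts)
    sub <- matrix(0L, length(vi), eng$n_node)
    sub[, eng$root] <- as.integer(dp$U1[, eng$root] < dp$U0[, eng$root])
    accel <- algorithm == "ACCTRAN"
    for (v in rev(eng$postorder)) {
      sv <- sub[, v]
      for (k in eng$children[[v]]) {
        same <- ifelse(sv == 0L, dp$U0[, k], dp$U1[, k])
        diff <- ifelse(sv == 0L, dp$U1[, k], dp$U0[, k]) + 1
        change <- if (accel) diff <= same else diff < same
        sub[, k] <- ifelse(change, 1L - sv, sv)
      }
    }
    states[vi, ] <- sub
    len[vi] <- dp$minlen
  }
  structure(list(tree = tree, algorithm = algorithm, states = states,
                 pattern_weight = spm$weight, is_variable = spm$is_variable,
                 pattern_length = len, segments = spm$segments,
                 samples = spm$samples, modification = spm$modification,
                 score = sum(spm$weight * len)),
            class = "ancestral_recon")
}

#' @export
print.ancestral_recon <- function(x, ...) {
  cat("<ancestral_recon> ", x$algorithm, ", ", length(x$pattern_weight),
      " patterns", if (!is.na(x$modification)) paste0(" [", x$modification, "]"),
      "\n  weighted parsimony score ", format(x$score, big.mark = ","),
      " bp changes\n", sep = "")
  invisible(x)
}

#' Per-branch change calls for every pattern
#'
#' Compares each child's resolved state with its parent's. The two root
#' half-edges are reported under the single merged root branch (the edge
#' the root subdivides, e.g. `M-L`), so the undirected root placement does
#' not create a spurious branch.
#'
#' @param recon An `ancestral_recon`.
#' @return Tibble with one row per (pattern, branch) change: `pattern_id`,
#'   `branch`, `class`, `direction` (`"GAIN"` = OFF to ON along the edge,
#'   `"LOSS"`), `weight` (bp).
#' @export
map_changes <- function(recon) {
  edges <- recon$tree$edges
  st <- recon$states
  out <- purrr::pmap(edges[, c("parent", "child", "branch", "class")],
                     function(parent, child, branch, class) {
                       ps <- st[, parent]
                       cs <- st[, child]
                       ch <- which(ps != cs)
                       if (!length(ch)) return(NULL)
                       tibble::tibble(pattern_id = ch, branch = branch,
                                      class = class,
                                      direction = ifelse(cs[ch] == 1L,
                                                         "GAIN", "LOSS"),
                                      weight = recon$pattern_weight[ch])
                     })
  out <- purrr::list_rbind(purrr::compact(out))
  if (nrow(out) == 0L) {
    out <- tibble::tibble(pattern_id = integer(), branch = character(),
                          class = character(), direction = character(),
                          weight = numeric())
  }
  out
}

#' Aggregate changes into a per-branch gain/loss bp table
#'
#' The analog of a per-branch change-count table: for every branch and
#' direction, the total bp of sites changing there. `change` uses the
#' ON/OFF vocabulary (`GAIN` of modification = change to "ON").
#'
#' @param recon An `ancestral_recon` (or a change tibble from
#'   [map_changes()] plus the tree via `tree`).
#' @param tree Required when `recon` is a change tibble.
#' @return Tibble (`modification`, `branch`, `class`, `change`, `bp`) over
#'   the full branch x \{ON, OFF\} grid (zeros included); the two root
#'   half-edges are already merged.
#' @export
aggregate_changes <- function(recon, tree = NULL) {
  if (inherits(recon, "ancestral_recon")) {
    changes <- map_changes(recon)
    tree <- recon$tree
    modification <- recon$modification
  } else {
    changes <- recon
    modification <- NA_character_
  }
  grid <- tree$edges |>
    dplyr::distinct(.data$branch, .data$class) |>
    tidyr::crossing(direction = c("GAIN", "LOSS"))
  changes |>
    dplyr::group_by(.data$branch, .data$class, .data$direction) |>
    dplyr::summarise(bp = sum(.data$weight), .groups = "drop") |>
    dplyr::right_join(grid, by = c("branch", "class", "direction")) |>
    dplyr::mutate(bp = dplyr::coalesce(.data$bp, 0),
                  change = ifelse(.data$direction == "GAIN", "ON", "OFF"),
                  modification = modification, .before = 1L) |>
    dplyr::select("modification", "branch", "class", "change", "bp") |>
    dplyr::arrange(match(.data$branch, unique(tree$edges$branch)),
                   dplyr::desc(.data$change))
}

#' Decode ancestral states into per-node ON interval tracks
#'
#' @param recon An `ancestral_recon` built from a matrix with a segment map.
#' @param nodes Node labels to decode; defaults to all internal nodes.
#' @return Tibble (`node`, `modification`, `chrom`, `start`, `end`) of
#'   merged ON intervals per node.
#' @export
node_state_tracks <- function(recon, nodes = NULL) {
  stopifnot(!is.null(recon$segments))
  labs <- colnames(recon$states)
  if (is.null(nodes)) {
    nodes <- setdiff(labs, recon$samples)
  }
  seg <- recon$segments
  out <- purrr::map(nodes, function(nd) {
    on <- recon$states[seg$pattern_id, nd] == 1L
    if (!any(on)) return(NULL)
    merge_intervals(seg[on, c("chrom", "start", "end")]) |>
      dplyr::mutate(node = nd, modification = recon$modification,
                    .before = 1L)
  }) |>
    purrr::compact() |>
    purrr::list_rbind()
  if (nrow(out) == 0L) {
    out <- tibble::tibble(node = character(), modification = character(),
                          chrom = character(), start = numeric(),
                          end = numeric())
  }
  out
}

#' Exhaustive parsimony oracle for small trees
#'
#' Enumerates every internal labeling; intended for tests only.
#'
#' @param tree A `cell_type_tree` or [ape::phylo] with at most ~14 internal
#'   nodes.
#' @param pattern Named 0/1 vector (names = leaf labels).
#' @return List: `length` (minimum changes), `labelings` (matrix of all
#'   most-parsimonious internal labelings, columns named by node), and
#'   `mpr_sets` (set codes per node as in [mpr_state_sets()]).
#' @export
brute_force_parsimony <- function(tree, pattern) {
  eng <- engine_tree(tree)
  n_int <- eng$n_node - eng$n_tip
  if (n_int > 14L) stop("tree too large for exhaustive enumeration",
                        call. = FALSE)
  ts <- tip_states(matrix(pattern, 1L, dimnames = list(NULL, names(pattern))),
                   eng)
  combos <- as.matrix(expand.grid(rep(list(0:1), n_int)))
  full <- cbind(matrix(ts, nrow(combos), eng$n_tip, byrow = TRUE), combos)
  edges <- rbind(eng$phylo$edge)
  cost <- rowSums(abs(full[, edges[, 1L], drop = FALSE] -
                        full[, edges[, 2L], drop = FALSE]))
  m <- min(cost)
  lab <- full[cost == m, , drop = FALSE]
  colnames(lab) <- eng$labels
  sets <- 1L * (apply(lab == 0L, 2L, any)) + 2L * (apply(lab == 1L, 2L, any))
  names(sets) <- eng$labels
  list(length = m, labelings = lab, mpr_sets = sets)
}

#' @method glance ancestral_recon
#' @export
glance.ancestral_recon <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm,
                 modification = x$modification,
                 n_samples = length(x$samples),
                 n_patterns = length(x$pattern_weight),
                 variable_bp = sum(x$pattern_weight[x$is_variable]),
                 total_bp = sum(x$pattern_weight),
                 score = x$score)
}

#' @method tidy ancestral_recon
#' @export
tidy.ancestral_recon <- function(x, ...) {
  aggregate_changes(x)
}
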