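#' Label tree leaves as reference or query
#'
#' Splits the leaves of a reference-seeded phylogeny into reference taxa
#' (curated, taxonomically named seed sequences) and query OTUs (everything
#' else). All downstream clade analysis is defined on this labelling.
#'
#' @param tree A `phylo` object.
#' @param reference_ids Character vector of reference leaf labels; must
#'   intersect the tree's leaf set.
#' @return A `roled_tree`: the `phylo` object with a `leaf_roles` element, a
#'   named character vector over the tips with values `"reference"` or
#'   `"query"`.
#' @export
assign_roles <- function(tree, reference_ids) {
  stopifnot(inherits(tree, "phylo"))
  refs <- intersect(tree$tip.label, reference_ids)
  if (!length(refs))
    stop("no reference id matches a tree leaf; wrong tree/reference pairing?",
         call. = FALSE)
  roles <- stats::setNames(
    ifelse(tree$tip.label %in% refs, "reference", "query"), tree$tip.label)
  tree$leaf_roles <- roles
  class(tree) <- unique(c("roled_tree", class(tree)))
  tree
}

#' Leaf labels by role
#' @param tree A `roled_tree`.
#' @return Character vector of leaf labels.
#' @export
reference_leaves <- function(tree) {
  names(tree$leaf_roles)[tree$leaf_roles == "reference"]
}

#' @rdname reference_leaves
#' @export
query_leaves <- function(tree) {
  names(tree$leaf_roles)[tree$leaf_roles == "query"]
}

# lexicographic min/sort under C collation, locale-independent
lex_sort <- function(x) sort(x, method = "radix")

#' Root a tree on a reference pendant edge
#'
#' Roots deterministically on the pendant edge of the lexicographically
#' smallest reference leaf. Pairwise leaf path lengths are unchanged, and the
#' set of maximal query-only subtrees is invariant to which reference hosts
#' the root, so results are reproducible regardless of how the (typically
#' unrooted) inference output was oriented.
#'
#' @param tree A `roled_tree` with at least one reference leaf.
#' @return The rooted `roled_tree`.
#' @export
root_at_reference <- function(tree) {
  stopifnot(inherits(tree, "roled_tree"))
  refs <- reference_leaves(tree)
  if (!length(refs)) stop("no reference leaf to root at", call. = FALSE)
  anchor <- lex_sort(refs)[1]
  roles <- tree$leaf_roles
  tr <- tree
  class(tr) <- "phylo"
  if (ape::is.rooted(tr) && length(tr$tip.label) > 2L) tr <- ape::unroot(tr)
  if (length(tr$tip.label) > 2L)
    tr <- ape::root(tr, outgroup = anchor, resolve.root = TRUE)
  tr$leaf_roles <- roles[tr$tip.label]
  class(tr) <- unique(c("roled_tree", class(tr)))
  tr
}

# parent pointer vector: parent[node] (0 for root)
node_parents <- function(tree) {
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  parent <- integer(n_nodes)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  parent
}

# depth of every node from the root, in branch-length units
node_depths_from_root <- function(tree) {
  n_tip <- ape::Ntip(tree)
  depth <- numeric(n_tip + tree$Nnode)
  po <- ape::reorder.phylo(tree, "postorder")
  for (i in rev(seq_len(nrow(po$edge)))) {    # reverse postorder = preorder
    depth[po$edge[i, 2]] <- depth[po$edge[i, 1]] + po$edge.length[i]
  }
  depth
}

#' Patristic distance between two leaves
#'
#' Sum of branch lengths along the unique path between two leaves, in
#' substitutions per site. Computed from root depths and the most recent
#' common ancestor.
#'
#' @param tree A `phylo` object.
#' @param leaf_a,leaf_b Leaf labels.
#' @return Non-negative numeric distance; 0 when `leaf_a == leaf_b`.
#' @export
patristic_distance <- function(tree, leaf_a, leaf_b) {
  ia <- match(leaf_a, tree$tip.label)
  ib <- match(leaf_b, tree$tip.label)
  if (anyNA(c(ia, ib)))
    stop("unknown leaf label: ",
         paste(c(leaf_a, leaf_b)[is.na(c(ia, ib))], collapse = ", "),
         call. = FALSE)
  if (ia == ib) return(0)
  parent <- node_parents(tree)
  depth <- node_depths_from_root(tree)
  anc <- integer(0)
  v <- ia
  while (v != 0L) { anc <- c(anc, v); v <- parent[v] }
  v <- ib
  while (!(v %in% anc)) v <- parent[v]
  depth[ia] + depth[ib] - 2 * depth[v]
}

#' Nearest-reference distances for all query leaves
#'
#' For every query leaf, the minimum patristic distance to any reference
#' leaf and the identity of that reference. Implemented as a two-pass
#' (post-order then pre-order) dynamic program, O(edges) for all queries at
#' once; ties are broken by the lexicographically smallest reference label.
#'
#' @param tree A `roled_tree` with at least one reference leaf.
#' @return A data.frame with columns `leaf`, `nearest_reference`,
#'   `distance`, one row per query leaf (tree tip order).
#' @export
nearest_reference_distances <- function(tree) {
  stopifnot(inherits(tree, "roled_tree"))
  n_tip <- ape::Ntip(tree)
  n_nodes <- n_tip + tree$Nnode
  roles <- tree$leaf_roles[tree$tip.label]
  if (!any(roles == "reference")) stop("no reference leaf", call. = FALSE)

  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge
  elen <- po$edge.length
  # down[v]: min distance from v to a reference leaf within v's subtree
  down <- rep(Inf, n_nodes)
  down_ref <- rep(NA_character_, n_nodes)
  is_ref_tip <- seq_len(n_tip)[roles == "reference"]
  down[is_ref_tip] <- 0
  down_ref[is_ref_tip] <- tree$tip.label[is_ref_tip]
  closer <- function(d1, r1, d2, r2) {
    # is candidate (d2, r2) strictly better than incumbent (d1, r1)?
    d2 < d1 || (d2 == d1 && !is.na(r2) && (is.na(r1) || r2 < r1))
  }
  for (i in seq_len(nrow(edge))) {
    p <- edge[i, 1]; ch <- edge[i, 2]
    cand <- down[ch] + elen[i]
    if (closer(down[p], down_ref[p], cand, down_ref[ch])) {
      down[p] <- cand; down_ref[p] <- down_ref[ch]
    }
  }
  # up[v]: min distance from v to a reference leaf outside v's subtree
  up <- rep(Inf, n_nodes)
  up_ref <- rep(NA_character_, n_nodes)
  children <- split(seq_len(nrow(edge)), edge[, 1])
  for (i in rev(seq_len(nrow(edge)))) {   # preorder over child edges
    p <- edge[i, 1]; ch <- edge[i, 2]
    best_d <- up[p]; best_r <- up_ref[p]
    for (j in children[[as.character(p)]]) {
      sib <- edge[j, 2]
      if (sib == ch) next
      cand <- down[sib] + elen[j]
      if (closer(best_d, best_r, cand, down_ref[sib])) {
        best_d <- cand; best_r <- down_ref[sib]
      }
    }
    up[ch] <- best_d + elen[i]
    up_ref[ch] <- best_r
  }
  q <- which(roles == "query")
  data.frame(leaf = tree$tip.label[q],
             nearest_reference = up_ref[q],
             distance = up[q],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Nearest reference for a single query leaf
#'
#' @param tree A `roled_tree`.
#' @param query_leaf A query-role leaf label.
#' @return A list with `reference` (the arg-min reference label, ties broken
#'   lexicographically) and `distance`.
#' @export
nearest_reference_distance <- function(tree, query_leaf) {
  stopifnot(inherits(tree, "roled_tree"))
  if (!query_leaf %in% tree$tip.label)
    stop("unknown leaf label: ", query_leaf, call. = FALSE)
  if (tree$leaf_roles[[query_leaf]] != "query")
    stop("'", query_leaf, "' is a reference leaf, not a query", call. = FALSE)
  nn <- nearest_reference_distances(tree)
  row <- nn[nn$leaf == query_leaf, ]
  list(reference = row$nearest_reference, distance = row$distance)
}
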