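#' Delimit novel clades: maximal query-only monophyletic groups
#'
#' A novel clade is the largest monophyletic group whose leaves are all
#' query OTUs; its parent clade contains at least one reference taxon. On a
#' tree rooted on a reference pendant edge these maximal query-pure subtrees
#' are unique, so a deterministic post-order sweep yields the same final
#' clade set as any progressive agglomeration from random starting leaves.
#' Under a polytomy, sibling query children of a reference-containing node
#' remain separate singleton/subtree clades: monophyly is only defined for
#' nodes of the given topology.
#'
#' @param tree A rooted `roled_tree` whose root has a reference tip child
#'   (see [root_at_reference()]).
#' @return A data.frame of class `novel_clades` with one row per clade:
#'   `clade_id` (stable `ncNNNN` ids assigned in deterministic traversal
#'   order), `n_otus`, `member_otus` (list column of query leaf labels),
#'   `clade_root` (internal node or tip index), and `stem_length` (length of
#'   the edge subtending the clade root). Scoring columns are filled by
#'   [score_clades()] / [rank_clades()].
#' @export
find_novel_clades <- function(tree) {
  stopifnot(inherits(tree, "roled_tree"))
  n_tip <- ape::Ntip(tree)
  root <- n_tip + 1L
  root_children <- tree$edge[tree$edge[, 1] == root, 2]
  root_ref_tip <- any(vapply(root_children, function(ch)
    ch <= n_tip && tree$leaf_roles[[tree$tip.label[ch]]] == "reference",
    logical(1)))
  if (!root_ref_tip)
    stop("root must lie on a reference pendant edge (use root_at_reference)",
         call. = FALSE)
  roles <- tree$leaf_roles[tree$tip.label]
  n_nodes <- n_tip + tree$Nnode

  po <- ape::reorder.phylo(tree, "postorder")
  # pure[v]: every leaf under v is a query leaf; postorder guarantees a
  # child's purity is final before its parent edge is processed
  pure <- logical(n_nodes)
  pure[seq_len(n_tip)] <- roles == "query"
  pure[(n_tip + 1L):n_nodes] <- TRUE
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1]; ch <- po$edge[i, 2]
    if (!pure[ch]) pure[p] <- FALSE
  }
  # maximal pure nodes: pure with an impure parent
  parent <- node_parents(tree)
  maximal <- logical(n_nodes)
  idx <- which(pure)
  maximal[idx] <- parent[idx] == 0L | !pure[pmax(parent[idx], 1L)]

  nodes <- which(maximal)
  # stem length of each clade root
  stem <- stats::setNames(numeric(length(nodes)), nodes)
  for (k in seq_along(nodes)) {
    e <- which(tree$edge[, 2] == nodes[k])
    stem[k] <- if (length(e)) tree$edge.length[e] else 0
  }
  # deterministic ordering: left-to-right post-order traversal with children
  # sorted by smallest descendant label; clades ordered by first leaf seen
  leaf_order <- traversal_leaf_order(tree)
  members <- lapply(nodes, function(v) descendant_leaves(tree, v))
  first_seen <- vapply(members, function(m) min(leaf_order[m]), numeric(1))
  ord <- order(first_seen)
  nodes <- nodes[ord]; members <- members[ord]; stem <- stem[ord]

  out <- data.frame(
    clade_id = sprintf("nc%04d", seq_along(nodes)),
    n_otus = lengths(members),
    clade_root = nodes,
    stem_length = unname(stem),
    stringsAsFactors = FALSE)
  out$member_otus <- members
  class(out) <- c("novel_clades", "data.frame")
  out
}

# labels of the leaves under node v
descendant_leaves <- function(tree, v) {
  n_tip <- ape::Ntip(tree)
  if (v <= n_tip) return(tree$tip.label[v])
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  out <- character(0)
  stack <- v
  while (length(stack)) {
    x <- stack[[1]]; stack <- stack[-1]
    if (x <= n_tip) out <- c(out, tree$tip.label[x])
    else stack <- c(kids[[as.character(x)]], stack)
  }
  out
}

# visit index of each leaf in a DFS from the root with children ordered by
# their smallest (radix-order) descendant label
traversal_leaf_order <- function(tree) {
  n_tip <- ape::Ntip(tree)
  n_nodes <- n_tip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  min_lab <- character(n_nodes)
  min_lab[seq_len(n_tip)] <- tree$tip.label
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1]; ch <- po$edge[i, 2]
    if (!nzchar(min_lab[p]) || lex_sort(c(min_lab[p], min_lab[ch]))[1] != min_lab[p])
      min_lab[p] <- min_lab[ch]
  }
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  order_idx <- stats::setNames(integer(n_tip), tree$tip.label)
  counter <- 0L
  stack <- n_tip + 1L
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v <= n_tip) {
      counter <- counter + 1L
      order_idx[tree$tip.label[v]] <- counter
    } else {
      ch <- kids[[as.character(v)]]
      ch <- ch[order(min_lab[ch], method = "radix")]
      stack <- c(ch, stack)
    }
  }
  order_idx
}

#' Validate a clade set against its tree
#'
#' Checks that the clades are pairwise disjoint, cover every query leaf, are
#' each monophyletic (the subtree at the recorded root contains exactly the
#' members), and are maximal (the parent of each clade root subtends at
#' least one reference leaf).
#'
#' @param tree The `roled_tree` the clades were found on.
#' @param clades A `novel_clades` data.frame.
#' @return A list with `ok` (logical) and `violation` (`"none"` or the name
#'   of the first failed property: `"disjoint"`, `"coverage"`,
#'   `"monophyly"`, `"maximality"`).
#' @export
clade_partition_check <- function(tree, clades) {
  all_members <- unlist(clades$member_otus)
  if (anyDuplicated(all_members))
    return(list(ok = FALSE, violation = "disjoint"))
  if (!setequal(all_members, query_leaves(tree)))
    return(list(ok = FALSE, violation = "coverage"))
  parent <- node_parents(tree)
  for (k in seq_len(nrow(clades))) {
    below <- descendant_leaves(tree, clades$clade_root[k])
    if (!setequal(below, clades$member_otus[[k]]))
      return(list(ok = FALSE, violation = "monophyly"))
    p <- parent[clades$clade_root[k]]
    if (p != 0L) {
      up_leaves <- descendant_leaves(tree, p)
      refs <- up_leaves[tree$leaf_roles[up_leaves] == "reference"]
      if (!length(refs))
        return(list(ok = FALSE, violation = "maximality"))
    }
  }
  list(ok = TRUE, violation = "none")
}
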