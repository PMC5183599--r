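# Shared fixtures and independent brute-force oracles.

toy_newick <- "((Q1:0.1,Q2:0.2):0.5,((Q3:0.3,R2:0.1):0.2,R1:0.1):0.1);"

toy_roled_tree <- function(rooted = TRUE) {
  tr <- read_newick(text = toy_newick)
  rt <- assign_roles(tr, c("R1", "R2"))
  if (rooted) root_at_reference(rt) else rt
}

toy_counts <- function() {
  matrix(c(30L, 0L, 10L, 0L, 15L, 0L), nrow = 3, byrow = TRUE,
         dimnames = list(c("Q1", "Q2", "Q3"), c("S1", "S2")))
}

toy_table <- function() {
  otu_table(toy_counts(), taxonomy = rep("k__Bacteria; p__; c__", 3))
}

# random tree with random reference/query roles; guarantees >=1 of each
# unless all_ref; branch lengths U(0, 1)
random_roled_tree <- function(n_leaves, p_ref = 0.4) {
  tr <- ape::rtree(n_leaves, br = function(k) stats::runif(k))
  tr$tip.label <- sprintf("L%02d", seq_len(n_leaves))
  n_ref <- sample(seq_len(n_leaves - 1L), 1L)
  refs <- sample(tr$tip.label, n_ref)
  assign_roles(tr, refs)
}

# oracle: full patristic matrix via ape's independent cophenetic routine
oracle_dist <- function(tree) ape::cophenetic.phylo(tree)

# oracle: nearest reference per query leaf, ties broken lexicographically
oracle_nearest <- function(tree) {
  dm <- oracle_dist(tree)
  refs <- sort(reference_leaves(tree), method = "radix")
  qs <- query_leaves(tree)
  do.call(rbind, lapply(qs, function(q) {
    d <- dm[q, refs]
    i <- which(d == min(d))[1]   # refs already in radix order
    data.frame(leaf = q, nearest_reference = refs[i], distance = unname(min(d)),
               stringsAsFactors = FALSE)
  }))
}

# oracle: enumerate every node, keep descendant leaf sets that are pure
# query and set-maximal; returns canonicalised list of member sets
oracle_clades <- function(tree) {
  n_tip <- ape::Ntip(tree)
  n_nodes <- n_tip + tree$Nnode
  roles <- tree$leaf_roles
  leafsets <- lapply(seq_len(n_nodes), function(v) {
    if (v <= n_tip) tree$tip.label[v]
    else ape::extract.clade(tree, v)$tip.label
  })
  pure <- vapply(leafsets, function(ls) all(roles[ls] == "query"), logical(1))
  keep <- which(pure)
  maximal <- vapply(keep, function(v) {
    !any(vapply(keep, function(w)
      w != v && all(leafsets[[v]] %in% leafsets[[w]]), logical(1)))
  }, logical(1))
  canonical_sets(leafsets[keep[maximal]])
}

canonical_sets <- function(sets) {
  sets <- lapply(sets, sort, method = "radix")
  sets[order(vapply(sets, `[[`, "", 1L), method = "radix")]
}
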