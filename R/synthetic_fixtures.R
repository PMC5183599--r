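#' Specification for a synthetic reference-seeded fixture
#'
#' Describes a synthetic data set emulating the pipeline's real inputs: a
#' backbone tree over taxonomically named reference leaves, query-only
#' subtrees of known stem length planted onto backbone edges, log-normal OTU
#' abundances spread multinomially over samples, taxonomy strings truncated
#' at class for the queries, and optional classified / artifact decoy OTUs.
#'
#' @param n_reference Number of reference leaves (>= 2).
#' @param planted_clades List of numeric vectors
#'   `c(n_otus, stem_length, abundance_mean)` — one per planted clade; stem
#'   length in substitutions/site, abundance mean in sequences per OTU.
#' @param backbone_branch_mean Mean of the exponential branch lengths on the
#'   backbone (and inside planted subtrees), substitutions/site.
#' @param abundance_dispersion Log-normal sigma of OTU abundances (0 =
#'   every OTU gets exactly its clade's abundance mean).
#' @param classified_decoys Number of decoy OTUs with full taxonomy (must be
#'   removed by the unclassified filter).
#' @param artifact_decoys Number of decoy OTUs with artifact sequences
#'   (short or ambiguity-ridden; must fail the structural screen).
#' @param n_samples Number of samples counts are spread over.
#' @param sequence_length Length of the synthetic representative sequences.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_reference = 20L,
                         planted_clades = list(c(5, 0.6, 100),
                                               c(3, 0.3, 100),
                                               c(1, 0.1, 100)),
                         backbone_branch_mean = 0.1,
                         abundance_dispersion = 0.5,
                         classified_decoys = 0L,
                         artifact_decoys = 0L,
                         n_samples = 5L,
                         sequence_length = 250L) {
  if (n_reference < 2L) stop("n_reference must be >= 2", call. = FALSE)
  stopifnot(backbone_branch_mean > 0, abundance_dispersion >= 0,
            classified_decoys >= 0, artifact_decoys >= 0, n_samples >= 1)
  for (pc in planted_clades)
    stopifnot(length(pc) == 3L, pc[1] >= 1, pc[2] >= 0, pc[3] >= 1)
  structure(list(n_reference = as.integer(n_reference),
                 planted_clades = planted_clades,
                 backbone_branch_mean = backbone_branch_mean,
                 abundance_dispersion = abundance_dispersion,
                 classified_decoys = as.integer(classified_decoys),
                 artifact_decoys = as.integer(artifact_decoys),
                 n_samples = as.integer(n_samples),
                 sequence_length = as.integer(sequence_length)),
            class = "fixture_spec")
}

# Yule topology over the given labels: start from one lineage and repeatedly
# split a uniformly chosen extant tip. Returned as a nested list
# (list(left, right) internal, character leaf); branch lengths drawn later.
yule_topology <- function(labels) {
  if (length(labels) == 1L) return(labels[[1]])
  tree <- "._stub_1"
  stubs <- "._stub_1"
  counter <- 1L
  while (length(stubs) < length(labels)) {
    pick <- sample(length(stubs), 1L)
    counter <- counter + 1L
    new <- sprintf("._stub_%d", counter)
    tree <- split_leaf(tree, stubs[pick], new)
    stubs <- c(stubs, new)
  }
  # random assignment of real labels to stubs
  perm <- sample(length(labels))
  relabel_leaves(tree, stats::setNames(labels[perm], stubs))
}

split_leaf <- function(node, target, new_label) {
  if (is.character(node) && length(node) == 1L && !is.list(node)) {
    if (node == target) return(list(target, new_label))
    return(node)
  }
  lapply(node, split_leaf, target = target, new_label = new_label)
}

relabel_leaves <- function(node, map) {
  if (is.character(node) && !is.list(node)) return(unname(map[[node]]))
  lapply(node, relabel_leaves, map = map)
}

# serialise nested-list topology to newick, drawing exponential branch
# lengths (mean = branch_mean) for every edge
to_newick <- function(node, branch_mean) {
  render <- function(x) {
    len <- stats::rexp(1L, rate = 1 / branch_mean)
    body <- if (is.character(x) && !is.list(x)) x
            else paste0("(", paste(vapply(x, render, ""), collapse = ","), ")")
    sprintf("%s:%.10f", body, len)
  }
  paste0("(", paste(vapply(node, render, ""), collapse = ","), ");")
}

random_dna <- function(n, length) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = ""),
    character(1))
}

#' Generate a synthetic fixture bundle
#'
#' Builds a Yule backbone over the reference leaves with exponential branch
#' lengths, plants each query clade as a Yule subtree attached to a
#' uniformly chosen backbone edge via a stem of the requested length, and
#' emits the matching OTU table, representative sequences, reference id list
#' and ground truth. The truth records, per planted clade, the member ids,
#' stem length, and the expected weighted novelty computed independently
#' from the full patristic distance matrix ([ape::cophenetic.phylo()]).
#' The same `(spec, seed)` pair always yields an identical bundle.
#'
#' @param spec A [fixture_spec()].
#' @param seed Integer seed.
#' @return A list of class `fixture_bundle`: `tree` (Newick text), `phylo`
#'   (parsed tree), `table` ([otu_table()]), `sequences` ([seqset()]),
#'   `reference_ids`, and `truth` (data.frame with list-column `members`,
#'   `stem_length`, `abundance`, `expected_novelty`).
#' @export
generate_fixture <- function(spec, seed) {
  stopifnot(inherits(spec, "fixture_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
         else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  ref_ids <- sprintf("REF%03d", seq_len(spec$n_reference))
  backbone <- yule_topology(ref_ids)
  nwk <- to_newick(backbone, spec$backbone_branch_mean)

  # plant clades: insert "(rest, clade_subtree:stem)" on a uniformly chosen
  # backbone edge by splitting that edge at a uniform point
  members_list <- list()
  for (k in seq_along(spec$planted_clades)) {
    pc <- spec$planted_clades[[k]]
    ids <- sprintf("OTU_%d_%03d", k, seq_len(pc[1]))
    members_list[[k]] <- ids
    sub <- yule_topology(ids)
    sub_nwk <- if (is.character(sub) && !is.list(sub)) sub
      else sub("\\);$", ")", sub(";$", "", to_newick(sub, spec$backbone_branch_mean)))
    nwk <- plant_on_edge(nwk, sub_nwk, pc[2])
  }
  tr <- read_newick(text = nwk)

  # abundances: log-normal around each clade's mean, min 1, multinomial
  # across samples
  query_ids <- unlist(members_list)
  ab_mean <- unlist(lapply(seq_along(spec$planted_clades), function(k)
    rep(spec$planted_clades[[k]][3], spec$planted_clades[[k]][1])))
  if (length(query_ids)) {
    totals <- pmax(1L, as.integer(round(stats::rlnorm(
      length(query_ids), meanlog = log(ab_mean),
      sdlog = spec$abundance_dispersion))))
    counts <- t(vapply(totals, function(n)
      as.integer(stats::rmultinom(1L, n, rep(1 / spec$n_samples, spec$n_samples))),
      integer(spec$n_samples)))
  } else {
    counts <- matrix(0L, 0L, spec$n_samples)
  }

  tax <- rep("k__Bacteria; p__Unknown; c__; o__; f__; g__; s__",
             length(query_ids))
  seq_ids <- query_ids
  seqs <- random_dna(length(query_ids), spec$sequence_length)

  if (spec$classified_decoys > 0L) {
    dec <- sprintf("DECOY_C%03d", seq_len(spec$classified_decoys))
    query_ids <- c(query_ids, dec)
    counts <- rbind(counts, matrix(50L %/% spec$n_samples + 1L,
                                   spec$classified_decoys, spec$n_samples))
    tax <- c(tax, rep(paste("k__Bacteria; p__Proteobacteria;",
                            "c__Gammaproteobacteria; o__Enterobacterales;",
                            "f__Enterobacteriaceae; g__Escherichia; s__coli"),
                      spec$classified_decoys))
    seq_ids <- c(seq_ids, dec)
    seqs <- c(seqs, random_dna(spec$classified_decoys, spec$sequence_length))
  }
  if (spec$artifact_decoys > 0L) {
    dec <- sprintf("DECOY_A%03d", seq_len(spec$artifact_decoys))
    query_ids <- c(query_ids, dec)
    counts <- rbind(counts, matrix(50L %/% spec$n_samples + 1L,
                                   spec$artifact_decoys, spec$n_samples))
    tax <- c(tax, rep("k__Bacteria; p__; c__; o__; f__; g__; s__",
                      spec$artifact_decoys))
    seq_ids <- c(seq_ids, dec)
    seqs <- c(seqs, random_dna(spec$artifact_decoys, 45L))  # fails min_length
  }
  dimnames(counts) <- list(query_ids %||% character(0),
                           sprintf("S%02d", seq_len(spec$n_samples)))
  table <- otu_table(counts, taxonomy = tax)
  sequences <- seqset(stats::setNames(seqs, seq_ids))

  # ground truth incl. expected novelty from the independent full distance
  # matrix
  dmat <- ape::cophenetic.phylo(tr)
  truth <- data.frame(
    planted_id = sprintf("planted%02d", seq_along(members_list)),
    n_otus = lengths(members_list),
    stem_length = vapply(spec$planted_clades, `[[`, numeric(1), 2L),
    stringsAsFactors = FALSE)
  truth$members <- members_list
  truth$abundance <- vapply(members_list, function(m)
    as.numeric(sum(table$counts[m, , drop = FALSE])), numeric(1))
  truth$expected_novelty <- vapply(seq_along(members_list), function(k) {
    m <- members_list[[k]]
    d <- apply(dmat[m, ref_ids, drop = FALSE], 1L, min)
    a <- rowSums(table$counts[m, , drop = FALSE])
    sum(a * d) / sum(a)
  }, numeric(1))

  structure(list(tree = nwk, phylo = tr, table = table, sequences = sequences,
                 reference_ids = ref_ids, truth = truth, seed = seed),
            class = "fixture_bundle")
}

# insert clade_nwk (a rooted subtree string WITHOUT trailing length) onto a
# uniformly chosen edge of tree_nwk via a stem of length stem_length
plant_on_edge <- function(tree_nwk, clade_nwk, stem_length) {
  tr <- ape::read.tree(text = tree_nwk)
  # only backbone edges are eligible: the child subtree must contain at
  # least one reference leaf, so planted subtrees never nest or merge
  n_tip_ <- ape::Ntip(tr)
  has_ref <- logical(n_tip_ + tr$Nnode)
  has_ref[seq_len(n_tip_)] <- startsWith(tr$tip.label, "REF")
  po <- ape::reorder.phylo(tr, "postorder")
  for (i in seq_len(nrow(po$edge)))
    if (has_ref[po$edge[i, 2]]) has_ref[po$edge[i, 1]] <- TRUE
  eligible <- which(has_ref[tr$edge[, 2]])
  e <- eligible[sample(length(eligible), 1L)]
  u <- stats::runif(1L)
  len <- tr$edge.length[e]
  child <- tr$edge[e, 2]
  # re-serialise with a split point on edge e
  n_tip <- ape::Ntip(tr)
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  elen <- stats::setNames(tr$edge.length, tr$edge[, 2])
  render <- function(v) {
    body <- if (v <= n_tip) tr$tip.label[v]
      else paste0("(", paste(vapply(kids[[as.character(v)]], render, ""),
                             collapse = ","), ")")
    if (v == child) {
      sprintf("(%s:%.10f,%s:%.10f):%.10f",
              body, (1 - u) * len, clade_nwk, stem_length, u * len)
    } else {
      lv <- elen[as.character(v)]
      if (is.na(lv)) body else sprintf("%s:%.10f", body, lv)
    }
  }
  paste0(render(n_tip + 1L), ";")
}

#' Evaluate planted-clade recovery
#'
#' Compares the planted truth of a fixture against a ranked clade list:
#' a planted clade counts as exactly recovered when some found clade has an
#' identical member set. Reports the found combined-rank position of each
#' recovered clade and the overall exact-recovery fraction.
#'
#' @param truth The `truth` data.frame of a [generate_fixture()] bundle.
#' @param found Ranked clades ([rank_clades()] output or
#'   `novelty_report$clades`).
#' @return A list with `per_clade` (data.frame: `planted_id`, `recovered`,
#'   `found_clade_id`, `found_rank`) and `recovery_fraction`.
#' @export
evaluate_recovery <- function(truth, found) {
  if (!nrow(truth)) stop("empty truth", call. = FALSE)
  per <- lapply(seq_len(nrow(truth)), function(k) {
    m <- truth$members[[k]]
    hit <- which(vapply(found$member_otus, setequal, logical(1), y = m))
    data.frame(planted_id = truth$planted_id[k],
               recovered = length(hit) > 0L,
               found_clade_id = if (length(hit)) found$clade_id[hit[1]] else NA,
               found_rank = if (length(hit)) hit[1] else NA_integer_,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  list(per_clade = per, recovery_fraction = mean(per$recovered))
}
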