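#' Ranking parameters
#'
#' @param weighted Abundance-weight the mean branch length to the nearest
#'   reference (default `TRUE`); unweighted mode takes the plain mean.
#' @param proportion_denominator `"full_library"` (total counts of the
#'   post-QC input table, before the unclassified filter; the default,
#'   matching proportions quoted against total sequence abundance) or
#'   `"filtered_library"` (total counts of the post-filter table).
#' @param ties `"fractional"` (mean of tied ranks, default) or
#'   `"competition"` (minimum rank for ties).
#' @param correlation `"pearson"` (default) or `"spearman"` for the
#'   library-size vs novelty correlation in per-category aggregates.
#' @return A list of class `rank_params`.
#' @export
rank_params <- function(weighted = TRUE,
                        proportion_denominator = c("full_library", "filtered_library"),
                        ties = c("fractional", "competition"),
                        correlation = c("pearson", "spearman")) {
  structure(list(weighted = isTRUE(weighted),
                 proportion_denominator = match.arg(proportion_denominator),
                 ties = match.arg(ties),
                 correlation = match.arg(correlation)),
            class = "rank_params")
}

#' Total sequence abundance of a clade
#'
#' @param members Character vector of member OTU ids.
#' @param table An [otu_table()] containing every member.
#' @return Integer sum of the members' row sums across all samples.
#' @export
clade_abundance <- function(members, table) {
  missing <- setdiff(members, otu_ids(table))
  if (length(missing))
    stop("clade members missing from table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  sum(table$counts[members, , drop = FALSE])
}

#' Phylogenetic novelty of a clade
#'
#' The (abundance-weighted) mean patristic branch length between each member
#' leaf and its nearest reference leaf, in substitutions per site. Weighted:
#' `sum(a_i d_i) / sum(a_i)` with `a_i` the member's total sequence count;
#' unweighted: `mean(d_i)`.
#'
#' @param tree A `roled_tree`.
#' @param members Character vector of member query leaves.
#' @param abundances Named numeric vector of member total counts (required
#'   when `weighted`).
#' @param weighted Logical.
#' @return Novelty distance in substitutions/site.
#' @export
clade_novelty <- function(tree, members, abundances = NULL, weighted = TRUE) {
  nn <- nearest_reference_distances(tree)
  d <- nn$distance[match(members, nn$leaf)]
  if (anyNA(d))
    stop("clade members are not query leaves of the tree: ",
         paste(members[is.na(d)], collapse = ", "), call. = FALSE)
  if (!weighted) return(mean(d))
  a <- abundances[members]
  if (anyNA(a)) stop("abundances missing for some members", call. = FALSE)
  if (sum(a) == 0)
    stop("weighted novelty undefined: all member abundances are zero",
         call. = FALSE)
  sum(a * d) / sum(a)
}

#' Fill abundance and novelty columns of a clade table
#'
#' @param tree The `roled_tree` the clades were found on.
#' @param clades A `novel_clades` data.frame from [find_novel_clades()].
#' @param table An [otu_table()] with counts for every member OTU.
#' @param params A [rank_params()].
#' @return `clades` with `total_abundance` and `novelty_distance` filled.
#' @export
score_clades <- function(tree, clades, table, params = rank_params()) {
  nn <- nearest_reference_distances(tree)
  dist_of <- stats::setNames(nn$distance, nn$leaf)
  totals <- otu_totals(table)
  clades$total_abundance <- vapply(clades$member_otus, function(m)
    as.numeric(clade_abundance(m, table)), numeric(1))
  clades$novelty_distance <- vapply(clades$member_otus, function(m) {
    d <- dist_of[m]
    if (anyNA(d)) stop("clade member not a query leaf: ",
                       paste(m[is.na(d)], collapse = ", "), call. = FALSE)
    if (params$weighted) {
      a <- totals[m]
      if (sum(a) == 0) stop("weighted novelty undefined for all-zero clade",
                            call. = FALSE)
      sum(a * d) / sum(a)
    } else mean(d)
  }, numeric(1))
  clades
}

#' Rank clades by combined novelty and abundance
#'
#' Ranks novelty distance and total abundance separately (rank 1 = most
#' novel / most abundant; ties get fractional mean ranks by default) and
#' averages the two ranks into `combined_score`. The output is sorted by
#' ascending combined score, ties broken by novelty rank and then clade id,
#' so the highest-ranked clades tend to be both numerically abundant and
#' phylogenetically novel.
#'
#' @param clades A `novel_clades` data.frame with `novelty_distance` and
#'   `total_abundance` filled (see [score_clades()]).
#' @param ties `"fractional"` or `"competition"`.
#' @return The reordered clades with `novelty_rank`, `abundance_rank` and
#'   `combined_score` columns.
#' @export
rank_clades <- function(clades, ties = c("fractional", "competition")) {
  ties <- match.arg(ties)
  if (!nrow(clades)) {
    clades$novelty_rank <- numeric(0)
    clades$abundance_rank <- numeric(0)
    clades$combined_score <- numeric(0)
    return(clades)
  }
  if (is.null(clades$novelty_distance) || is.null(clades$total_abundance) ||
      anyNA(clades$novelty_distance) || anyNA(clades$total_abundance))
    stop("novelty_distance / total_abundance must be filled before ranking",
         call. = FALSE)
  method <- if (ties == "fractional") "average" else "min"
  clades$novelty_rank <- rank(-clades$novelty_distance, ties.method = method)
  clades$abundance_rank <- rank(-clades$total_abundance, ties.method = method)
  clades$combined_score <- (clades$novelty_rank + clades$abundance_rank) / 2
  ord <- order(clades$combined_score, clades$novelty_rank, clades$clade_id,
               method = "radix")
  clades <- clades[ord, , drop = FALSE]
  rownames(clades) <- NULL
  clades
}

#' Proportion of a library contributed by a clade
#'
#' @param abundance Clade total abundance (sequences).
#' @param denominator_total Total sequence count of the denominator library
#'   (full post-QC library by default downstream).
#' @return Fraction in `[0, 1]`.
#' @export
clade_proportion <- function(abundance, denominator_total) {
  if (denominator_total <= 0)
    stop("library proportion undefined: zero denominator", call. = FALSE)
  abundance / denominator_total
}

#' Per-category novelty aggregates
#'
#' Sums abundance-weighted novelty per sample category and normalises by the
#' number of samples and number of sequences in the category, so that
#' novelty can be compared across categories with very different sampling
#' and sequencing intensity. With three or more categories the correlation
#' between per-category library size (`n_sequences`) and total weighted
#' novelty is also reported.
#'
#' @param clades Ranked clades with `novelty_distance` filled.
#' @param table The [otu_table()] used as the denominator library (counts
#'   for clade members are re-summed within each category's samples).
#' @param category Optional named character vector mapping sample id to
#'   category; defaults to the table's `sample_category`, or a single
#'   `"all"` category.
#' @param correlation `"pearson"` or `"spearman"`.
#' @return A data.frame with one row per category (`category`, `n_samples`,
#'   `n_sequences`, `n_clades`, `total_weighted_novelty`,
#'   `novelty_per_sample`, `novelty_per_sequence`) carrying the library
#'   size/novelty correlation in attribute
#'   `library_size_novelty_correlation` (NA with < 3 categories).
#' @export
aggregate_by_category <- function(clades, table, category = NULL,
                                  correlation = c("pearson", "spearman")) {
  correlation <- match.arg(correlation)
  if (is.null(category)) category <- table$sample_category
  if (is.null(category))
    category <- stats::setNames(rep("all", ncol(table$counts)), sample_ids(table))
  cats <- lex_sort(unique(category[sample_ids(table)]))
  rows <- lapply(cats, function(cc) {
    samp <- sample_ids(table)[category[sample_ids(table)] == cc]
    sub <- table$counts[, samp, drop = FALSE]
    cab <- vapply(clades$member_otus, function(m)
      as.numeric(sum(sub[intersect(m, rownames(sub)), , drop = FALSE])),
      numeric(1))
    twn <- sum(clades$novelty_distance * cab)
    data.frame(category = cc, n_samples = length(samp),
               n_sequences = sum(sub), n_clades = sum(cab > 0),
               total_weighted_novelty = twn,
               novelty_per_sample = twn / length(samp),
               novelty_per_sequence = twn / sum(sub),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  r <- if (nrow(out) >= 3)
    stats::cor(out$n_sequences, out$total_weighted_novelty, method = correlation)
  else NA_real_
  attr(out, "library_size_novelty_correlation") <- r
  out
}
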