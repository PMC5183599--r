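scored_toy <- function(weighted = TRUE) {
  rt <- toy_roled_tree()
  cl <- find_novel_clades(rt)
  score_clades(rt, cl, toy_table(), rank_params(weighted = weighted))
}

test_that("clade abundance is the sum of member row sums", {
  tab <- toy_table()
  expect_identical(clade_abundance(c("Q1", "Q2"), tab), 40L)
  expect_identical(clade_abundance("Q3", tab), 15L)
  zero <- otu_table(matrix(0L, 1, 1, dimnames = list("Z", "S1")))
  expect_identical(clade_abundance("Z", zero), 0L)
  expect_error(clade_abundance(c("Q1", "ghost"), tab), "ghost")
})

test_that("clade novelty is the (weighted) mean nearest-reference distance", {
  rt <- toy_roled_tree()
  ab <- otu_totals(toy_table())
  expect_equal(clade_novelty(rt, c("Q1", "Q2"), ab, weighted = TRUE),
               (30 * 0.8 + 10 * 0.9) / 40)   # 0.825
  expect_equal(clade_novelty(rt, c("Q1", "Q2"), weighted = FALSE),
               (0.8 + 0.9) / 2)              # 0.85
  expect_equal(clade_novelty(rt, "Q3", ab, weighted = TRUE), 0.4)
  expect_error(clade_novelty(rt, c("Q1", "Q2"), c(Q1 = 0, Q2 = 0), TRUE),
               "zero")
})

test_that("ranking averages fractional novelty and abundance ranks", {
  cl <- rank_clades(scored_toy())
  expect_equal(cl$novelty_distance, c(0.825, 0.4))
  expect_equal(cl$novelty_rank, c(1, 2))
  expect_equal(cl$abundance_rank, c(1, 2))
  expect_equal(cl$combined_score, c(1, 2))

  # crossing ranks tie on combined score; novelty rank breaks the tie
  cross <- cl
  cross$novelty_distance <- c(0.9, 0.1)
  cross$total_abundance <- c(10, 100)
  got <- rank_clades(cross)
  expect_equal(got$combined_score, c(1.5, 1.5))
  expect_equal(got$novelty_distance[1], 0.9)

  single <- rank_clades(cl[1, ])
  expect_equal(single$combined_score, 1)

  unscored <- scored_toy()
  unscored$novelty_distance <- NULL
  expect_error(rank_clades(unscored), "filled")
})

test_that("tied values get mean ranks (or minimum ranks in competition mode)", {
  cl <- scored_toy()
  cl$novelty_distance <- c(0.5, 0.5)
  cl$total_abundance <- c(10, 20)
  frac <- rank_clades(cl, "fractional")
  expect_equal(sort(frac$novelty_rank), c(1.5, 1.5))
  comp <- rank_clades(cl, "competition")
  expect_equal(sort(comp$novelty_rank), c(1, 1))
})

test_that("ranking is a permutation with non-decreasing combined scores", {
  set.seed(707)
  for (i in 1:20) {
    n <- sample(1:12, 1)
    cl <- data.frame(clade_id = sprintf("nc%04d", 1:n),
                     novelty_distance = round(runif(n), 2),
                     total_abundance = sample(1:5, n, replace = TRUE))
    cl$member_otus <- as.list(sprintf("Q%d", 1:n))
    got <- rank_clades(cl)
    expect_setequal(got$clade_id, cl$clade_id)
    expect_true(all(diff(got$combined_score) >= 0))
    expect_true(all(got$combined_score >= 1 & got$combined_score <= n))
  }
})

test_that("clade proportion uses the requested denominator", {
  expect_equal(clade_proportion(40, 4000), 0.01)
  expect_equal(clade_proportion(55, 55), 1)
  expect_equal(clade_proportion(0, 100), 0)
  expect_error(clade_proportion(5, 0), "denominator")
})

test_that("per-category aggregates normalise by samples and sequences", {
  cl <- rank_clades(scored_toy())
  counts <- matrix(c(30L, 0L, 10L, 0L, 15L, 0L), nrow = 3, byrow = TRUE,
                   dimnames = list(c("Q1", "Q2", "Q3"), c("S1", "S2")))
  tab <- otu_table(counts, taxonomy = rep("Unassigned", 3))
  agg <- aggregate_by_category(cl, tab)
  expect_identical(agg$category, "all")
  expect_equal(agg$n_samples, 2L)
  expect_equal(agg$n_sequences, 55)
  twn <- 0.825 * 40 + 0.4 * 15
  expect_equal(agg$total_weighted_novelty, twn)
  expect_equal(agg$novelty_per_sample, twn / 2)
  expect_equal(agg$novelty_per_sequence, twn / 55)

  # identical categories give identical aggregates
  cat2 <- c(S1 = "a", S2 = "b")
  tab2 <- otu_table(cbind(counts[, 1, drop = FALSE],
                          S2 = counts[, 1]),
                    taxonomy = rep("Unassigned", 3))
  agg2 <- aggregate_by_category(cl, tab2, cat2)
  expect_equal(agg2$total_weighted_novelty[1], agg2$total_weighted_novelty[2])
  expect_equal(agg2$novelty_per_sample[1], agg2$novelty_per_sample[2])
})

test_that("novelty proportional to library size gives correlation 1", {
  cl <- rank_clades(scored_toy())
  cl$novelty_distance <- c(1, 1)   # so weighted novelty ~ abundance
  counts <- matrix(0L, 3, 3, dimnames = list(c("Q1", "Q2", "Q3"),
                                             c("S1", "S2", "S3")))
  counts[, 1] <- c(10L, 10L, 10L)
  counts[, 2] <- c(20L, 20L, 20L)
  counts[, 3] <- c(40L, 40L, 40L)
  tab <- otu_table(counts, taxonomy = rep("Unassigned", 3))
  agg <- aggregate_by_category(cl, tab, c(S1 = "a", S2 = "b", S3 = "c"))
  expect_equal(attr(agg, "library_size_novelty_correlation"), 1)
})

test_that("scale equivariance, stem extension, and equal-weight collapse hold", {
  set.seed(808)
  for (i in 1:25) {
    rt <- root_at_reference(random_roled_tree(sample(6:24, 1)))
    cl <- find_novel_clades(rt)
    if (!nrow(cl)) next
    n_otu <- length(rt$tip.label)
    counts <- matrix(sample(10:100, n_otu, replace = TRUE), ncol = 1,
                     dimnames = list(rt$tip.label, "S1"))
    tab <- otu_table(counts, taxonomy = rep("Unassigned", n_otu))
    sc <- rank_clades(score_clades(rt, cl, tab))

    # scaling branches by s scales novelty by s, ranks unchanged
    s <- runif(1, 0.5, 3)
    scaled <- rt
    scaled$edge.length <- rt$edge.length * s
    sc_s <- rank_clades(score_clades(scaled, find_novel_clades(scaled), tab))
    expect_equal(sc_s$novelty_distance, sc$novelty_distance * s,
                 tolerance = 1e-12)
    expect_identical(sc_s$clade_id, sc$clade_id)
    expect_equal(sc_s$combined_score, sc$combined_score)

    # extending one clade's stem by delta adds exactly delta to its novelty
    k <- sample(nrow(cl), 1)
    delta <- runif(1, 0.1, 2)
    ext <- rt
    stem_edge <- which(ext$edge[, 2] == cl$clade_root[k])
    if (length(stem_edge)) {
      ext$edge.length[stem_edge] <- ext$edge.length[stem_edge] + delta
      sc_e <- score_clades(ext, find_novel_clades(ext), tab)
      before <- sc$novelty_distance[match(sc$clade_id, sc$clade_id)]
      id <- cl$clade_id[k]
      expect_equal(sc_e$novelty_distance[sc_e$clade_id == id],
                   sc$novelty_distance[sc$clade_id == id] + delta,
                   tolerance = 1e-12)
    }

    # equal abundances collapse weighted onto unweighted novelty
    eq_tab <- otu_table(matrix(7L, n_otu, 1,
                               dimnames = list(rt$tip.label, "S1")),
                        taxonomy = rep("Unassigned", n_otu))
    w <- score_clades(rt, cl, eq_tab, rank_params(weighted = TRUE))
    u <- score_clades(rt, cl, eq_tab, rank_params(weighted = FALSE))
    expect_equal(w$novelty_distance, u$novelty_distance, tolerance = 1e-12)
  }
})
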