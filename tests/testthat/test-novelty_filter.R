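mixed_table <- function() {
  counts <- matrix(c(30L, 0L,   # classified at class
                     10L, 5L,   # unclassified at class
                     4L, 5L,    # unclassified, low abundance (9 total)
                     6L, 4L),   # unclassified, boundary (10 total)
                   nrow = 4, byrow = TRUE,
                   dimnames = list(c("C1", "U1", "U2", "U3"), c("S1", "S2")))
  otu_table(counts, taxonomy = c(
    "k__Bacteria; p__Proteobacteria; c__Alphaproteobacteria",
    "k__Bacteria; p__Acidobacteria; c__",
    "k__Bacteria; p__; c__",
    "Unassigned"))
}

test_that("filter_unclassified keeps exactly the OTUs unassigned at the rank", {
  tab <- mixed_table()
  out <- filter_unclassified(tab, "class")
  expect_setequal(otu_ids(out), c("U1", "U2", "U3"))
  expect_identical(sample_ids(out), sample_ids(tab))
  expect_identical(out$counts["U1", ], tab$counts["U1", ])
  # unassigned at class but assigned at phylum: removed when rank = phylum
  out_p <- filter_unclassified(tab, "phylum")
  expect_setequal(otu_ids(out_p), c("U2", "U3"))
  # all classified is an empty table, not an error
  all_cls <- filter_unclassified(
    otu_table(tab$counts,
              taxonomy = rep("k__B; p__P; c__C; o__O; f__F; g__G; s__S", 4)),
    "class")
  expect_identical(nrow(all_cls$counts), 0L)
})

test_that("filter_low_abundance removes strictly-below-threshold OTUs", {
  tab <- mixed_table()
  out <- filter_low_abundance(tab, 10)
  expect_false("U2" %in% otu_ids(out))   # 9 sequences: removed
  expect_true("U3" %in% otu_ids(out))    # 10 sequences: retained
  expect_identical(otu_ids(filter_low_abundance(tab, 0)), otu_ids(tab))
})

test_that("low-abundance filtering is monotone and commutes with the rank filter", {
  set.seed(11)
  counts <- matrix(rpois(60, 8), nrow = 20,
                   dimnames = list(sprintf("O%02d", 1:20), c("S1", "S2", "S3")))
  tax <- ifelse(seq_len(20) %% 2 == 0,
                "k__Bacteria; p__X; c__Y", "k__Bacteria; p__X; c__")
  tab <- otu_table(counts, taxonomy = tax)
  prev <- otu_ids(tab)
  for (mc in c(0, 5, 10, 20, 50)) {
    cur <- otu_ids(filter_low_abundance(tab, mc))
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  ab <- filter_low_abundance(filter_unclassified(tab, "class"), 10)
  ba <- filter_unclassified(filter_low_abundance(tab, 10), "class")
  expect_setequal(otu_ids(ab), otu_ids(ba))
})

test_that("structural screen partitions input and reports artifact fraction", {
  seqs <- seqset(c(
    short = strrep("A", 45),
    clean = paste(rep(c("A", "C", "G", "T"), length.out = 250), collapse = ""),
    ambig = paste0(strrep("N", 26), strrep("ACGT", 119))))  # 26/502 > 5% N
  res <- structural_screen(seqs, screen_params())
  expect_setequal(names(res$pass), "clean")
  expect_setequal(res$report$fail_ids, c("short", "ambig"))
  expect_identical(res$report$n_input, 3L)
  expect_equal(res$report$n_pass + res$report$n_fail, res$report$n_input)
  # artifact fraction is count arithmetic: 3 failures out of 10
  ten <- seqset(stats::setNames(
    c(rep(strrep("ACGT", 60), 7), rep(strrep("A", 10), 3)),
    sprintf("s%02d", 1:10)))
  expect_equal(structural_screen(ten)$report$artifact_fraction, 0.3)
})

test_that("external report mode passes exactly the listed bacterial ids", {
  seqs <- seqset(c(a = strrep("ACGT", 60), b = strrep("ACGT", 60),
                   c = strrep("ACGT", 60)))
  rep_file <- withr::local_tempfile()
  writeLines(c("# per-sequence model assignment", "a bacteria", "b archaea", "c"),
             rep_file)
  res <- structural_screen(seqs, screen_params(external_mode = "ssu-align-report"),
                           external_report = rep_file)
  expect_setequal(names(res$pass), c("a", "c"))
  expect_error(
    structural_screen(seqs, screen_params(external_mode = "ssu-align-report")),
    "report")
})

test_that("apply_all_filters composes the three screens in order", {
  counts <- matrix(c(30L, 5L, 30L, 2L), ncol = 1,
                   dimnames = list(c("classified", "artifact", "clean", "rare"),
                                   "S1"))
  tab <- otu_table(counts, taxonomy = c(
    "k__B; p__P; c__C", "k__B; p__; c__", "k__B; p__; c__", "k__B; p__; c__"))
  seqs <- seqset(c(classified = strrep("ACGT", 60),
                   artifact = strrep("A", 20),
                   clean = strrep("ACGT", 60),
                   rare = strrep("ACGT", 60)))
  res <- apply_all_filters(tab, seqs, filter_params())
  expect_identical(otu_ids(res$table), "clean")
  expect_identical(names(res$sequences), "clean")
  expect_identical(unname(res$stage_counts),
                   c(4L, 3L, 2L, 1L))
  expect_equal(res$screen_report$artifact_fraction, 1 / 3)

  # identity configuration passes everything through
  all_unc <- otu_table(counts, taxonomy = rep("Unassigned", 4))
  res_id <- apply_all_filters(all_unc, seqs,
                              filter_params(min_count = 0,
                                            screen = screen_params(min_length = 0,
                                                                   max_ambiguous_fraction = 1)))
  expect_setequal(otu_ids(res_id$table), otu_ids(all_unc))

  # empty input table
  empty <- filter_low_abundance(all_unc, 10^6)
  res_e <- apply_all_filters(empty, seqs, filter_params())
  expect_identical(nrow(res_e$table$counts), 0L)
  expect_identical(res_e$screen_report$n_input, 0L)

  # missing sequence is a hard validation error naming the id
  expect_error(apply_all_filters(tab, seqs[c("clean", "rare")], filter_params()),
               "artifact")
})
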