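write_tsv_fixture <- function(path, rows,
                              header = "#OTU ID\tS1\tS2\ttaxonomy") {
  writeLines(c(header, rows), path)
}

biom_sparse_fixture <- function(path) {
  # BIOM v1.0 sparse layout encoding the same matrix as the TSV fixture
  txt <- paste0('{"id":null,"format":"Biological Observation Matrix 1.0.0",',
    '"format_url":"http://biom-format.org","type":"OTU table",',
    '"generated_by":"fixture","date":"2016-01-01","matrix_type":"sparse",',
    '"matrix_element_type":"int","shape":[2,2],',
    '"rows":[{"id":"Q1","metadata":{"taxonomy":["k__Bacteria","p__","c__"]}},',
    '{"id":"Q2","metadata":{"taxonomy":["k__Bacteria","p__Acidobacteria",',
    '"c__Acidobacteriia"]}}],',
    '"columns":[{"id":"S1","metadata":null},{"id":"S2","metadata":null}],',
    '"data":[[0,0,30],[1,0,10],[1,1,5]]}')
  writeLines(txt, path)
}

test_that("TSV dialect parses counts, ids and taxonomy", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_fixture(f, c("Q1\t30\t0\tk__Bacteria; p__; c__",
                         "Q2\t10\t5\tk__Bacteria; p__Acidobacteria; c__Acidobacteriia"))
  tab <- read_otu_table(f, "tsv")
  expect_identical(otu_ids(tab), c("Q1", "Q2"))
  expect_identical(sample_ids(tab), c("S1", "S2"))
  expect_equal(unname(otu_totals(tab)), c(30, 15))
  expect_true(is_unassigned_at(tab$taxonomy, "class")[["Q1"]])
  expect_false(is_unassigned_at(tab$taxonomy, "class")[["Q2"]])
})

test_that("BIOM v1.0 sparse input yields the identical table as TSV", {
  ftsv <- withr::local_tempfile(fileext = ".tsv")
  fbiom <- withr::local_tempfile(fileext = ".biom")
  write_tsv_fixture(ftsv, c("Q1\t30\t0\tk__Bacteria; p__; c__",
                            "Q2\t10\t5\tk__Bacteria; p__Acidobacteria; c__Acidobacteriia"))
  biom_sparse_fixture(fbiom)
  a <- read_otu_table(ftsv, "tsv")
  b <- read_otu_table(fbiom, "biom-json")
  expect_identical(a$counts, b$counts)
  expect_identical(a$taxonomy, b$taxonomy)
})

test_that("invalid counts and duplicate ids are rejected with clear errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_fixture(f, c("Q1\t-3\t0\tUnassigned"))
  expect_error(read_otu_table(f, "tsv"), "negative")
  write_tsv_fixture(f, c("Q1\t1.5\t0\tUnassigned"))
  expect_error(read_otu_table(f, "tsv"), "non-integral")
  write_tsv_fixture(f, c("Q1\t1\t0\tUnassigned", "Q1\t2\t0\tUnassigned"))
  expect_error(read_otu_table(f, "tsv"), "duplicate OTU id")
  write_tsv_fixture(f, c("Q1\t1\tUnassigned"))
  expect_error(read_otu_table(f, "tsv"), "line")
  expect_error(read_otu_table(f, "tsv"), "fields")
})

test_that("taxonomy parsing handles the three dialects and unassigned tokens", {
  gg <- parse_taxonomy("k__Bacteria; p__Acidobacteria; c__; o__; f__; g__; s__",
                       "greengenes")
  expect_identical(unname(gg[1:3]), c("Bacteria", "Acidobacteria", ""))
  expect_true(is_unassigned_at(gg, "class"))
  expect_false(is_unassigned_at(gg, "phylum"))

  expect_identical(unname(parse_taxonomy("Unassigned")), rep("", 7))
  expect_identical(unname(parse_taxonomy("unclassified; whatever", "plain")),
                   rep("", 7))

  sv <- parse_taxonomy("D_0__Bacteria; D_1__Proteobacteria; D_2__Alphaproteobacteria",
                       "silva")
  expect_identical(unname(sv[1:3]),
                   c("Bacteria", "Proteobacteria", "Alphaproteobacteria"))

  pl <- parse_taxonomy("Bacteria; Proteobacteria", "plain")
  expect_identical(unname(pl[1:2]), c("Bacteria", "Proteobacteria"))
  expect_true(is_unassigned_at(pl, "class"))
})

test_that("unassignment propagates downward and parsing is idempotent", {
  # assigned-below-unassigned collapses to unassigned
  p <- parse_taxonomy("k__Bacteria; p__; c__Spuria", "greengenes")
  expect_true(is_unassigned_at(p, "phylum"))
  expect_true(is_unassigned_at(p, "class"))
  # idempotence on the canonical rendering
  p2 <- parse_taxonomy("k__Bacteria; p__Acidobacteria; c__Acidobacteriia")
  expect_identical(parse_taxonomy(format_taxonomy(p2)), p2)
})

test_that("FASTA and Stockholm readers enforce their contracts", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">Q1 some description", "ACGT"), f)
  s <- read_sequences(f, "fasta")
  expect_identical(as.character(s), c(Q1 = "ACGT"))
  writeLines(c(">Q1", "ACGT", ">Q1", "GGGG"), f)
  expect_error(read_sequences(f, "fasta"), "duplicate")

  fs <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0", "Q1 AC-T", "Q2 ACGT", "//"), fs)
  a <- read_sequences(fs, "stockholm")
  expect_true(is_aligned(a))
  expect_identical(unname(nchar(a)), c(4L, 4L))
  writeLines(c("# STOCKHOLM 1.0", "Q1 AC-T", "Q2 ACGTT", "//"), fs)
  expect_error(read_sequences(fs, "stockholm"), "ragged")
})

test_that("newick reading preserves structure and rejects malformed input", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines(toy_newick, f)
  tr <- read_newick(f)
  expect_setequal(tr$tip.label, c("Q1", "Q2", "Q3", "R1", "R2"))
  expect_equal(sum(tr$edge.length), 1.6)   # sum of the printed lengths

  expect_silent(tr2 <- read_newick(text = "(A:1,B:1);"))
  expect_identical(ape::Ntip(tr2), 2L)
  expect_error(read_newick(text = "((A,B);"), "parse")
  expect_error(read_newick(text = "((A:1,A:2):1,B:1);"), "duplicate")
  expect_warning(tr3 <- read_newick(text = "((A,B),C);"), "branch lengths")
  expect_equal(sum(tr3$edge.length), 0)
})

test_that("newick reading is invariant to child rotation", {
  a <- read_newick(text = "((Q1:0.1,Q2:0.2):0.5,(R1:0.1,Q3:0.3):0.2);")
  b <- read_newick(text = "((Q3:0.3,R1:0.1):0.2,(Q2:0.2,Q1:0.1):0.5);")
  expect_setequal(a$tip.label, b$tip.label)
  da <- oracle_dist(a); db <- oracle_dist(b)
  expect_equal(da[a$tip.label, a$tip.label], db[a$tip.label, a$tip.label])
})

test_that("read-write-read round trips are identities", {
  tab <- toy_table()
  for (dialect in c("tsv", "biom-json")) {
    f <- withr::local_tempfile()
    write_otu_table(tab, f, dialect)
    back <- read_otu_table(f, dialect)
    expect_identical(back$counts, tab$counts)
    expect_identical(back$taxonomy, tab$taxonomy)
  }
  s <- seqset(c(Q1 = "ACGT", Q2 = "AC-T"), aligned = TRUE)
  for (format in c("fasta", "stockholm")) {
    f <- withr::local_tempfile()
    write_sequences(s, f, format)
    back <- read_sequences(f, format)
    expect_identical(as.character(back), as.character(s))
  }
  f <- withr::local_tempfile()
  tr <- read_newick(text = toy_newick)
  write_newick(tr, f)
  back <- read_newick(f)
  expect_setequal(back$tip.label, tr$tip.label)
  expect_equal(oracle_dist(back)[tr$tip.label, tr$tip.label],
               oracle_dist(tr)[tr$tip.label, tr$tip.label])
})
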