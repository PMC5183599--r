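#' Pipeline configuration
#'
#' Collects inputs and parameters for [run_pipeline()]. Inputs may be given
#' as file paths (read with the package's readers) or as in-memory objects.
#' Bring-your-own-tree is the primary mode; alternatively a merged alignment
#' plus the FastTree adapter can infer the tree.
#'
#' @param table [otu_table()] or path (BIOM v1.0 JSON or TSV).
#' @param sequences [seqset()] or FASTA/Stockholm path of OTU representative
#'   sequences.
#' @param tree `phylo` object or Newick path of the reference-seeded
#'   phylogeny (required unless `alignment` + `fasttree` are set).
#' @param reference_ids Character vector of reference leaf labels, or path
#'   to a one-id-per-line text file.
#' @param alignment Optional merged alignment ([seqset()] or path) used for
#'   per-clade alignment export, and for tree inference when `tree` is
#'   absent.
#' @param output_dir Optional directory; when set, the ranked report TSV,
#'   per-clade alignments and profiles, plot data, plots and a run log are
#'   written there.
#' @param filter A [filter_params()].
#' @param rank A [rank_params()].
#' @param category_key `NULL` to analyse the whole library at once, or
#'   `"sample_category"` to analyse each sample category independently (the
#'   low-abundance filter is then applied independently per subset), or a
#'   named character vector mapping sample id to category.
#' @param fasttree Optional path to a FastTree executable for
#'   [run_fasttree_adapter()].
#' @param ssu_align_report Optional path to an external structural-binner
#'   report (see [structural_screen()]).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(table, sequences, tree = NULL, reference_ids,
                            alignment = NULL, output_dir = NULL,
                            filter = filter_params(), rank = rank_params(),
                            category_key = NULL, fasttree = NULL,
                            ssu_align_report = NULL) {
  if (is.null(tree) && (is.null(alignment) || is.null(fasttree)))
    stop("either a tree or (alignment + fasttree adapter) must be given",
         call. = FALSE)
  structure(list(table = table, sequences = sequences, tree = tree,
                 reference_ids = reference_ids, alignment = alignment,
                 output_dir = output_dir, filter = filter, rank = rank,
                 category_key = category_key, fasttree = fasttree,
                 ssu_align_report = ssu_align_report),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; `filter`,
#' `screen` and `rank` sub-maps override individual parameter defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  scr <- do.call(screen_params, y$screen %||% list())
  filt <- do.call(filter_params, c(y$filter %||% list(), list(screen = scr)))
  rk <- do.call(rank_params, y$rank %||% list())
  pipeline_config(table = y$table, sequences = y$sequences, tree = y$tree,
                  reference_ids = y$reference_ids, alignment = y$alignment,
                  output_dir = y$output_dir, filter = filt, rank = rk,
                  category_key = y$category_key, fasttree = y$fasttree,
                  ssu_align_report = y$ssu_align_report)
}

load_input <- function(x, reader) if (is.character(x) && length(x) == 1L &&
                                      file.exists(x)) reader(x) else x

#' Run the full novelty pipeline
#'
#' Executes, per library (or per sample category independently when
#' `category_key` is set): unclassified/artifact/abundance filtering, leaf
#' role assignment, deterministic rooting on a reference pendant edge, novel
#' clade delimitation, novelty and abundance scoring, combined ranking,
#' library proportions and per-category aggregates. When `output_dir` is
#' set, the ranked report TSV, per-clade alignments (aligned FASTA +
#' Stockholm) and position frequency profiles (when an alignment is
#' available), plot-data TSV, plots and a run log are written. Query leaves
#' of the tree that did not survive filtering are pruned before clade
#' delimitation.
#'
#' @param config A [pipeline_config()].
#' @return A `novelty_report`: list with `clades` (ranked data.frame, with a
#'   `category` column), `aggregates`, `screen_report`, `stage_counts` and
#'   `params`. An empty post-filter query set yields an empty report, not an
#'   error.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character()
  say <- function(...) {
    msg <- sprintf(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }

  table <- load_input(config$table, read_otu_table)
  seqs <- load_input(config$sequences, read_sequences)
  refs <- config$reference_ids
  if (is.character(refs) && length(refs) == 1L && file.exists(refs))
    refs <- trimws(readLines(refs, warn = FALSE))
  refs <- refs[nzchar(refs)]
  aln <- if (!is.null(config$alignment)) load_input(config$alignment, read_sequences)
  tree <- config$tree
  if (is.null(tree)) {
    nwk <- run_fasttree_adapter(config$alignment, config$fasttree,
                                out_dir = config$output_dir)
    tree <- read_newick(nwk)
    say("inferred tree with FastTree adapter: %d leaves", ape::Ntip(tree))
  } else {
    tree <- load_input(tree, read_newick)
  }

  # categories: NULL = whole library; "sample_category" = table metadata
  category <- config$category_key
  if (identical(category, "sample_category")) category <- table$sample_category
  if (is.character(category) && is.null(names(category)) && length(category) == 1L)
    stop("category_key must be 'sample_category' or a named sample->category map",
         call. = FALSE)
  subsets <- if (is.null(category)) {
    list(all = sample_ids(table))
  } else {
    split(sample_ids(table), category[sample_ids(table)])
  }

  all_clades <- list()
  aggregates <- list()
  screen_report <- NULL
  stage_counts <- list()
  for (cc in lex_sort(names(subsets))) {
    sub_table <- subset_table(table, samples = subsets[[cc]])
    res <- run_library(sub_table, seqs, tree, refs, config, cc, say, aln)
    all_clades[[cc]] <- res$clades
    aggregates[[cc]] <- res$aggregate
    screen_report <- res$screen_report   # per-library report; keep the last
    stage_counts[[cc]] <- res$stage_counts
  }
  clades <- do.call(rbind, all_clades)
  rownames(clades) <- NULL
  aggregates <- do.call(rbind, aggregates)
  rownames(aggregates) <- NULL
  if (nrow(aggregates) >= 3)
    attr(aggregates, "library_size_novelty_correlation") <-
      stats::cor(aggregates$n_sequences, aggregates$total_weighted_novelty,
                 method = config$rank$correlation)

  report <- structure(list(clades = clades, aggregates = aggregates,
                           screen_report = screen_report,
                           stage_counts = stage_counts,
                           params = list(filter = config$filter,
                                         rank = config$rank)),
                      class = "novelty_report")

  if (!is.null(config$output_dir)) {
    write_report_files(report, aln, config$output_dir, log_lines)
    say("outputs written to %s", config$output_dir)
  }
  report
}

# one library (sample subset) end to end
run_library <- function(table, seqs, tree, refs, config, cc, say, aln) {
  # drop OTUs absent from this subset before filtering so the <10 rule is
  # judged independently per analysed subset
  table <- subset_table(table, otus = otu_ids(table)[otu_totals(table) > 0])
  filt <- apply_all_filters(table, seqs, config$filter,
                            external_report = config$ssu_align_report)
  say("[%s] filters: %s", cc,
      paste(names(filt$stage_counts), filt$stage_counts,
            sep = "=", collapse = ", "))
  say("[%s] artifact fraction: %.3f", cc, filt$screen_report$artifact_fraction)

  empty <- empty_clades()
  if (!nrow(filt$table$counts)) {
    say("[%s] no unclassified OTUs survive filtering; empty report", cc)
    agg <- aggregate_by_category(empty, table,
                                 stats::setNames(rep(cc, ncol(table$counts)),
                                                 sample_ids(table)),
                                 config$rank$correlation)
    return(list(clades = empty, aggregate = agg,
                screen_report = filt$screen_report,
                stage_counts = filt$stage_counts))
  }

  rt <- assign_roles(tree, refs)
  extra <- setdiff(query_leaves(rt), otu_ids(filt$table))
  if (length(extra)) {
    say("[%s] pruning %d query leaves not in the filtered table", cc,
        length(extra))
    roles <- rt$leaf_roles
    pruned <- ape::drop.tip(structure(rt, class = "phylo"), extra)
    pruned$leaf_roles <- roles[pruned$tip.label]
    class(pruned) <- unique(c("roled_tree", class(pruned)))
    rt <- pruned
  }
  if (!length(query_leaves(rt))) {
    say("[%s] no query leaves on the tree after pruning; empty report", cc)
    agg <- aggregate_by_category(empty, table,
                                 stats::setNames(rep(cc, ncol(table$counts)),
                                                 sample_ids(table)),
                                 config$rank$correlation)
    return(list(clades = empty, aggregate = agg,
                screen_report = filt$screen_report,
                stage_counts = filt$stage_counts))
  }
  rt <- root_at_reference(rt)
  clades <- find_novel_clades(rt)
  say("[%s] %d novel clades (%d single-OTU)", cc, nrow(clades),
      sum(clades$n_otus == 1L))
  clades <- score_clades(rt, clades, filt$table, config$rank)
  clades <- rank_clades(clades, config$rank$ties)
  denom <- if (config$rank$proportion_denominator == "full_library")
    sum(table$counts) else sum(filt$table$counts)
  clades$proportion <- vapply(clades$total_abundance, clade_proportion,
                              numeric(1), denominator_total = denom)
  clades$category <- cc
  agg <- aggregate_by_category(clades, table,
                               stats::setNames(rep(cc, ncol(table$counts)),
                                               sample_ids(table)),
                               config$rank$correlation)
  list(clades = clades, aggregate = agg, screen_report = filt$screen_report,
       stage_counts = filt$stage_counts)
}

empty_clades <- function() {
  out <- data.frame(clade_id = character(), n_otus = integer(),
                    clade_root = integer(), stem_length = numeric(),
                    total_abundance = numeric(), novelty_distance = numeric(),
                    novelty_rank = numeric(), abundance_rank = numeric(),
                    combined_score = numeric(), proportion = numeric(),
                    category = character(), stringsAsFactors = FALSE)
  out$member_otus <- list()
  class(out) <- c("novel_clades", "data.frame")
  out
}

write_report_files <- function(report, aln, out_dir, log_lines) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_clade_report(report$clades, file.path(out_dir, "ranked_clades.tsv"))
  rows <- bubble_plot_data(report)
  utils::write.table(rows, file.path(out_dir, "plot_data.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (nrow(rows)) render_plots(rows, out_dir)
  if (!is.null(aln) && nrow(report$clades)) {
    cl_dir <- file.path(out_dir, "clades")
    dir.create(cl_dir, showWarnings = FALSE)
    for (k in seq_len(nrow(report$clades))) {
      id <- paste0(report$clades$category[k], "_", report$clades$clade_id[k])
      members <- intersect(report$clades$member_otus[[k]], names(aln))
      if (!length(members)) next
      sub <- extract_clade_alignment(aln, members)
      write_sequences(sub, file.path(cl_dir, paste0(id, ".afa")), "fasta")
      write_sequences(sub, file.path(cl_dir, paste0(id, ".sto")), "stockholm")
      write_profile(build_profile(sub), file.path(cl_dir, paste0(id, "_pfm.tsv")))
    }
  }
  utils::write.table(report$aggregates,
                     file.path(out_dir, "category_aggregates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
}

#' @export
print.novelty_report <- function(x, ...) {
  cat(sprintf("Novelty report: %d clades across %d categor%s\n",
              nrow(x$clades), nrow(x$aggregates),
              if (nrow(x$aggregates) == 1L) "y" else "ies"))
  if (nrow(x$clades)) {
    top <- utils::head(x$clades, 5L)
    for (k in seq_len(nrow(top)))
      cat(sprintf("  %s [%s] novelty=%.4f abundance=%d score=%.1f\n",
                  top$clade_id[k], top$category[k], top$novelty_distance[k],
                  as.integer(top$total_abundance[k]), top$combined_score[k]))
  }
  invisible(x)
}

#' Infer a tree from a merged alignment with FastTree
#'
#' Thin adapter over an external FastTree executable, run with nucleotide
#' GTR settings (`-nt -gtr`). The tree itself is external to this package;
#' the adapter only shells out and validates the result.
#'
#' @param alignment Path to an aligned FASTA file.
#' @param executable Path to the FastTree binary (configuration error when
#'   missing — use tree-input mode instead).
#' @param out_dir Directory for the Newick output (default: tempdir).
#' @return Path to the produced Newick file.
#' @export
run_fasttree_adapter <- function(alignment, executable = "fasttree",
                                 out_dir = NULL) {
  exe <- Sys.which(executable)
  if (!nzchar(exe))
    stop("FastTree executable not found ('", executable,
         "'); supply a prebuilt tree instead", call. = FALSE)
  if (is.character(alignment) && !file.exists(alignment))
    stop("alignment file not found: ", alignment, call. = FALSE)
  out_dir <- out_dir %||% tempdir()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- file.path(out_dir, "fasttree.nwk")
  ver <- tryCatch(system2(exe, "-help", stdout = TRUE, stderr = TRUE)[1],
                  error = function(e) "unknown")
  message("FastTree adapter: ", ver)
  status <- system2(exe, c("-nt", "-gtr", "-quiet", shQuote(alignment)),
                    stdout = out, stderr = FALSE)
  if (!identical(status, 0L) || !file.size(out) > 0) {
    unlink(out)
    stop("FastTree failed (exit ", status, ")", call. = FALSE)
  }
  out
}
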