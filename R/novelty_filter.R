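#' Parameters for the artifact screen
#'
#' The built-in screen is a heuristic stand-in for structural binning against
#' an SSU covariance model: sequences pass when their ungapped length lies in
#' `[min_length, max_length]` and the fraction of characters outside
#' `ACGTU` is at most `max_ambiguous_fraction`. When a per-sequence report
#' from an external structural binner is available, `external_mode =
#' "ssu-align-report"` passes exactly the ids that report assigns to the
#' bacterial model instead.
#'
#' @param min_length,max_length Length bounds in nucleotides.
#' @param max_ambiguous_fraction Maximum tolerated fraction of non-ACGTU
#'   characters, in `[0, 1]`.
#' @param external_mode `"off"` (built-in heuristic) or
#'   `"ssu-align-report"`.
#' @return A list of class `screen_params`.
#' @export
screen_params <- function(min_length = 100L, max_length = 2500L,
                          max_ambiguous_fraction = 0.05,
                          external_mode = c("off", "ssu-align-report")) {
  external_mode <- match.arg(external_mode)
  stopifnot(min_length <= max_length,
            max_ambiguous_fraction >= 0, max_ambiguous_fraction <= 1)
  structure(list(min_length = min_length, max_length = max_length,
                 max_ambiguous_fraction = max_ambiguous_fraction,
                 external_mode = external_mode),
            class = "screen_params")
}

#' Parameters for the unclassified-OTU filters
#'
#' @param rank Canonical rank at which "unclassified" is judged (default
#'   `"class"`).
#' @param min_count Minimum total sequence count per OTU; OTUs with strictly
#'   fewer sequences are removed (default 10).
#' @param screen A [screen_params()] object.
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(rank = "class", min_count = 10L,
                          screen = screen_params()) {
  rank <- match.arg(rank, canonical_ranks())
  stopifnot(min_count >= 0)
  structure(list(rank = rank, min_count = as.integer(min_count),
                 screen = screen),
            class = "filter_params")
}

#' Keep only OTUs unclassified at a rank
#'
#' Retains exactly the OTUs whose taxonomy is unassigned at `rank`
#' (unassignment propagates downward, so an OTU unassigned at phylum is also
#' unclassified at class). Samples and retained counts are unchanged.
#'
#' @param table An [otu_table()].
#' @param rank Canonical rank name.
#' @return A filtered [otu_table()].
#' @export
filter_unclassified <- function(table, rank = "class") {
  rank <- match.arg(rank, canonical_ranks())
  keep <- is_unassigned_at(table$taxonomy, rank)
  subset_table(table, otus = otu_ids(table)[keep])
}

#' Remove very-low-abundance OTUs
#'
#' Retains OTUs whose total sequence count across all samples is at least
#' `min_count`; OTUs contributing strictly fewer sequences are removed. The
#' threshold is judged on the per-library total, not per sample.
#'
#' @param table An [otu_table()].
#' @param min_count Minimum total count (default 10).
#' @return A filtered [otu_table()].
#' @export
filter_low_abundance <- function(table, min_count = 10L) {
  stopifnot(min_count >= 0)
  keep <- otu_totals(table) >= min_count
  subset_table(table, otus = otu_ids(table)[keep])
}

#' Screen sequences for non-SSU artifacts
#'
#' @param seqs An ungapped [seqset()].
#' @param params A [screen_params()].
#' @param external_report Path to a per-sequence structural binning report
#'   (required when `params$external_mode == "ssu-align-report"`). Lines are
#'   whitespace-delimited `<id> <model>` pairs (a bare `<id>` counts as
#'   bacterial); `#` comment lines are ignored; ids assigned to a model whose
#'   name contains "bacteria" pass.
#' @return A list with `pass` (the surviving [seqset()]) and `report`, a
#'   `screen_report` with fields `n_input`, `n_pass`, `n_fail`, `fail_ids`
#'   and `artifact_fraction`.
#' @export
structural_screen <- function(seqs, params = screen_params(),
                              external_report = NULL) {
  x <- as.character(seqs)
  if (any(grepl("[-.]", x)))
    stop("structural_screen expects ungapped sequences", call. = FALSE)
  ids <- names(seqs)
  if (params$external_mode == "ssu-align-report") {
    if (is.null(external_report) || !file.exists(external_report %||% ""))
      stop("external_mode='ssu-align-report' but no readable report given",
           call. = FALSE)
    pass_ids <- parse_ssu_align_report(external_report)
    ok <- ids %in% pass_ids
  } else {
    len <- nchar(x)
    n_ambig <- len - vapply(strsplit(x, ""), function(ch)
      sum(ch %in% c("A", "C", "G", "T", "U")), integer(1))
    ok <- len >= params$min_length & len <= params$max_length &
      (len == 0L | n_ambig / pmax(len, 1L) <= params$max_ambiguous_fraction)
  }
  report <- structure(list(
    n_input = length(ids), n_pass = sum(ok), n_fail = sum(!ok),
    fail_ids = ids[!ok],
    artifact_fraction = if (length(ids)) sum(!ok) / length(ids) else 0),
    class = "screen_report")
  list(pass = seqs[ok], report = report)
}

parse_ssu_align_report <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")])
  if (!length(lines)) return(character())
  tok <- strsplit(lines, "\\s+")
  ids <- vapply(tok, `[[`, "", 1L)
  model <- vapply(tok, function(t) if (length(t) > 1L) t[2] else "bacteria",
                  character(1))
  ids[grepl("bacteria", model, ignore.case = TRUE)]
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("Artifact screen: %d in, %d pass, %d fail (%.1f%% artifacts)\n",
              x$n_input, x$n_pass, x$n_fail, 100 * x$artifact_fraction))
  invisible(x)
}

#' Apply the full unclassified / artifact / abundance filter cascade
#'
#' Applies, in order: the unclassified-at-rank filter, the structural
#' artifact screen, and the low-abundance filter. Counts are never
#' renormalised; proportions downstream are computed against a
#' caller-specified denominator.
#'
#' @param table An [otu_table()].
#' @param seqs An [seqset()] holding a representative sequence for every OTU
#'   in `table`.
#' @param params A [filter_params()].
#' @param external_report Optional structural-binner report path, see
#'   [structural_screen()].
#' @return A list with `table` and `sequences` (the filtered pair, identical
#'   OTU id sets), `screen_report`, and `stage_counts` — OTUs remaining after
#'   each stage.
#' @export
apply_all_filters <- function(table, seqs, params = filter_params(),
                              external_report = NULL) {
  missing <- setdiff(otu_ids(table), names(seqs))
  if (length(missing))
    stop("OTUs without a representative sequence: ",
         paste(missing, collapse = ", "), call. = FALSE)
  stage <- c(input = nrow(table$counts))
  tab <- filter_unclassified(table, params$rank)
  stage["unclassified"] <- nrow(tab$counts)
  scr <- structural_screen(seqs[otu_ids(tab)], params$screen, external_report)
  tab <- subset_table(tab, otus = names(scr$pass))
  stage["screened"] <- nrow(tab$counts)
  tab <- filter_low_abundance(tab, params$min_count)
  stage["abundant"] <- nrow(tab$counts)
  list(table = tab, sequences = scr$pass[otu_ids(tab)],
       screen_report = scr$report, stage_counts = stage)
}
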