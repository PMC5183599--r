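#' Construct an OTU count table
#'
#' Container for an OTU x sample matrix of sequence counts with per-OTU
#' taxonomy and optional per-sample category metadata (e.g. biome or body
#' site). Counts must be non-negative integers: the low-abundance filter and
#' abundance weighting are defined on sequence counts, so relative-abundance
#' tables are rejected.
#'
#' @param counts Non-negative integer matrix, OTUs in rows, samples in
#'   columns, with unique dimnames.
#' @param taxonomy Character vector of lineage strings (one per OTU), or a
#'   character matrix with [canonical_ranks()] columns, or `NULL` for fully
#'   unassigned taxonomy.
#' @param sample_category Optional named character vector mapping sample id
#'   to a category label.
#' @param taxonomy_dialect Dialect passed to [parse_taxonomy()] when
#'   `taxonomy` is given as strings.
#' @return An object of class `ssu_otu_table`: a list with elements
#'   `counts`, `taxonomy` (OTU x rank matrix) and `sample_category`.
#' @export
otu_table <- function(counts, taxonomy = NULL, sample_category = NULL,
                      taxonomy_dialect = "auto") {
  counts <- as.matrix(counts)
  # R normalises empty dimnames to NULL; an empty table is still valid
  if ((nrow(counts) > 0L && is.null(rownames(counts))) || is.null(colnames(counts)))
    stop("counts must have OTU row names and sample column names", call. = FALSE)
  validate_counts(counts)
  storage.mode(counts) <- "integer"
  if (nrow(counts) == 0L) {
    taxonomy <- matrix(character(), 0L, 7L,
                       dimnames = list(NULL, canonical_ranks()))
    return(structure(list(counts = counts, taxonomy = taxonomy,
                          sample_category = if (is.null(sample_category)) NULL
                                            else sample_category[colnames(counts)]),
                     class = "ssu_otu_table"))
  }
  if (anyDuplicated(rownames(counts)))
    stop("duplicate OTU id: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample id: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "),
         call. = FALSE)
  if (is.null(taxonomy)) {
    taxonomy <- matrix("", nrow(counts), 7,
                       dimnames = list(rownames(counts), canonical_ranks()))
  } else if (!is.matrix(taxonomy)) {
    taxonomy <- taxonomy_matrix(taxonomy, rownames(counts), taxonomy_dialect)
  }
  if (!identical(rownames(taxonomy), rownames(counts)))
    taxonomy <- taxonomy[rownames(counts), , drop = FALSE]
  if (!is.null(sample_category)) {
    missing <- setdiff(colnames(counts), names(sample_category))
    if (length(missing))
      stop("samples without category: ", paste(missing, collapse = ", "), call. = FALSE)
    sample_category <- sample_category[colnames(counts)]
  }
  structure(list(counts = counts, taxonomy = taxonomy,
                 sample_category = sample_category),
            class = "ssu_otu_table")
}

validate_counts <- function(counts) {
  if (!is.numeric(counts)) stop("counts must be numeric", call. = FALSE)
  if (anyNA(counts)) stop("counts contain missing values", call. = FALSE)
  if (any(counts < 0)) stop("negative count not allowed", call. = FALSE)
  if (any(counts != floor(counts)))
    stop("non-integral count not allowed (is this a relative-abundance table?)",
         call. = FALSE)
  invisible(counts)
}

#' @export
print.ssu_otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d OTUs x %d samples, %d total sequences\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  n_uncl <- sum(is_unassigned_at(x$taxonomy, "class"))
  cat(sprintf("  %d OTUs unclassified at class\n", n_uncl))
  if (!is.null(x$sample_category))
    cat("  sample categories: ",
        paste(unique(x$sample_category), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.ssu_otu_table <- function(x) dim(x$counts)

#' OTU and sample identifiers of a table
#' @param table An `ssu_otu_table`.
#' @return Character vector of ids.
#' @export
otu_ids <- function(table) rownames(table$counts) %||% character(0)

#' @rdname otu_ids
#' @export
sample_ids <- function(table) colnames(table$counts)

#' Per-OTU total sequence counts
#' @param table An `ssu_otu_table`.
#' @return Named integer vector of row sums.
#' @export
otu_totals <- function(table) rowSums(table$counts)

# Subset rows/columns keeping the class invariants.
subset_table <- function(table, otus = NULL, samples = NULL) {
  counts <- table$counts
  if (!is.null(otus)) counts <- counts[otus, , drop = FALSE]
  if (!is.null(samples)) counts <- counts[, samples, drop = FALSE]
  otu_table(counts,
            taxonomy = table$taxonomy[rownames(counts), , drop = FALSE],
            sample_category = if (is.null(table$sample_category)) NULL
                              else table$sample_category[colnames(counts)])
}

#' Read an OTU table
#'
#' Reads the BIOM v1.0 JSON dialect (sparse or dense observation matrix,
#' via \pkg{biomformat}) or a plain tab-separated dialect with header
#' `#OTU ID<TAB>sample...<TAB>taxonomy` and a semicolon-delimited lineage in
#' the last column. Both dialects yield identical tables for the same data.
#' Observation metadata under either a `taxonomy` or `Taxonomy` key is
#' accepted in BIOM input.
#'
#' @param path Path to the file.
#' @param dialect `"biom-json"` or `"tsv"`; `"auto"` decides from content.
#' @param taxonomy_dialect Passed to [parse_taxonomy()].
#' @return An [otu_table()].
#' @export
read_otu_table <- function(path, dialect = c("auto", "biom-json", "tsv"),
                           taxonomy_dialect = "auto") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "auto") {
    first <- readChar(path, 1L, useBytes = TRUE)
    dialect <- if (identical(first, "{")) "biom-json" else "tsv"
  }
  switch(dialect,
         "biom-json" = read_otu_table_biom(path, taxonomy_dialect),
         "tsv" = read_otu_table_tsv(path, taxonomy_dialect))
}

read_otu_table_biom <- function(path, taxonomy_dialect = "auto") {
  b <- tryCatch(biomformat::read_biom(path), error = function(e)
    stop("malformed BIOM JSON in ", path, ": ", conditionMessage(e), call. = FALSE))
  counts <- as.matrix(biomformat::biom_data(b))
  # taxonomy straight from the parsed row metadata so arbitrary extra keys
  # cannot pollute it; accept "taxonomy" and "Taxonomy"
  tax <- vapply(b$rows, function(row) {
    md <- row$metadata
    if (is.null(md)) return("")
    if (is.list(md)) {
      key <- intersect(c("taxonomy", "Taxonomy"), names(md))
      if (length(key)) return(paste(unlist(md[[key[1]]]), collapse = "; "))
    }
    paste(unlist(md), collapse = "; ")
  }, character(1))
  cat_ <- NULL
  cats <- vapply(b$columns, function(col) {
    md <- col$metadata
    if (is.null(md) || !length(md)) NA_character_ else as.character(unlist(md)[1])
  }, character(1))
  if (!all(is.na(cats)))
    cat_ <- stats::setNames(cats, vapply(b$columns, `[[`, "", "id"))
  otu_table(counts, taxonomy = tax, sample_category = cat_,
            taxonomy_dialect = taxonomy_dialect)
}

read_otu_table_tsv <- function(path, taxonomy_dialect = "auto") {
  lines <- readLines(path, warn = FALSE)
  header_idx <- grep("^#OTU ID\t", lines)[1]
  if (is.na(header_idx))
    stop("TSV OTU table in ", path, " lacks a '#OTU ID' header line", call. = FALSE)
  header <- strsplit(lines[header_idx], "\t", fixed = TRUE)[[1]]
  ncol_expect <- length(header)
  if (ncol_expect < 2L)
    stop("TSV header must name at least one sample column", call. = FALSE)
  has_tax <- tolower(header[ncol_expect]) == "taxonomy"
  sample_cols <- header[seq(2L, if (has_tax) ncol_expect - 1L else ncol_expect)]
  body <- lines[-seq_len(header_idx)]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != ncol_expect)
  if (length(bad))
    stop(sprintf("line %d of %s has %d fields, expected %d",
                 header_idx + bad[1], path, lengths(fields)[bad[1]], ncol_expect),
         call. = FALSE)
  ids <- vapply(fields, `[[`, "", 1L)
  raw <- vapply(fields, function(f)
    f[seq(2L, length.out = length(sample_cols))], character(length(sample_cols)))
  raw <- if (length(sample_cols) == 1L) matrix(raw, nrow = 1L) else raw
  num <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric count '%s' at line %d of %s",
                 raw[bad[1], bad[2]], header_idx + bad[2], path), call. = FALSE)
  }
  counts <- t(num)
  dimnames(counts) <- list(ids, sample_cols)
  tax <- if (has_tax) vapply(fields, `[[`, "", ncol_expect) else NULL
  otu_table(counts, taxonomy = tax, taxonomy_dialect = taxonomy_dialect)
}

#' Write an OTU table
#'
#' @param table An [otu_table()].
#' @param path Output path.
#' @param dialect `"biom-json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path, dialect = c("tsv", "biom-json")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    tax <- apply(table$taxonomy, 1L, format_taxonomy)
    header <- paste(c("#OTU ID", sample_ids(table), "taxonomy"), collapse = "\t")
    rows <- vapply(seq_len(nrow(table$counts)), function(i)
      paste(c(otu_ids(table)[i], table$counts[i, ], tax[i]), collapse = "\t"),
      character(1))
    writeLines(c(header, rows), path)
  } else {
    n <- nrow(table$counts)
    rows <- lapply(seq_len(n), function(i) list(
      id = otu_ids(table)[i],
      metadata = list(taxonomy = as.list(unname(
        paste0(.gg_prefixes, table$taxonomy[i, ]))))))
    cols <- lapply(sample_ids(table), function(s) list(
      id = s,
      metadata = if (is.null(table$sample_category)) NULL
                 else list(category = unname(table$sample_category[s]))))
    nz <- which(table$counts != 0L, arr.ind = TRUE)
    data <- lapply(seq_len(nrow(nz)), function(k)
      list(nz[k, 1] - 1L, nz[k, 2] - 1L, table$counts[nz[k, 1], nz[k, 2]]))
    obj <- list(
      id = NULL, format = "Biological Observation Matrix 1.0.0",
      format_url = "http://biom-format.org", type = "OTU table",
      generated_by = paste0("ssunovel ", utils::packageVersion("ssunovel")),
      date = "1970-01-01T00:00:00", matrix_type = "sparse",
      matrix_element_type = "int", shape = c(n, ncol(table$counts)),
      rows = rows, columns = cols, data = data)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null", digits = NA)
  }
  invisible(path)
}
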