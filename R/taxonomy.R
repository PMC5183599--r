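#' Canonical taxonomic ranks
#'
#' The seven canonical ranks used throughout the package, ordered from
#' domain to species.
#'
#' @return Character vector of rank names.
#' @export
canonical_ranks <- function() {
  c("domain", "phylum", "class", "order", "family", "genus", "species")
}

# tokens that mean "no assignment" regardless of dialect (compared
# case-insensitively after prefix stripping)
.unassigned_tokens <- c("", "unassigned", "unclassified")

# greengenes-style single-letter prefixes in rank order
.gg_prefixes <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")

#' Parse a taxonomy lineage string into a rank-addressable path
#'
#' Splits a semicolon-delimited lineage into assignments at the seven
#' canonical ranks. A rank is unassigned when its field is empty, is a bare
#' prefix (e.g. `c__`), or is one of the literal tokens `Unassigned` /
#' `unclassified` (case-insensitive). Unassignment propagates downward: once
#' a rank is unassigned all deeper ranks are unassigned too, so rank
#' filtering is monotone.
#'
#' @param raw Lineage string, e.g. `"k__Bacteria; p__Acidobacteria; c__"`.
#' @param dialect One of `"greengenes"` (`k__`/`p__`/... prefixes),
#'   `"silva"` (`D_0__`-style or bare level prefixes), `"plain"` (bare names,
#'   positional by rank), or `"auto"` to sniff the dialect from the string.
#' @return Named character vector over [canonical_ranks()]; `""` marks an
#'   unassigned rank.
#' @examples
#' parse_taxonomy("k__Bacteria; p__Acidobacteria; c__", "greengenes")
#' parse_taxonomy("Unassigned")
#' @export
parse_taxonomy <- function(raw, dialect = c("auto", "greengenes", "silva", "plain")) {
  dialect <- match.arg(dialect)
  ranks <- canonical_ranks()
  out <- stats::setNames(character(length(ranks)), ranks)
  if (is.na(raw) || !nzchar(trimws(raw))) return(out)
  fields <- trimws(strsplit(raw, ";", fixed = TRUE)[[1]])
  if (dialect == "auto") dialect <- sniff_taxonomy_dialect(fields)
  if (length(fields) > length(ranks)) {
    warning(sprintf("taxonomy string has %d levels; levels beyond species ignored",
                    length(fields)), call. = FALSE)
    fields <- fields[seq_along(ranks)]
  }
  for (i in seq_along(fields)) {
    name <- switch(dialect,
      greengenes = sub("^[a-zA-Z]__", "", fields[i]),
      silva = sub("^D_[0-9]+__", "", fields[i]),
      plain = fields[i]
    )
    if (tolower(trimws(name)) %in% .unassigned_tokens) break  # propagate down
    out[i] <- trimws(name)
  }
  out
}

sniff_taxonomy_dialect <- function(fields) {
  if (any(grepl("^[a-zA-Z]__", fields))) return("greengenes")
  if (any(grepl("^D_[0-9]+__", fields))) return("silva")
  "plain"
}

#' Render a taxonomy path as a greengenes-style lineage string
#'
#' Inverse of [parse_taxonomy()] on its canonical rendering; used when
#' writing OTU tables back out.
#'
#' @param path Named character vector as returned by [parse_taxonomy()].
#' @return A single semicolon-delimited lineage string.
#' @export
format_taxonomy <- function(path) {
  stopifnot(length(path) == length(canonical_ranks()))
  paste0(.gg_prefixes, path, collapse = "; ")
}

#' Is a taxonomy path unassigned at a given rank?
#'
#' @param path Named character vector from [parse_taxonomy()], or a character
#'   matrix with one row per OTU and [canonical_ranks()] columns.
#' @param rank Canonical rank name (default `"class"`).
#' @return Logical (vector when `path` is a matrix).
#' @export
is_unassigned_at <- function(path, rank = "class") {
  rank <- match.arg(rank, canonical_ranks())
  if (is.matrix(path))
    stats::setNames(!nzchar(path[, rank]), rownames(path))
  else !nzchar(path[[rank]])
}

# Parse many lineage strings into an OTU x rank character matrix.
taxonomy_matrix <- function(strings, ids, dialect = "auto") {
  mat <- t(vapply(strings, parse_taxonomy, character(7), dialect = dialect,
                  USE.NAMES = FALSE))
  dimnames(mat) <- list(ids, canonical_ranks())
  mat
}
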