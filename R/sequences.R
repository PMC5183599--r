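#' Construct a sequence set
#'
#' A named collection of IUPAC nucleotide strings, optionally gapped when it
#' represents an alignment (all sequences then share one length).
#'
#' @param x Named character vector of sequences.
#' @param aligned Logical; is this an alignment?
#' @return An object of class `ssu_seqset` (named character vector with an
#'   `aligned` attribute).
#' @export
seqset <- function(x, aligned = FALSE) {
  if (!length(x))
    return(structure(character(), aligned = aligned, class = "ssu_seqset"))
  if (is.null(names(x)) || !all(nzchar(names(x))))
    stop("all sequences must be named", call. = FALSE)
  if (anyDuplicated(names(x)))
    stop("duplicate sequence id: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "),
         call. = FALSE)
  if (aligned && length(unique(nchar(x))) > 1L)
    stop("ragged alignment: sequences differ in length", call. = FALSE)
  structure(toupper(x), aligned = aligned, class = "ssu_seqset")
}

#' @export
print.ssu_seqset <- function(x, ...) {
  cat(sprintf("%s of %d sequences (lengths %s)\n",
              if (isTRUE(attr(x, "aligned"))) "Alignment" else "Sequence set",
              length(x), paste(range(nchar(x)), collapse = "-")))
  invisible(x)
}

#' @export
as.character.ssu_seqset <- function(x, ...) c(unclass(x))

#' @export
`[.ssu_seqset` <- function(x, i) {
  seqset(unclass(x)[i], aligned = isTRUE(attr(x, "aligned")))
}

#' Is a sequence set an alignment?
#' @param x An `ssu_seqset`.
#' @return Logical.
#' @export
is_aligned <- function(x) isTRUE(attr(x, "aligned"))

#' Read sequences from FASTA or Stockholm
#'
#' FASTA parsing is delegated to \pkg{Biostrings}; ids are kept verbatim up
#' to the first whitespace. Stockholm input must be a single alignment block;
#' interleaved blocks are concatenated per sequence name and the equal-length
#' invariant is enforced.
#'
#' @param path Path to the file.
#' @param format `"fasta"`, `"stockholm"`, or `"auto"` (from content).
#' @return An [seqset()]; Stockholm input is flagged as aligned, FASTA input
#'   is flagged aligned when gapped and uniform length.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (startsWith(first, "# STOCKHOLM")) "stockholm" else "fasta"
  }
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    nm <- sub("\\s.*$", "", names(ss))
    if (anyDuplicated(nm))
      stop("duplicate sequence id in ", path, ": ",
           paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
    x <- stats::setNames(as.character(ss), nm)
    gapped <- any(grepl("[-.]", x))
    seqset(x, aligned = gapped && length(unique(nchar(x))) == 1L)
  } else {
    read_stockholm(path)
  }
}

read_stockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !startsWith(lines[1], "# STOCKHOLM"))
    stop("not a Stockholm file (missing '# STOCKHOLM' header): ", path,
         call. = FALSE)
  seqs <- list()
  for (ln in lines[-1]) {
    if (!nzchar(trimws(ln)) || startsWith(ln, "#")) next
    if (trimws(ln) == "//") break
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) != 2L)
      stop("malformed Stockholm sequence line: '", ln, "'", call. = FALSE)
    seqs[[tok[1]]] <- paste0(seqs[[tok[1]]] %||% "", tok[2])
  }
  if (!length(seqs)) stop("Stockholm file contains no sequences: ", path,
                          call. = FALSE)
  x <- unlist(seqs)
  if (length(unique(nchar(x))) > 1L)
    stop("ragged Stockholm alignment in ", path, call. = FALSE)
  seqset(x, aligned = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write sequences to FASTA or Stockholm
#'
#' @param seqs An [seqset()].
#' @param path Output path.
#' @param format `"fasta"` or `"stockholm"` (Stockholm requires an aligned
#'   set).
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  if (format == "fasta") {
    Biostrings::writeXStringSet(
      Biostrings::BStringSet(stats::setNames(as.character(seqs), names(seqs))),
      path)
  } else {
    if (!is_aligned(seqs))
      stop("Stockholm output requires an aligned sequence set", call. = FALSE)
    pad <- formatC(names(seqs), width = max(nchar(names(seqs))), flag = "-")
    writeLines(c("# STOCKHOLM 1.0",
                 paste(pad, as.character(seqs)),
                 "//"), path)
  }
  invisible(path)
}

#' Read a Newick tree
#'
#' Thin validating wrapper around [ape::read.tree()]: duplicate leaf labels
#' are rejected, missing branch lengths become 0 with a warning, polytomies
#' pass through.
#'
#' @param path Path to a Newick file, or a literal Newick string via `text`.
#' @param text Optional Newick string (overrides `path`).
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- if (!is.null(text)) {
    tryCatch(ape::read.tree(text = text), error = identity, warning = identity)
  } else {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    tryCatch(ape::read.tree(path), error = identity, warning = identity)
  }
  if (is.null(tr) || inherits(tr, "condition"))
    stop("Newick parse error",
         if (inherits(tr, "condition")) paste0(": ", conditionMessage(tr)) else "",
         call. = FALSE)
  if (inherits(tr, "multiPhylo")) tr <- tr[[1]]
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf label: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "),
         call. = FALSE)
  if (is.null(tr$edge.length)) {
    warning("tree has no branch lengths; all set to 0", call. = FALSE)
    tr$edge.length <- rep(0, nrow(tr$edge))
  } else if (anyNA(tr$edge.length)) {
    warning("missing branch lengths set to 0", call. = FALSE)
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  tr
}

#' Write a tree as Newick
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
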