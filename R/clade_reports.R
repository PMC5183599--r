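#' Extract the alignment rows of one clade
#'
#' Subsets a merged multiple alignment to the clade's member OTUs (rows in
#' clade member order) and drops columns that are gaps in every retained
#' row.
#'
#' @param merged_alignment An aligned [seqset()].
#' @param members Character vector of member ids, all present in the
#'   alignment.
#' @return An aligned [seqset()] with the members only.
#' @export
extract_clade_alignment <- function(merged_alignment, members) {
  if (!is_aligned(merged_alignment))
    stop("merged_alignment must be an aligned sequence set", call. = FALSE)
  missing <- setdiff(members, names(merged_alignment))
  if (length(missing))
    stop("clade members missing from alignment: ",
         paste(missing, collapse = ", "), call. = FALSE)
  rows <- unclass(merged_alignment)[members]
  chars <- do.call(rbind, strsplit(rows, ""))
  keep <- colSums(chars != "-" & chars != ".") > 0L
  out <- apply(chars[, keep, drop = FALSE], 1L, paste, collapse = "")
  seqset(stats::setNames(out, members), aligned = TRUE)
}

# IUPAC nucleotide ambiguity codes -> base sets (U folds into T)
.iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' Build a position frequency profile from a clade alignment
#'
#' Per-column character frequencies over `{A, C, G, T, -}` with `U` folded
#' into `T` and ambiguity codes distributed uniformly over their possible
#' bases (`N` adds 0.25 to each of A/C/G/T). The consensus takes the modal
#' character per column, ties broken in the order `A < C < G < T < -`. The
#' profile, together with the exported clade alignment, is the hand-off
#' point for building covariance/HMM models with external tools and for
#' screening metagenomic contigs.
#'
#' @param aln A non-empty aligned [seqset()].
#' @return A list of class `position_profile` with `length`, `frequencies`
#'   (5 x length matrix, rows `A,C,G,T,-`), `consensus` (string) and
#'   `n_sequences`.
#' @export
build_profile <- function(aln) {
  if (!length(aln)) stop("empty alignment", call. = FALSE)
  if (length(unique(nchar(aln))) != 1L)
    stop("profile requires equal-length rows", call. = FALSE)
  chars <- do.call(rbind, strsplit(toupper(as.character(aln)), ""))
  L <- ncol(chars)
  n <- nrow(chars)
  freq <- matrix(0, nrow = 5L, ncol = L,
                 dimnames = list(c("A", "C", "G", "T", "-"), NULL))
  for (j in seq_len(L)) {
    for (ch in chars[, j]) {
      if (ch %in% c("-", ".")) {
        freq["-", j] <- freq["-", j] + 1
      } else if (!is.null(.iupac_sets[[ch]])) {
        bases <- .iupac_sets[[ch]]
        freq[bases, j] <- freq[bases, j] + 1 / length(bases)
      } else {
        freq[c("A", "C", "G", "T"), j] <- freq[c("A", "C", "G", "T"), j] + 0.25
      }
    }
  }
  freq <- freq / n
  consensus <- paste(rownames(freq)[apply(freq, 2L, which.max)], collapse = "")
  structure(list(length = L, frequencies = freq, consensus = consensus,
                 n_sequences = n),
            class = "position_profile")
}

#' @export
print.position_profile <- function(x, ...) {
  cat(sprintf("Position frequency profile: %d columns, %d sequences\n",
              x$length, x$n_sequences))
  cat("consensus: ", x$consensus, "\n", sep = "")
  invisible(x)
}

#' Write a position frequency profile as TSV
#'
#' Columns: `position`, `A`, `C`, `G`, `T`, `gap`.
#'
#' @param profile A [build_profile()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(position = seq_len(profile$length),
                   t(profile$frequencies))
  colnames(df) <- c("position", "A", "C", "G", "T", "gap")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the ranked clade report as TSV
#'
#' Columns: `clade_id`, `n_otus`, `total_abundance`, `proportion`,
#' `novelty_distance`, `novelty_rank`, `abundance_rank`, `combined_score`,
#' `member_otus` (semicolon-joined).
#'
#' @param clades Ranked clades (with proportions filled).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clade_report <- function(clades, path) {
  df <- clades
  df$member_otus <- vapply(clades$member_otus, paste, "", collapse = ";")
  cols <- c("clade_id", "n_otus", "total_abundance", "proportion",
            "novelty_distance", "novelty_rank", "abundance_rank",
            "combined_score", "member_otus")
  cols <- intersect(cols, colnames(df))
  utils::write.table(as.data.frame(df)[, cols, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot-ready rows for the novelty bubble plot
#'
#' One row per (category, clade) with values copied from the ranked report,
#' never recomputed: `category`, `clade_id`, `novelty_distance`,
#' `proportion` (of the library, drives point size) and `combined_score`.
#' Rows are sorted by category then combined score.
#'
#' @param report A `novelty_report` (see [run_pipeline()]) or a ranked
#'   clades data.frame with a `category` column (default `"all"`).
#' @return A plain data.frame of plot rows.
#' @export
bubble_plot_data <- function(report) {
  clades <- if (inherits(report, "novelty_report")) report$clades else report
  if (!nrow(clades)) {
    return(data.frame(category = character(), clade_id = character(),
                      novelty_distance = numeric(), proportion = numeric(),
                      combined_score = numeric(), stringsAsFactors = FALSE))
  }
  cat_ <- if (is.null(clades$category)) rep("all", nrow(clades)) else clades$category
  out <- data.frame(category = cat_,
                    clade_id = clades$clade_id,
                    novelty_distance = clades$novelty_distance,
                    proportion = clades$proportion,
                    combined_score = clades$combined_score,
                    stringsAsFactors = FALSE)
  out <- out[order(out$category, out$combined_score, method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Render novelty plots
#'
#' Writes a scaled bubble plot (x = category, y = novelty distance, point
#' area proportional to the clade's share of the library) and one novelty
#' density dot plot per category. File names are deterministic:
#' `novelty_bubble.<ext>` and `novelty_density_<category>.<ext>`.
#'
#' @param rows Plot rows from [bubble_plot_data()].
#' @param out_dir Output directory (created if needed).
#' @param device `"svg"` or `"png"`.
#' @return Character vector of files written (empty for empty input).
#' @export
render_plots <- function(rows, out_dir, device = c("svg", "png")) {
  device <- match.arg(device)
  if (!nrow(rows)) {
    message("no clades to plot; nothing written")
    return(invisible(character()))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dev <- if (device == "svg") grDevices::svg else device
  files <- character()
  bubble <- ggplot2::ggplot(rows, ggplot2::aes(
      x = .data$category, y = .data$novelty_distance, size = .data$proportion)) +
    ggplot2::geom_point(alpha = 0.6, colour = "steelblue4") +
    ggplot2::scale_size_area(max_size = 10, name = "library proportion") +
    ggplot2::labs(x = NULL, y = "phylogenetic novelty (subs/site)") +
    ggplot2::theme_bw()
  f <- file.path(out_dir, paste0("novelty_bubble.", device))
  ggplot2::ggsave(f, bubble, width = 7, height = 5, device = dev)
  files <- c(files, f)
  for (cc in unique(rows$category)) {
    sub <- rows[rows$category == cc, , drop = FALSE]
    dens <- ggplot2::ggplot(sub, ggplot2::aes(x = .data$novelty_distance)) +
      ggplot2::geom_dotplot(binwidth = max(diff(range(sub$novelty_distance)) / 30,
                                           1e-3),
                            fill = "grey40") +
      ggplot2::labs(x = "phylogenetic novelty (subs/site)", y = NULL,
                    title = cc) +
      ggplot2::theme_bw()
    f <- file.path(out_dir, paste0("novelty_density_",
                                   gsub("[^A-Za-z0-9_.-]", "_", cc), ".", device))
    ggplot2::ggsave(f, dens, width = 7, height = 4, device = dev)
    files <- c(files, f)
  }
  invisible(files)
}
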