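# FASTA, pair-list and prediction input/output.

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Data frame with character columns `id` (first whitespace-
#'   delimited token of each header) and `sequence` (uppercased, wrapped
#'   lines joined, whitespace stripped).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("FASTA file contains no records: ", path,
                              call. = FALSE)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  if (any(!nzchar(ids) | is.na(ids))) {
    stop("FASTA record with an empty header in ", path, call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate FASTA id(s) in ", path, ": ",
         paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for id(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "), call. = FALSE)
  }
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins Data frame with columns `id` and `sequence`.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  stopifnot(is.data.frame(proteins), all(c("id", "sequence") %in% names(proteins)))
  set <- Biostrings::BStringSet(stats::setNames(proteins$sequence, proteins$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a labelled (or unlabelled) protein-pair list
#'
#' Tab- or comma-separated, two or three columns: `id_a`, `id_b` and an
#' optional binary `label` (1 = interacting, 0 = non-interacting).  A
#' header line is detected and skipped.  When `proteins` is supplied, every
#' referenced id must exist in it.
#'
#' @param path Pair list path.
#' @param proteins Optional data frame from [read_fasta()] to validate ids
#'   against.
#' @param labelled Require a label column (default `TRUE`).
#' @return Data frame with columns `id_a`, `id_b` and, if present, integer
#'   `label`.
#' @export
read_pairs <- function(path, proteins = NULL, labelled = TRUE) {
  if (!file.exists(path)) stop("pair list not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("pair list is empty: ", path, call. = FALSE)

  sep <- if (grepl("\t", lines[[1L]], fixed = TRUE)) "\t" else ","
  fields <- strsplit(lines, sep, fixed = TRUE)
  fields <- lapply(fields, trimws)

  # optional header
  if (identical(tolower(fields[[1L]][1:2]), c("id_a", "id_b"))) {
    fields <- fields[-1L]
    lineno <- lineno[-1L]
    if (length(fields) == 0L) stop("pair list has a header but no rows: ",
                                   path, call. = FALSE)
  }

  ncols <- lengths(fields)
  want <- if (labelled) 3L else 2L
  bad <- which(ncols < want)
  if (length(bad) > 0L) {
    stop("line ", lineno[bad[1L]], " of ", path, " has ", ncols[bad[1L]],
         " column(s); expected at least ", want,
         " (id_a", if (labelled) ", id_b, label)" else ", id_b)",
         call. = FALSE)
  }
  id_a <- vapply(fields, `[`, "", 1L)
  id_b <- vapply(fields, `[`, "", 2L)
  out <- data.frame(id_a = id_a, id_b = id_b, stringsAsFactors = FALSE)

  if (any(ncols >= 3L) && (labelled || all(ncols >= 3L))) {
    raw <- vapply(fields, function(f) if (length(f) >= 3L) f[[3L]] else NA_character_, "")
    bad <- which(!raw %in% c("0", "1"))
    if (length(bad) > 0L) {
      stop("line ", lineno[bad[1L]], " of ", path,
           ": label must be 0 or 1, got ", sQuote(raw[bad[1L]]), call. = FALSE)
    }
    out$label <- as.integer(raw)
  }

  if (!is.null(proteins)) {
    unknown <- !(out$id_a %in% proteins$id) | !(out$id_b %in% proteins$id)
    if (any(unknown)) {
      i <- which(unknown)[1L]
      miss <- setdiff(c(out$id_a[i], out$id_b[i]), proteins$id)
      stop("line ", lineno[i], " of ", path,
           " references unknown protein id(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  out
}

#' Write a pair list as tab-separated text
#'
#' @param pairs Data frame with columns `id_a`, `id_b` and optionally
#'   `label`.
#' @param path Output path.
#' @export
write_pairs <- function(pairs, path) {
  cols <- intersect(c("id_a", "id_b", "label"), names(pairs))
  utils::write.table(pairs[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove short protein sequences
#'
#' Drops every protein shorter than `min_len` residues (the conventional
#' pre-filter removes sequences of fewer than 50 residues; length exactly
#' `min_len` is kept).
#'
#' @param proteins Data frame from [read_fasta()].
#' @param min_len Minimum length in residues (default 50).
#' @return List with `kept` (filtered data frame) and `removed` (character
#'   vector of removed ids).
#' @seealso [drop_pairs_of()] to drop pairs touching a removed protein.
#' @export
filter_short <- function(proteins, min_len = 50L) {
  stopifnot(min_len >= 1L)
  len <- nchar(proteins$sequence)
  keep <- len >= min_len
  list(kept = proteins[keep, , drop = FALSE],
       removed = proteins$id[!keep])
}

#' Drop pairs that reference removed proteins
#'
#' @param pairs Pair data frame.
#' @param removed Character vector of removed protein ids.
#' @return Filtered pair data frame.
#' @export
drop_pairs_of <- function(pairs, removed) {
  keep <- !(pairs$id_a %in% removed) & !(pairs$id_b %in% removed)
  pairs[keep, , drop = FALSE]
}

#' Write per-pair predictions as tab-separated text
#'
#' Columns: `id_a`, `id_b`, `predicted_label`, `score`, then one residual
#' column per class (`residual_<class>`).
#'
#' @param pairs Data frame with `id_a`, `id_b`.
#' @param predicted Factor of predicted labels.
#' @param scores Numeric decision scores (residual margin).
#' @param residuals Samples x classes residual matrix from
#'   `predict(..., type = "residuals")`.
#' @param path Output path.
#' @export
write_predictions <- function(pairs, predicted, scores, residuals, path) {
  res <- as.data.frame(residuals)
  names(res) <- paste0("residual_", colnames(residuals))
  df <- data.frame(id_a = pairs$id_a, id_b = pairs$id_b,
                   predicted_label = as.character(predicted),
                   score = scores, res, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
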