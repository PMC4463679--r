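# n-peptide composition features over reduced alphabets.

#' Dimension of the n-peptide feature space
#'
#' For an alphabet of `k` groups there are \eqn{k^n} distinct n-peptides, so
#' the composition vector of a single protein has dimension \eqn{k^n} (e.g.
#' 512 for the 8-group profile with n = 3).
#'
#' @param profile A [cluster_profile()].
#' @param n Peptide length (window size), a positive integer.
#' @return Integer, \eqn{k^n}.
#' @export
feature_dimension <- function(profile, n) {
  stopifnot(inherits(profile, "cluster_profile"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  as.integer(round(profile$k^n))
}

# Names of the k^n cells in row-major order over group indices,
# e.g. "g1g1", "g1g2", ..., for n = 2.  Cached: the same (k, n) grid is
# needed for every sequence in a data set.
.cell_name_cache <- new.env(parent = emptyenv())

npeptide_cell_names <- function(k, n) {
  key <- paste(k, n, sep = ".")
  if (!is.null(.cell_name_cache[[key]])) return(.cell_name_cache[[key]])
  # expand.grid varies its first factor fastest; row-major order needs the
  # last peptide position fastest, hence the reversal.
  idx <- as.matrix(expand.grid(rep(list(seq_len(k)), n),
                               KEEP.OUT.ATTRS = FALSE))[, rev(seq_len(n)),
                                                        drop = FALSE]
  nm <- apply(idx, 1L, function(g) paste0("g", g, collapse = ""))
  .cell_name_cache[[key]] <- nm
  nm
}

#' n-peptide composition of a protein sequence
#'
#' Rewrites `seq` over the reduced alphabet and counts every length-`n`
#' window, normalising by the number of windows \eqn{L' - n + 1} (where
#' \eqn{L'} is the reduced-sequence length), so the vector sums to 1.
#' Cells are ordered row-major over group indices: the window
#' \eqn{(g_1, \ldots, g_n)} occupies position
#' \eqn{\sum_j (g_j - 1) k^{n-j} + 1}.
#'
#' @inheritParams reduce_sequence
#' @param n Peptide length; 1 (composition), 2 (dipeptide) or 3 (tripeptide).
#' @return Named numeric vector of length \eqn{k^n} with attributes
#'   `profile` (profile name) and `n`.
#' @examples
#' npeptide_composition("GIV", raaa_profile("CP(5)"), n = 1)
#' @export
npeptide_composition <- function(seq, profile, n = 3,
                                 ambiguous = c("drop", "error")) {
  if (!n %in% 1:3) stop("`n` must be 1, 2 or 3", call. = FALSE)
  reduced <- reduce_sequence(seq, profile, ambiguous)
  k <- profile$k
  L <- length(reduced)
  if (L < n) {
    stop("sequence too short for n = ", n, " after ambiguity handling (",
         L, " usable residues): ", strtrim(seq, 30L), call. = FALSE)
  }
  n_windows <- L - n + 1L
  # row-major cell index of each window
  cell <- reduced[seq_len(n_windows)]
  if (n >= 2L) {
    for (j in 2:n) {
      cell <- (cell - 1L) * k + reduced[seq.int(j, j + n_windows - 1L)]
    }
  }
  counts <- tabulate(cell, nbins = k^n)
  out <- counts / n_windows
  names(out) <- npeptide_cell_names(k, n)
  structure(out, profile = profile$name, n = n)
}

#' Combine two composition vectors into one pair feature vector
#'
#' Protein pairs are encoded by ordered concatenation `[a; b]` (the common
#' convention in sequence-based interaction prediction), doubling the
#' per-protein dimension.  The symmetrised alternative `[a + b; |a - b|]`
#' is available via `combine = "symmetric"`.
#'
#' @param a,b Composition vectors from [npeptide_composition()], computed
#'   with the same profile and `n`.
#' @param combine `"concatenate"` (default) or `"symmetric"`.
#' @return Numeric vector of length `2 * length(a)`.
#' @export
pair_features <- function(a, b, combine = c("concatenate", "symmetric")) {
  combine <- match.arg(combine)
  if (!identical(attr(a, "profile"), attr(b, "profile")) ||
      !identical(attr(a, "n"), attr(b, "n")) ||
      length(a) != length(b)) {
    stop("`a` and `b` must come from the same profile and n", call. = FALSE)
  }
  if (combine == "concatenate") {
    out <- c(a, b)
    names(out) <- c(paste0("A_", names(a)), paste0("B_", names(b)))
  } else {
    out <- c(a + b, abs(a - b))
    names(out) <- c(paste0("S_", names(a)), paste0("D_", names(b)))
  }
  unname_attrs(out)
}

unname_attrs <- function(x) {
  attr(x, "profile") <- NULL
  attr(x, "n") <- NULL
  x
}

#' Feature matrix for a list of labelled protein pairs
#'
#' Computes the n-peptide composition of every referenced protein once and
#' assembles one feature row per pair.
#'
#' @param proteins Data frame with columns `id` and `sequence` (as returned
#'   by [read_fasta()]).
#' @param pairs Data frame with columns `id_a`, `id_b` and (optionally)
#'   `label` in `{0, 1}` (as returned by [read_pairs()]).
#' @param profile A [cluster_profile()], or a built-in profile name.
#' @param n Peptide length (1, 2 or 3).
#' @param combine Pair encoding, see [pair_features()].
#' @inheritParams reduce_sequence
#' @return An object of class `"pair_features"`: a list with `x` (numeric
#'   matrix, one row per pair), `label` (factor with levels `0`, `1`, or
#'   `NULL` when `pairs` carries no labels), `pairs` (the id columns),
#'   `profile_name`, `n` and `combine`.
#' @export
pair_feature_matrix <- function(proteins, pairs, profile, n = 3,
                                combine = c("concatenate", "symmetric"),
                                ambiguous = c("drop", "error")) {
  combine <- match.arg(combine)
  if (is.character(profile)) profile <- raaa_profile(profile)
  stopifnot(inherits(profile, "cluster_profile"))
  ids <- unique(c(pairs$id_a, pairs$id_b))
  missing <- setdiff(ids, proteins$id)
  if (length(missing) > 0L) {
    stop("pair list references protein id(s) absent from the sequence set: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) ", ..." else "", call. = FALSE)
  }
  seqs <- stats::setNames(proteins$sequence, proteins$id)
  comp <- lapply(seqs[ids], npeptide_composition, profile = profile, n = n,
                 ambiguous = ambiguous)
  rows <- mapply(function(a, b) pair_features(comp[[a]], comp[[b]], combine),
                 pairs$id_a, pairs$id_b, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  x <- do.call(rbind, rows)
  rownames(x) <- paste(pairs$id_a, pairs$id_b, sep = ":")
  label <- if ("label" %in% names(pairs)) factor(pairs$label, levels = c(0, 1)) else NULL
  structure(
    list(x = x, label = label,
         pairs = pairs[, c("id_a", "id_b"), drop = FALSE],
         profile_name = profile$name, n = n, combine = combine),
    class = "pair_features"
  )
}

#' @export
print.pair_features <- function(x, ...) {
  cat("Pair feature matrix: ", nrow(x$x), " pairs x ", ncol(x$x),
      " features (", x$profile_name, ", n = ", x$n, ", ", x$combine, ")\n",
      sep = "")
  if (!is.null(x$label)) {
    tab <- table(x$label)
    cat("  labels: ", paste(names(tab), tab, sep = " = ", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Write / read a pair feature table as delimited text
#'
#' The table has columns `id_a`, `id_b`, `label` (NA when unlabelled)
#' followed by one column per feature cell; a comment header records the
#' profile, n and pair encoding so the table round-trips.
#'
#' @param features A `"pair_features"` object.
#' @param path Output (input) file path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns a `"pair_features"` object.
#' @export
write_feature_table <- function(features, path) {
  stopifnot(inherits(features, "pair_features"))
  hdr <- sprintf("# wsrcppi features\tprofile=%s\tn=%d\tcombine=%s",
                 features$profile_name, features$n, features$combine)
  lab <- if (is.null(features$label)) NA else as.character(features$label)
  df <- data.frame(id_a = features$pairs$id_a, id_b = features$pairs$id_b,
                   label = lab, features$x,
                   check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path, call. = FALSE)
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "# wsrcppi features")) {
    stop("not a wsrcppi feature table (missing header): ", path, call. = FALSE)
  }
  meta <- strsplit(hdr, "\t", fixed = TRUE)[[1]][-1]
  kv <- strsplit(meta, "=", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  df <- utils::read.delim(path, skip = 1L, check.names = FALSE,
                          stringsAsFactors = FALSE)
  x <- as.matrix(df[, -(1:3), drop = FALSE])
  rownames(x) <- paste(df$id_a, df$id_b, sep = ":")
  label <- if (all(is.na(df$label))) NULL else factor(df$label, levels = c(0, 1))
  structure(
    list(x = x, label = label,
         pairs = df[, c("id_a", "id_b"), drop = FALSE],
         profile_name = unname(meta[["profile"]]),
         n = as.integer(meta[["n"]]),
         combine = unname(meta[["combine"]])),
    class = "pair_features"
  )
}
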