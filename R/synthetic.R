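# Synthetic labelled protein-pair benchmark.
#
# Two residue emission distributions D1 and D2 over the 20 standard amino
# acids are built at a prescribed total-variation distance ("separation").
# Interacting pairs draw both proteins i.i.d. from D1; non-interacting
# pairs draw protein A from D1 and protein B from D2, so the two classes
# differ in (reduced-alphabet) composition with difficulty controlled by
# the separation.  At separation 0 the classes are indistinguishable; at
# separation 1 the distributions have disjoint supports.

#' Class emission distributions at a given separation
#'
#' `D1 = (1 - s) U20 + s V1` and `D2 = (1 - s) U20 + s V2`, where `U20` is
#' uniform over the 20 residues and `V1`, `V2` are uniform over two disjoint
#' 10-residue halves.  Their total-variation distance is then exactly `s`.
#'
#' @param separation Total-variation distance in `[0, 1]`.
#' @return List of two named probability vectors `d1`, `d2` over the 20
#'   standard residues.
#' @export
emission_distributions <- function(separation) {
  if (!is.numeric(separation) || length(separation) != 1L ||
      separation < 0 || separation > 1) {
    stop("`separation` must be a number in [0, 1]", call. = FALSE)
  }
  res <- standard_residues()
  u20 <- rep(1 / 20, 20L)
  v1 <- rep(c(1 / 10, 0), each = 10L)
  v2 <- rep(c(0, 1 / 10), each = 10L)
  d1 <- (1 - separation) * u20 + separation * v1
  d2 <- (1 - separation) * u20 + separation * v2
  list(d1 = stats::setNames(d1, res), d2 = stats::setNames(d2, res))
}

random_protein <- function(len, dist) {
  paste(sample(names(dist), len, replace = TRUE, prob = dist), collapse = "")
}

#' Simulate a labelled protein-pair interaction data set
#'
#' Generates `2 * n_pairs` protein pairs (balanced classes) with i.i.d.
#' residue emission: both proteins of an interacting pair (`label = 1`)
#' from `d1`, and the two proteins of a non-interacting pair (`label = 0`)
#' from `d1` and `d2` respectively.  Sequence lengths are uniform over
#' `length_range`.  Output is byte-reproducible for a fixed seed.
#'
#' @param n_pairs Pairs per class (default 200).
#' @param separation Total-variation distance between the class emission
#'   distributions, in `[0, 1]` (see [emission_distributions()]).
#' @param length_range Integer range of sequence lengths (default
#'   `c(50, 150)`, respecting the usual 50-residue minimum).
#' @param seed Integer seed.
#' @return List of class `"ppi_sim"`: `proteins` (data frame `id`,
#'   `sequence`), `pairs` (data frame `id_a`, `id_b`, `label`), and the
#'   generating parameters.
#' @examples
#' sim <- simulate_ppi_pairs(n_pairs = 10, separation = 0.8, seed = 1)
#' head(sim$pairs)
#' @export
simulate_ppi_pairs <- function(n_pairs = 200L, separation = 0.8,
                               length_range = c(50L, 150L), seed = 1L) {
  stopifnot(n_pairs >= 1L, length(length_range) == 2L,
            length_range[1L] >= 1L, length_range[1L] <= length_range[2L])
  em <- emission_distributions(separation)
  if (all(em$d1 == 0) || all(em$d2 == 0)) {
    stop("degenerate emission distribution (zero mass everywhere)", call. = FALSE)
  }
  set.seed(seed)

  n_prot <- 4L * n_pairs  # two fresh proteins per pair
  lens <- sample(seq.int(length_range[1L], length_range[2L]), n_prot,
                 replace = TRUE)
  ids <- sprintf("SYN%05d", seq_len(n_prot))

  # proteins 1..2*n_pairs: positive pairs (both from d1)
  # proteins (2*n_pairs+1)..4*n_pairs: negative pairs (A from d1, B from d2)
  from_d2 <- rep(FALSE, n_prot)
  neg_idx <- 2L * n_pairs + seq_len(2L * n_pairs)
  from_d2[neg_idx[seq_along(neg_idx) %% 2L == 0L]] <- TRUE

  seqs <- vapply(seq_len(n_prot), function(i) {
    random_protein(lens[i], if (from_d2[i]) em$d2 else em$d1)
  }, character(1))

  proteins <- data.frame(id = ids, sequence = seqs, stringsAsFactors = FALSE)
  pos <- data.frame(id_a = ids[seq(1L, 2L * n_pairs, by = 2L)],
                    id_b = ids[seq(2L, 2L * n_pairs, by = 2L)],
                    label = 1L, stringsAsFactors = FALSE)
  neg <- data.frame(id_a = ids[neg_idx[seq_along(neg_idx) %% 2L == 1L]],
                    id_b = ids[neg_idx[seq_along(neg_idx) %% 2L == 0L]],
                    label = 0L, stringsAsFactors = FALSE)
  pairs <- rbind(pos, neg)

  structure(
    list(proteins = proteins, pairs = pairs, n_pairs = n_pairs,
         separation = separation, length_range = length_range, seed = seed),
    class = "ppi_sim"
  )
}

#' @export
print.ppi_sim <- function(x, ...) {
  cat("Synthetic PPI data set: ", nrow(x$pairs), " pairs (",
      sum(x$pairs$label == 1L), " interacting / ",
      sum(x$pairs$label == 0L), " non-interacting), ",
      nrow(x$proteins), " proteins\n", sep = "")
  cat("  separation = ", x$separation, ", lengths in [",
      x$length_range[1L], ", ", x$length_range[2L], "], seed = ", x$seed,
      "\n", sep = "")
  invisible(x)
}
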