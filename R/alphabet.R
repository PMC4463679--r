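# Reduced amino acid alphabets (cluster profiles).

#' The 20 standard amino acid one-letter codes
#'
#' Alphabetical vector of the canonical residue letters used throughout the
#' package.
#'
#' @return Character vector of length 20.
#' @export
standard_residues <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Ambiguity / non-standard codes that may occur in real FASTA files.
AMBIGUOUS_RESIDUES <- c("B", "Z", "X", "U", "O", "J", "*")

# Cluster profiles derived from the protein blocks structural alphabet.
# Each partitions the 20 standard residues into k groups; the dash-separated
# string fixes the group order.
BUILTIN_PROFILE_SPECS <- c(
  "CP(13)" = "G-IV-FYW-A-L-M-E-QRK-P-ND-HS-T-C",
  "CP(11)" = "G-IV-FYW-A-LM-EQRK-P-ND-HS-T-C",
  "CP(9)"  = "G-IV-FYW-ALM-EQRK-P-ND-HS-TC",
  "CP(8)"  = "G-IV-FYW-ALM-EQRK-P-ND-HSTC",
  "CP(5)"  = "G-IVFYW-ALMEQRK-P-NDHSTC"
)

#' Create a cluster profile (reduced amino acid alphabet)
#'
#' A cluster profile is an ordered partition of the 20 standard amino acids
#' into `k` groups.  Sequences are rewritten over group indices before
#' n-peptide counting, which shrinks the feature space from \eqn{20^n} to
#' \eqn{k^n}.
#'
#' @param spec Dash-separated group string of uppercase one-letter residue
#'   codes, e.g. `"G-IVFYW-ALMEQRK-P-NDHSTC"`.  The groups must be pairwise
#'   disjoint and cover all 20 standard residues; group order is the
#'   left-to-right order in the string.
#' @param name Short label for the profile (e.g. `"CP(5)"`).  Defaults to
#'   `"custom(k)"`.
#'
#' @return An object of class `"cluster_profile"`: a list with elements
#'   `name`, `groups` (character vector, one string per group), `k` (number
#'   of groups) and `map` (named integer vector mapping each residue to its
#'   1-based group index).
#' @seealso [raaa_profile()] for the built-in profiles,
#'   [reduce_sequence()] to apply a profile to a sequence.
#' @examples
#' cp5 <- cluster_profile("G-IVFYW-ALMEQRK-P-NDHSTC", "CP(5)")
#' cp5$k
#' cp5$map[["V"]]
#' @export
cluster_profile <- function(spec, name = NULL) {
  if (!is.character(spec) || length(spec) != 1L || !nzchar(spec)) {
    stop("`spec` must be a single non-empty dash-separated string", call. = FALSE)
  }
  groups <- strsplit(spec, "-", fixed = TRUE)[[1]]
  if (any(!nzchar(groups))) {
    stop("profile spec contains an empty group (check for doubled or trailing dashes): ",
         sQuote(spec), call. = FALSE)
  }
  letters20 <- standard_residues()
  residues <- strsplit(groups, "", fixed = TRUE)
  flat <- unlist(residues)

  bad <- setdiff(flat, letters20)
  if (length(bad) > 0L) {
    stop("non-standard residue code(s) in profile spec: ",
         paste(sort(unique(bad)), collapse = ", "), call. = FALSE)
  }
  dup <- unique(flat[duplicated(flat)])
  if (length(dup) > 0L) {
    stop("residue(s) assigned to more than one group: ",
         paste(sort(dup), collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(letters20, flat)
  if (length(missing) > 0L) {
    stop("profile spec is missing ", length(missing), " residue(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  k <- length(groups)
  map <- integer(20L)
  names(map) <- letters20
  for (i in seq_len(k)) map[residues[[i]]] <- i

  if (is.null(name)) name <- sprintf("custom(%d)", k)
  structure(
    list(name = name, groups = groups, k = k, map = map),
    class = "cluster_profile"
  )
}

#' Look up a built-in cluster profile
#'
#' Five profiles derived from the protein blocks structural alphabet are
#' shipped: `"CP(13)"`, `"CP(11)"`, `"CP(9)"`, `"CP(8)"` and `"CP(5)"`,
#' where the number is the group count `k`.  `"identity"` gives the trivial
#' 20-group alphabet (every residue its own group).
#'
#' @param name Profile label.
#' @return A [cluster_profile()] object.
#' @examples
#' raaa_profile("CP(8)")$groups
#' @export
raaa_profile <- function(name) {
  if (identical(name, "identity")) {
    return(cluster_profile(paste(standard_residues(), collapse = "-"), "identity"))
  }
  if (!name %in% names(BUILTIN_PROFILE_SPECS)) {
    stop("unknown profile ", sQuote(name), "; built-ins are: ",
         paste(names(BUILTIN_PROFILE_SPECS), collapse = ", "),
         ", identity", call. = FALSE)
  }
  cluster_profile(BUILTIN_PROFILE_SPECS[[name]], name)
}

#' List the built-in cluster profiles
#'
#' @return Named character vector of dash-separated group specs, keyed by
#'   profile label.
#' @export
raaa_profiles <- function() BUILTIN_PROFILE_SPECS

#' Read a cluster profile from a text file
#'
#' The file must contain a single non-empty line holding the dash-separated
#' group specification.
#'
#' @param path Path to the profile file.
#' @param name Optional label; defaults to the file name.
#' @return A [cluster_profile()] object.
#' @export
read_profile <- function(path, name = NULL) {
  if (!file.exists(path)) stop("profile file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) != 1L) {
    stop("profile file must contain exactly one spec line, found ",
         length(lines), ": ", path, call. = FALSE)
  }
  if (is.null(name)) name <- basename(path)
  cluster_profile(toupper(lines), name)
}

#' @export
format.cluster_profile <- function(x, ...) {
  paste0(x$name, ": ", paste(x$groups, collapse = "-"), " (k = ", x$k, ")")
}

#' @export
print.cluster_profile <- function(x, ...) {
  cat("Reduced amino acid alphabet\n")
  cat("  name:   ", x$name, "\n", sep = "")
  cat("  groups: ", paste(x$groups, collapse = "-"), "\n", sep = "")
  cat("  k:      ", x$k, "\n", sep = "")
  invisible(x)
}

#' @export
as.character.cluster_profile <- function(x, ...) {
  paste(x$groups, collapse = "-")
}

#' Rewrite a protein sequence over a reduced alphabet
#'
#' Maps each residue of `seq` to its 1-based group index under `profile`.
#' Input is uppercased first.  Ambiguity codes (B, Z, X, U, O, J and `*`)
#' are removed under the default `"drop"` policy; with `ambiguous = "error"`
#' they raise an error naming the first offending position.
#'
#' @param seq Single residue string.
#' @param profile A [cluster_profile()].
#' @param ambiguous Policy for non-standard residue codes: `"drop"` or
#'   `"error"`.
#' @return Integer vector of group indices in `1:k` (possibly shorter than
#'   `nchar(seq)` when ambiguity codes are dropped).
#' @examples
#' reduce_sequence("GIV", raaa_profile("CP(5)"))   # 1 2 2
#' @export
reduce_sequence <- function(seq, profile, ambiguous = c("drop", "error")) {
  ambiguous <- match.arg(ambiguous)
  stopifnot(inherits(profile, "cluster_profile"))
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    stop("`seq` must be a single non-empty residue string", call. = FALSE)
  }
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  known <- chars %in% names(profile$map)
  if (!all(known)) {
    bad_pos <- which(!known)
    bad <- chars[bad_pos]
    unexpected <- setdiff(bad, AMBIGUOUS_RESIDUES)
    if (length(unexpected) > 0L || ambiguous == "error") {
      i <- bad_pos[1L]
      stop("unmappable residue ", sQuote(chars[i]), " at position ", i,
           call. = FALSE)
    }
    chars <- chars[known]
  }
  unname(profile$map[chars])
}
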