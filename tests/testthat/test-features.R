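# n-peptide composition and pair feature assembly.

test_that("feature dimension is k^n", {
  expect_identical(feature_dimension(raaa_profile("CP(8)"), 3), 512L)
  expect_identical(feature_dimension(raaa_profile("CP(13)"), 2), 169L)
  for (nm in names(raaa_profiles())) {
    p <- raaa_profile(nm)
    expect_identical(feature_dimension(p, 1), p$k)
  }
  expect_error(feature_dimension(raaa_profile("CP(5)"), 0), "positive integer")
})

test_that("single-residue composition matches hand counts", {
  v <- npeptide_composition("GIV", raaa_profile("CP(5)"), n = 1)
  expect_equal(as.vector(v), c(1 / 3, 2 / 3, 0, 0, 0))
  expect_identical(names(v), c("g1", "g2", "g3", "g4", "g5"))
})

test_that("dipeptide cells are placed row-major over group indices", {
  v <- npeptide_composition("GGI", raaa_profile("CP(13)"), n = 2)
  expect_length(v, 169L)
  # GG -> groups (1,1) -> cell 1; GI -> (1,2) -> cell 2; two windows
  expect_equal(unname(v[1]), 0.5)
  expect_equal(unname(v[2]), 0.5)
  expect_equal(sum(v), 1)
  expect_identical(sum(v > 0), 2L)
  # GI, GV, IG, VG all land in group-pair cells drawn from groups {1, 2}
  idx_gi <- which(names(v) == "g1g2")
  expect_identical(unname(idx_gi), 2L)
})

test_that("homopolymer composition concentrates in one cell", {
  for (nm in c("CP(5)", "CP(13)")) {
    v <- npeptide_composition("AAAA", raaa_profile(nm), n = 3)
    expect_identical(sum(v > 0), 1L)
    expect_equal(max(v), 1)
  }
})

test_that("composition sums to one and is order-free only for n = 1", {
  cp9 <- raaa_profile("CP(9)")
  set.seed(11)
  for (i in 1:40) {
    n <- sample(1:3, 1)
    s <- rand_seq(sample(n:60, 1) + 3L)
    v <- npeptide_composition(s, cp9, n = n)
    expect_equal(sum(v), 1, tolerance = 1e-12)
    expect_true(all(v >= 0))
    # permuting residues leaves n = 1 composition unchanged
    perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(npeptide_composition(perm, cp9, n = 1),
                 npeptide_composition(s, cp9, n = 1))
    # concatenating a sequence with itself leaves n = 1 unchanged
    expect_equal(npeptide_composition(paste0(s, s), cp9, n = 1),
                 npeptide_composition(s, cp9, n = 1))
  }
  # order sensitivity for n >= 2: same residue multiset, different vectors
  expect_false(isTRUE(all.equal(
    npeptide_composition("GGIV", cp9, n = 2),
    npeptide_composition("GIGV", cp9, n = 2))))
})

test_that("sequences shorter than n are rejected", {
  expect_error(npeptide_composition("GI", raaa_profile("CP(5)"), n = 3),
               "too short")
  # ambiguity dropping can push a sequence under the limit
  expect_error(npeptide_composition("GX", raaa_profile("CP(5)"), n = 2),
               "too short")
})

test_that("pair features concatenate two composition vectors", {
  cp5 <- raaa_profile("CP(5)")
  a <- npeptide_composition("GIVGIV", cp5, n = 1)
  b <- npeptide_composition("PPNDHH", cp5, n = 1)
  f <- pair_features(a, b)
  expect_length(f, 10L)
  expect_equal(sum(f[1:5]), 1)
  expect_equal(sum(f[6:10]), 1)
  expect_equal(unname(f), unname(c(a, b)))
  # self-pair has identical halves
  ff <- pair_features(a, a)
  expect_equal(ff[1:5], ff[6:10], ignore_attr = TRUE)
  # symmetrised encoding
  fs <- pair_features(a, b, combine = "symmetric")
  expect_equal(unname(fs), unname(c(a + b, abs(a - b))))
  # mismatched profile or n rejected
  b2 <- npeptide_composition("PPNDHH", cp5, n = 2)
  expect_error(pair_features(a, b2), "same profile and n")
  b3 <- npeptide_composition("PPNDHH", raaa_profile("CP(8)"), n = 1)
  expect_error(pair_features(a, b3), "same profile and n")
})

test_that("pair feature matrices assemble, validate ids and round-trip", {
  proteins <- data.frame(
    id = c("p1", "p2", "p3"),
    sequence = c("GIVGIVPPND", "ALMEQRKHST", "CCNDHSTGIV"),
    stringsAsFactors = FALSE)
  pairs <- data.frame(id_a = c("p1", "p2", "p3"),
                      id_b = c("p2", "p3", "p1"),
                      label = c(1L, 0L, 1L), stringsAsFactors = FALSE)
  feats <- pair_feature_matrix(proteins, pairs, "CP(5)", n = 1)
  expect_identical(dim(feats$x), c(3L, 10L))
  expect_identical(levels(feats$label), c("0", "1"))
  # per-protein halves each sum to 1
  expect_equal(unname(rowSums(feats$x[, 1:5])), rep(1, 3))
  expect_equal(unname(rowSums(feats$x[, 6:10])), rep(1, 3))

  bad <- rbind(pairs, data.frame(id_a = "p1", id_b = "p9", label = 0L))
  expect_error(pair_feature_matrix(proteins, bad, "CP(5)", n = 1),
               "absent from the sequence set: p9")

  path <- tempfile(fileext = ".tsv")
  write_feature_table(feats, path)
  back <- read_feature_table(path)
  expect_equal(back$x, feats$x, tolerance = 1e-12)
  expect_identical(back$label, feats$label)
  expect_identical(back$profile_name, "CP(5)")
  expect_identical(back$n, 1L)
  expect_identical(back$combine, "concatenate")
})
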