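# Sparse coding and the (weighted) sparse representation classifier.

test_that("gaussian weights behave like a similarity kernel", {
  set.seed(3)
  x <- rnorm(12); y <- rnorm(12)
  expect_equal(gaussian_weight(x, x, 50), 1)
  expect_equal(gaussian_weight(x, y, 50), gaussian_weight(y, x, 50))
  w <- gaussian_weight(x, y, 50)
  expect_true(w > 0 && w <= 1)
  # direct arithmetic at the working width sigma = 50: for small distances
  # w ~= 1 - ||x - y||^2 / 5000 up to the second-order term
  d2 <- sum((x - y)^2)
  expect_equal(w, exp(-d2 / 5000))
  expect_equal(w, 1 - d2 / 5000, tolerance = (d2 / 5000)^2)
  expect_error(gaussian_weight(x, y, 0), "positive")
  expect_error(gaussian_weight(x, y[-1], 50), "equal length")
})

test_that("basis pursuit denoising handles the degenerate cases exactly", {
  set.seed(4)
  X <- matrix(rnorm(24), 4)
  # zero (and sub-tolerance) queries code to zero
  s <- solve_bpdn(X, rep(0, 4), 0.05)
  expect_identical(s$alpha, rep(0, 6))
  s <- solve_bpdn(X, rep(1e-4, 4), 0.05)
  expect_identical(s$alpha, rep(0, 6))
  expect_equal(s$l1, 0)
})

test_that("a query equal to an orthonormal atom recovers that atom", {
  set.seed(5)
  Q <- qr.Q(qr(matrix(rnorm(64), 8)))   # 8 orthonormal columns
  eps <- 0.05
  s <- solve_bpdn(Q, Q[, 3], eps)
  # orthonormal case has the closed-form solution (1 - eps) e_j
  expect_equal(s$alpha, (1 - eps) * replace(rep(0, 8), 3, 1), tolerance = 1e-4)
  expect_equal(s$residual, eps, tolerance = 1e-3)
  expect_equal(s$l1, 1 - eps, tolerance = 1e-4)
})

test_that("solver agrees with an independent convex-program oracle", {
  set.seed(6)
  instances <- lapply(1:5, function(i) {
    d <- 4L; n <- 6L
    X <- matrix(rnorm(d * n), d)
    X <- sweep(X, 2, sqrt(colSums(X^2)), "/")
    a0 <- replace(rep(0, n), sample(n, 2), rnorm(2))
    e <- rnorm(d); eps <- 0.05
    list(X = X, y = as.numeric(X %*% a0 + 0.5 * eps * e / sqrt(sum(e^2))),
         eps = eps)
  })
  oracle <- bpdn_oracle(instances)
  for (i in seq_along(instances)) {
    s <- solve_bpdn(instances[[i]]$X, instances[[i]]$y, instances[[i]]$eps)
    expect_true(s$residual <= instances[[i]]$eps * (1 + 1e-6))
    expect_equal(s$l1, oracle$l1[i], tolerance = 1e-4)
  }
})

test_that("an unreachable query raises an explicit solver failure", {
  X <- cbind(c(1, 0, 0), c(0, 1, 0))
  expect_error(solve_bpdn(X, c(0, 0, 1), 0.5), class = "wsrc_solver_error")
})

test_that("per-class residuals match direct matrix arithmetic", {
  set.seed(8)
  x <- matrix(rnorm(60), 12)   # 12 samples x 5 features
  y3 <- factor(rep(c("a", "b", "c"), each = 4))
  fit <- wsrc(x, y3, sigma = 5, epsilon = 0.05)
  q <- rnorm(5)
  code <- predict(fit, q, type = "code")[[1]]
  G <- predict(fit, q, type = "residuals")
  D <- fit$dictionary
  Xw <- D * rep(code$weights, each = nrow(D))
  for (k in 1:3) {
    cols <- which(fit$labels == levels(y3)[k])
    g_direct <- sqrt(sum((q - Xw[, cols] %*% code$alpha[cols])^2))
    expect_equal(unname(G[1, k]), g_direct, tolerance = 1e-10)
  }
  expect_identical(code$predicted, levels(y3)[which.min(G[1, ])])
})

test_that("a sub-tolerance query yields equal residuals and the first class", {
  set.seed(9)
  x <- matrix(rnorm(40), 8)
  fit <- wsrc(x, rep(c("a", "b"), each = 4), epsilon = 0.05)
  q <- rep(1e-4, 5)
  G <- predict(fit, q, type = "residuals")
  expect_equal(unname(G[1, 1]), unname(G[1, 2]))
  expect_equal(unname(G[1, 1]), sqrt(sum(q^2)))
  expect_identical(as.character(predict(fit, q)), "a")  # tie -> lowest index
})

test_that("training samples are memorised", {
  set.seed(10)
  x <- rbind(matrix(rnorm(50, 0), 10), matrix(rnorm(50, 3), 10))
  y <- rep(c("neg", "pos"), each = 10)
  fit <- wsrc(x, y, sigma = 50, epsilon = 0.05)
  pred <- predict(fit, x)
  expect_identical(as.character(pred), y)
})

test_that("WSRC with a huge kernel width reproduces SRC exactly", {
  set.seed(12)
  xtr <- rbind(matrix(rnorm(120, 0), 20), matrix(rnorm(120, 1.5), 20))
  ytr <- rep(c("n", "p"), each = 20)
  xte <- rbind(matrix(rnorm(60, 0), 10), matrix(rnorm(60, 1.5), 10))
  src <- wsrc(xtr, ytr, weighted = FALSE)
  wsrc_wide <- wsrc(xtr, ytr, sigma = 1e9, weighted = TRUE)
  expect_identical(predict(src, xte), predict(wsrc_wide, xte))
  expect_equal(predict(src, xte, type = "score"),
               predict(wsrc_wide, xte, type = "score"), tolerance = 1e-6)
})

test_that("decisions are invariant to scaling query and tolerance together", {
  set.seed(13)
  xtr <- rbind(matrix(rnorm(80, 0), 10), matrix(rnorm(80, 2), 10))
  ytr <- rep(c("n", "p"), each = 10)
  q <- rnorm(8) + 1
  for (scale in c(0.5, 4)) {
    m1 <- wsrc(xtr, ytr, weighted = FALSE, epsilon = 0.05)
    m2 <- wsrc(xtr, ytr, weighted = FALSE, epsilon = 0.05 * scale)
    expect_identical(predict(m1, q), predict(m2, q * scale))
  }
})

test_that("decisions are invariant to permuting the training samples", {
  set.seed(14)
  xtr <- rbind(matrix(rnorm(80, 0), 10), matrix(rnorm(80, 2), 10))
  ytr <- rep(c("n", "p"), each = 10)
  xte <- matrix(rnorm(40, 1), 5)
  perm <- sample(20)
  f1 <- wsrc(xtr, ytr)
  f2 <- wsrc(xtr[perm, ], ytr[perm])
  expect_identical(predict(f1, xte), predict(f2, xte))
})

test_that("two well-separated Gaussian clusters are classified accurately", {
  # 8 dimensions, class means 5 noise-sd apart, 40 training / 40 test
  set.seed(15)
  mu <- 5 / sqrt(8)
  make <- function(n) rbind(matrix(rnorm(8 * n, 0), n),
                            matrix(rnorm(8 * n, mu), n))
  xtr <- make(20); xte <- make(20)
  y <- rep(c("n", "p"), each = 20)
  fit <- wsrc(xtr, y, sigma = 50, epsilon = 0.05)
  acc <- mean(predict(fit, xte) == y)
  expect_gte(acc, 0.95)
})

test_that("total weight underflow falls back to unweighted coding", {
  set.seed(16)
  xtr <- matrix(rnorm(60), 10)
  ytr <- rep(c("a", "b"), each = 5)
  narrow <- wsrc(xtr, ytr, sigma = 1e-3)
  src <- wsrc(xtr, ytr, weighted = FALSE)
  q <- rnorm(6) + 5
  expect_warning(g_w <- predict(narrow, q, type = "residuals"), "underflow")
  g_u <- predict(src, q, type = "residuals")
  expect_equal(g_w, g_u)
})

test_that("models archive and restore losslessly", {
  set.seed(17)
  x <- rbind(matrix(rnorm(40, 0), 8), matrix(rnorm(40, 2), 8))
  fit <- wsrc(x, rep(c("n", "p"), each = 8))
  path <- tempfile(fileext = ".rds")
  save_wsrc(fit, path)
  back <- load_wsrc(path)
  q <- matrix(rnorm(10, 1), 2)
  expect_identical(predict(fit, q), predict(back, q))
  expect_equal(back$dictionary, fit$dictionary)
  saveRDS(list(a = 1), path)
  expect_error(load_wsrc(path), "not a wsrcppi model")
})

test_that("fit-time validation rejects broken inputs", {
  x <- matrix(rnorm(20), 5)
  expect_error(wsrc(x, rep("a", 5)), "two classes")
  expect_error(wsrc(x, c("a", "a", "b", "b")), "length")
  expect_error(wsrc(rbind(x, 0), rep(c("a", "b"), 3)), "zero feature norm")
  fit <- wsrc(x, c("a", "a", "a", "b", "b"))
  expect_error(predict(fit, rnorm(3)), "does not match the dictionary")
  expect_error(predict(fit, matrix(rnorm(8), 2), type = "score"), NA)
})
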