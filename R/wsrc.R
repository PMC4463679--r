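# Weighted sparse representation classification.
#
# A query vector y is represented as a sparse linear combination of training
# columns by basis pursuit denoising,
#     min ||alpha||_1  s.t.  ||y - X alpha||_2 <= epsilon,
# and assigned the class whose columns alone reconstruct it with the
# smallest residual.  In the weighted variant each training column is scaled
# by its Gaussian-kernel similarity to the query before coding, so nearby
# training samples are cheaper to use and local structure dominates.

#' Gaussian kernel similarity between two feature vectors
#'
#' \eqn{w(x, y) = \exp(-\|x - y\|^2 / 2\sigma^2)}, a similarity in (0, 1]
#' used to weight training columns by their proximity to the query.
#'
#' @param x,y Numeric vectors of equal length.
#' @param sigma Kernel width, > 0.
#' @return A scalar in (0, 1].
#' @export
gaussian_weight <- function(x, y, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("`sigma` must be a positive number", call. = FALSE)
  }
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  exp(-sum((x - y)^2) / (2 * sigma^2))
}

solver_error <- function(msg) {
  stop(structure(class = c("wsrc_solver_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Basis pursuit denoising
#'
#' Solves \eqn{\min \|\alpha\|_1} subject to
#' \eqn{\|y - X\alpha\|_2 \le \epsilon}.  The constrained program is solved
#' through its penalised (lasso) form: the lasso path is computed with
#' \pkg{glmnet}, the penalty interval bracketing the target residual is
#' refined, and the solution on the (piecewise-linear) path with residual
#' norm exactly \eqn{\epsilon} is obtained by interpolation between the
#' bracketing path points.
#'
#' @param X Dictionary matrix (features x atoms).  Columns need not be
#'   unit-norm here; the classifier normalises before calling.
#' @param y Query vector, length `nrow(X)`.
#' @param epsilon Residual tolerance, > 0.
#' @param refine Number of bracket-refinement sweeps (each with 30
#'   logarithmically spaced penalties).
#' @return A list with `alpha` (coefficients, length `ncol(X)`), `residual`
#'   (attained \eqn{\|y - X\alpha\|_2}), and `l1` (\eqn{\|\alpha\|_1}).
#'   If the constraint cannot be satisfied (`y` further than `epsilon` from
#'   the column span) an error of class `"wsrc_solver_error"` is raised —
#'   never a silent zero vector.
#' @export
solve_bpdn <- function(X, y, epsilon = 0.05, refine = 2L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("`y` must have length nrow(X)", call. = FALSE)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0) {
    stop("`epsilon` must be a positive number", call. = FALSE)
  }
  n <- ncol(X)
  ynorm <- sqrt(sum(y^2))
  if (ynorm <= epsilon) {
    return(list(alpha = numeric(n), residual = ynorm, l1 = 0))
  }
  if (n == 1L) return(bpdn_single_atom(X, y, epsilon))

  # infeasible when y is further than epsilon from span(X)
  rmin <- sqrt(sum(qr.resid(qr(X), y)^2))
  if (rmin > epsilon * (1 + 1e-8) + 1e-12) {
    solver_error(sprintf(
      "constraint infeasible: minimum attainable residual %.3g > epsilon = %.3g (increase epsilon)",
      rmin, epsilon))
  }

  d <- nrow(X)
  lmax <- max(abs(crossprod(X, y))) / d   # glmnet's zero-coefficient penalty
  resid_norms <- function(B) {
    R <- y - X %*% B
    sqrt(colSums(R^2))
  }
  path <- function(lams) {
    fit <- glmnet::glmnet(X, y, family = "gaussian", alpha = 1,
                          lambda = lams, intercept = FALSE,
                          standardize = FALSE, thresh = 1e-14, maxit = 1e7)
    B <- as.matrix(fit$beta)
    list(lambda = fit$lambda, B = B, rn = resid_norms(B))
  }

  # coarse sweep, one decade at a time, stopping as soon as the residual
  # drops below epsilon (tiny penalties are both wasted work and badly
  # conditioned for near-duplicate columns)
  p <- NULL
  for (dec in 1:16) {
    lams <- lmax * 10^seq(-(dec - 1L), -dec, length.out = 11L)
    q <- path(lams)
    p <- if (is.null(p)) q else {
      list(lambda = c(p$lambda, q$lambda), B = cbind(p$B, q$B),
           rn = c(p$rn, q$rn))
    }
    if (min(q$rn) <= epsilon) break
  }
  if (min(p$rn) > epsilon) {
    solver_error(sprintf(
      "penalty sweep did not reach the residual tolerance (best %.3g > epsilon = %.3g)",
      min(p$rn), epsilon))
  }
  j <- which(p$rn <= epsilon)[1L]
  if (j == 1L) {
    a <- p$B[, 1L]
    return(list(alpha = as.numeric(a), residual = p$rn[1L], l1 = sum(abs(a))))
  }

  for (r in seq_len(refine)) {
    lams <- exp(seq(log(p$lambda[j - 1L]), log(p$lambda[j]), length.out = 30L))
    p <- path(lams)
    j <- which(p$rn <= epsilon)[1L]
    if (is.na(j)) {  # numerical wobble: take the closest point
      j <- which.min(p$rn)
      break
    }
    if (j == 1L) break
  }

  a_feas <- p$B[, j]
  if (j == 1L || p$rn[j] > epsilon) {
    a <- a_feas
    return(list(alpha = as.numeric(a), residual = p$rn[j], l1 = sum(abs(a))))
  }
  # The lasso path is piecewise linear in the coefficients, so between two
  # nearby path points the solution with residual exactly epsilon is the
  # convex combination solving a scalar quadratic.
  a_inf <- p$B[, j - 1L]
  ra <- y - X %*% a_inf
  rb <- y - X %*% a_feas
  dd <- rb - ra
  aa <- sum(dd^2)
  bb <- 2 * sum(ra * dd)
  cc <- sum(ra^2) - epsilon^2
  t <- if (aa < 1e-30) 1 else {
    disc <- bb^2 - 4 * aa * cc
    if (disc < 0) 1 else min(1, max(0, (-bb + sqrt(disc)) / (2 * aa)))
  }
  a <- (1 - t) * a_inf + t * a_feas
  rn <- sqrt(sum((y - X %*% a)^2))
  if (rn > epsilon * (1 + 1e-6)) {  # interpolation overshot: keep feasible end
    a <- a_feas
    rn <- p$rn[j]
  }
  list(alpha = as.numeric(a), residual = rn, l1 = sum(abs(a)))
}

# Closed form for a one-column dictionary: the smaller-|alpha| root of
# ||y - x a||^2 = epsilon^2.
bpdn_single_atom <- function(X, y, epsilon) {
  x <- as.numeric(X)
  xx <- sum(x^2)
  xy <- sum(x * y)
  disc <- xy^2 - xx * (sum(y^2) - epsilon^2)
  if (xx < 1e-30 || disc < 0) {
    solver_error("constraint infeasible for single-atom dictionary (increase epsilon)")
  }
  roots <- (xy + c(-1, 1) * sqrt(disc)) / xx
  a <- roots[which.min(abs(roots))]
  list(alpha = a, residual = sqrt(max(0, sum((y - x * a)^2))),
       l1 = abs(a))
}

#' Fit a (weighted) sparse representation classifier
#'
#' Stores the training samples as a dictionary with unit-norm columns
#' together with the classifier parameters.  All computation happens at
#' prediction time: for each query the (optionally Gaussian-weighted)
#' dictionary is sparse-coded by basis pursuit denoising and the query is
#' assigned to the class with the smallest class-restricted reconstruction
#' residual (ties broken towards the lowest class index).
#'
#' @param x Numeric matrix of training samples, one row per sample, or a
#'   `"pair_features"` object from [pair_feature_matrix()].
#' @param y Class labels (factor or coercible); ignored when `x` is a
#'   labelled `"pair_features"` object.
#' @param sigma Gaussian kernel width used to weight training columns by
#'   similarity to the query (default 50).
#' @param epsilon Residual tolerance of the sparse coding program
#'   (default 0.05).
#' @param weighted `TRUE` for the weighted classifier (WSRC); `FALSE` for
#'   plain sparse representation classification (SRC).
#' @param ... Passed between methods.
#' @return An object of class `"wsrc"`: list with `dictionary` (features x
#'   samples, unit-norm columns), `labels` (factor), `levels`, `sigma`,
#'   `epsilon`, `weighted`, optional `feature_meta` and the matched `call`.
#' @seealso [predict.wsrc()], [cross_validate()]
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40, 0), 10), matrix(rnorm(40, 3), 10))
#' fit <- wsrc(x, rep(c("a", "b"), each = 10), sigma = 50, epsilon = 0.05)
#' predict(fit, x[c(1, 15), ])
#' @export
wsrc <- function(x, ...) UseMethod("wsrc")

#' @rdname wsrc
#' @export
wsrc.pair_features <- function(x, y = NULL, ...) {
  if (is.null(y)) y <- x$label
  if (is.null(y)) stop("`x` carries no labels; supply `y`", call. = FALSE)
  fit <- wsrc.default(x$x, y, ...)
  fit$feature_meta <- list(profile_name = x$profile_name, n = x$n,
                           combine = x$combine)
  fit$call <- match.call()
  fit
}

#' @rdname wsrc
#' @export
wsrc.default <- function(x, y, sigma = 50, epsilon = 0.05, weighted = TRUE,
                         ...) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nrow(x) != length(y)) stop("length(y) must equal nrow(x)", call. = FALSE)
  if (nlevels(y) < 2L) stop("training data must contain at least two classes",
                            call. = FALSE)
  if (!is.numeric(sigma) || sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  if (!is.numeric(epsilon) || epsilon <= 0) stop("`epsilon` must be > 0", call. = FALSE)

  D <- t(x)                      # dictionary: features x samples
  norms <- sqrt(colSums(D^2))
  if (any(norms < 1e-12)) {
    stop("training sample(s) with zero feature norm: row(s) ",
         paste(utils::head(which(norms < 1e-12), 5L), collapse = ", "),
         call. = FALSE)
  }
  D <- sweep(D, 2L, norms, "/")  # unit l2-norm columns

  structure(
    list(dictionary = D, labels = y, levels = levels(y),
         sigma = sigma, epsilon = epsilon, weighted = weighted,
         feature_meta = NULL, call = match.call()),
    class = "wsrc"
  )
}

#' Predict method for sparse representation classifiers
#'
#' For each query row: (optionally) weight the unit-norm dictionary columns
#' by their Gaussian similarity to the query, sparse-code the query by basis
#' pursuit denoising, compute per-class reconstruction residuals
#' \eqn{g_k = \|y - X' \delta_k(\alpha)\|_2} (where \eqn{\delta_k} keeps
#' only class-k coefficients), and assign the class minimising \eqn{g_k}.
#'
#' The decision score for binary problems is the residual margin
#' `g(negative) - g(positive)` (positive class = last factor level): larger
#' means more confidently positive, and the sign reproduces the class
#' decision.
#'
#' @param object A fitted [wsrc()] model.
#' @param newx Query matrix (one row per sample), a single vector, or a
#'   `"pair_features"` object.
#' @param type `"class"` (factor of decisions), `"score"` (binary residual
#'   margin), `"residuals"` (samples x classes matrix of \eqn{g_k}), or
#'   `"code"` (list of full sparse-coding results per query).
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.wsrc <- function(object, newx,
                         type = c("class", "score", "residuals", "code"),
                         ...) {
  type <- match.arg(type)
  if (inherits(newx, "pair_features")) {
    fm <- object$feature_meta
    if (!is.null(fm) && (!identical(fm$profile_name, newx$profile_name) ||
                         !identical(fm$n, newx$n) ||
                         !identical(fm$combine, newx$combine))) {
      stop(sprintf(
        "feature mismatch: model expects profile %s, n = %d, %s encoding; got profile %s, n = %d, %s",
        fm$profile_name, fm$n, fm$combine,
        newx$profile_name, newx$n, newx$combine), call. = FALSE)
    }
    newx <- newx$x
  }
  if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1L)
  newx <- as.matrix(newx)
  D <- object$dictionary
  if (ncol(newx) != nrow(D)) {
    stop("query dimension ", ncol(newx), " does not match the dictionary (",
         nrow(D), " features)", call. = FALSE)
  }
  K <- length(object$levels)
  class_cols <- lapply(object$levels, function(l) which(object$labels == l))

  codes <- vector("list", nrow(newx))
  G <- matrix(NA_real_, nrow(newx), K,
              dimnames = list(rownames(newx), object$levels))
  for (i in seq_len(nrow(newx))) {
    yq <- newx[i, ]
    if (object$weighted) {
      dist2 <- colSums((D - yq)^2)
      w <- exp(-dist2 / (2 * object$sigma^2))
      if (max(w) < 1e-12) {
        warning("all Gaussian weights underflow (query far from training set); ",
                "falling back to unweighted coding for this query")
        w <- rep(1, ncol(D))
      }
    } else {
      w <- rep(1, ncol(D))
    }
    Xw <- D * rep(w, each = nrow(D))
    sol <- solve_bpdn(Xw, yq, object$epsilon)
    g <- vapply(class_cols, function(cols) {
      sqrt(sum((yq - Xw[, cols, drop = FALSE] %*% sol$alpha[cols])^2))
    }, numeric(1))
    G[i, ] <- g
    codes[[i]] <- list(alpha = sol$alpha, weights = w, residuals = g,
                       predicted = object$levels[which.min(g)])
  }

  cls <- factor(object$levels[apply(G, 1L, which.min)], levels = object$levels)
  switch(type,
    class = cls,
    residuals = G,
    score = {
      if (K != 2L) stop("`type = \"score\"` requires a binary classifier",
                        call. = FALSE)
      unname(G[, 1L] - G[, 2L])   # g(negative) - g(positive)
    },
    code = codes
  )
}

#' @export
print.wsrc <- function(x, ...) {
  cat(if (x$weighted) "Weighted sparse" else "Sparse",
      "representation classifier\n")
  cat("  dictionary: ", nrow(x$dictionary), " features x ",
      ncol(x$dictionary), " training samples\n", sep = "")
  tab <- table(x$labels)
  cat("  classes:    ", paste(names(tab), tab, sep = " = ", collapse = ", "),
      "\n", sep = "")
  cat("  sigma = ", format(x$sigma), ", epsilon = ", format(x$epsilon),
      "\n", sep = "")
  if (!is.null(x$feature_meta)) {
    cat("  features:   ", x$feature_meta$profile_name, ", n = ",
        x$feature_meta$n, ", ", x$feature_meta$combine, "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.wsrc <- function(object, ...) {
  structure(list(model = object), class = "summary.wsrc")
}

#' @export
print.summary.wsrc <- function(x, ...) {
  print(x$model)
  D <- x$model$dictionary
  cat("  column norms: all 1 (unit l2 normalisation at fit time)\n")
  cat("  decision:     argmin over per-class reconstruction residuals;\n")
  cat("                ties resolved towards the lowest class index\n")
  invisible(x)
}

#' Save / load a fitted classifier
#'
#' The archive stores the dictionary, labels, parameters and a format
#' version tag.
#'
#' @param object A `"wsrc"` model.
#' @param path File path.
#' @return `save_wsrc` returns `path` invisibly; `load_wsrc` the model.
#' @export
save_wsrc <- function(object, path) {
  stopifnot(inherits(object, "wsrc"))
  payload <- unclass(object)
  payload$call <- NULL
  saveRDS(list(format = "wsrcppi-model", version = 1L, model = payload), path)
  invisible(path)
}

#' @rdname save_wsrc
#' @export
load_wsrc <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "wsrcppi-model")) {
    stop("not a wsrcppi model archive: ", path, call. = FALSE)
  }
  if (obj$version > 1L) {
    stop("model archive version ", obj$version, " is newer than this package supports",
         call. = FALSE)
  }
  m <- obj$model
  m$call <- NULL
  structure(m, class = "wsrc")
}
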