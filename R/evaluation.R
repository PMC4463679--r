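# Evaluation criteria and cross-validation.

#' Confusion counts for a binary classifier
#'
#' @param truth True labels.
#' @param predicted Predicted labels.
#' @param positive Label counted as the positive class; default is the last
#'   factor level of `truth`.
#' @return Object of class `"confusion_counts"`: list with integer `TP`,
#'   `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, predicted, positive = NULL) {
  truth <- as.factor(truth)
  if (is.null(positive)) positive <- utils::tail(levels(truth), 1L)
  t_pos <- truth == positive
  p_pos <- as.character(predicted) == as.character(positive)
  if (length(t_pos) != length(p_pos)) {
    stop("`truth` and `predicted` must have equal length", call. = FALSE)
  }
  structure(
    list(TP = sum(t_pos & p_pos), TN = sum(!t_pos & !p_pos),
         FP = sum(!t_pos & p_pos), FN = sum(t_pos & !p_pos),
         positive = as.character(positive)),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("Confusion counts (positive = ", x$positive, "): TP = ", x$TP,
      ", TN = ", x$TN, ", FP = ", x$FP, ", FN = ", x$FN, "\n", sep = "")
  invisible(x)
}

#' Accuracy, sensitivity, precision and Matthews correlation coefficient
#'
#' All reported as percentages:
#' \deqn{ACC = (TP+TN)/(TP+FP+TN+FN)}
#' \deqn{SN = TP/(TP+FN)}
#' \deqn{PE = TP/(TP+FP)}
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) /
#'   \sqrt{(TP+FN)(TN+FP)(TP+FP)(TN+FN)}}
#' A metric whose denominator vanishes is reported as `NA` (undefined), not
#' silently as zero; the reason is attached as attribute `"undefined"`.
#'
#' @param counts A [confusion_counts()] object, or a list with elements
#'   `TP`, `TN`, `FP`, `FN`.
#' @return Named numeric vector `c(ACC, SN, PE, MCC)` in percent.
#' @export
classification_metrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  stopifnot(all(c(TP, TN, FP, FN) >= 0))
  total <- TP + TN + FP + FN
  undefined <- character(0)

  acc <- if (total > 0) 100 * (TP + TN) / total else {
    undefined <- c(undefined, "ACC: no samples"); NA_real_
  }
  sn <- if (TP + FN > 0) 100 * TP / (TP + FN) else {
    undefined <- c(undefined, "SN: no positive samples (TP + FN = 0)"); NA_real_
  }
  pe <- if (TP + FP > 0) 100 * TP / (TP + FP) else {
    undefined <- c(undefined, "PE: no positive predictions (TP + FP = 0)"); NA_real_
  }
  mcc_den <- as.numeric(TP + FN) * (TN + FP) * (TP + FP) * (TN + FN)
  mcc <- if (mcc_den > 0) {
    100 * (as.numeric(TP) * TN - as.numeric(FP) * FN) / sqrt(mcc_den)
  } else {
    undefined <- c(undefined, "MCC: a marginal total is zero"); NA_real_
  }

  out <- c(ACC = acc, SN = sn, PE = pe, MCC = mcc)
  if (length(undefined) > 0) attr(out, "undefined") <- undefined
  out
}

#' ROC curve and area under the curve
#'
#' Higher scores must indicate the positive class (for [wsrc()] models use
#' `predict(..., type = "score")`, the residual margin).  The curve and AUC
#' (trapezoidal) are computed with \pkg{pROC}; ties in the scores are
#' handled by pROC's threshold sweep, so label-independent constant scores
#' give AUC 0.5.
#'
#' @param scores Numeric decision scores.
#' @param labels True labels; must contain both classes.  Positive class =
#'   last factor level.
#' @return Object of class `"roc_data"`: list with `points` (data frame of
#'   `fpr`, `tpr` sorted by `fpr`), `auc`, `scores`, `labels`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2L) {
    stop("`labels` must contain exactly two classes", call. = FALSE)
  }
  labels <- droplevels(labels)
  r <- pROC::roc(response = labels, predictor = as.numeric(scores),
                 levels = levels(labels), direction = "<", quiet = TRUE)
  pts <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities)
  pts <- pts[order(pts$fpr, pts$tpr), , drop = FALSE]
  rownames(pts) <- NULL
  structure(
    list(points = pts, auc = as.numeric(pROC::auc(r)),
         scores = as.numeric(scores), labels = labels),
    class = "roc_data"
  )
}

#' @export
print.roc_data <- function(x, ...) {
  cat("ROC curve: ", length(x$scores), " samples, AUC = ",
      format(x$auc, digits = 5), "\n", sep = "")
  invisible(x)
}

#' @export
plot.roc_data <- function(x, ...) {
  plot(x$points$fpr, x$points$tpr, type = "l",
       xlab = "False positive rate", ylab = "True positive rate", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Write ROC points as two-column text
#'
#' @param roc A `"roc_data"` object.
#' @param path Output path.
#' @export
write_roc_points <- function(roc, path) {
  stopifnot(inherits(roc, "roc_data"))
  utils::write.table(roc$points, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Seeded stratified fold assignment
#'
#' Shuffles within each class and deals samples round-robin into `k` folds,
#' so fold sizes differ by at most one per class and every fold keeps the
#' class balance of the full data set.
#'
#' @param y Class labels.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed; fold assignment is a pure function of
#'   `(y, k, seed)`.
#' @return Integer vector of fold ids in `1:k`, one per sample.
#' @export
stratified_folds <- function(y, k = 5L, seed = 1L) {
  y <- as.factor(y)
  if (k < 2L) stop("`k` must be at least 2", call. = FALSE)
  if (min(table(y)) < k) {
    stop("each class needs at least k = ", k, " samples for stratified ",
         k, "-fold assignment", call. = FALSE)
  }
  folds <- integer(length(y))
  shuffled <- local({
    set.seed(seed)
    lapply(levels(y), function(l) {
      idx <- which(y == l)
      idx[sample.int(length(idx))]
    })
  })
  # one round-robin counter carried across the class blocks keeps both the
  # per-class and the overall fold sizes within 1 of each other
  dealing_order <- unlist(shuffled)
  folds[dealing_order] <- rep_len(seq_len(k), length(y))
  folds
}

#' Stratified k-fold cross-validation of a sparse representation classifier
#'
#' Repeats, for each fold: fit [wsrc()] on the other folds, predict the
#' held-out fold, tally the confusion counts and metrics.  Decision scores
#' of all folds are pooled for a single ROC/AUC.
#'
#' @param x Feature matrix (samples in rows) or a labelled
#'   `"pair_features"` object.
#' @param y Labels; taken from `x` when it is a labelled feature object.
#' @param k Number of folds (default 5).
#' @param sigma,epsilon,weighted Classifier parameters, see [wsrc()].
#' @param seed Seed for the fold assignment.
#' @return Object of class `"wsrc_cv"`: list with `folds` (assignment),
#'   `per_fold` (data frame of per-fold ACC/SN/PE/MCC), `mean`, `sd`,
#'   `auc` (pooled), `scores`, `predicted`, `truth` and the parameters.
#' @examples
#' \donttest{
#' sim <- simulate_ppi_pairs(n_pairs = 25, separation = 1, seed = 7)
#' feats <- pair_feature_matrix(sim$proteins, sim$pairs, "CP(5)", n = 1)
#' cv <- cross_validate(feats, k = 5, seed = 7)
#' cv$mean
#' }
#' @export
cross_validate <- function(x, y = NULL, k = 5L, sigma = 50, epsilon = 0.05,
                           weighted = TRUE, seed = 1L) {
  if (inherits(x, "pair_features")) {
    if (is.null(y)) y <- x$label
    x <- x$x
  }
  if (is.null(y)) stop("labels required (supply `y` or a labelled feature object)",
                       call. = FALSE)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("cross-validation needs both classes present",
                            call. = FALSE)
  folds <- stratified_folds(y, k, seed)

  lev <- levels(y)
  predicted <- factor(rep(NA_character_, length(y)), levels = lev)
  scores <- rep(NA_real_, length(y))
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    test <- folds == f
    if (length(unique(y[test])) < 2L || length(unique(y[!test])) < 2L) {
      stop("fold ", f, " lacks one of the classes; use a different seed or fewer folds",
           call. = FALSE)
    }
    fit <- wsrc(x[!test, , drop = FALSE], y[!test], sigma = sigma,
                epsilon = epsilon, weighted = weighted)
    G <- predict(fit, x[test, , drop = FALSE], type = "residuals")
    pred <- factor(lev[apply(G, 1L, which.min)], levels = lev)
    predicted[test] <- pred
    scores[test] <- G[, 1L] - G[, 2L]
    per_fold[[f]] <- classification_metrics(confusion_counts(y[test], pred))
  }
  per_fold <- as.data.frame(do.call(rbind, per_fold))
  per_fold <- cbind(fold = seq_len(k), per_fold)

  pooled <- roc_curve(scores, y)
  structure(
    list(folds = folds, per_fold = per_fold,
         mean = colMeans(per_fold[, -1L, drop = FALSE]),
         sd = apply(per_fold[, -1L, drop = FALSE], 2L, stats::sd),
         auc = pooled$auc, scores = scores, predicted = predicted, truth = y,
         k = k, sigma = sigma, epsilon = epsilon, weighted = weighted,
         seed = seed),
    class = "wsrc_cv"
  )
}

#' @export
print.wsrc_cv <- function(x, digits = 2, ...) {
  cat(x$k, "-fold cross-validation (",
      if (x$weighted) "WSRC" else "SRC",
      ", sigma = ", format(x$sigma), ", epsilon = ", format(x$epsilon),
      ", seed = ", x$seed, ")\n", sep = "")
  tab <- x$per_fold
  tab[, -1L] <- round(tab[, -1L], digits)
  print(tab, row.names = FALSE)
  m <- round(x$mean, digits); s <- round(x$sd, digits)
  cat("mean : ", paste(names(m), sprintf("%s +/- %s", m, s),
                       sep = " = ", collapse = ", "), "\n", sep = "")
  cat("pooled AUC: ", format(x$auc, digits = 5), "\n", sep = "")
  invisible(x)
}

#' Write a cross-validation report as delimited text
#'
#' @param cv A `"wsrc_cv"` object.
#' @param path Output path.
#' @export
write_cv_report <- function(cv, path) {
  stopifnot(inherits(cv, "wsrc_cv"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# wsrcppi cv\tk=%d\tmode=%s\tsigma=%s\tepsilon=%s\tseed=%d",
                     cv$k, if (cv$weighted) "WSRC" else "SRC",
                     format(cv$sigma), format(cv$epsilon), cv$seed), con)
  tab <- cv$per_fold
  tab <- rbind(tab, c(NA, cv$mean), c(NA, cv$sd))
  tab <- cbind(what = c(rep("fold", cv$k), "mean", "sd"), tab)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sprintf("# pooled AUC\t%.6f", cv$auc), con)
  invisible(path)
}
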