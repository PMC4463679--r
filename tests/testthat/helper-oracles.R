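# Shared fixtures and independent oracles.

# random amino-acid sequence over the 20 standard residues
rand_seq <- function(len) {
  paste(sample(standard_residues(), len, replace = TRUE), collapse = "")
}

# Independent confusion-table oracle: rebuild the per-sample truth/prediction
# vectors and use means and the Pearson correlation of the binary vectors
# (the phi coefficient) instead of the closed-form expressions.
metrics_oracle <- function(TP, TN, FP, FN) {
  truth <- c(rep(1L, TP + FN), rep(0L, TN + FP))
  pred <- c(rep(1L, TP), rep(0L, FN), rep(0L, TN), rep(1L, FP))
  total <- length(truth)
  c(
    ACC = if (total > 0) 100 * mean(truth == pred) else NA_real_,
    SN = if (sum(truth == 1L) > 0) 100 * mean(pred[truth == 1L] == 1L) else NA_real_,
    PE = if (sum(pred == 1L) > 0) 100 * mean(truth[pred == 1L] == 1L) else NA_real_,
    MCC = if (total > 1) 100 * suppressWarnings(stats::cor(truth, pred)) else NA_real_
  )
}

# Batch BPDN oracle: scipy's SLSQP on the constrained program directly.
# instances: list of list(X = matrix, y = vector, eps = scalar)
bpdn_oracle <- function(instances) {
  src <- tempfile(fileext = ".json")
  dst <- tempfile(fileext = ".json")
  # row-wise nested lists so the matrix shape survives the JSON round trip
  payload <- lapply(instances, function(inst) {
    X <- unname(as.matrix(inst$X))
    list(X = lapply(seq_len(nrow(X)), function(i) as.numeric(X[i, ])),
         y = as.numeric(inst$y), eps = inst$eps)
  })
  jsonlite::write_json(payload, src, digits = NA, auto_unbox = TRUE)
  script <- test_path("bpdn_oracle.py")
  status <- system2("python", c(script, src, dst), stdout = FALSE)
  if (!identical(status, 0L)) stop("python BPDN oracle failed with status ", status)
  jsonlite::read_json(dst, simplifyVector = TRUE)
}

# run the installed command-line script in a child process, propagating the
# current library paths
run_cli <- function(args) {
  script <- system.file("exec", "wsrcppi", package = "wsrcppi")
  if (!nzchar(script) || !file.exists(script)) {
    script <- file.path(testthat::test_path(), "..", "..", "exec", "wsrcppi")
  }
  out <- suppressWarnings(system2(
    "Rscript", shQuote(c(script, args)), stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  ))
  list(status = attr(out, "status") %||% 0L, output = paste(out, collapse = "\n"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
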