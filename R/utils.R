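## Content digests without external dependencies: serialize to a temp file
## (format version 2, header-stable) and md5 it.
object_digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

text_digest <- function(txt) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f, useBytes = TRUE)
  unname(tools::md5sum(f))
}

file_digest <- function(path) unname(tools::md5sum(path))

## Stratified k-fold assignment: within each class, a seeded permutation is
## dealt round-robin across folds, so every fold holds both classes whenever
## the class counts allow it.
stratified_folds <- function(y, k = 5, seed = 1) {
  fold <- integer(length(y))
  set.seed(seed)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

## SMOTE-style minority oversampling to a 1:1 class ratio. Each synthetic
## row interpolates a seeded-random minority row toward one of its k nearest
## minority neighbors. Returns the augmented data with a logical attribute
## marking synthetic rows (the leakage instrumentation hook).
smote_balance <- function(X, y, k = 5, seed = 1) {
  stopifnot(is.matrix(X), length(y) == nrow(X))
  tab <- table(y)
  if (length(tab) != 2) stop("smote_balance expects a binary outcome")
  minority <- names(tab)[which.min(tab)]
  need <- max(tab) - min(tab)
  if (need == 0) {
    return(list(X = X, y = y, synthetic = rep(FALSE, nrow(X))))
  }
  mi <- which(y == minority)
  Xm <- X[mi, , drop = FALSE]
  set.seed(seed)
  if (nrow(Xm) == 1) {
    Xs <- Xm[rep(1, need), , drop = FALSE]
  } else {
    kk <- min(k, nrow(Xm) - 1)
    d <- as.matrix(dist(Xm))
    diag(d) <- Inf
    nn <- do.call(rbind, lapply(seq_len(nrow(d)),
                                function(i) order(d[i, ])[seq_len(kk)]))
    base <- sample.int(nrow(Xm), need, replace = TRUE)
    pick <- nn[cbind(base, sample.int(kk, need, replace = TRUE))]
    u <- runif(need)
    Xs <- Xm[base, , drop = FALSE] +
      u * (Xm[pick, , drop = FALSE] - Xm[base, , drop = FALSE])
  }
  list(X = rbind(X, Xs),
       y = c(y, rep(as.numeric(minority), need)),
       synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, need)))
}
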