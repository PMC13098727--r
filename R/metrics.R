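#' Area under the ROC curve
#'
#' Rank-statistic implementation (Mann-Whitney with midrank tie handling):
#' equals the proportion of positive/negative pairs ranked correctly, ties
#' counted one half.
#'
#' @param y Binary 0/1 outcome vector.
#' @param p Numeric score vector.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(y, p) {
  stopifnot(length(y) == length(p))
  y <- as.numeric(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(p, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Precision-recall AUC (average precision)
#'
#' Average precision over positives taken in descending-score order; tied
#' scores are processed as a group (precision evaluated after the whole
#' group is included).
#'
#' @inheritParams auc_score
#' @return Average precision in `[0, 1]`.
#' @export
pr_auc_score <- function(y, p) {
  stopifnot(length(y) == length(p))
  y <- as.numeric(y)
  n1 <- sum(y == 1)
  if (n1 == 0) return(NA_real_)
  ord <- order(-p)
  y <- y[ord]; p <- p[ord]
  grp <- cumsum(!duplicated(p))
  tp <- cumsum(y); np <- seq_along(y)
  last <- !duplicated(grp, fromLast = TRUE)  # end of each tie group
  prec <- tp[last] / np[last]
  pos_in_grp <- diff(c(0, tp[last]))
  sum(prec * pos_in_grp) / n1
}

#' Macro-averaged F1
#'
#' Unweighted mean of per-class F1 scores over the classes present in the
#' reference labels; a class never predicted contributes F1 = 0.
#'
#' @param truth Reference class labels.
#' @param pred Predicted class labels.
#' @return Macro-F1 in `[0, 1]`.
#' @export
macro_f1 <- function(truth, pred) {
  classes <- sort(unique(truth))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

#' Brier score and expected calibration error
#'
#' Binary case: Brier is the mean squared error of the predicted
#' probabilities; ECE partitions `[0, 1]` into `n_bins` equal-width bins and
#' sums `(n_b / n) * |acc_b - conf_b|`. Multiclass case (`p` a probability
#' matrix, `y` class labels matching its column names or indices): Brier is
#' the mean over classes of the squared one-hot error, ECE uses the maximum
#' class probability as confidence and top-class correctness as accuracy.
#'
#' @param y Outcome: 0/1 vector (binary) or class labels (multiclass).
#' @param p Probability vector (binary) or matrix with one column per class.
#' @param n_bins Number of equal-width calibration bins.
#' @return List with elements `brier` and `ece`.
#' @export
calibration_metrics <- function(y, p, n_bins = 10) {
  if (is.matrix(p)) {
    if (length(y) != nrow(p)) stop("length(y) must equal nrow(p)")
    if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
    cls <- colnames(p)
    if (is.null(cls)) cls <- as.character(seq_len(ncol(p)))
    onehot <- outer(as.character(y), cls, "==") * 1
    brier <- mean(rowMeans((p - onehot)^2))
    conf <- apply(p, 1, max)
    pred <- cls[max.col(p, ties.method = "first")]
    correct <- as.numeric(pred == as.character(y))
    ece <- ece_bins(correct, conf, n_bins)
  } else {
    if (length(y) != length(p)) stop("length(y) must equal length(p)")
    if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
    y <- as.numeric(y)
    brier <- mean((p - y)^2)
    ece <- ece_bins(y, p, n_bins)
  }
  list(brier = brier, ece = ece)
}

ece_bins <- function(acc, conf, n_bins) {
  bin <- pmin(pmax(ceiling(conf * n_bins), 1), n_bins)
  n <- length(conf)
  tot <- 0
  for (b in seq_len(n_bins)) {
    idx <- bin == b
    nb <- sum(idx)
    if (nb == 0) next
    tot <- tot + (nb / n) * abs(mean(acc[idx]) - mean(conf[idx]))
  }
  tot
}

#' Jaccard overlap of two membership sets
#'
#' `|A intersect B| / |A union B|`; defined as 1 when both sets are empty.
#'
#' @param a,b Vectors of member identifiers.
#' @return Overlap in `[0, 1]`.
#' @export
jaccard_overlap <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) && !length(b)) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

accuracy_score <- function(truth, pred) mean(truth == pred)
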