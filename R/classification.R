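# Fit a linear soft-margin SVM and return the held-out decision score
# oriented so that positive = positive class, plus the predicted label.
.svmFoldPredict <- function(xTrain, yTrain, xTest, positive, cost) {
  fit <- e1071::svm(xTrain, yTrain, kernel = "linear", cost = cost,
                    scale = FALSE)
  pr <- predict(fit, xTest, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  # e1071's decision value is positive for the class named first in the
  # column header "A/B"; orient so higher score = positive class.
  firstClass <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]][1L]
  score <- if (identical(firstClass, positive)) dv[, 1L] else -dv[, 1L]
  list(predicted = as.character(pr), score = unname(score))
}

#' Leave-one-out linear SVM over selected connectivity edges
#'
#' Benchmarks a feature set with a linear-kernel soft-margin SVM (cost
#' \code{cost}, default 1, no feature scaling) under leave-one-out
#' cross-validation: each subject is held out once, the SVM is trained on the
#' rest and the held-out decision score and predicted label are recorded.
#' Two feature-selection protocols are provided:
#' \describe{
#'   \item{\code{"nested"} (default)}{the edge-wise t-test and p-threshold
#'     run inside each training fold, so the held-out subject never informs
#'     selection — the statistically sound protocol.}
#'   \item{\code{"paper"}}{selection runs once on the whole cohort before
#'     cross-validation; this reproduces whole-cohort selection as commonly
#'     practised but leaks the test subject into feature choice and is
#'     optimistically biased on null data.}
#' }
#' Metrics are computed from pooled predictions; the AUC from pooled decision
#' scores. With \code{alpha = NULL} all features are used and both protocols
#' coincide.
#'
#' @param features numeric matrix, subjects x edges (Fisher-z values).
#' @param labels factor or character vector of class labels.
#' @param alpha p-value threshold for edge selection, or NULL to use every
#'   edge.
#' @param protocol \code{"nested"} or \code{"paper"}.
#' @param positive label of the positive class (default \code{"AD"}).
#' @param cost SVM cost parameter C.
#' @param variant t-test variant passed to [edgeTTest()].
#' @param scale z-score features before fitting (off by default; Fisher-z
#'   edges already share a scale).
#' @return A [ClassificationResult-class].
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(60, 1), 10, 6), matrix(rnorm(60, -1), 10, 6))
#' y <- rep(c("AD", "NC"), each = 10)
#' metrics(looSvm(x, y))
#' @export
looSvm <- function(features, labels, alpha = NULL,
                   protocol = c("nested", "paper"), positive = "AD",
                   cost = 1, variant = "pooled", scale = FALSE) {
  protocol <- match.arg(protocol)
  features <- as.matrix(features)
  n <- nrow(features)
  labels <- as.character(labels)
  if (n < 4L) stop("need at least 4 subjects")
  if (length(labels) != n) stop("labels length must match rows of features")
  classes <- unique(labels)
  if (length(classes) != 2L || !positive %in% classes)
    stop("labels must contain exactly two classes including '", positive, "'")
  if (scale) features <- base::scale(features)
  y <- factor(labels)

  selectCols <- function(rows) {
    if (is.null(alpha)) return(seq_len(ncol(features)))
    isPos <- labels[rows] == positive
    st <- edgeTTest(features[rows[isPos], , drop = FALSE],
                    features[rows[!isPos], , drop = FALSE],
                    variant = variant)
    which(suppressWarnings(selectEdges(st, alpha))@selected)
  }

  globalSel <- if (protocol == "paper") selectCols(seq_len(n)) else NULL
  if (protocol == "paper" && length(globalSel) == 0L)
    stop("no edge selected at alpha = ", alpha,
         " on the full cohort (paper protocol)")

  predicted <- character(n)
  scores <- numeric(n)
  nFeat <- integer(n)
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    cols <- if (protocol == "paper") globalSel else selectCols(train)
    if (length(cols) == 0L)
      stop("no edge selected at alpha = ", alpha, " in fold ", i,
           " (nested protocol)")
    nFeat[i] <- length(cols)
    fold <- .svmFoldPredict(features[train, cols, drop = FALSE],
                            droplevels(y[train]),
                            features[i, cols, drop = FALSE],
                            positive, cost)
    predicted[i] <- fold$predicted
    scores[i] <- fold$score
  }

  negative <- setdiff(classes, positive)
  cf <- c(TP = sum(predicted == positive & labels == positive),
          TN = sum(predicted == negative & labels == negative),
          FP = sum(predicted == positive & labels == negative),
          FN = sum(predicted == negative & labels == positive))
  roc <- rocPoints(scores, labels, positive = positive)
  met <- computeMetrics(cf["TP"], cf["TN"], cf["FP"], cf["FN"])
  met["auc"] <- roc$auc
  new("ClassificationResult", predicted = predicted, labels = labels,
      scores = scores, confusion = as.integer(cf) |> setNames(names(cf)),
      metrics = met, roc = roc$points, protocol = protocol,
      alpha = if (is.null(alpha)) NA_real_ else alpha,
      nFeaturesPerFold = nFeat)
}

#' Classification metrics from a confusion matrix
#'
#' Computes the five evaluation indices from TP/TN/FP/FN counts (positive
#' class = AD): accuracy = (TP+TN)/total, sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), and F-score = 2 x precision x recall /
#' (precision + recall) with precision = TP/(TP+FP) and recall =
#' sensitivity — all as percentages. Undefined ratios (zero denominators)
#' are reported as NA, never as 0. When decision scores and labels are also
#' given, the AUC (a fraction in [0, 1]) is included.
#'
#' @param tp,tn,fp,fn non-negative integer counts.
#' @param scores optional pooled decision scores for the AUC.
#' @param labels optional true labels matching \code{scores}.
#' @param positive positive-class label for the AUC computation.
#' @return Named numeric vector: \code{acc}, \code{sen}, \code{spe},
#'   \code{fscore} (percent), plus \code{auc} when scores are supplied.
#' @examples
#' computeMetrics(38, 35, 10, 7)   # ACC 81.11, SEN 84.44, SPE 77.78
#' @export
computeMetrics <- function(tp, tn, fp, fn, scores = NULL, labels = NULL,
                           positive = "AD") {
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  if (sum(counts) == 0) stop("confusion matrix is empty")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  acc <- 100 * (tp + tn) / sum(counts)
  sen <- 100 * ratio(tp, tp + fn)
  spe <- 100 * ratio(tn, tn + fp)
  precision <- ratio(tp, tp + fp)
  recall <- ratio(tp, tp + fn)
  fscore <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 100 * 2 * precision * recall / (precision + recall)
  out <- c(acc = unname(acc), sen = unname(sen), spe = unname(spe),
           fscore = unname(fscore))
  if (!is.null(scores)) {
    stopifnot(!is.null(labels))
    out["auc"] <- rocPoints(scores, labels, positive = positive)$auc
  }
  out
}

#' ROC curve and AUC from pooled decision scores
#'
#' Standard threshold-sweep ROC: thresholds run over the unique score values
#' in descending order, a subject is called positive when its score >= the
#' threshold, and tied scores step the curve diagonally. The curve starts at
#' (0, 0), ends at (1, 1) and is monotone; the AUC is the trapezoidal area,
#' identical to the normalized Mann-Whitney U statistic (ties counted 1/2).
#'
#' @param scores real-valued decision scores, higher = more positive-class.
#' @param labels true class labels.
#' @param positive positive-class label.
#' @return List with \code{points} (data.frame \code{fpr}, \code{tpr}) and
#'   \code{auc}.
#' @export
rocPoints <- function(scores, labels, positive = "AD") {
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels))
  pos <- labels == positive
  if (!any(pos) || all(pos))
    stop("both classes must be present to build a ROC curve")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1L))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1L))
  pts <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  if (pts$fpr[nrow(pts)] != 1 || pts$tpr[nrow(pts)] != 1)
    pts <- rbind(pts, data.frame(fpr = 1, tpr = 1))
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1L) + pts$tpr[-1L]) / 2)
  list(points = pts, auc = auc)
}
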