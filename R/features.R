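#' Edge-wise two-sample t-test between groups
#'
#' Per edge (feature column), a two-sided two-sample t-test comparing groups
#' A and B. The default is the classical pooled-variance Student test with
#' nA + nB - 2 degrees of freedom; Welch's unequal-variance form is available
#' via \code{variant = "welch"}. Edges with zero pooled variance are
#' untestable and get t = 0, p = 1 (counted in a message). Benjamini-Hochberg
#' adjusted q-values are attached for reporting; selection happens separately
#' in [selectEdges()] on raw p-values.
#'
#' @param featuresA,featuresB numeric matrices, subjects x edges, with
#'   matching columns.
#' @param variant \code{"pooled"} (default) or \code{"welch"}.
#' @param edgeIdx optional data.frame (columns \code{row}, \code{col})
#'   labelling the edges, as from [vectorizeFC()].
#' @return An [EdgeStats-class] (no selection applied yet).
#' @examples
#' A <- matrix(rnorm(40), 10, 4); B <- matrix(rnorm(40), 10, 4)
#' edgeTTest(A, B)
#' @export
edgeTTest <- function(featuresA, featuresB, variant = c("pooled", "welch"),
                      edgeIdx = NULL) {
  variant <- match.arg(variant)
  featuresA <- as.matrix(featuresA)
  featuresB <- as.matrix(featuresB)
  nA <- nrow(featuresA); nB <- nrow(featuresB)
  if (nA < 2L || nB < 2L) stop("each group needs at least 2 subjects")
  if (ncol(featuresA) != ncol(featuresB))
    stop("groups have different numbers of edges")
  mA <- colMeans(featuresA); mB <- colMeans(featuresB)
  vA <- apply(featuresA, 2L, var); vB <- apply(featuresB, 2L, var)
  if (variant == "pooled") {
    sp2 <- ((nA - 1L) * vA + (nB - 1L) * vB) / (nA + nB - 2L)
    se <- sqrt(sp2 * (1 / nA + 1 / nB))
    df <- rep(nA + nB - 2L, length(se))
  } else {
    se <- sqrt(vA / nA + vB / nB)
    df <- (vA / nA + vB / nB)^2 /
      ((vA / nA)^2 / (nA - 1L) + (vB / nB)^2 / (nB - 1L))
  }
  degenerate <- se == 0 | !is.finite(se)
  t <- ifelse(degenerate, 0, (mA - mB) / se)
  p <- ifelse(degenerate, 1, 2 * pt(-abs(t), df))
  p <- pmax(p, .Machine$double.xmin)   # keep p in (0, 1]
  if (any(degenerate))
    message(sum(degenerate), " edge(s) with zero pooled variance: p set to 1")
  if (is.null(edgeIdx)) edgeIdx <- data.frame()
  new("EdgeStats", t = t, p = p, q = fdrCorrect(p),
      selected = rep(FALSE, length(p)), alpha = NA_real_,
      edgeIndex = edgeIdx)
}

#' Select edges at a p-value threshold
#'
#' Non-strict thresholding: an edge is selected when p <= alpha. An empty
#' selection is returned with a warning (the classifier then refuses it
#' informatively).
#'
#' @param stats an [EdgeStats-class].
#' @param alpha selection threshold in (0, 1).
#' @return The [EdgeStats-class] with the selection mask and alpha filled in.
#' @export
selectEdges <- function(stats, alpha) {
  stopifnot(is(stats, "EdgeStats"), alpha > 0, alpha <= 1)
  sel <- stats@p <= alpha
  if (!any(sel))
    warning("no edge reaches p <= ", alpha)
  initialize(stats, selected = sel, alpha = alpha)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin wrapper over \code{stats::p.adjust(p, "BH")}, the step-up false
#' discovery rate adjustment used for the reported top edges.
#'
#' @param p vector of p-values in (0, 1].
#' @return Adjusted values, same length and order as \code{p}.
#' @export
fdrCorrect <- function(p) {
  stopifnot(all(p > 0 & p <= 1))
  p.adjust(p, method = "BH")
}

#' Top-k most discriminative edges
#'
#' Ranks edges by ascending p-value, breaking ties by descending |t| and then
#' by edge position, so the order is deterministic across runs.
#'
#' @param stats an [EdgeStats-class] with a non-empty edge index.
#' @param k number of edges to report (default 15).
#' @return data.frame with columns \code{row} (WM label for cross edges),
#'   \code{col} (GM label), \code{t}, \code{p}, \code{q}.
#' @export
topEdges <- function(stats, k = 15L) {
  stopifnot(is(stats, "EdgeStats"))
  n <- length(stats@p)
  if (n < k) {
    warning("only ", n, " edges available; returning all")
    k <- n
  }
  ord <- order(stats@p, -abs(stats@t), seq_len(n))
  idx <- ord[seq_len(k)]
  out <- data.frame(t = stats@t[idx], p = stats@p[idx], q = stats@q[idx])
  if (nrow(stats@edgeIndex))
    out <- cbind(stats@edgeIndex[idx, , drop = FALSE], out)
  rownames(out) <- NULL
  out
}

#' Accuracy across a p-threshold sweep
#'
#' Runs the leave-one-out SVM protocol once per candidate threshold and
#' tabulates the resulting accuracy, mirroring how the operating thresholds
#' were picked from the threshold-versus-accuracy curve. Per-alpha failures
#' (e.g. an empty selection in some fold) are recorded as NA rather than
#' aborting the sweep.
#'
#' @param features numeric matrix, subjects x edges (Fisher-z values).
#' @param labels factor/character vector of group labels.
#' @param alphas numeric vector of candidate thresholds (>= 2 values).
#' @param protocol \code{"nested"} (selection inside each training fold;
#'   default) or \code{"paper"} (selection once on the full cohort).
#' @param positive label of the positive class; default \code{"AD"}.
#' @param cost SVM cost parameter.
#' @return data.frame with columns \code{alpha}, \code{accuracy} (percent),
#'   \code{n_selected}; attribute \code{bestAlpha} holds the argmax alpha
#'   (smallest alpha on ties).
#' @export
thresholdSweep <- function(features, labels, alphas, protocol = "nested",
                           positive = "AD", cost = 1) {
  stopifnot(length(alphas) >= 2L)
  alphas <- sort(alphas)
  acc <- nsel <- rep(NA_real_, length(alphas))
  for (a in seq_along(alphas)) {
    res <- tryCatch(
      looSvm(features, labels, alpha = alphas[a], protocol = protocol,
             positive = positive, cost = cost),
      error = function(e) e)
    if (!inherits(res, "error")) {
      acc[a] <- unname(metrics(res)["acc"])
      nsel[a] <- stats::median(res@nFeaturesPerFold)
    }
  }
  out <- data.frame(alpha = alphas, accuracy = acc, n_selected = nsel)
  if (any(is.finite(acc)))
    attr(out, "bestAlpha") <- alphas[which.max(acc)]
  out
}
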