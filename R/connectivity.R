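# Pearson correlation that maps zero-variance (degenerate) columns to 0
# instead of NA; returns the matrix and how many entries were degenerate.
.safeCor <- function(x, y = NULL) {
  r <- suppressWarnings(if (is.null(y)) cor(x) else cor(x, y))
  bad <- !is.finite(r)
  r[bad] <- 0
  r[r > 1] <- 1
  r[r < -1] <- -1
  list(r = r, nBad = sum(bad))
}

#' Static functional connectivity within one compartment
#'
#' Full-length Pearson correlation between every pair of ROI time series,
#' giving the symmetric static FC matrix (sGFC when applied to gray matter).
#' Zero-variance ROIs get 0 on all their edges, with a warning.
#'
#' @param ts a [RoiTimeSeriesSet-class] (typically the GM subset).
#' @return A symmetric [FCMatrix-class] of kind \code{"static_r"} with unit
#'   diagonal.
#' @seealso [staticFCCross()], [dynamicFC()]
#' @export
staticFCWithin <- function(ts) {
  stopifnot(is(ts, "RoiTimeSeriesSet"))
  if (nTimepoints(ts) < 3L) stop("need at least 3 timepoints")
  sc <- .safeCor(tsData(ts))
  if (sc$nBad > 0L)
    warning("zero-variance ROI(s): ", sc$nBad,
            " correlation(s) undefined, set to 0")
  r <- sc$r
  diag(r) <- 1
  FCMatrix(r, kind = "static_r", rowLabels = roiLabels(ts),
           colLabels = roiLabels(ts), symmetric = TRUE)
}

#' Static cross-compartment functional connectivity (WM rows x GM columns)
#'
#' @param tsWm,tsGm [RoiTimeSeriesSet-class] objects over the same timepoints.
#' @return A rectangular [FCMatrix-class] of kind \code{"static_r"}.
#' @export
staticFCCross <- function(tsWm, tsGm) {
  stopifnot(is(tsWm, "RoiTimeSeriesSet"), is(tsGm, "RoiTimeSeriesSet"))
  if (nTimepoints(tsWm) != nTimepoints(tsGm))
    stop("time series length mismatch: ", nTimepoints(tsWm), " vs ",
         nTimepoints(tsGm))
  sc <- .safeCor(tsData(tsWm), tsData(tsGm))
  if (sc$nBad > 0L)
    warning("zero-variance ROI(s): ", sc$nBad,
            " correlation(s) undefined, set to 0")
  FCMatrix(sc$r, kind = "static_r", rowLabels = roiLabels(tsWm),
           colLabels = roiLabels(tsGm), symmetric = FALSE)
}

# Stable edge order: within-set edges are the strict upper triangle in
# row-major order ((1,2), (1,3), ..., (G-1,G)); cross edges are the row-major
# flatten of the W x G matrix. Shared by dynamicFC and vectorizeFC.
.edgePairs <- function(rowLabels, colLabels, symmetric) {
  if (symmetric) {
    G <- length(rowLabels)
    i <- rep(seq_len(G - 1L), times = (G - 1L):1L)
    j <- unlist(lapply(seq_len(G - 1L), function(a) (a + 1L):G))
  } else {
    W <- length(rowLabels); G <- length(colLabels)
    i <- rep(seq_len(W), each = G)
    j <- rep(seq_len(G), times = W)
  }
  data.frame(i = i, j = j,
             row = rowLabels[i], col = colLabels[j],
             stringsAsFactors = FALSE)
}

#' Sliding-window dynamic functional connectivity
#'
#' Divides the series into K = floor((T - windowLength)/step) + 1 overlapping
#' windows and computes, per ROI pair and window, the Pearson correlation of
#' the two sub-series (window k covers samples (k-1)*step + 1 through
#' (k-1)*step + windowLength, 1-based). With \code{tsB = NULL} the edges are
#' the strict upper triangle of the within-set matrix; otherwise all
#' rows-of-A x columns-of-B pairs. Zero-variance windows yield correlation 0
#' (counted in the result) so K stays identical across edges.
#'
#' @param tsA a [RoiTimeSeriesSet-class].
#' @param tsB optional second set for cross-compartment dynamics.
#' @param windowLength window length in samples (volumes); default 30.
#' @param step window step in samples; default 1.
#' @return A [DynamicFCSeries-class], edges x K.
#' @examples
#' ts <- RoiTimeSeriesSet(matrix(rnorm(140 * 3), 140, 3),
#'                        roiLabels = paste0("GM_0", 1:3),
#'                        compartment = "GM", trSeconds = 3)
#' nWindows(dynamicFC(ts))  # 111
#' @export
dynamicFC <- function(tsA, tsB = NULL, windowLength = 30L, step = 1L) {
  stopifnot(is(tsA, "RoiTimeSeriesSet"))
  windowLength <- as.integer(windowLength)
  step <- as.integer(step)
  if (windowLength < 3L) stop("windowLength must be >= 3")
  nT <- nTimepoints(tsA)
  if (windowLength > nT)
    stop("window length ", windowLength, " exceeds series length ", nT)
  symmetric <- is.null(tsB)
  if (!symmetric) {
    stopifnot(is(tsB, "RoiTimeSeriesSet"))
    if (nTimepoints(tsB) != nT) stop("time series length mismatch")
  }
  A <- tsData(tsA)
  B <- if (symmetric) NULL else tsData(tsB)
  rowLab <- roiLabels(tsA)
  colLab <- if (symmetric) rowLab else roiLabels(tsB)
  pairs <- .edgePairs(rowLab, colLab, symmetric)
  K <- (nT - windowLength) %/% step + 1L

  vals <- matrix(NA_real_, nrow(pairs), K)
  nBad <- 0L
  lin <- cbind(pairs$i, pairs$j)    # row/col positions into the window matrix
  for (k in seq_len(K)) {
    idx <- ((k - 1L) * step + 1L):((k - 1L) * step + windowLength)
    sc <- if (symmetric) .safeCor(A[idx, , drop = FALSE])
          else .safeCor(A[idx, , drop = FALSE], B[idx, , drop = FALSE])
    nBad <- nBad + sc$nBad
    vals[, k] <- sc$r[lin]
  }
  new("DynamicFCSeries", values = vals, windowLength = windowLength,
      step = step, edgeIndex = pairs[, c("row", "col")],
      rowLabels = rowLab, colLabels = colLab, symmetric = symmetric,
      degenerateWindows = as.integer(nBad))
}

#' RMS summary of a dynamic connectivity series
#'
#' Summarises each edge's windowed correlations by their quadratic mean
#' \eqn{\sqrt{\sum_k (C^k)^2 / K}}, the RMS-dFC statistic measuring the
#' overall fluctuation level of the edge. The result is shaped like the
#' corresponding static matrix (symmetric with unit diagonal, or rectangular).
#'
#' @param d a [DynamicFCSeries-class].
#' @return An [FCMatrix-class] of kind \code{"rms"} with values in [0, 1].
#' @export
rmsFC <- function(d) {
  stopifnot(is(d, "DynamicFCSeries"))
  rms <- sqrt(rowMeans(d@values^2))
  if (d@symmetric) {
    G <- length(d@rowLabels)
    m <- matrix(0, G, G)
    pairs <- .edgePairs(d@rowLabels, d@colLabels, TRUE)
    m[cbind(pairs$i, pairs$j)] <- rms
    m <- m + t(m)
    diag(m) <- 1
  } else {
    m <- matrix(rms, length(d@rowLabels), length(d@colLabels), byrow = TRUE)
  }
  FCMatrix(m, kind = "rms", rowLabels = d@rowLabels, colLabels = d@colLabels,
           symmetric = d@symmetric)
}

#' Fisher r-to-z transform of a connectivity matrix
#'
#' Applies \eqn{z = \frac{1}{2}[\ln(1+r) - \ln(1-r)]} (= atanh) elementwise to
#' improve normality of correlation-derived values before edge-wise testing;
#' applied to static and RMS matrices alike. |r| is clipped to 1 - 1e-7 first
#' so numerically perfect correlations stay finite; values outside [-1, 1]
#' beyond 1e-9 are an error.
#'
#' @param m an [FCMatrix-class] with values in [-1, 1].
#' @return An [FCMatrix-class] of kind \code{"fisher_z"}.
#' @export
fisherZ <- function(m) {
  stopifnot(is(m, "FCMatrix"))
  v <- m@values
  if (any(abs(v) > 1 + 1e-9))
    stop("values outside [-1, 1]: max |r| = ", max(abs(v)))
  v <- pmin(pmax(v, -(1 - 1e-7)), 1 - 1e-7)
  new("FCMatrix", values = atanh(v), kind = "fisher_z",
      rowLabels = m@rowLabels, colLabels = m@colLabels,
      symmetric = m@symmetric)
}

#' Flatten a connectivity matrix to a stable feature vector
#'
#' Symmetric matrices give the strict upper triangle in row-major order
#' (G ROIs -> G(G-1)/2 features; 82 -> 3321); rectangular matrices the
#' row-major flatten (W x G features; 48 x 82 -> 3936). The accompanying edge
#' index maps each feature position to its (row ROI, column ROI) labels and
#' is identical across subjects sharing the canonical label order.
#'
#' @param m an [FCMatrix-class].
#' @param canon optional character vector of expected labels
#'   (row then column); a mismatch is an error, protecting cross-subject
#'   feature alignment.
#' @return List with \code{features} (named numeric vector) and
#'   \code{edgeIndex} (data.frame with columns \code{row}, \code{col}).
#' @export
vectorizeFC <- function(m, canon = NULL) {
  stopifnot(is(m, "FCMatrix"))
  if (!is.null(canon) && !identical(c(m@rowLabels, m@colLabels), canon))
    stop("ROI label order differs from the cohort's canonical order")
  pairs <- .edgePairs(m@rowLabels, m@colLabels, m@symmetric)
  feats <- m@values[cbind(pairs$i, pairs$j)]
  names(feats) <- paste(pairs$row, pairs$col, sep = "~")
  list(features = feats, edgeIndex = pairs[, c("row", "col")])
}

#' Rebuild a connectivity matrix from its feature vector
#'
#' Inverse of [vectorizeFC()] given the original labels; symmetric matrices
#' are restored with unit diagonal for \code{static_r}/\code{rms} kinds and
#' the clipped-z diagonal equivalent otherwise is left at 0.
#'
#' @param features numeric vector as produced by [vectorizeFC()].
#' @param rowLabels,colLabels ROI labels of the target matrix.
#' @param symmetric logical, shape of the target.
#' @param kind value kind of the rebuilt matrix.
#' @return An [FCMatrix-class].
#' @export
unvectorizeFC <- function(features, rowLabels, colLabels = rowLabels,
                          symmetric, kind = "static_r") {
  pairs <- .edgePairs(rowLabels, colLabels, symmetric)
  if (length(features) != nrow(pairs))
    stop("feature length ", length(features), " does not match ",
         nrow(pairs), " edges")
  if (symmetric) {
    G <- length(rowLabels)
    m <- matrix(0, G, G)
    m[cbind(pairs$i, pairs$j)] <- features
    m <- m + t(m)
    diag(m) <- if (kind %in% c("static_r", "rms")) 1 else 0
  } else {
    m <- matrix(features, length(rowLabels), length(colLabels), byrow = TRUE)
  }
  FCMatrix(m, kind = kind, rowLabels = rowLabels, colLabels = colLabels,
           symmetric = symmetric)
}

#' Elementwise mean of connectivity matrices
#'
#' Group-mean FC map: all inputs must share shape, kind and labels.
#'
#' @param matrices list of [FCMatrix-class] objects.
#' @return An [FCMatrix-class] of the same kind.
#' @export
groupMeanFC <- function(matrices) {
  stopifnot(length(matrices) >= 1L,
            all(vapply(matrices, is, logical(1L), "FCMatrix")))
  ref <- matrices[[1L]]
  for (m in matrices[-1L]) {
    if (!identical(dim(m@values), dim(ref@values)) ||
        !identical(m@kind, ref@kind) ||
        !identical(m@rowLabels, ref@rowLabels) ||
        !identical(m@colLabels, ref@colLabels))
      stop("matrices differ in shape, kind or labels")
  }
  avg <- Reduce(`+`, lapply(matrices, fcValues)) / length(matrices)
  new("FCMatrix", values = avg, kind = ref@kind, rowLabels = ref@rowLabels,
      colLabels = ref@colLabels, symmetric = ref@symmetric)
}

#' Threshold a connectivity matrix for display
#'
#' Marks edges whose absolute value strictly exceeds the display threshold
#' (|value| > thr), the convention used for group-mean FC maps.
#'
#' @param m an [FCMatrix-class].
#' @param thr display threshold; default 0.5.
#' @return A logical matrix of the same shape.
#' @export
thresholdMask <- function(m, thr = 0.5) {
  stopifnot(is(m, "FCMatrix"))
  abs(m@values) > thr
}
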