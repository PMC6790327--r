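#' @import methods
#' @importFrom stats cor pt rnorm rgeom sd var p.adjust predict setNames
#'   median ave
#' @importFrom utils head write.csv read.csv packageVersion
NULL

.COMPARTMENTS <- c("WM", "GM")
.FC_KINDS <- c("static_r", "rms", "fisher_z")

#' ROI-by-time BOLD series for one subject
#'
#' Holds a subject's region-averaged BOLD time series: a numeric matrix with
#' one row per timepoint and one column per region of interest (ROI), plus the
#' ROI labels, a white-matter/gray-matter compartment tag per ROI, and the
#' sampling interval (TR, seconds). Column order is the canonical atlas order
#' (ascending integer label within compartment) and is fixed across subjects.
#'
#' @slot data numeric matrix, timepoints x ROIs, no missing values.
#' @slot roiLabels character vector of ROI labels, one per column.
#' @slot compartment character vector, each \code{"WM"} or \code{"GM"}.
#' @slot trSeconds single positive numeric, the sampling interval.
#'
#' @seealso [RoiTimeSeriesSet()] constructor, [extractRoiTimeseries()],
#'   [bandpassFilter()]
#' @exportClass RoiTimeSeriesSet
setClass("RoiTimeSeriesSet",
  representation(
    data = "matrix",
    roiLabels = "character",
    compartment = "character",
    trSeconds = "numeric"
  )
)

setValidity("RoiTimeSeriesSet", function(object) {
  msg <- character()
  d <- object@data
  if (!is.numeric(d)) msg <- c(msg, "data must be a numeric matrix")
  if (anyNA(d)) msg <- c(msg, "data contains missing values")
  if (ncol(d) != length(object@roiLabels))
    msg <- c(msg, "length(roiLabels) must equal ncol(data)")
  if (ncol(d) != length(object@compartment))
    msg <- c(msg, "length(compartment) must equal ncol(data)")
  if (!all(object@compartment %in% .COMPARTMENTS))
    msg <- c(msg, "compartment entries must be 'WM' or 'GM'")
  if (anyDuplicated(object@roiLabels))
    msg <- c(msg, "roiLabels must be unique")
  if (length(object@trSeconds) != 1L || !is.finite(object@trSeconds) ||
      object@trSeconds <= 0)
    msg <- c(msg, "trSeconds must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a RoiTimeSeriesSet
#'
#' @param data numeric matrix, timepoints x ROIs.
#' @param roiLabels character vector of ROI labels (defaults to column names).
#' @param compartment per-ROI compartment tags (\code{"WM"}/\code{"GM"}); a
#'   single value is recycled.
#' @param trSeconds sampling interval in seconds.
#' @return A [RoiTimeSeriesSet-class] object.
#' @examples
#' ts <- RoiTimeSeriesSet(matrix(rnorm(40), 20, 2),
#'                        roiLabels = c("GM_01", "GM_02"),
#'                        compartment = "GM", trSeconds = 3)
#' nTimepoints(ts)
#' @export
RoiTimeSeriesSet <- function(data, roiLabels = colnames(data), compartment,
                             trSeconds) {
  data <- as.matrix(data)
  if (is.null(roiLabels))
    stop("roiLabels must be supplied when data has no column names")
  if (length(compartment) == 1L)
    compartment <- rep(compartment, ncol(data))
  colnames(data) <- roiLabels
  new("RoiTimeSeriesSet", data = data, roiLabels = as.character(roiLabels),
      compartment = as.character(compartment), trSeconds = trSeconds)
}

#' Integer-labelled atlas volume
#'
#' A 3D integer label grid (0 = background) naming the ROIs of one tissue
#' compartment, with a label-to-name map.
#'
#' @slot labels 3D integer array; 0 marks background voxels.
#' @slot labelNames named character vector mapping integer labels (as names)
#'   to ROI names.
#' @slot compartment \code{"WM"} or \code{"GM"}.
#' @exportClass AtlasVolume
setClass("AtlasVolume",
  representation(labels = "array", labelNames = "character",
                 compartment = "character")
)

setValidity("AtlasVolume", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L)
    msg <- c(msg, "labels must be a 3D array")
  labs <- sort(unique(as.integer(object@labels)))
  labs <- labs[labs != 0L]
  if (length(labs) == 0L) msg <- c(msg, "atlas contains no non-zero labels")
  if (any(labs < 0L)) msg <- c(msg, "all labels must be >= 0")
  if (!identical(object@compartment %in% .COMPARTMENTS, TRUE))
    msg <- c(msg, "compartment must be 'WM' or 'GM'")
  if (length(object@labelNames) &&
      !all(as.character(labs) %in% names(object@labelNames)))
    msg <- c(msg, "labelNames must cover every non-zero label")
  if (length(msg)) msg else TRUE
})

#' Construct an AtlasVolume
#'
#' @param labels 3D integer array of ROI labels (0 = background).
#' @param labelNames named character vector (names = integer labels as
#'   strings). If omitted, names \code{"<compartment>_<label>"} are generated.
#' @param compartment \code{"WM"} or \code{"GM"}.
#' @return An [AtlasVolume-class] object.
#' @export
AtlasVolume <- function(labels, labelNames = NULL, compartment) {
  labels <- array(as.integer(labels), dim = dim(labels))
  labs <- sort(unique(as.integer(labels)))
  labs <- labs[labs != 0L]
  if (is.null(labelNames)) {
    labelNames <- sprintf("%s_%02d", compartment, labs)
    names(labelNames) <- as.character(labs)
  }
  new("AtlasVolume", labels = labels, labelNames = labelNames,
      compartment = compartment)
}

#' Functional connectivity matrix
#'
#' One subject's (or one group mean's) edge-level connectivity values. Either
#' symmetric within-compartment (GM x GM, unit diagonal) or rectangular
#' cross-compartment (WM rows x GM columns). \code{kind} records what the
#' entries are: raw Pearson correlations (\code{"static_r"}), the RMS of
#' sliding-window correlations (\code{"rms"}), or Fisher-z transformed values
#' (\code{"fisher_z"}).
#'
#' @slot values numeric matrix of edge values.
#' @slot kind one of \code{"static_r"}, \code{"rms"}, \code{"fisher_z"}.
#' @slot rowLabels,colLabels ROI labels for rows/columns.
#' @slot symmetric logical; TRUE for within-compartment matrices.
#' @exportClass FCMatrix
setClass("FCMatrix",
  representation(values = "matrix", kind = "character",
                 rowLabels = "character", colLabels = "character",
                 symmetric = "logical")
)

setValidity("FCMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (!object@kind %in% .FC_KINDS)
    msg <- c(msg, sprintf("kind must be one of %s",
                          paste(.FC_KINDS, collapse = ", ")))
  if (nrow(v) != length(object@rowLabels) ||
      ncol(v) != length(object@colLabels))
    msg <- c(msg, "label lengths must match values dimensions")
  tol <- 1e-9
  if (object@kind == "static_r" && any(abs(v) > 1 + tol, na.rm = TRUE))
    msg <- c(msg, "static_r values must lie in [-1, 1]")
  if (object@kind == "rms" &&
      (any(v < -tol, na.rm = TRUE) || any(v > 1 + tol, na.rm = TRUE)))
    msg <- c(msg, "rms values must lie in [0, 1]")
  if (isTRUE(object@symmetric)) {
    if (nrow(v) != ncol(v) || !isTRUE(all.equal(v, t(v), tolerance = 1e-8)))
      msg <- c(msg, "symmetric FCMatrix must have a symmetric values matrix")
    if (!identical(object@rowLabels, object@colLabels))
      msg <- c(msg, "symmetric FCMatrix must have identical row/col labels")
  }
  if (length(msg)) msg else TRUE
})

FCMatrix <- function(values, kind, rowLabels = rownames(values),
                     colLabels = colnames(values), symmetric) {
  values <- as.matrix(values)
  rownames(values) <- rowLabels
  colnames(values) <- colLabels
  new("FCMatrix", values = values, kind = kind,
      rowLabels = as.character(rowLabels),
      colLabels = as.character(colLabels), symmetric = symmetric)
}

#' Sliding-window dynamic connectivity series
#'
#' Per-edge sequences of windowed Pearson correlations C^k, k = 1..K, where
#' K = floor((T - window_length)/step) + 1. Windows are half-open sample
#' ranges [ (k-1)*step + 1, (k-1)*step + window_length ] in 1-based indexing.
#'
#' @slot values numeric matrix, edges x K windows, entries in [-1, 1].
#' @slot windowLength,step window length and step in samples.
#' @slot edgeIndex data.frame with columns \code{row}, \code{col} giving the
#'   ROI labels of each edge, in the same (stable) order as the rows of
#'   \code{values}.
#' @slot rowLabels,colLabels ROI label universe of the two sides.
#' @slot symmetric logical; TRUE when built from one within-compartment set
#'   (edges are the strict upper triangle).
#' @slot degenerateWindows count of zero-variance windows whose correlation
#'   was set to 0.
#' @exportClass DynamicFCSeries
setClass("DynamicFCSeries",
  representation(values = "matrix", windowLength = "integer", step = "integer",
                 edgeIndex = "data.frame", rowLabels = "character",
                 colLabels = "character", symmetric = "logical",
                 degenerateWindows = "integer")
)

setValidity("DynamicFCSeries", function(object) {
  msg <- character()
  if (nrow(object@values) != nrow(object@edgeIndex))
    msg <- c(msg, "edgeIndex must have one row per edge")
  if (any(abs(object@values) > 1 + 1e-9))
    msg <- c(msg, "windowed correlations must lie in [-1, 1]")
  if (object@windowLength < 3L) msg <- c(msg, "windowLength must be >= 3")
  if (object@step < 1L) msg <- c(msg, "step must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Edge-wise two-group statistics
#'
#' Per-edge pooled (or Welch) two-sample t statistics on Fisher-z connectivity
#' features, two-sided p-values, Benjamini-Hochberg adjusted q-values, and a
#' selection mask at threshold \code{alpha} (non-strict: p <= alpha).
#'
#' @slot t,p,q numeric vectors, one entry per edge.
#' @slot selected logical selection mask.
#' @slot alpha selection threshold used (NA before [selectEdges()]).
#' @slot edgeIndex data.frame with columns \code{row}, \code{col}.
#' @exportClass EdgeStats
setClass("EdgeStats",
  representation(t = "numeric", p = "numeric", q = "numeric",
                 selected = "logical", alpha = "numeric",
                 edgeIndex = "data.frame")
)

setValidity("EdgeStats", function(object) {
  msg <- character()
  n <- length(object@t)
  if (length(object@p) != n || length(object@q) != n ||
      length(object@selected) != n)
    msg <- c(msg, "t, p, q and selected must have equal length")
  if (any(object@p <= 0 | object@p > 1))
    msg <- c(msg, "p-values must lie in (0, 1]")
  if (any(object@q < object@p - 1e-12))
    msg <- c(msg, "q-values cannot be smaller than p-values")
  if (nrow(object@edgeIndex) != 0L && nrow(object@edgeIndex) != n)
    msg <- c(msg, "edgeIndex must be empty or have one row per edge")
  if (length(msg)) msg else TRUE
})

#' Leave-one-out SVM classification result
#'
#' Pooled leave-one-out predictions of a linear soft-margin SVM, the implied
#' confusion matrix (positive class = AD), the five evaluation metrics
#' (accuracy, sensitivity, specificity, F-score as percentages; AUC as a
#' fraction) and the ROC curve from pooled decision scores.
#'
#' @slot predicted,labels character vectors of predicted and true labels.
#' @slot scores pooled real-valued decision scores (higher = more AD-like).
#' @slot confusion named integer vector TP, TN, FP, FN.
#' @slot metrics named numeric vector acc, sen, spe, fscore (percent) and
#'   auc (fraction).
#' @slot roc data.frame with columns \code{fpr}, \code{tpr}.
#' @slot protocol \code{"nested"} or \code{"paper"} feature-selection mode.
#' @slot alpha selection threshold used (NA when all features were used).
#' @slot nFeaturesPerFold integer vector, features entering each fold's model.
#' @exportClass ClassificationResult
setClass("ClassificationResult",
  representation(predicted = "character", labels = "character",
                 scores = "numeric", confusion = "integer",
                 metrics = "numeric", roc = "data.frame",
                 protocol = "character", alpha = "numeric",
                 nFeaturesPerFold = "integer")
)

setValidity("ClassificationResult", function(object) {
  msg <- character()
  n <- length(object@labels)
  if (length(object@predicted) != n || length(object@scores) != n)
    msg <- c(msg, "predicted, labels and scores must have equal length")
  cf <- object@confusion
  if (!all(c("TP", "TN", "FP", "FN") %in% names(cf)))
    msg <- c(msg, "confusion must contain TP, TN, FP, FN")
  else if (sum(cf) != n)
    msg <- c(msg, "confusion counts must sum to the number of subjects")
  if (!object@protocol %in% c("nested", "paper"))
    msg <- c(msg, "protocol must be 'nested' or 'paper'")
  if (length(msg)) msg else TRUE
})

#' Specification of a synthetic two-group cohort
#'
#' Parameters of the regime-switching multivariate Gaussian generator that
#' emulates a two-group (NC vs AD) resting-state cohort of WM + GM ROI time
#' series in the 0.01-0.1 Hz band. Group A (NC) has stationary correlation
#' \code{baseCorrelation} everywhere; group B (AD) differs by
#' \code{staticEffectDelta} on \code{staticEffectEdges} (a stationary,
#' static-FC effect) and alternates between \code{baseCorrelation +
#' dynamicEffectDelta} and \code{baseCorrelation - dynamicEffectDelta} on
#' \code{dynamicEffectEdges} (a fluctuation, RMS-dFC effect whose stationary
#' mean is unchanged). Regime dwell times are geometric with mean
#' \code{stateDwell} samples.
#'
#' Edges are given as 2-column integer matrices indexing the combined ROI
#' vector (WM ROIs 1..nWm, then GM ROIs nWm+1..nWm+nGm); see [crossEdges()].
#'
#' @slot nPerGroup subjects per group.
#' @slot nWm,nGm number of WM / GM ROIs.
#' @slot nTimepoints samples per series.
#' @slot trSeconds sampling interval (seconds).
#' @slot baseCorrelation background inter-ROI correlation in [0, 1).
#' @slot staticEffectEdges,staticEffectDelta edges and size of the stationary
#'   group difference.
#' @slot dynamicEffectEdges,dynamicEffectDelta edges and amplitude of the
#'   regime-switching group difference.
#' @slot stateDwell mean regime dwell time in samples.
#' @slot noiseSd additive white measurement-noise SD (attenuates observed
#'   correlations by 1/(1 + noiseSd^2)).
#' @slot seed integer RNG seed; identical spec + seed gives bit-identical
#'   cohorts.
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(nPerGroup = "integer", nWm = "integer", nGm = "integer",
                 nTimepoints = "integer", trSeconds = "numeric",
                 baseCorrelation = "numeric",
                 staticEffectEdges = "matrix", staticEffectDelta = "numeric",
                 dynamicEffectEdges = "matrix", dynamicEffectDelta = "numeric",
                 stateDwell = "numeric", noiseSd = "numeric", seed = "integer")
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nPerGroup < 2L) msg <- c(msg, "nPerGroup must be >= 2")
  if (object@nWm < 0L || object@nGm < 1L)
    msg <- c(msg, "nWm must be >= 0 and nGm >= 1")
  if (object@nTimepoints < 10L) msg <- c(msg, "nTimepoints must be >= 10")
  if (object@trSeconds <= 0) msg <- c(msg, "trSeconds must be positive")
  if (object@baseCorrelation < 0 || object@baseCorrelation >= 1)
    msg <- c(msg, "baseCorrelation must lie in [0, 1)")
  if (object@stateDwell < 1) msg <- c(msg, "stateDwell must be >= 1 sample")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
  nR <- object@nWm + object@nGm
  for (nm in c("staticEffectEdges", "dynamicEffectEdges")) {
    e <- slot(object, nm)
    if (length(e) && (ncol(e) != 2L || any(e < 1L) || any(e > nR) ||
                      any(e[, 1L] == e[, 2L])))
      msg <- c(msg, sprintf("%s must be a 2-column matrix of distinct ROI indices in 1..%d", nm, nR))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CohortSpec
#'
#' Defaults mirror the study design the generator emulates: 48 WM + 82 GM
#' ROIs, 140 timepoints at TR = 3 s, and a weak 0.1 background correlation.
#'
#' @param nPerGroup subjects per group.
#' @param nWm,nGm WM and GM ROI counts.
#' @param nTimepoints samples per series.
#' @param trSeconds sampling interval (seconds).
#' @param baseCorrelation background inter-ROI correlation in [0, 1).
#' @param staticEffectEdges 2-column integer matrix (combined ROI indices) of
#'   edges carrying a stationary group difference; NULL for none.
#' @param staticEffectDelta stationary correlation difference on those edges.
#' @param dynamicEffectEdges edges carrying a fluctuation group difference.
#' @param dynamicEffectDelta regime amplitude of the fluctuation effect.
#' @param stateDwell mean regime dwell (samples).
#' @param noiseSd additive white-noise SD.
#' @param seed integer RNG seed.
#' @return A [CohortSpec-class] object.
#' @examples
#' spec <- CohortSpec(nPerGroup = 5, nWm = 4, nGm = 6, nTimepoints = 80,
#'                    seed = 1)
#' @export
CohortSpec <- function(nPerGroup = 45L, nWm = 48L, nGm = 82L,
                       nTimepoints = 140L, trSeconds = 3.0,
                       baseCorrelation = 0.1,
                       staticEffectEdges = NULL, staticEffectDelta = 0,
                       dynamicEffectEdges = NULL, dynamicEffectDelta = 0.4,
                       stateDwell = 20, noiseSd = 0, seed = 1L) {
  toEdges <- function(e) {
    if (is.null(e) || length(e) == 0L)
      return(matrix(integer(), 0L, 2L))
    e <- as.matrix(e)
    storage.mode(e) <- "integer"
    e
  }
  new("CohortSpec", nPerGroup = as.integer(nPerGroup), nWm = as.integer(nWm),
      nGm = as.integer(nGm), nTimepoints = as.integer(nTimepoints),
      trSeconds = trSeconds, baseCorrelation = baseCorrelation,
      staticEffectEdges = toEdges(staticEffectEdges),
      staticEffectDelta = staticEffectDelta,
      dynamicEffectEdges = toEdges(dynamicEffectEdges),
      dynamicEffectDelta = dynamicEffectDelta,
      stateDwell = stateDwell, noiseSd = noiseSd, seed = as.integer(seed))
}

#' Combined-index edges between WM and GM ROIs
#'
#' Helper building the 2-column edge matrix [CohortSpec()] expects, from WM
#' and GM ROI indices in their own compartments.
#'
#' @param wmIdx,gmIdx equal-length integer vectors of WM / GM ROI indices.
#' @param nWm number of WM ROIs in the cohort (GM indices are offset by it).
#' @return 2-column integer matrix of combined ROI indices.
#' @examples
#' crossEdges(c(1, 2), c(5, 9), nWm = 48)
#' @export
crossEdges <- function(wmIdx, gmIdx, nWm = 48L) {
  stopifnot(length(wmIdx) == length(gmIdx))
  cbind(as.integer(wmIdx), as.integer(nWm) + as.integer(gmIdx))
}
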