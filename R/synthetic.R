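# Build a correlation matrix from the base level plus per-edge deltas, and
# check positive semidefiniteness; 'what' names the regime in error messages.
.buildCorr <- function(nR, base, edges, deltas, what) {
  S <- matrix(base, nR, nR)
  diag(S) <- 1
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1L]; j <- edges[k, 2L]
      S[i, j] <- S[i, j] + deltas[k]
      S[j, i] <- S[i, j]
    }
  }
  if (any(abs(S) > 1))
    stop(what, ": implied correlations exceed [-1, 1]; effect edges: ",
         paste(apply(edges, 1L, paste, collapse = "-"), collapse = ", "))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop(what, ": implied covariance is not positive semidefinite ",
         "(min eigenvalue ", signif(min(ev), 3), "); offending edge set: ",
         if (nrow(edges)) paste(apply(edges, 1L, paste, collapse = "-"),
                                collapse = ", ") else "(background)")
  S
}

# Alternating regime labels covering T samples; geometric dwell, mean dwell.
.regimeSequence <- function(nT, dwell) {
  state <- sample(c(1L, 2L), 1L)
  out <- integer(0L)
  while (length(out) < nT) {
    len <- rgeom(1L, prob = 1 / dwell) + 1L
    out <- c(out, rep(state, len))
    state <- 3L - state
  }
  out[seq_len(nT)]
}

#' Generate a synthetic two-group cohort of WM + GM ROI time series
#'
#' Samples each subject from a regime-switching multivariate Gaussian: within
#' a regime, timepoints are i.i.d. draws from a Gaussian whose correlation
#' matrix is the compound-symmetric background plus the group's effect deltas;
#' regimes alternate with geometric dwell times (mean \code{stateDwell}
#' samples) and differ only on \code{dynamicEffectEdges}, where group B's
#' correlation swings by \eqn{\pm}\code{dynamicEffectDelta} about its
#' stationary level. White measurement noise (\code{noiseSd}) is added and
#' every series is then bandpass-filtered to \code{lowHz}-\code{highHz} with
#' the same zero-phase filter the extraction stage uses, so synthetic and
#' extracted data enter the pipeline identically.
#'
#' All implied correlation matrices are checked for positive
#' semidefiniteness; invalid effect configurations are rejected with an error
#' naming the offending edges rather than silently repaired. Each subject's
#' stream is seeded from \code{seed} by a fixed offset, so cohorts are
#' bit-identical under an identical spec + seed, and subjects are mutually
#' independent.
#'
#' @param spec a [CohortSpec-class].
#' @param lowHz,highHz bandpass edges applied to the generated series.
#' @return A list with elements \code{subjects} (list of
#'   [RoiTimeSeriesSet-class]), \code{group} (factor with levels
#'   \code{c("NC", "AD")}; group A = NC, group B = AD), \code{ids} (subject
#'   identifiers) and \code{spec}.
#' @examples
#' coh <- generateCohort(CohortSpec(nPerGroup = 3, nWm = 4, nGm = 6,
#'                                  nTimepoints = 60, seed = 7))
#' table(coh$group)
#' @export
generateCohort <- function(spec, lowHz = 0.01, highHz = 0.1) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  nR <- spec@nWm + spec@nGm
  nT <- spec@nTimepoints
  nDyn <- nrow(spec@dynamicEffectEdges)
  noEdges <- matrix(integer(), 0L, 2L)

  # Group A (NC): background only, identical in both regimes.
  S_A <- .buildCorr(nR, spec@baseCorrelation, noEdges, numeric(0L),
                    "group A background")
  # Group B (AD): stationary static effect; dynamic edges swing +/- amplitude.
  statDelta <- rep(spec@staticEffectDelta, nrow(spec@staticEffectEdges))
  S_B_up <- .buildCorr(
    nR, spec@baseCorrelation,
    rbind(spec@staticEffectEdges, spec@dynamicEffectEdges),
    c(statDelta, rep(spec@dynamicEffectDelta, nDyn)),
    "group B, high-coupling regime")
  S_B_dn <- .buildCorr(
    nR, spec@baseCorrelation,
    rbind(spec@staticEffectEdges, spec@dynamicEffectEdges),
    c(statDelta, rep(-spec@dynamicEffectDelta, nDyn)),
    "group B, low-coupling regime")

  chol_A <- chol(S_A + diag(1e-9, nR))
  chol_B <- list(chol(S_B_up + diag(1e-9, nR)),
                 chol(S_B_dn + diag(1e-9, nR)))

  labels <- c(sprintf("WM_%02d", seq_len(spec@nWm)),
              sprintf("GM_%02d", seq_len(spec@nGm)))
  comp <- c(rep("WM", spec@nWm), rep("GM", spec@nGm))
  bf <- .bandpassCoef(lowHz, highHz, spec@trSeconds)

  makeSubject <- function(idx, cholList) {
    set.seed((spec@seed + 7919L * idx) %% .Machine$integer.max)
    reg <- .regimeSequence(nT, spec@stateDwell)
    Z <- matrix(rnorm(nT * nR), nT, nR)
    X <- matrix(0, nT, nR)
    for (r in 1:2) {
      sel <- reg == r
      if (any(sel))
        X[sel, ] <- Z[sel, , drop = FALSE] %*% cholList[[r]]
    }
    if (spec@noiseSd > 0)
      X <- X + spec@noiseSd * matrix(rnorm(nT * nR), nT, nR)
    for (j in seq_len(nR))
      X[, j] <- signal::filtfilt(bf, X[, j])
    X <- sweep(X, 2L, colMeans(X))
    RoiTimeSeriesSet(X, roiLabels = labels, compartment = comp,
                     trSeconds = spec@trSeconds)
  }

  n <- spec@nPerGroup
  subjects <- vector("list", 2L * n)
  for (i in seq_len(n))
    subjects[[i]] <- makeSubject(i, list(chol_A, chol_A))
  for (i in seq_len(n))
    subjects[[n + i]] <- makeSubject(n + i, chol_B)

  list(subjects = subjects,
       group = factor(rep(c("NC", "AD"), each = n), levels = c("NC", "AD")),
       ids = sprintf("sub-%03d", seq_len(2L * n)),
       spec = spec)
}

#' Write a cohort as per-subject CSVs plus a JSON manifest
#'
#' @param cohort result of [generateCohort()].
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
writeCohortCsv <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(cohort$subjects))
  for (i in seq_along(cohort$subjects)) {
    files[i] <- file.path(dir, paste0(cohort$ids[i], ".csv"))
    writeRoiSeriesCsv(cohort$subjects[[i]], files[i])
  }
  manifest <- list(
    subjects = data.frame(id = cohort$ids,
                          group = as.character(cohort$group),
                          file = basename(files)),
    tr_seconds = cohort$spec@trSeconds,
    seed = cohort$spec@seed)
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}

#' Read a cohort written by [writeCohortCsv()]
#'
#' @param dir directory holding the per-subject CSVs and manifest.
#' @return A cohort list as returned by [generateCohort()] (without the
#'   generating spec).
#' @export
readCohortCsv <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  subs <- manifest$subjects
  subjects <- lapply(file.path(dir, subs$file), readRoiSeriesCsv,
                     trSeconds = manifest$tr_seconds)
  list(subjects = subjects,
       group = factor(subs$group, levels = c("NC", "AD")),
       ids = subs$id, spec = NULL)
}

#' Render a subject as a 4D image fixture with paired label atlases
#'
#' Lays each ROI out as a block of \code{voxelsPerRoi} voxels in a 3D grid;
#' every voxel of ROI k carries that ROI's time series plus independent
#' Gaussian noise. Used to exercise [extractRoiTimeseries()] end to end: at
#' \code{noiseSd = 0} the extraction round-trip is exact.
#'
#' @param ts a [RoiTimeSeriesSet-class].
#' @param gridDim 3D grid dimensions; must hold all ROI voxels.
#' @param voxelsPerRoi voxels assigned to each ROI.
#' @param noiseSd per-voxel additive noise SD.
#' @param seed RNG seed for the voxel noise.
#' @param dir if non-NULL, the image and atlases are also written there as
#'   NIfTI (\code{bold.nii.gz}, \code{atlas_wm.nii.gz}, \code{atlas_gm.nii.gz}).
#' @return List with \code{img} (4D array), \code{atlases} (named list of
#'   [AtlasVolume-class] per compartment present) and, when written,
#'   \code{paths}.
#' @export
renderImageFixture <- function(ts, gridDim, voxelsPerRoi = 1L, noiseSd = 0,
                               seed = 1L, dir = NULL) {
  stopifnot(is(ts, "RoiTimeSeriesSet"))
  nVoxNeeded <- nRois(ts) * voxelsPerRoi
  if (prod(gridDim) < nVoxNeeded)
    stop("grid of ", prod(gridDim), " voxels too small for ", nRois(ts),
         " ROIs x ", voxelsPerRoi, " voxels")
  nT <- nTimepoints(ts)
  set.seed(seed)
  vox <- matrix(0, prod(gridDim), nT)
  labFlat <- rep(0L, prod(gridDim))
  compFlat <- character(prod(gridDim))
  comp <- compartments(ts)
  # per-compartment integer labels 1..n, in canonical column order
  labNum <- stats::ave(seq_len(nRois(ts)), comp, FUN = seq_along)
  pos <- 1L
  for (k in seq_len(nRois(ts))) {
    idx <- pos:(pos + voxelsPerRoi - 1L)
    series <- tsData(ts)[, k]
    for (v in idx) {
      vox[v, ] <- series + if (noiseSd > 0) rnorm(nT, sd = noiseSd) else 0
      labFlat[v] <- labNum[k]
      compFlat[v] <- comp[k]
    }
    pos <- pos + voxelsPerRoi
  }
  img <- array(vox, dim = c(gridDim, nT))
  atlases <- list()
  for (cc in unique(comp)) {
    lab <- labFlat
    lab[compFlat != cc] <- 0L
    nm <- roiLabels(ts)[comp == cc]
    names(nm) <- as.character(labNum[comp == cc])
    atlases[[cc]] <- AtlasVolume(array(lab, gridDim), labelNames = nm,
                                 compartment = cc)
  }
  out <- list(img = img, atlases = atlases)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(bold = file.path(dir, "bold.nii.gz"))
    nii <- RNifti::asNifti(img)
    nii <- RNifti::`pixdim<-`(nii, c(1, 1, 1, trSeconds(ts)))
    RNifti::writeNifti(nii, paths$bold)
    for (cc in names(atlases)) {
      p <- file.path(dir, sprintf("atlas_%s.nii.gz", tolower(cc)))
      RNifti::writeNifti(RNifti::asNifti(atlases[[cc]]@labels), p)
      paths[[paste0("atlas_", tolower(cc))]] <- p
    }
    out$paths <- paths
  }
  out
}
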