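#' Extract ROI-average time series from a 4D BOLD image
#'
#' Averages, at every timepoint, the BOLD signal over all voxels carrying each
#' atlas label (unweighted mean), producing one column per ROI in canonical
#' order (ascending integer label). ROIs with no voxels are excluded with a
#' warning, never silently zero-filled.
#'
#' @param img a 4D numeric array (x, y, z, t) or path to a NIfTI file.
#' @param atlas an [AtlasVolume-class] (or path to a NIfTI label volume, in
#'   which case \code{compartment} must be given).
#' @param trSeconds sampling interval; when \code{img} is a NIfTI path and
#'   this is NULL, the header's time step is used.
#' @param compartment compartment tag used when \code{atlas} is a path.
#' @return A [RoiTimeSeriesSet-class], columns in ascending label order.
#' @examples
#' img <- array(rnorm(2 * 2 * 1 * 10), c(2, 2, 1, 10))
#' atl <- AtlasVolume(array(c(1, 1, 2, 0), c(2, 2, 1)), compartment = "GM")
#' extractRoiTimeseries(img, atl, trSeconds = 3)
#' @export
extractRoiTimeseries <- function(img, atlas, trSeconds = NULL,
                                 compartment = NULL) {
  if (is.character(img)) {
    nii <- RNifti::readNifti(img)
    if (is.null(trSeconds)) {
      pd <- RNifti::pixdim(nii)
      if (length(pd) >= 4 && pd[4] > 0) trSeconds <- pd[4]
    }
    img <- as.array(nii)
  }
  if (is.character(atlas)) {
    if (is.null(compartment))
      stop("compartment must be given when atlas is a file path")
    a <- as.array(RNifti::readNifti(atlas))
    # NIfTI readers may drop trailing singleton dimensions
    if (length(dim(a)) < 3L)
      dim(a) <- c(dim(a), rep(1L, 3L - length(dim(a))))
    atlas <- AtlasVolume(a, compartment = compartment)
  }
  if (is.null(trSeconds))
    stop("trSeconds must be supplied (not recoverable from an array input)")
  if (length(dim(img)) != 4L)
    stop("img must be a 4D (x, y, z, t) array")
  if (!identical(dim(img)[1:3], dim(atlas@labels)))
    stop("image grid ", paste(dim(img)[1:3], collapse = "x"),
         " does not match atlas grid ",
         paste(dim(atlas@labels), collapse = "x"))

  # ROI universe: labels present in the volume plus any named in the atlas
  # map (so an ROI with zero voxels is reported, not silently dropped)
  labs <- sort(union(unique(as.integer(atlas@labels)),
                     as.integer(names(atlas@labelNames))))
  labs <- labs[labs != 0L]
  nT <- dim(img)[4L]
  vox <- matrix(img, ncol = nT)       # voxels x time
  flat <- as.integer(atlas@labels)

  out <- matrix(NA_real_, nT, length(labs))
  nVox <- integer(length(labs))
  for (k in seq_along(labs)) {
    idx <- which(flat == labs[k])
    nVox[k] <- length(idx)
    if (length(idx))
      out[, k] <- colMeans(vox[idx, , drop = FALSE])
  }
  empty <- nVox == 0L
  if (any(empty)) {
    warning("excluding ", sum(empty), " ROI(s) with no voxels: ",
            paste(labs[empty], collapse = ", "))
    out <- out[, !empty, drop = FALSE]
    labs <- labs[!empty]
  }
  names <- atlas@labelNames[as.character(labs)]
  names[is.na(names)] <- sprintf("%s_%02d", atlas@compartment,
                                 labs[is.na(names)])
  RoiTimeSeriesSet(out, roiLabels = unname(names),
                   compartment = atlas@compartment, trSeconds = trSeconds)
}

# Butterworth bandpass coefficients shared by the filter and the generator.
.bandpassCoef <- function(lowHz, highHz, trSeconds, order = 2L) {
  nyquist <- 1 / (2 * trSeconds)
  if (!(lowHz > 0 && lowHz < highHz && highHz < nyquist))
    stop(sprintf(
      "invalid band [%g, %g] Hz for TR = %g s (Nyquist %.4g Hz): need 0 < low < high < Nyquist",
      lowHz, highHz, trSeconds, nyquist))
  signal::butter(order, c(lowHz, highHz) / nyquist, type = "pass")
}

#' Zero-phase bandpass filter of a time-series set
#'
#' Applies a zero-phase (forward-backward) Butterworth bandpass, order 2 per
#' pass, identically to every column, then removes each column's mean. The
#' default 0.01-0.1 Hz band is the conventional resting-state BOLD range,
#' suppressing slow scanner drift below and respiratory/cardiac-aliased power
#' above. Output length equals input length; forward-backward filtering keeps
#' correlations free of phase distortion.
#'
#' @param ts a [RoiTimeSeriesSet-class].
#' @param lowHz,highHz band edges in Hz; \code{highHz} must be below the
#'   Nyquist frequency 1/(2 TR).
#' @return A filtered [RoiTimeSeriesSet-class] of identical shape.
#' @export
bandpassFilter <- function(ts, lowHz = 0.01, highHz = 0.1) {
  stopifnot(is(ts, "RoiTimeSeriesSet"))
  bf <- .bandpassCoef(lowHz, highHz, ts@trSeconds)
  # demean before filtering so the DC offset never excites edge transients
  d <- sweep(ts@data, 2L, colMeans(ts@data))
  for (j in seq_len(ncol(d)))
    d[, j] <- signal::filtfilt(bf, d[, j])
  d <- sweep(d, 2L, colMeans(d))
  initialize(ts, data = d)
}

#' Write / read a subject's ROI series as CSV
#'
#' The on-disk layout is rows = timepoints, columns = ROI labels; the
#' compartment of each ROI is recovered from its label prefix
#' (\code{"WM_"} / \code{"GM_"}).
#'
#' @param ts a [RoiTimeSeriesSet-class].
#' @param path CSV file path.
#' @return \code{writeRoiSeriesCsv}: \code{path}, invisibly.
#' @export
writeRoiSeriesCsv <- function(ts, path) {
  d <- as.data.frame(tsData(ts))
  colnames(d) <- roiLabels(ts)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRoiSeriesCsv
#' @param trSeconds sampling interval of the stored series.
#' @return \code{readRoiSeriesCsv}: a [RoiTimeSeriesSet-class].
#' @export
readRoiSeriesCsv <- function(path, trSeconds) {
  d <- as.matrix(read.csv(path, check.names = FALSE))
  comp <- ifelse(startsWith(colnames(d), "WM"), "WM", "GM")
  RoiTimeSeriesSet(d, roiLabels = colnames(d), compartment = comp,
                   trSeconds = trSeconds)
}
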