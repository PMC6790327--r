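.METHODS <- c("sGFC", "sWGFC", "dGFC", "dWGFC")

#' Connectivity feature matrices for a whole cohort
#'
#' Computes, per subject, the four connectivity representations — static
#' within-GM (sGFC), static WM-GM (sWGFC) and their sliding-window RMS
#' counterparts (dGFC, dWGFC) — applies the Fisher r-to-z transform, and
#' stacks the vectorized edges into subjects x edges feature matrices with a
#' shared edge index per method. For 82 GM and 48 WM ROIs the widths are
#' 3321 (within-GM) and 3936 (WM-GM).
#'
#' @param cohort list with \code{subjects} ([RoiTimeSeriesSet-class] list) and
#'   \code{group}, as from [generateCohort()] or [readCohortCsv()].
#' @param windowLength,step sliding-window parameters (samples).
#' @param methods subset of \code{c("sGFC", "sWGFC", "dGFC", "dWGFC")}.
#' @param rawMeans also return per-subject raw (untransformed) static and RMS
#'   matrices for group-mean maps.
#' @return List with \code{features} (named list of matrices),
#'   \code{edgeIndex} (named list of data.frames), \code{group}, and — when
#'   \code{rawMeans} — \code{raw} (per-method list of per-subject
#'   [FCMatrix-class]).
#' @export
cohortFeatures <- function(cohort, windowLength = 30L, step = 1L,
                           methods = .METHODS, rawMeans = FALSE) {
  methods <- match.arg(methods, .METHODS, several.ok = TRUE)
  n <- length(cohort$subjects)
  feats <- edgeIdx <- setNames(vector("list", length(methods)), methods)
  raw <- if (rawMeans) setNames(lapply(methods, function(m) vector("list", n)),
                                methods)
  needCross <- any(c("sWGFC", "dWGFC") %in% methods)
  for (i in seq_len(n)) {
    ts <- cohort$subjects[[i]]
    gm <- compartmentSubset(ts, "GM")
    wm <- if (needCross) compartmentSubset(ts, "WM")
    for (m in methods) {
      fc <- switch(m,
        sGFC  = staticFCWithin(gm),
        sWGFC = staticFCCross(wm, gm),
        dGFC  = rmsFC(dynamicFC(gm, windowLength = windowLength, step = step)),
        dWGFC = rmsFC(dynamicFC(wm, gm, windowLength = windowLength,
                                step = step)))
      if (rawMeans) raw[[m]][[i]] <- fc
      v <- vectorizeFC(fisherZ(fc))
      if (is.null(feats[[m]])) {
        feats[[m]] <- matrix(NA_real_, n, length(v$features),
                             dimnames = list(cohort$ids, names(v$features)))
        edgeIdx[[m]] <- v$edgeIndex
      }
      feats[[m]][i, ] <- v$features
    }
  }
  out <- list(features = feats, edgeIndex = edgeIdx, group = cohort$group)
  if (rawMeans) out$raw <- raw
  out
}

#' Pipeline run configuration
#'
#' Bundles every tunable of an end-to-end run with the conventional defaults:
#' window length 30 volumes / step 1, the 0.01-0.1 Hz band, selection
#' thresholds alpha = 0.001 (static methods) and 0.01 (dynamic methods),
#' nested leave-one-out protocol, SVM cost 1, FDR q = 0.05 for the top-edge
#' report and display threshold 0.5 for group-mean maps.
#'
#' @param mode \code{"simulate"} (generate a cohort from \code{spec}) or
#'   \code{"series"} (read a CSV cohort from \code{inputDir}).
#' @param spec a [CohortSpec-class] (simulate mode).
#' @param inputDir cohort directory (series mode).
#' @param windowLength,step sliding-window parameters.
#' @param lowHz,highHz bandpass edges (simulate mode passes them to the
#'   generator; series input is assumed already band-limited).
#' @param alphaStatic,alphaDynamic selection thresholds for the static /
#'   dynamic methods.
#' @param sweepAlphas optional vector of thresholds for an accuracy sweep.
#' @param protocol \code{"nested"} or \code{"paper"}.
#' @param cost SVM cost.
#' @param fdrQ FDR level noted in the top-edge report.
#' @param displayThreshold |value| cutoff for group-mean FC masks.
#' @param topK edges in the top-edge table.
#' @param seed integer seed recorded in the manifest (simulate mode overrides
#'   the spec's seed with this one).
#' @param outDir output directory.
#' @return A validated configuration list of class \code{"wgfcConfig"}.
#' @export
runConfig <- function(mode = c("simulate", "series"), spec = NULL,
                      inputDir = NULL, windowLength = 30L, step = 1L,
                      lowHz = 0.01, highHz = 0.1, alphaStatic = 0.001,
                      alphaDynamic = 0.01, sweepAlphas = NULL,
                      protocol = c("nested", "paper"), cost = 1,
                      fdrQ = 0.05, displayThreshold = 0.5, topK = 15L,
                      seed = 1L, outDir = tempfile("wgfc_run_")) {
  mode <- match.arg(mode)
  protocol <- match.arg(protocol)
  if (mode == "simulate") {
    if (is.null(spec)) stop("simulate mode needs a CohortSpec")
    spec@seed <- as.integer(seed)
    validObject(spec)
  } else if (is.null(inputDir) || !dir.exists(inputDir)) {
    stop("series mode needs an existing inputDir")
  }
  stopifnot(windowLength >= 3, step >= 1, lowHz > 0, highHz > lowHz,
            alphaStatic > 0, alphaStatic <= 1, alphaDynamic > 0,
            alphaDynamic <= 1, cost > 0, fdrQ > 0, fdrQ < 1,
            displayThreshold >= 0, topK >= 1)
  structure(list(mode = mode, spec = spec, inputDir = inputDir,
                 windowLength = as.integer(windowLength),
                 step = as.integer(step), lowHz = lowHz, highHz = highHz,
                 alphaStatic = alphaStatic, alphaDynamic = alphaDynamic,
                 sweepAlphas = sweepAlphas, protocol = protocol, cost = cost,
                 fdrQ = fdrQ, displayThreshold = displayThreshold,
                 topK = as.integer(topK), seed = as.integer(seed),
                 outDir = outDir),
            class = "wgfcConfig")
}

.methodAlpha <- function(cfg, method) {
  if (method %in% c("sGFC", "sWGFC")) cfg$alphaStatic else cfg$alphaDynamic
}

#' Run the full connectivity-classification pipeline
#'
#' Orchestrates one end-to-end run: obtain the cohort (simulated or read from
#' CSV), build the four feature sets, compute edge statistics and group-mean
#' maps, classify each feature set by leave-one-out linear SVM, and write all
#' tables under \code{cfg$outDir}:
#' \itemize{
#'   \item per method: \code{features_<m>.csv}, \code{edge_stats_<m>.csv},
#'     \code{metrics_<m>.json}, \code{roc_<m>.csv},
#'     \code{group_mean_mask_<m>_<group>.csv};
#'   \item \code{summary.csv} — one metrics row per method;
#'   \item \code{top_edges_dWGFC.csv} — the FDR-annotated top-k table;
#'   \item \code{sweep_<m>.csv} when \code{sweepAlphas} is set;
#'   \item \code{manifest.json} — full config, seed and package version.
#' }
#' Outputs are bit-reproducible from (config, seed, inputs).
#'
#' @param cfg a configuration from [runConfig()].
#' @return Invisibly, a list with \code{results} (per-method
#'   [ClassificationResult-class]), \code{stats} (per-method
#'   [EdgeStats-class]), \code{summary} (data.frame), \code{topEdges} and
#'   \code{outDir}.
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "wgfcConfig"))
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  cohort <- if (cfg$mode == "simulate")
    generateCohort(cfg$spec, lowHz = cfg$lowHz, highHz = cfg$highHz)
  else readCohortCsv(cfg$inputDir)
  labels <- as.character(cohort$group)
  if (length(unique(labels)) != 2L)
    stop("cohort must contain exactly two groups")

  fx <- cohortFeatures(cohort, windowLength = cfg$windowLength,
                       step = cfg$step, rawMeans = TRUE)
  results <- stats <- setNames(vector("list", length(.METHODS)), .METHODS)
  summary <- NULL
  for (m in .METHODS) {
    alpha <- .methodAlpha(cfg, m)
    X <- fx$features[[m]]
    isAD <- labels == "AD"
    st <- edgeTTest(X[isAD, , drop = FALSE], X[!isAD, , drop = FALSE],
                    edgeIdx = fx$edgeIndex[[m]])
    st <- suppressWarnings(selectEdges(st, alpha))
    stats[[m]] <- st
    res <- looSvm(X, labels, alpha = alpha, protocol = cfg$protocol,
                  cost = cfg$cost)
    results[[m]] <- res

    write.csv(data.frame(id = rownames(X), group = labels, X,
                         check.names = FALSE),
              file.path(cfg$outDir, sprintf("features_%s.csv", m)),
              row.names = FALSE)
    write.csv(edgeTable(st),
              file.path(cfg$outDir, sprintf("edge_stats_%s.csv", m)),
              row.names = FALSE)
    jsonlite::write_json(
      list(method = m, protocol = cfg$protocol, alpha = alpha,
           seed = cfg$seed, confusion = as.list(confusion(res)),
           metrics = as.list(round(metrics(res), 6))),
      file.path(cfg$outDir, sprintf("metrics_%s.json", m)),
      auto_unbox = TRUE, digits = NA)
    write.csv(rocCurve(res),
              file.path(cfg$outDir, sprintf("roc_%s.csv", m)),
              row.names = FALSE)
    for (g in unique(labels)) {
      gm <- groupMeanFC(fx$raw[[m]][labels == g])
      mask <- thresholdMask(gm, cfg$displayThreshold)
      write.csv(mask * 1L,
                file.path(cfg$outDir,
                          sprintf("group_mean_mask_%s_%s.csv", m, g)),
                row.names = TRUE)
    }
    mrow <- data.frame(method = m, t(round(metrics(res), 4)),
                       n_selected = sum(st@selected), alpha = alpha)
    summary <- rbind(summary, mrow)

    if (!is.null(cfg$sweepAlphas)) {
      sw <- thresholdSweep(X, labels, cfg$sweepAlphas,
                           protocol = cfg$protocol, cost = cfg$cost)
      write.csv(sw, file.path(cfg$outDir, sprintf("sweep_%s.csv", m)),
                row.names = FALSE)
    }
  }
  top <- topEdges(stats[["dWGFC"]], k = cfg$topK)
  write.csv(top, file.path(cfg$outDir, "top_edges_dWGFC.csv"),
            row.names = FALSE)
  write.csv(summary, file.path(cfg$outDir, "summary.csv"), row.names = FALSE)

  manifest <- cfg
  manifest$spec <- if (!is.null(cfg$spec)) {
    s <- cfg$spec
    list(nPerGroup = s@nPerGroup, nWm = s@nWm, nGm = s@nGm,
         nTimepoints = s@nTimepoints, trSeconds = s@trSeconds,
         baseCorrelation = s@baseCorrelation,
         staticEffectEdges = apply(s@staticEffectEdges, 1L, paste,
                                   collapse = "-"),
         staticEffectDelta = s@staticEffectDelta,
         dynamicEffectEdges = apply(s@dynamicEffectEdges, 1L, paste,
                                    collapse = "-"),
         dynamicEffectDelta = s@dynamicEffectDelta,
         stateDwell = s@stateDwell, noiseSd = s@noiseSd, seed = s@seed)
  }
  manifest$packageVersion <- as.character(packageVersion("wgfc"))
  jsonlite::write_json(unclass(manifest),
                       file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(results = results, stats = stats, summary = summary,
                 topEdges = top, outDir = cfg$outDir))
}
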