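#' @include AllClasses.R
NULL

#' Sort a UBC population along the fast-to-slow continuum
#'
#' Cells whose reference-burst `peak_change` strictly exceeds
#' `peakChangeThreshold` (clear increases in firing) come first, in ascending
#' order of `half_width` (fast to slow); the remaining cells follow in
#' ascending order of `pause_duration`. The sort is stable, ties are broken
#' by `cell_id`, and a missing sort key places the cell last within its group
#' (flagged in `sort_flagged`).
#'
#' @param table data.frame with columns `cell_id`, `peak_change`,
#'   `half_width`, `pause_duration` (one row per cell, reference protocol).
#' @param peakChangeThreshold spk/s; default 8.
#' @param descending logical; reverse the within-group order (slow at top).
#' @return The table reordered, with columns `order_index` (1-based rank),
#'   `sort_key` (`"half_width"` or `"pause_duration"`) and `sort_flagged`.
#' @export
sortPopulation <- function(table, peakChangeThreshold = 8,
                           descending = FALSE) {
  need <- c("cell_id", "peak_change", "half_width", "pause_duration")
  if (!all(need %in% names(table)))
    stop("table must have columns ", paste(need, collapse = ", "))
  excit <- !is.na(table$peak_change) &
    table$peak_change > peakChangeThreshold
  key <- ifelse(excit, table$half_width, table$pause_duration)
  flagged <- is.na(key)
  keyOrd <- ifelse(is.na(key), Inf, if (descending) -key else key)
  ord <- order(!excit, keyOrd, table$cell_id)
  out <- table[ord, , drop = FALSE]
  out$order_index <- seq_len(nrow(out))
  out$sort_key <- ifelse(excit[ord], "half_width", "pause_duration")
  out$sort_flagged <- flagged[ord]
  rownames(out) <- NULL
  out
}

#' Per-cell peak normalization for population heatmaps
#'
#' Divides each cell's rate trace(s) by that cell's reference peak (for
#' instance its peak response to the 20 x 100 spk/s burst, with or without
#' mGluR2/3 blocked, per figure convention). Cells whose reference peak is
#' not positive are flagged and left unnormalized.
#'
#' @param mat numeric matrix, one row per cell (rate traces on a common grid).
#' @param referencePeaks numeric vector, one reference peak per row.
#' @return The normalized matrix, with attribute `flagged`: logical vector
#'   marking rows left unnormalized.
#' @export
normalizeForHeatmap <- function(mat, referencePeaks) {
  stopifnot(is.matrix(mat), length(referencePeaks) == nrow(mat))
  flagged <- !is.finite(referencePeaks) | referencePeaks <= 0
  scale <- ifelse(flagged, 1, referencePeaks)
  structure(mat / scale, flagged = flagged)
}

#' Percentage of the response mediated by a receptor
#'
#' From the evoked-spike counts immediately before (`nBefore`) and after
#' (`nAfter`) blocking that receptor:
#' `100 * (nBefore - nAfter) / nBefore`. Excluded (NA) when the pre-block
#' response is smaller than `minSpikes` spikes; negative percentages
#' (blocking increased firing) are permitted.
#'
#' @param nBefore,nAfter evoked-spike counts at consecutive wash-in stages
#'   (vectorized).
#' @param minSpikes exclusion threshold on the denominator stage; default 5.
#' @return Numeric percentage(s), NA where excluded.
#' @export
componentPercentage <- function(nBefore, nAfter, minSpikes = 5) {
  out <- 100 * (nBefore - nAfter) / nBefore
  out[is.na(nBefore) | nBefore < minSpikes] <- NA_real_
  out
}

#' Spike-count ratios relative to a per-cell reference response
#'
#' Normalizes a baseline-stage and a blocked-stage spike count to a per-cell
#' reference count (e.g. the spikes evoked by the 20 x 100 spk/s burst, or by
#' the 60 spk/s step, under baseline conditions), for violin-plot style
#' population summaries of the effect of a block.
#'
#' @param nBaseline,nBlocked,nReference spike counts (vectorized).
#' @return data.frame with columns `baseline_ratio` and `blocked_ratio`; rows
#'   with `nReference <= 0` are NA (excluded).
#' @export
blockEffectRatio <- function(nBaseline, nBlocked, nReference) {
  bad <- !is.finite(nReference) | nReference <= 0
  data.frame(
    baseline_ratio = ifelse(bad, NA_real_, nBaseline / nReference),
    blocked_ratio = ifelse(bad, NA_real_, nBlocked / nReference))
}

#' Evoked spikes per wash-in stage and component decomposition
#'
#' Runs the full single-cell burst quantification on the noiseless model
#' intensity at each stage of the cumulative wash-in series (baseline, then
#' mGluR2/3, AMPAR and mGluR1 blocked in that order) and decomposes the
#' response: `mglur23_ratio` is the spike count after blocking mGluR2/3
#' relative to baseline, `pct_ampar` the percentage of the then-current
#' response removed by blocking AMPARs, `pct_mglur1` the percentage of the
#' remaining response removed by blocking mGluR1s. The percentage
#' denominators are the stage immediately before each block; stages whose
#' denominator is below 5 spikes are excluded (NA). Set
#' `commonDenominator = TRUE` to reference both percentages to the
#' mGluR2/3-blocked stage instead.
#'
#' @param params a [ReceptorParams-class] (baseline stage).
#' @param pattern a [StimulusPattern-class] (the burst to quantify).
#' @param gridDt intensity grid (s).
#' @param tSearch peak-search window (s), see [burstResponseMetrics()].
#' @param commonDenominator logical; see Details.
#' @return data.frame with one row: spike counts `n_baseline`, `n_ly`,
#'   `n_ly_nbqx`, `n_ly_nbqx_jnj` and derived `mglur23_ratio`, `pct_ampar`,
#'   `pct_mglur1`.
#' @export
decomposeComponents <- function(params, pattern, gridDt = 1e-3, tSearch = 4,
                                commonDenominator = FALSE) {
  stim <- stimulusTimes(pattern)
  stopifnot(length(stim) >= 1)
  onset <- stim[1]
  end <- stim[length(stim)]
  if (onset < 1) stop("pattern must start at t >= 1 s (baseline window)")
  stages <- washInSeries(params)
  counts <- vapply(stages, function(p) {
    lam <- responseIntensity(p, pattern, gridDt)
    m <- burstResponseMetrics(lam, onset, end, tSearch = tSearch)
    as.numeric(evokedSpikeCount(lam, onset, m$response_start, m$half_width,
                                m$baseline_rate))
  }, numeric(1))
  denomA <- counts[2]
  denomM1 <- if (commonDenominator) counts[2] else counts[3]
  data.frame(
    n_baseline = counts[1], n_ly = counts[2], n_ly_nbqx = counts[3],
    n_ly_nbqx_jnj = counts[4],
    mglur23_ratio = if (counts[1] > 0) counts[2] / counts[1] else NA_real_,
    pct_ampar = componentPercentage(denomA, counts[3]),
    pct_mglur1 = componentPercentage(denomM1, counts[4]),
    row.names = NULL)
}
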