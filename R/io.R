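#' @include AllClasses.R
NULL

# Antagonist token <-> blocked receptor mapping. Conditions are encoded as
# ordered "+"-joined tokens mirroring cumulative wash-in ("LY", "LY+NBQX",
# "LY+NBQX+JNJ"); "baseline" is the empty set.
DRUG_TOKENS <- c(LY = "mGluR2/3", NBQX = "AMPAR", JNJ = "mGluR1",
                 CPP = "NMDAR")

parseCondition <- function(label) {
  label <- trimws(label)
  if (label == "" || tolower(label) == "baseline") return(character(0))
  toks <- strsplit(label, "+", fixed = TRUE)[[1]]
  out <- character(0)
  for (tk in toks) {
    tk <- trimws(tk)
    rec <- if (tk %in% names(DRUG_TOKENS)) DRUG_TOKENS[[tk]]
           else if (tk %in% RECEPTOR_NAMES) tk
           else stop("unknown condition token: '", tk, "'")
    out <- union(out, rec)
  }
  out
}

formatCondition <- function(blocked) {
  if (!length(blocked)) return("baseline")
  ord <- DRUG_TOKENS[match(intersect(unname(DRUG_TOKENS), blocked),
                           DRUG_TOKENS)]
  paste(names(ord), collapse = "+")
}

annotationPath <- function(path) sub("\\.csv$", ".annotations.csv", path)

#' Read a cell recording from a spike table
#'
#' The spike table is a CSV with header
#' `cell_id,protocol_id,condition,trial,spike_time_s` and one row per spike
#' (trials with zero spikes may be declared with an empty `spike_time_s`
#' field). The file must contain a single (cell, protocol, condition)
#' combination; conditions are "+"-joined antagonist tokens (`LY`, `NBQX`,
#' `JNJ`, `CPP`) or `baseline`. All type invariants are validated; malformed
#' rows and non-monotonic spike times are errors, never silently coerced.
#'
#' @param path spike table path.
#' @param stimulus optional [StimulusPattern-class] (or path to one) attached
#'   to the recording; when absent an empty pattern with the file's protocol
#'   id is used.
#' @param tStart,tStop recording window (s); `tStop` defaults to the later of
#'   last spike and last stimulus, plus 10 s.
#' @return A [CellRecording-class].
#' @export
readRecording <- function(path, stimulus = NULL, tStart = 0, tStop = NULL) {
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  need <- c("cell_id", "protocol_id", "condition", "trial", "spike_time_s")
  if (!all(need %in% names(df)))
    stop("spike table must have columns ", paste(need, collapse = ","))
  if (length(unique(df$cell_id)) > 1 || length(unique(df$protocol_id)) > 1 ||
      length(unique(df$condition)) > 1)
    stop("spike table must contain a single cell/protocol/condition; ",
         "split the file per recording")
  trialNum <- suppressWarnings(as.integer(df$trial))
  if (anyNA(trialNum))
    stop("malformed trial id at line ",
         which(is.na(trialNum))[1] + 1L)
  hasSpike <- trimws(df$spike_time_s) != ""
  spikeNum <- rep(NA_real_, nrow(df))
  spikeNum[hasSpike] <- suppressWarnings(as.numeric(df$spike_time_s[hasSpike]))
  if (any(hasSpike & is.na(spikeNum)))
    stop("malformed spike time at line ",
         which(hasSpike & is.na(spikeNum))[1] + 1L)

  if (is.character(stimulus)) stimulus <- readStimulusPattern(stimulus)
  if (is.null(stimulus))
    stimulus <- StimulusPattern(protocolId = df$protocol_id[1])

  if (is.null(tStop)) {
    lastSpike <- if (any(hasSpike)) max(spikeNum, na.rm = TRUE) else tStart
    lastStim <- if (length(stimulusTimes(stimulus)))
      max(stimulusTimes(stimulus)) else tStart
    tStop <- max(lastSpike, lastStim) + 10
  }

  trainList <- lapply(sort(unique(trialNum)), function(tr) {
    s <- spikeNum[trialNum == tr & hasSpike]
    if (is.unsorted(s, strictly = TRUE))
      stop("non-monotonic spike times in trial ", tr)
    SpikeTrain(s, trialId = tr, tStart = tStart, tStop = tStop)
  })
  CellRecording(cellId = df$cell_id[1], trials = trainList,
                stimulus = stimulus,
                condition = parseCondition(df$condition[1]),
                protocolId = df$protocol_id[1])
}

#' Write a cell recording as a spike table
#'
#' Inverse of [readRecording()]; times are written with enough digits that a
#' round trip reproduces them to well under 1 ns. Trials without spikes are
#' declared with an empty `spike_time_s` field.
#'
#' @param recording a [CellRecording-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRecording <- function(recording, path) {
  stopifnot(is(recording, "CellRecording"))
  cond <- formatCondition(recording@condition)
  rows <- lapply(recording@trials, function(tr) {
    s <- spikeTimes(tr)
    data.frame(cell_id = recording@cellId,
               protocol_id = recording@protocolId,
               condition = cond,
               trial = tr@trialId,
               spike_time_s = if (length(s)) fmtNum(s) else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = ",", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' Read a stimulus pattern
#'
#' The stimulus table is a CSV with columns `protocol_id,stimulus_time_s`;
#' interval annotations live in a sidecar `<name>.annotations.csv` with
#' columns `protocol_id,kind,t0_s,t1_s,nominal_rate` and are read back when
#' the sidecar exists. All invariants are validated on read (including the
#' rejection of overlapping same-kind annotations).
#'
#' @param path stimulus table path.
#' @return A [StimulusPattern-class].
#' @export
readStimulusPattern <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  need <- c("protocol_id", "stimulus_time_s")
  if (!all(need %in% names(df)))
    stop("stimulus table must have columns ", paste(need, collapse = ","))
  times <- suppressWarnings(as.numeric(df$stimulus_time_s))
  if (anyNA(times) && nrow(df))
    stop("malformed stimulus time at line ", which(is.na(times))[1] + 1L)
  pid <- if (nrow(df)) df$protocol_id[1] else "protocol"
  ann <- emptyAnnotations()
  sidecar <- annotationPath(path)
  if (file.exists(sidecar)) {
    adf <- utils::read.csv(sidecar, stringsAsFactors = FALSE)
    ann <- data.frame(kind = adf$kind, t0 = adf$t0_s, t1 = adf$t1_s,
                      nominal_rate = adf$nominal_rate,
                      stringsAsFactors = FALSE)
  }
  StimulusPattern(times, ann, pid)
}

#' Write a stimulus pattern (and its annotation sidecar)
#'
#' @param pattern a [StimulusPattern-class].
#' @param path output path; annotations go to `<name>.annotations.csv` when
#'   present.
#' @return `path`, invisibly.
#' @export
writeStimulusPattern <- function(pattern, path) {
  stopifnot(is(pattern, "StimulusPattern"))
  df <- data.frame(protocol_id = rep(pattern@protocolId,
                                     length(pattern@times)),
                   stimulus_time_s = fmtNum(pattern@times),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  ann <- annotations(pattern)
  if (nrow(ann)) {
    adf <- data.frame(protocol_id = pattern@protocolId, kind = ann$kind,
                      t0_s = fmtNum(ann$t0), t1_s = fmtNum(ann$t1),
                      nominal_rate = fmtNum(ann$nominal_rate),
                      stringsAsFactors = FALSE)
    utils::write.table(adf, annotationPath(path), sep = ",", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Write a metrics table
#'
#' One row per (cell, condition, protocol, metric scope) record. Columns are
#' written in the order of the first record's fields (deterministic), missing
#' values as empty fields (never the text "NA"/"nan"), and numbers with a
#' fixed format so that write -> read -> write is byte-identical.
#'
#' @param metrics data.frame (or list of identically-named lists) of records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMetricsTable <- function(metrics, path) {
  if (!is.data.frame(metrics)) {
    if (!length(metrics)) stop("no records to write")
    nms <- names(metrics[[1]])
    if (!all(vapply(metrics, function(r) identical(names(r), nms),
                    logical(1))))
      stop("records must share a schema")
    metrics <- do.call(rbind, lapply(metrics, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  }
  out <- metrics
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- fmtNum(out[[j]])
    else {
      v <- as.character(out[[j]])
      v[is.na(v)] <- ""
      out[[j]] <- v
    }
  }
  utils::write.table(out, path, sep = ",", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' Read a metrics table written by [writeMetricsTable()]
#'
#' @param path metrics table path.
#' @return data.frame; empty fields become NA, numeric columns are restored.
#' @export
readMetricsTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  df
}
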