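## Plain-text serialization of sessions: a wide CSV of counts (one row per
## trial x channel, bins as columns, NA past the trial window) plus a JSON
## sidecar with bin width, metadata and ground truth.

#' Write a session to CSV + JSON sidecar
#'
#' @param recording a [SessionRecording-class].
#' @param basename output path prefix; writes `<basename>_counts.csv` and
#'   `<basename>_meta.json` (and `<basename>_states.csv` when ground truth
#'   is present).
#' @return the written file paths, invisibly.
#' @export
writeSession <- function(recording, basename) {
  cnt <- counts(recording)
  d <- dim(cnt)
  wide <- matrix(aperm(cnt, c(3, 1, 2)), nrow = d[1] * d[2], byrow = TRUE)
  dt <- data.table::data.table(
    trial = rep(seq_len(d[2]), each = d[1]),
    channel = rep(seq_len(d[1]), d[2]))
  dt <- cbind(dt, data.table::as.data.table(wide))
  fCounts <- paste0(basename, "_counts.csv")
  data.table::fwrite(dt, fCounts)
  cd <- as.data.frame(SummarizedExperiment::colData(recording))
  rd <- as.data.frame(SummarizedExperiment::rowData(recording))
  gt <- groundTruth(recording)
  meta <- list(bin_width = binWidth(recording),
               session_type = S4Vectors::metadata(recording)$session_type,
               trial_meta = cd, channel_meta = rd)
  files <- c(fCounts)
  if (!is.null(gt)) {
    fStates <- paste0(basename, "_states.csv")
    data.table::fwrite(data.table::as.data.table(gt$states), fStates)
    meta$ground_truth <- list(r_on = gt$r_on, r_off = gt$r_off, dr = gt$dr,
                              alpha_control = c(alpha1(gt$rates_control),
                                                alpha2(gt$rates_control)),
                              alpha_attention = c(alpha1(gt$rates_attention),
                                                  alpha2(gt$rates_attention)))
    files <- c(files, fStates)
  }
  fMeta <- paste0(basename, "_meta.json")
  jsonlite::write_json(meta, fMeta, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(files, fMeta))
}

#' Read a session written by [writeSession()]
#'
#' @param basename the path prefix used when writing.
#' @return a [SessionRecording-class].
#' @export
readSession <- function(basename) {
  meta <- jsonlite::fromJSON(paste0(basename, "_meta.json"))
  dt <- data.table::fread(paste0(basename, "_counts.csv"))
  nTrials <- max(dt$trial)
  nCh <- max(dt$channel)
  binCols <- setdiff(names(dt), c("trial", "channel"))
  maxBins <- length(binCols)
  cnt <- array(NA_integer_, dim = c(nCh, nTrials, maxBins))
  m <- as.matrix(dt[, binCols, with = FALSE])
  cnt[cbind(rep(dt$channel, maxBins), rep(dt$trial, maxBins),
            rep(seq_len(maxBins), each = nrow(dt)))] <- as.integer(m)
  md <- list(bin_width = meta$bin_width, session_type = meta$session_type)
  gt <- meta$ground_truth
  if (!is.null(gt)) {
    states <- as.matrix(data.table::fread(paste0(basename, "_states.csv")))
    dimnames(states) <- NULL
    md$ground_truth <- list(states = states, r_on = gt$r_on,
                            r_off = gt$r_off, dr = gt$dr,
                            rates_control = markovRates(gt$alpha_control[1],
                                                        gt$alpha_control[2]),
                            rates_attention = markovRates(gt$alpha_attention[1],
                                                          gt$alpha_attention[2]))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cnt),
    rowData = S4Vectors::DataFrame(meta$channel_meta),
    colData = S4Vectors::DataFrame(meta$trial_meta),
    metadata = md)
  as(se, "SessionRecording")
}
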