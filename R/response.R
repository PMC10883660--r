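#' Convert a raw fluorescence trace to dF/F0
#'
#' For one stimulus presentation, F0 is the mean raw fluorescence over the
#' first \code{n_baseline_frames} frames (the stationary pre period) and
#' the trace is returned as (F - F0) / F0. Missing frames (NA, e.g. frames
#' excluded during motion correction) are skipped when computing F0 and
#' propagate as NA in the output.
#'
#' @param trace numeric vector of raw fluorescence for one presentation.
#' @param n_baseline_frames number of leading frames that form the baseline.
#' @return numeric dF/F0 vector of the same length.
#' @examples
#' compute_dff <- computeDff(c(100, 100, 150, 150), 2)  # 0 0 0.5 0.5
#' @export
computeDff <- function(trace, n_baseline_frames) {
  if (n_baseline_frames < 1 || n_baseline_frames >= length(trace))
    stop("n_baseline_frames must be >= 1 and < trace length")
  f0 <- mean(trace[seq_len(n_baseline_frames)], na.rm = TRUE)
  if (!is.finite(f0) || f0 <= 0)
    stop("degenerate baseline: F0 must be positive")
  (trace - f0) / f0
}

#' Mean response of one neuron to one stimulus
#'
#' The response is the mean dF/F0 over the moving-phase frames of each
#' repetition, averaged across repetitions. Repetition counts may differ
#' between neurons; missing frames are skipped.
#'
#' @param dff matrix of dF/F0 traces, frames x repetitions (a vector is
#'   treated as a single repetition).
#' @param moving_frames integer indices of the moving-phase frames.
#' @return list with \code{response} (scalar), \code{n_repetitions}.
#' @export
stimulusResponse <- function(dff, moving_frames) {
  dff <- as.matrix(dff)
  if (ncol(dff) < 1) stop("at least one repetition required")
  per_rep <- colMeans(dff[moving_frames, , drop = FALSE], na.rm = TRUE)
  list(response = mean(per_rep), n_repetitions = ncol(dff))
}

#' Responding criterion for one neuron x stimulus
#'
#' A neuron responds to a stimulus if its repetition-averaged moving-phase
#' mean dF/F0 strictly exceeds the baseline mean dF/F0 plus two baseline
#' standard deviations.
#'
#' @param response repetition-averaged moving-phase mean dF/F0.
#' @param baseline_mean mean baseline dF/F0 (0 by construction when the
#'   baseline defines F0).
#' @param baseline_sd SD of per-frame baseline dF/F0, pooled across
#'   repetitions of that stimulus.
#' @return logical.
#' @export
isResponding <- function(response, baseline_mean, baseline_sd) {
  stopifnot(baseline_sd >= 0)
  response > baseline_mean + 2 * baseline_sd
}

#' Active criterion for one neuron
#'
#' A neuron is active if it responds to at least one stimulus of the set.
#'
#' @param responding logical vector of per-stimulus responding flags.
#' @return logical.
#' @export
isActive <- function(responding) {
  if (length(responding) == 0) stop("empty stimulus set")
  any(responding)
}

# dF/F0 statistics for one neuron x one epoch: repetition-averaged
# moving-phase response, pooled baseline mean/SD, responding flag.
epochStats <- function(trace_mat, epoch) {
  base_idx <- seq_len(epoch$n_pre)
  mov_idx <- (epoch$n_pre + 1):(epoch$n_pre + epoch$n_move)
  dff <- apply(as.matrix(trace_mat), 2, computeDff,
               n_baseline_frames = epoch$n_pre)
  base_vals <- as.vector(dff[base_idx, , drop = FALSE])
  sr <- stimulusResponse(dff, mov_idx)
  bm <- mean(base_vals, na.rm = TRUE)
  bs <- sd(base_vals, na.rm = TRUE)
  if (is.na(bs)) bs <- 0
  list(response = sr$response, n_repetitions = sr$n_repetitions,
       baseline_mean = bm, baseline_sd = bs,
       responding = isResponding(sr$response, bm, bs),
       rep_responses = colMeans(dff[mov_idx, , drop = FALSE], na.rm = TRUE))
}

#' Build the neuron x stimulus response table
#'
#' Runs dF/F0 conversion, moving-phase averaging and the responding/active
#' criteria for every neuron and every non-discarded stimulus epoch, and
#' returns a \linkS4class{SummarizedExperiment}: rows are neurons (rowData:
#' id, centroid, side, active flag), columns are stimuli (colData: the epoch
#' table), assays \code{response}, \code{baseline_mean}, \code{baseline_sd},
#' \code{responding}, \code{n_repetitions}. Per-presentation responses (the
#' shuffle-test unit) are kept in \code{metadata()$rep_responses}, a list
#' indexed [neuron][epoch].
#'
#' Epochs flagged \code{discard} (duplicated first stimulus of a block) are
#' dropped before any statistic.
#'
#' @param dataset a [SyntheticDataset-class], or a list of
#'   [NeuronRecord-class] with \code{protocol} supplied.
#' @param protocol the [StimulusProtocol-class] (taken from the dataset when
#'   omitted).
#' @return a SummarizedExperiment.
#' @export
responseTable <- function(dataset, protocol = NULL) {
  if (is(dataset, "SyntheticDataset")) {
    neurons <- dataset@neurons
    if (is.null(protocol)) protocol <- dataset@protocol
  } else {
    neurons <- dataset
    if (is.null(protocol)) stop("protocol required")
  }
  ep_all <- epochs(protocol)
  keep <- which(!ep_all$discard)
  ep <- ep_all[keep, , drop = FALSE]
  n_n <- length(neurons); n_s <- nrow(ep)

  assay_names <- c("response", "baseline_mean", "baseline_sd",
                   "responding", "n_repetitions")
  assays <- lapply(assay_names, function(a) matrix(NA_real_, n_n, n_s))
  names(assays) <- assay_names
  rep_responses <- vector("list", n_n)

  for (i in seq_len(n_n)) {
    nr <- neurons[[i]]
    rep_responses[[i]] <- vector("list", n_s)
    for (j in seq_len(n_s)) {
      st <- epochStats(nr@traces[[keep[j]]], ep[j, ])
      assays$response[i, j] <- st$response
      assays$baseline_mean[i, j] <- st$baseline_mean
      assays$baseline_sd[i, j] <- st$baseline_sd
      assays$responding[i, j] <- as.numeric(st$responding)
      assays$n_repetitions[i, j] <- st$n_repetitions
      rep_responses[[i]][[j]] <- st$rep_responses
    }
  }

  ids <- vapply(neurons, function(x) x@id, character(1))
  cen <- t(vapply(neurons, function(x) x@centroid, numeric(3)))
  rd <- S4Vectors::DataFrame(
    id = ids, rc = cen[, 1], lr = cen[, 2], dv = cen[, 3],
    side = vapply(neurons, function(x) x@side, character(1)),
    active = apply(assays$responding == 1, 1, isActive)
  )
  rownames(rd) <- ids
  for (a in assay_names) dimnames(assays[[a]]) <- list(ids, ep$stim_id)
  names(rep_responses) <- ids

  SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = rd,
    colData = S4Vectors::DataFrame(ep, row.names = ep$stim_id),
    metadata = list(rep_responses = rep_responses,
                    frame_period_s = protocol@frame_period_s)
  )
}

#' Round-trip a response table to CSV
#'
#' One row per neuron x stimulus, flags as 0/1 columns.
#'
#' @param se SummarizedExperiment from [responseTable()].
#' @param path CSV path.
#' @return (write) the path, invisibly; (read) a long-format data.frame.
#' @export
writeResponseCsv <- function(se, path) {
  ids <- rownames(se); stims <- colnames(se)
  long <- do.call(rbind, lapply(seq_along(stims), function(j) {
    data.frame(
      id = ids, stim_id = stims[j],
      response = SummarizedExperiment::assay(se, "response")[, j],
      baseline_mean = SummarizedExperiment::assay(se, "baseline_mean")[, j],
      baseline_sd = SummarizedExperiment::assay(se, "baseline_sd")[, j],
      responding = as.integer(
        SummarizedExperiment::assay(se, "responding")[, j]),
      n_repetitions = SummarizedExperiment::assay(se, "n_repetitions")[, j],
      active = as.integer(SummarizedExperiment::rowData(se)$active),
      row.names = NULL
    )
  }))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeResponseCsv
#' @param path CSV path written by \code{writeResponseCsv}.
#' @export
readResponseCsv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
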