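#' Voxel-selectivity thresholds
#'
#' The category thresholds applied to voxelwise mean dF/F0 responses:
#' forward-selective voxels need cos(PD) > 0 and mean dF/F0 > 0.5 over the
#' three forward-component stimuli; backward-selective voxels cos(PD) < 0
#' and > 0.25 over the three backward stimuli (the asymmetry reflects the
#' weaker backward response amplitudes); rotation-selective voxels need
#' > 0.75 to one rotational direction and < 0.25 to the other; the
#' left/right comparison selects voxels above 0.25 in either direction
#' group. Labeled voxels are those whose mean brightness exceeds background
#' by \code{brightness_offset} camera gray values.
#'
#' @param forward_thresh,backward_thresh,rot_high,rot_low,lr_thresh dF/F0
#'   thresholds.
#' @param brightness_offset gray values above background.
#' @return list of class "VoxelCategoryConfig".
#' @export
voxelCategoryConfig <- function(forward_thresh = 0.5, backward_thresh = 0.25,
                                rot_high = 0.75, rot_low = 0.25,
                                lr_thresh = 0.25, brightness_offset = 2) {
  stopifnot(rot_high > rot_low, forward_thresh >= 0, backward_thresh >= 0,
            rot_low >= 0, lr_thresh >= 0)
  structure(list(forward_thresh = forward_thresh,
                 backward_thresh = backward_thresh,
                 rot_high = rot_high, rot_low = rot_low,
                 lr_thresh = lr_thresh,
                 brightness_offset = brightness_offset),
            class = "VoxelCategoryConfig")
}

#' Select labeled voxels by brightness
#'
#' @param brightness 3D array of mean raw brightness (camera gray values).
#' @param background background brightness estimate (scalar).
#' @param offset required exceedance (gray values); strict.
#' @return logical array of the same dimension.
#' @export
labelVoxels <- function(brightness, background, offset = 2) {
  stopifnot(all(is.finite(brightness)))
  brightness > background + offset
}

#' Per-stimulus voxel responses
#'
#' Computes the repetition-averaged mean dF/F0 response of every voxel to
#' every stimulus. Two input forms are supported: a 4D raw-fluorescence
#' time series (x, y, z, frame) together with the protocol that timestamps
#' it (per repetition, F0 is the mean over the stationary pre frames and F
#' the mean over the moving frames of that presentation; responses are then
#' averaged across repetitions), or an already-per-stimulus 5D stack
#' (x, y, z, stimulus, repetition) which is averaged over repetitions.
#'
#' @param x 4D time-series array or 5D per-stimulus response stack.
#' @param protocol [StimulusProtocol-class]; required for the time-series
#'   form. Epochs are assumed contiguous in acquisition order, the whole
#'   protocol repeated \code{n_repetitions} times.
#' @param n_repetitions protocol repeats in the time series.
#' @return 4D array (x, y, z, stimulus) of mean dF/F0; stimulus order
#'   follows the non-discarded protocol epochs.
#' @export
voxelResponses <- function(x, protocol = NULL, n_repetitions = 1) {
  nd <- length(dim(x))
  if (nd == 5) {
    d <- dim(x)
    out <- array(0, d[1:4])
    for (j in seq_len(d[4]))
      out[, , , j] <- apply(x[, , , j, , drop = FALSE], 1:3, mean)
    return(out)
  }
  if (nd != 4 || is.null(protocol))
    stop("need a 5D per-stimulus stack, or a 4D time series plus protocol")
  ep <- epochs(protocol)
  len <- ep$n_pre + ep$n_move + ep$n_post
  total <- sum(len)
  if (dim(x)[4] < total * n_repetitions)
    stop("stimulus window outside recording")
  keep <- which(!ep$discard)
  d <- dim(x)[1:3]
  out <- array(0, c(d, length(keep)))
  starts <- cumsum(c(0, len[-length(len)]))
  for (jj in seq_along(keep)) {
    j <- keep[jj]
    acc <- array(0, d)
    for (r in seq_len(n_repetitions)) {
      off <- (r - 1) * total + starts[j]
      f0 <- apply(x[, , , off + seq_len(ep$n_pre[j]), drop = FALSE], 1:3,
                  mean)
      fm <- apply(x[, , , off + ep$n_pre[j] + seq_len(ep$n_move[j]),
                    drop = FALSE], 1:3, mean)
      acc <- acc + (fm - f0) / f0
    }
    out[, , , jj] <- acc / n_repetitions
  }
  out
}

# Per-voxel preferred direction by the same rectified vector-sum rule as
# computeDsi, vectorized over voxels. NA where all rectified responses are 0.
voxelPd <- function(resp_mat, directions_deg) {
  r <- pmax(resp_mat, 0)
  th <- deg2rad(directions_deg)
  vx <- r %*% cos(th); vy <- r %*% sin(th)
  s <- rowSums(r)
  pd <- wrapAngle(atan2(vy, vx) * 180 / pi)
  pd[s <= 0] <- NA_real_
  as.vector(pd)
}

#' Categorize voxels by motion preference
#'
#' Applies the threshold rules of [voxelCategoryConfig()] to a per-stimulus
#' response stack within the labeled-voxel mask. The per-voxel preferred
#' direction is the rectified vector sum over the eight translational
#' responses. Forward stimuli are the three with a forward component
#' (-45, 0, +45 degrees), backward the three with a backward component
#' (135, 180, 225); the left/right comparison uses left, right,
#' forward-left and forward-right (270, 90, 315, 45) and assigns a voxel to
#' the stronger group. All comparisons are strict.
#'
#' @param responses 4D array (x, y, z, stimulus) from [voxelResponses()] or
#'   [generateVoxelVolume()].
#' @param stimuli epoch table describing the 4th dimension (columns kind,
#'   direction_deg, rotation_label).
#' @param mask logical labeled-voxel array, from [labelVoxels()].
#' @param config a [voxelCategoryConfig()].
#' @return list of logical arrays: forward, backward, cw_rot, ccw_rot,
#'   leftward, rightward; plus \code{pd} (per-voxel PD array, NA outside
#'   the mask).
#' @export
categorizeVoxels <- function(responses, stimuli, mask = NULL,
                             config = voxelCategoryConfig()) {
  d <- dim(responses)[1:3]
  n_stim <- dim(responses)[4]
  stopifnot(nrow(stimuli) == n_stim)
  if (is.null(mask)) mask <- array(TRUE, d)
  rm_ <- matrix(responses, prod(d), n_stim)
  tr <- which(stimuli$kind == "translation")
  dirs <- stimuli$direction_deg[tr]
  stopifnot(length(tr) == 8)

  pd <- voxelPd(rm_[, tr, drop = FALSE], dirs)
  cospd <- cos(deg2rad(pd))

  dircol <- function(a) tr[which(((dirs - a) %% 360) == 0)]
  mean_over <- function(angles) {
    cols <- vapply(angles, dircol, integer(1))
    rowMeans(rm_[, cols, drop = FALSE])
  }
  fwd_mean <- mean_over(c(-45, 0, 45))
  bwd_mean <- mean_over(c(135, 180, 225))
  left_mean <- mean_over(c(270, 315))
  right_mean <- mean_over(c(90, 45))

  cw_col <- which(stimuli$rotation_label == "CW")
  ccw_col <- which(stimuli$rotation_label == "CCW")
  cw <- if (length(cw_col)) rm_[, cw_col] else rep(0, nrow(rm_))
  ccw <- if (length(ccw_col)) rm_[, ccw_col] else rep(0, nrow(rm_))

  mk <- function(v) {
    out <- array(v & as.vector(mask), d)
    out[is.na(out)] <- FALSE
    out
  }
  list(
    forward = mk(!is.na(cospd) & cospd > 0 & fwd_mean > config$forward_thresh),
    backward = mk(!is.na(cospd) & cospd < 0 &
                    bwd_mean > config$backward_thresh),
    cw_rot = mk(cw > config$rot_high & ccw < config$rot_low),
    ccw_rot = mk(ccw > config$rot_high & cw < config$rot_low),
    leftward = mk(pmax(left_mean, right_mean) > config$lr_thresh &
                    left_mean > right_mean),
    rightward = mk(pmax(left_mean, right_mean) > config$lr_thresh &
                     right_mean > left_mean),
    pd = array(ifelse(as.vector(mask), pd, NA_real_), d)
  )
}

#' Project a category volume to a 2D count map
#'
#' Sums category voxels along one axis. With \code{split_halves}, the two
#' halves of the image along its first dimension (by default split at the
#' middle row, configurable with \code{split_at}) are normalized
#' independently to their own maxima, so that a dense compartment does not
#' visually swamp a sparse one; an all-zero half stays zero.
#'
#' @param volume logical or numeric 3D array.
#' @param axis axis to collapse (1, 2 or 3).
#' @param split_halves normalize the two image halves independently.
#' @param split_at row index ending the first half; default middle.
#' @return numeric matrix (counts, or per-half normalized values).
#' @export
projectMap <- function(volume, axis = 3, split_halves = FALSE,
                       split_at = NULL) {
  stopifnot(length(dim(volume)) == 3, axis %in% 1:3)
  img <- apply(volume, setdiff(1:3, axis), sum)
  if (!split_halves) return(img)
  if (is.null(split_at)) split_at <- nrow(img) %/% 2
  normHalf <- function(m) {
    mx <- max(m)
    if (mx > 0) m / mx else m
  }
  rbind(normHalf(img[seq_len(split_at), , drop = FALSE]),
        normHalf(img[seq(split_at + 1, nrow(img)), , drop = FALSE]))
}

#' Read and write volumes as multi-page TIFF
#'
#' Pages are z slices, stored as 32-bit samples scaled to [0, 1]; the
#' original value range is kept in a small JSON sidecar (\code{<path>.json})
#' and restored on read, so numeric volumes (dF/F0, brightness) and
#' logical category masks both round-trip.
#'
#' @param volume numeric or logical 3D array.
#' @param path TIFF path.
#' @return (write) the path invisibly; (read) a numeric 3D array.
#' @export
writeVolumeTiff <- function(volume, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the tiff package is required for TIFF volume I/O")
  stopifnot(length(dim(volume)) == 3)
  rng <- range(volume)
  span <- if (diff(rng) > 0) diff(rng) else 1
  pages <- lapply(seq_len(dim(volume)[3]),
                  function(k) (volume[, , k] - rng[1]) / span)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(min = rng[1], max = rng[2]),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeVolumeTiff
#' @export
readVolumeTiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the tiff package is required for TIFF volume I/O")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  vol <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    rng <- jsonlite::read_json(side, simplifyVector = TRUE)
    span <- if (rng$max > rng$min) rng$max - rng$min else 1
    vol <- vol * span + rng$min
  }
  vol
}

#' Partition values at the 95th and 99th percentiles
#'
#' Splits values into the top 1%, the next 4% (between the 95th and 99th
#' percentiles) and the remaining 95%, using the package's empirical
#' quantile convention (linear interpolation, strict exceedance).
#'
#' @param values numeric vector (at least one value).
#' @param cuts two percentiles, default c(95, 99).
#' @return factor with levels "rest", "top5", "top1" aligned with
#'   \code{values}.
#' @export
percentilePartition <- function(values, cuts = c(95, 99)) {
  if (length(values) == 0) stop("empty input")
  stopifnot(length(cuts) == 2, cuts[1] < cuts[2])
  q <- empiricalQuantile(values, cuts / 100)
  lab <- ifelse(values > q[2], "top1", ifelse(values > q[1], "top5", "rest"))
  factor(lab, levels = c("rest", "top5", "top1"))
}
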