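#' @import methods
#' @importFrom stats dnorm quantile rnorm runif sd density setNames
#' @importFrom utils read.csv write.csv head
NULL

#' Stimulus protocol for visual-motion experiments
#'
#' An ordered set of stimulus epochs. Each epoch is one grating or windmill
#' presentation with a 3-phase temporal structure: a stationary pre period
#' (the dF/F0 baseline), a moving period (the response window), and a
#' stationary post period. Translational epochs carry a direction in degrees
#' (0 = forward, 90 = rightward, 180 = backward, -90/270 = leftward);
#' rotational epochs carry a label among CW, CCW, CONV, DIV.
#'
#' @slot epochs data.frame with one row per epoch and columns
#'   \code{block} (left/right/both), \code{kind} (translation/rotation),
#'   \code{direction_deg}, \code{rotation_label}, \code{eye},
#'   \code{n_pre}, \code{n_move}, \code{n_post} (frame counts),
#'   \code{discard} (logical; duplicated first stimulus of a block),
#'   \code{stim_id} (stable stimulus identity label).
#' @slot frame_period_s seconds per imaging frame.
#' @slot seed integer seed used to draw the direction order.
#'
#' @seealso [generateProtocol()]
#' @export
setClass("StimulusProtocol",
  representation(
    epochs = "data.frame",
    frame_period_s = "numeric",
    seed = "integer"
  )
)

setValidity("StimulusProtocol", function(object) {
  ep <- object@epochs
  need <- c("block", "kind", "direction_deg", "rotation_label", "eye",
            "n_pre", "n_move", "n_post", "discard", "stim_id")
  if (!all(need %in% names(ep)))
    return(paste("epochs must have columns:", paste(need, collapse = ", ")))
  if (nrow(ep) == 0) return("protocol has no epochs")
  if (any(ep$n_pre <= 0 | ep$n_move <= 0 | ep$n_post <= 0))
    return("all phase frame counts must be positive")
  tr <- ep$kind == "translation"
  if (any(tr & !is.na(ep$rotation_label)))
    return("translation epochs must not carry a rotation label")
  if (any(!tr & !is.na(ep$direction_deg)))
    return("rotation epochs must not carry a direction")
  if (length(object@frame_period_s) != 1 || object@frame_period_s <= 0)
    return("frame_period_s must be a single positive number")
  TRUE
})

#' Single-neuron record: centroid plus fluorescence traces
#'
#' @slot id character identifier.
#' @slot centroid numeric length-3 position in the registered frame,
#'   ordered (rostro-caudal, left-right, dorso-ventral), micrometres.
#' @slot side "left" or "right" relative to the midline (decides which eye
#'   is contra- vs ipsilateral).
#' @slot traces list with one element per protocol epoch; each element a
#'   numeric matrix of raw fluorescence, frames x repetitions.
#' @export
setClass("NeuronRecord",
  representation(
    id = "character",
    centroid = "numeric",
    side = "character",
    traces = "list"
  )
)

setValidity("NeuronRecord", function(object) {
  if (length(object@centroid) != 3) return("centroid must have length 3")
  if (!object@side %in% c("left", "right")) return("side must be left or right")
  if (length(object@traces) == 0) return("record has no traces")
  TRUE
})

#' Synthetic dataset: protocol, neurons, ground truth, anatomy
#'
#' @slot protocol the [StimulusProtocol-class] the traces follow.
#' @slot neurons list of [NeuronRecord-class].
#' @slot groundTruth data.frame of per-neuron generating parameters
#'   (class label, preferred direction, tuning concentration, eye weights...).
#' @slot anatomy list of data.frames: \code{somata} and \code{terminals},
#'   each with columns x, y(, z) and \code{class}.
#' @export
setClass("SyntheticDataset",
  representation(
    protocol = "StimulusProtocol",
    neurons = "list",
    groundTruth = "data.frame",
    anatomy = "list"
  )
)

setValidity("SyntheticDataset", function(object) {
  n_ep <- nrow(object@protocol@epochs)
  ok <- vapply(object@neurons, function(nr) {
    length(nr@traces) == n_ep &&
      all(vapply(nr@traces, function(m) ncol(m) >= 1, logical(1)))
  }, logical(1))
  if (!all(ok)) return("every neuron needs >= 1 trace per protocol epoch")
  if (nrow(object@groundTruth) != length(object@neurons))
    return("groundTruth must have one row per neuron")
  TRUE
})

#' Labeled 2D point set (soma centroids, axon-terminal endpoints, voxels)
#'
#' @slot coords numeric matrix, n x 2, in pixels of the registered frame.
#' @slot label class name.
#' @slot projection which 2D view the points live in
#'   ("z_projection" for the cerebellar cortex, "lateral_projection" for
#'   the inferior olive).
#' @export
setClass("PointSet2D",
  representation(
    coords = "matrix",
    label = "character",
    projection = "character"
  ),
  prototype(label = NA_character_, projection = "z_projection")
)

setValidity("PointSet2D", function(object) {
  if (ncol(object@coords) != 2) return("coords must have 2 columns")
  if (!is.numeric(object@coords)) return("coords must be numeric")
  TRUE
})

#' 2D kernel density estimate on a regular grid
#'
#' Normalized so that sum(z) * prod(grid spacing) == 1.
#'
#' @slot x,y grid node coordinates (regularly spaced).
#' @slot z density matrix, length(x) by length(y).
#' @slot kernelSd Gaussian kernel SD in the same units as x and y.
#' @export
setClass("KernelDensity2D",
  representation(
    x = "numeric",
    y = "numeric",
    z = "matrix",
    kernelSd = "numeric"
  )
)

setValidity("KernelDensity2D", function(object) {
  if (!all(dim(object@z) == c(length(object@x), length(object@y))))
    return("z must be length(x) by length(y)")
  if (object@kernelSd <= 0) return("kernelSd must be positive")
  area <- .gridCellArea(object@x, object@y)
  tot <- sum(object@z) * area
  if (abs(tot - 1) > 1e-6)
    return(sprintf("density must integrate to 1 over the grid (got %.8f)", tot))
  TRUE
})

#' Result of the functional/anatomical overlap test
#'
#' Holds the 2x2 matching-score table for two anatomical and two functional
#' classes, the matching index (mean diagonal MS minus mean off-diagonal MS),
#' its bootstrap null distribution, and the one-tailed Bonferroni-corrected
#' significance decision.
#'
#' @slot ms 2x2 numeric matrix; rows anatomy classes, columns function classes.
#' @slot mi matching index in [-1, 1].
#' @slot nullMi bootstrap null distribution of the MI.
#' @slot thresholdPercentile percentile of the null used as threshold
#'   (100 - 100 * alpha / n_comparisons).
#' @slot threshold the empirical null quantile at that percentile.
#' @slot significant TRUE iff mi > threshold (strict).
#' @export
setClass("MatchResult",
  representation(
    ms = "matrix",
    mi = "numeric",
    nullMi = "numeric",
    thresholdPercentile = "numeric",
    threshold = "numeric",
    significant = "logical"
  )
)

setValidity("MatchResult", function(object) {
  if (!all(dim(object@ms) == c(2, 2))) return("ms must be 2x2")
  if (any(object@ms < -1e-9 | object@ms > 1 + 1e-9))
    return("matching scores must lie in [0, 1]")
  if (abs(object@mi) > 1 + 1e-9) return("mi must lie in [-1, 1]")
  TRUE
})
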