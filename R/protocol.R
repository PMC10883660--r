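#' Build a stimulus protocol
#'
#' Assembles the ordered epoch table for one imaging plane: translational
#' gratings in \code{n_directions} directions presented in a seeded random
#' order, optionally followed by clockwise (CW) and counter-clockwise (CCW)
#' windmill rotation, and optionally converging/diverging rotation in the
#' binocular block. With \code{monocular_blocks = TRUE} the set is presented
#' three times — to the left eye, the right eye, and binocularly, in that
#' order — and the first stimulus of each block is duplicated with its first
#' presentation flagged \code{discard} (it absorbs the stimulus-onset
#' transient and is dropped from all statistics).
#'
#' Phase durations are converted to frame counts by rounding each phase
#' independently to the nearest frame; at the default 0.3456 s frame period
#' the 6 / 10 / 5.4 s phases span 17 + 29 + 16 = 62 frames.
#'
#' @param n_directions number of translation directions; must divide 360.
#' @param include_rotations add CW and CCW windmill epochs to each block.
#' @param include_conv_div add converging/diverging rotation (binocular
#'   block only).
#' @param monocular_blocks present left-eye, right-eye and binocular blocks.
#' @param frame_period_s seconds per imaging frame.
#' @param phase_durations_s numeric length 3: stationary pre, moving,
#'   stationary post durations in seconds.
#' @param seed integer; the direction permutations are drawn from it.
#' @return A [StimulusProtocol-class].
#' @examples
#' p <- generateProtocol(seed = 1)
#' nEpochs(p)       # 10: 8 directions + CW + CCW
#' totalFrames(p)   # 620
#' @export
generateProtocol <- function(n_directions = 8,
                             include_rotations = TRUE,
                             include_conv_div = FALSE,
                             monocular_blocks = FALSE,
                             frame_period_s = 0.3456,
                             phase_durations_s = c(6, 10, 5.4),
                             seed = 1L) {
  if (length(phase_durations_s) != 3 || any(phase_durations_s <= 0))
    stop("phase_durations_s must be 3 positive durations")
  if (n_directions < 1 || 360 %% n_directions != 0)
    stop("n_directions must divide 360")
  if (frame_period_s <= 0) stop("frame_period_s must be positive")

  nf <- pmax(1L, as.integer(round(phase_durations_s / frame_period_s)))
  dirs <- seq(0, 360 - 360 / n_directions, by = 360 / n_directions)
  blocks <- if (monocular_blocks) c("left", "right", "both") else "both"

  epoch_rows <- withSeed(seed, {
    lapply(blocks, function(bl) {
      ord <- sample(dirs)
      ids <- sprintf("T%03d", ord)
      df <- data.frame(
        block = bl, kind = "translation",
        direction_deg = ord, rotation_label = NA_character_,
        stim_id = ids, stringsAsFactors = FALSE
      )
      if (include_rotations) {
        rot <- c("CW", "CCW")
        if (include_conv_div && bl == "both") rot <- c(rot, "CONV", "DIV")
        df <- rbind(df, data.frame(
          block = bl, kind = "rotation",
          direction_deg = NA_real_, rotation_label = rot,
          stim_id = rot, stringsAsFactors = FALSE
        ))
      }
      df$discard <- FALSE
      if (monocular_blocks) df <- rbind(transform(df[1, ], discard = TRUE), df)
      df
    })
  })
  ep <- do.call(rbind, epoch_rows)
  rownames(ep) <- NULL
  ep$eye <- ep$block
  ep$n_pre <- nf[1]; ep$n_move <- nf[2]; ep$n_post <- nf[3]

  new("StimulusProtocol", epochs = ep,
      frame_period_s = frame_period_s, seed = as.integer(seed))
}

#' @describeIn StimulusProtocol-class the epoch table.
#' @param object,x a \code{StimulusProtocol}.
#' @export
setGeneric("epochs", function(x) standardGeneric("epochs"))

#' @rdname StimulusProtocol-class
#' @export
setMethod("epochs", "StimulusProtocol", function(x) x@epochs)

#' @rdname StimulusProtocol-class
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' @rdname StimulusProtocol-class
#' @export
setMethod("nEpochs", "StimulusProtocol", function(x) nrow(x@epochs))

#' @describeIn StimulusProtocol-class total imaging frames spanned by the
#'   protocol (all epochs, including any discard-flagged presentations).
#' @export
setGeneric("totalFrames", function(x) standardGeneric("totalFrames"))

#' @rdname StimulusProtocol-class
#' @export
setMethod("totalFrames", "StimulusProtocol", function(x) {
  ep <- x@epochs
  sum(ep$n_pre + ep$n_move + ep$n_post)
})

#' @describeIn StimulusProtocol-class number of distinct stimuli per block
#'   (duplicated discard presentations not counted).
#' @param block block name ("left", "right" or "both").
#' @export
nStimuli <- function(x, block = "both") {
  stopifnot(is(x, "StimulusProtocol"))
  ep <- x@epochs
  sum(ep$block == block & !ep$discard)
}

setMethod("show", "StimulusProtocol", function(object) {
  ep <- object@epochs
  cat("StimulusProtocol:", nrow(ep), "epochs in",
      length(unique(ep$block)), "block(s);",
      sum(ep$kind == "translation" & !ep$discard), "translation /",
      sum(ep$kind == "rotation" & !ep$discard), "rotation stimuli\n")
  cat(sprintf("  frames per epoch: %d + %d + %d = %d  (%.4f s/frame)\n",
              ep$n_pre[1], ep$n_move[1], ep$n_post[1],
              ep$n_pre[1] + ep$n_move[1] + ep$n_post[1],
              object@frame_period_s))
  cat("  total frames:", totalFrames(object), " seed:", object@seed, "\n")
})

#' Protocol timing helpers
#'
#' \code{stimulusDuration} sums the three phase durations;
#' \code{framesPerStimulus} converts them to imaging frames (each phase
#' rounded to the nearest frame); \code{volumeRate} gives the volumetric
#' acquisition rate of a plane-scanned microscope.
#'
#' @param phase_durations_s numeric length 3, seconds.
#' @param frame_period_s seconds per frame.
#' @param plane_rate_hz planes acquired per second.
#' @param n_planes planes per volume.
#' @return A single number: seconds, frames, or Hz.
#' @examples
#' stimulusDuration(c(6, 10, 5.4))            # 21.4 s
#' framesPerStimulus(c(6, 10, 5.4), 0.3456)   # 62 frames
#' volumeRate(100, 44)                        # 2.3 Hz
#' @export
stimulusDuration <- function(phase_durations_s = c(6, 10, 5.4)) {
  stopifnot(length(phase_durations_s) == 3, all(phase_durations_s > 0))
  sum(phase_durations_s)
}

#' @rdname stimulusDuration
#' @export
framesPerStimulus <- function(phase_durations_s = c(6, 10, 5.4),
                              frame_period_s = 0.3456) {
  stopifnot(frame_period_s > 0)
  sum(pmax(1L, as.integer(round(phase_durations_s / frame_period_s))))
}

#' @rdname stimulusDuration
#' @export
volumeRate <- function(plane_rate_hz, n_planes) {
  stopifnot(plane_rate_hz > 0, n_planes >= 1)
  plane_rate_hz / n_planes
}
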