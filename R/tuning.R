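#' Direction selectivity index and preferred direction
#'
#' The DSI is the magnitude of the vector sum of the eight direction-labeled
#' mean responses divided by their scalar sum; the preferred direction (PD)
#' is the angle of that vector (0 degrees = forward, 90 = rightward). A
#' neuron responding to a single direction has DSI 1; equal responses in all
#' directions give DSI 0. Negative mean responses are rectified to 0 before
#' the sum, which guarantees DSI in [0, 1] and the single-stimulus anchor.
#'
#' @param responses numeric vector of 8 mean responses.
#' @param directions_deg their directions; must be 8 angles at 45-degree
#'   spacing.
#' @return list with \code{dsi} and \code{pd_deg} (wrapped to (-180, 180]).
#' @examples
#' computeDsi(c(1, 0, 0, 0, 0, 0, 0, 0))           # dsi 1, pd 0
#' computeDsi(rep(0.3, 8))                         # dsi 0
#' computeDsi(c(1, 1, 0, 0, 0, 0, 0, 0))$dsi       # cos(22.5 deg)
#' @export
computeDsi <- function(responses, directions_deg = seq(0, 315, by = 45)) {
  if (length(responses) != 8 || length(directions_deg) != 8)
    stop("exactly 8 direction-labeled responses required")
  if (any(sort(wrapAngle(directions_deg) %% 360) != seq(0, 315, by = 45)))
    stop("directions must be 8 angles at 45-degree spacing")
  r <- pmax(responses, 0)
  s <- sum(r)
  if (s <= 0)
    stop("undefined tuning: all responses <= 0", call. = FALSE)
  th <- deg2rad(directions_deg)
  vx <- sum(r * cos(th)); vy <- sum(r * sin(th))
  list(dsi = sqrt(vx^2 + vy^2) / s,
       pd_deg = wrapAngle(atan2(vy, vx) * 180 / pi))
}

#' Shuffle test for direction selectivity
#'
#' Tests the null hypothesis that a neuron is not direction selective by
#' randomly permuting direction labels across individual stimulus
#' presentations, recomputing repetition means and the DSI each time
#' (\code{n_shuffles} draws), and comparing the observed DSI with the
#' (1 - alpha) empirical quantile of the null distribution (linear
#' interpolation; strict exceedance). Deterministic given \code{seed}.
#'
#' @param rep_responses per-presentation responses: a list of 8 numeric
#'   vectors (one per direction, one entry per repetition), or a matrix with
#'   8 columns.
#' @param directions_deg direction of each list element / column.
#' @param n_shuffles number of label permutations.
#' @param alpha significance level.
#' @param seed integer seed, or NULL.
#' @return list with \code{dsi}, \code{pd_deg},
#'   \code{is_direction_selective}, \code{null_dsi} (length
#'   \code{n_shuffles}), \code{threshold}.
#' @export
shuffleTest <- function(rep_responses, directions_deg = seq(0, 315, by = 45),
                        n_shuffles = 1000, alpha = 0.05, seed = NULL) {
  if (is.matrix(rep_responses))
    rep_responses <- lapply(seq_len(ncol(rep_responses)),
                            function(j) rep_responses[, j])
  stopifnot(length(rep_responses) == 8,
            all(lengths(rep_responses) >= 1))
  obs_means <- vapply(rep_responses, mean, 1)
  obs <- computeDsi(obs_means, directions_deg)

  flat <- unlist(rep_responses, use.names = FALSE)
  if (length(unique(flat)) < 2) {
    warning("degenerate null: fewer than 2 distinct response values")
    return(list(dsi = obs$dsi, pd_deg = obs$pd_deg,
                is_direction_selective = FALSE,
                null_dsi = rep(obs$dsi, n_shuffles), threshold = obs$dsi))
  }
  grp <- rep(seq_len(8), lengths(rep_responses))
  null_dsi <- withSeed(seed, shuffleNullDsi(flat, grp, directions_deg,
                                            n_shuffles))
  thr <- empiricalQuantile(null_dsi, 1 - alpha)
  list(dsi = obs$dsi, pd_deg = obs$pd_deg,
       is_direction_selective = obs$dsi > thr,
       null_dsi = null_dsi, threshold = thr)
}

# Vectorized null: each column of the permutation matrix is one shuffle of
# the presentation responses; direction means are taken over the fixed
# grouping, rectified, and reduced to a DSI.
shuffleNullDsi <- function(flat, grp, directions_deg, n_shuffles) {
  n <- length(flat)
  ord <- apply(matrix(runif(n * n_shuffles), n), 2, order)
  perm <- matrix(flat[ord], n, n_shuffles)
  G <- outer(seq_len(8), grp, "==") + 0           # 8 x n indicator
  cnt <- as.vector(G %*% rep(1, n))
  means <- (G %*% perm) / cnt                     # 8 x n_shuffles
  means[means < 0] <- 0
  th <- deg2rad(directions_deg)
  vx <- as.vector(cos(th) %*% means)
  vy <- as.vector(sin(th) %*% means)
  s <- as.vector(rep(1, 8) %*% means)
  dsi <- sqrt(vx^2 + vy^2) / s
  dsi[s <= 0] <- 0   # all-rectified shuffle: treated as untuned
  dsi
}

#' Rotation-response class of a direction-selective neuron
#'
#' Direction-selective neurons are subdivided by whether they also respond
#' to clockwise and/or counter-clockwise rotation: "DS" (translation only),
#' "DS+CW", "DS+CCW", "DS+CW+CCW". Non-selective neurons get "none".
#'
#' @param is_direction_selective logical.
#' @param responding_cw,responding_ccw responding flags for the two
#'   rotational stimuli.
#' @return character class label.
#' @export
classifyRotation <- function(is_direction_selective, responding_cw,
                             responding_ccw) {
  if (!is_direction_selective) return("none")
  if (responding_cw && responding_ccw) "DS+CW+CCW"
  else if (responding_cw) "DS+CW"
  else if (responding_ccw) "DS+CCW"
  else "DS"
}

#' Split neurons into forward- and backward-preferring by the PD cosine
#'
#' Forward iff cos(PD) > 0, backward iff cos(PD) < 0. The measure-zero
#' boundary cos(PD) == 0 (PD exactly +-90 degrees) is assigned to neither
#' group and reported in the \code{boundary} element.
#'
#' @param pd_deg numeric vector of preferred directions (degrees).
#' @return list of index vectors \code{forward}, \code{backward},
#'   \code{boundary}.
#' @export
pdCosineSplit <- function(pd_deg) {
  cs <- cos(deg2rad(pd_deg))
  eps <- 1e-12
  list(forward = which(cs > eps),
       backward = which(cs < -eps),
       boundary = which(abs(cs) <= eps))
}

#' Tuning analysis of a whole response table
#'
#' Runs [computeDsi()] + [shuffleTest()] on the binocular translational
#' responses of every active neuron in a [responseTable()] result, flags
#' direction selectivity, and attaches the rotation-response class from the
#' CW/CCW responding flags. Neurons that are not active, or whose rectified
#' responses are all zero, are reported with NA dsi and class "none".
#'
#' @param se SummarizedExperiment from [responseTable()].
#' @param block which stimulation block to analyze ("both", "left",
#'   "right").
#' @param n_shuffles,alpha shuffle-test settings.
#' @param seed integer seed; per-neuron seeds are derived from it.
#' @return data.frame: id, active, dsi, pd_deg, selective, threshold, class.
#' @export
tuningTable <- function(se, block = "both", n_shuffles = 1000, alpha = 0.05,
                        seed = 1L) {
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  sel_t <- which(cd$block == block & cd$kind == "translation")
  sel_r <- which(cd$block == block & cd$kind == "rotation")
  stopifnot(length(sel_t) == 8)
  dirs <- cd$direction_deg[sel_t]
  rd <- SummarizedExperiment::rowData(se)
  responding <- SummarizedExperiment::assay(se, "responding")
  reps <- S4Vectors::metadata(se)$rep_responses

  out <- data.frame(id = rownames(se), active = rd$active,
                    dsi = NA_real_, pd_deg = NA_real_, selective = FALSE,
                    threshold = NA_real_, class = "none",
                    stringsAsFactors = FALSE)
  seeds <- withSeed(seed, sample.int(.Machine$integer.max %/% 2,
                                     nrow(se)))
  for (i in seq_len(nrow(se))) {
    if (!rd$active[i]) next
    rr <- reps[[i]][sel_t]
    st <- tryCatch(
      shuffleTest(rr, dirs, n_shuffles = n_shuffles, alpha = alpha,
                  seed = seeds[i]),
      error = function(e) NULL)
    if (is.null(st)) next
    out$dsi[i] <- st$dsi
    out$pd_deg[i] <- st$pd_deg
    out$selective[i] <- st$is_direction_selective
    out$threshold[i] <- st$threshold
    cw <- sel_r[cd$rotation_label[sel_r] == "CW"]
    ccw <- sel_r[cd$rotation_label[sel_r] == "CCW"]
    out$class[i] <- classifyRotation(
      st$is_direction_selective,
      length(cw) == 1 && responding[i, cw] == 1,
      length(ccw) == 1 && responding[i, ccw] == 1)
  }
  out
}
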