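#' Tuning parameters of one simulated neuron
#'
#' The generative model for a neuron's visual-motion response. The expected
#' dF/F0 drive during the moving phase of a translational stimulus at
#' direction theta, seen through one eye, is the peak-normalized von Mises
#' curve \code{amplitude * exp(kappa * (cos(theta - pd) - 1))}; binocular
#' drive is the weighted sum of the two per-eye drives (weights
#' \code{w_contra}, \code{w_ipsi}, resolved against the neuron's side).
#' Rotational stimuli produce a direction-independent drive
#' \code{rot_gain_cw} / \code{rot_gain_ccw} (and optionally conv/div gains),
#' scaled by the same eye weights. The drive is passed through a causal
#' single-exponential indicator kernel with decay constant
#' \code{tau_decay_s}, and i.i.d. Gaussian noise of SD \code{noise_sd} is
#' added on raw fluorescence around \code{baseline_F}.
#'
#' Per-eye preferred directions may be overridden with \code{pd_left_deg} /
#' \code{pd_right_deg} (e.g. to build rotation-type neurons whose left field
#' prefers forward and right field backward); they default to \code{pd_deg}.
#' \code{binoc_inhibition} subtracts a fraction of the weaker eye's drive
#' from the binocular sum (a simple sub-linear combination), default 0.
#'
#' @param baseline_F baseline fluorescence, camera units > 0.
#' @param amplitude peak moving-phase drive, dF/F0 units >= 0.
#' @param pd_deg preferred direction, degrees (0 forward, 90 rightward).
#' @param kappa von Mises concentration >= 0 (0 = direction-uniform).
#' @param rot_gain_cw,rot_gain_ccw,rot_gain_conv,rot_gain_div rotational
#'   drives, dF/F0 units >= 0.
#' @param w_contra,w_ipsi eye weights in [0, 1].
#' @param tau_decay_s indicator decay constant, seconds > 0.
#' @param noise_sd fluorescence noise SD >= 0.
#' @param pd_left_deg,pd_right_deg optional per-eye preferred directions.
#' @param binoc_inhibition fraction in [0, 1] of the weaker-eye drive
#'   subtracted from the binocular sum.
#' @return A validated list of class "TuningParams".
#' @export
tuningParams <- function(baseline_F = 100, amplitude = 0.8, pd_deg = 0,
                         kappa = 4, rot_gain_cw = 0, rot_gain_ccw = 0,
                         rot_gain_conv = 0, rot_gain_div = 0,
                         w_contra = 1, w_ipsi = 1, tau_decay_s = 0.7,
                         noise_sd = 0, pd_left_deg = NA_real_,
                         pd_right_deg = NA_real_, binoc_inhibition = 0) {
  stopifnot(baseline_F > 0, amplitude >= 0, kappa >= 0,
            rot_gain_cw >= 0, rot_gain_ccw >= 0,
            rot_gain_conv >= 0, rot_gain_div >= 0,
            w_contra >= 0, w_contra <= 1, w_ipsi >= 0, w_ipsi <= 1,
            tau_decay_s > 0, noise_sd >= 0,
            binoc_inhibition >= 0, binoc_inhibition <= 1)
  structure(list(
    baseline_F = baseline_F, amplitude = amplitude, pd_deg = pd_deg,
    kappa = kappa, rot_gain_cw = rot_gain_cw, rot_gain_ccw = rot_gain_ccw,
    rot_gain_conv = rot_gain_conv, rot_gain_div = rot_gain_div,
    w_contra = w_contra, w_ipsi = w_ipsi, tau_decay_s = tau_decay_s,
    noise_sd = noise_sd, pd_left_deg = pd_left_deg,
    pd_right_deg = pd_right_deg, binoc_inhibition = binoc_inhibition
  ), class = "TuningParams")
}

# von Mises drive, peak-normalized: 1 at theta == pd, exp(-2*kappa) opposite.
vonMisesDrive <- function(theta_deg, pd_deg, kappa) {
  exp(kappa * (cos(deg2rad(theta_deg - pd_deg)) - 1))
}

# Per-eye drive weights for a neuron on `side`; the contralateral eye is the
# eye opposite the soma.
eyeWeights <- function(params, side) {
  if (side == "left") c(left = params$w_ipsi, right = params$w_contra)
  else c(left = params$w_contra, right = params$w_ipsi)
}

# Expected moving-phase dF/F0 drive (a constant) for one epoch.
expectedDrive <- function(params, epoch, side = "left") {
  w <- eyeWeights(params, side)
  pdl <- if (is.na(params$pd_left_deg)) params$pd_deg else params$pd_left_deg
  pdr <- if (is.na(params$pd_right_deg)) params$pd_deg else params$pd_right_deg
  if (epoch$kind == "translation") {
    th <- epoch$direction_deg
    dl <- params$amplitude * vonMisesDrive(th, pdl, params$kappa)
    dr <- params$amplitude * vonMisesDrive(th, pdr, params$kappa)
  } else {
    g <- switch(epoch$rotation_label,
                CW = params$rot_gain_cw, CCW = params$rot_gain_ccw,
                CONV = params$rot_gain_conv, DIV = params$rot_gain_div)
    dl <- dr <- g
  }
  switch(epoch$eye,
    left  = w["left"] * dl,
    right = w["right"] * dr,
    both  = {
      a <- w["left"] * dl; b <- w["right"] * dr
      a + b - params$binoc_inhibition * min(a, b)
    })[[1]]
}

# Noise-free dF/F0 trace for one epoch: boxcar drive during the moving
# phase, filtered by a unit-gain causal exponential (indicator kinetics).
expectedTrace <- function(params, epoch, side = "left", frame_period_s) {
  n <- epoch$n_pre + epoch$n_move + epoch$n_post
  x <- numeric(n)
  x[(epoch$n_pre + 1):(epoch$n_pre + epoch$n_move)] <-
    expectedDrive(params, epoch, side)
  a <- exp(-frame_period_s / params$tau_decay_s)
  y <- numeric(n)
  acc <- 0
  for (t in seq_len(n)) {
    acc <- a * acc + (1 - a) * x[t]
    y[t] <- acc
  }
  y
}

#' Simulate raw fluorescence traces for one stimulus epoch
#'
#' Applies the generative model of [tuningParams()]: constant moving-phase
#' drive, exponential indicator filtering, Gaussian noise on raw
#' fluorescence. Deterministic given \code{seed}.
#'
#' @param params a [tuningParams()] object.
#' @param epoch one epoch: a single row of [epochs()] (data.frame or list).
#' @param n_repetitions number of repetitions (columns) to draw.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @param side neuron side ("left"/"right"), resolves contra vs ipsi.
#' @param frame_period_s seconds per frame.
#' @return numeric matrix, frames x repetitions, raw fluorescence.
#' @export
simulateTrace <- function(params, epoch, n_repetitions = 1, seed = NULL,
                          side = "left", frame_period_s = 0.3456) {
  stopifnot(inherits(params, "TuningParams"), n_repetitions >= 1)
  if (is.data.frame(epoch)) epoch <- as.list(epoch[1, ])
  y <- expectedTrace(params, epoch, side, frame_period_s)
  f <- params$baseline_F * (1 + y)
  withSeed(seed, {
    noise <- matrix(rnorm(length(f) * n_repetitions, 0, params$noise_sd),
                    nrow = length(f))
    matrix(f, nrow = length(f), ncol = n_repetitions) + noise
  })
}

#' Specification of a synthetic neuron population
#'
#' Class counts, spatial layout and tuning parameters for
#' [generatePopulation()]. The defaults encode the qualitative topography
#' the analysis is meant to recover: forward-preferring neurons cluster
#' rostrally, backward-preferring neurons caudally, and rotation-responsive
#' neurons are lateralized (CW-responsive on the right, CCW on the left).
#' Anatomical point sets place unipolar somata/terminals near the forward
#' cluster and multipolar ones near the backward cluster.
#'
#' Coordinates are micrometres in the registered frame, ordered
#' (rostro-caudal, left-right, dorso-ventral); rostral is small rc.
#'
#' @param n_per_class named integer vector over classes
#'   forward, backward, cw_rotation, ccw_rotation, nonselective.
#' @param class_centroids_um 5x3 matrix of class centroid means.
#' @param class_spread_um per-axis SD of centroid scatter.
#' @param tuning a [tuningParams()] template; per-class fields
#'   (pd, rotation gains, kappa) are overridden per neuron.
#' @param pd_jitter_deg SD of preferred-direction scatter within a class.
#' @param n_repetitions trace repetitions per stimulus.
#' @param n_anatomy_points points per anatomical class (somata and
#'   terminals, unipolar and multipolar).
#' @param anatomy_offset_um separation between the two anatomical clusters.
#' @param anatomy_spread_um SD of anatomical cluster scatter.
#' @param seed integer seed.
#' @return list of class "PopulationSpec".
#' @export
populationSpec <- function(n_per_class = c(forward = 30, backward = 30,
                                           cw_rotation = 15,
                                           ccw_rotation = 15,
                                           nonselective = 30),
                           class_centroids_um = NULL,
                           class_spread_um = c(10, 8, 5),
                           tuning = tuningParams(amplitude = 0.8, kappa = 4,
                                                 noise_sd = 2,
                                                 w_contra = 1, w_ipsi = 0.6),
                           pd_jitter_deg = 15,
                           n_repetitions = 3,
                           n_anatomy_points = 60,
                           anatomy_offset_um = 40,
                           anatomy_spread_um = 8,
                           seed = 1L) {
  classes <- c("forward", "backward", "cw_rotation", "ccw_rotation",
               "nonselective")
  stopifnot(all(names(n_per_class) %in% classes), all(n_per_class >= 0),
            all(class_spread_um > 0), n_repetitions >= 1,
            anatomy_spread_um > 0)
  n <- setNames(integer(5), classes)
  n[names(n_per_class)] <- as.integer(n_per_class)
  if (is.null(class_centroids_um)) {
    class_centroids_um <- rbind(
      forward      = c(30, 0, 20),
      backward     = c(70, 0, 20),
      cw_rotation  = c(40, 12, 20),   # right-lateralized
      ccw_rotation = c(40, -12, 20),  # left-lateralized
      nonselective = c(50, 0, 20)
    )
  }
  structure(list(
    n_per_class = n, class_centroids_um = class_centroids_um,
    class_spread_um = class_spread_um, tuning = tuning,
    pd_jitter_deg = pd_jitter_deg, n_repetitions = n_repetitions,
    n_anatomy_points = n_anatomy_points,
    anatomy_offset_um = anatomy_offset_um,
    anatomy_spread_um = anatomy_spread_um, seed = as.integer(seed)
  ), class = "PopulationSpec")
}

classTuning <- function(spec, cls, pd) {
  tp <- spec$tuning
  switch(cls,
    forward = , backward = {
      tp$pd_deg <- pd
    },
    cw_rotation = {
      tp$pd_deg <- pd
      tp$rot_gain_cw <- 0.8 * tp$amplitude
      tp$rot_gain_ccw <- 0
    },
    ccw_rotation = {
      tp$pd_deg <- pd
      tp$rot_gain_ccw <- 0.8 * tp$amplitude
      tp$rot_gain_cw <- 0
    },
    nonselective = {
      tp$pd_deg <- 0
      tp$kappa <- 0
    })
  tp
}

#' Generate a synthetic population with ground truth
#'
#' Draws neuron centroids per functional class, assigns per-neuron tuning
#' parameters, simulates all traces against \code{protocol}, and attaches
#' labeled anatomical point sets (unipolar/multipolar somata and terminal
#' clusters). Deterministic given \code{spec$seed}.
#'
#' @param spec a [populationSpec()].
#' @param protocol a [StimulusProtocol-class]; default binocular 8+CW+CCW.
#' @return A [SyntheticDataset-class].
#' @export
generatePopulation <- function(spec = populationSpec(),
                               protocol = generateProtocol(seed = spec$seed)) {
  stopifnot(inherits(spec, "PopulationSpec"))
  n_tot <- sum(spec$n_per_class)
  if (n_tot == 0) stop("population has zero neurons")
  ep <- epochs(protocol)

  withSeed(spec$seed, {
    gt <- do.call(rbind, lapply(names(spec$n_per_class), function(cls) {
      k <- spec$n_per_class[[cls]]
      if (k == 0) return(NULL)
      pd0 <- switch(cls, forward = 0, backward = 180, cw_rotation = 90,
                    ccw_rotation = -90, nonselective = 0)
      data.frame(class = cls,
                 pd_true = wrapAngle(pd0 + rnorm(k, 0, spec$pd_jitter_deg)),
                 stringsAsFactors = FALSE)
    }))
    n_tot <- nrow(gt)
    gt$id <- sprintf("n%03d", seq_len(n_tot))
    mu <- spec$class_centroids_um[gt$class, , drop = FALSE]
    cen <- mu + matrix(rnorm(3 * n_tot), ncol = 3) %*% diag(spec$class_spread_um)
    gt$rc <- cen[, 1]; gt$lr <- cen[, 2]; gt$dv <- cen[, 3]
    gt$side <- ifelse(gt$lr < 0, "left", "right")

    tps <- lapply(seq_len(n_tot),
                  function(i) classTuning(spec, gt$class[i], gt$pd_true[i]))
    neurons <- lapply(seq_len(n_tot), function(i) {
      traces <- lapply(seq_len(nrow(ep)), function(j) {
        simulateTrace(tps[[i]], ep[j, ], n_repetitions = spec$n_repetitions,
                      seed = NULL, side = gt$side[i],
                      frame_period_s = protocol@frame_period_s)
      })
      new("NeuronRecord", id = gt$id[i],
          centroid = c(rc = cen[i, 1], lr = cen[i, 2], dv = cen[i, 3]),
          side = gt$side[i], traces = traces)
    })
    # record every generating parameter so downstream code (and users) can
    # rebuild each neuron's TuningParams from the ground-truth table alone
    parfields <- setdiff(names(tps[[1]]), "pd_deg")
    for (f in parfields) gt[[f]] <- vapply(tps, function(tp) tp[[f]], 1)

    anat <- generateAnatomy(spec)
    new("SyntheticDataset", protocol = protocol, neurons = neurons,
        groundTruth = gt, anatomy = anat)
  })
}

# Two anatomical classes per compartment as 2D Gaussian clusters, separated
# along the first coordinate by anatomy_offset_um.
generateAnatomy <- function(spec) {
  k <- spec$n_anatomy_points
  d <- spec$anatomy_offset_um
  s <- spec$anatomy_spread_um
  cl2 <- function(mu, lab) {
    data.frame(x = rnorm(k, mu[1], s), y = rnorm(k, mu[2], s),
               class = lab, stringsAsFactors = FALSE)
  }
  list(
    somata = rbind(cl2(c(30, 0), "unipolar"), cl2(c(30 + d, 0), "multipolar")),
    terminals = rbind(cl2(c(20, 10), "unipolar"),
                      cl2(c(20 + d, 10), "multipolar"))
  )
}

#' Render a synthetic volumetric response stack
#'
#' Renders each neuron as an isotropic Gaussian blob. The per-stimulus
#' response volume holds the neuron's expected repetition-averaged mean
#' moving-phase dF/F0 (from the same closed-form drive and indicator kernel
#' that [simulateTrace()] uses); the raw brightness volume is
#' \code{background_level} plus a labeling blob at each soma, plus optional
#' Gaussian noise.
#'
#' @param dataset a [SyntheticDataset-class].
#' @param voxel_size_um edge length of a voxel.
#' @param background_level camera gray value of unlabeled background.
#' @param seed integer seed for the brightness noise.
#' @param blob_sd_um soma blob SD.
#' @param blob_peak peak brightness of a labeled soma above background.
#' @param noise_sd brightness noise SD (gray values).
#' @param margin_um padding of the volume around the centroid bounding box.
#' @return list with \code{response} (4D array x,y,z,stimulus, dF/F0),
#'   \code{brightness} (3D array, gray values), \code{stimuli} (epoch table
#'   rows rendered), and the voxel grid (\code{origin_um},
#'   \code{voxel_size_um}).
#' @export
generateVoxelVolume <- function(dataset, voxel_size_um = 2,
                                background_level = 10, seed = 1L,
                                blob_sd_um = 3, blob_peak = 20,
                                noise_sd = 0, margin_um = 10) {
  stopifnot(is(dataset, "SyntheticDataset"), voxel_size_um > 0)
  if (length(dataset@neurons) == 0) stop("empty dataset")
  gt <- dataset@groundTruth
  cen <- cbind(gt$rc, gt$lr, gt$dv)
  lo <- apply(cen, 2, min) - margin_um
  hi <- apply(cen, 2, max) + margin_um
  dims <- pmax(3L, as.integer(ceiling((hi - lo) / voxel_size_um)) + 1L)
  ax <- lapply(1:3, function(k) lo[k] + (seq_len(dims[k]) - 1) * voxel_size_um)

  ep <- epochs(dataset@protocol)
  ep <- ep[ep$block == "both" & !ep$discard, , drop = FALSE]
  n_stim <- nrow(ep)

  # expected mean moving-phase dF/F0 per neuron x stimulus (noise-free)
  resp <- matrix(0, nrow(gt), n_stim)
  for (i in seq_len(nrow(gt))) {
    tp <- classTuningFromTruth(dataset, i)
    for (j in seq_len(n_stim)) {
      y <- expectedTrace(tp, as.list(ep[j, ]), gt$side[i],
                         dataset@protocol@frame_period_s)
      mv <- (ep$n_pre[j] + 1):(ep$n_pre[j] + ep$n_move[j])
      resp[i, j] <- mean(y[mv])
    }
  }

  # separable Gaussian blob weights per axis per neuron
  wts <- lapply(1:3, function(k)
    vapply(seq_len(nrow(gt)), function(i)
      exp(-(ax[[k]] - cen[i, k])^2 / (2 * blob_sd_um^2)), numeric(dims[k])))

  response <- array(0, c(dims, n_stim))
  bright <- array(background_level, dims)
  for (i in seq_len(nrow(gt))) {
    blob <- outer(outer(wts[[1]][, i], wts[[2]][, i]), wts[[3]][, i])
    bright <- bright + blob_peak * blob
    for (j in seq_len(n_stim))
      response[, , , j] <- response[, , , j] + resp[i, j] * blob
  }
  if (noise_sd > 0)
    bright <- bright + withSeed(seed, array(rnorm(length(bright), 0, noise_sd),
                                            dims))
  list(response = response, brightness = bright, stimuli = ep,
       origin_um = lo, voxel_size_um = voxel_size_um)
}

# Rebuild the TuningParams a dataset neuron was generated with, from the
# parameter columns recorded in the ground-truth table.
classTuningFromTruth <- function(dataset, i) {
  gt <- dataset@groundTruth[i, ]
  tuningParams(
    baseline_F = gt$baseline_F, amplitude = gt$amplitude,
    pd_deg = gt$pd_true, kappa = gt$kappa,
    rot_gain_cw = gt$rot_gain_cw, rot_gain_ccw = gt$rot_gain_ccw,
    rot_gain_conv = gt$rot_gain_conv, rot_gain_div = gt$rot_gain_div,
    w_contra = gt$w_contra, w_ipsi = gt$w_ipsi,
    tau_decay_s = gt$tau_decay_s, noise_sd = gt$noise_sd,
    pd_left_deg = gt$pd_left_deg, pd_right_deg = gt$pd_right_deg,
    binoc_inhibition = gt$binoc_inhibition)
}

#' Generate polyline-tree skeletons with prescribed endpoints
#'
#' Builds one skeleton per soma: a rooted tree whose root sits at the soma
#' and whose leaves sit exactly at the requested terminal points (one branch
#' node between root and leaves when a skeleton has more than one terminal).
#' Returned in SWC form.
#'
#' @param terminal_points list with one numeric matrix (n x 2 or n x 3) per
#'   skeleton: that skeleton's terminal coordinates.
#' @param soma_points numeric matrix of soma coordinates, one row per
#'   skeleton.
#' @param seed integer seed (jitters the branch node so trees are not
#'   degenerate collinear).
#' @return list of SWC data.frames (columns id, type, x, y, z, radius,
#'   parent).
#' @export
generateSkeletons <- function(terminal_points, soma_points, seed = 1L) {
  if (!is.list(terminal_points)) terminal_points <- list(terminal_points)
  soma_points <- rbind(soma_points)
  stopifnot(length(terminal_points) == nrow(soma_points))
  pad3 <- function(m) {
    m <- rbind(m)
    if (ncol(m) == 2) cbind(m, 0) else m[, 1:3, drop = FALSE]
  }
  withSeed(seed, lapply(seq_along(terminal_points), function(i) {
    term <- terminal_points[[i]]
    if (is.null(term) || NROW(term) == 0)
      stop("each skeleton needs >= 1 terminal point")
    term <- pad3(term)
    soma <- pad3(soma_points[i, , drop = FALSE])
    if (nrow(term) == 1) {
      coords <- rbind(soma, term)
      parent <- c(-1L, 1L)
      type <- c(1L, 6L)
    } else {
      br <- colMeans(rbind(soma, term)) + rnorm(3, 0, 0.5)
      coords <- rbind(soma, br, term)
      parent <- c(-1L, 1L, rep(2L, nrow(term)))
      type <- c(1L, 5L, rep(6L, nrow(term)))
    }
    data.frame(id = seq_len(nrow(coords)), type = type,
               x = coords[, 1], y = coords[, 2], z = coords[, 3],
               radius = 0.5, parent = parent)
  }))
}

#' Rasterize an SWC skeleton onto a 2D pixel mask
#'
#' Draws each node-to-parent segment with Bresenham's line algorithm in the
#' (x, y) plane.
#'
#' @param swc an SWC data.frame as produced by [generateSkeletons()].
#' @param spacing pixel size in the skeleton's coordinate units.
#' @param pad margin in pixels around the skeleton bounding box.
#' @return logical matrix mask; attributes \code{origin} and \code{spacing}
#'   map pixel (i, j) back to coordinates.
#' @export
rasterizeSkeleton <- function(swc, spacing = 1, pad = 2L) {
  stopifnot(nrow(swc) >= 1)
  if (anyDuplicated(swc$id)) stop("duplicate node ids")
  px <- round(swc$x / spacing); py <- round(swc$y / spacing)
  ox <- min(px) - pad; oy <- min(py) - pad
  px <- px - ox + 1; py <- py - oy + 1
  mask <- matrix(FALSE, max(px) + pad, max(py) + pad)
  for (k in seq_len(nrow(swc))) {
    mask[px[k], py[k]] <- TRUE
    p <- swc$parent[k]
    if (p > 0) {
      j <- match(p, swc$id)
      for (pt in bresenham(px[j], py[j], px[k], py[k]))
        mask[pt[1], pt[2]] <- TRUE
    }
  }
  attr(mask, "origin") <- c(ox, oy) * spacing
  attr(mask, "spacing") <- spacing
  mask
}

# Integer line rasterization between two pixels (inclusive).
bresenham <- function(x0, y0, x1, y1) {
  dx <- abs(x1 - x0); dy <- -abs(y1 - y0)
  sx <- sign(x1 - x0); sy <- sign(y1 - y0)
  if (sx == 0) sx <- 1L
  if (sy == 0) sy <- 1L
  err <- dx + dy
  out <- list()
  repeat {
    out[[length(out) + 1]] <- c(x0, y0)
    if (x0 == x1 && y0 == y1) break
    e2 <- 2 * err
    if (e2 >= dy) { err <- err + dy; x0 <- x0 + sx }
    if (e2 <= dx) { err <- err + dx; y0 <- y0 + sy }
  }
  out
}
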