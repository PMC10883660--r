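#' Pool bilateral data by reflecting across the midline
#'
#' Keeps points on the chosen side of the midline and reflects points from
#' the other side onto it, so left- and right-side data contribute to one
#' distribution. Idempotent; output size equals input size.
#'
#' @param points numeric matrix (n x 2) or [PointSet2D-class].
#' @param midline midline coordinate along \code{axis}.
#' @param axis which column is the left-right axis (default 1).
#' @param keep which side to fold onto: "low" (coordinates <= midline) or
#'   "high".
#' @return same type as the input, with reflected coordinates.
#' @export
mirrorPool <- function(points, midline, axis = 1, keep = c("low", "high")) {
  keep <- match.arg(keep)
  ps <- NULL
  if (is(points, "PointSet2D")) { ps <- points; points <- points@coords }
  x <- points[, axis]
  flip <- if (keep == "low") x > midline else x < midline
  points[flip, axis] <- 2 * midline - x[flip]
  if (!is.null(ps)) { ps@coords <- points; ps } else points
}

#' Common evaluation grid for kernel density estimates
#'
#' A regular grid covering the joint bounding box of the supplied point
#' sets, padded by \code{pad_sd} kernel SDs on every side so that kernel
#' mass is not clipped.
#'
#' @param ... point matrices (n x 2) and/or [PointSet2D-class] objects.
#' @param kernel_sd Gaussian kernel SD (pixels).
#' @param spacing grid node spacing (pixels).
#' @param pad_sd margin in kernel SDs.
#' @return list with node vectors \code{x}, \code{y}.
#' @export
kdeGrid <- function(..., kernel_sd = 10, spacing = 1, pad_sd = 4) {
  mats <- lapply(list(...), function(p)
    if (is(p, "PointSet2D")) p@coords else rbind(p))
  all_pts <- do.call(rbind, mats)
  stopifnot(nrow(all_pts) >= 1, kernel_sd > 0, spacing > 0)
  pad <- pad_sd * kernel_sd
  lo <- apply(all_pts, 2, min) - pad
  hi <- apply(all_pts, 2, max) + pad
  list(x = seq(lo[1], hi[1], by = spacing),
       y = seq(lo[2], hi[2], by = spacing))
}

#' 2D Gaussian kernel density estimate
#'
#' Places an isotropic Gaussian of SD \code{kernel_sd} on every point,
#' evaluates the sum exactly on the grid (separable evaluation: no binning,
#' no kernel truncation), and renormalizes so the density integrates to 1
#' over the grid — this absorbs the small mass lost to edge truncation.
#'
#' @param points numeric matrix (n x 2) or [PointSet2D-class].
#' @param grid grid from [kdeGrid()] (must be shared by densities that are
#'   compared).
#' @param kernel_sd Gaussian kernel SD (default 10 pixels = 7.8 um at the
#'   reference scale of 0.78 um/pixel).
#' @return a [KernelDensity2D-class].
#' @export
kde2d <- function(points, grid = kdeGrid(points, kernel_sd = kernel_sd),
                  kernel_sd = 10) {
  if (is(points, "PointSet2D")) points <- points@coords
  points <- rbind(points)
  if (nrow(points) == 0) stop("empty point set")
  A <- dnorm(outer(grid$x, points[, 1], "-"), sd = kernel_sd)
  B <- dnorm(outer(grid$y, points[, 2], "-"), sd = kernel_sd)
  z <- A %*% t(B)
  area <- .gridCellArea(grid$x, grid$y)
  z <- z / (sum(z) * area)
  new("KernelDensity2D", x = grid$x, y = grid$y, z = z, kernelSd = kernel_sd)
}

setMethod("show", "KernelDensity2D", function(object) {
  cat(sprintf(
    "KernelDensity2D: %d x %d grid, kernel SD %.3g, integral %.6f\n",
    length(object@x), length(object@y), object@kernelSd,
    sum(object@z) * .gridCellArea(object@x, object@y)))
})

#' Matching score: min-integral overlap of two densities
#'
#' The 2D integral of the pointwise minimum of two probability densities on
#' a shared grid: 0 for disjoint supports, 1 for identical distributions.
#' Symmetric in its arguments.
#'
#' @param p,q [KernelDensity2D-class] objects on the same grid.
#' @return scalar in [0, 1].
#' @export
matchingScore <- function(p, q) {
  stopifnot(is(p, "KernelDensity2D"), is(q, "KernelDensity2D"))
  if (length(p@x) != length(q@x) || length(p@y) != length(q@y) ||
      any(p@x != q@x) || any(p@y != q@y))
    stop("densities must share one grid")
  sum(pmin(p@z, q@z)) * .gridCellArea(p@x, p@y)
}

#' Matching index from a 2x2 matching-score table
#'
#' The mean MS of the tested anatomy/function pairing (A1-F1 with A2-F2)
#' minus the mean MS of the opposite pairing (A1-F2 with A2-F1). Ranges
#' over [-1, 1]; the sign says which pairing matches better.
#'
#' @param ms 2x2 numeric matrix, rows anatomy classes, columns function
#'   classes, no missing entries.
#' @return scalar.
#' @export
matchingIndex <- function(ms) {
  stopifnot(is.matrix(ms), all(dim(ms) == c(2, 2)))
  if (any(!is.finite(ms))) stop("missing matching-score entry")
  (ms[1, 1] + ms[2, 2]) / 2 - (ms[1, 2] + ms[2, 1]) / 2
}

# MS table for two anatomy and two function point sets on a shared grid.
msTable <- function(anat, fun, grid, kernel_sd) {
  dens_a <- lapply(anat, kde2d, grid = grid, kernel_sd = kernel_sd)
  dens_f <- lapply(fun, kde2d, grid = grid, kernel_sd = kernel_sd)
  ms <- matrix(NA_real_, 2, 2,
               dimnames = list(names(anat), names(fun)))
  for (i in 1:2) for (j in 1:2)
    ms[i, j] <- matchingScore(dens_a[[i]], dens_f[[j]])
  ms
}

#' Bootstrap null distribution of the matching index
#'
#' Generates random class pairs by resampling with replacement: per
#' iterate, the two anatomical point sets are pooled and two pseudo-classes
#' of the original sizes are drawn from the pool (likewise for the two
#' functional sets), and the MI of the resampled classes is computed. This
#' preserves class sizes and each modality's marginal spatial structure
#' while destroying the class-position association. Deterministic given
#' \code{seed}.
#'
#' @param anat,fun lists of two point matrices (or [PointSet2D-class]) each.
#' @param n number of resamples.
#' @param kernel_sd KDE kernel SD (pixels).
#' @param grid shared grid; default covers all four sets.
#' @param seed integer seed.
#' @return numeric vector of length \code{n}.
#' @export
bootstrapMiNull <- function(anat, fun, n = 10000, kernel_sd = 10,
                            grid = NULL, seed = 1L) {
  cm <- function(p) if (is(p, "PointSet2D")) p@coords else rbind(p)
  anat <- lapply(anat, cm); fun <- lapply(fun, cm)
  stopifnot(length(anat) == 2, length(fun) == 2,
            all(vapply(c(anat, fun), nrow, 1L) >= 2))
  if (is.null(grid))
    grid <- kdeGrid(anat[[1]], anat[[2]], fun[[1]], fun[[2]],
                    kernel_sd = kernel_sd)
  pool_a <- rbind(anat[[1]], anat[[2]])
  pool_f <- rbind(fun[[1]], fun[[2]])
  na <- vapply(anat, nrow, 1L); nf <- vapply(fun, nrow, 1L)
  withSeed(seed, vapply(seq_len(n), function(k) {
    ia <- sample.int(nrow(pool_a), sum(na), replace = TRUE)
    jf <- sample.int(nrow(pool_f), sum(nf), replace = TRUE)
    a <- list(pool_a[ia[seq_len(na[1])], , drop = FALSE],
              pool_a[ia[na[1] + seq_len(na[2])], , drop = FALSE])
    f <- list(pool_f[jf[seq_len(nf[1])], , drop = FALSE],
              pool_f[jf[nf[1] + seq_len(nf[2])], , drop = FALSE])
    matchingIndex(msTable(a, f, grid, kernel_sd))
  }, numeric(1)))
}

#' One-tailed Bonferroni-corrected significance of a matching index
#'
#' The threshold is the empirical (100 - 100 * alpha / n_comparisons)th
#' percentile of the bootstrap null (99.17 for alpha 0.05 and the six
#' comparisons: three functional mappings times two brain regions); the MI
#' is significant iff it strictly exceeds the threshold. A pairing claim
#' for the population requires significance in both regions — see
#' \code{combineRegions}.
#'
#' @param mi observed matching index.
#' @param null bootstrap null distribution.
#' @param alpha one-tailed significance level.
#' @param n_comparisons Bonferroni correction factor.
#' @return list with \code{significant}, \code{threshold},
#'   \code{threshold_percentile}.
#' @export
decideSignificance <- function(mi, null, alpha = 0.05, n_comparisons = 6) {
  stopifnot(length(null) >= 1, alpha > 0, alpha < 1, n_comparisons >= 1)
  pct <- 100 - 100 * alpha / n_comparisons
  thr <- empiricalQuantile(null, pct / 100)
  list(significant = mi > thr, threshold = thr, threshold_percentile = pct)
}

#' @rdname decideSignificance
#' @param region_results list of per-region results from
#'   \code{decideSignificance} (e.g. soma and axon-terminal regions).
#' @return \code{combineRegions}: TRUE iff every region is significant.
#' @export
combineRegions <- function(region_results) {
  sig1 <- function(r) {
    if (is(r, "MatchResult")) r@significant else isTRUE(r$significant)
  }
  all(vapply(region_results, sig1, logical(1)))
}

#' Full overlap test for one anatomy/function mapping in one region
#'
#' Mirror-pools nothing (do that upstream if needed), builds the shared
#' grid, the four KDEs and the MS table, computes the MI, its bootstrap
#' null, and the significance decision.
#'
#' @inheritParams bootstrapMiNull
#' @param alpha,n_comparisons see [decideSignificance()].
#' @param spacing grid spacing in pixels.
#' @return a [MatchResult-class].
#' @export
overlapTest <- function(anat, fun, n = 10000, kernel_sd = 10, spacing = 1,
                        alpha = 0.05, n_comparisons = 6, seed = 1L) {
  cm <- function(p) if (is(p, "PointSet2D")) p@coords else rbind(p)
  anat <- lapply(anat, cm); fun <- lapply(fun, cm)
  grid <- kdeGrid(anat[[1]], anat[[2]], fun[[1]], fun[[2]],
                  kernel_sd = kernel_sd, spacing = spacing)
  ms <- msTable(anat, fun, grid, kernel_sd)
  mi <- matchingIndex(ms)
  null <- bootstrapMiNull(anat, fun, n = n, kernel_sd = kernel_sd,
                          grid = grid, seed = seed)
  dec <- decideSignificance(mi, null, alpha, n_comparisons)
  new("MatchResult", ms = ms, mi = mi, nullMi = null,
      thresholdPercentile = dec$threshold_percentile,
      threshold = dec$threshold, significant = dec$significant)
}

setMethod("show", "MatchResult", function(object) {
  cat("MatchResult\n  matching scores:\n")
  print(round(object@ms, 4))
  cat(sprintf(
    "  MI = %.4f; null %.2fth percentile = %.4f (%d resamples) -> %s\n",
    object@mi, object@thresholdPercentile, object@threshold,
    length(object@nullMi),
    if (object@significant) "significant" else "not significant"))
})

#' Endpoints of a rasterized skeleton
#'
#' Skeleton pixels with at most one 8-connected skeleton neighbor: tips of
#' branches (and the root of a path). An isolated pixel is its own
#' endpoint. If the mask is not a thin skeleton (some pixel has a filled
#' 2x2 neighborhood), it is thinned first (Zhang-Suen) with a warning.
#'
#' @param mask logical matrix, TRUE on skeleton pixels.
#' @return integer matrix (n x 2) of endpoint pixel coordinates (row, col).
#' @export
skeletonEndpoints <- function(mask) {
  mask <- mask == TRUE
  if (!any(mask)) return(matrix(integer(0), 0, 2))
  if (hasThickBlock(mask)) {
    warning("input is not a thin skeleton; thinning before endpoint search")
    mask <- thinMask(mask)
  }
  nb <- neighborCount(mask)
  which(mask & nb <= 1, arr.ind = TRUE)
}

# 8-neighbor count by shifting a zero-padded copy.
neighborCount <- function(mask) {
  p <- matrix(0L, nrow(mask) + 2, ncol(mask) + 2)
  p[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  n <- matrix(0L, nrow(mask), ncol(mask))
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    n <- n + p[2:(nrow(mask) + 1) + di, 2:(ncol(mask) + 1) + dj]
  }
  n
}

hasThickBlock <- function(mask) {
  if (nrow(mask) < 2 || ncol(mask) < 2) return(FALSE)
  m <- mask + 0
  blk <- m[-nrow(m), -ncol(m)] + m[-1, -ncol(m)] +
    m[-nrow(m), -1] + m[-1, -1]
  any(blk == 4)
}

# Zhang-Suen thinning to a 1-pixel skeleton.
thinMask <- function(mask) {
  m <- mask == TRUE
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p <- matrix(FALSE, nrow(m) + 2, ncol(m) + 2)
      p[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
      idx <- which(m, arr.ind = TRUE)
      if (nrow(idx) == 0) break
      i <- idx[, 1] + 1L; j <- idx[, 2] + 1L
      P2 <- p[cbind(i - 1, j)];     P3 <- p[cbind(i - 1, j + 1)]
      P4 <- p[cbind(i, j + 1)];     P5 <- p[cbind(i + 1, j + 1)]
      P6 <- p[cbind(i + 1, j)];     P7 <- p[cbind(i + 1, j - 1)]
      P8 <- p[cbind(i, j - 1)];     P9 <- p[cbind(i - 1, j - 1)]
      ring <- cbind(P2, P3, P4, P5, P6, P7, P8, P9)
      B <- rowSums(ring)
      ringn <- cbind(ring[, -1, drop = FALSE], ring[, 1, drop = FALSE])
      A <- rowSums(!ring & ringn)
      if (step == 1) {
        cond <- B >= 2 & B <= 6 & A == 1 &
          !(P2 & P4 & P6) & !(P4 & P6 & P8)
      } else {
        cond <- B >= 2 & B <= 6 & A == 1 &
          !(P2 & P4 & P8) & !(P2 & P6 & P8)
      }
      if (any(cond)) {
        m[idx[cond, , drop = FALSE]] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

#' 1D class-conditional marginal density along an anatomical axis
#'
#' Gaussian kernel density of one coordinate of a point set (e.g. the
#' rostro-caudal positions of forward-preferring neurons), normalized to
#' integrate to 1.
#'
#' @param points numeric matrix or [PointSet2D-class].
#' @param axis which column to marginalize onto.
#' @param kernel_sd Gaussian kernel SD (same units as the coordinate).
#' @return a \code{stats::density} object.
#' @export
axisDensity <- function(points, axis = 1, kernel_sd = 10) {
  if (is(points, "PointSet2D")) points <- points@coords
  points <- rbind(points)
  if (nrow(points) == 0) stop("empty point set")
  x <- points[, axis]
  if (nrow(points) == 1)
    return(density(x, bw = kernel_sd, n = 512,
                   from = x - 6 * kernel_sd, to = x + 6 * kernel_sd))
  density(x, bw = kernel_sd, n = 512)
}

#' Read and write point sets as CSV
#'
#' Columns x, y, class, region (projection).
#'
#' @param sets list of [PointSet2D-class].
#' @param path CSV path.
#' @return (write) the path invisibly; (read) a list of PointSet2D.
#' @export
writePointSetsCsv <- function(sets, path) {
  df <- do.call(rbind, lapply(sets, function(ps)
    data.frame(x = ps@coords[, 1], y = ps@coords[, 2],
               class = ps@label, region = ps@projection)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writePointSetsCsv
#' @export
readPointSetsCsv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, interaction(df$class, df$region, drop = TRUE)),
         function(d) new("PointSet2D", coords = cbind(d$x, d$y),
                         label = d$class[1], projection = d$region[1]))
}

#' Read and write SWC skeleton files
#'
#' Standard 7-column SWC (id, type, x, y, z, radius, parent), plain text.
#'
#' @param swc SWC data.frame.
#' @param path file path.
#' @return (write) the path invisibly; (read) an SWC data.frame.
#' @export
writeSwc <- function(swc, path) {
  lines <- sprintf("%d %d %.4f %.4f %.4f %.4f %d",
                   swc$id, swc$type, swc$x, swc$y, swc$z, swc$radius,
                   swc$parent)
  writeLines(c("# SWC", lines), path)
  invisible(path)
}

#' @rdname writeSwc
#' @export
readSwc <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
             x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
             parent = as.integer(m[, 7]))
}
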