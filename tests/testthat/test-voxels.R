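test_that("brightness labeling is a strict threshold above background", {
  vol <- array(10, c(4, 4, 3))
  expect_false(any(labelVoxels(vol, 10, 2)))
  vol[2, 2, 2] <- 20
  m <- labelVoxels(vol, 10, 2)
  expect_true(m[2, 2, 2]); expect_equal(sum(m), 1)
  vol2 <- array(10, c(4, 4, 3)); vol2[1, 1, 1] <- 12
  expect_false(any(labelVoxels(vol2, 10, 2)))  # boundary: strict
})

test_that("voxel responses average repetitions and recover generator plateaus", {
  # 5D per-stimulus stacks: repetition mean
  x <- array(0, c(2, 2, 1, 1, 2))
  x[, , , 1, 1] <- 1; x[, , , 1, 2] <- 3
  expect_true(all(voxelResponses(x) == 2))
  # 4D time series against the generator's closed form, zero noise
  p <- generateProtocol(frame_period_s = 0.6912, seed = 2)  # shorter epochs
  ep <- epochs(p)
  tp <- tuningParams(amplitude = 0.5, kappa = 0, noise_sd = 0)
  frames <- unlist(lapply(seq_len(nrow(ep)), function(j)
    simulateTrace(tp, ep[j, ], 1)[, 1]))
  x4 <- array(rep(frames, each = 4), c(2, 2, 1, length(frames)))
  vr <- voxelResponses(x4, p)
  mv <- (ep$n_pre[1] + 1):(ep$n_pre[1] + ep$n_move[1])
  want <- mean(computeDff(simulateTrace(tp, ep[1, ], 1)[, 1],
                          ep$n_pre[1])[mv])
  expect_equal(vr[1, 1, 1, 1], want, tolerance = 1e-10)
  expect_error(voxelResponses(x4[, , , 1:10, drop = FALSE], p), "window")
  # constant volume: zero response
  xc <- array(50, c(2, 2, 1, sum(ep$n_pre + ep$n_move + ep$n_post)))
  expect_true(all(voxelResponses(xc, p) == 0))
})

test_that("voxel categorization applies the printed thresholds strictly", {
  # hand-built single-voxel response set over 10 stimuli
  p <- generateProtocol(seed = 1)
  st <- epochs(p)
  mk <- function(dirvals, cw = 0, ccw = 0) {
    r <- array(0, c(1, 1, 1, nrow(st)))
    for (d in names(dirvals))
      r[1, 1, 1, which(st$direction_deg == as.numeric(d))] <- dirvals[[d]]
    r[1, 1, 1, which(st$rotation_label == "CW")] <- cw
    r[1, 1, 1, which(st$rotation_label == "CCW")] <- ccw
    r
  }
  fwd <- mk(list(`0` = 0.7, `45` = 0.6, `315` = 0.5))
  cats <- categorizeVoxels(fwd, st)
  expect_true(cats$forward[1, 1, 1])
  expect_false(cats$backward[1, 1, 1])
  # forward mean 0.4 < 0.5: not forward-selective even with cos(PD) > 0
  weak <- mk(list(`0` = 0.6, `45` = 0.3, `315` = 0.3))
  expect_false(categorizeVoxels(weak, st)$forward[1, 1, 1])
  # rotation rule: > 0.75 one direction and < 0.25 the other
  expect_true(categorizeVoxels(mk(list(`0` = 0.1), cw = 0.8, ccw = 0.1),
                               st)$cw_rot[1, 1, 1])
  expect_false(categorizeVoxels(mk(list(`0` = 0.1), cw = 0.8, ccw = 0.3),
                                st)$cw_rot[1, 1, 1])
  # left/right: stronger side wins above 0.25
  lr <- mk(list(`270` = 0.4, `315` = 0.4, `90` = 0.3, `45` = 0.3,
                `0` = 0.1))
  c2 <- categorizeVoxels(lr, st)
  expect_true(c2$leftward[1, 1, 1]); expect_false(c2$rightward[1, 1, 1])
})

test_that("forward and backward categories are disjoint and monotone in thresholds", {
  ds <- smallPopulation(n_fwd = 6, n_bwd = 6, n_ns = 0, seed = 23)
  vol <- generateVoxelVolume(ds, voxel_size_um = 4)
  mask <- labelVoxels(vol$brightness, 10, 2)
  cats <- categorizeVoxels(vol$response, vol$stimuli, mask)
  expect_false(any(cats$forward & cats$backward))
  expect_true(all(cats$forward[!mask] == FALSE))
  stricter <- categorizeVoxels(vol$response, vol$stimuli, mask,
                               voxelCategoryConfig(forward_thresh = 0.8))
  expect_true(all(cats$forward[stricter$forward]))
  expect_lte(sum(stricter$forward), sum(cats$forward))
})

test_that("projection maps count voxels and normalize halves independently", {
  vol <- array(FALSE, c(6, 4, 3))
  expect_true(all(projectMap(vol, 3) == 0))
  vol[2, 2, 1] <- TRUE
  expect_equal(sum(projectMap(vol, 3)), 1)
  # top half max 4, bottom half max 2: both peak at 1 after normalization
  vol2 <- array(FALSE, c(6, 4, 4))
  vol2[2, 2, 1:4] <- TRUE   # 4 voxels in the top half column
  vol2[5, 3, 1:2] <- TRUE   # 2 voxels in the bottom half
  img <- projectMap(vol2, 3, split_halves = TRUE)
  expect_equal(max(img[1:3, ]), 1)
  expect_equal(max(img[4:6, ]), 1)
  # an all-zero half stays zero
  vol2[5, 3, ] <- FALSE
  img2 <- projectMap(vol2, 3, split_halves = TRUE)
  expect_true(all(img2[4:6, ] == 0))
})

test_that("volumes round-trip through multi-page TIFF", {
  skip_if_not_installed("tiff")
  v <- array(rnorm(2 * 3 * 4, 5, 2), c(2, 3, 4))
  f <- tempfile(fileext = ".tif")
  writeVolumeTiff(v, f)
  expect_equal(readVolumeTiff(f), v, tolerance = 1e-6)
  mask <- array(c(TRUE, FALSE), c(2, 3, 4))
  writeVolumeTiff(mask, f)
  expect_equal(readVolumeTiff(f) > 0.5, mask, ignore_attr = TRUE)
})

test_that("percentile partition isolates the top 1% and next 4%", {
  g <- percentilePartition(1:100)
  expect_equal(as.vector(table(g)), c(95, 4, 1))
  expect_equal(which(g == "top1"), 100L)
  # all equal: everything in the bottom group (strict exceedance)
  expect_true(all(percentilePartition(rep(3, 40)) == "rest"))
  expect_error(percentilePartition(numeric(0)), "empty")
})

test_that("forward voxels sit rostral to backward voxels end to end", {
  ds <- smallPopulation(n_fwd = 10, n_bwd = 10, n_ns = 0, seed = 37)
  vol <- generateVoxelVolume(ds, voxel_size_um = 4)
  mask <- labelVoxels(vol$brightness, 10, 2)
  cats <- categorizeVoxels(vol$response, vol$stimuli, mask)
  rcOf <- function(a) {
    idx <- which(a, arr.ind = TRUE)
    mean(vol$origin_um[1] + (idx[, 1] - 1) * vol$voxel_size_um)
  }
  expect_gt(sum(cats$forward), 0)
  expect_gt(sum(cats$backward), 0)
  expect_lt(rcOf(cats$forward), rcOf(cats$backward))
})
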