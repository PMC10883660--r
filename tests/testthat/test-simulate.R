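test_that("zero drive and uniform tuning produce the expected traces", {
  ep <- defaultEpoch()
  # amplitude 0, no noise: flat at baseline
  tr <- simulateTrace(tuningParams(amplitude = 0, noise_sd = 0), ep)
  expect_true(all(tr == 100))
  # kappa 0: same moving-phase plateau for every direction
  p <- generateProtocol(seed = 2)
  epl <- epochs(p)
  # contra-only neuron so the binocular drive equals the amplitude
  tp <- tuningParams(amplitude = 0.5, kappa = 0, noise_sd = 0,
                     w_contra = 1, w_ipsi = 0)
  plateaus <- vapply(which(epl$kind == "translation"), function(j) {
    tr <- simulateTrace(tp, epl[j, ], 1)
    max(tr) / 100 - 1
  }, numeric(1))
  expect_equal(plateaus, rep(plateaus[1], 8))
  expect_lt(abs(plateaus[1] - 0.5), 0.01)   # plateau approaches amplitude
})

test_that("von Mises drive has the closed-form anti-preferred ratio and is linear in amplitude", {
  ep <- as.list(defaultEpoch())
  ep$direction_deg <- 0
  tp <- tuningParams(amplitude = 1, kappa = 4, pd_deg = 0, noise_sd = 0)
  r0 <- max(simulateTrace(tp, ep) / 100 - 1)
  ep$direction_deg <- 180
  r180 <- max(simulateTrace(tp, ep) / 100 - 1)
  expect_equal(r180 / r0, exp(-8), tolerance = 1e-10)
  # doubling amplitude doubles the plateau
  tp2 <- tuningParams(amplitude = 2, kappa = 4, pd_deg = 0, noise_sd = 0)
  ep$direction_deg <- 0
  expect_equal(max(simulateTrace(tp2, ep) / 100 - 1), 2 * r0,
               tolerance = 1e-10)
})

test_that("monocular weighting gates the per-eye drive", {
  ep <- as.list(defaultEpoch())
  ep$eye <- "left"
  # left-side neuron, w_ipsi = 0: left-eye stimulation drives nothing
  tp <- tuningParams(amplitude = 1, kappa = 0, w_contra = 1, w_ipsi = 0,
                     noise_sd = 0)
  expect_true(all(simulateTrace(tp, ep, side = "left") == 100))
  # same epoch seen from the right side is contralateral: full drive
  expect_gt(max(simulateTrace(tp, ep, side = "right")), 100)
  # binocular drive is the sum of the per-eye drives
  ep$eye <- "both"
  tpb <- tuningParams(amplitude = 1, kappa = 0, w_contra = 0.7,
                      w_ipsi = 0.3, noise_sd = 0)
  ep_l <- ep; ep_l$eye <- "left"
  ep_r <- ep; ep_r$eye <- "right"
  both <- max(simulateTrace(tpb, ep, side = "left") - 100)
  expect_equal(both,
               max(simulateTrace(tpb, ep_l, side = "left") - 100) +
                 max(simulateTrace(tpb, ep_r, side = "left") - 100),
               tolerance = 1e-9)
})

test_that("population generation is seeded, labeled and topographic", {
  spec <- populationSpec(n_per_class = c(forward = 10, backward = 10,
                                         cw_rotation = 0, ccw_rotation = 0,
                                         nonselective = 0), seed = 21)
  d1 <- generatePopulation(spec)
  d2 <- generatePopulation(spec)
  expect_identical(d1@groundTruth, d2@groundTruth)
  expect_identical(d1@neurons[[3]]@traces[[2]], d2@neurons[[3]]@traces[[2]])
  gt <- d1@groundTruth
  # forward PDs in the forward half, and rostral to backward neurons
  expect_true(all(cos(gt$pd_true[gt$class == "forward"] * pi / 180) > 0))
  expect_lt(mean(gt$rc[gt$class == "forward"]),
            mean(gt$rc[gt$class == "backward"]))
  expect_error(generatePopulation(populationSpec(
    n_per_class = c(forward = 0, backward = 0, cw_rotation = 0,
                    ccw_rotation = 0, nonselective = 0))),
    "zero neurons")
})

test_that("rotation classes are lateralized (CW right, CCW left)", {
  spec <- populationSpec(n_per_class = c(forward = 0, backward = 0,
                                         cw_rotation = 12,
                                         ccw_rotation = 12,
                                         nonselective = 0), seed = 4)
  gt <- generatePopulation(spec)@groundTruth
  expect_gt(mean(gt$lr[gt$class == "cw_rotation"]), 0)
  expect_lt(mean(gt$lr[gt$class == "ccw_rotation"]), 0)
})

test_that("voxel volume renders blobs at centroids with tuned responses", {
  spec <- populationSpec(n_per_class = c(forward = 1, backward = 0,
                                         cw_rotation = 0, ccw_rotation = 0,
                                         nonselective = 0),
                         pd_jitter_deg = 0, seed = 8)
  ds <- generatePopulation(spec)
  vol <- generateVoxelVolume(ds, voxel_size_um = 2)
  # brightness peak at the neuron centroid voxel
  peak <- which(vol$brightness == max(vol$brightness), arr.ind = TRUE)[1, ]
  cen <- ds@groundTruth[1, c("rc", "lr", "dv")]
  est <- vol$origin_um + (peak - 1) * vol$voxel_size_um
  expect_true(all(abs(est - as.numeric(cen)) <= vol$voxel_size_um))
  # forward-tuned: mean over forward stimuli beats mean over backward ones
  st <- vol$stimuli
  fwd <- which(st$direction_deg %in% c(315, 0, 45))
  bwd <- which(st$direction_deg %in% c(135, 180, 225))
  v <- vol$response[peak[1], peak[2], peak[3], ]
  expect_gt(mean(v[fwd]), mean(v[bwd]))
  expect_error(generateVoxelVolume(
    new("SyntheticDataset", protocol = ds@protocol, neurons = list(),
        groundTruth = ds@groundTruth[0, ], anatomy = list())),
    "empty|neuron")
})

test_that("skeleton generation honors terminals and endpoint counts", {
  # straight soma-terminal polyline: 2 endpoints
  sk <- generateSkeletons(list(rbind(c(10, 0))), rbind(c(0, 0)), seed = 1)
  expect_equal(nrow(skeletonEndpoints(rasterizeSkeleton(sk[[1]]))), 2)
  # 3-leaf tree: root + 3 leaves = 4 endpoints on the rasterized mask
  sk3 <- generateSkeletons(list(rbind(c(10, 10), c(10, -10), c(14, 0))),
                           rbind(c(-10, 0)), seed = 2)
  m3 <- rasterizeSkeleton(sk3[[1]])
  expect_equal(nrow(suppressWarnings(skeletonEndpoints(m3))), 4)
  # leaves sit exactly at the requested terminals
  leaves <- sk3[[1]][sk3[[1]]$type == 6, c("x", "y")]
  expect_equal(as.matrix(leaves), rbind(c(10, 10), c(10, -10), c(14, 0)),
               ignore_attr = TRUE)
  expect_error(generateSkeletons(list(NULL), rbind(c(0, 0))), "terminal")
})

test_that("SWC files round-trip", {
  sk <- generateSkeletons(list(rbind(c(5, 3), c(2, 8))), rbind(c(0, 0)),
                          seed = 3)[[1]]
  f <- tempfile(fileext = ".swc")
  writeSwc(sk, f)
  back <- readSwc(f)
  expect_equal(back$x, sk$x, tolerance = 1e-4)
  expect_equal(back$parent, sk$parent)
})
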