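test_that("monocular index anchors, antisymmetry and scale invariance", {
  expect_equal(monocularIndex(0.6, 0), 1)
  expect_equal(monocularIndex(0.3, 0.3), 0)
  expect_equal(monocularIndex(0.6, 0.2), 0.5)
  set.seed(2)
  for (k in 1:10) {
    a <- runif(1); b <- runif(1)
    expect_equal(monocularIndex(a, b), -monocularIndex(b, a))
    expect_equal(monocularIndex(3 * a, 3 * b), monocularIndex(a, b))
  }
  expect_warning(out <- monocularIndex(0, 0), "undefined")
  expect_true(is.na(out))
})

test_that("quadrant groups follow the signs of the monocular PD cosines", {
  expect_equal(as.character(quadrantGroup(10, -20)), "both_forward")
  expect_equal(as.character(quadrantGroup(10, 170)),
               "left_forward_right_backward")
  expect_equal(as.character(quadrantGroup(-170, 20)),
               "right_forward_left_backward")
  expect_equal(as.character(quadrantGroup(-170, 170)), "both_backward")
  expect_equal(as.character(quadrantGroup(10, NA)), "unclassified")
  expect_true(attr(quadrantGroup(10, 170), "opposing"))
  expect_false(attr(quadrantGroup(10, 20), "opposing"))
})

test_that("per-eye tuning separates contralateral-only neurons and symmetric ones", {
  pm <- generateProtocol(monocular_blocks = TRUE, seed = 4)
  ep <- epochs(pm)
  # w_ipsi = 0, left-side neuron: tuned via the right (contra) eye only
  tp <- tuningParams(amplitude = 0.8, kappa = 4, pd_deg = 0,
                     w_contra = 1, w_ipsi = 0, noise_sd = 0.5)
  traces <- lapply(seq_len(nrow(ep)), function(j)
    simulateTrace(tp, ep[j, ], 3, seed = 100 + j, side = "left"))
  nr <- new("NeuronRecord", id = "n1", centroid = c(0, -5, 0),
            side = "left", traces = traces)
  se <- responseTable(list(nr), pm)
  ey <- perEyeTuning(se, 1, n_shuffles = 300, seed = 6)
  expect_false(ey$left$selective)
  expect_true(ey$right$selective)
  expect_true(ey$both$selective)
  # symmetric weights, same pd per eye: all three PDs agree
  tps <- tuningParams(amplitude = 0.8, kappa = 4, pd_deg = 45,
                      w_contra = 0.8, w_ipsi = 0.8, noise_sd = 0.5)
  traces2 <- lapply(seq_len(nrow(ep)), function(j)
    simulateTrace(tps, ep[j, ], 3, seed = 200 + j, side = "left"))
  nr2 <- new("NeuronRecord", id = "n2", centroid = c(0, -5, 0),
             side = "left", traces = traces2)
  se2 <- responseTable(list(nr2), pm)
  ey2 <- perEyeTuning(se2, 1, n_shuffles = 300, seed = 6)
  expect_true(ey2$left$selective && ey2$right$selective &&
                ey2$both$selective)
  expect_lt(max(abs(olivemotion:::wrapAngle(
    c(ey2$left$pd_deg, ey2$right$pd_deg, ey2$both$pd_deg) - 45))), 10)
})

test_that("monocular table shows the configured contralateral bias and opposing PDs", {
  pm <- generateProtocol(monocular_blocks = TRUE, seed = 9)
  spec <- populationSpec(
    n_per_class = c(forward = 6, backward = 6, cw_rotation = 0,
                    ccw_rotation = 0, nonselective = 0),
    tuning = tuningParams(amplitude = 0.8, kappa = 4, noise_sd = 2,
                          w_contra = 1, w_ipsi = 0.4),
    seed = 19)
  ds <- generatePopulation(spec, pm)
  mt <- monocularTable(se = responseTable(ds), n_shuffles = 300, seed = 8)
  expect_gt(median(mt$monocular_index, na.rm = TRUE), 0)
  # opposing ground-truth per-eye PDs produce the opposing flag
  ep <- epochs(pm)
  tpo <- tuningParams(amplitude = 0.8, kappa = 4, noise_sd = 0.5,
                      pd_left_deg = 0, pd_right_deg = 180,
                      w_contra = 1, w_ipsi = 1)
  traces <- lapply(seq_len(nrow(ep)), function(j)
    simulateTrace(tpo, ep[j, ], 3, seed = 300 + j, side = "left"))
  nr <- new("NeuronRecord", id = "op", centroid = c(0, -5, 0),
            side = "left", traces = traces)
  mo <- monocularTable(responseTable(list(nr), pm), n_shuffles = 300,
                       seed = 10)
  expect_true(mo$opposing[1])
  expect_equal(mo$quadrant_group[1], "left_forward_right_backward")
})

test_that("CW-type opposing-field neurons respond maximally to binocular CW when gains follow the fields", {
  # emulation contract: a neuron whose left field prefers forward and right
  # field backward is built as CW-rotation-responsive
  ep <- epochs(generateProtocol(include_conv_div = TRUE,
                                monocular_blocks = TRUE, seed = 3))
  tpo <- tuningParams(amplitude = 0.8, kappa = 4, noise_sd = 0,
                      pd_left_deg = 0, pd_right_deg = 180,
                      rot_gain_cw = 0.6, rot_gain_ccw = 0.05,
                      w_contra = 1, w_ipsi = 1)
  rot <- ep[ep$block == "both" & ep$kind == "rotation" & !ep$discard, ]
  resp <- vapply(seq_len(nrow(rot)), function(j) {
    tr <- simulateTrace(tpo, rot[j, ], 1, side = "left")
    max(tr) / 100 - 1
  }, numeric(1))
  names(resp) <- rot$rotation_label
  expect_equal(names(which.max(resp)), "CW")
})
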