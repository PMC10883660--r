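#' Pipeline run configuration
#'
#' Bundles the stimulus-protocol parameters, the synthetic population
#' specification and the analysis constants. Defaults are the canonical
#' analysis settings: the 2-SD responding criterion, 1,000 shuffles at
#' alpha 0.05 for direction selectivity, 10,000 bootstrap resamples with
#' Bonferroni correction over 6 comparisons (threshold percentile 99.17)
#' for the matching index, a 10-pixel KDE kernel, and the voxel category
#' thresholds of [voxelCategoryConfig()].
#'
#' @param protocol list of arguments for [generateProtocol()].
#' @param population a [populationSpec()].
#' @param n_shuffles,alpha shuffle-test settings.
#' @param n_boot,n_comparisons matching-index bootstrap settings.
#' @param kernel_sd KDE kernel SD, pixels.
#' @param grid_spacing KDE grid spacing, pixels.
#' @param voxel a [voxelCategoryConfig()].
#' @param voxel_size_um,background_level synthetic volume settings.
#' @param seed master seed; all stage seeds derive from it.
#' @param outdir output directory, or NULL to keep results in memory only.
#' @return list of class "RunConfig".
#' @export
runConfig <- function(protocol = list(), population = populationSpec(),
                      n_shuffles = 1000, alpha = 0.05, n_boot = 10000,
                      n_comparisons = 6, kernel_sd = 10, grid_spacing = 2,
                      voxel = voxelCategoryConfig(), voxel_size_um = 2,
                      background_level = 10, seed = 1L, outdir = NULL) {
  stopifnot(n_shuffles > 0, alpha > 0, alpha < 1, n_boot > 0,
            n_comparisons >= 1, kernel_sd > 0, grid_spacing > 0,
            voxel_size_um > 0, inherits(population, "PopulationSpec"),
            inherits(voxel, "VoxelCategoryConfig"))
  if (sum(population$n_per_class) == 0)
    stop("population has zero neurons")
  structure(list(protocol = protocol, population = population,
                 n_shuffles = n_shuffles, alpha = alpha, n_boot = n_boot,
                 n_comparisons = n_comparisons, kernel_sd = kernel_sd,
                 grid_spacing = grid_spacing, voxel = voxel,
                 voxel_size_um = voxel_size_um,
                 background_level = background_level,
                 seed = as.integer(seed), outdir = outdir),
            class = "RunConfig")
}

#' @rdname runConfig
#' @param path YAML file whose top-level keys are \code{runConfig}
#'   arguments (nested lists for \code{protocol}, \code{population},
#'   \code{voxel}).
#' @export
readRunConfig <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read config files")
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$population)) {
    if (is.list(raw$population$n_per_class))
      raw$population$n_per_class <- unlist(raw$population$n_per_class)
    raw$population <- do.call(populationSpec, raw$population)
  }
  if (!is.null(raw$voxel)) raw$voxel <- do.call(voxelCategoryConfig,
                                                raw$voxel)
  do.call(runConfig, raw)
}

#' Run the full analysis pipeline on a synthetic population
#'
#' Stages: simulate (protocol + population), extract (response table),
#' tuning (DSI/PD/shuffle test/rotation class), voxels (volume rendering,
#' labeling, categorization, projections) and overlap (matching index for
#' the forward/backward vs unipolar/multipolar mapping, in the soma region
#' and, via synthetic skeleton endpoints, the axon-terminal region). When
#' the protocol has monocular blocks a binocular stage (monocular index,
#' per-eye PDs, quadrant groups) is added. Identical config and seed
#' reproduce every table exactly; when \code{config$outdir} is set, tables
#' are written as CSV with a JSON manifest.
#'
#' @param config a [runConfig()].
#' @return list of class "RunReport" with per-stage results and counts.
#' @export
runPipeline <- function(config = runConfig()) {
  stopifnot(inherits(config, "RunConfig"))
  seeds <- withSeed(config$seed,
                    sample.int(.Machine$integer.max %/% 2, 8))
  warn <- character(0)
  addWarn <- function(w) warn <<- c(warn, conditionMessage(w))

  # --- simulate ---------------------------------------------------------
  proto_args <- config$protocol
  proto_args$seed <- proto_args$seed %||% seeds[1]
  protocol <- do.call(generateProtocol, proto_args)
  pop <- config$population
  pop$seed <- seeds[2]
  dataset <- generatePopulation(pop, protocol)

  # --- extract ----------------------------------------------------------
  se <- withCallingHandlers(responseTable(dataset), warning = function(w) {
    addWarn(w); invokeRestart("muffleWarning")
  })
  rd <- SummarizedExperiment::rowData(se)

  # --- tuning -----------------------------------------------------------
  tt <- withCallingHandlers(
    tuningTable(se, n_shuffles = config$n_shuffles, alpha = config$alpha,
                seed = seeds[3]),
    warning = function(w) { addWarn(w); invokeRestart("muffleWarning") })
  gt <- dataset@groundTruth

  # --- binocular (monocular protocols only) -----------------------------
  mono <- NULL
  if (isTRUE(proto_args$monocular_blocks))
    mono <- withCallingHandlers(
      monocularTable(se, n_shuffles = config$n_shuffles,
                     alpha = config$alpha, seed = seeds[4]),
      warning = function(w) { addWarn(w); invokeRestart("muffleWarning") })

  # --- voxels -----------------------------------------------------------
  vol <- generateVoxelVolume(dataset, voxel_size_um = config$voxel_size_um,
                             background_level = config$background_level,
                             seed = seeds[5])
  mask <- labelVoxels(vol$brightness, config$background_level,
                      config$voxel$brightness_offset)
  cats <- categorizeVoxels(vol$response, vol$stimuli, mask, config$voxel)
  proj <- lapply(cats[c("forward", "backward", "cw_rot", "ccw_rot")],
                 projectMap, axis = 3)

  # --- overlap ----------------------------------------------------------
  fb <- pdCosineSplit(tt$pd_deg[tt$selective])
  sel_idx <- which(tt$selective)
  fwd_idx <- sel_idx[fb$forward]; bwd_idx <- sel_idx[fb$backward]
  overlap <- NULL
  if (length(fwd_idx) >= 2 && length(bwd_idx) >= 2) {
    fun_soma <- list(forward = cbind(rd$rc[fwd_idx], rd$lr[fwd_idx]),
                     backward = cbind(rd$rc[bwd_idx], rd$lr[bwd_idx]))
    an <- dataset@anatomy
    anat_soma <- split(cbind(an$somata$x, an$somata$y), an$somata$class)
    anat_soma <- lapply(anat_soma[c("unipolar", "multipolar")],
                        matrix, ncol = 2)
    anat_term <- split(cbind(an$terminals$x, an$terminals$y),
                       an$terminals$class)
    anat_term <- lapply(anat_term[c("unipolar", "multipolar")],
                        matrix, ncol = 2)
    fun_term <- functionalTerminalPoints(an, length(fwd_idx),
                                         length(bwd_idx), pop, seeds[6])
    overlap <- list(
      soma = overlapTest(anat_soma, fun_soma, n = config$n_boot,
                         kernel_sd = config$kernel_sd,
                         spacing = config$grid_spacing,
                         alpha = config$alpha,
                         n_comparisons = config$n_comparisons,
                         seed = seeds[7]),
      neuropil = overlapTest(anat_term, fun_term, n = config$n_boot,
                             kernel_sd = config$kernel_sd,
                             spacing = config$grid_spacing,
                             alpha = config$alpha,
                             n_comparisons = config$n_comparisons,
                             seed = seeds[8]))
    overlap$both_regions <- combineRegions(overlap[c("soma", "neuropil")])
  }

  counts <- list(
    n_neurons = nrow(gt),
    n_active = sum(rd$active),
    n_selective = sum(tt$selective),
    class_counts = table(tt$class),
    voxel_counts = vapply(cats[c("forward", "backward", "cw_rot",
                                 "ccw_rot", "leftward", "rightward")],
                          sum, 1)
  )
  report <- structure(list(
    config = config, protocol = protocol, dataset = dataset,
    responses = se, tuning = tt, monocular = mono,
    voxels = list(volume = vol, mask = mask, categories = cats,
                  projections = proj),
    overlap = overlap, counts = counts, warnings = warn,
    seeds = seeds
  ), class = "RunReport")
  if (!is.null(config$outdir)) writeRunReport(report, config$outdir)
  report
}

# Functional axon-terminal point sets for the neuropil region: each
# forward (backward) neuron gets a skeleton whose terminals scatter around
# the unipolar (multipolar) terminal cluster; endpoint extraction on the
# rasterized skeletons supplies the points, exercising the same machinery a
# traced morphology would go through.
functionalTerminalPoints <- function(anatomy, n_fwd, n_bwd, pop, seed) {
  withSeed(seed, {
    mk <- function(n, cls) {
      mu <- colMeans(as.matrix(
        anatomy$terminals[anatomy$terminals$class == cls, c("x", "y")]))
      s <- pop$anatomy_spread_um
      pts <- lapply(seq_len(n), function(i)
        cbind(rnorm(2, mu[1], s), rnorm(2, mu[2], s)))
      somas <- cbind(rnorm(n, mu[1], 3 * s), rnorm(n, mu[2], 3 * s))
      sk <- generateSkeletons(pts, somas, seed = NULL)
      do.call(rbind, lapply(sk, function(s1) {
        m <- rasterizeSkeleton(s1)
        # segments meeting at the branch node can rasterize 2x2-thick;
        # the endpoint search then thins first, which is fine here
        epix <- suppressWarnings(skeletonEndpoints(m))
        org <- attr(m, "origin"); sp <- attr(m, "spacing")
        cbind(org[1] + (epix[, 1] - 1) * sp, org[2] + (epix[, 2] - 1) * sp)
      }))
    }
    list(forward = mk(n_fwd, "unipolar"), backward = mk(n_bwd, "multipolar"))
  })
}

#' Format a count as "n/N (percent)"
#'
#' @param n,N numerator and denominator counts.
#' @param digits decimal places of the percentage (0 for whole-population
#'   fractions, 1 for subgroup fractions).
#' @return character scalar, e.g. \code{"891/1,106 (81\%)"}.
#' @examples
#' formatFraction(891, 1106)            # "891/1,106 (81%)"
#' formatFraction(91, 340, digits = 1)  # "91/340 (26.8%)"
#' @export
formatFraction <- function(n, N, digits = 0) {
  stopifnot(N > 0, n >= 0, n <= N)
  pct <- round(100 * n / N, digits)
  sprintf("%s/%s (%s%%)",
          format(n, big.mark = ",", scientific = FALSE, trim = TRUE),
          format(N, big.mark = ",", scientific = FALSE, trim = TRUE),
          format(pct, nsmall = digits, trim = TRUE))
}

#' Summary table of a pipeline run
#'
#' Headline fractions in reporting style: active neurons out of all
#' imaged, direction-selective out of active, per-class counts, and the
#' overlap verdicts.
#'
#' @param report a "RunReport" from [runPipeline()].
#' @return data.frame with columns quantity, value.
#' @export
summarizeRun <- function(report) {
  stopifnot(inherits(report, "RunReport"))
  ct <- report$counts
  rows <- list(
    c("active neurons", formatFraction(ct$n_active, ct$n_neurons)),
    c("direction-selective (of active)",
      if (ct$n_active > 0)
        formatFraction(ct$n_selective, ct$n_active, digits = 1) else "0/0")
  )
  for (cl in names(ct$class_counts))
    if (cl != "none")
      rows <- c(rows, list(c(paste0("class ", cl),
                             format(ct$class_counts[[cl]]))))
  if (!is.null(report$overlap)) {
    rows <- c(rows, list(
      c("MI soma region", sprintf("%.3f (thr %.3f)%s",
                                  report$overlap$soma@mi,
                                  report$overlap$soma@threshold,
                                  if (report$overlap$soma@significant)
                                    " *" else "")),
      c("MI neuropil region", sprintf("%.3f (thr %.3f)%s",
                                      report$overlap$neuropil@mi,
                                      report$overlap$neuropil@threshold,
                                      if (report$overlap$neuropil@significant)
                                        " *" else "")),
      c("matched in both regions",
        if (report$overlap$both_regions) "yes" else "no")))
  }
  data.frame(quantity = vapply(rows, `[`, "", 1),
             value = vapply(rows, `[`, "", 2), stringsAsFactors = FALSE)
}

# CSV tables + JSON manifest for a run.
writeRunReport <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  writeResponseCsv(report$responses, file.path(outdir, "responses.csv"))
  write.csv(report$tuning, file.path(outdir, "tuning.csv"),
            row.names = FALSE)
  if (!is.null(report$monocular))
    write.csv(report$monocular, file.path(outdir, "monocular.csv"),
              row.names = FALSE)
  write.csv(report$dataset@groundTruth,
            file.path(outdir, "ground_truth.csv"), row.names = FALSE)
  summ <- summarizeRun(report)
  write.csv(summ, file.path(outdir, "summary.csv"), row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("olivemotion")),
    seed = report$config$seed,
    stage_seeds = report$seeds,
    counts = list(n_neurons = report$counts$n_neurons,
                  n_active = report$counts$n_active,
                  n_selective = report$counts$n_selective),
    warnings = report$warnings
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}
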