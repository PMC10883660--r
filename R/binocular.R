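#' Monocular index
#'
#' Quantifies the eye bias of a neuron as (contra - ipsi) / (contra + ipsi),
#' where contra and ipsi are its mean responses to stimuli presented to the
#' contralateral and ipsilateral eye, averaged across repetitions and the
#' eight translational directions (rotational stimuli carry no direction
#' label and are excluded). Ranges from -1 (ipsi-monocular) through 0
#' (balanced binocular) to +1 (contra-monocular).
#'
#' @param contra,ipsi mean responses (scalars, or vectors over the same
#'   stimulus subset which are averaged first).
#' @return scalar index, or NA (with a warning) when contra + ipsi == 0.
#' @examples
#' monocularIndex(0.6, 0)    # +1
#' monocularIndex(0.3, 0.3)  # 0
#' @export
monocularIndex <- function(contra, ipsi) {
  mc <- mean(contra); mi <- mean(ipsi)
  s <- mc + mi
  if (s == 0) {
    warning("monocular index undefined: contra + ipsi == 0")
    return(NA_real_)
  }
  (mc - mi) / s
}

#' Per-eye tuning of one neuron
#'
#' Applies the DSI + shuffle-test machinery independently to the left-eye,
#' right-eye and binocular stimulation blocks of a monocular protocol. A
#' neuron may be selective in one block only.
#'
#' @param se [responseTable()] result built from a monocular-block protocol.
#' @param neuron row index or id.
#' @param n_shuffles,alpha,seed shuffle-test settings.
#' @return list with per-block elements (dsi, pd_deg, selective) named
#'   left, right, both.
#' @export
perEyeTuning <- function(se, neuron, n_shuffles = 1000, alpha = 0.05,
                         seed = 1L) {
  if (is.character(neuron)) neuron <- match(neuron, rownames(se))
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  blocks <- c("left", "right", "both")
  if (!all(blocks %in% cd$block))
    stop("protocol must contain left, right and binocular blocks")
  reps <- S4Vectors::metadata(se)$rep_responses[[neuron]]
  seeds <- withSeed(seed, sample.int(.Machine$integer.max %/% 2, 3))
  out <- lapply(seq_along(blocks), function(b) {
    sel <- which(cd$block == blocks[b] & cd$kind == "translation")
    st <- tryCatch(
      shuffleTest(reps[sel], cd$direction_deg[sel], n_shuffles = n_shuffles,
                  alpha = alpha, seed = seeds[b]),
      error = function(e) NULL)
    if (is.null(st))
      list(dsi = NA_real_, pd_deg = NA_real_, selective = FALSE)
    else
      list(dsi = st$dsi, pd_deg = st$pd_deg,
           selective = st$is_direction_selective)
  })
  names(out) <- blocks
  out
}

#' Opposing-PD quadrant group
#'
#' Groups a neuron by the signs of the cosines of its left-eye and
#' right-eye preferred directions: (+,+) both_forward; (-,-) both_backward;
#' (+,-) left_forward_right_backward (the CW-rotation-type combination);
#' (-,+) right_forward_left_backward (CCW-type). Neurons lacking a defined
#' PD in either eye are "unclassified".
#'
#' @param pd_left_deg,pd_right_deg monocular preferred directions (degrees);
#'   NA when the neuron is not selective in that block.
#' @return character group label; also reports \code{opposing} as an
#'   attribute (TRUE when the two cosine signs differ).
#' @export
quadrantGroup <- function(pd_left_deg, pd_right_deg) {
  if (is.na(pd_left_deg) || is.na(pd_right_deg)) {
    out <- "unclassified"
    attr(out, "opposing") <- NA
    return(out)
  }
  cl <- cos(deg2rad(pd_left_deg)); cr <- cos(deg2rad(pd_right_deg))
  out <- if (cl > 0 && cr > 0) "both_forward"
    else if (cl < 0 && cr < 0) "both_backward"
    else if (cl > 0 && cr < 0) "left_forward_right_backward"
    else if (cl < 0 && cr > 0) "right_forward_left_backward"
    else "unclassified"   # a cosine exactly 0
  attr(out, "opposing") <- (sign(cl) != sign(cr)) && cl != 0 && cr != 0
  out
}

#' Binocular-integration analysis of a whole response table
#'
#' For every neuron of a monocular-protocol [responseTable()]: the monocular
#' index over the eight translational directions (contra/ipsi resolved from
#' the neuron's side), per-eye and binocular tuning, the opposing-PD flag
#' and the quadrant group.
#'
#' @inheritParams perEyeTuning
#' @param se the response table.
#' @param n_shuffles,alpha,seed shuffle-test settings.
#' @return data.frame: id, side, monocular_index, pd_left_deg,
#'   pd_right_deg, pd_binocular_deg, selective flags, opposing,
#'   quadrant_group.
#' @export
monocularTable <- function(se, n_shuffles = 1000, alpha = 0.05, seed = 1L) {
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  rd <- SummarizedExperiment::rowData(se)
  resp <- SummarizedExperiment::assay(se, "response")
  sel_L <- which(cd$block == "left" & cd$kind == "translation")
  sel_R <- which(cd$block == "right" & cd$kind == "translation")
  seeds <- withSeed(seed, sample.int(.Machine$integer.max %/% 2, nrow(se)))

  rows <- lapply(seq_len(nrow(se)), function(i) {
    contra_sel <- if (rd$side[i] == "left") sel_R else sel_L
    ipsi_sel <- if (rd$side[i] == "left") sel_L else sel_R
    mi <- withCallingHandlers(
      monocularIndex(resp[i, contra_sel], resp[i, ipsi_sel]),
      warning = function(w) invokeRestart("muffleWarning"))
    ey <- perEyeTuning(se, i, n_shuffles = n_shuffles, alpha = alpha,
                       seed = seeds[i])
    pdl <- if (ey$left$selective) ey$left$pd_deg else NA_real_
    pdr <- if (ey$right$selective) ey$right$pd_deg else NA_real_
    qg <- quadrantGroup(pdl, pdr)
    data.frame(id = rownames(se)[i], side = rd$side[i],
               monocular_index = mi,
               pd_left_deg = pdl, pd_right_deg = pdr,
               pd_binocular_deg = if (ey$both$selective) ey$both$pd_deg
                                  else NA_real_,
               selective_left = ey$left$selective,
               selective_right = ey$right$selective,
               selective_binocular = ey$both$selective,
               opposing = attr(qg, "opposing"),
               quadrant_group = as.character(qg),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
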