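# End-to-end phantom validation experiment and the generic stage chain.

#' Default configuration of the phantom validation experiment
#'
#' All printed acquisition/reconstruction parameters are the shipped
#' defaults: the default phantom, Poisson noise, structure tensors at
#' centre frequency pi/(3 sqrt 2) with an 11^3 kernel and 2-octave
#' bandwidth, 7^3 Gaussian element smoothing, 28^3 block downsampling
#' (nominally 100 um from 3.6 um data), and the five-point centre
#' frequency / kernel size sweep.
#'
#' @param spec a [phantomSpec()].
#' @param noiseSeed integer Poisson seed.
#' @param sweep data.frame of \code{centreFreq}/\code{size} pairs examined
#'   in addition to the main reconstruction (set to NULL to skip).
#' @param ... overrides for the remaining fields (centreFreq, bandwidth,
#'   kernelSize, smoothSize, downsampleFactor, tensorVariant, pad,
#'   truthEigenvalues).
#' @return A named list understood by [runPhantomValidation()].
#' @export
validationConfig <- function(spec = phantomSpec(), noiseSeed = 1L,
                             sweep = kernelSweepTable(), ...) {
  cfg <- list(
    spec = spec,
    noiseSeed = noiseSeed,
    centreFreq = pi / (3 * sqrt(2)),
    bandwidth = 2,
    kernelSize = 11L,
    smoothSize = 7L,
    downsampleFactor = 28L,
    tensorVariant = "printed",
    pad = "replicate",
    truthEigenvalues = c(1.5e-3, 1.0e-3, 0.7e-3),
    sweep = sweep)
  extra <- list(...)
  bad <- setdiff(names(extra), names(cfg))
  if (length(bad)) stop("unknown config fields: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(extra)] <- extra
  cfg
}

#' Read / write a validation configuration as YAML
#'
#' The phantom specification is embedded as a named list; all other fields
#' are scalars, so a round trip reproduces an identical run plan.
#'
#' @param cfg a [validationConfig()] list.
#' @param path YAML file path.
#' @return \code{readValidationConfig} returns the configuration list.
#' @export
writeValidationConfig <- function(cfg, path) {
  sl <- slotNames(cfg$spec)
  specList <- lapply(sl, function(s) slot(cfg$spec, s))
  names(specList) <- sl
  out <- cfg
  out$spec <- specList
  out$sweep <- if (is.null(cfg$sweep)) NULL else as.list(cfg$sweep)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname writeValidationConfig
#' @export
readValidationConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$spec <- do.call(phantomSpec, raw$spec)
  if (!is.null(raw$sweep))
    raw$sweep <- data.frame(centreFreq = unlist(raw$sweep$centreFreq),
                            size = as.integer(unlist(raw$sweep$size)))
  raw$kernelSize <- as.integer(raw$kernelSize)
  raw$smoothSize <- as.integer(raw$smoothSize)
  raw$downsampleFactor <- as.integer(raw$downsampleFactor)
  raw$noiseSeed <- as.integer(raw$noiseSeed)
  raw
}

# Structure-tensor stage chain: filter, assemble, smooth, downsample,
# eigendecompose. Partial trailing blocks are kept so the coarse grid
# reaches the far faces of the slab.
#' @noRd
.stChain <- function(volume, voxelSize, centreFreq, kernelSize, bandwidth,
                     smoothSize, factor, variant, pad, exclude = NULL) {
  bank <- designBank(centreFreq, bandwidth, kernelSize)
  st <- computeStructureTensor(volume, bank, voxelSize, variant, pad)
  st <- smoothTensors(st, smoothSize, pad = pad)
  coarse <- downsampleTensors(st, factor, exclude = exclude, partial = TRUE)
  eigenDecompose(coarse)
}

# Classify the correspondence of each ST eigenvector with the truth axes
# by the mean absolute dot product over defined coarse voxels.
#' @noRd
.classifyEigenvectors <- function(es, ref, vol) {
  cd <- dim(ref$count)
  th <- NULL
  # truth axes per coarse voxel from the reference orientation (long axis)
  # and the slab sheet-normal (+x)
  labels <- c("sheet-normal", "sheetlet", "cell long-axis")
  score <- matrix(0, 3, 3,
                  dimnames = list(paste0("v", 1:3), labels))
  nUsed <- 0L
  for (i in seq_len(prod(cd))) {
    ijk <- arrayInd(i, cd)
    u <- ref$orientation[ijk[1], ijk[2], ijk[3], ]
    if (anyNA(u)) next
    nrm <- c(1, 0, 0)
    nrm <- nrm - sum(nrm * u) * u
    nrm <- nrm / sqrt(sum(nrm^2))
    s <- c(nrm[2] * u[3] - nrm[3] * u[2], nrm[3] * u[1] - nrm[1] * u[3],
           nrm[1] * u[2] - nrm[2] * u[1])
    axes <- cbind(nrm, s, u)
    for (k in 1:3) {
      v <- es@vectors[ijk[1], ijk[2], ijk[3], , k]
      if (anyNA(v)) next
      score[k, ] <- score[k, ] + abs(drop(v %*% axes))
    }
    nUsed <- nUsed + 1L
  }
  score <- score / nUsed
  data.frame(eigenvector = rownames(score),
             correspondence = labels[apply(score, 1, which.max)],
             meanAbsDot = apply(score, 1, max))
}

#' Run the phantom validation experiment
#'
#' Executes the full chain: build the phantom, add Poisson noise, compute
#' the structure tensor field (filter bank, Eq-style assembly, Gaussian
#' smoothing, block downsampling to the nominal 100 um grid),
#' eigendecompose, and map helix/transverse angles in the slab frame; then
#' compute the voxel-averaged ground-truth reference and compare:
#' per-transmural-layer mean +/- SD tables, Bland-Altman agreement, and —
#' for every sweep entry — the classification of which truth axis each ST
#' eigenvector tracks.
#'
#' @param cfg a [validationConfig()].
#' @param verbose print stage progress.
#' @return list with \code{layerTable} (data.frame), \code{agreement}
#'   (list of HA and TA [AgreementReport-class]s), \code{stAngles},
#'   \code{refAngles} ([AngleMaps-class]), \code{eigen}
#'   ([EigenSystem-class]), \code{sweep} (data.frame of eigenvector
#'   correspondences per kernel), \code{config}.
#' @export
runPhantomValidation <- function(cfg = validationConfig(), verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  stage <- function(tag, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", tag, conditionMessage(e)), call. = FALSE))
  }
  say("building phantom")
  vol <- stage("phantom", buildPhantom(cfg$spec))
  noisy <- stage("noise", addPoissonNoise(vol, cfg$noiseSeed))
  f <- cfg$downsampleFactor
  say("structure tensor chain")
  es <- stage("structure-tensor",
              .stChain(intensity(noisy), voxelSize(vol), cfg$centreFreq,
                       cfg$kernelSize, cfg$bandwidth, cfg$smoothSize, f,
                       cfg$tensorVariant, cfg$pad))
  cd <- dim(es@values)[1:3]
  frames <- slabFrames(cd, es@voxelSize)
  stAngles <- stage("angles", computeAngles(es, frames, cellVector = "v3",
                                            sheetVector = "v2"))
  say("ground-truth reference")
  ref <- stage("reference",
               voxelAverageReference(vol, f * voxelSize(vol),
                                     partial = TRUE))
  refAngles <- ref$angles
  layer <- function(m) apply(m, 1, mean, na.rm = TRUE)
  layerSd <- function(m) apply(m, 1, stats::sd, na.rm = TRUE)
  layerTable <- data.frame(
    layer = seq_len(cd[1]),
    depthFrom = (seq_len(cd[1]) - 1) * f * voxelSize(vol),
    haSt = layer(stAngles@ha), haStSd = layerSd(stAngles@ha),
    taSt = layer(stAngles@ta), taStSd = layerSd(stAngles@ta),
    haRef = layer(refAngles@ha), taRef = layer(refAngles@ta))
  agreement <- list(
    ha = stage("agreement", blandAltman(stAngles@ha, refAngles@ha)),
    ta = stage("agreement", blandAltman(stAngles@ta, refAngles@ta)))
  sweep <- NULL
  if (!is.null(cfg$sweep) && nrow(cfg$sweep)) {
    rows <- list()
    for (i in seq_len(nrow(cfg$sweep))) {
      cf <- cfg$sweep$centreFreq[i]; sz <- cfg$sweep$size[i]
      say(sprintf("sweep: centre frequency %.4f, kernel %d^3", cf, sz))
      esI <- if (sz == cfg$kernelSize &&
                 abs(cf - cfg$centreFreq) < 1e-12) es else
        stage("sweep", .stChain(intensity(noisy), voxelSize(vol), cf, sz,
                                cfg$bandwidth, cfg$smoothSize, f,
                                cfg$tensorVariant, cfg$pad))
      cls <- .classifyEigenvectors(esI, ref, vol)
      cls$centreFreq <- cf
      cls$size <- sz
      rows[[i]] <- cls
    }
    sweep <- do.call(rbind, rows)
  }
  list(layerTable = layerTable, agreement = agreement, stAngles = stAngles,
       refAngles = refAngles, eigen = es, sweep = sweep, config = cfg)
}

#' Run the stage chain on supplied volumes
#'
#' Applies the same stages as [runPhantomValidation()] to user-supplied
#' data: a structure-tensor chain on the high-resolution volume (with
#' optional vessel exclusion), a nonlinear least-squares diffusion-tensor
#' fit with ADC-based heart segmentation on the DWI series, frames (slab
#' frames, or Laplace frames from supplied boundary masks), angle maps for
#' both modalities and their Bland-Altman agreement. A phantom intensity
#' volume passed through this entry point reproduces the
#' [runPhantomValidation()] structure-tensor outputs.
#'
#' @param sriVolume 3D array of reconstructed phase-contrast intensities.
#' @param sriVoxelSize its voxel size in micrometres.
#' @param dwi optional 4D DWI array.
#' @param protocol the [DwiProtocol-class] for \code{dwi}.
#' @param dwiVoxelSize DWI voxel size in micrometres.
#' @param cfg a [validationConfig()] (phantom fields ignored).
#' @param frames optional [FrameField-class] at the coarse ST grid;
#'   defaults to slab frames.
#' @param excludeVessels optional [VesselMask-class] at SRI resolution.
#' @param mask optional logical array at the coarse grid restricting the
#'   comparison.
#' @return list with \code{stEigen}, \code{stAngles}, and when DWI is
#'   supplied \code{dtFit}, \code{dtAngles}, \code{heartMask},
#'   \code{agreement}.
#' @export
runRealData <- function(sriVolume, sriVoxelSize, dwi = NULL, protocol = NULL,
                        dwiVoxelSize = 100, cfg = validationConfig(),
                        frames = NULL, excludeVessels = NULL, mask = NULL) {
  stage <- function(tag, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", tag, conditionMessage(e)), call. = FALSE))
  }
  if (!is.null(mask) && !any(mask))
    stop("[mask] no voxels selected", call. = FALSE)
  es <- stage("structure-tensor",
              .stChain(sriVolume, sriVoxelSize, cfg$centreFreq,
                       cfg$kernelSize, cfg$bandwidth, cfg$smoothSize,
                       cfg$downsampleFactor, cfg$tensorVariant, cfg$pad,
                       exclude = excludeVessels))
  cd <- dim(es@values)[1:3]
  if (is.null(frames)) frames <- slabFrames(cd, es@voxelSize)
  stAngles <- stage("angles", computeAngles(es, frames, cellVector = "v3",
                                            sheetVector = "v2"))
  out <- list(stEigen = es, stAngles = stAngles)
  if (!is.null(dwi)) {
    fit <- stage("dt-fit", fitDiffusionTensor(dwi, protocol, dwiVoxelSize))
    dtEigen <- stage("dt-eigen", eigenDecompose(fit$tensors))
    adc <- meanADC(dtEigen)
    b0mean <- apply(dwi[, , , seq_len(protocol@nB0), drop = FALSE],
                    1:3, mean)
    heart <- stage("segmentation", segmentHeart(b0mean, adc))
    dtFrames <- if (identical(dim(adc), cd)) frames else
      slabFrames(dim(adc), dwiVoxelSize)
    dtAngles <- stage("angles", computeAngles(dtEigen, dtFrames,
                                              cellVector = "v1",
                                              sheetVector = "v3"))
    out$dtFit <- fit
    out$dtAngles <- dtAngles
    out$heartMask <- heart
    if (identical(dim(adc), cd)) {
      out$agreement <- stage("agreement",
                             blandAltman(dtAngles@ha, stAngles@ha,
                                         mask = mask))
    }
  }
  out
}
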