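# AHA 17-segment partition and transmural profile statistics.

#' AHA 17-segment partition of the left ventricle
#'
#' Standard model on a long-axis-aligned volume (long axis = +z, base at
#' high z): the ventricular extent containing cavity is split into basal,
#' mid-cavity and apical thirds; basal and mid thirds are divided into six
#' 60-degree circumferential sectors and the apical third into four
#' 90-degree sectors, anchored at the anterior right-ventricular insertion
#' landmark; the apical cap (segment 17) is the myocardium apical of the
#' cavity. Sector numbering increases with the in-plane angle measured
#' counterclockwise (in the x-y plane viewed from +z) from the anchor.
#'
#' @param lvMask logical 3D array of LV myocardium.
#' @param rvInsertion numeric(3) voxel coordinate of the anterior RV
#'   insertion landmark (defines the angular anchor in its slice).
#' @param cavityMask optional logical 3D array of the LV cavity; when
#'   missing the apical cap is the apical 8th of the masked extent.
#' @return integer 3D array of labels 1-17 (0 outside the mask).
#' @export
aha17Segment <- function(lvMask, rvInsertion, cavityMask = NULL) {
  d <- dim(lvMask)
  if (missing(rvInsertion) || length(rvInsertion) != 3L)
    stop("an RV-insertion landmark (x, y, z) is required", call. = FALSE)
  zsAll <- which(apply(lvMask, 3, any))
  if (!length(zsAll)) stop("empty LV mask", call. = FALSE)
  if (!is.null(cavityMask)) {
    zsCav <- which(apply(cavityMask, 3, any))
    apexEnd <- min(zsCav)
  } else {
    apexEnd <- min(zsAll) + ceiling(length(zsAll) / 8)
  }
  ring <- zsAll[zsAll >= apexEnd]
  if (length(ring) < 3L)
    stop("mask too short along the long axis for the 17-segment model",
         call. = FALSE)
  third <- (max(ring) - min(ring) + 1) / 3
  labels <- array(0L, d)
  # per-slice centroid for the angular coordinate
  cent <- vapply(seq_len(d[3]), function(z) {
    if (!any(lvMask[, , z])) return(c(NA_real_, NA_real_))
    idx <- which(lvMask[, , z], arr.ind = TRUE)
    c(mean(idx[, 1]), mean(idx[, 2]))
  }, numeric(2))
  zl <- as.integer(round(rvInsertion[3]))
  anchor <- atan2(rvInsertion[2] - cent[2, zl], rvInsertion[1] - cent[1, zl])
  for (z in zsAll) {
    idx <- which(lvMask[, , z], arr.ind = TRUE)
    if (z < apexEnd) { labels[, , z][lvMask[, , z]] <- 17L; next }
    ang <- atan2(idx[, 2] - cent[2, z], idx[, 1] - cent[1, z]) - anchor
    ang <- ang %% (2 * pi)
    ringPos <- (z - min(ring)) / (third * 3)
    if (ringPos >= 2 / 3) {        # basal third
      sec <- 1L + as.integer(floor(ang / (pi / 3))) %% 6L
    } else if (ringPos >= 1 / 3) { # mid third
      sec <- 7L + as.integer(floor(ang / (pi / 3))) %% 6L
    } else {                       # apical third
      sec <- 13L + as.integer(floor(ang / (pi / 2))) %% 4L
    }
    labels[, , z][lvMask[, , z]] <- sec
  }
  labels
}

#' Transmural profiles with linearity and range
#'
#' Bins each segment's angles by normalised transmural depth and fits an
#' ordinary least-squares line of angle on depth per segment. Linearity is
#' the R-squared of that line; range is the signed difference between the
#' fitted values at 100 percent and 0 percent depth. Segments with fewer
#' than \code{minVoxels} defined voxels are reported as NA.
#'
#' @param angles an [AngleMaps-class] or a 3D array of angles in degrees.
#' @param depth 3D array of normalised transmural depth in [0, 1].
#' @param segments optional integer 3D array of segment labels (0 =
#'   outside); when NULL the whole volume is one segment.
#' @param which map selector when \code{angles} is an [AngleMaps-class].
#' @param binWidth depth bin width as a fraction (default 0.05 = 5 percent).
#' @param minVoxels minimum defined voxels per segment.
#' @return list with \code{profiles} (data.frame: segment, depthMid, mean,
#'   sd, n) and \code{stats} (data.frame: segment, linearity, range, n).
#' @export
transmuralProfiles <- function(angles, depth, segments = NULL, which = "ha",
                               binWidth = 0.05, minVoxels = 10L) {
  if (is(angles, "AngleMaps")) angles <- angleMap(angles, which)
  stopifnot(identical(dim(angles), dim(depth)))
  if (is.null(segments)) segments <- array(1L, dim(angles))
  segIds <- sort(setdiff(unique(segments[segments > 0L]), NA))
  breaks <- seq(0, 1, by = binWidth)
  profiles <- list(); stats <- list()
  for (s in segIds) {
    sel <- segments == s & !is.na(angles) & !is.na(depth)
    n <- sum(sel)
    if (n < minVoxels) {
      stats[[length(stats) + 1L]] <-
        data.frame(segment = s, linearity = NA_real_, range = NA_real_,
                   n = n)
      next
    }
    a <- angles[sel]; dph <- depth[sel]
    bin <- cut(dph, breaks, include.lowest = TRUE, labels = FALSE)
    agg <- tapply(a, bin, function(x) c(mean(x), stats::sd(x), length(x)))
    bm <- do.call(rbind, agg)
    profiles[[length(profiles) + 1L]] <- data.frame(
      segment = s,
      depthMid = (breaks[as.integer(names(agg))] +
                    breaks[as.integer(names(agg)) + 1L]) / 2,
      mean = bm[, 1], sd = bm[, 2], n = bm[, 3])
    fit <- stats::lm(a ~ dph)
    rss <- sum(stats::residuals(fit)^2)
    tss <- sum((a - mean(a))^2)
    r2 <- if (tss > 0) 1 - rss / tss else 1
    rng <- unname(stats::coef(fit)[2])  # fitted(1) - fitted(0) = slope
    stats[[length(stats) + 1L]] <- data.frame(
      segment = s, linearity = r2, range = rng, n = n)
  }
  list(profiles = if (length(profiles)) do.call(rbind, profiles)
         else data.frame(),
       stats = do.call(rbind, stats))
}
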