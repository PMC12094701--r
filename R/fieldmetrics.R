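# Grid-field detection and spacing/size metrics: rate thresholding,
# density-based clustering of supra-threshold bins, centroid geometry,
# central-field + six-neighbour spacing and the spacing-to-size ratio.

# Exact DBSCAN on a small point set (coordinates in bins). Returns integer
# cluster labels, 0 = noise. Deterministic: points are processed in index
# order. (No density-clustering implementation ships with the R
# distribution in use, and the algorithm is 40 lines, so it lives here.)
.dbscan <- function(pts, eps, minPts) {
  n <- nrow(pts)
  if (n == 0L) return(integer(0))
  d <- as.matrix(stats::dist(pts))
  nbrs <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nbrs, length, integer(1)) >= minPts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      p <- queue[1L]; queue <- queue[-1L]
      for (q in nbrs[[p]]) {
        if (labels[q] == 0L) {
          labels[q] <- cl
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

#' Detect firing fields in a rate map
#'
#' Bins with rate at least \code{thresholdFrac} times the map peak are
#' segmented into fields by density-based clustering (DBSCAN with
#' neighbourhood radius \code{eps} in bins and minimum cluster size
#' \code{minBins}); smaller clusters and unclustered bins become
#' background. Unvisited (NA) bins are background by construction. A
#' threshold of 31\% of the peak rate is the standard operating point; too
#' low a threshold merges neighbouring fields, too high a threshold
#' shrinks and eventually loses them.
#'
#' @param m A \linkS4class{RateMap}.
#' @param thresholdFrac Fraction of the peak rate, in (0, 1].
#' @param eps DBSCAN neighbourhood radius in bins.
#' @param minBins Minimum number of bins per field.
#' @return A \linkS4class{FieldLabeling}.
#' @export
detectFields <- function(m, thresholdFrac = 0.31, eps = 1.5, minBins = 4L) {
  if (thresholdFrac <= 0 || thresholdFrac > 1)
    stop("'thresholdFrac' must be in (0, 1]")
  v <- rateValues(m)
  peak <- suppressWarnings(max(v, na.rm = TRUE))
  if (!is.finite(peak) || peak <= 0)
    stop("rate map has no positive peak")
  sel <- which(!is.na(v) & v >= thresholdFrac * peak, arr.ind = TRUE)
  lab <- matrix(0L, nrow(v), ncol(v))
  if (nrow(sel)) {
    cl <- .dbscan(sel, eps = eps, minPts = minBins)
    keep <- sort(unique(cl[cl > 0L]))
    relab <- integer(max(c(0L, keep)))
    relab[keep] <- seq_along(keep)
    cl[cl > 0L] <- relab[cl[cl > 0L]]
    lab[sel] <- cl
  }
  new("FieldLabeling", labels = lab, thresholdFrac = thresholdFrac,
      binSize = binSize(m))
}

#' Per-field centroid, area and circle-equivalent diameter
#'
#' Centroids are the unweighted means of member-bin centres; the area is
#' the bin count times the bin area; the diameter is that of a circle of
#' equal area, \code{d = 2 * sqrt(area / pi)}.
#'
#' @param l A \linkS4class{FieldLabeling} with at least one field.
#' @return data.frame with columns \code{field}, \code{cx}, \code{cy} (cm),
#'   \code{nBins}, \code{areaCm2}, \code{diameterCm}, \code{touchesBorder}.
#' @export
fieldStats <- function(l) {
  lab <- fieldLabels(l)
  nf <- nFields(l)
  if (nf == 0L) stop("no fields in labeling")
  b <- l@binSize
  out <- lapply(seq_len(nf), function(f) {
    idx <- which(lab == f, arr.ind = TRUE)
    data.frame(
      field = f,
      cx = mean((idx[, 2L] - 0.5) * b),
      cy = mean((idx[, 1L] - 0.5) * b),
      nBins = nrow(idx),
      areaCm2 = nrow(idx) * b^2,
      diameterCm = 2 * sqrt(nrow(idx) * b^2 / pi),
      touchesBorder = any(idx == 1L) || any(idx[, 1L] == nrow(lab)) ||
        any(idx[, 2L] == ncol(lab)))
  })
  do.call(rbind, out)
}

#' Select the central field and its six nearest neighbours
#'
#' The central field is the centroid nearest the map centre among fields
#' that do not touch the map border (truncated border fields cannot serve
#' as the central field); the ring is the six nearest remaining centroids.
#' Distance ties are broken by polar angle and then by field index, so the
#' selection is deterministic.
#'
#' @param stats Field table from \code{\link{fieldStats}}.
#' @param center Map centre, length-2 (cm).
#' @return List with elements \code{central} (one-row data.frame) and
#'   \code{ring} (six-row data.frame).
#' @export
selectCentralRing <- function(stats, center) {
  if (nrow(stats) < 7L) stop("insufficient fields: need at least 7")
  cand <- stats[!stats$touchesBorder, , drop = FALSE]
  if (nrow(cand) == 0L) stop("insufficient fields: all touch the border")
  dc <- sqrt((cand$cx - center[1L])^2 + (cand$cy - center[2L])^2)
  ang <- atan2(cand$cy - center[2L], cand$cx - center[1L])
  cen <- cand[order(dc, ang, cand$field)[1L], , drop = FALSE]
  rest <- stats[stats$field != cen$field, , drop = FALSE]
  dr <- sqrt((rest$cx - cen$cx)^2 + (rest$cy - cen$cy)^2)
  angr <- atan2(rest$cy - cen$cy, rest$cx - cen$cx)
  ring <- rest[order(dr, angr, rest$field)[seq_len(6L)], , drop = FALSE]
  list(central = cen, ring = ring)
}

#' Grid spacing, field size and their ratio from a rate map
#'
#' Runs the full detection pipeline: threshold at a fraction of the peak,
#' density-cluster into fields, select the central field plus its six
#' nearest neighbours, and compute the mean of the six centre-to-centre
#' spacings, the mean circle-equivalent diameter of the seven fields, and
#' the spacing-to-size ratio. For densely packed circular fields the model
#' predicts a ratio of sqrt(7), about 2.65; out-of-field firing in noisy
#' recordings biases the measured ratio below that bound.
#'
#' @param m A \linkS4class{RateMap}.
#' @param thresholdFrac Fraction of the peak rate (default 0.31).
#' @param eps DBSCAN radius in bins.
#' @param minBins Minimum bins per field.
#' @return A \linkS4class{MetricsResult}.
#' @export
spacingAndRatio <- function(m, thresholdFrac = 0.31, eps = 1.5,
                            minBins = 4L) {
  l <- detectFields(m, thresholdFrac, eps, minBins)
  st <- fieldStats(l)
  ctr <- rep(arenaSize(m) / 2, 2L)
  sel <- selectCentralRing(st, ctr)
  sp <- sqrt((sel$ring$cx - sel$central$cx)^2 +
             (sel$ring$cy - sel$central$cy)^2)
  seven <- rbind(sel$central, sel$ring)
  ms <- mean(sp)
  sz <- mean(seven$diameterCm)
  new("MetricsResult", meanSpacing = ms, meanSize = sz, ratio = ms / sz,
      nFieldsUsed = 7L)
}

#' Detection success across field-detection thresholds
#'
#' For each threshold fraction, the fraction of maps on which exactly
#' seven fields are detected and the central-plus-ring selection succeeds.
#' Success drops at low thresholds (fields merge) and at high thresholds
#' (fields shrink below the minimum size or vanish).
#'
#' @param maps List of \linkS4class{RateMap} objects.
#' @param fracs Numeric vector of threshold fractions.
#' @param eps,minBins Clustering parameters passed on.
#' @return data.frame with columns \code{thresholdFrac}, \code{success}.
#' @export
thresholdSweep <- function(maps, fracs, eps = 1.5, minBins = 4L) {
  stopifnot(length(maps) > 0L, length(fracs) > 0L)
  succ <- vapply(fracs, function(f) {
    ok <- vapply(maps, function(m) {
      res <- tryCatch({
        l <- detectFields(m, f, eps, minBins)
        if (nFields(l) != 7L) return(FALSE)
        selectCentralRing(fieldStats(l), rep(arenaSize(m) / 2, 2L))
        TRUE
      }, error = function(e) FALSE)
      isTRUE(res)
    }, logical(1))
    mean(ok)
  }, numeric(1))
  data.frame(thresholdFrac = fracs, success = succ)
}
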