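# Synthetic open-field sessions and rate-map processing: correlated
# random-walk foraging, inhomogeneous Poisson spiking over Gaussian grid
# fields, occupancy-normalised smoothed rate maps, spatial autocorrelograms
# and the grid score.

# fold an unbounded coordinate into [0, L] (triangle wave); equivalent to
# specular reflection at both walls and preserves step lengths
.reflect <- function(x, L) {
  m <- x %% (2 * L)
  ifelse(m > L, 2 * L - m, m)
}

#' Simulate a foraging trajectory in a square arena
#'
#' Correlated random walk emulating a rodent open-field session: running
#' speed follows a clipped AR(1) process, heading diffuses as a Brownian
#' angle, and the path reflects specularly at the walls. The defaults give
#' a 20-minute session at 50 Hz in a 1 m x 1 m arena with near-uniform
#' coverage at 3 cm binning.
#'
#' @param arenaCm Arena side (cm).
#' @param durationS Session duration (s); 0 gives a single sample.
#' @param dtS Sampling interval (s).
#' @param meanSpeed Mean running speed (cm/s).
#' @param sdSpeed Stationary SD of the speed process (cm/s).
#' @param speedTau Speed autocorrelation time (s).
#' @param headingDiff Heading diffusion (rad / sqrt(s)).
#' @param seed Integer seed; identical seeds reproduce the trajectory.
#' @param start Start position (cm); default arena centre.
#' @return data.frame with columns \code{t}, \code{x}, \code{y}.
#' @export
simulateForaging <- function(arenaCm = 100, durationS = 1200, dtS = 0.02,
                             meanSpeed = 15, sdSpeed = 6, speedTau = 1,
                             headingDiff = 1.2, seed = 1L,
                             start = NULL) {
  if (arenaCm <= 0 || dtS <= 0 || durationS < 0)
    stop("arenaCm and dtS must be positive, durationS non-negative")
  if (is.null(start)) start <- c(arenaCm / 2, arenaCm / 2)
  nSteps <- floor(durationS / dtS)
  set.seed(seed)
  t <- seq(0, by = dtS, length.out = nSteps + 1L)
  if (nSteps == 0L)
    return(data.frame(t = 0, x = start[1L], y = start[2L]))
  phi <- exp(-dtS / speedTau)
  innov <- stats::rnorm(nSteps, 0, sdSpeed * sqrt(1 - phi^2))
  speed <- meanSpeed +
    as.numeric(stats::filter(innov, phi, method = "recursive"))
  speed <- pmin(pmax(speed, 0), meanSpeed + 4 * sdSpeed)
  heading <- cumsum(c(stats::runif(1, 0, 2 * pi),
                      stats::rnorm(nSteps - 1L, 0, headingDiff * sqrt(dtS))))
  dx <- speed * cos(heading) * dtS
  dy <- speed * sin(heading) * dtS
  x <- .reflect(start[1L] + cumsum(c(0, dx)), arenaCm)
  y <- .reflect(start[2L] + cumsum(c(0, dy)), arenaCm)
  data.frame(t = t, x = x, y = y)
}

# kernel sum of Gaussian fields at query points (rows of xy)
.fieldKernel <- function(xy, centers, sigma) {
  if (nrow(centers) == 0L) return(numeric(nrow(xy)))
  out <- numeric(nrow(xy))
  for (i in seq_len(nrow(centers))) {
    d2 <- (xy[, 1L] - centers[i, 1L])^2 + (xy[, 2L] - centers[i, 2L])^2
    out <- out + exp(-d2 / (2 * sigma^2))
  }
  out
}

#' Simulate grid-cell spikes along a trajectory
#'
#' Inhomogeneous Poisson process with rate
#' \code{baseline + peakRate * sum_c exp(-d_c^2 / (2 sigma^2))} over the
#' given field centres, generated by thinning: candidate spikes are drawn
#' from a homogeneous process at an upper rate bound (baseline plus peak
#' times the maximal kernel sum over the arena) and accepted with
#' probability rate/bound at their linearly interpolated positions.
#' A peak rate of 15 Hz on a 7-field layout in a 1 m arena reproduces the
#' firing-rate regime of a typical mouse grid cell (peak about 15 Hz, mean
#' about 2 Hz).
#'
#' @param traj Trajectory data.frame from \code{\link{simulateForaging}}.
#' @param centers Field-centre matrix (columns x, y, in cm).
#' @param fieldSigma Gaussian field SD (cm).
#' @param peakRate In-field peak rate (Hz).
#' @param baseline Out-of-field baseline rate (Hz).
#' @param seed Integer seed.
#' @return Sorted numeric vector of spike times (s).
#' @export
simulateSpikes <- function(traj, centers, fieldSigma = 4, peakRate = 15,
                           baseline = 0, seed = 1L) {
  if (fieldSigma <= 0 || peakRate < 0 || baseline < 0)
    stop("fieldSigma must be positive, rates non-negative")
  centers <- as.matrix(centers)
  set.seed(seed)
  T <- max(traj$t) - min(traj$t)
  if (T <= 0 || (peakRate == 0 && baseline == 0)) return(numeric(0))
  span <- range(c(traj$x, traj$y, if (nrow(centers)) centers))
  gx <- seq(span[1L], span[2L], length.out = 60L)
  gr <- as.matrix(expand.grid(x = gx, y = gx))
  kmax <- if (nrow(centers)) max(.fieldKernel(gr, centers, fieldSigma)) else 0
  bound <- baseline + peakRate * kmax * 1.05 + 1e-9
  nCand <- stats::rpois(1L, bound * T)
  if (nCand == 0L) return(numeric(0))
  tc <- sort(stats::runif(nCand, min(traj$t), max(traj$t)))
  px <- stats::approx(traj$t, traj$x, xout = tc)$y
  py <- stats::approx(traj$t, traj$y, xout = tc)$y
  rate <- baseline +
    peakRate * .fieldKernel(cbind(px, py), centers, fieldSigma)
  keep <- stats::runif(nCand) < pmin(rate / bound, 1)
  tc[keep]
}

#' Bin a session into spike counts and occupancy
#'
#' @param traj Trajectory data.frame.
#' @param spikes Spike-time vector (s).
#' @param binCm Bin side (cm).
#' @param arenaCm Arena side (cm).
#' @return List with matrices \code{counts} and \code{occupancy} (seconds),
#'   rows = y bins (bottom to top), columns = x bins.
#' @export
binSession <- function(traj, spikes, binCm = 3, arenaCm = 100) {
  stopifnot(binCm > 0, arenaCm > 0)
  nb <- ceiling(arenaCm / binCm - 1e-9)
  binOf <- function(z) pmin(pmax(ceiling(z / binCm), 1L), nb)
  dt <- if (nrow(traj) > 1L) diff(traj$t)[1L] else 0
  # each sample owns the interval [t, t + dt): the last sample is excluded
  # so that total occupancy equals the session duration exactly
  occIdx <- if (nrow(traj) > 1L) seq_len(nrow(traj) - 1L) else integer(0)
  tb <- table(factor(binOf(traj$y[occIdx]), levels = seq_len(nb)),
              factor(binOf(traj$x[occIdx]), levels = seq_len(nb)))
  occ <- matrix(as.numeric(tb) * dt, nb, nb)
  cnt <- matrix(0, nb, nb)
  if (length(spikes)) {
    sx <- stats::approx(traj$t, traj$x, xout = spikes, rule = 2L)$y
    sy <- stats::approx(traj$t, traj$y, xout = spikes, rule = 2L)$y
    sb <- table(factor(binOf(sy), levels = seq_len(nb)),
                factor(binOf(sx), levels = seq_len(nb)))
    cnt <- matrix(as.numeric(sb), nb, nb)
  }
  list(counts = cnt, occupancy = occ)
}

# Gaussian smoothing that ignores NA bins (kernel renormalised over the
# valid support); sigma and truncation in bins
.smoothNA <- function(m, sigmaBins, truncSd = 3) {
  if (sigmaBins <= 0) return(m)
  h <- max(1L, ceiling(truncSd * sigmaBins))
  g <- exp(-((-h:h)^2) / (2 * sigmaBins^2))
  K <- outer(g, g)
  valid <- !is.na(m)
  m0 <- m; m0[!valid] <- 0
  num <- .conv2(m0, K)
  den <- .conv2(valid * 1, K)
  out <- num / den
  out[!valid] <- NA
  out[valid & den == 0] <- 0
  out
}

# direct 2-D convolution with zero padding (small kernels only)
.conv2 <- function(m, K) {
  hr <- (nrow(K) - 1L) %/% 2L
  hc <- (ncol(K) - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nrow(K))) {
    di <- i - 1L - hr
    rs <- max(1L, 1L - di):min(nr, nr - di)
    if (length(rs) == 0L) next
    for (j in seq_len(ncol(K))) {
      dj <- j - 1L - hc
      cs <- max(1L, 1L - dj):min(nc, nc - dj)
      if (length(cs) == 0L) next
      out[rs, cs] <- out[rs, cs] + K[i, j] * m[rs + di, cs + dj]
    }
  }
  out
}

#' Occupancy-normalised, smoothed firing-rate map
#'
#' Divides the arena into square bins, computes per-bin spike count over
#' occupancy time, marks bins with occupancy below \code{minOccupancy} as
#' unvisited (NA), and smooths with a 2-D Gaussian kernel (SD
#' \code{smoothCm}, truncated at 3 SD) whose weights are renormalised over
#' visited bins.
#'
#' @param traj Trajectory data.frame.
#' @param spikes Spike-time vector (s).
#' @param binCm Spatial bin side (cm; 3 cm standard).
#' @param smoothCm Gaussian kernel SD (cm).
#' @param arenaCm Arena side (cm).
#' @param minOccupancy Minimum seconds in a bin for it to count as visited.
#' @return A \linkS4class{RateMap}.
#' @export
computeRateMap <- function(traj, spikes, binCm = 3, smoothCm = 3,
                           arenaCm = 100, minOccupancy = 0.1) {
  if (nrow(traj) == 0L) stop("empty trajectory")
  b <- binSession(traj, spikes, binCm, arenaCm)
  rate <- b$counts / b$occupancy
  rate[b$occupancy < minOccupancy] <- NA
  rate <- .smoothNA(rate, smoothCm / binCm)
  RateMap(rate, binSize = binCm, arenaSize = arenaCm)
}

#' Noiseless rate map from field centres
#'
#' Deterministic fixture map: disk fields (rate = peak inside the radius, 0
#' outside) or Gaussian fields as in \code{\link{simulateSpikes}}, sampled
#' at bin centres. No occupancy noise, no unvisited bins.
#'
#' @param centers Field-centre matrix (columns x, y, cm).
#' @param profile \code{"disk"} or \code{"gaussian"}.
#' @param fieldSize Disk radius or Gaussian SD (cm).
#' @param peakRate Peak rate (Hz).
#' @param binCm Bin side (cm).
#' @param arenaCm Arena side (cm).
#' @return A \linkS4class{RateMap}.
#' @export
idealRateMap <- function(centers, profile = c("disk", "gaussian"),
                         fieldSize, peakRate = 15, binCm = 3,
                         arenaCm = 100) {
  profile <- match.arg(profile)
  stopifnot(fieldSize > 0, peakRate > 0)
  centers <- as.matrix(centers)
  nb <- ceiling(arenaCm / binCm - 1e-9)
  ctr <- (seq_len(nb) - 0.5) * binCm
  xy <- as.matrix(expand.grid(x = ctr, y = ctr))
  v <- if (profile == "disk") {
    inside <- numeric(nrow(xy))
    for (i in seq_len(nrow(centers))) {
      d2 <- (xy[, 1L] - centers[i, 1L])^2 + (xy[, 2L] - centers[i, 2L])^2
      inside <- pmax(inside, as.numeric(d2 <= fieldSize^2))
    }
    peakRate * inside
  } else {
    peakRate * .fieldKernel(xy, centers, fieldSize)
  }
  m <- matrix(0, nb, nb)
  m[cbind(match(xy[, 2L], ctr), match(xy[, 1L], ctr))] <- v
  RateMap(m, binSize = binCm, arenaSize = arenaCm)
}

#' Spatial autocorrelogram of a rate map
#'
#' Pearson correlation of the map with itself at every integer bin lag,
#' using only bins that are valid in both shifted copies; lags with fewer
#' than \code{minOverlap} overlapping bins are NA. The zero-lag centre is 1
#' and the matrix is point-symmetric.
#'
#' @param m A \linkS4class{RateMap}.
#' @param minOverlap Minimum number of overlapping valid bins per lag.
#' @return An \linkS4class{Autocorrelogram}.
#' @export
spatialAutocorrelogram <- function(m, minOverlap = 20L) {
  v <- rateValues(m)
  nr <- nrow(v); nc <- ncol(v)
  if (sum(!is.na(v)) < minOverlap) stop("too few valid bins")
  out <- matrix(NA_real_, 2L * nr - 1L, 2L * nc - 1L)
  for (dr in -(nr - 1L):(nr - 1L)) {
    r1 <- max(1L, 1L + dr):min(nr, nr + dr)
    r2 <- r1 - dr
    for (dc in -(nc - 1L):(nc - 1L)) {
      c1 <- max(1L, 1L + dc):min(nc, nc + dc)
      c2 <- c1 - dc
      a <- v[r1, c1]; b <- v[r2, c2]
      ok <- !is.na(a) & !is.na(b)
      nOk <- sum(ok)
      if (nOk < minOverlap) next
      x <- a[ok]; y <- b[ok]
      sx <- stats::sd(x); sy <- stats::sd(y)
      if (sx == 0 || sy == 0) next
      out[nr + dr, nc + dc] <- stats::cor(x, y)
    }
  }
  out[nr, nc] <- 1
  new("Autocorrelogram", values = out, binSize = binSize(m))
}

# local maxima of an autocorrelogram (8-neighbourhood), excluding NA
.localMaxima <- function(v) {
  nr <- nrow(v); nc <- ncol(v)
  res <- NULL
  for (i in 2:(nr - 1L)) for (j in 2:(nc - 1L)) {
    x <- v[i, j]
    if (is.na(x)) next
    nb <- v[(i - 1L):(i + 1L), (j - 1L):(j + 1L)]
    nb[2L, 2L] <- -Inf
    if (all(is.na(nb) | nb < x)) res <- rbind(res, c(i, j, x))
  }
  res
}

#' Grid score of an autocorrelogram
#'
#' Standard rotational-symmetry statistic: an annulus is taken between the
#' edge of the central peak (first radius at which the mean
#' autocorrelation falls below 0.1) and 1.25 times the median distance of
#' the six surrounding peaks; the score is the minimum correlation of the
#' annulus with its 60- and 120-degree rotations minus the maximum
#' correlation with the 30-, 90- and 150-degree rotations. Values above
#' about 0.19 indicate grid-like six-fold symmetry; square lattices score
#' negative.
#'
#' @param ac An \linkS4class{Autocorrelogram}.
#' @return Numeric score in [-2, 2], or NA when no peak ring is detectable.
#' @export
gridScore <- function(ac) {
  v <- acValues(ac)
  cr <- (nrow(v) + 1L) %/% 2L
  cc <- (ncol(v) + 1L) %/% 2L
  ii <- row(v) - cr
  jj <- col(v) - cc
  rad <- sqrt(ii^2 + jj^2)
  maxR <- floor(min(cr, cc) - 1L)
  prof <- vapply(seq_len(maxR), function(r)
    mean(v[rad >= r - 0.5 & rad < r + 0.5], na.rm = TRUE), numeric(1))
  inner <- which(prof < 0.1)[1L]
  if (is.na(inner)) return(NA_real_)
  pk <- .localMaxima(v)
  if (is.null(pk)) return(NA_real_)
  pr <- sqrt((pk[, 1L] - cr)^2 + (pk[, 2L] - cc)^2)
  keep <- pr > inner & pk[, 3L] > 0
  if (sum(keep) < 3L) return(NA_real_)
  pr <- sort(pr[keep])
  ringR <- stats::median(pr[seq_len(min(6L, length(pr)))])
  outer <- min(1.25 * ringR, maxR)
  mask <- rad > inner & rad <= outer
  if (sum(mask & !is.na(v)) < 20L) return(NA_real_)
  rotCor <- function(deg) {
    th <- deg * pi / 180
    # sample the rotated autocorrelogram at the annulus bins (bilinear)
    ri <- ii[mask]; rj <- jj[mask]
    si <- ri * cos(th) - rj * sin(th) + cr
    sj <- ri * sin(th) + rj * cos(th) + cc
    rot <- .bilinear(v, si, sj)
    ok <- !is.na(rot) & !is.na(v[mask])
    if (sum(ok) < 20L) return(NA_real_)
    stats::cor(v[mask][ok], rot[ok])
  }
  same <- c(rotCor(60), rotCor(120))
  diff <- c(rotCor(30), rotCor(90), rotCor(150))
  if (anyNA(c(same, diff))) return(NA_real_)
  min(same) - max(diff)
}

.bilinear <- function(v, si, sj) {
  nr <- nrow(v); nc <- ncol(v)
  i0 <- floor(si); j0 <- floor(sj)
  fi <- si - i0; fj <- sj - j0
  get <- function(i, j) {
    out <- rep(NA_real_, length(i))
    ok <- i >= 1 & i <= nr & j >= 1 & j <= nc
    out[ok] <- v[cbind(i[ok], j[ok])]
    out
  }
  v00 <- get(i0, j0); v01 <- get(i0, j0 + 1L)
  v10 <- get(i0 + 1L, j0); v11 <- get(i0 + 1L, j0 + 1L)
  v00 * (1 - fi) * (1 - fj) + v01 * (1 - fi) * fj +
    v10 * fi * (1 - fj) + v11 * fi * fj
}
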