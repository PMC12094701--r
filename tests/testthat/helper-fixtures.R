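# Shared fixtures: reference arrangements, an independent axiom oracle and
# noiseless rate-map builders. Everything is generated in code.

# the two 7-element solutions (row translations 2 and 4, mirror images)
arr7 <- function(t = 2L) Arrangement(rows = list(1:7), offsets = t)

# 9 elements, three disjoint rows; zero offsets give the hexagonal
# repeat-3 solution, other offset sums give the (3, 9, 9) obliques
arr9 <- function(offsets = c(0L, 0L, 0L))
  Arrangement(rows = list(1:3, 4:6, 7:9), offsets = offsets)

# Independent brute-force axiom oracle: scans an explicit label grid over
# three full periods in each direction and checks, from the global pair
# tables, that (i) each (element, direction) has a unique successor and a
# unique predecessor and (ii) each ordered element pair codes a unique
# direction. No use of the local 6-neighbour shortcut.
oracleValid <- function(a) {
  k <- rowRepeat(a)
  R <- length(arrangementRows(a))
  qs <- 0:(3L * k - 1L)
  rs <- 0:(3L * R - 1L)
  grid <- as.matrix(expand.grid(q = qs, r = rs))
  labs <- elementAt(a, grid)
  lab <- matrix(labs, nrow = length(qs))  # [q+1, r+1]
  dirs <- rbind(E = c(1, 0), NE = c(0, 1), NW = c(-1, 1),
                W = c(-1, 0), SW = c(0, -1), SE = c(1, -1))
  succ <- list(); pred <- list(); pairDir <- list()
  for (qi in seq_along(qs)[2:(length(qs) - 1L)]) {
    for (ri in seq_along(rs)[2:(length(rs) - 1L)]) {
      e <- lab[qi, ri]
      for (d in seq_len(6L)) {
        f <- lab[qi + dirs[d, 1L], ri + dirs[d, 2L]]
        if (e == f) return(FALSE)  # self-succession
        ks <- paste(e, d); kp <- paste(f, d); kpair <- paste(e, f)
        succ[[ks]] <- union(succ[[ks]], f)
        pred[[kp]] <- union(pred[[kp]], e)
        pairDir[[kpair]] <- union(pairDir[[kpair]], d)
      }
    }
  }
  all(lengths(succ) == 1L) && all(lengths(pred) == 1L) &&
    all(lengths(pairDir) == 1L)
}

# every structurally admissible candidate (valid or not) for oracle tests
allCandidates <- function(n) {
  out <- list()
  for (k in (3:n)[n %% (3:n) == 0]) {
    R <- n %/% k
    rows <- split(seq_len(n), rep(seq_len(R), each = k))
    names(rows) <- NULL
    offs <- if (R == 1L) {
      if (k >= 5L) as.list(2:(k - 3L)) else list()
    } else {
      g <- expand.grid(rep(list(0:(k - 1L)), R))
      lapply(seq_len(nrow(g)), function(i) as.integer(g[i, ]))
    }
    for (o in offs) out[[length(out) + 1L]] <- Arrangement(rows, o)
  }
  out
}

# noiseless map of one element's touching-disk fields, one field centred
# in the arena (the sqrt(7) fixture when a has 7 elements)
diskFixture <- function(a = arr7(), fieldDiameter = 12, arenaCm = 100,
                        binCm = 3, profile = "disk", ringOnly = FALSE,
                        peakRate = 15) {
  ctr <- if (ringOnly) {
    ringFieldCenters(a, 1L, spacing = fieldDiameter,
                     center = c(arenaCm / 2, arenaCm / 2))
  } else {
    cc <- fieldCenters(a, 1L, extent = arenaCm, spacing = fieldDiameter)
    i0 <- which.min((cc[, 1L] - arenaCm / 2)^2 + (cc[, 2L] - arenaCm / 2)^2)
    sweep(cc, 2L, cc[i0, ] - c(arenaCm / 2, arenaCm / 2), "-")
  }
  size <- if (profile == "disk") fieldDiameter / 2 else fieldDiameter / 3
  idealRateMap(ctr, profile, fieldSize = size, peakRate = peakRate,
               binCm = binCm, arenaCm = arenaCm)
}

# one noisy synthetic session (foraging + Poisson spikes + rate map); the
# Gaussian field width is calibrated so that the 31%-of-peak contour has
# the dense-packing diameter spacing/sqrt(7) -- the model geometry whose
# noiseless ratio is sqrt(7)
noisySession <- function(seed, durationS = 600, spacing = 40,
                         baseline = 0.5) {
  a <- arr7()
  fieldSigma <- (spacing / sqrt(7)) / (2 * sqrt(2 * log(1 / 0.31)))
  traj <- simulateForaging(durationS = durationS, seed = seed)
  ctr <- fieldCenters(a, 1L, extent = 100, spacing = spacing / sqrt(7))
  sp <- simulateSpikes(traj, ctr, fieldSigma = fieldSigma, peakRate = 15,
                       baseline = baseline, seed = seed + 1000L)
  computeRateMap(traj, sp)
}
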