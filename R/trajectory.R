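# Encoding and decoding of lattice trajectories as element sequences, path
# integration over the six-direction alphabet, and phase-shifted multigrid
# stacks.

.checkSteps <- function(steps) {
  if (length(steps) == 0L) return(character(0))
  steps <- as.character(steps)
  bad <- setdiff(unique(steps), rownames(.hexDirections))
  if (length(bad))
    stop("unknown direction step(s): ", paste(bad, collapse = ", "))
  steps
}

#' Encode a lattice walk as an element sequence
#'
#' Walks from \code{start} through the given direction steps and reads off
#' the active element at every visited lattice point. The identity of the
#' next active element is fully determined by the current element and the
#' movement direction, which is what makes the sequence a trajectory code.
#'
#' @param a A valid \linkS4class{Arrangement}.
#' @param start Axial coordinate of the first field.
#' @param steps Character vector of directions (E, NE, NW, W, SW, SE).
#' @return Integer vector of element ids of length \code{length(steps) + 1},
#'   with the anchor coordinate attached as attribute \code{"anchor"}.
#' @export
encodeTrajectory <- function(a, start = c(0L, 0L), steps = character(0)) {
  steps <- .checkSteps(steps)
  validObject(a)
  start <- as.integer(start)
  offs <- .hexDirections[steps, , drop = FALSE]
  path <- rbind(start, cbind(start[1L] + cumsum(offs[, 1L]),
                             start[2L] + cumsum(offs[, 2L])))
  ids <- .elementAtRaw(a, path)
  attr(ids, "anchor") <- start
  ids
}

#' Decode an element sequence back into direction steps
#'
#' For each consecutive id pair the unique direction whose neighbouring
#' field carries the next id is returned. Decoding only needs the id pairs
#' (the code is location independent); the anchor fixes which occurrence of
#' the first element the walk starts from so the step directions can be
#' read off the lattice.
#'
#' @param a A valid \linkS4class{Arrangement}.
#' @param anchor Axial coordinate of the first element's field;
#'   \code{elementAt(a, anchor)} must equal the first id.
#' @param ids Integer vector of element ids (an encoded sequence).
#' @return Character vector of directions of length \code{length(ids) - 1}.
#' @export
decodeTrajectory <- function(a, anchor, ids) {
  validObject(a)
  anchor <- as.integer(anchor)
  ids <- as.integer(ids)
  if (length(ids) == 0L) return(character(0))
  if (elementAt(a, anchor) != ids[1L])
    stop("anchor does not carry the first element of the sequence")
  pos <- anchor
  steps <- character(length(ids) - 1L)
  for (i in seq_len(length(ids) - 1L)) {
    nb <- hexNeighbors(pos)
    nbIds <- .elementAtRaw(a, nb)
    hit <- which(nbIds == ids[i + 1L])
    if (length(hit) == 0L)
      stop(sprintf("non-adjacent transition %d -> %d at position %d",
                   ids[i], ids[i + 1L], i))
    if (length(hit) > 1L)  # impossible for valid arrangements
      stop(sprintf("ambiguous transition %d -> %d", ids[i], ids[i + 1L]))
    steps[i] <- rownames(nb)[hit]
    pos <- nb[hit, ]
  }
  steps
}

#' Path-integrate a sequence of direction steps
#'
#' @param steps Character vector of directions.
#' @return Axial displacement (integer length-2 vector).
#' @export
pathIntegrate <- function(steps) {
  steps <- .checkSteps(steps)
  if (length(steps) == 0L) return(c(q = 0L, r = 0L))
  d <- colSums(.hexDirections[steps, , drop = FALSE])
  c(q = as.integer(d[1L]), r = as.integer(d[2L]))
}

#' Reverse and negate a step sequence
#'
#' The reverse cell sequence codes for the reverse trajectory; on steps this
#' is reversal plus direction negation (E <-> W, NE <-> SW, NW <-> SE).
#'
#' @param steps Character vector of directions.
#' @return Character vector of the reversed, negated steps.
#' @export
reverseSteps <- function(steps) {
  steps <- .checkSteps(steps)
  nm <- rownames(.hexDirections)
  opp <- stats::setNames(nm[c(4L, 5L, 6L, 1L, 2L, 3L)], nm)
  unname(opp[rev(steps)])
}

#' Build a phase-shifted multigrid stack
#'
#' Adds to the base grid three copies whose field centres are shifted by
#' half the inter-field distance along each of the three major lattice axes
#' (E, NE, NW). The union of the four grids' field centres is again a
#' hexagonal lattice with half the nearest-neighbour spacing of the base
#' grid, which is how a stack of grids refines spatial resolution. Counts
#' that are higher powers of 4 apply the construction recursively.
#'
#' @param a A valid \linkS4class{Arrangement} (the base grid).
#' @param count Number of grids: 4, 16 or 64.
#' @param spacing Nearest-neighbour field distance of the base grid.
#' @return A \linkS4class{MultiGrid}.
#' @export
buildMultiGrid <- function(a, count = 4L, spacing = 1) {
  count <- as.integer(count)
  if (!count %in% c(4L, 16L, 64L))
    stop("'count' must be 4 or a power of 4 (16, 64)")
  validObject(a)
  levels <- as.integer(round(log(count, 4)))
  phases <- matrix(0, nrow = 1L, ncol = 2L)
  s <- spacing
  for (l in seq_len(levels)) {
    shifts <- rbind(c(0, 0),
                    s / 2 * c(1, 0),
                    s / 2 * c(cos(pi / 3), sin(pi / 3)),
                    s / 2 * c(cos(2 * pi / 3), sin(2 * pi / 3)))
    phases <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(i)
      sweep(phases, 2L, shifts[i, ], "+")))
    s <- s / 2
  }
  phases <- unique(round(phases, 12L))
  new("MultiGrid", base = a, spacing = spacing, phases = phases)
}

#' Field centres of the compound multigrid inside a window
#'
#' @param mg A \linkS4class{MultiGrid}.
#' @param extent Window side.
#' @return Matrix with columns x, y: the union over grids of all elements'
#'   field centres.
#' @export
compoundCenters <- function(mg, extent) {
  pts <- do.call(rbind, lapply(seq_len(nrow(mg@phases)), function(i)
    hexCenters(extent, mg@spacing, offset = mg@phases[i, ])))
  unique(round(pts, 10L))
}

#' Lattice basis estimated from a point set
#'
#' Takes the point nearest the centroid, forms difference vectors to all
#' other points, and returns the Lagrange-reduced basis of the two shortest
#' linearly independent differences. Intended for exact synthetic centre
#' sets (multigrid compounds, module-scaling checks).
#'
#' @param points Matrix with columns x, y (at least 7 points).
#' @return 2 x 2 basis matrix.
#' @export
pointLatticeBasis <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 7L) stop("need at least 7 points")
  ctr <- colMeans(points)
  i0 <- which.min(colSums((t(points) - ctr)^2))
  d <- sweep(points, 2L, points[i0, ], "-")
  d <- d[rowSums(d^2) > 1e-18, , drop = FALSE]
  d <- d[order(rowSums(d^2)), , drop = FALSE]
  v1 <- d[1L, ]
  cross <- abs(d[, 1L] * v1[2L] - d[, 2L] * v1[1L])
  v2 <- d[which(cross > 1e-9 * sqrt(rowSums(d^2)) * sqrt(sum(v1^2)))[1L], ]
  reduceBasis(cbind(v1, v2))
}

#' Nearest-neighbour spacing of a point set
#'
#' @param points Matrix with columns x, y.
#' @return Minimal pairwise distance.
#' @export
nearestSpacing <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("need at least 2 points")
  min(stats::dist(points))
}

#' Spacing change under a change in field density
#'
#' Generates the dense hexagonal field-centre packing at unit density and
#' at \code{factor} times the field density (fields per unit area) and
#' returns the ratio of measured nearest-neighbour spacings
#' (base / scaled). Doubling the density divides the spacing by sqrt(2),
#' the scale step observed between successive grid modules.
#'
#' @param factor Density scaling factor (> 0).
#' @param extent Window side used to generate the centre sets.
#' @return Spacing ratio (base spacing over scaled spacing).
#' @export
moduleScaling <- function(factor = 2, extent = 10) {
  stopifnot(factor > 0)
  base <- hexCenters(extent, spacing = 1)
  scaled <- hexCenters(extent, spacing = 1 / sqrt(factor))
  nearestSpacing(base) / nearestSpacing(scaled)
}

# cube-coordinate rounding: nearest hexagonal lattice point to a Cartesian
# position
.nearestHex <- function(xy, spacing) {
  rf <- xy[, 2L] / (spacing * sqrt(3) / 2)
  qf <- xy[, 1L] / spacing - rf / 2
  x <- qf; z <- rf; y <- -x - z
  rx <- round(x); ry <- round(y); rz <- round(z)
  dx <- abs(rx - x); dy <- abs(ry - y); dz <- abs(rz - z)
  fixX <- dx > dy & dx > dz
  fixZ <- !fixX & dz > dy
  rx[fixX] <- -ry[fixX] - rz[fixX]
  rz[fixZ] <- -rx[fixZ] - ry[fixZ]
  cbind(q = as.integer(rx), r = as.integer(rz))
}

#' Assign continuous positions to elements
#'
#' Maps each Cartesian position to the element whose field centre is
#' nearest (the Voronoi cell of the dense hexagonal packing), bridging
#' continuous 2-D positions and the discrete element code.
#'
#' @param a A valid \linkS4class{Arrangement}.
#' @param positions Matrix with columns x, y.
#' @param spacing Nearest-neighbour field distance.
#' @return Integer vector of element ids.
#' @export
assignElements <- function(a, positions, spacing = 1) {
  stopifnot(spacing > 0)
  positions <- as.matrix(positions)
  if (is.null(dim(positions)) || ncol(positions) != 2L)
    stop("'positions' must have columns x, y")
  validObject(a)
  .elementAtRaw(a, .nearestHex(positions, spacing))
}
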