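#' @import methods
NULL

# Axial coordinate convention shared by the whole package:
#   E  = (1, 0)   NE = (0, 1)   NW = (-1, 1)
#   W  = (-1, 0)  SW = (0, -1)  SE = (1, -1)
# Rows (constant r) run along the E axis; the two diagonals run along NE/NW.

.hexDirections <- matrix(
  c(1L, 0L,
    0L, 1L,
    -1L, 1L,
    -1L, 0L,
    0L, -1L,
    1L, -1L),
  ncol = 2L, byrow = TRUE,
  dimnames = list(c("E", "NE", "NW", "W", "SW", "SE"), c("q", "r"))
)

#' Names of the six lattice step directions
#'
#' Fixed order E, NE, NW, W, SW, SE; opposite directions are three apart
#' (W = -E, SW = -NE, SE = -NW).
#'
#' @return Character vector of length six.
#' @export
hexDirectionNames <- function() rownames(.hexDirections)

.asHexCoord <- function(c) {
  if (is.null(dim(c))) {
    stopifnot(length(c) == 2L)
    c <- matrix(c, ncol = 2L)
  }
  c <- as.matrix(c)
  if (ncol(c) != 2L)
    stop("hex coordinates must have two columns (q, r)")
  if (any(c != round(c)))
    stop("hex coordinates must be integer-valued")
  storage.mode(c) <- "integer"
  colnames(c) <- c("q", "r")
  c
}

#' Convert axial hexagonal coordinates to Cartesian positions
#'
#' The E step maps to (spacing, 0) and the NE step to
#' (spacing/2, spacing * sqrt(3)/2), so rows of the lattice are horizontal.
#'
#' @param c Integer axial coordinates: length-2 vector or a two-column
#'   matrix with one (q, r) pair per row.
#' @param spacing Positive nearest-neighbour distance (lattice units or cm).
#' @return Numeric matrix with columns x, y.
#' @examples
#' axialToCartesian(c(0, 1), spacing = 2)  # (1, sqrt(3))
#' @export
axialToCartesian <- function(c, spacing = 1) {
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0)
    stop("'spacing' must be a single positive number")
  c <- .asHexCoord(c)
  out <- cbind(x = spacing * (c[, 1L] + c[, 2L] / 2),
               y = spacing * c[, 2L] * sqrt(3) / 2)
  rownames(out) <- NULL
  out
}

#' Six lattice neighbours of a hexagonal coordinate
#'
#' Returns the axial offsets E, NE, NW, W, SW, SE added to \code{c}, in that
#' fixed order. The hexagonal lattice realises the planar kissing number 6:
#' every point has exactly six distinct unit-distance neighbours.
#'
#' @param c A single axial coordinate (length-2 integer vector).
#' @return A 6 x 2 integer matrix with rownames E, NE, NW, W, SW, SE.
#' @export
hexNeighbors <- function(c) {
  c <- .asHexCoord(c)
  if (nrow(c) != 1L) stop("'c' must be a single coordinate")
  out <- sweep(.hexDirections, 2L, c[1L, ], "+")
  colnames(out) <- c("q", "r")
  out
}

.asBasis <- function(b) {
  b <- as.matrix(b)
  if (!all(dim(b) == c(2L, 2L)))
    stop("a lattice basis must be a 2 x 2 matrix with basis vectors in columns")
  if (!all(is.finite(b)))
    stop("basis entries must be finite")
  if (abs(det(b)) < 1e-12 * max(1, max(abs(b)))^2)
    stop("degenerate basis: vectors are linearly dependent")
  unname(b)
}

#' Lagrange/Gauss reduction of a planar lattice basis
#'
#' Returns a basis of the same lattice with \code{|v1| <= |v2|} and
#' \code{|v1 . v2| <= |v1|^2 / 2} (the classical reduced form). Basis vectors
#' are the columns of the matrix.
#'
#' @param b 2 x 2 numeric matrix, basis vectors in columns.
#' @return Reduced 2 x 2 basis matrix spanning the same lattice.
#' @export
reduceBasis <- function(b) {
  b <- .asBasis(b)
  v1 <- b[, 1L]; v2 <- b[, 2L]
  repeat {
    if (sum(v1^2) > sum(v2^2)) { tmp <- v1; v1 <- v2; v2 <- tmp }
    m <- round(sum(v1 * v2) / sum(v1^2))
    v2 <- v2 - m * v1
    if (sum(v2^2) >= sum(v1^2)) break
  }
  if (sum(v1 * v2) < 0) v2 <- -v2  # fix a sign convention for determinism
  cbind(v1, v2, deparse.level = 0L)
}

#' Classify a planar lattice into one of the five plane lattice types
#'
#' Works on the Lagrange-reduced basis: equal lengths with a 60 (or 120)
#' degree angle give \code{"hexagonal"}; orthogonal vectors give
#' \code{"square"} (equal lengths) or \code{"rectangular"}; equal lengths at
#' any other angle give \code{"centered_rectangular"}; everything else is
#' \code{"oblique"}.
#'
#' @param b 2 x 2 numeric basis matrix (columns are basis vectors).
#' @param relTol Relative tolerance for length and cosine comparisons.
#' @return One of \code{"hexagonal"}, \code{"square"}, \code{"rectangular"},
#'   \code{"centered_rectangular"}, \code{"oblique"}.
#' @export
classifyLattice <- function(b, relTol = 1e-9) {
  rb <- reduceBasis(b)
  v1 <- rb[, 1L]; v2 <- rb[, 2L]
  l1 <- sqrt(sum(v1^2)); l2 <- sqrt(sum(v2^2))
  cosang <- abs(sum(v1 * v2)) / (l1 * l2)
  equalLen <- abs(l1 - l2) <= relTol * max(l1, l2)
  ortho <- cosang <= relTol
  # |v1.v2| = |v1|^2/2 on a reduced basis means |v2| = |v2 -/+ v1|: the
  # lattice is rhombic with v1 a rectangle side rather than a rhombus side
  boundary <- abs(abs(sum(v1 * v2)) - sum(v1^2) / 2) <=
    relTol * max(sum(v1^2), sum(v2^2))
  if (equalLen && abs(cosang - 0.5) <= relTol) return("hexagonal")
  if (equalLen && ortho) return("square")
  if (ortho) return("rectangular")
  if (equalLen || boundary) return("centered_rectangular")
  "oblique"
}

#' Smallest angle between a lattice axis and the walls of a rectangular arena
#'
#' The basis must be expressed in the frame in which the element-sequence row
#' direction is the x axis (one row of fields parallel to a wall). The grid
#' axes are the directions from a lattice point to its six nearest lattice
#' neighbours (three axes up to sign). The returned value is the minimum over
#' those axes and over the two wall directions (0 and 90 degrees) of the
#' acute angle between axis and wall, in degrees, in [0, 45].
#'
#' @param b 2 x 2 numeric basis matrix (columns are basis vectors).
#' @return Angle in degrees.
#' @export
wallAngle <- function(b) {
  ax <- latticeAxes(b)
  th <- atan2(ax[, 2L], ax[, 1L]) * 180 / pi
  th <- th %% 90
  min(pmin(th, 90 - th))
}

#' Directions of the six nearest lattice neighbours (three axes)
#'
#' @param b 2 x 2 numeric basis matrix.
#' @param tol Relative tolerance used when grouping tied vector lengths.
#' @return Matrix with up to three rows, one unit-free axis vector per row
#'   (one representative per +/- pair).
#' @keywords internal
latticeAxes <- function(b, tol = 1e-9) {
  b <- .asBasis(b)
  combos <- as.matrix(expand.grid(m1 = -2:2, m2 = -2:2))
  combos <- combos[!(combos[, 1L] == 0 & combos[, 2L] == 0), , drop = FALSE]
  vecs <- combos %*% t(b)
  nrm <- sqrt(rowSums(vecs^2))
  ord <- order(nrm)
  vecs <- vecs[ord, , drop = FALSE]
  nrm <- nrm[ord]
  # keep one representative per +/- pair, in increasing length order, until
  # the ring of six nearest points is covered; ties at the cutoff length are
  # all included (a rectangular lattice has two equal diagonals, so its ring
  # spans four axis directions)
  axes <- matrix(numeric(0), ncol = 2L)
  lastNorm <- NA_real_
  for (i in seq_len(nrow(vecs))) {
    v <- vecs[i, ]
    if (2L * nrow(axes) >= 6L && nrm[i] > lastNorm * (1 + 1e-9)) break
    dup <- FALSE
    if (nrow(axes) > 0) {
      cr <- abs(axes[, 1L] * v[2L] - axes[, 2L] * v[1L])
      dup <- any(cr <= tol * nrm[i] * sqrt(rowSums(axes^2)))
    }
    if (!dup) {
      axes <- rbind(axes, v)
      lastNorm <- nrm[i]
    }
  }
  unname(axes)
}

# Solve an integer linear system b %*% x = v for x, used to verify that two
# bases span the same lattice.
.integerCoords <- function(b, v, tol = 1e-7) {
  x <- solve(b, v)
  if (all(abs(x - round(x)) <= tol)) round(x) else NULL
}

#' Do two bases span the same planar lattice?
#'
#' @param a,b 2 x 2 basis matrices.
#' @return Logical.
#' @keywords internal
sameLattice <- function(a, b) {
  ok <- TRUE
  for (j in 1:2) {
    if (is.null(.integerCoords(a, b[, j]))) ok <- FALSE
    if (is.null(.integerCoords(b, a[, j]))) ok <- FALSE
  }
  ok && abs(abs(det(a)) - abs(det(b))) <= 1e-7 * abs(det(a))
}
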