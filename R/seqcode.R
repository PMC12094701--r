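# Sequence-code arrangements: validity, canonical forms, enumeration and
# grid-map geometry.
#
# Key structural facts used throughout (all re-checked by the validity
# brute force and the test suite):
#   - every row of the lattice repeats with the common row repeat length k,
#     and k divides the element count n;
#   - within one fundamental domain of R = n/k rows each element appears
#     exactly once, so for R >= 2 the rows are pairwise disjoint and, up to
#     relabeling, can be taken to be consecutive integer blocks -- the only
#     degrees of freedom are the per-row horizontal offsets;
#   - for R = 1 every row is a translation of the single row and the
#     translation must lie in 2..k-3.

#' Element id at lattice coordinates
#'
#' Evaluates the periodic labeling of an arrangement at one or more axial
#' coordinates. Lattice row \code{r} carries row \code{(r mod R) + 1} of the
#' arrangement, read with the cumulative horizontal offset of all row steps
#' below it, modulo the row repeat length.
#'
#' @param a An \linkS4class{Arrangement}.
#' @param c Axial coordinates: length-2 integer vector or two-column matrix.
#' @return Integer vector of element ids in \code{1:nElements(a)}.
#' @export
elementAt <- function(a, c) {
  validObject(a)
  .elementAtRaw(a, .asHexCoord(c))
}

# elementAt without argument validation, for hot loops
.elementAtRaw <- function(a, c) {
  R <- length(a@rows)
  k <- a@k
  total <- sum(a@offsets)
  partial <- c(0L, cumsum(a@offsets))
  r <- c[, 2L]
  m <- floor(r / R)
  s <- r - m * R
  shift <- m * total + partial[s + 1L]
  rmod <- s
  pos <- (((c[, 1L] - shift) %% k) + k) %% k
  rowmat <- do.call(rbind, a@rows)       # R x k
  rowmat[cbind(rmod + 1L, pos + 1L)]
}

#' Axial basis of the arrangement's period lattice
#'
#' The labeling repeats under the sublattice generated by \code{(k, 0)} and
#' \code{(T, R)} in axial coordinates, where \code{T} is the sum of all row
#' offsets; the sublattice has index \code{n} in the hexagonal lattice.
#'
#' @param a An \linkS4class{Arrangement}.
#' @return 2 x 2 integer matrix with the period vectors in columns.
#' @export
periodBasisAxial <- function(a) {
  R <- length(a@rows)
  matrix(c(a@k, 0L, sum(a@offsets), R), nrow = 2L)
}

#' Check an arrangement against the sequence-coding axioms
#'
#' Brute force over every lattice point of one fundamental domain and every
#' one of the six directions. A valid sequence code requires that around
#' every field the six neighbouring fields carry identities that are
#' pairwise distinct and different from the centre (axiom 3); any
#' duplication makes an ordered element pair code for more than one
#' direction (axiom 1), or, when the duplicated directions are opposite,
#' breaks the reverse-trajectory reading and the minimum repeat of 3
#' (axiom 2). Self-succession along any direction violates axiom 1.
#'
#' @param a An \linkS4class{Arrangement}.
#' @return A \linkS4class{ValidityReport}; never throws for structurally
#'   sound arrangements.
#' @export
validateArrangement <- function(a) {
  validObject(a)
  R <- length(a@rows)
  k <- a@k
  dom <- as.matrix(expand.grid(q = 0:(k - 1L), r = 0:(R - 1L)))
  centre <- .elementAtRaw(a, dom)
  dirs <- .hexDirections
  nb <- sapply(seq_len(6L), function(d)
    .elementAtRaw(a, sweep(dom, 2L, dirs[d, ], "+")))
  viol <- list()
  add <- function(axiom, element, direction, detail)
    viol[[length(viol) + 1L]] <<- data.frame(
      axiom = axiom, element = element, direction = direction,
      detail = detail, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(dom))) {
    e <- centre[i]
    ids <- nb[i, ]
    selfd <- which(ids == e)
    for (d in selfd)
      add(1L, e, rownames(dirs)[d], "element succeeds itself")
    for (d1 in 1:5) for (d2 in (d1 + 1L):6L) {
      if (ids[d1] == ids[d2] && ids[d1] != e) {
        opposite <- (d2 - d1) == 3L
        add(if (opposite) 2L else 1L, e,
            paste(rownames(dirs)[c(d1, d2)], collapse = "/"),
            sprintf("pair (%d -> %d) codes two directions%s", e, ids[d1],
                    if (opposite) " (2-cycle, repeat < 3)" else ""))
      }
    }
    if (anyDuplicated(c(e, ids)) > 0L)
      add(3L, e, "*", "surround is not six distinct elements")
  }
  viol <- if (length(viol)) do.call(rbind, viol) else
    data.frame(axiom = integer(0), element = integer(0),
               direction = character(0), detail = character(0),
               stringsAsFactors = FALSE)
  new("ValidityReport", valid = nrow(viol) == 0L, violations = viol)
}

# 60-degree rotation and x-axis mirror in axial coordinates (row vectors
# act on the right: x' = x %*% t(M))
.rot60 <- matrix(c(0L, -1L, 1L, 1L), nrow = 2L, byrow = TRUE)
.mirrorX <- matrix(c(1L, 1L, 0L, -1L), nrow = 2L, byrow = TRUE)

.pointGroup <- function(moduloReflection) {
  g <- list(diag(2L))
  for (i in 1:5) g[[i + 1L]] <- g[[i]] %*% .rot60
  if (moduloReflection)
    g <- c(g, lapply(g, function(m) m %*% .mirrorX))
  g
}

#' Canonical key of an arrangement
#'
#' A string invariant under relabeling of the elements, lattice translation
#' and the six-fold lattice rotation group; with
#' \code{moduloReflection = TRUE} also under mirror reflection. Two
#' arrangements represent the same sequence code exactly when their keys are
#' equal. The key is the lexicographically minimal first-occurrence
#' relabeling of the labeling scanned over an n x n window, taken over the
#' orbit, prefixed by the sorted axis repeat lengths.
#'
#' @param a A valid \linkS4class{Arrangement}.
#' @param moduloReflection Logical; merge mirror-image arrangements.
#' @return Character scalar.
#' @export
canonicalForm <- function(a, moduloReflection = FALSE) {
  rep3 <- repeatLengths(a)
  n <- a@n
  scan <- as.matrix(expand.grid(q = 0:(n - 1L), r = 0:(n - 1L)))
  scan <- scan[order(scan[, 2L], scan[, 1L]), , drop = FALSE]
  dom <- as.matrix(expand.grid(q = 0:(a@k - 1L),
                               r = 0:(length(a@rows) - 1L)))
  best <- NULL
  for (g in .pointGroup(moduloReflection)) {
    base <- scan %*% t(g)
    for (j in seq_len(nrow(dom))) {
      labs <- .elementAtRaw(a, sweep(base, 2L, dom[j, ], "+"))
      relab <- match(labs, unique(labs))
      key <- paste(relab, collapse = ",")
      if (is.null(best) || key < best) best <- key
    }
  }
  paste0(paste(rep3, collapse = "-"), "|", best)
}

# All structurally admissible candidates for n elements, in deterministic
# order (k ascending, offsets lexicographic), filtered by the axiom check.
# Within one fundamental domain every element appears exactly once, so up
# to relabeling the disjoint rows can be fixed as consecutive integer
# blocks; for R = 1 the translation bound 2..k-3 applies.
.validCandidates <- function(n) {
  n <- as.integer(n)
  if (n < 1L || n > 20L) stop("'n' must be between 1 and 20")
  out <- list()
  ks <- Filter(function(k) n %% k == 0L, 3:n)
  for (k in ks) {
    R <- n %/% k
    rows <- split(seq_len(n), rep(seq_len(R), each = k))
    names(rows) <- NULL
    offs <- if (R == 1L) {
      if (k >= 5L) lapply(2:(k - 3L), function(t) t) else list()
    } else {
      grid <- expand.grid(rep(list(0:(k - 1L)), R))
      grid <- grid[do.call(order, as.list(grid)), , drop = FALSE]
      lapply(seq_len(nrow(grid)), function(i) as.integer(grid[i, ]))
    }
    for (o in offs) {
      a <- Arrangement(rows = rows, offsets = o)
      if (validateArrangement(a)@valid)
        out[[length(out) + 1L]] <- a
    }
  }
  out
}

#' Enumerate all sequence-code arrangements for n elements
#'
#' Exhaustive search over all row repeat lengths \code{k} dividing \code{n}
#' (\code{k >= 3}), all disjoint-row partitions in canonical block order,
#' and all per-row offset vectors (restricted to the translation bound
#' \code{2..k-3} when a single row fills the lattice), filtered by
#' \code{\link{validateArrangement}} and deduplicated by
#' \code{\link{canonicalForm}} (relabeling, translation, 60-degree
#' rotations, and optionally reflection). The result order is
#' deterministic (lexicographic over \code{(k, offsets)}).
#'
#' @param n Number of elements (1..20).
#' @param moduloReflection Logical; count mirror images once.
#' @return List of \linkS4class{Arrangement} objects; empty when no valid
#'   sequence code exists (in particular for all \code{n < 7}).
#' @examples
#' length(enumerateArrangements(7, moduloReflection = FALSE))  # 2
#' @export
enumerateArrangements <- function(n, moduloReflection = TRUE) {
  out <- list()
  keys <- character(0)
  for (a in .validCandidates(n)) {
    key <- canonicalForm(a, moduloReflection = moduloReflection)
    if (key %in% keys) next
    keys <- c(keys, key)
    out[[length(out) + 1L]] <- a
  }
  out
}

#' Basis of one element's field-centre sublattice
#'
#' The set of lattice points carrying element \code{e} is a coset of the
#' arrangement's period lattice; all elements therefore share congruent
#' sublattices of index \code{n} in the hexagonal lattice. The basis is
#' returned Lagrange-reduced, in the Cartesian frame in which the row axis
#' is horizontal.
#'
#' @param a A valid \linkS4class{Arrangement}.
#' @param e Element id (only used for validation; the basis is shared).
#' @param spacing Nearest-neighbour field distance.
#' @return 2 x 2 matrix with basis vectors in columns.
#' @export
sublatticeBasis <- function(a, e = 1L, spacing = 1) {
  validObject(a)
  if (e < 1L || e > a@n) stop("element id out of range")
  pb <- periodBasisAxial(a)
  cart <- rbind(
    axialToCartesian(t(pb[, 1L]), spacing),
    axialToCartesian(t(pb[, 2L]), spacing))
  reduceBasis(t(cart))
}

#' Axis repeat lengths of an arrangement
#'
#' Minimal period of the element sequence along each of the three major
#' axes of the hexagonal lattice (the row axis E and the two diagonals NE
#' and NW), sorted ascending. Each repeat length divides \code{n} and is at
#' least 3 for valid arrangements.
#'
#' @param a An \linkS4class{Arrangement}.
#' @return Sorted integer triple.
#' @export
repeatLengths <- function(a) {
  pb <- periodBasisAxial(a)
  axes <- list(c(1L, 0L), c(0L, 1L), c(-1L, 1L))
  reps <- vapply(axes, function(d) {
    for (p in seq_len(a@n)) {
      if (!is.null(.integerCoords(pb, p * d))) return(p)
    }
    stop("no axis period found within n steps")  # unreachable: index is n
  }, integer(1))
  sort(reps)
}

#' Table of grid maps derivable from sequence-code arrangements
#'
#' For every valid arrangement candidate with rows wall-parallel (every
#' anchoring of every arrangement class: which of the three sequence axes
#' lies along the wall matters for the observable grid map), the table
#' records the three axis repeat lengths, the plane lattice type of the
#' single-element sublattice, and the smallest angle between a grid axis
#' and a wall of the rectangular enclosure (reported to 0.1 degree).
#' Rows with identical (n, repeats, type, angle) are collapsed; mirror
#' images never differ in any of these values and so appear once.
#'
#' @param nMin,nMax Element count range (below 7 no arrangements exist).
#' @param moduloReflection Kept for interface stability; reflections are
#'   always merged by the value-deduplication described above.
#' @return A data.frame with columns \code{n}, \code{repeat1..repeat3},
#'   \code{repeats}, \code{lattice_type}, \code{angle_deg}, sorted by
#'   \code{(n, repeats, angle)}.
#' @export
gridMapTable <- function(nMin = 7L, nMax = 12L, moduloReflection = TRUE) {
  stopifnot(nMin <= nMax)
  recs <- list()
  for (n in nMin:nMax) {
    for (a in .validCandidates(n)) {
      rl <- repeatLengths(a)
      b <- sublatticeBasis(a)
      recs[[length(recs) + 1L]] <- data.frame(
        n = n, repeat1 = rl[1L], repeat2 = rl[2L], repeat3 = rl[3L],
        repeats = paste(rl, collapse = ", "),
        lattice_type = classifyLattice(b),
        angle_deg = round(wallAngle(b), 1L),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(recs))
    return(data.frame(n = integer(0), repeat1 = integer(0),
                      repeat2 = integer(0), repeat3 = integer(0),
                      repeats = character(0), lattice_type = character(0),
                      angle_deg = numeric(0)))
  tab <- unique(do.call(rbind, recs))
  tab <- tab[order(tab$n, tab$repeat1, tab$repeat2, tab$repeat3,
                   tab$angle_deg), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Field centres of one element inside a square window
#'
#' All Cartesian centres of element \code{e}'s firing fields within the
#' window \code{[0, extent] x [0, extent]}, derived from the element's
#' sublattice (one field per sublattice point).
#'
#' @param a A valid \linkS4class{Arrangement}.
#' @param e Element id.
#' @param extent Window side (same units as \code{spacing}).
#' @param spacing Nearest-neighbour field distance.
#' @return Matrix with columns x, y.
#' @export
fieldCenters <- function(a, e = 1L, extent, spacing = 1) {
  stopifnot(extent > 0, spacing > 0)
  validObject(a)
  if (e < 1L || e > a@n) stop("element id out of range")
  dom <- as.matrix(expand.grid(q = 0:(a@k - 1L),
                               r = 0:(length(a@rows) - 1L)))
  labs <- elementAt(a, dom)
  c0 <- dom[match(e, labs), , drop = FALSE]
  pb <- periodBasisAxial(a)
  M <- ceiling(extent / spacing) + a@n + 2L
  combos <- as.matrix(expand.grid(m1 = -M:M, m2 = -M:M))
  ax <- combos %*% t(pb)
  ax <- sweep(ax, 2L, as.numeric(c0), "+")
  xy <- axialToCartesian(ax, spacing)
  keep <- xy[, 1L] >= -1e-9 & xy[, 1L] <= extent + 1e-9 &
    xy[, 2L] >= -1e-9 & xy[, 2L] <= extent + 1e-9
  xy[keep, , drop = FALSE]
}

#' Central field centre plus its six ring neighbours, exactly
#'
#' The centre of one field of element \code{e} placed at \code{center},
#' together with the six nearest centres of the same element's sublattice
#' (the ring the spacing metrics are defined on), computed from the exact
#' sublattice basis rather than from a window search.
#'
#' @param a A valid \linkS4class{Arrangement}.
#' @param e Element id.
#' @param spacing Nearest-neighbour distance of the dense packing (cm).
#' @param center Cartesian position of the central field (cm).
#' @return 7 x 2 matrix (central first, then the ring).
#' @export
ringFieldCenters <- function(a, e = 1L, spacing = 1, center = c(0, 0)) {
  b <- sublatticeBasis(a, e, spacing)
  ax <- latticeAxes(b)
  ring <- rbind(ax, -ax)
  nrm <- sqrt(rowSums(ring^2))
  ring <- ring[order(nrm)[seq_len(6L)], , drop = FALSE]
  sweep(rbind(c(0, 0), ring), 2L, center, "+")
}

#' Centres of the full dense field packing inside a square window
#'
#' All hexagonal-lattice points (fields of all elements) within
#' \code{[0, extent]^2}, optionally shifted by \code{offset}.
#'
#' @param extent Window side.
#' @param spacing Nearest-neighbour distance.
#' @param offset Cartesian shift applied to the lattice, length 2.
#' @return Matrix with columns x, y.
#' @export
hexCenters <- function(extent, spacing = 1, offset = c(0, 0)) {
  stopifnot(extent > 0, spacing > 0)
  M <- ceiling(2 * extent / spacing) + 2L
  ax <- as.matrix(expand.grid(q = -M:M, r = -M:M))
  xy <- axialToCartesian(ax, spacing)
  xy <- sweep(xy, 2L, offset, "+")
  keep <- xy[, 1L] >= -1e-9 & xy[, 1L] <= extent + 1e-9 &
    xy[, 2L] >= -1e-9 & xy[, 2L] <= extent + 1e-9
  xy[keep, , drop = FALSE]
}
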