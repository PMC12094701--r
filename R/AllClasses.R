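#' Arrangement: a periodic labeling of the hexagonal lattice by element ids
#'
#' An arrangement assigns one of \code{n} element ids to every point of the
#' hexagonal lattice, periodically. It is stored as \code{R = n/k} pairwise
#' disjoint cyclic rows of length \code{k} (the row repeat length) together
#' with one integer offset per row: \code{offsets[i]} is the horizontal shift
#' applied when stepping from row \code{i} to row \code{i + 1}; the vertical
#' period is \code{R} rows. Row 0 of the lattice carries \code{rows[[1]]}
#' with zero cumulative shift.
#'
#' @slot n Integer, total number of elements.
#' @slot k Integer row repeat length; \code{k >= 3} and \code{k} divides
#'   \code{n}.
#' @slot rows List of \code{n/k} integer vectors, pairwise disjoint, whose
#'   union is \code{1:n}.
#' @slot offsets Integer vector of length \code{n/k}, each in \code{[0, k)}.
#' @export
setClass("Arrangement",
  representation(n = "integer", k = "integer", rows = "list",
                 offsets = "integer"))

setValidity("Arrangement", function(object) {
  msgs <- character(0)
  n <- object@n; k <- object@k
  if (length(n) != 1L || length(k) != 1L)
    return("'n' and 'k' must be single integers")
  if (k < 3L) msgs <- c(msgs, "row repeat length k must be at least 3")
  if (n %% k != 0L) msgs <- c(msgs, "k must divide n")
  R <- n %/% k
  if (length(object@rows) != R)
    msgs <- c(msgs, sprintf("expected %d rows, got %d", R,
                            length(object@rows)))
  ids <- unlist(object@rows, use.names = FALSE)
  if (length(ids) != n || !setequal(ids, seq_len(n)) ||
      anyDuplicated(ids) > 0L)
    msgs <- c(msgs, "rows must be pairwise disjoint and cover 1..n")
  if (any(lengths(object@rows) != k))
    msgs <- c(msgs, "every row must have length k")
  if (length(object@offsets) != R ||
      any(object@offsets < 0L | object@offsets >= k))
    msgs <- c(msgs, "offsets must be R integers in [0, k)")
  if (R == 1L) {
    t <- object@offsets[1L]
    if (t < 2L || t > k - 3L)
      msgs <- c(msgs, sprintf(
        "adjacent rows share elements: translation %d outside 2..k-3", t))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an Arrangement
#'
#' @param rows List of disjoint integer rows (cyclic sequences) covering
#'   \code{1:n}, each of the common repeat length \code{k}.
#' @param offsets Integer vector, one horizontal shift per row step.
#' @return An \linkS4class{Arrangement}.
#' @examples
#' # one of the two valid 7-element arrangements (row translation 2)
#' a <- Arrangement(rows = list(1:7), offsets = 2)
#' @export
Arrangement <- function(rows, offsets) {
  rows <- lapply(rows, function(r) as.integer(r))
  n <- length(unlist(rows, use.names = FALSE))
  k <- length(rows[[1L]])
  new("Arrangement", n = as.integer(n), k = as.integer(k), rows = rows,
      offsets = as.integer(offsets))
}

#' @describeIn Arrangement-class number of elements
#' @param x An \code{Arrangement}.
#' @export
nElements <- function(x) x@n

#' @describeIn Arrangement-class row repeat length
#' @export
rowRepeat <- function(x) x@k

#' @describeIn Arrangement-class list of element rows
#' @export
arrangementRows <- function(x) x@rows

#' @describeIn Arrangement-class per-row horizontal offsets
#' @export
arrangementOffsets <- function(x) x@offsets

setMethod("show", "Arrangement", function(object) {
  cat(sprintf("Arrangement: %d elements, row repeat %d, %d row(s)\n",
              object@n, object@k, length(object@rows)))
  for (i in seq_along(object@rows))
    cat(sprintf("  row %d: %s  (offset %d)\n", i,
                paste(object@rows[[i]], collapse = " "),
                object@offsets[i]))
})

#' ValidityReport: result of checking an arrangement against the coding axioms
#'
#' @slot valid Logical.
#' @slot violations data.frame with columns \code{axiom}, \code{element},
#'   \code{direction}, \code{detail}; empty iff \code{valid}.
#' @export
setClass("ValidityReport",
  representation(valid = "logical", violations = "data.frame"))

setValidity("ValidityReport", function(object) {
  if (object@valid != (nrow(object@violations) == 0L))
    "valid flag must match emptiness of the violations table" else TRUE
})

setMethod("show", "ValidityReport", function(object) {
  if (object@valid) {
    cat("Valid sequence-code arrangement (axioms 1-3 satisfied)\n")
  } else {
    cat(sprintf("Invalid arrangement: %d violation(s)\n",
                nrow(object@violations)))
    print(utils::head(object@violations, 10L))
  }
})

#' @describeIn ValidityReport-class is the arrangement valid?
#' @param x A \code{ValidityReport}.
#' @export
isValid <- function(x) x@valid

#' @describeIn ValidityReport-class table of axiom violations
#' @export
violations <- function(x) x@violations

#' RateMap: binned, occupancy-normalised, smoothed firing-rate matrix
#'
#' Rows index the y (north) axis from bottom to top, columns the x axis from
#' west to east; \code{values[i, j]} is the rate (Hz) in the bin whose centre
#' is at \code{((j - 0.5) * binSize, (i - 0.5) * binSize)} cm. Unvisited bins
#' are \code{NA}.
#'
#' @slot values Numeric matrix of rates (Hz), \code{NA} for unvisited bins.
#' @slot binSize Bin side in cm.
#' @slot arenaSize Arena side in cm.
#' @export
setClass("RateMap",
  representation(values = "matrix", binSize = "numeric",
                 arenaSize = "numeric"))

setValidity("RateMap", function(object) {
  msgs <- character(0)
  if (object@binSize <= 0 || object@arenaSize <= 0)
    msgs <- c(msgs, "binSize and arenaSize must be positive")
  v <- object@values
  if (any(v[!is.na(v)] < 0))
    msgs <- c(msgs, "rates must be non-negative or NA")
  nb <- ceiling(object@arenaSize / object@binSize - 1e-9)
  if (!all(dim(v) == c(nb, nb)))
    msgs <- c(msgs, sprintf("values must be %d x %d for this arena/bin", nb, nb))
  if (length(msgs)) msgs else TRUE
})

#' Construct a RateMap
#' @param values Rate matrix (Hz), NA for unvisited bins.
#' @param binSize Bin side (cm).
#' @param arenaSize Arena side (cm).
#' @return A \linkS4class{RateMap}.
#' @export
RateMap <- function(values, binSize, arenaSize) {
  new("RateMap", values = as.matrix(values), binSize = binSize,
      arenaSize = arenaSize)
}

#' @describeIn RateMap-class rate matrix
#' @param x A \code{RateMap}.
#' @export
rateValues <- function(x) x@values

#' @describeIn RateMap-class bin side in cm
#' @export
binSize <- function(x) x@binSize

#' @describeIn RateMap-class arena side in cm
#' @export
arenaSize <- function(x) x@arenaSize

setMethod("show", "RateMap", function(object) {
  v <- object@values
  cat(sprintf(
    "RateMap: %d x %d bins of %.3g cm (%.3g cm arena)\n",
    nrow(v), ncol(v), object@binSize, object@arenaSize))
  cat(sprintf("  peak %.3g Hz, mean %.3g Hz, %d unvisited bin(s)\n",
              suppressWarnings(max(v, na.rm = TRUE)),
              mean(v, na.rm = TRUE), sum(is.na(v))))
})

#' Autocorrelogram: spatial autocorrelation of a rate map
#'
#' @slot values Correlation matrix in [-1, 1] (NA where overlap was too
#'   small); odd side length, centre = zero lag.
#' @slot binSize Bin side in cm (inherited from the source map).
#' @export
setClass("Autocorrelogram",
  representation(values = "matrix", binSize = "numeric"))

setValidity("Autocorrelogram", function(object) {
  v <- object@values
  msgs <- character(0)
  if (nrow(v) %% 2L != 1L || ncol(v) %% 2L != 1L)
    msgs <- c(msgs, "autocorrelogram must have odd dimensions")
  if (any(abs(v[!is.na(v)]) > 1 + 1e-8))
    msgs <- c(msgs, "correlations must lie in [-1, 1]")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn Autocorrelogram-class correlation matrix
#' @param x An \code{Autocorrelogram}.
#' @export
acValues <- function(x) x@values

setMethod("show", "Autocorrelogram", function(object) {
  cat(sprintf("Autocorrelogram: %d x %d lags, centre value %.3f\n",
              nrow(object@values), ncol(object@values),
              object@values[(nrow(object@values) + 1L) %/% 2L,
                            (ncol(object@values) + 1L) %/% 2L]))
})

#' FieldLabeling: segmented firing fields of a rate map
#'
#' @slot labels Integer matrix, same shape as the source map: 0 background,
#'   1..F field ids.
#' @slot thresholdFrac Fraction of the peak rate used as field threshold.
#' @slot binSize Bin side in cm.
#' @export
setClass("FieldLabeling",
  representation(labels = "matrix", thresholdFrac = "numeric",
                 binSize = "numeric"))

setValidity("FieldLabeling", function(object) {
  lab <- object@labels
  ids <- sort(unique(as.vector(lab[lab > 0L])))
  if (length(ids) && !identical(ids, seq_along(ids)))
    return("field labels must be contiguous 1..F")
  if (object@thresholdFrac <= 0 || object@thresholdFrac > 1)
    return("thresholdFrac must be in (0, 1]")
  TRUE
})

#' @describeIn FieldLabeling-class label matrix
#' @param x A \code{FieldLabeling}.
#' @export
fieldLabels <- function(x) x@labels

#' @describeIn FieldLabeling-class number of detected fields
#' @export
nFields <- function(x) max(0L, max(x@labels))

setMethod("show", "FieldLabeling", function(object) {
  cat(sprintf("FieldLabeling: %d field(s) at threshold %.2f x peak\n",
              nFields(object), object@thresholdFrac))
})

#' MetricsResult: grid spacing, field size and their ratio
#'
#' @slot meanSpacing Mean centre-to-centre distance (cm) from the central
#'   field to its six ring neighbours.
#' @slot meanSize Mean circle-equivalent diameter (cm) of the seven fields.
#' @slot ratio \code{meanSpacing / meanSize}.
#' @slot nFieldsUsed Number of fields entering the metrics (7 on success).
#' @export
setClass("MetricsResult",
  representation(meanSpacing = "numeric", meanSize = "numeric",
                 ratio = "numeric", nFieldsUsed = "integer"))

setValidity("MetricsResult", function(object) {
  if (abs(object@ratio - object@meanSpacing / object@meanSize) >
      1e-8 * max(1, object@ratio))
    "ratio must equal meanSpacing / meanSize" else TRUE
})

#' @describeIn MetricsResult-class spacing-to-size ratio
#' @param x A \code{MetricsResult}.
#' @export
spacingSizeRatio <- function(x) x@ratio

#' @describeIn MetricsResult-class mean field spacing (cm)
#' @export
meanSpacing <- function(x) x@meanSpacing

#' @describeIn MetricsResult-class mean field diameter (cm)
#' @export
meanFieldSize <- function(x) x@meanSize

setMethod("show", "MetricsResult", function(object) {
  cat(sprintf(
    "Grid metrics: spacing %.2f cm, field size %.2f cm, ratio %.3f (%d fields)\n",
    object@meanSpacing, object@meanSize, object@ratio, object@nFieldsUsed))
})

#' MultiGrid: a stack of phase-shifted copies of one arrangement
#'
#' @slot base The base \linkS4class{Arrangement}.
#' @slot spacing Nearest-neighbour field distance of the base grid.
#' @slot phases Numeric matrix (one row per grid) of Cartesian phase offsets;
#'   the first row is (0, 0).
#' @export
setClass("MultiGrid",
  representation(base = "Arrangement", spacing = "numeric",
                 phases = "matrix"))

setValidity("MultiGrid", function(object) {
  ph <- object@phases
  if (any(duplicated(ph))) return("phase offsets must be distinct")
  if (any(abs(ph[1L, ]) > 1e-12)) return("first grid must have zero phase")
  TRUE
})

#' @describeIn MultiGrid-class total number of elements across grids
#' @param x A \code{MultiGrid}.
#' @export
totalElements <- function(x) nrow(x@phases) * x@base@n

#' @describeIn MultiGrid-class phase offsets (one row per grid)
#' @export
gridPhases <- function(x) x@phases

setMethod("show", "MultiGrid", function(object) {
  cat(sprintf("MultiGrid: %d grids of %d elements (%d total), base spacing %.3g\n",
              nrow(object@phases), object@base@n, totalElements(object),
              object@spacing))
})
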