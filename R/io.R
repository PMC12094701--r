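# Plain-text serialization: arrangements as JSON, rate maps as delimited
# matrices with a JSON sidecar, tables and sessions as CSV.

#' Write an arrangement to JSON
#'
#' @param a An \linkS4class{Arrangement}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
writeArrangement <- function(a, path) {
  validObject(a)
  jsonlite::write_json(
    list(n = a@n, k = a@k, rows = a@rows, offsets = a@offsets),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an arrangement from JSON
#'
#' @param path JSON file written by \code{\link{writeArrangement}}.
#' @return An \linkS4class{Arrangement}.
#' @export
readArrangement <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rows <- x$rows
  if (is.matrix(rows)) rows <- lapply(seq_len(nrow(rows)), function(i) rows[i, ])
  if (!is.list(rows)) rows <- list(rows)
  Arrangement(rows = rows, offsets = x$offsets)
}

#' Write a rate map as delimited text plus JSON sidecar
#'
#' The matrix goes to \code{path} as comma-separated values (no header,
#' rows = y bins bottom to top); the spatial calibration goes to
#' \code{paste0(path, ".json")} as \code{\{bin_size_cm, arena_cm\}}.
#'
#' @param m A \linkS4class{RateMap}.
#' @param path Output CSV file.
#' @return \code{path}, invisibly.
#' @export
writeRateMap <- function(m, path) {
  utils::write.table(rateValues(m), path, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "NA")
  jsonlite::write_json(
    list(bin_size_cm = binSize(m), arena_cm = arenaSize(m)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a rate map written by \code{\link{writeRateMap}}
#'
#' @param path CSV file with JSON sidecar \code{paste0(path, ".json")}.
#' @return A \linkS4class{RateMap}.
#' @export
readRateMap <- function(path) {
  v <- as.matrix(utils::read.table(path, sep = ",", header = FALSE,
                                   na.strings = "NA"))
  dimnames(v) <- NULL
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  RateMap(v, binSize = side$bin_size_cm, arenaSize = side$arena_cm)
}

#' Enumerate arrangements and write the grid-map table (CSV) and, on
#' request, the arrangements themselves (JSON)
#'
#' @param n Element count or range (e.g. \code{7} or \code{7:12}).
#' @param tablePath Output CSV for the grid-map table.
#' @param jsonPath Optional output JSON for the arrangement list.
#' @param moduloReflection Passed to \code{\link{enumerateArrangements}}.
#' @return The grid-map table, invisibly.
#' @export
runEnumerate <- function(n, tablePath = NULL, jsonPath = NULL,
                         moduloReflection = TRUE) {
  n <- as.integer(n)
  tab <- gridMapTable(min(n), max(n), moduloReflection)
  if (nrow(tab) == 0L)
    warning("no valid arrangements in this range (minimum element count is 7)")
  if (!is.null(tablePath))
    utils::write.csv(tab, tablePath, row.names = FALSE)
  if (!is.null(jsonPath)) {
    arr <- unlist(lapply(n, function(ni)
      enumerateArrangements(ni, moduloReflection)), recursive = FALSE)
    jsonlite::write_json(
      lapply(arr, function(a)
        list(n = a@n, k = a@k, rows = a@rows, offsets = a@offsets)),
      jsonPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(tab)
}

#' Simulate a full synthetic session and write its artifacts
#'
#' Generates a foraging trajectory, grid-cell spikes for one element of an
#' arrangement, and the smoothed rate map; writes trajectory and spikes as
#' two-column/one-column CSV and the map via \code{\link{writeRateMap}}.
#' Fully reproducible from the seed.
#'
#' @param a An \linkS4class{Arrangement}.
#' @param element Element id whose fields drive the firing.
#' @param outDir Output directory (created if missing).
#' @param arenaCm,durationS,spacing,fieldSigma,peakRate,baseline,seed
#'   Session parameters; \code{spacing} is the element-grid field spacing
#'   in cm.
#' @param binCm,smoothCm Rate-map parameters.
#' @return List with \code{traj}, \code{spikes}, \code{map} (invisibly).
#' @export
runSimulate <- function(a, element = 1L, outDir = NULL, arenaCm = 100,
                        durationS = 1200, spacing = 40, fieldSigma = 4,
                        peakRate = 15, baseline = 0, seed = 1L,
                        binCm = 3, smoothCm = 3) {
  if (durationS <= 0) stop("durationS must be positive")
  traj <- simulateForaging(arenaCm = arenaCm, durationS = durationS,
                           seed = seed)
  centers <- fieldCenters(a, element, extent = arenaCm,
                          spacing = spacing / sqrt(a@n))
  spikes <- simulateSpikes(traj, centers, fieldSigma = fieldSigma,
                           peakRate = peakRate, baseline = baseline,
                           seed = seed + 1L)
  map <- computeRateMap(traj, spikes, binCm = binCm, smoothCm = smoothCm,
                        arenaCm = arenaCm)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(traj, file.path(outDir, "trajectory.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(t = spikes),
                     file.path(outDir, "spikes.csv"), row.names = FALSE)
    writeRateMap(map, file.path(outDir, "ratemap.csv"))
    jsonlite::write_json(
      list(seed = seed, arena_cm = arenaCm, duration_s = durationS,
           spacing_cm = spacing, field_sigma_cm = fieldSigma,
           peak_rate_hz = peakRate, baseline_hz = baseline,
           bin_cm = binCm, smooth_cm = smoothCm, element = element),
      file.path(outDir, "config.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(list(traj = traj, spikes = spikes, map = map))
}

#' Field metrics for a rate-map file
#'
#' @param path Rate-map CSV (with JSON sidecar) as written by
#'   \code{\link{writeRateMap}}.
#' @param thresholdFrac,eps,minBins Passed to \code{\link{spacingAndRatio}}.
#' @return A \linkS4class{MetricsResult}.
#' @export
runMetrics <- function(path, thresholdFrac = 0.31, eps = 1.5,
                       minBins = 4L) {
  spacingAndRatio(readRateMap(path), thresholdFrac, eps, minBins)
}
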