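#' Construct an MS1 map
#'
#' An MS1 map is the time-ordered sequence of survey (MS level 1) scans used
#' for extracted-ion-chromatogram quantification: per scan, a retention time
#' in seconds and aligned, m/z-sorted arrays of m/z values (Th) and
#' non-negative intensities.
#'
#' @param rt numeric vector of strictly increasing retention times (seconds).
#' @param peaks list of two-column matrices `cbind(mz, intensity)`, one per
#'   scan, each sorted by ascending m/z.
#' @return an object of class `"ms1_map"`.
#' @export
ms1_map <- function(rt, peaks) {
  if (length(rt) != length(peaks)) stop_msg("rt/peaks length mismatch")
  if (length(rt) > 1 && any(diff(rt) <= 0)) {
    stop_msg("retention times must be strictly increasing")
  }
  peaks <- lapply(peaks, function(p) {
    p <- matrix(as.numeric(p), ncol = 2, dimnames = list(NULL, c("mz", "intensity")))
    if (nrow(p) > 1 && is.unsorted(p[, 1])) p <- p[order(p[, 1]), , drop = FALSE]
    if (any(p[, 2] < 0)) stop_msg("negative intensity in scan")
    p
  })
  structure(list(rt = as.numeric(rt), peaks = peaks), class = "ms1_map")
}

#' @export
print.ms1_map <- function(x, ...) {
  cat(sprintf("MS1 map: %d scans, RT %g-%g s, %d ions total\n",
              length(x$rt), if (length(x$rt)) min(x$rt) else NA,
              if (length(x$rt)) max(x$rt) else NA,
              sum(vapply(x$peaks, nrow, integer(1)))))
  invisible(x)
}

#' Read MS1 scans from an mzML or mzXML file
#'
#' Retains only MS level-1 scans, time-ordered, with retention time
#' normalised to seconds.
#'
#' @param path path to an mzML or mzXML file.
#' @param rt_unit unit of the retention times stored in the file header as
#'   surfaced by the reader; `"seconds"` (the mzR convention) or `"minutes"`
#'   (multiplied by 60 on read).
#' @return an [ms1_map].
#' @export
read_ms1_scans <- function(path, rt_unit = c("seconds", "minutes")) {
  rt_unit <- match.arg(rt_unit)
  if (!file.exists(path)) stop_msg("file not found: ", path)
  fh <- tryCatch(mzR::openMSfile(path),
                 error = function(e) stop_msg("unreadable MS file: ", path,
                                              " (", conditionMessage(e), ")"))
  on.exit(mzR::close(fh), add = TRUE)
  hd <- mzR::header(fh)
  ms1 <- which(hd$msLevel == 1L)
  if (!length(ms1)) stop_msg("no MS1 scans in file: ", path)
  rt <- hd$retentionTime[ms1]
  if (rt_unit == "minutes") rt <- rt * 60
  pk <- mzR::peaks(fh, ms1)
  if (is.matrix(pk)) pk <- list(pk)
  ord <- order(rt)
  ms1_map(rt[ord], pk[ord])
}

#' Write an MS1 map to an mzML file
#'
#' Fixture writer: serialises an in-memory [ms1_map] through mzR so that
#' synthetic maps round-trip through [read_ms1_scans].
#'
#' @param map an [ms1_map].
#' @param path output path (`.mzML`).
#' @return `path`, invisibly.
#' @export
write_ms1_scans <- function(map, path) {
  n <- length(map$rt)
  if (n == 0L) stop_msg("cannot write an empty MS1 map")
  pc <- vapply(map$peaks, nrow, integer(1))
  tic <- vapply(map$peaks, function(p) sum(p[, 2]), numeric(1))
  bp <- lapply(map$peaks, function(p) {
    if (nrow(p) == 0) c(0, 0) else p[which.max(p[, 2]), ]
  })
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = rep(1L, n), polarity = rep(1L, n),
    peaksCount = pc, totIonCurrent = tic,
    retentionTime = map$rt,
    basePeakMZ = vapply(bp, `[`, numeric(1), 1),
    basePeakIntensity = vapply(bp, `[`, numeric(1), 2),
    collisionEnergy = numeric(n), ionisationEnergy = numeric(n),
    lowMZ = vapply(map$peaks, function(p) if (nrow(p)) min(p[, 1]) else 0, numeric(1)),
    highMZ = vapply(map$peaks, function(p) if (nrow(p)) max(p[, 1]) else 0, numeric(1)),
    precursorScanNum = integer(n), precursorMZ = numeric(n),
    precursorCharge = integer(n), precursorIntensity = numeric(n),
    mergedScan = integer(n), mergedResultScanNum = integer(n),
    mergedResultStartScanNum = integer(n), mergedResultEndScanNum = integer(n),
    injectionTime = numeric(n), filterString = rep("", n),
    spectrumId = sprintf("scan=%d", seq_len(n)),
    centroided = rep(TRUE, n), ionMobilityDriftTime = rep(NA_real_, n),
    isolationWindowTargetMZ = rep(NA_real_, n),
    isolationWindowLowerOffset = rep(NA_real_, n),
    isolationWindowUpperOffset = rep(NA_real_, n),
    scanWindowLowerLimit = rep(NA_real_, n),
    scanWindowUpperLimit = rep(NA_real_, n),
    stringsAsFactors = FALSE)
  mzR::writeMSData(object = map$peaks, file = path, header = hdr)
  invisible(path)
}
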