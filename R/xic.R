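#' Extract an ion chromatogram from an MS1 map
#'
#' Traces the summed intensity of all ions within a ppm window of a query m/z
#' across the MS1 scans inside a retention-time window. One point is produced
#' per scan with `|scan_rt - rt_center| <= rt_window/2`; scans with no
#' matching ion contribute intensity 0. Summing (rather than taking the
#' maximum) within the tolerance is robust to isotope-shoulder splitting at
#' 10 ppm. An empty window yields an empty chromatogram, not an error.
#'
#' @param ms1 an [ms1_map].
#' @param mz query m/z (Th).
#' @param ppm_tol mass tolerance in parts-per-million; default 10 (the usual
#'   Orbitrap precursor tolerance).
#' @param rt_center centre of the retention-time window (seconds).
#' @param rt_window total window width (seconds); default 300 (i.e. +-150 s).
#' @return a `"chromatogram"`: list with increasing `rt` and aligned
#'   non-negative `intensity`.
#' @export
extract_xic <- function(ms1, mz, ppm_tol = 10, rt_center, rt_window = 300) {
  if (ppm_tol <= 0) stop_msg("ppm_tol must be positive")
  if (rt_window <= 0) stop_msg("rt_window must be positive")
  tol <- mz * ppm_tol * 1e-6
  idx <- which(abs(ms1$rt - rt_center) <= rt_window / 2)
  ints <- vapply(idx, function(i) {
    p <- ms1$peaks[[i]]
    if (nrow(p) == 0) return(0)
    sum(p[abs(p[, 1] - mz) <= tol, 2])
  }, numeric(1))
  structure(list(rt = ms1$rt[idx], intensity = ints), class = "chromatogram")
}

#' Integrate a chromatographic peak area
#'
#' Picks the apex as the maximum-intensity local maximum nearest
#' `rt_center`, extends the integration boundaries outward from the apex
#' until the trace falls below `boundary_frac` of the apex intensity or a
#' local minimum is reached, and integrates by the trapezoid rule between the
#' boundaries. An empty or single-point chromatogram has area 0. Optional
#' 3-point moving-average smoothing (off by default) is applied only for
#' apex/boundary picking, never to the integrated intensities.
#'
#' @param chrom a `"chromatogram"` from [extract_xic].
#' @param rt_center retention time the peak is expected at (seconds).
#' @param boundary_frac boundary threshold as a fraction of apex intensity;
#'   default 0.01.
#' @param smooth logical, apply 3-point moving-average before peak picking.
#' @return an `"xic_result"`: list with `area` (intensity x seconds),
#'   `apex_rt`, `left_rt`, `right_rt`, `n_points`.
#' @export
integrate_peak_area <- function(chrom, rt_center, boundary_frac = 0.01,
                                smooth = FALSE) {
  n <- length(chrom$rt)
  empty <- structure(list(area = 0, apex_rt = NA_real_, left_rt = NA_real_,
                          right_rt = NA_real_, n_points = n),
                     class = "xic_result")
  if (n < 2L || all(chrom$intensity <= 0)) return(empty)
  y <- chrom$intensity
  ypick <- if (smooth && n >= 3L) {
    stats::filter(y, rep(1 / 3, 3), sides = 2) -> sm
    as.numeric(ifelse(is.na(sm), y, sm))
  } else y
  # local maxima (plateaus count via >=/<= on both sides; endpoints allowed)
  left_ok <- c(TRUE, diff(ypick) >= 0)
  right_ok <- c(diff(ypick) <= 0, TRUE)
  cand <- which(left_ok & right_ok & ypick > 0)
  if (!length(cand)) cand <- which.max(ypick)
  maxint <- max(ypick[cand])
  top <- cand[ypick[cand] >= maxint * (1 - 1e-12)]
  apex <- top[which.min(abs(chrom$rt[top] - rt_center))]
  thr <- boundary_frac * y[apex]
  left <- apex
  while (left > 1L) {
    if (y[left - 1L] < thr) break
    if (y[left - 1L] > y[left]) break  # local minimum at `left`
    left <- left - 1L
  }
  right <- apex
  while (right < n) {
    if (y[right + 1L] < thr) break
    if (y[right + 1L] > y[right]) break
    right <- right + 1L
  }
  area <- 0
  if (right > left) {
    sel <- left:right
    area <- sum(diff(chrom$rt[sel]) *
                  (utils::head(y[sel], -1) + utils::tail(y[sel], -1)) / 2)
  }
  structure(list(area = area, apex_rt = chrom$rt[apex],
                 left_rt = chrom$rt[left], right_rt = chrom$rt[right],
                 n_points = n),
            class = "xic_result")
}

#' @export
print.xic_result <- function(x, ...) {
  cat(sprintf("XIC peak: area %.4g, apex %.1f s, bounds [%.1f, %.1f] s, %d points\n",
              x$area, x$apex_rt, x$left_rt, x$right_rt, x$n_points))
  invisible(x)
}

#' Assign MS1 XIC peptide-abundance features to PSMs
#'
#' Computes one extracted-ion-chromatogram area per PSM at its precursor m/z
#' and retention time: the peptide-abundance rescoring feature. Decoy PSMs
#' are processed identically to targets, since their spectra are real. A PSM
#' lacking a precursor m/z or retention time receives 0 with a warning.
#'
#' @param psms a [psm_table] carrying `PrecursorMz` and `RetentionTime`
#'   feature columns (see [precursor_mz]).
#' @param ms1 an [ms1_map].
#' @param ppm_tol,rt_window,boundary_frac,smooth passed to [extract_xic] and
#'   [integrate_peak_area].
#' @return named numeric vector of XIC areas, names = `spec_id`.
#' @export
assign_xic_features <- function(psms, ms1, ppm_tol = 10, rt_window = 300,
                                boundary_frac = 0.01, smooth = FALSE) {
  mz <- precursor_mz(psms)
  rt <- retention_time(psms)
  n <- nrow(psms)
  if (is.null(mz) || is.null(rt)) {
    warning("PSM table lacks PrecursorMz/RetentionTime columns; ",
            "XIC feature set to 0 for all PSMs", call. = FALSE)
    return(stats::setNames(rep(0, n), psms$spec_id))
  }
  areas <- vapply(seq_len(n), function(i) {
    if (!is.finite(mz[i]) || !is.finite(rt[i]) || mz[i] <= 0) return(NA_real_)
    ch <- extract_xic(ms1, mz[i], ppm_tol = ppm_tol, rt_center = rt[i],
                      rt_window = rt_window)
    integrate_peak_area(ch, rt[i], boundary_frac = boundary_frac,
                        smooth = smooth)$area
  }, numeric(1))
  if (anyNA(areas)) {
    warning(sum(is.na(areas)), " PSM(s) lacking precursor m/z or RT; ",
            "XIC feature set to 0", call. = FALSE)
    areas[is.na(areas)] <- 0
  }
  stats::setNames(areas, psms$spec_id)
}
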