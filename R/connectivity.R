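#' Post-process network time series before connectivity
#'
#' Applies, in order: per-network Z-score transformation, regression of
#' the motion traces, linear de-trending, de-spiking (values beyond 4
#' median-absolute-deviations from a window-7 running median are
#' replaced by the window median), and zero-phase Butterworth band-pass
#' filtering (order 5) in 0.01-0.15 Hz. Output series are demeaned.
#'
#' @param series K x T numeric matrix of network time courses.
#' @param motion optional 6 x T motion regressor matrix.
#' @param tr sampling interval in seconds.
#' @param band band-pass edges in Hz; the upper edge must lie below
#'   the Nyquist frequency 1/(2 tr).
#' @return K x T matrix of processed, zero-mean series.
#' @export
postprocess_timeseries <- function(series, motion = NULL, tr = 2,
                                   band = c(0.01, 0.15)) {
  series <- as.matrix(series)
  Tn <- ncol(series)
  stopifnot(Tn > 2, all(is.finite(series)))
  nyq <- 1 / (2 * tr)
  if (band[2] >= nyq)
    stop("band upper edge ", band[2], " Hz is not below Nyquist ", nyq, " Hz")
  if (band[1] <= 0) stop("band lower edge must be positive")

  out <- t(apply(series, 1, function(x) {
    s <- sd(x)
    x <- if (s > 0) (x - mean(x)) / s else x - mean(x)
    if (!is.null(motion)) {
      X <- cbind(1, t(motion))
      x <- lm.fit(X, x)$residuals
    }
    tt <- seq_len(Tn)
    x <- lm.fit(cbind(1, tt), x)$residuals        # linear detrend
    x <- despike(x)
    bf <- signal::butter(5, band / nyq, type = "pass")
    x <- signal::filtfilt(bf, x)
    x - mean(x)
  }))
  dimnames(out) <- dimnames(series)
  out
}

# replace samples beyond 4 MADs from a window-7 running median by the
# window median; when the residual MAD degenerates (smooth series,
# sparse spikes) the residual sd supplies the scale instead
despike <- function(x, k = 7, n_mad = 4) {
  med <- runmed(x, k, endrule = "median")
  resid <- x - med
  # the larger of residual MAD and sd: MAD alone collapses on smooth
  # oscillatory series (most residuals exactly zero) and would flatten
  # genuine signal peaks
  s <- max(mad(resid), sd(resid))
  if (s > 0) {
    spikes <- abs(resid) > n_mad * s
    x[spikes] <- med[spikes]
  }
  x
}

#' Functional network connectivity matrix
#'
#' Pearson correlations between all pairs of (post-processed) network
#' time courses, Fisher z-transformed. Entries with |r| at 1 (e.g.
#' duplicated series) are clipped to atanh(0.999999) and flagged, and
#' entries involving a constant series are flagged invalid (NA).
#'
#' @param series K x T matrix.
#' @return an `fnc_matrix` list: `z` (K x K symmetric Fisher-z matrix,
#'   zero diagonal), `r` (correlations), `flagged` (logical matrix).
#' @export
compute_fnc <- function(series) {
  series <- as.matrix(series)
  K <- nrow(series)
  stopifnot(K >= 2, ncol(series) > 2)
  sds <- apply(series, 1, sd)
  r <- suppressWarnings(cor(t(series)))
  r[sds == 0, ] <- NA
  r[, sds == 0] <- NA
  fz <- fisher_z(r)
  z <- fz$z
  flagged <- fz$flagged | is.na(r)
  diag(z) <- 0; diag(r) <- 1; diag(flagged) <- FALSE
  structure(list(z = z, r = r, flagged = flagged), class = "fnc_matrix")
}

#' Lower-triangle edge vector of an FNC/FC matrix
#'
#' @param fnc an `fnc_matrix` or square matrix.
#' @return named numeric vector of unique off-diagonal entries
#'   (`"i_j"` names, i < j).
#' @export
fnc_edges <- function(fnc) {
  z <- if (inherits(fnc, "fnc_matrix")) fnc$z else as.matrix(fnc)
  K <- nrow(z)
  idx <- which(lower.tri(z), arr.ind = TRUE)
  v <- z[idx]
  names(v) <- sprintf("%d_%d", idx[, 2], idx[, 1])  # i < j
  v
}

#' Representative ROI time series from voxel data
#'
#' Unweighted mean over in-mask voxels per atlas region. Regions empty
#' in the (optional) analysis mask are returned as all-NA rows and
#' marked missing.
#'
#' @param voxel_data voxels x T matrix, or 4-D array (x, y, z, T).
#' @param atlas integer label per voxel (vector aligned with rows of
#'   `voxel_data`, or 3-D label array matching the 4-D grid); label 0 =
#'   background.
#' @param mask optional logical vector/array: voxels eligible for
#'   averaging.
#' @return list: `series` (regions x T matrix, rownames = labels) and
#'   `missing` (labels with no in-mask voxels).
#' @export
roi_representative_timeseries <- function(voxel_data, atlas, mask = NULL) {
  if (is.array(voxel_data) && length(dim(voxel_data)) == 4) {
    d <- dim(voxel_data)
    voxel_data <- matrix(voxel_data, prod(d[1:3]), d[4])
    atlas <- as.vector(atlas)
    if (!is.null(mask)) mask <- as.vector(mask)
  }
  voxel_data <- as.matrix(voxel_data)
  atlas <- as.integer(atlas)
  stopifnot(length(atlas) == nrow(voxel_data))
  if (is.null(mask)) mask <- rep(TRUE, length(atlas))
  labels <- sort(unique(atlas[atlas > 0]))
  series <- matrix(NA_real_, length(labels), ncol(voxel_data),
                   dimnames = list(labels, NULL))
  missing <- integer()
  for (i in seq_along(labels)) {
    sel <- atlas == labels[i] & mask
    if (!any(sel)) { missing <- c(missing, labels[i]); next }
    series[i, ] <- colMeans(voxel_data[sel, , drop = FALSE])
  }
  list(series = series, missing = missing)
}

#' Exclude low-signal ROIs across subjects
#'
#' A region is excluded when its representative series is flat — its
#' variance below `eps_var` and absolute mean below `eps_mean` — in
#' more than fraction `f` of subjects.
#'
#' @param series_list list of regions x T matrices (same row order).
#' @param eps_var,eps_mean flatness thresholds.
#' @param f subject fraction above which a flat region is dropped.
#' @return integer vector of retained row indices.
#' @export
roi_exclusion <- function(series_list, eps_var = 1e-6, eps_mean = 1e-6,
                          f = 0.9) {
  stopifnot(length(series_list) >= 1)
  R <- nrow(series_list[[1]])
  flat <- sapply(series_list, function(s) {
    v <- apply(s, 1, var)
    m <- abs(rowMeans(s))
    (is.na(v) | v < eps_var) & (is.na(m) | m < eps_mean)
  })
  flat <- matrix(flat, nrow = R)
  frac <- rowMeans(flat)
  keep <- which(frac <= f)
  if (!length(keep)) stop("all regions excluded")
  keep
}

#' ROI-based FC matrices per subject
#'
#' Pearson correlations between retained representative series, Fisher
#' z-transformed (mirroring the FNC handling).
#'
#' @param series_list list of regions x T matrices.
#' @param keep retained region row indices from [roi_exclusion()].
#' @return list of `fnc_matrix` objects, one per subject.
#' @export
compute_roi_fc <- function(series_list, keep = NULL) {
  if (is.null(keep)) keep <- roi_exclusion(series_list)
  if (length(keep) < 2L) stop("fewer than 2 retained regions")
  lapply(series_list, function(s) compute_fnc(s[keep, , drop = FALSE]))
}
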