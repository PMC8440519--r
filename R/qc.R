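#' QC screening thresholds
#'
#' Defaults follow the normalization-quality screening rules: for fMRI
#' masks, spatial correlations must exceed 0.75 in the top 10 slices,
#' 0.55 in the bottom 10 slices and 0.8 over the whole mask; for sMRI
#' images the limits are 0.6 / 0.6 / 0.8.
#'
#' @param top_r,bottom_r,whole_r correlation thresholds (exceeded
#'   strictly to pass).
#' @param slab_size number of slices in the top/bottom slabs.
#' @param max_rot_deg,max_trans_mm,min_timepoints motion and scan
#'   length screening limits (fMRI only): pass needs rotation < 3 deg,
#'   translation < 3 mm, and more than 120 timepoints.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(top_r = 0.75, bottom_r = 0.55, whole_r = 0.8,
                          slab_size = 10, max_rot_deg = 3, max_trans_mm = 3,
                          min_timepoints = 120) {
  stopifnot(slab_size >= 1)
  structure(list(top_r = top_r, bottom_r = bottom_r, whole_r = whole_r,
                 slab_size = as.integer(slab_size),
                 max_rot_deg = max_rot_deg, max_trans_mm = max_trans_mm,
                 min_timepoints = min_timepoints),
            class = "qc_thresholds")
}

#' @rdname qc_thresholds
#' @export
qc_thresholds_smri <- function() qc_thresholds(top_r = 0.6, bottom_r = 0.6,
                                               whole_r = 0.8)

#' Individual brain mask from the first fMRI volume
#'
#' A voxel enters the mask iff its intensity strictly exceeds 90% of
#' the whole-volume mean.
#'
#' @param volume 3-D numeric array.
#' @param slice_axis axis treated as inferior-superior (slabs).
#' @return logical 3-D array with attribute `slice_axis`.
#' @export
individual_mask_fmri <- function(volume, slice_axis = 3L) {
  stopifnot(is.array(volume), length(dim(volume)) == 3)
  mask <- volume > 0.9 * mean(volume)
  if (!any(mask)) stop("empty mask: volume has no voxels above 90% of its mean")
  attr(mask, "slice_axis") <- as.integer(slice_axis)
  mask
}

#' Group mask from individual masks
#'
#' A voxel enters the group mask iff it is present in strictly more
#' than 90% of the individual masks.
#'
#' @param masks list of logical arrays on a common grid.
#' @return logical array.
#' @export
group_mask <- function(masks) {
  stopifnot(length(masks) >= 1)
  d <- dim(masks[[1]])
  for (m in masks) if (!identical(dim(m), d)) stop("mismatched mask grids")
  frac <- Reduce(`+`, lapply(masks, function(m) m * 1)) / length(masks)
  gm <- frac > 0.9
  attr(gm, "slice_axis") <- attr(masks[[1]], "slice_axis")
  gm
}

# extract a slab of `size` slices at the low ("bottom") or high ("top")
# end of `axis`; returns the sub-array's values as a vector
slab_values <- function(x, axis, size, end = c("top", "bottom")) {
  end <- match.arg(end)
  n <- dim(x)[axis]
  stopifnot(size <= n)
  idx <- if (end == "top") seq(n - size + 1L, n) else seq_len(size)
  args <- rep(list(quote(expr = )), 3)
  args[[axis]] <- idx
  do.call(`[`, c(list(x), args, drop = FALSE))
}

#' Slab and whole-mask spatial correlations
#'
#' Pearson correlation of the two masks' voxel values (binary 0/1)
#' restricted to the top slab, the bottom slab, and the full grid. A
#' slab in which either mask is constant has no defined correlation and
#' is reported as NA with a "degenerate slab" reason.
#'
#' @param ind,grp individual and group masks (or images) on one grid.
#' @param slab_size slices per slab.
#' @param slice_axis axis along which slabs are taken.
#' @return list with `r_top`, `r_bottom`, `r_whole` and character
#'   vector `reasons` for any degenerate slab.
#' @export
slab_correlations <- function(ind, grp, slab_size = 10,
                              slice_axis = attr(ind, "slice_axis") %||% 3L) {
  if (!identical(dim(ind), dim(grp))) stop("mismatched grids")
  corr <- function(a, b, label) {
    a <- as.numeric(a); b <- as.numeric(b)
    if (sd(a) == 0 || sd(b) == 0)
      return(list(r = NA_real_, reason = paste("degenerate slab:", label)))
    list(r = cor(a, b), reason = NULL)
  }
  top <- corr(slab_values(ind, slice_axis, slab_size, "top"),
              slab_values(grp, slice_axis, slab_size, "top"), "top")
  bot <- corr(slab_values(ind, slice_axis, slab_size, "bottom"),
              slab_values(grp, slice_axis, slab_size, "bottom"), "bottom")
  who <- corr(ind, grp, "whole")
  list(r_top = top$r, r_bottom = bot$r, r_whole = who$r,
       reasons = c(top$reason, bot$reason, who$reason))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Screen one fMRI subject
#'
#' Pass requires max rotation < 3 degrees, max translation < 3 mm,
#' strictly more than 120 timepoints, and all three mask correlations
#' strictly above their thresholds. Reasons list every violated
#' criterion.
#'
#' @param ind,grp individual and group binary masks.
#' @param motion list or vector with `trans_mm` and `rot_deg` maxima;
#'   `NULL` fails with a missing-motion reason.
#' @param n_timepoints scan length.
#' @param thresholds a [qc_thresholds()].
#' @return list with `pass`, `reasons`, and the three correlations.
#' @export
screen_fmri_subject <- function(ind, grp, motion, n_timepoints,
                                thresholds = qc_thresholds()) {
  reasons <- character()
  if (is.null(motion) || any(is.na(c(motion[["trans_mm"]], motion[["rot_deg"]])))) {
    reasons <- c(reasons, "missing motion record")
  } else {
    if (motion[["rot_deg"]] >= thresholds$max_rot_deg)
      reasons <- c(reasons, sprintf("rotation %.2f deg not < %g",
                                    motion[["rot_deg"]], thresholds$max_rot_deg))
    if (motion[["trans_mm"]] >= thresholds$max_trans_mm)
      reasons <- c(reasons, sprintf("translation %.2f mm not < %g",
                                    motion[["trans_mm"]], thresholds$max_trans_mm))
  }
  if (n_timepoints <= thresholds$min_timepoints)
    reasons <- c(reasons, sprintf("need >%d time points, have %d",
                                  thresholds$min_timepoints, n_timepoints))
  sc <- slab_correlations(ind, grp, thresholds$slab_size)
  reasons <- c(reasons, sc$reasons)
  for (nm in c("top", "bottom", "whole")) {
    r <- sc[[paste0("r_", nm)]]
    th <- thresholds[[paste0(nm, "_r")]]
    if (!is.na(r) && r <= th)
      reasons <- c(reasons, sprintf("%s-mask correlation %.3f not > %g", nm, r, th))
  }
  list(pass = length(reasons) == 0L, reasons = reasons,
       r_top = sc$r_top, r_bottom = sc$r_bottom, r_whole = sc$r_whole)
}

#' Screen one sMRI subject
#'
#' The group mask keeps voxels where the group-mean image exceeds 0.2;
#' correlations are computed between the continuous individual and
#' group-mean image values within that mask's top slab, bottom slab
#' and whole extent, and compared to the sMRI thresholds.
#'
#' @param ind_image individual structural image (3-D array).
#' @param group_mean_image group mean structural image, same grid.
#' @param thresholds a [qc_thresholds()]; defaults to sMRI limits.
#' @param slice_axis slab axis.
#' @return list with `pass`, `reasons`, three correlations.
#' @export
screen_smri_subject <- function(ind_image, group_mean_image,
                                thresholds = qc_thresholds_smri(),
                                slice_axis = 3L) {
  if (!identical(dim(ind_image), dim(group_mean_image)))
    stop("images on different grids")
  gmask <- group_mean_image > 0.2
  if (!any(gmask)) stop("empty group mask: no voxels above 0.2")
  # correlations over in-mask voxels only, per slab and whole mask
  corr_in_mask <- function(sel, label) {
    keep <- as.logical(sel) & as.logical(gmask)
    a <- ind_image[keep]; b <- group_mean_image[keep]
    if (length(a) < 2L || sd(a) == 0 || sd(b) == 0)
      return(list(r = NA_real_, reason = paste("degenerate slab:", label)))
    list(r = cor(a, b), reason = NULL)
  }
  n_slices <- dim(gmask)[slice_axis]
  slab_sel <- function(end) {
    idx <- if (end == "top")
      seq(n_slices - thresholds$slab_size + 1L, n_slices)
    else seq_len(thresholds$slab_size)
    sel <- array(FALSE, dim(gmask))
    args <- rep(list(quote(expr = )), 3)
    args[[slice_axis]] <- idx
    do.call(`[<-`, c(list(sel), args, list(TRUE)))
  }
  top <- corr_in_mask(slab_sel("top"), "top")
  bot <- corr_in_mask(slab_sel("bottom"), "bottom")
  who <- corr_in_mask(gmask, "whole")
  sc <- list(r_top = top$r, r_bottom = bot$r, r_whole = who$r)
  reasons <- c(top$reason, bot$reason, who$reason)
  for (nm in c("top", "bottom", "whole")) {
    r <- sc[[paste0("r_", nm)]]
    th <- thresholds[[paste0(nm, "_r")]]
    if (!is.na(r) && r <= th)
      reasons <- c(reasons, sprintf("%s-mask correlation %.3f not > %g", nm, r, th))
  }
  list(pass = length(reasons) == 0L, reasons = reasons,
       r_top = sc$r_top, r_bottom = sc$r_bottom, r_whole = sc$r_whole)
}

#' Full fMRI QC pass with one group-mask recomputation
#'
#' Computes individual masks, an initial group mask over all subjects,
#' screens every subject against it, then recomputes the group mask
#' from the passing subjects' masks (a single recomputation; no further
#' iteration).
#'
#' @param volumes list of first-timepoint 3-D volumes, one per subject.
#' @param motion data.frame with `trans_mm`, `rot_deg` rows per
#'   subject, or `NULL` rows for missing records.
#' @param n_timepoints integer vector of scan lengths per subject.
#' @param thresholds a [qc_thresholds()].
#' @return a `qc_report` list: per-subject data.frame `report`
#'   (correlations, pass, reason), the `final_mask`, and indices
#'   `selected`.
#' @export
qc_fmri_pipeline <- function(volumes, motion = NULL, n_timepoints = NULL,
                             thresholds = qc_thresholds()) {
  n <- length(volumes)
  stopifnot(n >= 1)
  if (is.null(motion))
    motion <- data.frame(trans_mm = rep(0, n), rot_deg = rep(0, n))
  if (is.null(n_timepoints)) n_timepoints <- rep(150L, n)
  masks <- lapply(volumes, individual_mask_fmri)
  gm <- group_mask(masks)
  screens <- lapply(seq_len(n), function(s)
    screen_fmri_subject(masks[[s]], gm,
                        list(trans_mm = motion$trans_mm[s],
                             rot_deg = motion$rot_deg[s]),
                        n_timepoints[s], thresholds))
  pass <- vapply(screens, `[[`, logical(1), "pass")
  if (!any(pass)) stop("all subjects failed QC screening")
  final_mask <- group_mask(masks[pass])
  report <- data.frame(
    subject = seq_len(n),
    r_top = vapply(screens, `[[`, numeric(1), "r_top"),
    r_bottom = vapply(screens, `[[`, numeric(1), "r_bottom"),
    r_whole = vapply(screens, `[[`, numeric(1), "r_whole"),
    pass = pass,
    reason = vapply(screens, function(s) paste(s$reasons, collapse = "; "),
                    character(1)))
  structure(list(report = report, final_mask = final_mask,
                 selected = which(pass),
                 recomputed_after_selection = TRUE),
            class = "qc_report")
}

#' Write a QC report as TSV and JSON
#' @param qc a `qc_report` from [qc_fmri_pipeline()].
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_qc_report <- function(qc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "qc_report.tsv")
  write.table(qc$report, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- file.path(dir, "qc_report.json")
  jsonlite::write_json(list(selected = qc$selected,
                            recomputed_after_selection = qc$recomputed_after_selection),
                       p2, auto_unbox = TRUE)
  invisible(c(p1, p2))
}
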