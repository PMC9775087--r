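#' Exocytosis trace container
#'
#' Per-cell pHluorin fluorescence time trace with the three event frames
#' needed for exocytosis quantification: last pre-stimulation frame block
#' (basal), the post-stimulation peak, and the NH4Cl plateau revealing the
#' total vesicle pool.
#'
#' @param time Frame times, s.
#' @param fluorescence Mean ROI fluorescence per frame, a.u.
#' @param stim_frame,peak_frame,nh4cl_frame Frame indices, ordered
#'   `stim < peak < nh4cl`; `stim_frame` is the last pre-stimulation frame
#'   and `nh4cl_frame` the first frame of the NH4Cl plateau.
#'   `peak_frame = NA` requests auto-detection as the argmax of a 5-frame
#'   running mean between `stim_frame` and `nh4cl_frame`.
#' @param cell_id Cell identifier.
#' @param condition Condition label (variant / expression level).
#' @return An object of class `exo_trace`.
#' @export
exo_trace <- function(time, fluorescence, stim_frame, peak_frame = NA,
                      nh4cl_frame, cell_id = "cell", condition = "control") {
  stopifnot(length(time) == length(fluorescence))
  n <- length(time)
  if (is.na(peak_frame)) {
    # stop the search early enough that the stimulated window and the
    # smoothing support stay clear of the NH4Cl response
    lo <- stim_frame + 1L; hi <- nh4cl_frame - 5L
    sm <- stats::filter(fluorescence, rep(1 / 5, 5), sides = 2)
    sm[is.na(sm)] <- fluorescence[is.na(sm)]
    peak_frame <- (lo:hi)[which.max(sm[lo:hi])]
  }
  if (!(stim_frame < peak_frame && peak_frame < nh4cl_frame))
    stopf("frames must be ordered stim < peak < nh4cl")
  if (stim_frame < 5 || peak_frame < 5 || nh4cl_frame + 4 > n)
    stopf("need >= 5 frames available in each averaging window")
  structure(list(time = time, fluorescence = fluorescence,
                 stim_frame = as.integer(stim_frame),
                 peak_frame = as.integer(peak_frame),
                 nh4cl_frame = as.integer(nh4cl_frame),
                 cell_id = cell_id, condition = condition),
            class = "exo_trace")
}

#' Fraction of vesicles exocytosed from a pHluorin trace
#'
#' `Exo = (F_stimulated - F_basal) / (F_total - F_basal)` where each F is
#' the mean of a 5-frame window: the 5 frames ending at the stimulation
#' frame (basal), the 5 frames starting at the detected post-stimulation
#' peak (stimulated) and the 5 frames starting 4 frames after NH4Cl
#' administration (total pool). As a ratio of differences the measure is
#' invariant to affine gain/offset rescaling of the trace. Values outside
#' [0, 1] are flagged, not clipped.
#'
#' @param trace An [exo_trace()].
#' @param tol Relative tolerance below which `F_total - F_basal` is
#'   treated as zero (default 1e-6).
#' @return List with `cell_id`, `condition`, `exo`, `outlier` (set later
#'   by filtering, initialised FALSE), `flagged` (out-of-range or
#'   undefined), and the three window means.
#' @export
compute_exo <- function(trace, tol = 1e-6) {
  stopifnot(inherits(trace, "exo_trace"))
  f <- trace$fluorescence
  w_basal <- (trace$stim_frame - 4):trace$stim_frame
  w_stim  <- trace$peak_frame:(trace$peak_frame + 4)
  w_total <- trace$nh4cl_frame:(trace$nh4cl_frame + 4)
  if (max(w_basal) >= min(w_stim) || max(w_stim) >= min(w_total))
    stopf("averaging windows must be disjoint and ordered")
  F_basal <- mean(f[w_basal]); F_stim <- mean(f[w_stim]); F_total <- mean(f[w_total])
  den <- F_total - F_basal
  undefined <- abs(den) <= tol * max(abs(F_total), abs(F_basal), tol)
  exo <- if (undefined) NA_real_ else (F_stim - F_basal) / den
  list(cell_id = trace$cell_id, condition = trace$condition, exo = exo,
       outlier = FALSE, flagged = undefined || (!is.na(exo) && (exo < 0 || exo > 1)),
       F_basal = F_basal, F_stimulated = F_stim, F_total = F_total)
}

#' 1.5 x IQR outlier filter
#'
#' Removes values below `Q1 - 1.5 IQR` or above `Q3 + 1.5 IQR`. Quartiles
#' use linear interpolation between order statistics (R's default type-7
#' quantile), fixed and documented because conventions differ.
#'
#' @param values Numeric vector (>= 4 values).
#' @param k IQR multiplier (default 1.5).
#' @return List with `kept`, `removed`, and the logical `is_outlier` mask;
#'   `kept` and `removed` partition the input.
#' @export
iqr_filter <- function(values, k = 1.5) {
  if (length(values) < 4) stopf("need >= 4 values for the IQR rule")
  q <- quantile(values, c(0.25, 0.75), na.rm = TRUE, type = 7)
  iqr <- q[2] - q[1]
  out <- values < q[1] - k * iqr | values > q[2] + k * iqr
  out[is.na(out)] <- FALSE
  list(kept = values[!out], removed = values[out], is_outlier = out,
       bounds = unname(c(q[1] - k * iqr, q[2] + k * iqr)))
}

#' Compare exocytosis between expression conditions
#'
#' The potentiation measure is the mean difference `high - low` after
#' 1.5 x IQR outlier filtering within each group, with a Welch two-sample
#' t-test and the printed significance categories (`***` p < 0.001,
#' `*` p < 0.05, `NS` otherwise). Conclusions are also reported without
#' outlier removal, mirroring the robustness check of the source analysis
#' design. Groups of fewer than 2 cells get descriptive output only.
#'
#' @param low,high Numeric vectors of per-cell Exo values, or lists of
#'   [compute_exo()] results.
#' @param filter_outliers Apply [iqr_filter()] before testing (default TRUE).
#' @return List with `difference`, `p_value`, `category`, group summaries,
#'   and `unfiltered` (same statistics without outlier removal).
#' @export
compare_conditions <- function(low, high, filter_outliers = TRUE) {
  as_vec <- function(x) {
    if (is.list(x) && !is.null(x[[1]]$exo))
      x <- vapply(x, function(e) e$exo, 0)
    as.numeric(x[is.finite(x)])
  }
  lo_all <- as_vec(low); hi_all <- as_vec(high)
  if (length(lo_all) == 0 || length(hi_all) == 0)
    stopf("both groups must be non-empty")

  run <- function(lo, hi) {
    d <- mean(hi) - mean(lo)
    if (length(lo) < 2 || length(hi) < 2)
      return(list(difference = d, p_value = NA_real_, category = NA_character_,
                  n_low = length(lo), n_high = length(hi)))
    p <- t.test(hi, lo)$p.value
    list(difference = d, p_value = p,
         category = if (p < 0.001) "***" else if (p < 0.05) "*" else "NS",
         n_low = length(lo), n_high = length(hi))
  }
  unfiltered <- run(lo_all, hi_all)
  if (filter_outliers && length(lo_all) >= 4 && length(hi_all) >= 4) {
    lo <- iqr_filter(lo_all)$kept; hi <- iqr_filter(hi_all)$kept
  } else {
    lo <- lo_all; hi <- hi_all
  }
  out <- run(lo, hi)
  out$mean_low <- mean(lo); out$mean_high <- mean(hi)
  out$unfiltered <- unfiltered
  out
}

#' Peripheral (membrane-proximal) fraction of a fluorescence signal
#'
#' Percentage of total in-cell fluorescence lying in an inner shell of the
#' requested physical thickness along the cell-mask boundary; used to
#' quantify the fraction of recycling endosomes proximal to the plasma
#' membrane from mCherry-Rab11 images.
#'
#' @param image Numeric matrix, single-channel intensities.
#' @param cell_mask Logical matrix, closed cell mask.
#' @param pixel_size_nm Pixel edge length, nm.
#' @param shell_thickness_nm Shell thickness, nm (default 800).
#' @return Percent of masked fluorescence within the shell.
#' @export
peripheral_fraction <- function(image, cell_mask, pixel_size_nm,
                                shell_thickness_nm = 800) {
  stopifnot(is.matrix(image), is.matrix(cell_mask),
            all(dim(image) == dim(cell_mask)))
  t_px <- shell_thickness_nm / pixel_size_nm
  if (t_px < 1)
    stopf("shell thickness below 1 pixel (%.2f px): need finer pixel size", t_px)
  r <- round(t_px)
  eroded <- as_mat(EBImage::erode(cell_mask * 1, EBImage::makeBrush(2 * r + 1, "disc")))
  shell <- cell_mask & !(eroded > 0.5)
  total <- sum(image[cell_mask])
  if (total <= 0) stopf("zero total fluorescence inside the cell mask")
  100 * sum(image[shell]) / total
}
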