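#' Li minimum-cross-entropy threshold
#'
#' Iterative minimum cross-entropy thresholding for nonnegative images:
#' starting from the global mean, the threshold is updated as
#' `t <- (m0 - m1) / (log(m0) - log(m1))` with `m0`, `m1` the means of the
#' two classes, until convergence.
#'
#' @param x Numeric matrix/vector of nonnegative intensities.
#' @param tol Convergence tolerance on the threshold (default 1e-6 of the
#'   intensity range).
#' @param max_iter Iteration cap.
#' @param floor_frac Numerical floor on class means as a fraction of the
#'   dynamic range (default 1e-3): the cross-entropy update takes logs of
#'   the class means, which degenerates when an idealized background is
#'   exactly zero after background subtraction.
#' @return The threshold value.
#' @export
threshold_li <- function(x, tol = 1e-6, max_iter = 200, floor_frac = 1e-3) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  lo <- min(v)
  rng <- diff(range(v))
  if (rng == 0) return(lo)
  eps <- rng * floor_frac
  v <- v - lo
  t0 <- mean(v)
  for (i in seq_len(max_iter)) {
    m0 <- max(mean(v[v <= t0]), eps)
    m1 <- max(mean(v[v > t0]), eps)
    if (!is.finite(m0) || !is.finite(m1) || m0 == m1) break
    t1 <- (m0 - m1) / (log(m0) - log(m1))
    if (abs(t1 - t0) < tol * rng) { t0 <- t1; break }
    t0 <- t1
  }
  t0 + lo
}

# strip EBImage's Image class back to a base matrix
as_mat <- function(x) if (inherits(x, "Image")) EBImage::imageData(x) else x

# 8-connected labelling: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally with a union-find pass.
label_8connected <- function(mask) {
  L <- as_mat(EBImage::bwlabel(as_mat(mask) * 1))
  n <- max(L)
  if (n < 2) return(L)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[rb] <<- ra }
  nr <- nrow(L); nc <- ncol(L)
  pairs <- rbind(
    cbind(as.vector(L[-nr, -nc]), as.vector(L[-1, -1])),   # down-right
    cbind(as.vector(L[-1, -nc]),  as.vector(L[-nr, -1])))  # up-right
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs)) apply(unique(pairs), 1, function(p) union2(p[1], p[2]))
  roots <- vapply(seq_len(n), find, 0L)
  relab <- match(roots, sort(unique(roots)))
  out <- L
  out[L > 0] <- relab[L[L > 0]]
  out
}

# grayscale opening with a flat disc: the morphological equivalent of
# rolling-ball background estimation for a ball larger than any feature.
# EBImage grayscale morphology operates on [0,1], so rescale around it.
disc_opening <- function(x, diameter) {
  brush <- EBImage::makeBrush(2 * floor(diameter / 2) + 1, "disc")
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(x)
  xn <- (x - lo) / (hi - lo)
  as_mat(EBImage::opening(xn, brush)) * (hi - lo) + lo
}

#' Segment condensate droplets and measure SUV partition coefficients
#'
#' Processing follows the standard condensate-image pipeline: a 2-pixel
#' Gaussian blur of the eGFP (synapsin) channel, background subtraction by
#' grayscale opening with a 40-pixel flat disc (chosen larger than the
#' largest droplet), Li minimum-cross-entropy thresholding, 8-connected
#' labelling, and an area filter at 0.2 square microns. The partition
#' coefficient of each droplet is the mean rhodamine (SUV) fluorescence
#' inside it divided by the mean rhodamine fluorescence outside all
#' droplets (inverted threshold). Blur-contaminated boundary pixels are
#' excluded from both sides of the ratio: a guard band around every
#' droplet is excluded from "outside", and an inner margin of the droplet
#' mask is excluded from "inside" (disable with `guard_px = 0`,
#' `inside_margin_px = 0` for literal inverted-threshold replication;
#' areas are always measured on the unshrunken mask). Droplets
#' containing any rhodamine pixel at or above `sat_level` are dropped
#' (automated stand-in for manual removal of saturated droplets).
#'
#' @param egfp,rhodamine Numeric matrices: synapsin-eGFP and
#'   rhodamine-SUV channels, registered, same size.
#' @param pixel_size_um Pixel edge length, microns.
#' @param blur_sigma Gaussian blur sigma, px (default 2).
#' @param ball_diameter Background disc diameter, px (default 40).
#' @param min_area_um2 Minimum droplet area, square microns (default 0.2).
#' @param guard_px Guard-band width around droplets excluded from the
#'   outside region, px (default 2).
#' @param inside_margin_px Boundary band excluded from the inside mean,
#'   px (default `ceiling(blur_sigma) + 1`); falls back to the full mask
#'   for droplets the erosion would remove entirely.
#' @param sat_level Rhodamine saturation level; `NULL` disables saturated
#'   droplet removal.
#' @return data.frame of class `droplet_stats`: `droplet_id`, `area_um2`,
#'   `mean_inside`, `mean_outside`, `partition_coefficient`, `log_pc`.
#'   Empty segmentation returns an empty data.frame, not an error.
#' @export
droplet_partition <- function(egfp, rhodamine, pixel_size_um,
                              blur_sigma = 2, ball_diameter = 40,
                              min_area_um2 = 0.2, guard_px = 2,
                              inside_margin_px = ceiling(blur_sigma) + 1,
                              sat_level = NULL) {
  stopifnot(is.matrix(egfp), is.matrix(rhodamine),
            all(dim(egfp) == dim(rhodamine)))
  proc <- as_mat(EBImage::gblur(egfp, sigma = blur_sigma))
  proc <- proc - disc_opening(proc, ball_diameter)
  thr <- threshold_li(proc)
  mask <- proc > thr
  L <- label_8connected(mask)
  n <- max(L)
  empty <- data.frame(droplet_id = integer(0), area_um2 = numeric(0),
                      mean_inside = numeric(0), mean_outside = numeric(0),
                      partition_coefficient = numeric(0), log_pc = numeric(0))
  if (n == 0) return(structure(empty, class = c("droplet_stats", "data.frame")))

  outside_mask <- L == 0
  if (guard_px > 0) {
    grown <- as_mat(EBImage::dilate((L > 0) * 1, EBImage::makeBrush(2 * guard_px + 1, "disc")))
    outside_mask <- grown < 0.5
  }
  mean_out <- mean(rhodamine[outside_mask])
  core <- if (inside_margin_px > 0)
    as_mat(EBImage::erode((L > 0) * 1,
                          EBImage::makeBrush(2 * inside_margin_px + 1, "disc"))) > 0.5
  else L > 0
  rows <- lapply(seq_len(n), function(i) {
    px <- L == i
    area <- sum(px) * pixel_size_um^2
    if (area <= min_area_um2) return(NULL)
    if (!is.null(sat_level) && any(rhodamine[px] >= sat_level)) return(NULL)
    if (!is.finite(mean_out) || mean_out <= 0) {
      warnf("droplet %d dropped: zero/invalid outside mean", i)
      return(NULL)
    }
    inner <- px & core
    if (!any(inner)) inner <- px
    pc <- mean(rhodamine[inner]) / mean_out
    data.frame(droplet_id = i, area_um2 = area,
               mean_inside = mean(rhodamine[inner]), mean_outside = mean_out,
               partition_coefficient = pc, log_pc = log(pc))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- empty
  rownames(out) <- NULL
  structure(out, class = c("droplet_stats", "data.frame"))
}

#' Compare droplet partition coefficients between two conditions
#'
#' Log-transforms partition coefficients, removes 1.5 x IQR outliers,
#' checks near-normality of each filtered group (Shapiro-Wilk) and runs a
#' two-sample t-test on the log values. The same comparison without
#' outlier removal is reported alongside, as the robustness check.
#'
#' @param pc_a,pc_b Partition coefficients of the two conditions (vectors
#'   or [droplet_partition()] results).
#' @return List with group log-means, `p_value`, `shapiro_p` per group,
#'   `category` and `unfiltered` statistics.
#' @export
droplet_group_stats <- function(pc_a, pc_b) {
  get_pc <- function(x) if (is.data.frame(x)) x$partition_coefficient else as.numeric(x)
  la <- log(get_pc(pc_a)); lb <- log(get_pc(pc_b))
  run <- function(a, b) {
    p <- if (length(a) >= 2 && length(b) >= 2) t.test(a, b)$p.value else NA_real_
    list(mean_log_a = mean(a), mean_log_b = mean(b), p_value = p,
         category = if (is.na(p)) NA_character_ else
           if (p < 0.001) "***" else if (p < 0.05) "*" else "NS",
         n_a = length(a), n_b = length(b))
  }
  unf <- run(la, lb)
  fa <- if (length(la) >= 4) iqr_filter(la)$kept else la
  fb <- if (length(lb) >= 4) iqr_filter(lb)$kept else lb
  out <- run(fa, fb)
  out$shapiro_p_a <- if (length(fa) >= 3 && sd(fa) > 0) shapiro.test(fa)$p.value else NA_real_
  out$shapiro_p_b <- if (length(fb) >= 3 && sd(fb) > 0) shapiro.test(fb)$p.value else NA_real_
  out$unfiltered <- unf
  out
}
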