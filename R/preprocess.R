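#' Rigid motion correction by cross-correlation to the mean image
#'
#' The reference is the pixel-wise mean of all frames. Each frame's integer
#' (x, y) displacement is the argmax of the 2-D cross-correlation with the
#' reference (computed via FFT, searched within `max_shift`); the inverse
#' shift is applied with edge fill. No sub-pixel interpolation is
#' performed.
#'
#' @param movie array height x width x frames (>= 2 frames).
#' @param max_shift largest |shift| considered, pixels.
#' @return list with `movie` (corrected array) and `shifts` (frames x 2
#'   matrix, columns `dx`, `dy`: the estimated content displacement of each
#'   raw frame relative to the reference).
#' @export
motion_correct <- function(movie, max_shift = NULL) {
  d <- dim(movie)
  if (length(d) != 3 || d[3] < 2) stop("need a movie with at least 2 frames")
  if (is.null(max_shift)) max_shift <- floor(min(d[1], d[2]) / 4)
  ref <- apply(movie, c(1, 2), mean)
  fr_ref <- stats::fft(ref)
  shifts <- matrix(0L, d[3], 2, dimnames = list(NULL, c("dx", "dy")))
  out <- array(0, d)
  for (t in seq_len(d[3])) {
    fr <- movie[, , t]
    if (stats::sd(fr) == 0) {
      warning("frame ", t, " has zero variance; shift set to 0")
      out[, , t] <- fr
      next
    }
    s <- .xcorr_shift(fr_ref, fr, max_shift)
    shifts[t, ] <- c(s["dx"], s["dy"])
    out[, , t] <- .shift_image(fr, -s["dy"], -s["dx"],
                               fill = stats::median(fr))
  }
  list(movie = out, shifts = shifts)
}

# integer displacement of `frame` content relative to the reference whose
# FFT is `fft_ref`: frame ~ .shift_image(ref, dy, dx)
.xcorr_shift <- function(fft_ref, frame, max_shift) {
  h <- nrow(frame); w <- ncol(frame)
  cc <- Re(stats::fft(fft_ref * Conj(stats::fft(frame)),
                      inverse = TRUE)) / (h * w)
  # cc[i, j] corresponds to circular lag (i-1, j-1); content shift is the
  # negative of the argmax lag, wrapped to (-dim/2, dim/2]
  wrap <- function(k, n) ifelse(k > n / 2, k - n, k)
  lag_r <- wrap(0:(h - 1), h)
  lag_c <- wrap(0:(w - 1), w)
  ok <- outer(abs(lag_r) <= max_shift, abs(lag_c) <= max_shift)
  cc[!ok] <- -Inf
  idx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  c(dx = -lag_c[idx[2]], dy = -lag_r[idx[1]])
}

#' Segment somata from the activity map of a motion-corrected movie
#'
#' The per-pixel activity statistic is the temporal variance of the
#' high-pass-filtered pixel trace (trace minus a `hp_width`-frame moving
#' average), which highlights pixels with stimulus-locked transients.
#' Pixels exceeding a local adaptive threshold (local mean within
#' `window_um` plus `offset_sd` global standard deviations) are labelled
#' into connected components; components above `max_area` are split by
#' recursively raising the threshold inside them.
#'
#' @param movie motion-corrected array height x width x frames.
#' @param window_um local-threshold window size, micrometres.
#' @param um_per_px image scale.
#' @param offset_sd threshold offset in global SD units of the activity
#'   map.
#' @param min_area,max_area component size bounds, pixels.
#' @param hp_width moving-average width (frames) of the high-pass filter.
#' @return list of logical mask matrices (possibly empty); masks are
#'   disjoint.
#' @export
segment_rois <- function(movie, window_um = 50, um_per_px = 1,
                         offset_sd = 3, min_area = 4, max_area = 80,
                         hp_width = 10) {
  d <- dim(movie)
  np <- d[1] * d[2]
  X <- t(matrix(movie, np, d[3]))            # frames x pixels
  ma <- stats::filter(X, rep(1 / hp_width, hp_width), sides = 2)
  hp <- X - ma
  amap <- matrix(apply(hp, 2, stats::var, na.rm = TRUE), d[1], d[2])
  w_px <- max(3, round(window_um / um_per_px))
  if (w_px %% 2 == 0) w_px <- w_px + 1
  local_mean <- .box_mean(amap, w_px)
  thr_mask <- amap > local_mean + offset_sd * stats::sd(amap)
  if (!any(thr_mask)) return(list())
  comps <- .label_components(thr_mask)
  masks <- list()
  split_comp <- function(mask, depth = 0) {
    area <- sum(mask)
    if (area < min_area) return()
    if (area <= max_area || depth >= 6) {
      masks[[length(masks) + 1]] <<- mask
      return()
    }
    vals <- amap[mask]
    sub <- mask & (amap > stats::quantile(vals, 0.5))
    if (sum(sub) == 0 || sum(sub) == area) {
      masks[[length(masks) + 1]] <<- mask
      return()
    }
    for (m in .label_components(sub)) split_comp(m, depth + 1)
  }
  for (m in comps) split_comp(m)
  masks
}

# connected components (8-connectivity) as a list of logical masks
.label_components <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- EBImage::imageData(lab)
  ids <- setdiff(unique(as.vector(lab)), 0)
  lapply(ids, function(i) lab == i)
}

# box (moving-average) filter with edge replication
.box_mean <- function(img, w) {
  r <- (w - 1) / 2
  k <- rep(1 / w, w)
  padr <- img[pmin(pmax(seq_len(nrow(img) + 2 * r) - r, 1), nrow(img)), ,
              drop = FALSE]
  m1 <- apply(padr, 2, function(col) stats::filter(col, k, sides = 2))
  m1 <- m1[(r + 1):(r + nrow(img)), , drop = FALSE]
  padc <- t(m1)[pmin(pmax(seq_len(ncol(img) + 2 * r) - r, 1), ncol(img)), ,
                drop = FALSE]
  m2 <- apply(padc, 2, function(col) stats::filter(col, k, sides = 2))
  t(m2[(r + 1):(r + ncol(img)), , drop = FALSE])
}

#' Centroid of a pixel mask
#'
#' @param mask logical matrix.
#' @return named vector `x` (column), `y` (row).
#' @export
roi_centroid <- function(mask) {
  px <- which(mask, arr.ind = TRUE)
  c(x = mean(px[, 2]), y = mean(px[, 1]))
}

#' Extract somatic and neuropil fluorescence for ROI masks
#'
#' The somatic trace is the mean over mask pixels per frame. The neuropil
#' trace is the mean over an annulus extending `neuropil_range_um` from
#' the ROI border, excluding the pixels of every ROI.
#'
#' @param movie motion-corrected array.
#' @param masks list of logical masks from [segment_rois()].
#' @param neuropil_range_um annulus extent from the ROI border,
#'   micrometres `c(inner, outer)`.
#' @param um_per_px image scale.
#' @return list of ROI records, each with `roi_id`, `mask`, `centroid`,
#'   `F_raw_soma`, `F_neuropil`.
#' @export
extract_roi_traces <- function(movie, masks, neuropil_range_um = c(0, 15),
                               um_per_px = 1) {
  if (!length(masks)) return(list())
  d <- dim(movie)
  all_rois <- Reduce(`|`, masks)
  flat <- matrix(movie, d[1] * d[2], d[3])
  r_in <- max(0, round(neuropil_range_um[1] / um_per_px))
  r_out <- max(1, round(neuropil_range_um[2] / um_per_px))
  lapply(seq_along(masks), function(j) {
    m <- masks[[j]]
    outer_m <- .dilate_mask(m, r_out)
    inner_m <- if (r_in > 0) .dilate_mask(m, r_in) else m
    annulus <- outer_m & !inner_m & !all_rois
    if (!any(annulus)) annulus <- outer_m & !all_rois
    list(roi_id = j, mask = m, centroid = roi_centroid(m),
         F_raw_soma = colMeans(flat[which(m), , drop = FALSE]),
         F_neuropil = if (any(annulus))
           colMeans(flat[which(annulus), , drop = FALSE])
         else rep(NA_real_, d[3]))
  })
}

.dilate_mask <- function(mask, r) {
  if (r <= 0) return(mask)
  sz <- 2 * r + 1
  br <- EBImage::makeBrush(sz, shape = "disc")
  out <- EBImage::dilate(EBImage::Image(mask * 1), br)
  EBImage::imageData(out) > 0
}

#' Neuropil subtraction
#'
#' `F_corrected(t) = F_raw_soma(t) - r * F_neuropil(t)`.
#'
#' @param F_raw_soma,F_neuropil equal-length fluorescence traces (a.u.).
#' @param r neuropil contamination coefficient.
#' @return corrected trace.
#' @export
neuropil_correct <- function(F_raw_soma, F_neuropil, r = 0.7) {
  if (length(F_raw_soma) != length(F_neuropil))
    stop("soma and neuropil traces differ in length")
  F_raw_soma - r * F_neuropil
}

#' Normalise a fluorescence trace to dF/F
#'
#' The baseline F0 is the mode of the fluorescence density (kernel density
#' estimate, Silverman bandwidth), which is robust to sparse positive
#' transients; dF/F = (F - F0) / F0.
#'
#' @param F fluorescence trace (a.u.); its density mode must be positive.
#' @return dF/F trace with attribute `F0`.
#' @export
compute_dff <- function(F) {
  if (length(F) < 2) stop("trace too short")
  if (stats::sd(F) == 0) {
    F0 <- F[1]
  } else {
    dens <- stats::density(F, bw = "nrd0")
    F0 <- dens$x[which.max(dens$y)]
  }
  if (F0 <= 0) stop("nonpositive baseline F0; corrupted trace")
  structure((F - F0) / F0, F0 = F0)
}

#' Align ROIs across chronically imaged sessions
#'
#' Anchor points (manually matched landmarks) define a predicted
#' displacement field: for each ROI the predicted vector is the
#' inverse-distance-weighted mean of the anchor vectors. A square region
#' around the ROI (about 4x the ROI size) is then matched against the
#' other session's mean image by normalized cross-correlation; the
#' correlation map is multiplied point-wise by a Gaussian mask (sd
#' `mask_sigma`) centred on the predicted vector and smoothed with a 2-D
#' Gaussian (sd `smooth_sigma`), and its peak is the computed displacement.
#' ROIs whose computed vector differs from the prediction by more than
#' 5 px in either coordinate are flagged for inspection.
#'
#' @param mean_img_A,mean_img_B average projection images of the two
#'   sessions.
#' @param rois_A list of logical ROI masks in session A.
#' @param anchors data.frame with columns `x`, `y` (position in A) and
#'   `dx`, `dy` (displacement A -> B), at least one row.
#' @param search max displacement searched, pixels.
#' @param mask_sigma,smooth_sigma Gaussian mask / smoothing widths, px.
#' @param flag_px flag threshold on the sup-norm difference, pixels.
#' @return data.frame with one row per ROI: predicted and computed
#'   displacement vectors and the `flagged` indicator; skipped ROIs (window
#'   outside the image) carry NA.
#' @export
align_rois_across_sessions <- function(mean_img_A, mean_img_B, rois_A,
                                       anchors, search = 12,
                                       mask_sigma = 10, smooth_sigma = 1,
                                       flag_px = 5) {
  stopifnot(nrow(anchors) >= 1)
  res <- lapply(seq_along(rois_A), function(j) {
    m <- rois_A[[j]]
    ctr <- roi_centroid(m)
    # inverse-distance-weighted prediction from anchors
    dd <- sqrt((anchors$x - ctr["x"])^2 + (anchors$y - ctr["y"])^2)
    wts <- 1 / pmax(dd, 1e-6)
    pred <- c(dx = sum(wts * anchors$dx) / sum(wts),
              dy = sum(wts * anchors$dy) / sum(wts))
    px <- which(m, arr.ind = TRUE)
    half <- 2 * max(diff(range(px[, 1])) + 1, diff(range(px[, 2])) + 1)
    r0 <- round(ctr["y"]); c0 <- round(ctr["x"])
    rows <- (r0 - half):(r0 + half)
    cols <- (c0 - half):(c0 + half)
    if (min(rows) < 1 || max(rows) > nrow(mean_img_A) ||
        min(cols) < 1 || max(cols) > ncol(mean_img_A)) {
      warning("ROI ", j, " window leaves the image; skipped")
      return(data.frame(roi = j, pred_dx = pred["dx"], pred_dy = pred["dy"],
                        comp_dx = NA_real_, comp_dy = NA_real_,
                        flagged = NA))
    }
    templ <- mean_img_A[rows, cols]
    dgrid <- -search:search
    ncc <- matrix(-Inf, length(dgrid), length(dgrid))
    for (iy in seq_along(dgrid)) for (ix in seq_along(dgrid)) {
      rr <- rows + dgrid[iy]; cc <- cols + dgrid[ix]
      if (min(rr) < 1 || max(rr) > nrow(mean_img_B) ||
          min(cc) < 1 || max(cc) > ncol(mean_img_B)) next
      patch <- mean_img_B[rr, cc]
      if (stats::sd(patch) == 0 || stats::sd(templ) == 0) next
      ncc[iy, ix] <- stats::cor(as.vector(templ), as.vector(patch))
    }
    valid <- is.finite(ncc)
    ncc[!valid] <- 0
    gmask <- outer(stats::dnorm(dgrid, pred["dy"], mask_sigma),
                   stats::dnorm(dgrid, pred["dx"], mask_sigma))
    masked <- ncc * gmask / max(gmask)
    # validity-weighted smoothing avoids edge bias from displacements that
    # could not be evaluated (window outside the image)
    num <- .gauss_blur(masked * valid, smooth_sigma)
    den <- .gauss_blur(valid * 1, smooth_sigma)
    score <- ifelse(den > 1e-8 & valid, num / den, -Inf)
    idx <- which(score == max(score), arr.ind = TRUE)[1, ]
    comp <- c(dx = dgrid[idx[2]], dy = dgrid[idx[1]])
    data.frame(roi = j, pred_dx = unname(pred["dx"]),
               pred_dy = unname(pred["dy"]),
               comp_dx = unname(comp["dx"]), comp_dy = unname(comp["dy"]),
               flagged = max(abs(comp - pred)) > flag_px)
  })
  do.call(rbind, res)
}
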