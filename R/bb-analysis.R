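#' Extract an intensity profile from a portal image
#'
#' Pulls a single row (horizontal) or column (vertical) of pixel values,
#' inverted (`max(image) - value`) so that attenuation dips become positive
#' peaks, with physical mm coordinates from the pixel pitch. A constant image
#' therefore yields a flat zero profile.
#'
#' @param image A [portal_image()].
#' @param axis `"horizontal"` (along u, fixed row) or `"vertical"` (along v,
#'   fixed column).
#' @param index 0-based row (horizontal) or column (vertical) index.
#' @param span Optional 0-based inclusive index range c(from, to) along the
#'   profile; `NULL` for the full extent. Must lie inside the image.
#' @return A tibble of class `bb_profile` with columns `position_mm`,
#'   `value`, and attributes `axis` and `source_index`.
#' @export
extract_profile <- function(image, axis = c("horizontal", "vertical"),
                            index, span = NULL) {
  stopifnot(inherits(image, "portal_image"))
  axis <- match.arg(axis)
  px <- image$pixels
  n_along <- if (axis == "horizontal") ncol(px) else nrow(px)
  n_across <- if (axis == "horizontal") nrow(px) else ncol(px)
  if (index < 0 || index > n_across - 1) {
    stop("`index` outside the image (0..", n_across - 1, ")", call. = FALSE)
  }
  if (is.null(span)) span <- c(0L, n_along - 1L)
  if (span[1] < 0 || span[2] > n_along - 1 || span[1] > span[2]) {
    stop("`span` outside the image (0..", n_along - 1, ")", call. = FALSE)
  }
  idx <- (span[1]:span[2]) + 1L
  vals <- if (axis == "horizontal") px[index + 1L, idx] else px[idx, index + 1L]
  pos <- if (axis == "horizontal") {
    panel_u_mm(image, span[1]:span[2])
  } else {
    panel_v_mm(image, span[1]:span[2])
  }
  new_bb_profile(pos, max(px) - vals, axis, index)
}

new_bb_profile <- function(position_mm, value, axis = "horizontal",
                           source_index = NA_integer_) {
  out <- tibble::tibble(position_mm = as.numeric(position_mm),
                        value = as.numeric(value))
  if (nrow(out) > 1) {
    d <- diff(out$position_mm)
    if (any(d <= 0) || diff(range(d)) > 1e-9 * max(abs(d))) {
      stop("profile coordinates must be strictly increasing and uniform",
           call. = FALSE)
    }
  }
  attr(out, "axis") <- axis
  attr(out, "source_index") <- source_index
  class(out) <- c("bb_profile", class(out))
  out
}

#' Subtract an averaged background from a ballbearing profile
#'
#' Background profiles acquired just above and just below the ballbearing are
#' averaged and subtracted element-wise from the profile through the
#' ballbearing. When the background field is affine in the image plane and
#' the two flanking profiles are symmetric about the ballbearing row, the
#' background cancels exactly and only the peak remains.
#'
#' @param bb_profile,above,below `bb_profile`s on identical coordinates.
#' @return A `bb_profile` of the residual.
#' @export
subtract_background <- function(bb_profile, above, below) {
  for (p in list(bb_profile, above, below)) {
    if (!inherits(p, "bb_profile")) stop("inputs must be bb_profile objects",
                                         call. = FALSE)
  }
  if (nrow(above) != nrow(bb_profile) || nrow(below) != nrow(bb_profile) ||
      max(abs(above$position_mm - bb_profile$position_mm)) > 1e-9 ||
      max(abs(below$position_mm - bb_profile$position_mm)) > 1e-9) {
    stop("background profiles must share the ballbearing profile's coordinates",
         call. = FALSE)
  }
  new_bb_profile(bb_profile$position_mm,
                 bb_profile$value - (above$value + below$value) / 2,
                 attr(bb_profile, "axis"), attr(bb_profile, "source_index"))
}

#' Sub-pixel peak centre and width by FWHM
#'
#' Locates the centre and full width at half maximum of a single peak. The
#' baseline is the median of the outer 20 % of samples (10 % each end),
#' robust to residual background ramps; the half-maximum level is
#' `baseline + (peak - baseline) / 2`; the two half-maximum crossings are
#' found by linear interpolation between the bracketing samples and the
#' centre is their midpoint (for a flat-topped peak this is the plateau
#' midpoint). Shifting the profile coordinates shifts the centre by exactly
#' the same amount.
#'
#' Errors: a peak not dropping below half maximum on both sides is reported
#' as `"peak truncated"`; more than one contiguous region above the
#' half-maximum level as `"ambiguous peak"`.
#'
#' @param profile A `bb_profile` (or tibble with `position_mm`, `value`).
#' @return A list with `center_mm`, `width_mm`, `peak_height`, `baseline`.
#' @export
fwhm_center <- function(profile) {
  x <- profile$position_mm
  y <- profile$value
  n <- length(y)
  if (n < 3) stop("profile too short for FWHM analysis", call. = FALSE)
  n_edge <- max(1L, floor(0.1 * n))
  baseline <- median(c(head(y, n_edge), tail(y, n_edge)))
  peak <- max(y)
  if (peak <= baseline) {
    stop("no peak above baseline in profile", call. = FALSE)
  }
  half <- baseline + (peak - baseline) / 2
  above <- y >= half
  runs <- rle(above)
  if (sum(runs$values) > 1L) {
    stop("ambiguous peak: multiple disjoint regions above half maximum",
         call. = FALSE)
  }
  i_first <- which(above)[1]
  i_last <- tail(which(above), 1)
  if (i_first == 1L || i_last == n) {
    stop("peak truncated: no half-maximum crossing on ",
         if (i_first == 1L) "the left" else "the right", call. = FALSE)
  }
  interp_cross <- function(i0, i1) {
    # linear interpolation of the half-max crossing between samples i0, i1
    x[i0] + (half - y[i0]) * (x[i1] - x[i0]) / (y[i1] - y[i0])
  }
  x_left <- interp_cross(i_first - 1L, i_first)
  x_right <- interp_cross(i_last + 1L, i_last)
  list(center_mm = (x_left + x_right) / 2,
       width_mm = x_right - x_left,
       peak_height = peak - baseline,
       baseline = baseline)
}

#' Locate a single ballbearing in a region of interest
#'
#' Finds the brightest (most attenuating) pixel in the ROI, extracts the
#' horizontal profile through it with flanking background rows symmetric
#' about the peak (at the ROI edges), subtracts the averaged background, and
#' takes the FWHM centre for u; likewise with flanking columns for v. The
#' centre is reported in pixels and in mm at the panel relative to the
#' central pixel. The ROI must contain exactly one ballbearing — two peaks
#' make the FWHM ambiguous and raise an error.
#'
#' @param image A [portal_image()].
#' @param roi List with 0-based inclusive pixel ranges `rows = c(r0, r1)`,
#'   `cols = c(c0, c1)`; `NULL` for a centred square of half-width
#'   `roi_half_mm`.
#' @param roi_half_mm Half-width of the default centred ROI, mm at the panel.
#' @param background Subtract flanking background profiles? (Recommended
#'   whenever couch or phantom edges cross the image.)
#' @return A one-row tibble: `u_mm`, `v_mm`, `u_px`, `v_px`, `fwhm_u_mm`,
#'   `fwhm_v_mm`, `peak_height`, `background_corrected`.
#' @export
locate_bb <- function(image, roi = NULL, roi_half_mm = 12,
                      background = TRUE) {
  stopifnot(inherits(image, "portal_image"))
  px <- image$pixels
  pitch <- image$geom$pixel_pitch_mm
  if (is.null(roi)) {
    hw <- round(roi_half_mm / pitch)
    cu <- round(image$central_px[1]); cv <- round(image$central_px[2])
    roi <- list(rows = c(max(0, cv - hw), min(nrow(px) - 1, cv + hw)),
                cols = c(max(0, cu - hw), min(ncol(px) - 1, cu + hw)))
  }
  r0 <- roi$rows[1]; r1 <- roi$rows[2]; c0 <- roi$cols[1]; c1 <- roi$cols[2]
  if (r0 < 0 || r1 > nrow(px) - 1 || c0 < 0 || c1 > ncol(px) - 1) {
    stop("ROI outside the image", call. = FALSE)
  }
  sub <- px[(r0:r1) + 1L, (c0:c1) + 1L, drop = FALSE]
  pk <- which(sub == min(sub), arr.ind = TRUE)[1, ]  # deepest dip
  pr <- r0 + pk[1] - 1L  # 0-based peak row
  pc <- c0 + pk[2] - 1L

  profile_with_bg <- function(axis, peak_idx, lo, hi, span) {
    main <- extract_profile(image, axis, peak_idx, span)
    if (!background) return(main)
    d <- min(peak_idx - lo, hi - peak_idx)
    if (d < 1) return(main)
    subtract_background(main,
                        extract_profile(image, axis, peak_idx - d, span),
                        extract_profile(image, axis, peak_idx + d, span))
  }
  ph <- profile_with_bg("horizontal", pr, r0, r1, c(c0, c1))
  pv <- profile_with_bg("vertical", pc, c0, c1, c(r0, r1))
  fh <- fwhm_center(ph)
  fv <- fwhm_center(pv)
  u_px <- image$central_px[1] + fh$center_mm / pitch
  v_px <- image$central_px[2] + fv$center_mm / pitch
  tibble::tibble(u_mm = fh$center_mm, v_mm = fv$center_mm,
                 u_px = u_px, v_px = v_px,
                 fwhm_u_mm = fh$width_mm, fwhm_v_mm = fv$width_mm,
                 peak_height = fh$peak_height,
                 background_corrected = isTRUE(background))
}

# Contiguous regions of a profile above a fractional threshold of its peak;
# returns a tibble of intensity-weighted centroids and FWHM-style widths.
profile_peak_regions <- function(profile, threshold_frac = 0.3) {
  y <- profile$value
  x <- profile$position_mm
  n_edge <- max(1L, floor(0.1 * length(y)))
  base <- median(c(head(y, n_edge), tail(y, n_edge)))
  yy <- y - base
  thr <- threshold_frac * max(yy)
  above <- yy >= thr & thr > 0
  if (!any(above)) return(tibble::tibble(centroid_mm = numeric(),
                                         width_mm = numeric(),
                                         height = numeric()))
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  purrr::map_dfr(keep, function(k) {
    i <- starts[k]:ends[k]
    w <- yy[i]
    tibble::tibble(centroid_mm = sum(x[i] * w) / sum(w),
                   width_mm = diff(range(x[i])) + (x[2] - x[1]),
                   height = max(w))
  })
}

#' Gantry-angle reproducibility metrics against a baseline image
#'
#' Compares a phantom image with the reference (gantry-zero) image of the
#' same arrangement using the horizontal profile through the ballbearing
#' row. Three quantitative surrogates replace the visual judgement:
#'
#' * `rms_profile_diff` — RMS difference of the peak-normalized,
#'   baseline-subtracted profiles (0 for identical images);
#' * `peripheral_separation_diffs` — change, in mm, of the separations
#'   between successive ballbearing blob centroids relative to the baseline
#'   (a gantry rotation moves the projections of the near and far ring
#'   ballbearings in opposite senses, so these separations asymmetrize);
#' * `peripheral_width_diffs` — change, in mm, of each blob's width. The
#'   partially eclipsed ballbearing pairs at the image peripheries merge into
#'   single blobs, so their internal separation change appears as blob
#'   broadening or narrowing rather than centroid motion;
#' * `eclipse_score` — in \[0, 1\]: ratio of the narrower to the wider central
#'   blob FWHM between the two images. Diametrically opposed ballbearings
#'   aligned with the beam eclipse into one blob; any angular offset widens
#'   it, lowering the score below 1.
#'
#' The function does not return an absolute gantry angle — the comparison
#' only establishes reproducibility against the baseline.
#'
#' @param image,baseline_image [portal_image()]s of the same phantom
#'   arrangement.
#' @param row 0-based profile row; default the central-pixel row.
#' @param threshold_frac Fractional peak threshold for blob segmentation.
#' A large angular offset (around a degree) resolves the eclipsed pairs into
#' doublets: the image then shows more blobs than the baseline. Split blobs
#' are aggregated back onto their nearest baseline blob for the separation
#' metrics, and the split is visible in `n_blobs`. An image with *fewer*
#' blobs than the baseline is an error (a ballbearing is missing).
#'
#' @return A list with `rms_profile_diff`, `peripheral_separation_diffs`,
#'   `peripheral_width_diffs`, `eclipse_score`, `n_blobs` (image) and
#'   `n_blobs_baseline`.
#' @export
gantry_reproducibility <- function(image, baseline_image, row = NULL,
                                   threshold_frac = 0.3) {
  stopifnot(inherits(image, "portal_image"),
            inherits(baseline_image, "portal_image"))
  get_row <- function(im) row %||% round(im$central_px[2])
  p_img <- extract_profile(image, "horizontal", get_row(image))
  p_base <- extract_profile(baseline_image, "horizontal", get_row(baseline_image))
  if (nrow(p_img) != nrow(p_base)) {
    stop("images have different widths; same phantom arrangement required",
         call. = FALSE)
  }
  norm <- function(p) {
    n_edge <- max(1L, floor(0.1 * nrow(p)))
    base <- median(c(head(p$value, n_edge), tail(p$value, n_edge)))
    v <- p$value - base
    pk <- max(v)
    if (pk <= 0) stop("no ballbearing signal in profile", call. = FALSE)
    v / pk
  }
  rms <- sqrt(mean((norm(p_img) - norm(p_base))^2))

  reg_img <- profile_peak_regions(p_img, threshold_frac)
  reg_base <- profile_peak_regions(p_base, threshold_frac)
  if (nrow(reg_base) < 1 || nrow(reg_img) < nrow(reg_base)) {
    missing_at <- if (nrow(reg_base)) {
      paste(sprintf("%.1f mm", reg_base$centroid_mm), collapse = ", ")
    } else "everywhere"
    stop(sprintf(paste0("missing peripheral peaks: %d blob(s) in image vs %d ",
                        "in baseline (baseline blobs at %s)"),
                 nrow(reg_img), nrow(reg_base), missing_at),
         call. = FALSE)
  }
  # aggregate (possibly split) image blobs onto their nearest baseline blob
  assign_to <- purrr::map_int(reg_img$centroid_mm, function(cm) {
    which.min(abs(reg_base$centroid_mm - cm))
  })
  agg <- purrr::map_dfr(seq_len(nrow(reg_base)), function(k) {
    sub <- reg_img[assign_to == k, , drop = FALSE]
    if (!nrow(sub)) {
      stop(sprintf("missing peripheral peaks: no image blob near %.1f mm",
                   reg_base$centroid_mm[k]), call. = FALSE)
    }
    w <- sub$height * sub$width_mm
    tibble::tibble(
      centroid_mm = sum(sub$centroid_mm * w) / sum(w),
      width_mm = max(sub$centroid_mm + sub$width_mm / 2) -
        min(sub$centroid_mm - sub$width_mm / 2))
  })
  sep_diffs <- if (nrow(reg_base) > 1) {
    diff(agg$centroid_mm) - diff(reg_base$centroid_mm)
  } else {
    numeric()
  }
  i_central <- which.min(abs(reg_base$centroid_mm))
  w1 <- agg$width_mm[i_central]; w0 <- reg_base$width_mm[i_central]
  list(rms_profile_diff = rms,
       peripheral_separation_diffs = sep_diffs,
       peripheral_width_diffs = agg$width_mm - reg_base$width_mm,
       eclipse_score = min(w0, w1) / max(w0, w1),
       n_blobs = nrow(reg_img),
       n_blobs_baseline = nrow(reg_base))
}
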