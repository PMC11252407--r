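#' Intensity skewness of a cell crop (actin bundling index)
#'
#' Third standardized moment \eqn{g_1 = m_3 / m_2^{3/2}} of the pixel
#' intensity distribution, with population (biased) central moments by
#' default. Bundled actin concentrates fluorescence into few bright
#' cables, right-skewing the histogram, so \eqn{g_1} rises with bundling.
#' Computed on raw maximum-intensity-projection pixels with no background
#' subtraction; invariant under any affine intensity transform
#' \eqn{aI + b} with \eqn{a > 0}.
#'
#' @param crop Numeric matrix or vector of pixel intensities.
#' @param sample_adjusted Use the sample (G1, bias-corrected) form.
#' @return Skewness value. Errors when the intensity variance is zero.
#' @export
intensity_skewness <- function(crop, sample_adjusted = FALSE) {
  x <- as.numeric(crop)
  n <- length(x)
  if (n < 2L) stop("need at least 2 pixels")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero intensity variance; skewness undefined")
  g1 <- mean((x - m)^3) / m2^1.5
  if (sample_adjusted) g1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  g1
}

#' Dominant filament orientation of a crop via the structure tensor
#'
#' Estimates the dominant orientation from the gradient structure tensor
#' (summed over the crop, intensity-gradient weighted): the filament
#' direction is perpendicular to the dominant gradient direction. The
#' angle is reported in \[0, 90\] degrees relative to the declared
#' reference axis of a horizontally aligned cell: `"longitudinal"` (the
#' cell long axis, horizontal) or `"radial"` (transverse). Crops with
#' tensor coherence below `coherence_min` are flagged low confidence.
#'
#' @param crop Numeric matrix (rows = image y, columns = x).
#' @param reference_axis `"longitudinal"` or `"radial"`.
#' @param coherence_min Coherence below which the estimate is flagged.
#' @return List: `angle` (degrees in \[0, 90\] from the reference axis),
#'   `angle_horizontal` (signed degrees from horizontal in (-90, 90\]),
#'   `coherence` in \[0, 1\], `low_confidence` flag.
#' @export
dominant_angle <- function(crop, reference_axis = c("longitudinal", "radial"),
                           coherence_min = 0.1) {
  reference_axis <- match.arg(reference_axis)
  a <- as.matrix(crop)
  if (nrow(a) < 3L || ncol(a) < 3L) stop("crop too small")
  # central differences on the interior
  gx <- (a[, -(1:2)] - a[, seq_len(ncol(a) - 2L)])[-c(1L, nrow(a)), ] / 2
  gy <- (a[-(1:2), ] - a[seq_len(nrow(a) - 2L), ])[, -c(1L, ncol(a))] / 2
  jxx <- sum(gx * gx); jyy <- sum(gy * gy); jxy <- sum(gx * gy)
  denom <- jxx + jyy
  if (denom == 0) stop("flat crop; orientation undefined")
  coherence <- sqrt((jxx - jyy)^2 + 4 * jxy^2) / denom
  # dominant gradient orientation; filaments run perpendicular to it.
  # Angles are in image coordinates (x = columns, y = rows, positive
  # rotation from +x toward +y), matching the filament renderer.
  phi_grad <- 0.5 * atan2(2 * jxy, jxx - jyy)
  theta <- (phi_grad + pi / 2) * 180 / pi  # filament axis
  theta <- ((theta + 90) %% 180) - 90
  if (theta == -90) theta <- 90
  from_horizontal <- abs(theta)
  angle <- if (reference_axis == "longitudinal") from_horizontal else
    90 - from_horizontal
  list(angle = angle, angle_horizontal = theta, coherence = coherence,
       low_confidence = coherence < coherence_min)
}

#' Maximum-entropy (Kapur) intensity threshold
#'
#' Selects the threshold `t` maximizing the sum of Shannon entropies of
#' the normalized sub-histograms below (intensity <= t) and above
#' (intensity > t), the MaxEntropy criterion of common image software.
#' Ties take the lowest maximizing `t`. The result is invariant to
#' rescaling the histogram by a constant.
#'
#' @param x Image or intensity vector on a 0..255 8-bit scale (values are
#'   rounded and clamped), or `NULL` when `counts` is given.
#' @param counts Optional histogram: counts for intensities
#'   `0:(length(counts) - 1)`.
#' @return Integer threshold `t` (foreground is intensity > t). Errors on
#'   a single-valued image.
#' @export
kapur_threshold <- function(x = NULL, counts = NULL) {
  if (is.null(counts)) {
    v <- pmin(pmax(round(as.numeric(x)), 0), 255)
    counts <- tabulate(v + 1L, nbins = 256L)
  }
  if (sum(counts > 0) < 2L) stop("degenerate histogram: single intensity value")
  p <- counts / sum(counts)
  plogp <- ifelse(p > 0, -p * log(p), 0)
  P <- cumsum(p)
  S <- cumsum(plogp)
  Stot <- S[length(S)]
  t_cand <- seq_along(p) - 1L           # thresholds 0 .. max
  Pb <- P; Pa <- 1 - P
  valid <- Pb > 0 & Pa > 0
  Hb <- ifelse(valid, S / Pb + log(Pb), -Inf)
  Ha <- ifelse(valid, (Stot - S) / Pa + log(Pa), -Inf)
  tot <- Hb + Ha
  t_cand[which.max(tot)]                 # which.max -> lowest on ties
}

#' Lay out square ROIs across a span of tissue
#'
#' Places `n_rois` square regions of interest of physical side `roi_um`
#' left-to-right across a `span_um` stretch (e.g. 8 ROIs of 24 um across
#' a 150 um transition zone), converted to pixel coordinates.
#'
#' @param px_um Pixel size, micrometres per pixel.
#' @param n_rois Number of ROIs.
#' @param roi_um ROI side, micrometres.
#' @param span_um Span covered by the ROI centres, micrometres.
#' @param x0,y0 Pixel coordinates of the first ROI's top-left corner.
#' @return Data frame `roi`, `x`, `y`, `width`, `height` (pixels).
#' @export
roi_grid <- function(px_um, n_rois = 8L, roi_um = 24, span_um = 150,
                     x0 = 1L, y0 = 1L) {
  side <- max(1L, round(roi_um / px_um))
  step <- if (n_rois > 1L)
    (span_um / px_um - side) / (n_rois - 1L) else 0
  data.frame(roi = seq_len(n_rois),
             x = round(x0 + (seq_len(n_rois) - 1L) * step),
             y = y0, width = side, height = side)
}

#' Detect calcium spikes in an image stack
#'
#' Applies a maximum-entropy threshold (computed once from the whole
#' stack) and, per ROI and frame, keeps suprathreshold connected
#' components of at least `min_pixels` pixels (smaller components are
#' sporadic signals and discarded). Qualifying components that overlap
#' spatially in consecutive frames are merged into one spike event with a
#' duration; event counts are converted to spikes per hour when the frame
#' interval is known.
#'
#' Before thresholding, a signal-contrast guard checks that the
#' foreground class is distinguishable from background (foreground minus
#' background class mean at least `min_contrast_sd` background standard
#' deviations and at least `min_contrast_abs` gray levels); a stack of
#' pure noise has no signal class and returns zero events, since the
#' maximum-entropy criterion would otherwise split the noise mode.
#'
#' @param stack 3-D array (height x width x frames), 0..255 scale.
#' @param rois Data frame `roi`, `x`, `y`, `width`, `height` in pixels
#'   (e.g. from [roi_grid()]).
#' @param min_pixels Minimum suprathreshold component size.
#' @param frame_interval Seconds between frames (NULL = rates omitted).
#' @param threshold Override the automatic threshold.
#' @param min_contrast_sd,min_contrast_abs Signal-contrast guard.
#' @return List: `summary` (per ROI: `roi`, `n_events`,
#'   `spikes_per_hour`), `events` (`roi`, `start_frame`, `end_frame`,
#'   `max_pixels`), `threshold`, `signal_detected`.
#' @export
detect_spikes <- function(stack, rois, min_pixels = 6L,
                          frame_interval = NULL, threshold = NULL,
                          min_contrast_sd = 4, min_contrast_abs = 8) {
  d <- dim(stack)
  if (length(d) != 3L) stop("stack must be a 3-D array")
  if (any(rois$x < 1 | rois$y < 1 | rois$x + rois$width - 1 > d[2L] |
          rois$y + rois$height - 1 > d[1L]))
    stop("ROI outside image bounds")

  signal_detected <- TRUE
  if (is.null(threshold)) {
    v <- pmin(pmax(round(as.numeric(stack)), 0), 255)
    threshold <- kapur_threshold(counts = tabulate(v + 1L, nbins = 256L))
    below <- v[v <= threshold]; above <- v[v > threshold]
    contrast <- mean(above) - mean(below)
    sd_b <- stats::sd(below)
    if (length(above) == 0L || !is.finite(contrast) ||
        contrast < max(min_contrast_abs, min_contrast_sd * max(sd_b, 1e-8)))
      signal_detected <- FALSE
  }

  events <- list(); k <- 0L
  hours <- if (!is.null(frame_interval)) d[3L] * frame_interval / 3600 else NA
  summary <- data.frame(roi = rois$roi, n_events = 0L,
                        spikes_per_hour = if (is.na(hours)) NA_real_ else 0)
  if (signal_detected) {
    for (r in seq_len(nrow(rois))) {
      ys <- rois$y[r] + seq_len(rois$height[r]) - 1L
      xs <- rois$x[r] + seq_len(rois$width[r]) - 1L
      prev_mask <- NULL; cur <- NULL
      for (f in seq_len(d[3L])) {
        m <- stack[ys, xs, f] > threshold
        mask <- matrix(FALSE, length(ys), length(xs))
        if (any(m)) {
          lab <- EBImage::bwlabel(m)
          sizes <- tabulate(lab[lab > 0])
          keep <- which(sizes >= min_pixels)
          if (length(keep)) mask <- matrix(lab %in% keep, length(ys))
        }
        if (any(mask)) {
          new_event <- is.null(prev_mask) || !any(mask & prev_mask)
          if (new_event) {
            if (!is.null(cur)) { k <- k + 1L; events[[k]] <- cur }
            cur <- data.frame(roi = rois$roi[r], start_frame = f,
                              end_frame = f, max_pixels = sum(mask))
          } else {
            cur$end_frame <- f
            cur$max_pixels <- max(cur$max_pixels, sum(mask))
          }
          prev_mask <- mask
        } else {
          if (!is.null(cur)) { k <- k + 1L; events[[k]] <- cur; cur <- NULL }
          prev_mask <- NULL
        }
      }
      if (!is.null(cur)) { k <- k + 1L; events[[k]] <- cur }
    }
  }
  events <- if (k > 0L) do.call(rbind, events) else
    data.frame(roi = integer(0), start_frame = integer(0),
               end_frame = integer(0), max_pixels = integer(0))
  ne <- table(factor(events$roi, levels = rois$roi))
  summary$n_events <- as.integer(ne)
  if (!is.na(hours)) summary$spikes_per_hour <- summary$n_events / hours
  list(summary = summary, events = events, threshold = threshold,
       signal_detected = signal_detected)
}

#' Plasmolysis shrinkage percentage
#'
#' Percentage of cell shrinkage from the protoplast area (membrane
#' marker) and the total cell area (bright-field cell wall):
#' \eqn{100 (1 - A_{protoplast} / A_{total})}.
#'
#' @param protoplast,total Areas in the same units, both > 0,
#'   `protoplast <= total` (vectorized).
#' @return Shrinkage percentage(s) in \[0, 100\].
#' @export
shrinkage_percent <- function(protoplast, total) {
  if (any(protoplast <= 0) || any(total <= 0))
    stop("areas must be > 0")
  if (any(protoplast > total))
    stop("protoplast area cannot exceed total cell area")
  100 * (1 - protoplast / total)
}
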