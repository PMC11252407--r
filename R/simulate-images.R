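#' Render a synthetic actin-filament cell crop
#'
#' Draws `n_filaments` Gaussian-profile line structures crossing a square
#' crop at a common orientation, over optional Gaussian background noise.
#' `bundling` concentrates the same total signal onto fewer, brighter
#' cables (`ceiling(n_filaments / bundling)` lines, amplitude scaled up to
#' conserve total intensity), mimicking actin bundling, which makes the
#' intensity histogram increasingly right-skewed. Filament offsets are
#' stratified across the crop with seeded jitter, like the roughly even
#' spacing of cortical actin cables.
#'
#' The scene is defined in a centred, rotated coordinate frame, so
#' rendering the same seed at orientations 0 and 90 degrees yields images
#' related by an exact quarter-turn (when `noise_sd = 0`).
#'
#' @param size Crop side in pixels.
#' @param px_um Pixel size in micrometres per pixel (metadata only).
#' @param n_filaments Number of filaments before bundling (0 = noise only).
#' @param orientation Filament angle in degrees from horizontal, in
#'   \[-90, 90\].
#' @param bundling Bundling factor >= 1.
#' @param amplitude Peak intensity of an unbundled filament.
#' @param width_px Gaussian half-width of a filament profile, pixels.
#' @param noise_sd Background Gaussian noise sd (intensity units).
#' @param baseline Constant background level.
#' @param seed Integer seed.
#' @return Numeric `size` x `size` matrix with attributes `px_um` and
#'   `orientation`.
#' @export
render_filament_image <- function(size = 128L, px_um = 0.1, n_filaments = 12L,
                                  orientation = 0, bundling = 1,
                                  amplitude = 50, width_px = 1.5,
                                  noise_sd = 0, baseline = 0, seed = 1L) {
  stop_if_not_count(size, "size", 8L)
  if (orientation < -90 || orientation > 90)
    stop("orientation must lie in [-90, 90]")
  if (bundling < 1) stop("bundling must be >= 1")
  n_eff <- if (n_filaments > 0) max(1L, ceiling(n_filaments / bundling)) else 0L

  ctr <- (size + 1) / 2
  xc <- matrix(rep(seq_len(size) - ctr, each = size), size, size)  # column
  yc <- matrix(rep(seq_len(size) - ctr, times = size), size, size) # row
  th <- orientation * pi / 180
  # perpendicular (signed) coordinate of each pixel in the rotated frame
  v <- -sin(th) * xc + cos(th) * yc

  with_seed(seed, {
    img <- matrix(baseline, size, size)
    if (n_eff > 0L) {
      spacing <- size / n_eff
      offs <- (seq_len(n_eff) - 0.5) * spacing - size / 2 +
        stats::runif(n_eff, -0.4, 0.4) * spacing
      amp <- amplitude * n_filaments / n_eff
      for (o in offs) img <- img + amp * exp(-(v - o)^2 / (2 * width_px^2))
    }
    if (noise_sd > 0) img <- img + stats::rnorm(size^2, sd = noise_sd)
    structure(img, px_um = px_um, orientation = orientation)
  })
}

#' Simulate a calcium-imaging ROI movie with planted spikes
#'
#' Builds an image stack of Gaussian background noise around `baseline`
#' and plants compact suprathreshold events per a schedule: each scheduled
#' spike is a connected blob of exactly `area_px` pixels (nearest pixels
#' to its centre) raised by `amplitude` (with per-pixel jitter) for
#' `duration` consecutive frames.
#'
#' @param n_frames Number of frames.
#' @param height,width Frame size in pixels.
#' @param schedule Data frame with columns `frame`, `x`, `y` and
#'   optionally `area_px` and `duration` (defaults applied); `x` = column,
#'   `y` = row of the spike centre.
#' @param area_px Default spike area in pixels (>= 1).
#' @param duration Default spike duration in frames.
#' @param amplitude Mean intensity added to spike pixels.
#' @param amp_jitter_sd Per-pixel sd of the added intensity.
#' @param baseline,noise_sd Background level and noise sd.
#' @param seed Integer seed.
#' @return List: `stack` (height x width x n_frames array, clamped to
#'   \[0, 255\]) and `truth` (the resolved schedule).
#' @export
simulate_roi_movie <- function(n_frames, height = 64L, width = 64L,
                               schedule = NULL, area_px = 12L, duration = 2L,
                               amplitude = 150, amp_jitter_sd = 10,
                               baseline = 20, noise_sd = 2, seed = 1L) {
  stop_if_not_count(n_frames, "n_frames", 1L)
  if (area_px < 1) stop("spike area must be >= 1 pixel")
  if (is.null(schedule))
    schedule <- data.frame(frame = integer(0), x = integer(0), y = integer(0))
  if (is.null(schedule$area_px))
    schedule$area_px <- rep(as.integer(area_px), nrow(schedule))
  if (is.null(schedule$duration))
    schedule$duration <- rep(as.integer(duration), nrow(schedule))
  if (nrow(schedule) > 0) {
    bad <- schedule$frame < 1 | schedule$frame + schedule$duration - 1 > n_frames |
      schedule$x < 1 | schedule$x > width | schedule$y < 1 | schedule$y > height
    if (any(bad)) stop("spike schedule outside frame/image range")
    if (any(schedule$area_px < 1)) stop("spike area must be >= 1 pixel")
  }

  with_seed(seed, {
    stack <- array(stats::rnorm(height * width * n_frames,
                                mean = baseline, sd = noise_sd),
                   dim = c(height, width, n_frames))
    if (nrow(schedule) > 0) {
      cols <- matrix(rep(seq_len(width), each = height), height, width)
      rows <- matrix(rep(seq_len(height), times = width), height, width)
      for (i in seq_len(nrow(schedule))) {
        d2 <- (cols - schedule$x[i])^2 + (rows - schedule$y[i])^2
        px <- order(d2)[seq_len(schedule$area_px[i])]  # compact blob
        for (f in schedule$frame[i] + seq_len(schedule$duration[i]) - 1L) {
          frame <- stack[, , f]
          frame[px] <- frame[px] + amplitude +
            stats::rnorm(length(px), sd = amp_jitter_sd)
          stack[, , f] <- frame
        }
      }
    }
    stack[stack < 0] <- 0; stack[stack > 255] <- 255
    list(stack = stack, truth = schedule)
  })
}

#' Simulate a 96-well secondary-screen plate
#'
#' Produces per-well mean intensities for a plate layout (each genotype's
#' wells get its growth intensity plus well-to-well Gaussian noise) and
#' optionally renders an 8-bit grayscale-convertible RGB plate image in
#' which each well is a uniform disk of its intensity.
#'
#' @param layout Data frame with columns `row`, `col`, `genotype`,
#'   `is_wt` (logical) and optionally `excluded` (bubbles / irregular
#'   clamping; such wells carry no intensity).
#' @param growth Named numeric vector: genotype -> mean well intensity
#'   (0-255 scale).
#' @param noise_sd Well-to-well intensity noise sd.
#' @param seed Integer seed.
#' @param render Also return an RGB image array?
#' @param well_px Well pitch in pixels (image rendering).
#' @param radius_px Well disk radius in pixels.
#' @return List: `wells` (layout plus `intensity`, excluded wells NA) and,
#'   if `render`, `image` (rows x cols x 3 RGB array, 0-255) plus
#'   `geometry` (list `x0`, `y0`, `dx`, `dy`, `radius` for
#'   [quantify_wells()]).
#' @export
simulate_plate <- function(layout, growth, noise_sd = 0, seed = 1L,
                           render = FALSE, well_px = 24L, radius_px = 9L) {
  if (is.null(layout$excluded)) layout$excluded <- FALSE
  if (sum(layout$is_wt & !layout$excluded) < 2L)
    stop("layout must contain at least 2 non-excluded wild-type wells")
  if (!all(layout$genotype %in% names(growth)))
    stop("growth must name every genotype in the layout")

  with_seed(seed, {
    base <- unname(growth[layout$genotype])
    intensity <- base + stats::rnorm(nrow(layout), sd = noise_sd)
    intensity <- pmin(pmax(intensity, 0), 255)
    intensity[layout$excluded] <- NA_real_
    wells <- cbind(layout, intensity = intensity)

    out <- list(wells = wells)
    if (render) {
      nr <- max(layout$row); nc <- max(layout$col)
      h <- nr * well_px; w <- nc * well_px
      gray <- matrix(0, h, w)
      ic <- matrix(rep(seq_len(w), each = h), h, w)
      ir <- matrix(rep(seq_len(h), times = w), h, w)
      geom <- list(x0 = (well_px + 1) / 2, y0 = (well_px + 1) / 2,
                   dx = well_px, dy = well_px, radius = radius_px)
      for (i in seq_len(nrow(wells))) {
        if (is.na(wells$intensity[i])) next
        cx <- geom$x0 + (wells$col[i] - 1) * geom$dx
        cy <- geom$y0 + (wells$row[i] - 1) * geom$dy
        disk <- (ic - cx)^2 + (ir - cy)^2 <= geom$radius^2
        gray[disk] <- wells$intensity[i]
      }
      gray <- round(gray)
      out$image <- array(rep(gray, 3L), dim = c(h, w, 3L))
      out$geometry <- geom
    }
    out
  })
}
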