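#' Convert an RGB image array to grayscale luminance
#'
#' Standard Rec. 601 weighting (0.299 R + 0.587 G + 0.114 B), the default
#' of common image-analysis software; custom weights may be supplied.
#'
#' @param image Numeric array `h x w x 3` (or an `h x w` matrix, returned
#'   unchanged).
#' @param weights Length-3 channel weights, normalized to sum to 1.
#' @return `h x w` numeric matrix.
#' @export
rgb_to_gray <- function(image, weights = c(0.299, 0.587, 0.114)) {
  if (is.matrix(image)) return(image)
  if (length(dim(image)) != 3L || dim(image)[3L] != 3L)
    stop("image must be an h x w x 3 array or a matrix")
  w <- weights / sum(weights)
  image[, , 1L] * w[1L] + image[, , 2L] * w[2L] + image[, , 3L] * w[3L]
}

#' Measure mean well intensities on a scanned plate image
#'
#' Converts the 8-bit RGB scan to grayscale and averages pixel intensity
#' over the full circular sampling area of each well. Wells marked
#' `excluded` in the layout (bubbles, irregular clamping) are not
#' quantified and are absent from the output.
#'
#' @param image RGB array or grayscale matrix (0-255 scale).
#' @param layout Data frame `row`, `col`, `genotype`, `is_wt`, optional
#'   `excluded`.
#' @param geometry List `x0`, `y0` (centre of well at row 1, col 1, in
#'   pixels: x = image column, y = image row), `dx`, `dy` (well pitch)
#'   and `radius` (sampling radius, pixels).
#' @param weights Grayscale conversion weights, see [rgb_to_gray()].
#' @return Data frame `row`, `col`, `genotype`, `is_wt`, `intensity`
#'   (mean gray value over the well disk).
#' @export
quantify_wells <- function(image, layout, geometry,
                           weights = c(0.299, 0.587, 0.114)) {
  gray <- rgb_to_gray(image, weights)
  h <- nrow(gray); w <- ncol(gray)
  if (is.null(layout$excluded)) layout$excluded <- FALSE
  keep <- !layout$excluded
  lay <- layout[keep, , drop = FALSE]
  ic <- matrix(rep(seq_len(w), each = h), h, w)
  ir <- matrix(rep(seq_len(h), times = w), h, w)
  intensity <- numeric(nrow(lay))
  for (i in seq_len(nrow(lay))) {
    cx <- geometry$x0 + (lay$col[i] - 1) * geometry$dx
    cy <- geometry$y0 + (lay$row[i] - 1) * geometry$dy
    if (cx - geometry$radius < 0.5 || cx + geometry$radius > w + 0.5 ||
        cy - geometry$radius < 0.5 || cy + geometry$radius > h + 0.5)
      stop("well sampling area falls outside the image")
    disk <- (ic - cx)^2 + (ir - cy)^2 <= geometry$radius^2
    intensity[i] <- mean(gray[disk])
  }
  data.frame(row = lay$row, col = lay$col, genotype = lay$genotype,
             is_wt = lay$is_wt, intensity = intensity,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Z-score mutant growth against same-plate wild-type wells
#'
#' For each genotype, \eqn{Z = (\bar{x}_{genotype} -
#' \bar{x}_{wt}) / s_{wt}} with the sample sd (n-1) of the wild-type
#' wells on the same plate. Replicate wells of a genotype are averaged
#' before scoring (set `per_well = TRUE` to score wells individually).
#' Z is invariant to any affine gain/offset applied to the whole plate.
#'
#' @param wells Data frame with `genotype`, `is_wt`, `intensity`
#'   (e.g. from [quantify_wells()]; NA intensities are dropped).
#' @param per_well Score each well separately instead of averaging
#'   replicate wells.
#' @return Data frame `genotype`, `n_wells`, `z`; attribute `"wt"` holds
#'   the wild-type mean and sd. A wild-type sd of zero sets the
#'   `"sd_zero"` error-flag attribute (with a warning); Z is then 0 where
#'   the mean difference is exactly 0 (an entirely flat plate) and `NaN`
#'   otherwise.
#' @export
growth_z_scores <- function(wells, per_well = FALSE) {
  wells <- wells[!is.na(wells$intensity), , drop = FALSE]
  wt <- wells$intensity[wells$is_wt]
  if (length(wt) < 2L) stop("need >= 2 wild-type wells with intensities")
  mu <- mean(wt); sdev <- stats::sd(wt)
  zscore <- function(x) {
    d <- x - mu
    if (sdev == 0) ifelse(d == 0, 0, NaN) else d / sdev
  }
  if (sdev == 0)
    warning("wild-type well sd is zero on this plate; Z flagged unreliable")
  if (per_well) {
    out <- data.frame(genotype = wells$genotype, n_wells = 1L,
                      z = zscore(wells$intensity),
                      stringsAsFactors = FALSE, row.names = NULL)
  } else {
    m <- tapply(wells$intensity, wells$genotype, mean)
    n <- tapply(wells$intensity, wells$genotype, length)
    out <- data.frame(genotype = names(m), n_wells = as.integer(n),
                      z = as.numeric(zscore(m)),
                      stringsAsFactors = FALSE, row.names = NULL)
  }
  attr(out, "wt") <- c(mean = mu, sd = sdev)
  attr(out, "sd_zero") <- sdev == 0
  out
}
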