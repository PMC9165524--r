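.img_values <- function(x) if (inherits(x, "image_grid")) x$values else as.matrix(x)

#' Root-mean-square error between two images
#'
#' @param image,reference Image grids or matrices of identical shape.
#' @param mask Optional logical matrix restricting the comparison (e.g.
#'   [circle_mask()]).
#' @return RMSE as a single number.
#' @export
rmse <- function(image, reference, mask = NULL) {
  a <- .img_values(image); b <- .img_values(reference)
  if (!all(dim(a) == dim(b))) stop("image and reference shapes differ")
  d <- (a - b)^2
  if (!is.null(mask)) d <- d[mask]
  sqrt(mean(d))
}

#' Peak signal-to-noise ratio
#'
#' `psnr = 20 * log10(range(reference) / rmse)`; `Inf` when the images are
#' identical.
#'
#' @inheritParams rmse
#' @return PSNR in dB.
#' @export
psnr <- function(image, reference, mask = NULL) {
  r <- rmse(image, reference, mask)
  if (r == 0) return(Inf)
  b <- .img_values(reference)
  if (!is.null(mask)) b <- b[mask]
  20 * log10((max(b) - min(b)) / r)
}

#' Diagnostic contingency table
#'
#' @param tp,fp,fn,tn Nonnegative integer counts.
#' @return An object of class `"contingency_table"`.
#' @export
contingency_table <- function(tp = 0, fp = 0, fn = 0, tn = 0) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  structure(as.list(counts), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("contingency_table: TP %d  FP %d  FN %d  TN %d\n",
              x$tp, x$fp, x$fn, x$tn))
  s <- contingency_stats(x)
  cat(sprintf("  sensitivity %.1f%%  specificity %.1f%%  accuracy %.1f%%\n",
              s["sensitivity"], s["specificity"], s["accuracy"]))
  invisible(x)
}

#' Sensitivity, specificity and accuracy from a contingency table
#'
#' `sensitivity = TP/(TP+FN)`, `specificity = TN/(TN+FP)`,
#' `accuracy = (TP+TN)/total`, each returned as a percentage. A rate whose
#' denominator is zero is reported as `NA` (undefined), never as 0.
#'
#' @param table A [contingency_table()].
#' @return Named numeric vector (percentages).
#' @export
contingency_stats <- function(table) {
  tp <- table$tp; fp <- table$fp; fn <- table$fn; tn <- table$tn
  total <- tp + fp + fn + tn
  if (total == 0) stop("empty contingency table")
  rate <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  c(sensitivity = rate(tp, tp + fn),
    specificity = rate(tn, tn + fp),
    accuracy = rate(tp + tn, total))
}

#' Grade a percent-diameter stenosis
#'
#' Clinical convention: mild below the moderate cut-off, severe at or above
#' the severe cut-off (defaults 50% and 70%, both inclusive on the upper
#' grade).
#'
#' @param stenosis_pct Percent diameter stenosis in \[0, 100\] (vectorized).
#' @param thresholds Named numeric: `moderate` and `severe` cut-offs.
#' @return Factor with levels `mild`, `moderate`, `severe`.
#' @export
grade_stenosis <- function(stenosis_pct, thresholds = c(moderate = 50, severe = 70)) {
  if (any(!is.finite(stenosis_pct)) || any(stenosis_pct < 0 | stenosis_pct > 100))
    stop("stenosis_pct must lie in [0, 100]")
  g <- ifelse(stenosis_pct >= thresholds[["severe"]], "severe",
       ifelse(stenosis_pct >= thresholds[["moderate"]], "moderate", "mild"))
  factor(g, levels = c("mild", "moderate", "severe"))
}

#' Configuration for automated vessel measurement
#'
#' @param x_range Profiles are taken at every pixel column with
#'   `|x| <= x_range` (the vessel axis is the x axis of the phantom).
#' @param threshold_frac Lumen segmentation threshold as a fraction of the
#'   background-to-lumen intensity step (0.5 = half maximum).
#' @param bg_quantile,lumen_quantile Image quantiles used to estimate the
#'   background and lumen intensity levels.
#' @param roi_halfwidth Half-width in x of the plaque search region.
#' @param roi_offset Gap between the measured lumen surface and the start of
#'   the plaque search region, skipping the partial-volume / blur band at
#'   the lumen edge.
#' @param roi_depth Radial depth of the plaque search region beyond that
#'   offset.
#' @param calcified_frac Intensity (as a fraction of the background-to-lumen
#'   step above background) that the ROI maximum must exceed to call a
#'   calcified plaque.
#' @param noncalc_window Intensity window (fractions of the step above
#'   background) for noncalcified plaque tissue.
#' @param noncalc_min_frac Minimum fraction of ROI pixels inside the window
#'   to call a noncalcified plaque.
#' @return A list of class `"stenosis_config"`.
#' @export
stenosis_config <- function(x_range = 0.5, threshold_frac = 0.5,
                            bg_quantile = 0.5, lumen_quantile = 0.98,
                            roi_halfwidth = 0.13, roi_offset = 0.03,
                            roi_depth = 0.12,
                            calcified_frac = 1.5,
                            noncalc_window = c(0.2, 0.75),
                            noncalc_min_frac = 0.3) {
  structure(list(x_range = x_range, threshold_frac = threshold_frac,
                 bg_quantile = bg_quantile, lumen_quantile = lumen_quantile,
                 roi_halfwidth = roi_halfwidth, roi_offset = roi_offset,
                 roi_depth = roi_depth,
                 calcified_frac = calcified_frac,
                 noncalc_window = noncalc_window,
                 noncalc_min_frac = noncalc_min_frac),
            class = "stenosis_config")
}

# lumen width along one profile: the above-threshold run containing the
# vessel axis (coordinate `center`), with linear sub-pixel edge
# interpolation. Taking only the axis run keeps bright wall plaque, which is
# separated from the lumen by the vessel wall, out of the diameter.
.profile_width <- function(vals, coords, thr, center = 0) {
  above <- vals > thr
  if (!any(above)) return(0)
  n <- length(vals)
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  for (k in which(runs$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    lo <- coords[i0]; hi <- coords[i1]
    if (i0 > 1) {    # interpolate the rising crossing
      f <- (thr - vals[i0 - 1]) / (vals[i0] - vals[i0 - 1])
      lo <- coords[i0 - 1] + f * (coords[i0] - coords[i0 - 1])
    }
    if (i1 < n) {    # falling crossing
      f <- (thr - vals[i1]) / (vals[i1 + 1] - vals[i1])
      hi <- coords[i1] + f * (coords[i1 + 1] - coords[i1])
    }
    if (lo <= center && center <= hi) return(hi - lo)
  }
  0
}

#' Measure percent-diameter stenosis on a vessel image
#'
#' Segments the lumen by half-maximum thresholding along intensity profiles
#' perpendicular to the vessel axis (the x axis): the threshold sits at
#' `threshold_frac` of the background-to-lumen intensity step, both levels
#' estimated from image quantiles. Each profile's lumen width is the total
#' above-threshold length with sub-pixel edge interpolation. The reference
#' diameter is the median profile width over the measurement range, the
#' minimal diameter the smallest width, and
#' `stenosis_pct = 100 * (1 - minimal / reference)`.
#'
#' @param img An [image_grid()] containing a vessel cross-section.
#' @param config A [stenosis_config()].
#' @return An object of class `"stenosis_measurement"`: fields
#'   `reference_diameter`, `minimal_diameter`, `stenosis_pct`, `grade`, plus
#'   per-profile `widths`, profile positions `x`, estimated intensity levels
#'   and the index of the narrowest profile.
#' @export
measure_stenosis <- function(img, config = stenosis_config()) {
  stopifnot(inherits(img, "image_grid"))
  xs <- grid_coords(img)
  bg <- stats::quantile(img$values, config$bg_quantile, names = FALSE)
  lum <- stats::quantile(img$values, config$lumen_quantile, names = FALSE)
  thr <- bg + config$threshold_frac * (lum - bg)
  cols <- which(abs(xs) <= config$x_range)
  widths <- vapply(cols, function(i)
    .profile_width(img$values[i, ], xs, thr), numeric(1))
  if (all(widths == 0)) stop("vessel not found: no profile exceeds the segmentation threshold")
  reference <- stats::median(widths)
  minimal <- min(widths)
  if (reference <= 0) stop("vessel not found: zero reference diameter")
  pct <- max(0, min(100, 100 * (1 - minimal / reference)))
  structure(list(reference_diameter = reference, minimal_diameter = minimal,
                 stenosis_pct = pct, grade = grade_stenosis(pct),
                 widths = widths, x = xs[cols],
                 narrowest_x = xs[cols][which.min(widths)],
                 background_level = bg, lumen_level = lum, threshold = thr),
            class = "stenosis_measurement")
}

#' @export
print.stenosis_measurement <- function(x, ...) {
  cat(sprintf("stenosis_measurement: reference %.4g, minimal %.4g -> %.1f%% (%s)\n",
              x$reference_diameter, x$minimal_diameter, x$stenosis_pct,
              as.character(x$grade)))
  invisible(x)
}

#' Detect calcified and noncalcified plaque near the vessel narrowing
#'
#' Searches two rectangular regions of interest on the outer vessel wall at
#' the narrowing (above the lumen for calcified, below for noncalcified,
#' mirroring where the phantom generator places them). A calcified plaque is
#' called when the upper-ROI maximum exceeds the lumen level by
#' `calcified_frac` of the background-to-lumen step; a noncalcified plaque
#' when at least `noncalc_min_frac` of lower-ROI pixels fall in the
#' intermediate intensity window.
#'
#' @param img An [image_grid()].
#' @param measurement A [measure_stenosis()] result for the same image
#'   (supplies the lumen surface position and intensity levels).
#' @param config A [stenosis_config()].
#' @return Named logical vector `c(calcified = , noncalcified = )`.
#' @export
detect_plaque <- function(img, measurement, config = stenosis_config()) {
  xs <- grid_coords(img)
  bg <- measurement$background_level
  step <- measurement$lumen_level - bg
  half <- measurement$reference_diameter / 2
  x0 <- measurement$narrowest_x
  in_x <- abs(xs - x0) <= config$roi_halfwidth
  y0 <- half + config$roi_offset
  roi_y_top <- xs > y0 & xs <= y0 + config$roi_depth
  roi_y_bot <- xs < -y0 & xs >= -y0 - config$roi_depth
  top <- img$values[in_x, roi_y_top]
  bot <- img$values[in_x, roi_y_bot]
  calc <- length(top) > 0 && max(top) > bg + config$calcified_frac * step
  win <- bg + config$noncalc_window * step
  noncalc <- length(bot) > 0 &&
    mean(bot > win[1] & bot < win[2]) > config$noncalc_min_frac
  c(calcified = calc, noncalcified = noncalc)
}
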