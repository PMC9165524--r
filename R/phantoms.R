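#' Define an ellipse for an analytic phantom
#'
#' Phantoms are additive collections of ellipses: the value of the phantom at
#' a point is the sum of the intensities `rho` of every ellipse containing it.
#' Coordinates are physical, with the image half-width equal to 1, so a
#' phantom lives in the square \[-1, 1\] x \[-1, 1\].
#'
#' @param cx,cy Center of the ellipse.
#' @param a,b Semi-axes along the ellipse's own x and y directions (both > 0).
#' @param phi Rotation angle in radians (counter-clockwise).
#' @param rho Additive intensity (dimensionless attenuation). May be negative;
#'   negative ellipses carve intensity out of whatever they overlap.
#' @return An object of class `"ellipse"` (a named list).
#' @export
ellipse <- function(cx, cy, a, b, phi = 0, rho = 1) {
  stopifnot(is.numeric(a), is.numeric(b), a > 0, b > 0)
  structure(list(cx = cx, cy = cy, a = a, b = b, phi = phi, rho = rho),
            class = "ellipse")
}

#' Build a phantom from a list of ellipses
#'
#' @param ellipses List of [ellipse()] objects.
#' @param name Label for printing and file sidecars.
#' @return An object of class `"phantom"`.
#' @export
phantom <- function(ellipses, name = "phantom") {
  stopifnot(all(vapply(ellipses, inherits, logical(1), "ellipse")))
  structure(list(ellipses = ellipses, name = name), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("phantom \"%s\": %d ellipse(s)\n", x$name, length(x$ellipses)))
  df <- as.data.frame(x)
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
as.data.frame.phantom <- function(x, ...) {
  do.call(rbind, lapply(x$ellipses, function(e)
    data.frame(cx = e$cx, cy = e$cy, a = e$a, b = e$b,
               phi_rot_deg = e$phi * 180 / pi, rho = e$rho)))
}

#' Evaluate a phantom analytically at points
#'
#' @param phan A [phantom()].
#' @param x,y Numeric vectors of equal length (recycled): evaluation points.
#' @return Numeric vector of phantom values (sum of `rho` over ellipses
#'   containing each point).
#' @export
phantom_value <- function(phan, x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  val <- numeric(n)
  for (e in phan$ellipses) {
    dx <- x - e$cx; dy <- y - e$cy
    cphi <- cos(e$phi); sphi <- sin(e$phi)
    u <- dx * cphi + dy * sphi
    v <- -dx * sphi + dy * cphi
    inside <- (u / e$a)^2 + (v / e$b)^2 <= 1
    val[inside] <- val[inside] + e$rho
  }
  val
}

# Canonical Shepp-Logan parameter table (a, b, cx, cy, phi in degrees, rho).
# Original low-contrast intensities; `modified` swaps in the high-contrast
# variant commonly used for display.
.shepp_logan_table <- function(modified = FALSE) {
  m <- matrix(c(
    0.69,   0.92,    0,       0,      0,   2,
    0.6624, 0.874,   0,      -0.0184, 0,  -0.98,
    0.11,   0.31,    0.22,    0,    -18,  -0.02,
    0.16,   0.41,   -0.22,    0,     18,  -0.02,
    0.21,   0.25,    0,       0.35,   0,   0.01,
    0.046,  0.046,   0,       0.1,    0,   0.01,
    0.046,  0.046,   0,      -0.1,    0,   0.01,
    0.046,  0.023,  -0.08,   -0.605,  0,   0.01,
    0.023,  0.023,   0,      -0.606,  0,   0.01,
    0.023,  0.046,   0.06,   -0.605,  0,   0.01), ncol = 6, byrow = TRUE)
  if (modified)
    m[, 6] <- c(1, -0.8, -0.2, -0.2, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1)
  m
}

#' The Shepp-Logan head phantom
#'
#' The standard 10-ellipse test object for tomographic reconstruction: a large
#' "skull" ellipse of intensity 2 containing a slightly smaller "brain"
#' ellipse of intensity -0.98, two tilted low-intensity "ventricles" and six
#' small high-intensity features.
#'
#' @param modified If `TRUE`, use the high-contrast intensity variant
#'   (features at 0.1 instead of 0.01) which is easier to look at; geometry is
#'   identical.
#' @return A [phantom()].
#' @export
shepp_logan_phantom <- function(modified = FALSE) {
  m <- .shepp_logan_table(modified)
  ells <- lapply(seq_len(nrow(m)), function(i)
    ellipse(cx = m[i, 3], cy = m[i, 4], a = m[i, 1], b = m[i, 2],
            phi = m[i, 5] * pi / 180, rho = m[i, 6]))
  phantom(ells, name = if (modified) "shepp-logan (modified)" else "shepp-logan")
}

#' Synthetic coronary-vessel cross-section phantom
#'
#' Models a longitudinal section of a contrast-filled vessel as a bright
#' elongated lumen along the x axis, narrowed at its midpoint by a pair of
#' symmetric wall indentations so that the lumen diameter at the stenotic
#' site equals `reference_diameter * (1 - stenosis_pct/100)`. Optional plaque
#' ellipses sit on the outer wall at the narrowing: a calcified plaque is
#' hyperintense (brighter than the lumen, placed above the vessel) and a
#' noncalcified plaque is hypointense (between background and lumen, placed
#' below). The whole object is built from at most six ellipses so that its
#' Radon transform stays available in closed form.
#'
#' @param reference_diameter Healthy lumen diameter, in physical units
#'   (image half-width = 1); must be < 1.
#' @param stenosis_pct Percent diameter stenosis in \[0, 100).
#' @param plaque Character vector drawn from `"calcified"`, `"noncalcified"`
#'   (either, both, or `character(0)`/`"none"` for no plaque).
#' @param background Intensity of the large circular background region.
#' @param lumen_intensity Additive intensity of the lumen over background.
#' @param lumen_half_length Half-length of the lumen ellipse along x. The
#'   default (10) extends far beyond the image so the vessel walls are
#'   parallel to within 0.15% over the measurement range, like a real vessel
#'   segment crossing the field of view.
#' @param stenosis_half_length Half-extent of the narrowing along x.
#' @return A list with components `phantom` (a [phantom()]) and `truth`
#'   (a `"vessel_truth"` list: `lumen_reference_diameter`,
#'   `lumen_minimal_diameter`, `stenosis_pct`, `plaque_calcified`,
#'   `plaque_noncalcified`, `plaque_intensity`, plus the construction
#'   geometry needed by downstream measurement tests).
#' @export
vessel_phantom <- function(reference_diameter = 0.4, stenosis_pct = 0,
                           plaque = "none", background = 0.1,
                           lumen_intensity = 1, lumen_half_length = 10,
                           stenosis_half_length = 0.15) {
  if (!is.numeric(stenosis_pct) || stenosis_pct < 0 || stenosis_pct >= 100)
    stop("stenosis_pct must lie in [0, 100)")
  if (reference_diameter <= 0 || reference_diameter >= 1)
    stop("reference_diameter must lie in (0, 1)")
  plaque <- setdiff(plaque, "none")
  if (!all(plaque %in% c("calcified", "noncalcified")))
    stop("plaque must be 'none', 'calcified' and/or 'noncalcified'")

  b <- reference_diameter / 2
  minimal <- reference_diameter * (1 - stenosis_pct / 100)
  ells <- list(ellipse(0, 0, 0.95, 0.95, rho = background),
               ellipse(0, 0, lumen_half_length, b, rho = lumen_intensity))
  if (stenosis_pct > 0) {
    # symmetric indentations spanning [minimal/2, b] in |y| at x = 0
    depth <- (b - minimal / 2) / 2
    yc <- (b + minimal / 2) / 2
    ells <- c(ells, list(
      ellipse(0,  yc, stenosis_half_length, depth, rho = -lumen_intensity),
      ellipse(0, -yc, stenosis_half_length, depth, rho = -lumen_intensity)))
  }
  plaque_int <- c(calcified = 2 * lumen_intensity,
                  noncalcified = 0.4 * lumen_intensity)
  pa <- 0.12; pb <- 0.05                  # plaque semi-axes
  py <- b + pb + 0.03                     # on the wall, clear of the lumen
  if (py + pb > 0.95)
    stop("plaque ellipse would exceed the background region; reduce reference_diameter")
  if ("calcified" %in% plaque)
    ells <- c(ells, list(ellipse(0,  py, pa, pb, rho = plaque_int[["calcified"]])))
  if ("noncalcified" %in% plaque)
    ells <- c(ells, list(ellipse(0, -py, pa, pb, rho = plaque_int[["noncalcified"]])))

  truth <- structure(list(
    lumen_reference_diameter = reference_diameter,
    lumen_minimal_diameter = minimal,
    stenosis_pct = 100 * (1 - minimal / reference_diameter),
    plaque_calcified = "calcified" %in% plaque,
    plaque_noncalcified = "noncalcified" %in% plaque,
    plaque_intensity = plaque_int,
    background = background, lumen_intensity = lumen_intensity,
    lumen_half_length = lumen_half_length,
    stenosis_half_length = stenosis_half_length,
    plaque_center_y = py, plaque_semi_axes = c(pa, pb)), class = "vessel_truth")
  list(phantom = phantom(ells, name = sprintf("vessel (%.0f%% stenosis)",
                                              stenosis_pct)),
       truth = truth)
}

#' Create an image grid
#'
#' An `image_grid` is an N x N raster over \[-1, 1\]^2 with the centered pixel
#' convention: pixel (i, j) (0-based) has center
#' `x_i = (i - (N-1)/2) * spacing`, `y_j = (j - (N-1)/2) * spacing`, with
#' `spacing = 2/N`. Values are stored as a matrix whose first index runs
#' along x and second along y.
#'
#' @param values N x N numeric matrix, or a single N to create a zero grid.
#' @return An object of class `"image_grid"`.
#' @export
image_grid <- function(values) {
  if (!is.matrix(values) && length(values) == 1)
    values <- matrix(0, values, values)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("image_grid must be square")
  structure(list(values = values, N = nrow(values), spacing = 2 / nrow(values)),
            class = "image_grid")
}

#' Pixel-center coordinates of an image grid
#'
#' @param img An [image_grid()] or a grid size N.
#' @return Numeric vector of N centered coordinates (shared by x and y).
#' @export
grid_coords <- function(img) {
  N <- if (inherits(img, "image_grid")) img$N else img
  ((0:(N - 1)) - (N - 1) / 2) * (2 / N)
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("image_grid: %d x %d, spacing %.4g, range [%.4g, %.4g]\n",
              x$N, x$N, x$spacing, min(x$values), max(x$values)))
  invisible(x)
}

#' Rasterize a phantom onto an image grid
#'
#' By default each pixel takes the analytic phantom value at its center
#' (point sampling), which makes rasterization exactly additive across
#' phantoms and bit-reproducible. `supersample = s` instead averages an
#' s x s grid of subsamples per pixel for smoother reference images.
#'
#' @param phan A [phantom()].
#' @param N Grid size (>= 2).
#' @param supersample Integer >= 1; subsamples per pixel side.
#' @return An [image_grid()].
#' @export
rasterize <- function(phan, N, supersample = 1) {
  stopifnot(N >= 2, supersample >= 1)
  xs <- grid_coords(N)
  if (supersample == 1) {
    pts <- expand.grid(x = xs, y = xs)
    vals <- phantom_value(phan, pts$x, pts$y)
    return(image_grid(matrix(vals, N, N)))
  }
  s <- as.integer(supersample)
  spacing <- 2 / N
  offs <- ((seq_len(s) - 0.5) / s - 0.5) * spacing
  acc <- matrix(0, N, N)
  for (ox in offs) for (oy in offs) {
    pts <- expand.grid(x = xs + ox, y = xs + oy)
    acc <- acc + matrix(phantom_value(phan, pts$x, pts$y), N, N)
  }
  image_grid(acc / s^2)
}
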