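#' Parallel-beam acquisition geometry
#'
#' Describes a first-generation (translate/rotate) parallel-beam scan:
#' `M` view angles `theta_m = m * Delta` for m = 0..M-1 covering the
#' half-turn \[0, pi), and `K` detector bins at offsets
#' `t_n = (n - (K-1)/2) * d` so the detector is centered on the rotation
#' axis. `d * K >= 2*sqrt(2)` is recommended so the detector spans the
#' diagonal of the \[-1,1\]^2 image; shorter detectors give truncated
#' sinograms (a warning, not an error).
#'
#' @param M Number of projection angles.
#' @param K Number of detector bins.
#' @param d Detector spacing (physical units).
#' @param Delta Angular increment in radians; defaults to `pi / M`.
#' @return An object of class `"proj_geometry"`.
#' @export
proj_geometry <- function(M = 180, K, d, Delta = pi / M) {
  stopifnot(M >= 1, K >= 2, d > 0, Delta > 0)
  if (M * Delta > pi + 1e-9)
    stop("M * Delta must not exceed pi (half-turn coverage)")
  if (d * K < 2 * sqrt(2))
    warning("detector span d*K < 2*sqrt(2): sinograms of objects reaching the image corners will be truncated")
  structure(list(M = M, K = K, d = d, Delta = Delta,
                 theta = (0:(M - 1)) * Delta,
                 t = ((0:(K - 1)) - (K - 1) / 2) * d),
            class = "proj_geometry")
}

#' Default geometry matched to an N x N image grid
#'
#' Chooses detector spacing `d = 2/N` (one pixel) and an odd number of bins
#' covering the grid diagonal, so `t = 0` falls exactly on a bin center.
#'
#' @param N Image grid size.
#' @param M Number of angles (default 180 over a half turn).
#' @return A [proj_geometry()].
#' @export
standard_geometry <- function(N, M = 180) {
  d <- 2 / N
  K <- 2L * ceiling(sqrt(2) * N / 2) + 1L
  proj_geometry(M = M, K = K, d = d)
}

#' @export
print.proj_geometry <- function(x, ...) {
  cat(sprintf("proj_geometry: M = %d angles (Delta = %.5g rad), K = %d bins (d = %.5g, span %.4g)\n",
              x$M, x$Delta, x$K, x$d, x$d * x$K))
  invisible(x)
}

#' Construct a sinogram object
#'
#' @param values M x K matrix; row m is the projection at angle `theta_m`,
#'   column n the ray at detector offset `t_n`.
#' @param geometry A [proj_geometry()].
#' @return An object of class `"sinogram"`.
#' @export
sinogram <- function(values, geometry) {
  values <- as.matrix(values)
  stopifnot(inherits(geometry, "proj_geometry"),
            nrow(values) == geometry$M, ncol(values) == geometry$K)
  structure(list(values = values, geometry = geometry), class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("sinogram: %d angles x %d bins, range [%.4g, %.4g]\n",
              g$M, g$K, min(x$values), max(x$values)))
  invisible(x)
}

#' Ray coordinate of a point at a view angle
#'
#' The ray through the point `(x, y)` perpendicular to the detector at angle
#' `theta` has detector offset `t = x*cos(theta) + y*sin(theta)`.
#'
#' @param x,y Point coordinates (vectorized).
#' @param theta View angle in radians.
#' @return Numeric vector of detector offsets.
#' @export
ray_coordinate <- function(x, y, theta) {
  x * cos(theta) + y * sin(theta)
}

# Exact Radon transform of one ellipse at offsets t (vector) and angle theta:
# the chord length through the ellipse times rho.
.ellipse_projection <- function(e, t, theta) {
  th <- theta - e$phi
  s <- (e$a * cos(th))^2 + (e$b * sin(th))^2
  tc <- t - (e$cx * cos(theta) + e$cy * sin(theta))
  inside <- tc^2 < s
  out <- numeric(length(t))
  out[inside] <- 2 * e$rho * e$a * e$b * sqrt(s - tc[inside]^2) / s
  out
}

#' Analytic (closed-form) Radon transform of an ellipse phantom
#'
#' Each sinogram entry is the exact line integral of the phantom along the
#' ray `x*cos(theta_m) + y*sin(theta_m) = t_n`, using the closed-form chord
#' length through each ellipse; ellipse contributions add.
#'
#' @param phan A [phantom()].
#' @param geometry A [proj_geometry()].
#' @return A [sinogram()].
#' @export
radon_analytic <- function(phan, geometry) {
  p <- matrix(0, geometry$M, geometry$K)
  for (m in seq_len(geometry$M)) {
    th <- geometry$theta[m]
    for (e in phan$ellipses)
      p[m, ] <- p[m, ] + .ellipse_projection(e, geometry$t, th)
  }
  sinogram(p, geometry)
}

# Interpolation bookkeeping shared by the discrete projector and the
# back-projector: detector-index coordinate u = t/d + (K-1)/2 split into
# lower bin n0 (0-based) and fractional offset delta in [0, 1).
.ray_split <- function(t, d, K) {
  u <- t / d + (K - 1) / 2
  n0 <- floor(u)
  delta <- u - n0
  out <- u < 0 | u > K - 1
  # u == K-1 exactly: keep the upper neighbour index in range, weight 0
  hi <- !out & n0 >= K - 1
  n0[hi] <- K - 2
  delta[hi] <- 1
  n0[out] <- 0      # safe placeholder; out rays are zeroed by callers
  delta[out] <- 0
  list(n0 = as.integer(n0), delta = delta, out = out)
}

#' Decompose a ray offset into detector bin and fractional offset
#'
#' Splits `t` into an integer lower bin index `n0` (0-based) and a fractional
#' offset `delta` in \[0, 1) such that `t = (n0 + delta - (K-1)/2) * d`.
#' Rays falling outside the detector (`t` beyond the first or last bin) are
#' flagged `out_of_range` rather than rejected.
#'
#' @param t Ray offset(s), physical units.
#' @param d Detector spacing (> 0).
#' @param K Number of detector bins.
#' @return A list with integer `n0`, numeric `delta`, logical `out_of_range`.
#' @export
split_ray <- function(t, d, K) {
  stopifnot(d > 0)
  u <- t / d + (K - 1) / 2
  n0 <- floor(u)
  list(n0 = as.integer(n0), delta = u - n0, out_of_range = u < 0 | u > K - 1)
}

#' Linearly interpolate a projection row at a split ray position
#'
#' Returns `(1 - delta) * row[n0] + delta * row[n0 + 1]` (0-based indices);
#' out-of-range rays contribute 0.
#'
#' @param row Numeric vector: one angle's K projection values.
#' @param state Result of [split_ray()].
#' @return Numeric vector of interpolated projection values.
#' @export
interp_projection <- function(row, state) {
  K <- length(row)
  n0 <- state$n0
  delta <- state$delta
  out <- state$out_of_range
  hi <- !out & n0 >= K - 1          # t exactly on the last bin
  n0[hi] <- K - 2L; delta[hi] <- 1
  n0[out] <- 0L; delta[out] <- 0    # placeholder indices, zeroed below
  val <- (1 - delta) * row[n0 + 1L] + delta * row[n0 + 2L]
  val[out] <- 0
  val
}

#' Discrete (pixel-driven) forward projection
#'
#' Spreads each pixel's value onto the two detector bins bracketing its ray
#' coordinate with linear-interpolation weights — exactly the transpose of
#' the footprint used by [back_project()], so the pair forms an adjoint
#' operator pair (up to the back-projector's 1/M average). This matched pair
#' is what the iterative reconstructor relies on.
#'
#' @param img An [image_grid()].
#' @param geometry A [proj_geometry()].
#' @return A [sinogram()].
#' @export
radon_discrete <- function(img, geometry) {
  xs <- grid_coords(img)
  X <- rep(xs, times = img$N)           # first index runs along x
  Y <- rep(xs, each = img$N)
  f <- as.vector(img$values)
  p <- matrix(0, geometry$M, geometry$K)
  K <- geometry$K
  for (m in seq_len(geometry$M)) {
    th <- geometry$theta[m]
    sp <- .ray_split(X * cos(th) + Y * sin(th), geometry$d, K)
    keep <- !sp$out
    n0 <- sp$n0[keep]; de <- sp$delta[keep]; fv <- f[keep]
    idx <- c(n0 + 1L, n0 + 2L)
    w <- c(fv * (1 - de), fv * de)
    acc <- rowsum(w, idx)
    row <- numeric(K)
    row[as.integer(rownames(acc))] <- acc
    p[m, ] <- row
  }
  sinogram(p, geometry)
}

#' Add seeded Gaussian noise to a sinogram
#'
#' Adds i.i.d. zero-mean Gaussian noise of standard deviation `sigma` to
#' every entry. The caller's RNG state is left untouched; the same
#' `(sinogram, sigma, seed)` always produces the same output.
#'
#' @param sino A [sinogram()].
#' @param sigma Noise standard deviation (>= 0), in line-integral units.
#' @param seed Integer seed.
#' @return A [sinogram()] with noisy values.
#' @export
add_noise <- function(sino, sigma, seed = 1L) {
  if (!is.numeric(sigma) || sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(sino)
  rs <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv()))
  set.seed(as.integer(seed))
  noisy <- sino$values + matrix(stats::rnorm(length(sino$values), sd = sigma),
                                nrow(sino$values), ncol(sino$values))
  sinogram(noisy, sino$geometry)
}
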