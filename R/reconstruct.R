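#' Back-project a sinogram onto an image grid
#'
#' Implements plain (unfiltered) back-projection with linear interpolation:
#' each pixel's value is the average over view angles of the projection value
#' of the ray passing through the pixel,
#' `f(i, j) = (1/M) * sum_m p~(x_i cos(theta_m) + y_j sin(theta_m), theta_m)`,
#' where `p~` interpolates linearly between the two detector bins bracketing
#' the ray. Rays falling off the detector contribute 0. No reconstruction-
#' circle masking is applied here so the accumulation can be compared
#' literally against its defining sum.
#'
#' @param sino A [sinogram()].
#' @param N Output grid size; defaults to a grid whose pixel matches the
#'   detector spacing (`N = round(2/d)`).
#' @return An [image_grid()].
#' @export
back_project <- function(sino, N = NULL) {
  g <- sino$geometry
  if (is.null(N)) N <- max(2L, round(2 / g$d))
  xs <- grid_coords(N)
  X <- rep(xs, times = N)
  Y <- rep(xs, each = N)
  acc <- numeric(N * N)
  for (m in seq_len(g$M)) {
    th <- g$theta[m]
    sp <- .ray_split(X * cos(th) + Y * sin(th), g$d, g$K)
    row <- sino$values[m, ]
    val <- (1 - sp$delta) * row[sp$n0 + 1L] + sp$delta * row[sp$n0 + 2L]
    val[sp$out] <- 0
    acc <- acc + val
  }
  image_grid(matrix(acc / g$M, N, N))
}

# zero pixels outside the inscribed unit circle (detector coverage there is
# incomplete for half-turn scans)
.apply_circle <- function(img) {
  xs <- grid_coords(img)
  mask <- outer(xs^2, xs^2, "+") > 1
  img$values[mask] <- 0
  img
}

#' Reconstruction-circle mask for an image grid
#'
#' @param N Grid size.
#' @param radius Radius of the retained disc (default 1, the inscribed circle).
#' @return Logical N x N matrix, `TRUE` inside the circle.
#' @export
circle_mask <- function(N, radius = 1) {
  xs <- grid_coords(N)
  outer(xs^2, xs^2, "+") <= radius^2
}

#' Filtered back-projection reconstruction
#'
#' The core reconstructor: convolve each angle's projection with a ramp-type
#' filter ([build_filter()], [filter_sinogram()]) and back-project the
#' filtered sinogram. The angular average in [back_project()] is rescaled by
#' `pi` so the total angle weight is `pi/M`, the Riemann weight of the
#' continuous inversion integral over \[0, pi); together with the filter's
#' detector-spacing weight this makes the reconstruction amplitude-correct.
#'
#' @param sino A [sinogram()].
#' @param filter Filter kind: `"ram-lak"` (sharpest), `"shepp-logan"`
#'   (noise-suppressing) or `"none"` (plain back-projection, blurry).
#' @param N Output grid size (defaults as in [back_project()]).
#' @param circle If `TRUE` (default) zero pixels outside the inscribed unit
#'   circle, where half-turn detector coverage is incomplete.
#' @return An [image_grid()].
#' @export
fbp_reconstruct <- function(sino, filter = "ram-lak", N = NULL, circle = TRUE) {
  g <- sino$geometry
  kernel <- build_filter(filter, K = g$K, d = g$d)
  filtered <- filter_sinogram(sino, kernel)
  img <- back_project(filtered, N = N)
  if (filter != "none") img$values <- img$values * pi
  if (circle) img <- .apply_circle(img)
  img
}

#' Direct Fourier reconstruction (central slice theorem)
#'
#' Reconstructs by placing the 1D Fourier transform of each projection on the
#' corresponding radial line of the 2D frequency plane (the central slice
#' theorem), resampling those polar samples onto the Cartesian DFT grid of
#' the output image by bilinear interpolation in (angle, radius), and
#' applying an inverse 2D Fourier transform. Radial samples come from
#' zero-padded FFTs of the projections with the phase shift accounting for
#' the centered detector; frequencies beyond the detector Nyquist are set
#' to 0.
#'
#' @param sino A [sinogram()]; needs at least 2 angles.
#' @param N Output grid size (defaults as in [back_project()]).
#' @param circle If `TRUE` (default) apply the reconstruction-circle mask.
#' @param oversample Integer >= 1: resample onto the DFT grid of an
#'   `oversample * N` image and crop the center after inversion. Finer
#'   Cartesian frequency spacing substantially reduces polar-interpolation
#'   error; 2 is a good default.
#' @return An [image_grid()].
#' @export
fourier_reconstruct <- function(sino, N = NULL, circle = TRUE, oversample = 2L) {
  g <- sino$geometry
  if (g$M < 2) stop("fourier_reconstruct needs at least 2 angles")
  if (is.null(N)) N <- max(2L, round(2 / g$d))
  stopifnot(oversample >= 1)
  L <- .next_pow2(4L * g$K)              # fine radial sampling
  t_shift <- (g$K - 1) / 2 * g$d
  nu_l <- (0:(L / 2)) / (L * g$d)        # nonnegative radial frequencies
  # P[m, l]: 1D FT of projection m at frequency nu_l (physical convention,
  # phase-shifted for the centered detector)
  P <- matrix(0 + 0i, g$M, L / 2 + 1)
  for (m in seq_len(g$M)) {
    row <- c(sino$values[m, ], numeric(L - g$K))
    F <- stats::fft(row)[1:(L / 2 + 1)]
    P[m, ] <- g$d * F * exp(2i * pi * nu_l * t_shift)
  }
  Np <- as.integer(oversample) * N
  dx <- 2 / N
  dnu <- 1 / (Np * dx)
  k <- 0:(Np - 1)
  ks <- ifelse(k <= Np / 2, k, k - Np)   # signed DFT index
  nux <- matrix(ks * dnu, Np, Np)
  nuy <- matrix(ks * dnu, Np, Np, byrow = TRUE)
  r <- sqrt(nux^2 + nuy^2)
  psi <- atan2(nuy, nux)
  neg <- psi < 0                          # fold onto [0, pi): opposite ray, -r
  psi[neg] <- psi[neg] + pi
  sgn <- ifelse(neg, -1, 1)
  # bilinear interpolation in (angle, radius)
  am <- psi / g$Delta
  a0 <- floor(am); fa <- am - a0
  ridx <- r * (L * g$d)                   # radial sample coordinate
  r0 <- floor(ridx); fr <- ridx - r0
  Fc <- matrix(0 + 0i, Np, Np)
  valid <- r <= 1 / (2 * g$d) & a0 <= g$M - 1 & r0 <= L / 2 - 1
  lookup <- function(ai, ri, sg) {
    # angle index ai may reach M (wrap past the last view): theta = pi is
    # the theta = 0 slice with reversed radius
    wrap <- ai >= g$M
    ai[wrap] <- 0L
    sg[wrap] <- -sg[wrap]
    v <- P[cbind(ai + 1L, ri + 1L)]
    conj_needed <- sg < 0
    v[conj_needed] <- Conj(v[conj_needed])
    v
  }
  ai0 <- as.integer(a0[valid]); ai1 <- ai0 + 1L
  ri0 <- as.integer(r0[valid]); ri1 <- ri0 + 1L
  sg <- sgn[valid]
  fav <- fa[valid]; frv <- fr[valid]
  Fc[valid] <-
    (1 - fav) * ((1 - frv) * lookup(ai0, ri0, sg) + frv * lookup(ai0, ri1, sg)) +
    fav       * ((1 - frv) * lookup(ai1, ri0, sg) + frv * lookup(ai1, ri1, sg))
  # inverse 2D DFT back to centered pixel coordinates, then center crop
  phase <- exp(-1i * pi * (Np - 1) / Np * outer(ks, ks, "+"))
  img_c <- stats::fft(Fc * phase, inverse = TRUE) * dnu^2
  off <- (Np - N) %/% 2
  img <- image_grid(Re(img_c)[(off + 1):(off + N), (off + 1):(off + N)])
  if (circle) img <- .apply_circle(img)
  img
}

#' SIRT iterative reconstruction
#'
#' Simultaneous iterative reconstruction technique: treats reconstruction as
#' the linear system `A f = p` with `A` the discrete forward projector
#' ([radon_discrete()]) and iterates
#' `f <- f + relax * C * A^T * R * (p - A f)`,
#' where `R` and `C` are the inverse row-sum and column-sum weights of `A`
#' and `A^T` is the matched adjoint (the back-projector without its 1/M
#' average). Starting from zero, the data residual `||A f - p||` is monotone
#' nonincreasing for `0 < relax <= 2` on consistent data.
#'
#' @param sino A [sinogram()].
#' @param n_iters Number of iterations (>= 0; 0 returns the zero image).
#' @param relax Relaxation factor in (0, 2\].
#' @param N Output grid size (defaults as in [back_project()]).
#' @param circle If `TRUE` (default) apply the reconstruction-circle mask to
#'   the final image.
#' @return An [image_grid()] with attribute `"residuals"`: the residual norm
#'   `||A f - p||` after each iteration.
#' @export
sirt_reconstruct <- function(sino, n_iters = 50, relax = 1, N = NULL,
                             circle = TRUE) {
  if (!is.numeric(relax) || relax <= 0 || relax > 2)
    stop("relax must lie in (0, 2]")
  stopifnot(n_iters >= 0)
  g <- sino$geometry
  if (is.null(N)) N <- max(2L, round(2 / g$d))
  # physical scale: the interpolation-weight projector approximates the line
  # integral times d/spacing^2, so scale it to line-integral units; the
  # row/column weights adapt and the iteration's fixed point A f = p then has
  # amplitude-correct f for sinograms in line-integral units
  scale <- (2 / N)^2 / g$d
  A <- function(fmat) radon_discrete(image_grid(fmat), g)$values * scale
  At <- function(pmat) back_project(sinogram(pmat, g), N = N)$values * g$M * scale
  rowsums <- A(matrix(1, N, N))                # per-ray weight sums
  colsums <- At(matrix(1, g$M, g$K))           # per-pixel weight sums
  Rw <- ifelse(rowsums > 0, 1 / rowsums, 0)
  Cw <- ifelse(colsums > 0, 1 / colsums, 0)
  f <- matrix(0, N, N)
  p <- sino$values
  residuals <- numeric(n_iters)
  r <- p - A(f)
  for (it in seq_len(n_iters)) {
    f <- f + relax * Cw * At(Rw * r)
    r <- p - A(f)
    residuals[it] <- sqrt(sum(r^2))
  }
  img <- image_grid(f)
  if (circle) img <- .apply_circle(img)
  attr(img, "residuals") <- residuals
  img
}

#' Reconstruct a sinogram with any of the available methods
#'
#' Convenience dispatcher over [back_project()] (`"bp"`),
#' [fbp_reconstruct()] (`"fbp"`), [fourier_reconstruct()] (`"fourier"`) and
#' [sirt_reconstruct()] (`"sirt"`).
#'
#' @param sino A [sinogram()].
#' @param method One of `"fbp"`, `"bp"`, `"fourier"`, `"sirt"`.
#' @param filter Filter kind for `"fbp"`.
#' @param n_iters,relax SIRT settings.
#' @param N Output grid size.
#' @param circle Apply the reconstruction-circle mask (not for `"bp"`).
#' @return An [image_grid()].
#' @export
reconstruct <- function(sino, method = c("fbp", "bp", "fourier", "sirt"),
                        filter = "ram-lak", n_iters = 50, relax = 1,
                        N = NULL, circle = TRUE) {
  method <- match.arg(method)
  switch(method,
    fbp = fbp_reconstruct(sino, filter = filter, N = N, circle = circle),
    bp = back_project(sino, N = N),
    fourier = fourier_reconstruct(sino, N = N, circle = circle),
    sirt = sirt_reconstruct(sino, n_iters = n_iters, relax = relax, N = N,
                            circle = circle))
}
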