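.next_pow2 <- function(n) 2L^as.integer(ceiling(log2(n)))

#' Build a discrete reconstruction filter
#'
#' Constructs the ramp-type filters used by filtered back-projection on a
#' zero-padded grid of length `K_pad` (next power of two >= 2K, so that
#' frequency-domain multiplication performs a padded, non-wrapping
#' convolution):
#'
#' * `"ram-lak"`: the ideal band-limited ramp, response `|nu|` up to the
#'   detector Nyquist frequency `nu_N = 1/(2d)`;
#' * `"shepp-logan"`: the ramp windowed by a sinc,
#'   `|nu| * sinc(nu / (2 nu_N))` — equivalently the ramp convolved with
#'   `sin(x)/x` in the spatial domain, which damps the high frequencies that
#'   amplify measurement noise;
#' * `"none"`: an all-pass (identity) used for plain back-projection.
#'
#' The stored `spatial_kernel` is the inverse DFT of the response expressed
#' in physical units, i.e. samples `h(n*d)`; for the Ram-Lak filter it
#' matches the band-limited closed form `h(0) = 1/(4 d^2)`,
#' `h(n odd) = -1/(pi^2 n^2 d^2)`, `h(n even) = 0`.
#'
#' @param kind One of `"none"`, `"ram-lak"`, `"shepp-logan"`.
#' @param K Number of detector bins the filter will be applied to.
#' @param d Detector spacing.
#' @return An object of class `"filter_kernel"` with fields `kind`, `K`,
#'   `d`, `K_pad`, `freq` (DFT frequencies, cycles per unit length),
#'   `frequency_response`, `spatial_kernel`.
#' @export
build_filter <- function(kind = c("ram-lak", "shepp-logan", "none"), K, d) {
  kind <- match.arg(kind)
  stopifnot(K >= 2, d > 0)
  K_pad <- .next_pow2(2L * K)
  k <- 0:(K_pad - 1)
  k_signed <- ifelse(k <= K_pad / 2, k, k - K_pad)
  nu <- k_signed / (K_pad * d)            # physical DFT frequencies
  nu_N <- 1 / (2 * d)
  H <- switch(kind,
    "none" = rep(1, K_pad),
    "ram-lak" = abs(nu),
    "shepp-logan" = {
      x <- abs(nu) / (2 * nu_N)           # in [0, 1/2]
      sincx <- ifelse(x == 0, 1, sin(pi * x) / (pi * x))
      abs(nu) * sincx
    })
  spatial <- Re(stats::fft(H, inverse = TRUE)) / K_pad / d
  structure(list(kind = kind, K = K, d = d, K_pad = K_pad, freq = nu,
                 frequency_response = H, spatial_kernel = spatial),
            class = "filter_kernel")
}

#' @export
print.filter_kernel <- function(x, ...) {
  cat(sprintf("filter_kernel: %s, K = %d (padded to %d), d = %.5g, Nyquist %.5g\n",
              x$kind, x$K, x$K_pad, x$d, 1 / (2 * x$d)))
  invisible(x)
}

#' Filter a sinogram row-by-row in the frequency domain
#'
#' Each angle's projection is zero-padded to the kernel's `K_pad`, multiplied
#' by the frequency response, inverse-transformed and cropped back to K.
#' Because the response is defined over physical frequencies, the result
#' equals the Riemann-weighted spatial convolution
#' `d * sum_n' p(n') h((n - n') d)` with the band-limited filter kernel.
#' A `"none"` kernel returns the input unchanged.
#'
#' @param sino A [sinogram()].
#' @param kernel A [build_filter()] kernel built for this sinogram's K and d.
#' @return A [sinogram()] of filtered projections.
#' @export
filter_sinogram <- function(sino, kernel) {
  g <- sino$geometry
  if (!inherits(kernel, "filter_kernel") || kernel$K != g$K ||
      abs(kernel$d - g$d) > 1e-12)
    stop(sprintf("kernel (K = %s, d = %s) does not match sinogram (K = %d, d = %g)",
                 kernel$K, kernel$d, g$K, g$d))
  if (kernel$kind == "none") return(sino)
  K_pad <- kernel$K_pad
  H <- kernel$frequency_response
  out <- matrix(0, g$M, g$K)
  for (m in seq_len(g$M)) {
    row <- c(sino$values[m, ], numeric(K_pad - g$K))
    q <- Re(stats::fft(stats::fft(row) * H, inverse = TRUE)) / K_pad
    out[m, ] <- q[seq_len(g$K)]
  }
  sinogram(out, g)
}
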