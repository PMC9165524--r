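# Independent brute-force oracles used to pin expected values.

# Point-wise phantom evaluation from a raw parameter table
# (cx, cy, a, b, phi_rad, rho per row), written without the package's
# vectorized containment test.
oracle_point_value <- function(tab, x, y) {
  v <- 0
  for (i in seq_len(nrow(tab))) {
    dx <- x - tab[i, 1]; dy <- y - tab[i, 2]
    u <- dx * cos(tab[i, 5]) + dy * sin(tab[i, 5])
    w <- -dx * sin(tab[i, 5]) + dy * cos(tab[i, 5])
    if ((u / tab[i, 3])^2 + (w / tab[i, 4])^2 <= 1) v <- v + tab[i, 6]
  }
  v
}

phantom_table <- function(phan) {
  do.call(rbind, lapply(phan$ellipses, function(e)
    c(e$cx, e$cy, e$a, e$b, e$phi, e$rho)))
}

# Dense midpoint-rule quadrature of the line integral along the ray
# (t, theta) through a phantom: x = t cos - s sin, y = t sin + s cos.
oracle_line_integral <- function(phan, t, theta, n = 1e6, smax = 1.1) {
  s <- seq(-smax, smax, length.out = n)
  ds <- s[2] - s[1]
  x <- t * cos(theta) - s * sin(theta)
  y <- t * sin(theta) + s * cos(theta)
  tab <- phantom_table(phan)
  v <- numeric(n)
  for (i in seq_len(nrow(tab))) {
    dx <- x - tab[i, 1]; dy <- y - tab[i, 2]
    u <- dx * cos(tab[i, 5]) + dy * sin(tab[i, 5])
    w <- -dx * sin(tab[i, 5]) + dy * cos(tab[i, 5])
    inside <- (u / tab[i, 3])^2 + (w / tab[i, 4])^2 <= 1
    v[inside] <- v[inside] + tab[i, 6]
  }
  sum(v) * ds
}

# Literal per-pixel, per-angle back-projection accumulation with scalar
# linear interpolation (the defining triple loop), independent of the
# package's vectorized path.
oracle_back_project <- function(sino, N) {
  g <- sino$geometry
  xs <- grid_coords(N)
  out <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    acc <- 0
    for (m in seq_len(g$M)) {
      t <- xs[i] * cos(g$theta[m]) + xs[j] * sin(g$theta[m])
      u <- t / g$d + (g$K - 1) / 2
      if (u < 0 || u > g$K - 1) next
      n0 <- floor(u); de <- u - n0
      if (n0 >= g$K - 1) { n0 <- g$K - 2; de <- 1 }
      row <- sino$values[m, ]
      acc <- acc + ((1 - de) * row[n0 + 1] + de * row[n0 + 2])
    }
    out[i, j] <- acc / g$M
  }
  out
}

# Band-limited ramp filter closed form, sampled at spacing d.
oracle_ramlak_kernel <- function(n, d) {
  ifelse(n == 0, 1 / (4 * d^2),
         ifelse(n %% 2 == 0, 0, -1 / (pi^2 * n^2 * d^2)))
}

# Continuous-convention 1D Fourier transform of a centered-detector
# projection row: d * DFT * phase shift, at frequencies k/(K*d) (signed).
oracle_projection_ft <- function(row, d) {
  K <- length(row)
  nu <- (0:(K - 1)) / (K * d)
  nu <- ifelse(nu > 1 / (2 * d), nu - 1 / d, nu)
  d * stats::fft(row) * exp(2i * pi * nu * (K - 1) / 2 * d)
}
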