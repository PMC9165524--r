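.sidecar_path <- function(path) paste0(sub("\\.bin$", "", path), ".json")

#' Write / read an image as flat binary float32 with a JSON sidecar
#'
#' The native on-disk image format: row-major (C-order) float32 payload in
#' `<path>` and a JSON sidecar `<path minus .bin>.json` recording
#' `{N, spacing, dtype, order}`. Write-then-read round trips are bit-exact
#' at float32 precision. "Row-major" rows run along y for fixed x, matching
#' the in-memory convention (first index x, second y).
#'
#' @param img An [image_grid()].
#' @param path Output path (conventionally `*.bin`).
#' @return `path` invisibly (write); an [image_grid()] (read).
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "image_grid"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(t(img$values)), con, size = 4, endian = "little")
  jsonlite::write_json(
    list(N = img$N, spacing = img$spacing, dtype = "float32", order = "C"),
    .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  sc <- .sidecar_path(path)
  if (!file.exists(sc)) stop("missing sidecar JSON: ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  for (f in c("N", "dtype", "order"))
    if (is.null(meta[[f]])) stop("sidecar missing field '", f, "': ", sc)
  if (meta$dtype != "float32") stop("unsupported dtype '", meta$dtype, "'")
  n_expected <- meta$N^2
  payload <- readBin(path, numeric(), n = n_expected + 1, size = 4,
                     endian = "little")
  if (length(payload) != n_expected)
    stop(sprintf("payload has %d values but sidecar N = %d implies %d",
                 length(payload), meta$N, n_expected))
  image_grid(matrix(payload, meta$N, meta$N, byrow = TRUE))
}

#' Write / read a sinogram as flat binary float32 with a JSON sidecar
#'
#' Payload is row-major over (angle, detector bin); the sidecar records
#' `{M, K, Delta, d, row_major}`.
#'
#' @param sino A [sinogram()].
#' @param path Output path (conventionally `*.bin`).
#' @return `path` invisibly (write); a [sinogram()] (read).
#' @export
write_sinogram <- function(sino, path) {
  stopifnot(inherits(sino, "sinogram"))
  g <- sino$geometry
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(t(sino$values)), con, size = 4, endian = "little")
  jsonlite::write_json(
    list(M = g$M, K = g$K, Delta = g$Delta, d = g$d, row_major = TRUE),
    .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  sc <- .sidecar_path(path)
  if (!file.exists(sc)) stop("missing sidecar JSON: ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  for (f in c("M", "K", "Delta", "d"))
    if (is.null(meta[[f]])) stop("sidecar missing field '", f, "': ", sc)
  n_expected <- meta$M * meta$K
  payload <- readBin(path, numeric(), n = n_expected + 1, size = 4,
                     endian = "little")
  if (length(payload) != n_expected)
    stop(sprintf("payload has %d values but sidecar M*K = %d", length(payload),
                 n_expected))
  g <- proj_geometry(M = meta$M, K = meta$K, d = meta$d, Delta = meta$Delta)
  sinogram(matrix(payload, meta$M, meta$K, byrow = TRUE), g)
}

#' Export / import a sinogram as CSV (one row per angle)
#'
#' Text export for inspection and interchange; values are written with 9
#' significant digits, so a round trip agrees to about 1e-6 relative.
#'
#' @param sino A [sinogram()].
#' @param path CSV path.
#' @param geometry A [proj_geometry()] describing the stored values (CSV
#'   carries no geometry itself).
#' @return `path` invisibly (write); a [sinogram()] (read).
#' @export
write_sinogram_csv <- function(sino, path) {
  m <- format(sino$values, digits = 9, scientific = TRUE, trim = TRUE)
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_sinogram_csv
#' @export
read_sinogram_csv <- function(path, geometry) {
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  sinogram(m, geometry)
}

#' Serialize / load a phantom (CSV or JSON)
#'
#' CSV columns: `cx, cy, a, b, phi_rot_deg, rho` (one ellipse per row).
#' JSON carries the same table plus the phantom name. The format is chosen
#' by file extension.
#'
#' @param phan A [phantom()].
#' @param path Path ending in `.csv` or `.json`.
#' @return `path` invisibly (write); a [phantom()] (read).
#' @export
write_phantom <- function(phan, path) {
  df <- as.data.frame(phan)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(name = phan$name, ellipses = df), path,
                         auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(format(df, digits = 12), path, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  if (grepl("\\.json$", path)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- as.data.frame(obj$ellipses)
    name <- obj$name %||% "phantom"
  } else {
    df <- utils::read.csv(path)
    name <- sub("\\.csv$", "", basename(path))
  }
  ells <- lapply(seq_len(nrow(df)), function(i)
    ellipse(cx = df$cx[i], cy = df$cy[i], a = df$a[i], b = df$b[i],
            phi = df$phi_rot_deg[i] * pi / 180, rho = df$rho[i]))
  phantom(ells, name = name)
}

#' Export an image as an 8-bit PNG (lossy, for inspection only)
#'
#' Min-max windows the image to \[0, 1\] and writes an 8-bit grayscale PNG.
#' PNG rows run top-to-bottom, so y is flipped to display with y upward.
#'
#' @param img An [image_grid()].
#' @param path Output PNG path.
#' @param window Optional `c(low, high)` intensity window; defaults to the
#'   image's min and max.
#' @return `path`, invisibly.
#' @export
export_png <- function(img, path, window = NULL) {
  v <- img$values
  if (is.null(window)) window <- range(v)
  if (diff(window) == 0) window[2] <- window[1] + 1
  v <- (v - window[1]) / diff(window)
  v[v < 0] <- 0
  v[v > 1] <- 1
  # rows of the PNG = y from top; transpose and flip
  png::writePNG(t(v)[img$N:1, ], path)
  invisible(path)
}
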