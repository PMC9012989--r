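#' Temperature field
#'
#' The central container of the pipeline: a rows x cols grid of skin /
#' background temperatures in degrees Celsius. Coordinates are 1-based
#' `(row, col)` with the origin at the top-left, matching R matrix indexing.
#' After background filtering, background cells are exactly 0.0 degC.
#'
#' @param values numeric matrix of temperatures in degC; all values must be
#'   finite and the grid non-empty.
#' @return An object of class `temperature_field` with elements `values`
#'   (double matrix), `rows` and `cols`.
#' @examples
#' f <- temperature_field(matrix(c(25, 33.5, 0, 30.25), 2, 2))
#' dim(f)
#' @export
temperature_field <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(values) == 0L)
    ta_error("temperature field must contain at least one cell", "validation_error")
  if (!all(is.finite(values)))
    ta_error("temperature field contains non-finite values", "validation_error")
  structure(list(values = values, rows = nrow(values), cols = ncol(values)),
            class = "temperature_field")
}

#' @export
dim.temperature_field <- function(x) c(x$rows, x$cols)

#' @export
as.matrix.temperature_field <- function(x, ...) x$values

#' @export
print.temperature_field <- function(x, ...) {
  nz <- x$values[x$values != 0]
  cat(sprintf("<temperature_field> %d x %d pixels\n", x$rows, x$cols))
  if (length(nz))
    cat(sprintf("  nonzero: %d px, range %.2f-%.2f degC, mean %.2f degC\n",
                length(nz), min(nz), max(nz), mean(nz)))
  cat(sprintf("  zero (background) pixels: %d\n", sum(x$values == 0)))
  invisible(x)
}

#' @export
plot.temperature_field <- function(x, ...) {
  # flip rows so the top-left origin renders upright
  graphics::image(t(x$values[x$rows:1, , drop = FALSE]),
                  col = grDevices::gray.colors(256), axes = FALSE,
                  asp = x$rows / x$cols, ...)
  invisible(x)
}

#' Raw grid file dialect
#'
#' Describes the on-disk format for raw temperature grids (`.tgrid`):
#' an 8-byte header (rows, then cols, as little-endian 32-bit unsigned
#' integers) followed by a row-major payload of 16-bit unsigned integers in
#' counts of `1/scale` degC (default centi-degrees). The dialect is lossless
#' to `1/scale` degC and round-trips bit-exactly.
#'
#' @param scale integer counts per degC (default 100).
#' @return An object of class `raw_grid_dialect`.
#' @export
raw_grid_dialect <- function(scale = 100L) {
  scale <- as.integer(scale)
  if (is.na(scale) || scale <= 0L)
    ta_error("dialect scale must be a positive integer", "parameter_error")
  structure(list(scale = scale, byte_order = "little", layout = "row-major"),
            class = "raw_grid_dialect")
}

#' Read a raw temperature grid
#'
#' @param path path to a `.tgrid` file.
#' @param dialect a [raw_grid_dialect()].
#' @return A [temperature_field()].
#' @seealso [write_temperature_grid()]
#' @export
read_temperature_grid <- function(path, dialect = raw_grid_dialect()) {
  if (!file.exists(path))
    ta_error(sprintf("file not found: %s", path), "io_error")
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", n = 2L, size = 4L, endian = "little")
  if (length(hdr) < 2L)
    ta_error("truncated header: expected 8 bytes of dimensions", "format_error")
  rows <- hdr[1L]; cols <- hdr[2L]
  if (is.na(rows) || is.na(cols) || rows <= 0L || cols <= 0L)
    ta_error("non-positive grid dimensions in header", "format_error")
  expected <- 8 + 2 * as.double(rows) * as.double(cols)
  actual <- file.info(path)$size
  if (!isTRUE(actual == expected))
    ta_error(sprintf("payload size mismatch: header promises %d x %d (%g bytes), file has %g",
                     rows, cols, expected, actual), "format_error")
  counts <- readBin(con, "integer", n = rows * cols, size = 2L,
                    signed = FALSE, endian = "little")
  temperature_field(matrix(counts / dialect$scale, nrow = rows, ncol = cols,
                           byrow = TRUE))
}

#' Write a raw temperature grid
#'
#' Values must be representable as 16-bit unsigned counts at the dialect's
#' scale, i.e. `0 <= round(value * scale) <= 65535`.
#'
#' @inheritParams read_temperature_grid
#' @param field a [temperature_field()].
#' @return `path`, invisibly.
#' @export
write_temperature_grid <- function(field, path, dialect = raw_grid_dialect()) {
  stopifnot(inherits(field, "temperature_field"))
  counts <- floor(field$values * dialect$scale + 0.5)  # round half up
  if (any(counts < 0 | counts > 65535))
    ta_error(sprintf("temperatures outside the representable range [0, %.2f] degC",
                     65535 / dialect$scale), "range_error")
  con <- tryCatch(suppressWarnings(file(path, "wb")),
                  error = function(e) ta_error(
                    sprintf("cannot open '%s' for writing: %s", path, conditionMessage(e)),
                    "io_error"))
  on.exit(close(con))
  writeBin(c(field$rows, field$cols), con, size = 4L, endian = "little")
  # row-major payload; writeBin stores the low 16 bits, which is exact for
  # the validated range 0..65535
  writeBin(as.integer(t(counts)), con, size = 2L, endian = "little")
  invisible(path)
}

#' Rendering parameters for grayscale standardization
#'
#' `tfw` is the temperature-forming width and `tfs` the temperature-forming
#' start: together they window the temperature axis that is mapped onto the
#' 0-255 gray scale. [auto_render_params()] applies the medical-IRT default:
#' `tfw = 10` degC and `tfs = max(T) - tfw`, so the hottest pixel always maps
#' to 255 regardless of the subject's absolute temperature.
#'
#' @param tfw temperature-forming width in degC; must be positive.
#' @param tfs temperature-forming start in degC.
#' @return An object of class `render_params`.
#' @export
render_params <- function(tfw, tfs) {
  if (!is.finite(tfw) || tfw <= 0)
    ta_error("tfw must be a positive temperature width", "parameter_error")
  if (!is.finite(tfs))
    ta_error("tfs must be finite", "parameter_error")
  structure(list(tfw = tfw, tfs = tfs), class = "render_params")
}

#' @rdname render_params
#' @param field a [temperature_field()] with at least one nonzero value.
#' @export
auto_render_params <- function(field) {
  stopifnot(inherits(field, "temperature_field"))
  if (all(field$values == 0))
    ta_error("all-zero field: render parameters are undefined", "degenerate_input_error")
  render_params(tfw = 10, tfs = max(field$values) - 10)
}

#' Render a temperature field to gray levels
#'
#' Maps temperature to `round(255 * clamp((T - tfs) / tfw, 0, 1))` with
#' round-half-up, a monotone (order-preserving) standardization that removes
#' the influence of pseudo-color palettes before any downstream processing.
#'
#' @inheritParams auto_render_params
#' @param params a [render_params()]; defaults to [auto_render_params()].
#' @return Integer matrix of gray levels 0-255, same shape as the field.
#' @export
render_grayscale <- function(field, params = auto_render_params(field)) {
  stopifnot(inherits(field, "temperature_field"), inherits(params, "render_params"))
  u <- (field$values - params$tfs) / params$tfw
  u[u < 0] <- 0
  u[u > 1] <- 1
  g <- floor(255 * u + 0.5)  # round half up, platform-independent
  storage.mode(g) <- "integer"
  g
}

#' Export a grayscale render as PNG
#'
#' @inheritParams render_grayscale
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_grayscale_png <- function(field, path, params = auto_render_params(field)) {
  if (!requireNamespace("png", quietly = TRUE))
    ta_error("the 'png' package is required for PNG export", "parameter_error")
  g <- render_grayscale(field, params)
  png::writePNG(g / 255, target = path)
  invisible(path)
}

#' Export a temperature field as CSV (debugging aid)
#'
#' @inheritParams write_temperature_grid
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(field, path) {
  stopifnot(inherits(field, "temperature_field"))
  utils::write.table(field$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
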