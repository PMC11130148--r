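#' Read a target pattern from PNG or CSV
#'
#' PNG images are converted to grayscale intensity in [0, 1] (mean over color
#' channels); CSV files must contain a numeric matrix. Non-square images are
#' zero-padded to square (recorded in the `padding` attribute) so that `Li`
#' refers to the padded side. The image is oriented so that matrix rows run
#' along x and columns along y.
#'
#' @param path File path (.png or .csv).
#' @param Li Physical side length of the (padded) pattern plane (mm).
#' @param z Target depth (mm).
#' @return A [target_pattern()] (with `padding` attribute if padded).
#' @export
read_pattern <- function(path, Li, z) {
  if (!file.exists(path)) stop("pattern file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = {
      a <- png::readPNG(path)
      if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE],
                                           c(1, 2), mean)
      # PNG rows run top-to-bottom along y; transpose to rows-along-x
      t(a[rev(seq_len(nrow(a))), , drop = FALSE])
    },
    csv = as.matrix(utils::read.csv(path, header = FALSE)),
    stop("unsupported pattern format: .", ext, " (use PNG or CSV)"))
  if (!is.numeric(img) || anyNA(img))
    stop("malformed pattern file: ", path, " (non-numeric cells)")
  pad <- c(0L, 0L)
  if (nrow(img) != ncol(img)) {
    side <- max(dim(img))
    out <- matrix(0, side, side)
    r0 <- (side - nrow(img)) %/% 2; c0 <- (side - ncol(img)) %/% 2
    out[r0 + seq_len(nrow(img)), c0 + seq_len(ncol(img))] <- img
    pad <- c(side - nrow(img), side - ncol(img))
    img <- out
  }
  tp <- target_pattern(img, Li, z)
  attr(tp, "padding") <- pad
  tp
}

#' Serialize a complex field to CSV with a JSON sidecar
#'
#' Writes `<path>` as CSV with columns re, im (column-major samples) and
#' `<path>.json` carrying nx, ny, dx, dy, z, f. The round trip
#' `read_field(write_field(x))` restores metadata bitwise and values to
#' float precision.
#'
#' @param field A [complex_field()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  g <- field$grid
  utils::write.csv(data.frame(re = as.vector(Re(field$values)),
                              im = as.vector(Im(field$values))),
                   path, row.names = FALSE)
  jsonlite::write_json(list(nx = g$nx, ny = g$ny, dx = g$dx, dy = g$dy,
                            z = field$z, f = field$f),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(meta_path))
    stop("field files not found: ", path, " (+ .json sidecar)")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  d <- utils::read.csv(path)
  if (!all(c("re", "im") %in% names(d)))
    stop("malformed field CSV: ", path, " (need columns re, im)")
  if (nrow(d) != meta$nx * meta$ny)
    stop("field CSV row count does not match nx * ny in ", meta_path)
  g <- grid_2d(meta$nx, meta$ny, meta$dx, meta$dy)
  complex_field(g, matrix(complex(real = d$re, imaginary = d$im),
                          meta$nx, meta$ny),
                z = meta$z, f = meta$f)
}

#' Serialize a drive solution to CSV or JSON
#'
#' CSV columns: elem_x, elem_y (1-based element indices), amplitude,
#' phase_rad. JSON carries the same plus the array geometry. Round trips are
#' lossless to float precision.
#'
#' @param drive A [drive_solution()].
#' @param path Output path (.csv or .json).
#' @return `path`, invisibly.
#' @export
write_drive <- function(drive, path) {
  a <- drive$array
  df <- data.frame(elem_x = rep(seq_len(a$n_elem_x), times = a$n_elem_y),
                   elem_y = rep(seq_len(a$n_elem_y), each = a$n_elem_x),
                   amplitude = as.vector(drive$amplitude),
                   phase_rad = as.vector(drive$phase))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(list(array = unclass(a), elements = df), path,
                         auto_unbox = TRUE, digits = NA)
  } else stop("unsupported drive format: .", ext)
  invisible(path)
}

#' @rdname write_drive
#' @export
read_drive <- function(path) {
  if (!file.exists(path)) stop("drive file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- utils::read.csv(path)
    need <- c("elem_x", "elem_y", "amplitude", "phase_rad")
    if (!all(need %in% names(df)))
      stop("malformed drive CSV: ", path, " (need columns ",
           paste(need, collapse = ", "), ")")
    arr <- array_spec(n_elem_x = max(df$elem_x), n_elem_y = max(df$elem_y))
  } else if (ext == "json") {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    arr <- do.call(array_spec, j$array[c("n_elem_x", "n_elem_y", "pitch",
                                         "f0", "fill_factor")])
    df <- j$elements
  } else stop("unsupported drive format: .", ext)
  ord <- order(df$elem_y, df$elem_x)
  df <- df[ord, ]
  drive_solution(matrix(df$amplitude, arr$n_elem_x, arr$n_elem_y),
                 matrix(df$phase_rad, arr$n_elem_x, arr$n_elem_y), arr)
}

#' Export a magnitude map as a grayscale PNG
#'
#' @param values Numeric matrix (rows along x); normalized to max 1.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_magnitude_png <- function(values, path) {
  m <- as.matrix(values)
  mx <- max(m)
  if (mx > 0) m <- m / mx
  # rows-along-x -> PNG row order (top-to-bottom along y)
  png::writePNG(t(m)[rev(seq_len(ncol(m))), , drop = FALSE], path)
  invisible(path)
}

#' Built-in binary letter and symbol masks
#'
#' Programmatic stimulation-target masks on an n x n grid: the letters "U",
#' "S", "C" and the symbols "right" (arrow) and "stop" (octagon outline) used
#' to demonstrate pattern projection.
#'
#' @param glyph One of "C", "U", "S", "right", "stop".
#' @param n Image side (pixels).
#' @return Binary numeric matrix (rows along x).
#' @export
letter_mask <- function(glyph = c("C", "U", "S", "right", "stop"), n = 48) {
  glyph <- match.arg(glyph)
  xs <- seq(-1, 1, length.out = n)
  X <- matrix(xs, n, n); Y <- matrix(xs, n, n, byrow = TRUE)
  R <- sqrt(X^2 + Y^2)
  TH <- atan2(Y, X)
  m <- switch(glyph,
    C = (R > 0.45 & R < 0.8) & !(abs(TH) < pi / 4),
    U = (abs(X) > 0.45 & abs(X) < 0.8 & Y < 0.6 & Y > -0.3) |
      (R > 0.45 & R < 0.8 & Y <= -0.25 & Y >= -0.85),
    S = ((sqrt(X^2 + (Y - 0.4)^2) > 0.25 & sqrt(X^2 + (Y - 0.4)^2) < 0.52) &
           !(Y < 0.4 & X > 0)) |
      ((sqrt(X^2 + (Y + 0.4)^2) > 0.25 & sqrt(X^2 + (Y + 0.4)^2) < 0.52) &
         !(Y > -0.4 & X < 0)),
    right = (abs(Y) < 0.22 & X > -0.85 & X < 0.2) |
      (X >= 0.2 & X < 0.8 & abs(Y) < (0.8 - X)),
    stop = {
      oct <- pmax(abs(X), abs(Y), (abs(X) + abs(Y)) / sqrt(2))
      oct > 0.55 & oct < 0.85
    })
  storage.mode(m) <- "double"
  m
}
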