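#' Write a stimulus image to PNG or PGM
#'
#' Pixels are rounded to integers and stored at the requested bit depth;
#' values outside `[0, 2^bits - 1]` are clipped with a warning. Raster
#' formats carry no visual-angle calibration, so the resolution is written to
#' a small YAML sidecar (`<path>.yaml`) that [read_image()] picks up.
#'
#' @param image A [stimulus_image].
#' @param path Output file; the format follows the extension (`.png`, `.pgm`).
#' @param bits Bit depth, 8 or 16.
#' @param sidecar Write the calibration sidecar? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bits = 8, sidecar = TRUE) {
  img <- as_stimulus_image(image)
  if (!bits %in% c(8, 16)) stop("`bits` must be 8 or 16")
  maxval <- 2^bits - 1
  px <- round(img$pixels)
  if (any(px < 0) || any(px > maxval)) {
    warning(sprintf("pixel values clipped to [0, %d] on write", maxval))
    px <- pmin(pmax(px, 0), maxval)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (bits != 8) stop("PNG output is 8-bit; use .pgm for 16-bit storage")
    png::writePNG(px / maxval, target = path)
  } else if (ext == "pgm") {
    write_pgm(px, path, maxval)
  } else {
    stop("unsupported image format: ", ext, " (use .png or .pgm)")
  }
  if (sidecar) {
    writeLines(sprintf("resolution: %.10g", img$resolution),
      con = paste0(path, ".yaml")
    )
  }
  invisible(path)
}

#' Read a raster image as a stimulus
#'
#' Reads 8/16-bit grayscale PNG or binary PGM (P5) into a [stimulus_image]
#' with pixel values on the integer scale of the stored bit depth. Colour
#' input is converted to grayscale (channel mean) with a warning. The
#' pixels-per-degree calibration is taken from a `<path>.yaml` sidecar when
#' present, else from the `resolution` argument.
#'
#' @param path Image file (`.png` or `.pgm`).
#' @param resolution Fallback pixels per degree when no sidecar exists.
#' @return A [stimulus_image].
#' @export
read_image <- function(path, resolution = 60) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  side <- paste0(path, ".yaml")
  if (file.exists(side)) {
    cfg <- read_sidecar(side)
    if (!is.null(cfg$resolution)) resolution <- as.numeric(cfg$resolution)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path, info = TRUE)
    info <- attr(arr, "info")
    bits <- if (!is.null(info$bit.depth)) info$bit.depth else 8
    if (length(dim(arr)) == 3L) {
      warning("colour image converted to grayscale (channel mean)")
      arr <- apply(arr[, , seq_len(min(3L, dim(arr)[3])), drop = FALSE],
        c(1, 2), mean
      )
    }
    px <- matrix(round(as.numeric(arr) * (2^bits - 1)), nrow = dim(arr)[1])
  } else if (ext == "pgm") {
    px <- read_pgm(path)
  } else {
    stop("unsupported image format: ", ext)
  }
  stimulus_image(px, resolution, id = basename(path))
}

read_sidecar <- function(path) {
  if (requireNamespace("yaml", quietly = TRUE)) {
    return(yaml::read_yaml(path))
  }
  # minimal key: value fallback
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines[nzchar(lines)], ":", fixed = TRUE)
  stats::setNames(
    lapply(kv, function(p) trimws(paste(p[-1], collapse = ":"))),
    vapply(kv, function(p) trimws(p[1]), character(1))
  )
}

# Binary (P5) PGM, big-endian 16-bit per the netpbm convention.
write_pgm <- function(px, path, maxval) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P5", sprintf("%d %d", ncol(px), nrow(px)), as.character(maxval)),
    con = con, sep = "\n"
  )
  vals <- as.integer(t(px)) # row-major scan order
  size <- if (maxval > 255) 2L else 1L
  writeBin(vals, con, size = size, endian = "big")
  invisible(path)
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- read_pgm_token(con)
  if (magic != "P5") stop("only binary (P5) PGM is supported, got: ", magic)
  w <- as.integer(read_pgm_token(con))
  h <- as.integer(read_pgm_token(con))
  maxval <- as.integer(read_pgm_token(con))
  size <- if (maxval > 255) 2L else 1L
  vals <- readBin(con, "integer",
    n = w * h, size = size, signed = FALSE, endian = "big"
  )
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

# Reads one whitespace-delimited header token, skipping '#' comments.
read_pgm_token <- function(con) {
  tok <- character(0)
  repeat {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) stop("unexpected end of PGM header")
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch == "\n") break
      }
      next
    }
    if (grepl("[[:space:]]", ch)) {
      if (length(tok) > 0L) break else next
    }
    tok <- c(tok, ch)
  }
  paste(tok, collapse = "")
}

#' Read a headerless 16-bit raw luminance image
#'
#' Optional reader for the raw format used by a classic calibrated
#' natural-image collection: headerless unsigned 16-bit integers, 1536 x 1024
#' pixels, stored in row-major scanline order. The byte order is not part of
#' the format description available here; it defaults to big-endian and is
#' configurable. This reader is a convenience for scoring real photographs
#' and is exercised in tests only against synthetic raw files built in code.
#'
#' @param path Raw image file.
#' @param width,height Image dimensions in pixels (default 1536 x 1024).
#' @param endian Byte order, `"big"` (default) or `"little"`.
#' @param resolution Pixels per degree to attach (default 60).
#' @return A [stimulus_image] of `height` rows by `width` columns.
#' @export
read_raw_luminance <- function(path, width = 1536, height = 1024,
                               endian = c("big", "little"), resolution = 60) {
  endian <- match.arg(endian)
  if (!file.exists(path)) stop("cannot read raw image: ", path)
  expected <- width * height
  vals <- readBin(path, "integer",
    n = expected, size = 2L, signed = FALSE, endian = endian
  )
  if (length(vals) != expected) {
    stop(sprintf(
      "raw file holds %d values, expected %d (%d x %d)",
      length(vals), expected, width, height
    ))
  }
  stimulus_image(matrix(vals, nrow = height, ncol = width, byrow = TRUE),
    resolution,
    id = basename(path)
  )
}
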