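# Raster and tabular I/O.
#
# Internal image convention: a plain integer matrix with values in
# [0, 255], row index increasing downward, column index rightward,
# origin at the top-left.  Binary masks are logical matrices of the same
# shape.  Readers never rescale or convert: an image is returned with the
# stored 8-bit values, and multi-channel or >8-bit input is rejected.

#' Read an 8-bit grayscale image (PGM or PNG)
#'
#' Supports the PGM dialects used by public mammography archives (ASCII
#' `P2` and binary `P5`, maxval <= 255) and 8-bit grayscale PNG.  Pixel
#' values are returned exactly as stored.
#'
#' @param path path to a `.pgm` or `.png` file.
#' @return integer matrix with values in [0, 255].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  magic <- readBin(path, "raw", n = 2L)
  if (length(magic) >= 2L && magic[1L] == as.raw(0x50) &&
      magic[2L] %in% as.raw(c(0x32, 0x35))) {
    read_pgm(path)
  } else if (length(magic) >= 2L && magic[1L] == as.raw(0x89)) {
    read_png_gray(path)
  } else {
    stop(sprintf("unsupported format: %s", path), call. = FALSE)
  }
}

read_pgm <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  n <- length(raw)
  is_space <- function(b) b %in% as.raw(c(0x20, 0x09, 0x0a, 0x0d, 0x0b, 0x0c))
  pos <- 1L
  next_token <- function() {
    repeat {
      while (pos <= n && is_space(raw[pos])) pos <<- pos + 1L
      if (pos <= n && raw[pos] == as.raw(0x23)) {  # '#' comment to end of line
        while (pos <= n && raw[pos] != as.raw(0x0a)) pos <<- pos + 1L
      } else break
    }
    start <- pos
    while (pos <= n && !is_space(raw[pos]) && raw[pos] != as.raw(0x23)) pos <<- pos + 1L
    if (start > n) stop("truncated PGM header", call. = FALSE)
    rawToChar(raw[start:(pos - 1L)])
  }
  magic <- next_token()
  if (!magic %in% c("P2", "P5")) stop("unsupported format: not a PGM image", call. = FALSE)
  width <- as.integer(next_token())
  height <- as.integer(next_token())
  maxval <- as.integer(next_token())
  if (anyNA(c(width, height, maxval)) || width < 1L || height < 1L)
    stop("malformed PGM header", call. = FALSE)
  if (maxval > 255L) stop("unsupported: bit depth > 8", call. = FALSE)
  npx <- width * height
  if (magic == "P5") {
    pos <- pos + 1L  # single whitespace byte after maxval
    if (n - pos + 1L < npx) stop("truncated PGM pixel data", call. = FALSE)
    vals <- as.integer(raw[pos:(pos + npx - 1L)])
  } else {
    txt <- rawToChar(raw[pos:n])
    txt <- gsub("#[^\n]*", " ", txt)
    vals <- suppressWarnings(as.integer(scan(text = txt, what = integer(),
                                             quiet = TRUE, n = npx)))
    if (length(vals) < npx || anyNA(vals)) stop("truncated PGM pixel data", call. = FALSE)
  }
  if (max(vals) > maxval) stop("PGM pixel value exceeds declared maxval", call. = FALSE)
  matrix(vals, nrow = height, ncol = width, byrow = TRUE)
}

read_png_gray <- function(path) {
  arr <- png::readPNG(path, info = TRUE)
  info <- attr(arr, "info")
  if (!is.null(info) && !is.null(info$bit.depth) && info$bit.depth > 8L)
    stop("unsupported: bit depth > 8", call. = FALSE)
  if (length(dim(arr)) == 3L) {
    # gray+alpha with a constant, fully opaque alpha channel is tolerated
    if (dim(arr)[3L] == 2L && all(arr[, , 2L] == 1)) {
      arr <- arr[, , 1L]
    } else {
      stop("unsupported: multi-channel image", call. = FALSE)
    }
  }
  matrix(as.integer(round(arr * 255)), nrow(arr), ncol(arr))
}

#' Write an 8-bit grayscale image
#'
#' Format is chosen by the file extension: `.pgm` writes binary `P5`,
#' `.png` writes 8-bit grayscale PNG.  Round-trips bit-identically
#' through [read_image()].
#'
#' @param img integer matrix with values in [0, 255].
#' @param path output path; its parent directory must exist.
#' @export
write_image <- function(img, path) {
  assert_gray(img)
  if (!dir.exists(dirname(path)))
    stop(sprintf("directory does not exist: %s", dirname(path)), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(sprintf("P5\n%d %d\n255\n", ncol(img), nrow(img))), con)
    writeBin(as.raw(as.integer(t(img))), con)
  } else if (ext == "png") {
    png::writePNG(img / 255, path)
  } else {
    stop(sprintf("unsupported output format: .%s", ext), call. = FALSE)
  }
  invisible(path)
}

#' Write / read a binary mask as a PNG with values {0, 255}
#'
#' @param mask logical matrix.
#' @param path output `.png` path.
#' @export
write_mask <- function(mask, path) {
  assert_mask(mask)
  write_image(matrix(ifelse(mask, 255L, 0L), nrow(mask), ncol(mask)), path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- read_image(path)
  vals <- sort(unique(as.vector(img)))
  if (!all(vals %in% c(0L, 255L)))
    stop("mask image must contain only values 0 and 255", call. = FALSE)
  img == 255L
}

#' Pad an image to a square canvas
#'
#' The original pixels are kept at the top-left; padding (right and
#' bottom) is filled with 0, the mammogram background value.
#'
#' @param img integer matrix in [0, 255].
#' @param side target side length; must be >= both image dimensions.
#' @return `side` x `side` integer matrix.
#' @export
pad_to_square <- function(img, side) {
  assert_gray(img)
  side <- as.integer(side)
  if (side < max(nrow(img), ncol(img)))
    stop("side smaller than an image dimension", call. = FALSE)
  out <- matrix(0L, side, side)
  out[seq_len(nrow(img)), seq_len(ncol(img))] <- img
  out
}

VIEWS <- c("CC", "MLO")
LATERALITIES <- c("left", "right")

#' Load a mammogram metadata table
#'
#' Reads a CSV with columns `id`, `view` (CC or MLO), `laterality`
#' (left or right), `birads` (integer 0-6) and `path`, validating each
#' row against the fixed vocabularies.
#'
#' @param path CSV file path.
#' @return data.frame with one row per image.
#' @export
load_metadata <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("id", "view", "laterality", "birads", "path")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop(sprintf("metadata missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  if (nrow(df) == 0L) return(df[, required])
  for (i in seq_len(nrow(df))) {
    if (!df$view[i] %in% VIEWS)
      stop(sprintf("row %d: unknown view '%s'", i, df$view[i]), call. = FALSE)
    if (!df$laterality[i] %in% LATERALITIES)
      stop(sprintf("row %d: unknown laterality '%s'", i, df$laterality[i]), call. = FALSE)
    b <- suppressWarnings(as.integer(df$birads[i]))
    if (is.na(b) || b < 0L || b > 6L)
      stop(sprintf("row %d: birads '%s' outside 0-6", i, df$birads[i]), call. = FALSE)
  }
  df$birads <- as.integer(df$birads)
  df[, required]
}
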