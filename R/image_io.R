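#' Construct a grayscale image object
#'
#' A `gray_image` holds a 2-D grid of non-negative real intensities in
#' gray-value units, the bit depth of the source file (8, 16 or 32), and
#' free-form metadata (e.g. excitation/emission bands). Coordinates used
#' throughout the package are `(row, col)`, 0-based, with pixel centers at
#' integer coordinates.
#'
#' @param pixels numeric matrix of intensities; all finite, `>= 0`, at least
#'   3 x 3.
#' @param bit_depth integer; 8, 16 or 32. 32 denotes IEEE float storage.
#' @param metadata named list of free-form metadata.
#' @return an object of class `gray_image`.
#' @export
gray_image <- function(pixels, bit_depth = 32L, metadata = list()) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (nrow(pixels) < 3L || ncol(pixels) < 3L)
    stop("image must be at least 3 x 3 pixels")
  if (!all(is.finite(pixels)))
    stop("all intensities must be finite")
  if (any(pixels < 0))
    stop("all intensities must be >= 0")
  if (!bit_depth %in% c(8L, 16L, 32L))
    stop("`bit_depth` must be 8, 16 or 32")
  structure(list(pixels = pixels, bit_depth = as.integer(bit_depth),
                 metadata = metadata),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("gray_image: %d x %d pixels, %d-bit, range [%g, %g]\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

#' Read a single-channel grayscale image
#'
#' Reads TIFF (8/16-bit unsigned integer or 32-bit float) or PNG (8/16-bit)
#' images. Stored values are represented losslessly as reals: integer formats
#' are returned on their native integer scale (0..2^depth - 1) and float
#' TIFFs as stored. Multi-channel (RGB/RGBA) inputs are rejected unless a
#' `channel` is named explicitly, in which case that channel is extracted.
#'
#' @param path path to a `.tif`/`.tiff` or `.png` file.
#' @param channel `NULL` (require single-channel input) or one of
#'   `"R"`, `"G"`, `"B"` / channel index to extract from a color image.
#' @return a [gray_image].
#' @export
read_gray_image <- function(path, channel = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE)
    fmt <- attr(img, "sample.format")
    bits <- attr(img, "bits.per.sample")
    if (is.null(fmt)) fmt <- "uint"
    if (identical(fmt, "uint")) {
      img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    } else if (!identical(fmt, "float")) {
      stop("unsupported TIFF sample format: ", fmt)
    }
    depth <- as.integer(bits)
  } else if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    depth <- as.integer(attr(img, "info")$bit.depth)
    # readPNG scales to [0,1]; restore native integer scale
    img_attr <- attributes(img)
    img <- img * (2^depth - 1)
    dim(img) <- img_attr$dim
  } else {
    stop("unsupported image format: .", ext)
  }
  if (length(dim(img)) == 3L) {
    if (is.null(channel))
      stop("multi-channel image: pass `channel` to extract one channel from ",
           path)
    ch <- channel
    if (is.character(ch)) ch <- match(toupper(ch), c("R", "G", "B"))
    if (is.na(ch) || ch < 1L || ch > dim(img)[3L])
      stop("invalid channel selector")
    img <- img[, , ch]
  }
  if (!depth %in% c(8L, 16L, 32L))
    stop("unsupported bit depth: ", depth)
  gray_image(round_trip_matrix(img), bit_depth = depth,
             metadata = list(source = path))
}

# strip readTIFF/readPNG attributes, keep a plain matrix
round_trip_matrix <- function(x) {
  m <- as.numeric(x)
  dim(m) <- dim(x)[1:2]
  m
}

#' Write a grayscale image
#'
#' 8/16-bit images are stored as unsigned-integer TIFF (8-bit also as PNG);
#' 32-bit images are stored as IEEE float TIFF (PNG has no float format).
#' Round trips through [read_gray_image] are lossless: integer grids
#' bit-exactly, float grids to single precision.
#'
#' @param image a [gray_image].
#' @param path output path; `.tif`/`.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path) {
  stopifnot(inherits(image, "gray_image"))
  ext <- tolower(tools::file_ext(path))
  px <- image$pixels
  if (image$bit_depth == 32L) {
    if (ext == "png") stop("PNG cannot store 32-bit float images")
    write_float_tiff(px, path)
  } else {
    maxval <- 2^image$bit_depth - 1
    if (max(px) > maxval)
      stop("intensities exceed the ", image$bit_depth, "-bit range")
    if (ext %in% c("tif", "tiff")) {
      tiff::writeTIFF(px / maxval, path,
                      bits.per.sample = image$bit_depth, reduce = FALSE)
    } else if (ext == "png") {
      if (image$bit_depth != 8L)
        stop("PNG output supports 8-bit images only; use TIFF for ",
             image$bit_depth, "-bit")
      png::writePNG(px / maxval, path)
    } else stop("unsupported image format: .", ext)
  }
  invisible(path)
}

# Minimal single-strip uncompressed little-endian TIFF with 32-bit IEEE float
# samples (SampleFormat = 3). The tiff package reads this back via libtiff;
# it only writes unsigned-integer sample formats itself.
write_float_tiff <- function(px, path) {
  nr <- nrow(px); nc <- ncol(px)
  nbytes <- 4L * nr * nc
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)                       # little-endian
  writeBin(42L, con, size = 2, endian = "little")      # TIFF magic
  writeBin(8L + nbytes, con, size = 4, endian = "little")  # IFD offset
  writeBin(as.numeric(t(px)), con, size = 4, endian = "little")  # strip data
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
  entries <- list(
    c(256L, 4L, 1L, nc),       # ImageWidth
    c(257L, 4L, 1L, nr),       # ImageLength
    c(258L, 3L, 1L, 32L),      # BitsPerSample
    c(259L, 3L, 1L, 1L),       # Compression: none
    c(262L, 3L, 1L, 1L),       # Photometric: BlackIsZero
    c(273L, 4L, 1L, 8L),       # StripOffsets
    c(277L, 3L, 1L, 1L),       # SamplesPerPixel
    c(278L, 4L, 1L, nr),       # RowsPerStrip
    c(279L, 4L, 1L, nbytes),   # StripByteCounts
    c(339L, 3L, 1L, 3L)        # SampleFormat: IEEE float
  )
  writeBin(length(entries), con, size = 2, endian = "little")
  for (e in entries) entry(e[1], e[2], e[3], e[4])
  writeBin(0L, con, size = 4, endian = "little")       # no next IFD
  invisible(path)
}

#' Construct a basal-to-surface line annotation
#'
#' Endpoints are `(row, col)` real coordinates, 0-based; `start` lies at the
#' epithelial basement membrane and `end` at the epithelial surface. The
#' orientation is always basal to surface.
#'
#' @param image_id image identifier the line belongs to.
#' @param start,end numeric length-2 `(row, col)` coordinates.
#' @return an object of class `line_annotation`.
#' @export
line_annotation <- function(image_id, start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != 2L || length(end) != 2L ||
      !all(is.finite(c(start, end))))
    stop("endpoints must be finite (row, col) pairs")
  if (isTRUE(all(start == end)))
    stop("degenerate line: start equals end")
  structure(list(image_id = as.character(image_id),
                 start = start, end = end),
            class = "line_annotation")
}

#' Validate an annotation against its image
#'
#' Checks that both endpoints fall inside the image bounds (0-based pixel
#' centers, so rows in `[0, nrow-1]` and cols in `[0, ncol-1]`).
#'
#' @param ann a [line_annotation].
#' @param image a [gray_image].
#' @return `ann`, invisibly; errors otherwise.
#' @export
validate_annotation <- function(ann, image) {
  d <- dim(image$pixels)
  pts <- rbind(ann$start, ann$end)
  if (any(pts[, 1] < 0) || any(pts[, 1] > d[1] - 1) ||
      any(pts[, 2] < 0) || any(pts[, 2] > d[2] - 1))
    stop(sprintf("annotation for image '%s' has out-of-bounds endpoints",
                 ann$image_id))
  invisible(ann)
}

#' Read line annotations from JSON or CSV
#'
#' JSON is a list of objects `{"image_id": str, "start": [row, col],
#' "end": [row, col]}`; the equivalent CSV dialect has header
#' `image_id,row0,col0,row1,col1`. Both use 0-based `(row, col)` coordinates
#' and basal-to-surface orientation. Malformed records are reported with
#' their record index.
#'
#' @param path a `.json` or `.csv` file.
#' @return list of [line_annotation] objects.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    out <- vector("list", length(recs))
    for (i in seq_along(recs)) {
      r <- recs[[i]]
      if (is.null(r$image_id) || is.null(r$start) || is.null(r$end))
        stop("malformed annotation record ", i, ": missing field")
      out[[i]] <- tryCatch(
        line_annotation(r$image_id, unlist(r$start), unlist(r$end)),
        error = function(e) stop("annotation record ", i, ": ",
                                 conditionMessage(e), call. = FALSE))
    }
    out
  } else if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("image_id", "row0", "col0", "row1", "col1")
    if (!all(need %in% names(df)))
      stop("annotation CSV must have header: ", paste(need, collapse = ","))
    lapply(seq_len(nrow(df)), function(i) {
      tryCatch(
        line_annotation(df$image_id[i], c(df$row0[i], df$col0[i]),
                        c(df$row1[i], df$col1[i])),
        error = function(e) stop("annotation record ", i, ": ",
                                 conditionMessage(e), call. = FALSE))
    })
  } else stop("unsupported annotation format: .", ext)
}

#' Write line annotations
#'
#' @param annotations list of [line_annotation] objects.
#' @param path output `.json` or `.csv` path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    recs <- lapply(annotations, function(a)
      list(image_id = a$image_id, start = a$start, end = a$end))
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  } else if (ext == "csv") {
    df <- data.frame(
      image_id = vapply(annotations, `[[`, "", "image_id"),
      row0 = vapply(annotations, function(a) a$start[1], 0),
      col0 = vapply(annotations, function(a) a$start[2], 0),
      row1 = vapply(annotations, function(a) a$end[1], 0),
      col1 = vapply(annotations, function(a) a$end[2], 0))
    utils::write.csv(df, path, row.names = FALSE)
  } else stop("unsupported annotation format: .", ext)
  invisible(path)
}

#' Spectrum-style pseudo-color lookup table specification
#'
#' The lookup table maps low intensity to the red end and high intensity to
#' the blue end, through yellow and green in between (blue > green > yellow
#' > red, high to low). The table is a fixed 256-entry hue ramp.
#'
#' @param scaling `"image"` (per-image min-max) or a numeric length-2 fixed
#'   range `c(lo, hi)`.
#' @return an object of class `colormap_spec`.
#' @export
colormap_spec <- function(scaling = "image") {
  if (is.numeric(scaling)) {
    if (length(scaling) != 2L || scaling[2] <= scaling[1])
      stop("fixed scaling range must be c(lo, hi) with hi > lo")
  } else if (!identical(scaling, "image")) {
    stop("`scaling` must be \"image\" or a numeric range")
  }
  structure(list(name = "spectrum", scaling = scaling),
            class = "colormap_spec")
}

#' The 256-entry spectrum lookup table
#'
#' @return a 256 x 3 matrix of RGB values in `[0, 1]`, row 1 = red end
#'   (lowest intensity), row 256 = blue end (highest intensity).
#' @export
spectrum_lut <- function() {
  hues <- seq(0, 2 / 3, length.out = 256L)  # red -> yellow -> green -> blue
  t(grDevices::col2rgb(grDevices::hsv(hues, 1, 1)) / 255)
}

#' Pseudo-color an intensity image
#'
#' Maps intensity to the spectrum lookup table so that higher intensities are
#' closer to the blue end and lower ones to the red end. Under per-image
#' scaling the minimum maps to red and the maximum to blue; a constant image
#' is mapped entirely to the red end with a warning.
#'
#' @param image a [gray_image].
#' @param spec a [colormap_spec].
#' @return an `nrow x ncol x 3` RGB array in `[0, 1]`.
#' @export
pseudocolor <- function(image, spec = colormap_spec()) {
  stopifnot(inherits(image, "gray_image"), inherits(spec, "colormap_spec"))
  px <- image$pixels
  if (identical(spec$scaling, "image")) {
    lo <- min(px); hi <- max(px)
    if (hi == lo) {
      warning("constant image under per-image scaling; mapping all pixels ",
              "to the red end")
      idx <- matrix(1L, nrow(px), ncol(px))
    } else {
      idx <- matrix(1L + as.integer(round((px - lo) / (hi - lo) * 255)),
                    nrow(px), ncol(px))
    }
  } else {
    lo <- spec$scaling[1]; hi <- spec$scaling[2]
    frac <- pmin(1, pmax(0, (px - lo) / (hi - lo)))
    idx <- matrix(1L + as.integer(round(frac * 255)), nrow(px), ncol(px))
  }
  lut <- spectrum_lut()
  out <- array(0, c(nrow(px), ncol(px), 3L))
  for (k in 1:3) out[, , k] <- matrix(lut[idx, k], nrow(px), ncol(px))
  out
}

#' Write an RGB pseudo-color map as PNG
#'
#' @param rgb an `nrow x ncol x 3` array in `[0, 1]` as returned by
#'   [pseudocolor].
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
write_pseudocolor_png <- function(rgb, path) {
  png::writePNG(rgb, path)
  invisible(path)
}
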