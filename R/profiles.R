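#' Bilinear interpolation of an image at real coordinates
#'
#' Coordinates are 0-based `(row, col)` with pixel centers at integers.
#' Points must lie within the convex hull of pixel centers, i.e. rows in
#' `[0, nrow-1]` and cols in `[0, ncol-1]`; anything outside is an error
#' rather than a silent clamp.
#'
#' @param pixels numeric matrix.
#' @param row,col numeric vectors of equal length.
#' @return numeric vector of interpolated intensities.
#' @keywords internal
bilinear <- function(pixels, row, col) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  eps <- 1e-9
  if (any(row < -eps | row > nr - 1 + eps | col < -eps | col > nc - 1 + eps))
    stop("sample point outside the image pixel hull")
  row <- pmin(pmax(row, 0), nr - 1)
  col <- pmin(pmax(col, 0), nc - 1)
  r0 <- pmin(floor(row), nr - 2); c0 <- pmin(floor(col), nc - 2)
  fr <- row - r0; fc <- col - c0
  i00 <- pixels[cbind(r0 + 1, c0 + 1)]
  i01 <- pixels[cbind(r0 + 1, c0 + 2)]
  i10 <- pixels[cbind(r0 + 2, c0 + 1)]
  i11 <- pixels[cbind(r0 + 2, c0 + 2)]
  (1 - fr) * (1 - fc) * i00 + (1 - fr) * fc * i01 +
    fr * (1 - fc) * i10 + fr * fc * i11
}

#' Sample an intensity profile along an annotated line
#'
#' Samples the image by bilinear interpolation at equally spaced points from
#' the basal endpoint towards the surface endpoint. Sample `i` (0-based) lies
#' at `start + i * step * unit_vector`; the number of samples is
#' `floor(length / step) + 1`, so the first sample is exactly the basal
#' endpoint. At least 9 samples (3 per segment) are required.
#'
#' @param image a [gray_image].
#' @param line a [line_annotation]; validated against the image.
#' @param step sampling spacing in pixels (default 1, matching pixel-indexed
#'   profile plots).
#' @return an object of class `intensity_profile` with fields `annotation`,
#'   `values` (index 1 at the basal end) and `step`.
#' @export
sample_line <- function(image, line, step = 1) {
  stopifnot(inherits(image, "gray_image"), inherits(line, "line_annotation"))
  if (!is.numeric(step) || length(step) != 1L || !is.finite(step) || step <= 0)
    stop("`step` must be a positive number")
  validate_annotation(line, image)
  d <- line$end - line$start
  len <- sqrt(sum(d^2))
  n <- floor(len / step) + 1
  if (n < 9)
    stop("line too short for three segments: ", n,
         " samples at step ", step, " (need >= 9)")
  u <- d / len
  i <- seq_len(n) - 1
  vals <- bilinear(image$pixels,
                   line$start[1] + i * step * u[1],
                   line$start[2] + i * step * u[2])
  structure(list(annotation = line, values = vals, step = step),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("intensity_profile: %d samples (step %g px), basal->surface, range [%g, %g]\n",
              length(x$values), x$step, min(x$values), max(x$values)))
  invisible(x)
}

#' Segment lengths for an n-sample profile
#'
#' Each segment gets `n %/% 3` samples; when `n` is not divisible by 3 the
#' remainder is distributed one extra sample per segment starting from the
#' lower (basal) segment.
#'
#' @param n number of samples, `>= 9`.
#' @return integer vector of 3 lengths summing to `n`, pairwise differing by
#'   at most 1.
#' @keywords internal
segment_lengths <- function(n) {
  if (n < 9) stop("profile too short to segment: ", n, " samples (need >= 9)")
  base <- n %/% 3L
  rem <- n %% 3L
  base + as.integer(seq_len(3L) <= rem)
}

#' Split a profile into three equidistant segments
#'
#' Mirrors the CIN grading convention of lower/middle/upper epithelial
#' thirds: the ordered basal-to-surface samples are cut into three
#' contiguous, equally sized segments (lengths differing by at most one
#' sample, extras assigned basal-first). Concatenating the segments
#' reproduces the original values exactly.
#'
#' @param profile an [intensity_profile] or a numeric vector of ordered
#'   basal-to-surface intensities.
#' @return an object of class `segmented_profile`: list with `lower`,
#'   `middle`, `upper` numeric vectors.
#' @export
split_into_segments <- function(profile) {
  values <- if (inherits(profile, "intensity_profile")) profile$values
            else as.numeric(profile)
  lens <- segment_lengths(length(values))
  ends <- cumsum(lens)
  structure(list(lower  = values[seq_len(lens[1])],
                 middle = values[(ends[1] + 1):ends[2]],
                 upper  = values[(ends[2] + 1):ends[3]]),
            class = "segmented_profile")
}

#' Export profiles as a tidy CSV table
#'
#' One row per sample: `image_id,line_index,sample_index,distance_px,intensity`.
#' `sample_index` is 0-based; `distance_px` is `sample_index * step`.
#'
#' @param profiles list of [intensity_profile] objects.
#' @param path output CSV path, or `NULL` to return the data frame.
#' @return the data frame, invisibly when written.
#' @export
profiles_to_csv <- function(profiles, path = NULL) {
  rows <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    idx <- seq_along(p$values) - 1
    data.frame(image_id = p$annotation$image_id, line_index = i,
               sample_index = idx, distance_px = idx * p$step,
               intensity = p$values)
  })
  df <- do.call(rbind, rows)
  if (is.null(path)) return(df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
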