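# Image container, image file I/O, and dataset manifests.
#
# Conventions used throughout the package: rasters are numeric matrices in
# row-major reading order (origin top-left, 0-based pixel coordinates in all
# formulas), crops are half-open intervals, and every stochastic operation
# takes an explicit seed.

#' Grayscale image container
#'
#' A `gray_image` is a 2-D intensity raster together with its representable
#' dynamic range. The range travels with the pixels so that quantisation,
#' PSNR/SSIM computation and file writing never have to guess the scale.
#'
#' @param pixels Numeric matrix of intensities (rows = image rows).
#' @param dynamic_range Length-2 numeric, `(min_representable,
#'   max_representable)`. Defaults to `c(0, 255)` (8-bit).
#' @return An object of class `gray_image` with fields `pixels`, `height`,
#'   `width`, `dynamic_range`.
#' @export
gray_image <- function(pixels, dynamic_range = c(0, 255)) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("gray_image: height and width must be >= 1")
  if (!all(is.finite(pixels)))
    stop("gray_image: all pixel values must be finite")
  if (length(dynamic_range) != 2L || dynamic_range[1] >= dynamic_range[2])
    stop("gray_image: dynamic_range must be (min, max) with min < max")
  structure(
    list(pixels = unname(pixels), height = nrow(pixels), width = ncol(pixels),
         dynamic_range = as.numeric(dynamic_range)),
    class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %dx%d, range [%g, %g], pixels in [%g, %g]>\n",
              x$height, x$width, x$dynamic_range[1], x$dynamic_range[2],
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

is_gray_image <- function(x) inherits(x, "gray_image")

as_pixels <- function(image) {
  if (is_gray_image(image)) image$pixels else as.matrix(image)
}

# BT.601 luminance weights; the dominant grayscale convention in fundus work.
.luma <- c(0.299, 0.587, 0.114)

#' Read an image file
#'
#' Reads PNG (8/16-bit gray or RGB[A]) or uncompressed baseline TIFF
#' (8/16-bit gray). RGB is collapsed to BT.601 luminance
#' (0.299 R + 0.587 G + 0.114 B) when `as_gray` is `TRUE`. JPEG files are
#' recognised but rejected: no JPEG decoder is available in this build.
#'
#' @param path Path to the image file.
#' @param as_gray Collapse RGB to luminance (default `TRUE`). Reading an RGB
#'   file with `as_gray = FALSE` is an error, as the package container is
#'   single-channel.
#' @return A [gray_image] whose `dynamic_range` reflects the file bit depth
#'   (`(0, 255)` or `(0, 65535)`).
#' @export
read_image <- function(path, as_gray = TRUE) {
  if (!file.exists(path)) stop(sprintf("read_image: file not found: '%s'", path))
  magic <- readBin(path, "raw", n = 4L)
  is_png  <- length(magic) >= 4 && identical(as.integer(magic[1:4]), c(137L, 80L, 78L, 71L))
  is_tiff <- length(magic) >= 2 &&
    (identical(rawToChar(magic[1:2]), "II") || identical(rawToChar(magic[1:2]), "MM"))
  is_jpeg <- length(magic) >= 2 && identical(as.integer(magic[1:2]), c(255L, 216L))
  if (is_jpeg)
    stop("read_image: JPEG decoding is not supported in this build; convert to PNG or TIFF")
  if (is_png) {
    dec <- .png_read(path)
    rng <- c(0, 2^dec$bit_depth - 1)
    if (dec$channels == 1L) return(gray_image(dec$pixels[, , 1L], rng))
    if (!as_gray)
      stop("read_image: RGB image requires as_gray = TRUE (single-channel container)")
    px <- .luma[1] * dec$pixels[, , 1L] + .luma[2] * dec$pixels[, , 2L] +
      .luma[3] * dec$pixels[, , 3L]
    return(gray_image(px, rng))
  }
  if (is_tiff) {
    dec <- .tiff_read_gray(path)
    return(gray_image(dec$pixels, c(0, 2^dec$bit_depth - 1)))
  }
  stop(sprintf("read_image: '%s' is not a recognised PNG/TIFF file", path))
}

#' Write an image file
#'
#' Writes a lossless PNG or uncompressed TIFF (by file extension). Integer
#' rasters within the declared dynamic range round-trip bit-exactly. Float
#' rasters must either already be integers within range, or `quantize = TRUE`
#' must be set, in which case pixels in `[-1, 1]` are mapped linearly to
#' `[0, 255]` with round-half-even (-1 -> 0, 0 -> 128, 1 -> 255).
#'
#' @param image A [gray_image].
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @param quantize Map a normalised `[-1, 1]` raster to 8-bit before writing.
#' @export
write_image <- function(image, path, quantize = FALSE) {
  stopifnot(is_gray_image(image))
  if (!dir.exists(dirname(path)))
    stop(sprintf("write_image: parent directory does not exist: '%s'", dirname(path)))
  px <- image$pixels
  rng <- image$dynamic_range
  if (quantize) {
    px <- round((px - rng[1]) / (rng[2] - rng[1]) * 255)
    rng <- c(0, 255)
  }
  if (any(px < rng[1]) || any(px > rng[2]))
    stop("write_image: pixels outside dynamic_range; quantize first")
  if (any(px != round(px)))
    stop("write_image: non-integer pixels; set quantize = TRUE or round first")
  bit_depth <- if (rng[2] > 255) 16L else 8L
  ext <- tolower(tools::file_ext(path))
  ipx <- matrix(as.integer(round(px)), nrow(px), ncol(px))
  if (ext == "png") .png_write_gray(path, ipx, bit_depth)
  else if (ext %in% c("tif", "tiff")) .tiff_write_gray(path, ipx, bit_depth)
  else stop(sprintf("write_image: unsupported extension '.%s' (use png/tif/tiff)", ext))
  invisible(path)
}

#' Build a dataset manifest in memory
#'
#' @param path Character vector of image paths.
#' @param grade Integer grades in 0..4 (ICDR severity).
#' @param split Optional per-record split labels (`train`/`test`/`unassigned`).
#' @param seed Seed recorded for any split already applied (`NA` if none).
#' @return A `dataset_manifest`: ordered records, per-grade `class_counts`,
#'   and the split seed.
#' @export
dataset_manifest <- function(path, grade, split = NULL, seed = NA_integer_) {
  grade <- as.integer(grade)
  n <- length(path)
  if (length(grade) != n) stop("dataset_manifest: path/grade length mismatch")
  bad <- which(is.na(grade) | grade < 0L | grade > 4L)
  if (length(bad))
    stop(sprintf("dataset_manifest: grade outside 0-4 at row %d", bad[1]))
  if (anyDuplicated(path))
    stop(sprintf("dataset_manifest: duplicate path '%s'", path[anyDuplicated(path)]))
  if (is.null(split)) split <- rep("unassigned", n)
  if (!all(split %in% c("train", "test", "unassigned")))
    stop("dataset_manifest: split must be train/test/unassigned")
  records <- data.frame(path = as.character(path), grade = grade,
                        split = as.character(split), stringsAsFactors = FALSE)
  counts <- as.integer(table(factor(grade, levels = 0:4)))
  names(counts) <- as.character(0:4)
  structure(list(records = records, class_counts = counts, seed = seed),
            class = "dataset_manifest")
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat(sprintf("<dataset_manifest: %d records; counts %s>\n",
              nrow(x$records),
              paste(sprintf("%s:%d", names(x$class_counts), x$class_counts),
                    collapse = " ")))
  invisible(x)
}

#' Load a dataset manifest from CSV
#'
#' Expects header columns `path,grade` and optionally `split`.
#'
#' @param path CSV file path.
#' @return A `dataset_manifest` with records in file order.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("load_manifest: file not found: '%s'", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("path", "grade") %in% names(df)))
    stop("load_manifest: CSV must have columns 'path' and 'grade'")
  if (nrow(df) == 0)
    return(dataset_manifest(character(0), integer(0)))
  g <- suppressWarnings(as.integer(df$grade))
  bad <- which(is.na(g) | g < 0L | g > 4L)
  if (length(bad))
    stop(sprintf("load_manifest: invalid grade '%s' at row %d", df$grade[bad[1]], bad[1]))
  dataset_manifest(df$path, g, if ("split" %in% names(df)) df$split else NULL)
}

#' Write a dataset manifest to CSV
#' @param manifest A `dataset_manifest`.
#' @param path Output CSV path.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  write.csv(manifest$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Stratified train/test split
#'
#' Marks `ceiling(test_fraction * n_g)` records of every grade `g` as `test`
#' and the rest as `train`. Deterministic for a given seed.
#'
#' @param manifest A `dataset_manifest`.
#' @param test_fraction Fraction in (0, 1).
#' @param seed Integer seed controlling the per-grade sampling.
#' @return A new `dataset_manifest` with `split` assigned and `seed` recorded.
#' @export
split_manifest <- function(manifest, test_fraction, seed) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("split_manifest: test_fraction must be in (0, 1)")
  rec <- manifest$records
  present <- sort(unique(rec$grade))
  for (g in present) {
    if (sum(rec$grade == g) < 2L)
      stop(sprintf("split_manifest: grade %d has fewer than 2 records", g))
  }
  split <- rep("train", nrow(rec))
  rng <- local_seed(seed)
  on.exit(restore_seed(rng), add = TRUE)
  for (g in present) {
    idx <- which(rec$grade == g)
    n_test <- ceiling(test_fraction * length(idx))
    split[sample(idx, n_test)] <- "test"
  }
  dataset_manifest(rec$path, rec$grade, split, seed = as.integer(seed))
}

# Scoped RNG: seed the generator, hand back the previous state so callers can
# restore it. Keeps the package's explicit-seed policy from leaking into the
# caller's RNG stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
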