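#' Fundus image container
#'
#' A fundus image is stored as an `H x W x 3` numeric array of RGB values in
#' `[0, 1]`, indexed `[row, col, channel]` (row-major, 0-based coordinates are
#' used in all exported coordinate output). The constructor validates range,
#' shape and finiteness; every processing stage in the package returns objects
#' of this class.
#'
#' @param pixels numeric `H x W x 3` array with finite values in `[0, 1]`.
#' @param source_id optional character tag identifying the image origin.
#' @return A `fundus_image` object: the pixel array with class and
#'   `source_id` attributes, plus `height`/`width` accessors via `dim()`.
#' @export
fundus_image <- function(pixels, source_id = "unknown") {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3L), c(dim(pixels), 3L))
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  if (dim(pixels)[1] < 64L || dim(pixels)[2] < 64L)
    stop("fundus_image: height and width must be at least 64 pixels")
  if (!all(is.finite(pixels)))
    stop("fundus_image: pixel values must be finite")
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("fundus_image: pixel values must lie in [0, 1]")
  structure(pixels, class = "fundus_image", source_id = source_id)
}

#' @export
print.fundus_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("fundus_image '%s': %d x %d RGB, range [%.3f, %.3f]\n",
              attr(x, "source_id"), d[1], d[2], min(x), max(x)))
  invisible(x)
}

#' @rdname fundus_image
#' @param x object to test.
#' @export
is_fundus_image <- function(x) inherits(x, "fundus_image")

# Clip to [0,1] preserving attributes; applied after every arithmetic stage.
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Rebuild a fundus_image from a raw array, keeping the source tag of `like`.
as_fundus <- function(pixels, like) {
  fundus_image(clip01(unclass(pixels)),
               source_id = if (is_fundus_image(like)) attr(like, "source_id") else "derived")
}

#' Read a fundus photograph
#'
#' Reads a PNG/JPEG/TIFF RGB image into a [fundus_image]. Greyscale input is
#' replicated over three channels; an alpha channel, if present, is dropped.
#'
#' @param path path to the image file.
#' @return A [fundus_image].
#' @export
read_fundus <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) {
    a <- array(rep(a, 3L), c(dim(a), 3L))
  } else if (dim(a)[3] > 3L) {
    a <- a[, , 1:3, drop = FALSE]
  }
  # EBImage stores (x, y, c); transpose to (row, col, c)
  a <- aperm(a, c(2L, 1L, 3L))
  fundus_image(clip01(a), source_id = basename(path))
}

#' Write a fundus image or mask as PNG
#'
#' @param x a [fundus_image], an `H x W` numeric matrix, or a logical mask
#'   (written as 0/255).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fundus_png <- function(x, path) {
  if (is.logical(x)) x <- x * 1
  a <- unclass(x)
  png::writePNG(clip01(a), target = path)
  invisible(path)
}

#' RGB to hue-saturation-intensity conversion
#'
#' Classical geometric HSI: intensity is the channel mean, saturation
#' `1 - min(R,G,B)/I`, and hue the angle (radians in `[0, 2*pi)`) of the color
#' point around the achromatic axis. Hue is an angle, so averages over it must
#' use circular statistics (see [circular_mean_hue]).
#'
#' @param rgb `H x W x 3` array in `[0, 1]`.
#' @return list with matrices `h` (radians), `s`, `i`.
#' @export
rgb_to_hsi <- function(rgb) {
  r <- rgb[, , 1]; g <- rgb[, , 2]; b <- rgb[, , 3]
  i <- (r + g + b) / 3
  mn <- pmin(r, g, b)
  s <- ifelse(i > 0, 1 - mn / pmax(i, .Machine$double.eps), 0)
  num <- 0.5 * ((r - g) + (r - b))
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  theta <- acos(pmin(1, pmax(-1, num / pmax(den, .Machine$double.eps))))
  h <- ifelse(b > g, 2 * pi - theta, theta)
  h[den < .Machine$double.eps] <- 0
  list(h = h, s = s, i = i)
}

#' Hue-saturation-intensity to RGB conversion
#'
#' Inverse of [rgb_to_hsi] by the standard sector construction. Values are
#' clipped to `[0, 1]` afterwards since edited H/S/I triples need not map into
#' the RGB cube.
#'
#' @param h hue matrix, radians (any real; wrapped into `[0, 2*pi)`).
#' @param s saturation matrix in `[0, 1]`.
#' @param i intensity matrix in `[0, 1]`.
#' @return `H x W x 3` array in `[0, 1]`.
#' @export
hsi_to_rgb <- function(h, s, i) {
  h <- h %% (2 * pi)
  s <- pmin(1, pmax(0, s))
  sector <- ifelse(h < 2 * pi / 3, 0L, ifelse(h < 4 * pi / 3, 1L, 2L))
  hl <- h - sector * (2 * pi / 3)
  x <- i * (1 - s)                                   # the "floor" channel
  y <- i * (1 + s * cos(hl) / cos(pi / 3 - hl))      # the "leading" channel
  z <- 3 * i - x - y
  r <- ifelse(sector == 0L, y, ifelse(sector == 1L, x, z))
  g <- ifelse(sector == 0L, z, ifelse(sector == 1L, y, x))
  b <- ifelse(sector == 0L, x, ifelse(sector == 1L, z, y))
  out <- array(0, c(dim(as.matrix(h)), 3L))
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  clip01(out)
}

# s x s mean (box) filter with replicated borders; s forced to odd >= 1.
mean_filter <- function(x, s) {
  s <- as.integer(s)
  if (s %% 2L == 0L) s <- s + 1L
  if (s <= 1L) return(x)
  filt2(x, matrix(1 / (s * s), s, s))
}

# filter2 returning a plain matrix (EBImage returns an S4 Image)
filt2 <- function(x, k) {
  EBImage::imageData(EBImage::filter2(x, k, boundary = "replicate"))
}

# Nearest odd integer, never below lo.
odd_near <- function(x, lo = 1L) {
  v <- max(lo, as.integer(round(x)))
  if (v %% 2L == 0L) v <- v + 1L
  v
}
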