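## Images are plain base-R arrays, H x W x 3, intensities in [0, 1] --
## the same convention png::readPNG uses, so disk round-trips are free.

as_image <- function(x) {
  if (is.matrix(x)) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  fm_assert(is.array(x) && length(dim(x)) == 3L, "image",
            "expected an H x W x C array, got dims [%s]",
            paste(dim(x), collapse = ", "))
  if (dim(x)[3] == 1L) x <- array(rep(x, 3L), dim = c(dim(x)[1:2], 3L))
  if (dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]  # drop alpha
  fm_assert(dim(x)[3] == 3L, "image", "expected 1, 3 or 4 channels, got %d", dim(x)[3])
  fm_assert(all(is.finite(x)), "image", "image contains non-finite values")
  x
}

check_unit_range <- function(x, what = "image") {
  fm_assert(all(x >= 0 & x <= 1), "image", "%s has intensities outside [0, 1]", what)
  invisible(x)
}

#' Read an image file (PNG or JPEG) as an H x W x 3 array in [0, 1]
#'
#' @param path file path; format chosen by extension.
#' @return numeric array H x W x 3.
#' @export
read_image <- function(path) {
  fm_assert(file.exists(path), "io", "no such image file: %s", path)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        fm_stop("io", "the 'jpeg' package is required to read %s", path)
      jpeg::readJPEG(path)
    },
    fm_stop("io", "unsupported image extension '%s' (use png/jpg/jpeg)", ext)
  )
  as_image(x)
}

#' Write an image array to a PNG file
#'
#' @param image H x W x 3 array in [0, 1].
#' @param path output path (.png).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  image <- as_image(image)
  check_unit_range(image)
  png::writePNG(image, path)
  invisible(path)
}

## Luminance used for histograms and the nearest-centroid baseline.
to_gray <- function(image) {
  image <- as_image(image)
  (image[, , 1] + image[, , 2] + image[, , 3]) / 3
}

#' Resize an image to the canonical square side
#'
#' Bilinear interpolation; grayscale (2-D) inputs are replicated to three
#' channels first. Downscaling by more than 2x applies an integer-factor box
#' prefilter (anti-aliasing) before the bilinear pass.
#'
#' @param image H x W x 3 array (or 2-D grayscale matrix) in [0, 1].
#' @param side target side length in pixels, >= 8. The study protocol's
#'   canonical input is 1000; desk-scale work uses 64.
#' @return `side` x `side` x 3 array.
#' @export
#' @examples
#' img <- array(runif(12 * 10 * 3), dim = c(12, 10, 3))
#' dim(resize_to_canonical(img, 16))
resize_to_canonical <- function(image, side) {
  image <- as_image(image)
  fm_assert(side >= 8, "resize", "side must be >= 8, got %s", format(side))
  fm_assert(all(dim(image)[1:2] >= 1), "resize", "empty image")
  h <- dim(image)[1]; w <- dim(image)[2]
  if (h == side && w == side) return(image)
  ## box prefilter when shrinking aggressively
  f <- floor(min(h, w) / side)
  if (f >= 2) {
    image <- block_mean(image, f)
    h <- dim(image)[1]; w <- dim(image)[2]
  }
  bilinear_resize(image, side, side)
}

block_mean <- function(image, f) {
  h <- dim(image)[1]; w <- dim(image)[2]
  h2 <- floor(h / f); w2 <- floor(w / f)
  out <- array(0, dim = c(h2, w2, 3L))
  for (c in 1:3) {
    m <- image[seq_len(h2 * f), seq_len(w2 * f), c]
    ## average f x f blocks via two grouped row sums
    m <- rowsum(m, rep(seq_len(h2), each = f)) / f
    m <- t(rowsum(t(m), rep(seq_len(w2), each = f)) / f)
    out[, , c] <- m
  }
  out
}

bilinear_resize <- function(image, out_h, out_w) {
  h <- dim(image)[1]; w <- dim(image)[2]
  ## map output pixel centers onto input pixel centers
  ys <- (seq_len(out_h) - 0.5) * h / out_h + 0.5
  xs <- (seq_len(out_w) - 0.5) * w / out_w + 0.5
  y0 <- clamp(floor(ys), 1, h); y1 <- clamp(y0 + 1, 1, h)
  x0 <- clamp(floor(xs), 1, w); x1 <- clamp(x0 + 1, 1, w)
  wy <- clamp(ys - y0, 0, 1);   wx <- clamp(xs - x0, 0, 1)
  out <- array(0, dim = c(out_h, out_w, 3L))
  WY <- matrix(wy, out_h, out_w)
  WX <- matrix(wx, out_h, out_w, byrow = TRUE)
  for (c in 1:3) {
    ch <- image[, , c]
    a <- ch[y0, x0]; b <- ch[y0, x1]; d <- ch[y1, x0]; e <- ch[y1, x1]
    top <- a * (1 - WX) + b * WX
    bot <- d * (1 - WX) + e * WX
    out[, , c] <- top * (1 - WY) + bot * WY
  }
  out
}

## 90-degree counter-clockwise rotation (order 4: four applications = identity)
rotate90 <- function(image) {
  image <- as_image(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  out <- array(0, dim = c(w, h, 3L))
  for (c in 1:3) out[, , c] <- t(image[, , c])[w:1, , drop = FALSE]
  out
}

mirror_flip <- function(image) {
  image <- as_image(image)
  image[, dim(image)[2]:1, , drop = FALSE]
}
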