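## Contrast enhancement by weighted exposure fusion.
##
## The enhanced image is R^c = sum_i W_i * P_i^c, where P_i = g(P, k_i) are
## synthetic exposures of the input generated by a brightness transform
## function (BTF) g with exposure ratio k_i, W_i are per-pixel weight maps
## summing to one, and c indexes the colour channel. The fusion here uses two
## exposures: the original (weight W) and one brightened rendition (weight
## 1 - W), with W an illumination estimate, so only the under-exposed regions
## are lifted.

#' Enhancement configuration
#'
#' The camera-model BTF is `g(P, k) = exp(b (1 - k^a)) * P^(k^a)`; `a` and `b`
#' are camera-response constants and `mu` shapes the illumination weight
#' `W = T^mu` (T = per-pixel channel maximum). Defaults are the standard
#' instantiation of the exposure-fusion framework the enhancement follows.
#'
#' @param a,b BTF camera-response parameters.
#' @param mu illumination weight exponent, in (0, 1].
#' @param grid candidate exposure ratios (> 1) searched by
#'   [find_exposure_ratio()]. The default reaches high ratios so that even
#'   severely under-exposed input is lifted in a single pass (after which a
#'   second pass degenerates to the smallest ratio and the enhancement
#'   saturates).
#' @return an `enhance_config` list.
#' @export
enhance_config <- function(a = -0.3293, b = 1.1258, mu = 0.5,
                           grid = c(1.5, 2, 3, 4, 6, 8, 12, 16, 24)) {
  fm_assert(mu > 0 && mu <= 1, "config", "mu must lie in (0, 1]")
  fm_assert(length(grid) >= 1 && all(grid > 1), "config",
            "exposure-ratio grid must be non-empty with all ratios > 1")
  structure(list(a = a, b = b, mu = mu, grid = sort(grid)),
            class = "enhance_config")
}

#' Brightness transform function (BTF)
#'
#' Simulates an exposure of the input at ratio `k`:
#' `g(P, k) = exp(b (1 - k^a)) * P^(k^a)`, applied pixelwise per channel and
#' clipped to [0, 1]. At `k = 1` this is the identity; black is a fixed point
#' for any `k`; the map is monotone non-decreasing in input intensity.
#'
#' @param image H x W x 3 array in [0, 1].
#' @param exposure_ratio positive exposure ratio `k`.
#' @param config an [enhance_config()] supplying `a` and `b`.
#' @return transformed image in [0, 1].
#' @export
#' @examples
#' img <- array(0.5, dim = c(4, 4, 3))
#' brightness_transform(img, 2)[1, 1, 1]
brightness_transform <- function(image, exposure_ratio, config = enhance_config()) {
  image <- as_image(image)
  check_unit_range(image)
  fm_assert(is.numeric(exposure_ratio) && length(exposure_ratio) == 1 && exposure_ratio > 0,
            "btf", "exposure ratio must be a single value > 0, got %s",
            format(exposure_ratio))
  ka <- exposure_ratio^config$a
  out <- exp(config$b * (1 - ka)) * image^ka
  clamp(out, 0, 1)
}

#' Illumination-based fusion weight map
#'
#' `W = T^mu` with `T(x)` the per-pixel maximum over colour channels (a
#' standard illumination estimate): well-exposed pixels get weight near 1 and
#' keep the original image; dark pixels get low weight and are dominated by
#' the brightened exposure.
#'
#' @param image H x W x 3 array in [0, 1].
#' @param mu exponent in (0, 1].
#' @return H x W matrix in [0, 1].
#' @export
estimate_weight_map <- function(image, mu = 0.5) {
  image <- as_image(image)
  check_unit_range(image)
  fm_assert(mu > 0 && mu <= 1, "weight", "mu must lie in (0, 1]")
  d <- dim(image)
  t_ilm <- pmax(matrix(image[, , 1], d[1], d[2]),
                matrix(image[, , 2], d[1], d[2]),
                matrix(image[, , 3], d[1], d[2]))
  t_ilm^mu
}

#' Select the exposure ratio for the synthetic exposure
#'
#' Evaluates each candidate ratio on the under-exposed pixels (weight < 0.5)
#' and returns the one maximising the Shannon entropy of their brightness
#' histogram after transformation — the ratio that reveals the most detail in
#' the dark regions. Ties, and images with no under-exposed pixels, resolve to
#' the smallest grid ratio.
#'
#' @param image H x W x 3 array in [0, 1].
#' @param config an [enhance_config()] (supplies the candidate `grid`, BTF
#'   constants and `mu`).
#' @return a single exposure ratio from the grid.
#' @export
find_exposure_ratio <- function(image, config = enhance_config()) {
  image <- as_image(image)
  grid <- config$grid
  fm_assert(length(grid) >= 1, "ratio", "empty exposure-ratio grid")
  w <- estimate_weight_map(image, config$mu)
  under <- w < 0.5
  if (!any(under)) return(grid[1])
  ent <- vapply(grid, function(k) {
    tr <- brightness_transform(image, k, config)
    v <- to_gray(tr)[under]
    shannon_entropy(v)
  }, numeric(1))
  grid[which.max(ent)]  # which.max takes the first (smallest) on ties
}

shannon_entropy <- function(v, bins = 64L) {
  h <- tabulate(pmin(bins, floor(v * bins) + 1L), nbins = bins)
  p <- h / sum(h)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Construct an exposure set for fusion
#'
#' @param images list of H x W x 3 arrays sharing one shape.
#' @param weights list of H x W weight maps; must sum to 1 at every pixel
#'   (within 1e-6).
#' @param ratios exposure ratios `k_i` (> 0), one per image.
#' @return an `exposure_set`.
#' @export
exposure_set <- function(images, weights, ratios) {
  fm_assert(length(images) >= 1, "fusion", "exposure set needs N >= 1 images")
  fm_assert(length(weights) == length(images) && length(ratios) == length(images),
            "fusion", "need one weight map and one ratio per image")
  fm_assert(all(ratios > 0), "fusion", "exposure ratios must be > 0")
  d <- dim(as_image(images[[1]]))
  images <- lapply(images, as_image)
  for (i in seq_along(images)) {
    fm_assert(identical(dim(images[[i]]), d), "fusion",
              "exposure %d has mismatched shape", i)
    fm_assert(identical(dim(weights[[i]]), d[1:2]), "fusion",
              "weight map %d has mismatched shape", i)
  }
  wsum <- Reduce(`+`, weights)
  fm_assert(max(abs(wsum - 1)) < 1e-6, "fusion",
            "weight maps must sum to 1 at every pixel (max dev %.2e)",
            max(abs(wsum - 1)))
  structure(list(images = images, weights = weights, ratios = ratios),
            class = "exposure_set")
}

#' Fuse an exposure set into one image
#'
#' Per channel c, the result is `sum_i W_i * P_i(c)` — a per-pixel convex
#' combination, so the output stays in [0, 1].
#'
#' @param es an [exposure_set()].
#' @return fused H x W x 3 array.
#' @export
fuse_exposures <- function(es) {
  fm_assert(inherits(es, "exposure_set"), "fusion", "expected an exposure_set")
  d <- dim(es$images[[1]])
  out <- array(0, dim = d)
  for (c in 1:3) {
    acc <- matrix(0, d[1], d[2])
    for (i in seq_along(es$images)) acc <- acc + es$weights[[i]] * es$images[[i]][, , c]
    out[, , c] <- acc
  }
  out
}

#' Enhance an image by two-exposure weighted fusion
#'
#' Pipeline: estimate the illumination weight map, pick the exposure ratio on
#' the under-exposed pixels, synthesise the brightened exposure with the BTF,
#' and fuse `(original, brightened)` with weights `(W, 1 - W)`. Well-exposed
#' images pass through nearly unchanged; the mean intensity of under-exposed
#' regions never decreases.
#'
#' @param image H x W x 3 array in [0, 1].
#' @param config an [enhance_config()].
#' @return enhanced image in [0, 1].
#' @export
#' @examples
#' dark <- array(0.2, dim = c(8, 8, 3))
#' mean(enhance(dark)) > mean(dark)
enhance <- function(image, config = enhance_config()) {
  image <- as_image(image)
  check_unit_range(image)
  w <- estimate_weight_map(image, config$mu)
  k <- find_exposure_ratio(image, config)
  bright <- brightness_transform(image, k, config)
  es <- exposure_set(list(image, bright), list(w, 1 - w), c(1, k))
  clamp(fuse_exposures(es), 0, 1)
}

#' Augmentation configuration
#'
#' Mirrors the augmentation protocol: a 90-degree rotation variant and a
#' centre-zoom variant with factor drawn uniformly from the zoom range
#' (factors below 1 crop centrally, then rescale to the original size).
#'
#' @param rotate emit the 90-degree rotation variant.
#' @param zoom zoom-factor range, within (0, 2].
#' @param mirror additionally emit a horizontal mirror variant (off by
#'   default; the protocol's "flipping 90" is read as rotation).
#' @param seed integer seed for the zoom draw.
#' @return an `augment_config` list.
#' @export
augment_config <- function(rotate = TRUE, zoom = c(0.5, 1.0), mirror = FALSE, seed = 0L) {
  fm_assert(length(zoom) == 2 && zoom[1] <= zoom[2] && zoom[1] > 0 && zoom[2] <= 2,
            "config", "zoom range must lie within (0, 2]")
  structure(list(rotate = isTRUE(rotate), zoom = zoom, mirror = isTRUE(mirror),
                 seed = as.integer(seed)),
            class = "augment_config")
}

center_zoom <- function(image, factor) {
  if (abs(factor - 1) < 1e-12) return(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  ch <- max(2, round(h * factor)); cw <- max(2, round(w * factor))
  y0 <- floor((h - ch) / 2) + 1L; x0 <- floor((w - cw) / 2) + 1L
  crop <- image[y0:(y0 + ch - 1L), x0:(x0 + cw - 1L), , drop = FALSE]
  bilinear_resize(crop, h, w)
}

#' Augment one image
#'
#' Emits the original plus one variant per enabled kind (rotation, zoom,
#' optional mirror); the zoom factor is drawn once per call under the config
#' seed, so the output is deterministic.
#'
#' @param image H x W x 3 array in [0, 1].
#' @param config an [augment_config()].
#' @return list of images; length `1 + number of enabled variant kinds`.
#' @export
augment <- function(image, config = augment_config()) {
  image <- as_image(image)
  out <- list(image)
  if (config$rotate) out <- c(out, list(rotate90(image)))
  zf <- with_seed(config$seed, stats::runif(1, config$zoom[1], config$zoom[2]))
  out <- c(out, list(clamp(center_zoom(image, zf), 0, 1)))
  if (config$mirror) out <- c(out, list(mirror_flip(image)))
  out
}

#' Augment a dataset of labelled images
#'
#' @param dataset list of `labeled_image`.
#' @param config an [augment_config()]; each image uses a seed derived from
#'   the config seed and its index.
#' @return expanded list of `labeled_image` (variants inherit the label).
#' @export
augment_dataset <- function(dataset, config = augment_config()) {
  out <- list()
  for (i in seq_along(dataset)) {
    img <- dataset[[i]]
    cfg_i <- config
    cfg_i$seed <- stage_seed(config$seed, paste0("augment", i))
    vars <- augment(img$pixels, cfg_i)
    out <- c(out, lapply(vars, function(px) {
      structure(list(pixels = px, label = img$label, meta = img$meta),
                class = "labeled_image")
    }))
  }
  out
}
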