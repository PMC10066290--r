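## Synthetic two-class bite-mark images.
##
## The study's clinical photographs are private, so every downstream stage is
## exercised on generated images that keep the one signal the classes rely on:
## venomous fang punctures (two large elliptical marks at a sampled inter-fang
## distance) versus a non-venomous tooth row (a curved double arc of many small
## marks). Skin is a smooth low-frequency texture; acquisition quality is
## emulated with a global brightness scale and additive Gaussian noise.

#' Configuration for the synthetic bite-mark generator
#'
#' @param size image side in pixels (square images), >= 32.
#' @param fang_dist inter-fang distance range, in pixels at `size = 256`
#'   (scaled proportionally for other sizes).
#' @param puncture_radius fang puncture radius range (same pixel scale).
#' @param bg_amp amplitude of the smooth background skin texture.
#' @param brightness global brightness scale range; the low end emulates the
#'   poorly lit field photographs the enhancement stage exists for.
#' @param noise_sd additive Gaussian noise standard-deviation range.
#' @return a `generator_config` list.
#' @export
#' @examples
#' cfg <- generator_config(size = 64)
generator_config <- function(size = 256L,
                             fang_dist = c(40, 70),
                             puncture_radius = c(20, 30),
                             bg_amp = 0.06,
                             brightness = c(0.3, 1.0),
                             noise_sd = c(0.0, 0.05)) {
  fm_assert(size >= 32, "config", "image size must be >= 32, got %s", format(size))
  for (nm in c("fang_dist", "puncture_radius", "brightness", "noise_sd")) {
    r <- get(nm)
    fm_assert(length(r) == 2 && r[2] >= r[1], "config", "%s must be a non-empty range", nm)
  }
  fm_assert(bg_amp >= 0, "config", "bg_amp must be >= 0")
  structure(list(size = as.integer(size), fang_dist = fang_dist,
                 puncture_radius = puncture_radius, bg_amp = bg_amp,
                 brightness = brightness, noise_sd = noise_sd),
            class = "generator_config")
}

bite_labels <- function() c("cobra", "other")

## smooth pseudo-skin background: a warm base plus a few random sinusoids
skin_background <- function(size, amp) {
  xs <- seq(0, 1, length.out = size)
  field <- matrix(0, size, size)
  for (i in 1:4) {
    fx <- stats::runif(1, 1, 4); fy <- stats::runif(1, 1, 4)
    px <- stats::runif(1, 0, 2 * pi); py <- stats::runif(1, 0, 2 * pi)
    field <- field + outer(sin(2 * pi * fy * xs + py), sin(2 * pi * fx * xs + px)) / i
  }
  0.8 + amp * field / max(abs(field), 1e-12)
}

## subtract a soft (Gaussian-profile) elliptical mark from one channel matrix
stamp_mark <- function(mat, cx, cy, rx, ry, angle, depth, xx, yy) {
  dx <- xx - cx; dy <- yy - cy
  u <- cos(angle) * dx + sin(angle) * dy
  v <- -sin(angle) * dx + cos(angle) * dy
  mat - depth * exp(-((u / rx)^2 + (v / ry)^2))
}

#' Generate one labelled synthetic bite-mark image
#'
#' Cobra images carry exactly two elliptical fang punctures separated by a
#' sampled inter-fang distance; "other" images carry a curved double row of at
#' least six small tooth marks. Mark centres are recorded in the metadata.
#' Output is deterministic for a fixed `(label, config, seed)`.
#'
#' @param label `"cobra"` or `"other"`.
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @return a `labeled_image`: list with `pixels` (H x W x 3 in [0, 1]),
#'   `label`, and `meta` (mark `centers`, `brightness`, `noise_sd`, `seed`).
#' @export
#' @examples
#' img <- generate_bite_image("cobra", generator_config(size = 64), seed = 7)
#' nrow(img$meta$centers)  # 2 fang punctures
generate_bite_image <- function(label, config = generator_config(), seed = 0L) {
  fm_assert(inherits(config, "generator_config"), "config", "config must be a generator_config")
  fm_assert(is.character(label) && length(label) == 1 && label %in% bite_labels(),
            "label", "unknown label '%s' (expected one of: %s)",
            paste(label, collapse = ","), paste(bite_labels(), collapse = ", "))
  with_seed(seed, {
    n <- config$size
    sc <- n / 256                       # pixel-scale factor relative to reference size
    xx <- matrix(seq_len(n), n, n, byrow = TRUE)
    yy <- matrix(seq_len(n), n, n)
    base <- skin_background(n, config$bg_amp)
    ## pattern anchored near the image centre with modest jitter: keeps the
    ## two classes linearly separable at thumbnail resolution
    cx0 <- n / 2 + stats::runif(1, -0.05, 0.05) * n
    cy0 <- n / 2 + stats::runif(1, -0.05, 0.05) * n
    theta <- stats::runif(1, 0, pi)
    centers <- NULL
    ## Both classes draw their total mark darkness (integrated depth x area)
    ## from one shared distribution, then scale stamp depths to hit it: the
    ## classes differ in spatial layout (two central punctures vs a
    ## peripheral tooth ring), not in overall darkness, so class identity
    ## stays orthogonal to the global brightness axis.
    marks <- NULL
    if (label == "cobra") {
      d <- stats::runif(1, config$fang_dist[1], config$fang_dist[2]) * sc
      r <- stats::runif(1, config$puncture_radius[1], config$puncture_radius[2]) * sc
      for (s in c(-0.5, 0.5)) {
        marks <- rbind(marks, data.frame(
          cx = cx0 + s * d * cos(theta), cy = cy0 + s * d * sin(theta),
          rx = r, ry = r * stats::runif(1, 1.3, 1.6), angle = theta + pi / 2,
          depth = stats::runif(1, 0.45, 0.6)))
      }
    } else {
      ## curved double row of small tooth marks along an arc
      n_teeth <- sample(6:9, 1)
      arc_r <- stats::runif(1, 0.24, 0.30) * n
      span <- stats::runif(1, 1.8, 2.4)      # radians of arc covered
      angs <- theta + seq(-span / 2, span / 2, length.out = n_teeth)
      rt <- stats::runif(1, 9.5, 11.5) * sc * sqrt(7 / n_teeth)
      for (row_off in c(-0.04, 0.04) * n) {
        for (a in angs) {
          marks <- rbind(marks, data.frame(
            cx = cx0 + (arc_r + row_off) * cos(a) + stats::rnorm(1, 0, 0.5 * sc),
            cy = cy0 + (arc_r + row_off) * sin(a) + stats::rnorm(1, 0, 0.5 * sc),
            rx = rt, ry = rt * stats::runif(1, 1.0, 1.3), angle = a,
            depth = stats::runif(1, 0.4, 0.5)))
        }
      }
    }
    ## normalise total ink (a Gaussian stamp integrates depth * pi * rx * ry)
    ink_target <- stats::runif(1, 0.9, 1.1) * 3200 * sc^2
    ink_raw <- sum(marks$depth * pi * marks$rx * marks$ry)
    marks$depth <- pmin(0.65, marks$depth * ink_target / ink_raw)
    for (j in seq_len(nrow(marks))) {
      base <- stamp_mark(base, marks$cx[j], marks$cy[j], marks$rx[j], marks$ry[j],
                         marks$angle[j], marks$depth[j], xx, yy)
    }
    centers <- cbind(x = marks$cx, y = marks$cy)
    bright <- stats::runif(1, config$brightness[1], config$brightness[2])
    sdn <- stats::runif(1, config$noise_sd[1], config$noise_sd[2])
    pix <- array(0, dim = c(n, n, 3L))
    tint <- c(1.0, 0.82, 0.72)          # skin tone across R, G, B
    for (c in 1:3) {
      ch <- base * tint[c] * bright
      if (sdn > 0) ch <- ch + matrix(stats::rnorm(n * n, 0, sdn), n, n)
      pix[, , c] <- ch
    }
    pix <- clamp(pix, 0, 1)
    structure(list(pixels = pix, label = label,
                   meta = list(centers = centers, brightness = bright,
                               noise_sd = sdn, seed = as.integer(seed))),
              class = "labeled_image")
  })
}

#' Generate a labelled synthetic dataset
#'
#' Per-image seeds are derived deterministically from the master seed, so the
#' dataset is reproducible and any single image can be regenerated in
#' isolation from its recorded seed.
#'
#' @param n_cobra,n_other non-negative class counts. Defaults follow the
#'   study's stated collection of 500 cobra and 600 other-species images.
#' @param config a [generator_config()].
#' @param seed master integer seed.
#' @return list of `labeled_image`, cobra images first.
#' @export
generate_dataset <- function(n_cobra = 500L, n_other = 600L,
                             config = generator_config(), seed = 0L) {
  fm_assert(n_cobra >= 0 && n_other >= 0, "count",
            "class counts must be >= 0, got (%s, %s)", n_cobra, n_other)
  labels <- rep(bite_labels(), times = c(n_cobra, n_other))
  seeds <- (as.numeric(seed) * 7919 + seq_along(labels) * 104729) %% 2147483629
  mapply(function(lb, sd) generate_bite_image(lb, config, as.integer(sd)),
         labels, seeds, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Generate a synthetic per-state snakebite epidemiology table
#'
#' Each state row carries the total bite count `n`, deaths `d`, and blind or
#' otherwise dangerous cases `p`, with `p + d <= n` guaranteed — the inputs of
#' the edge-node profit objective.
#'
#' @param n_states number of states, >= 0.
#' @param seed integer seed.
#' @return data.frame with columns `state`, `n`, `d`, `p`.
#' @export
generate_state_table <- function(n_states, seed = 0L) {
  fm_assert(n_states >= 0, "count", "n_states must be >= 0")
  if (n_states == 0) {
    return(data.frame(state = character(), n = integer(), d = integer(), p = integer()))
  }
  with_seed(seed, {
    n <- pmax(1L, stats::rpois(n_states, lambda = 400))
    d <- stats::rbinom(n_states, n, prob = 0.03)
    p <- stats::rbinom(n_states, n - d, prob = 0.08)
    data.frame(state = sprintf("S%02d", seq_len(n_states)), n = n, d = d, p = p)
  })
}

validate_state_table <- function(epi) {
  fm_assert(is.data.frame(epi) && all(c("n", "d", "p") %in% names(epi)),
            "epi", "epidemiology table needs columns n, d, p")
  fm_assert(all(epi$n >= 1), "epi", "state bite counts n must be >= 1")
  fm_assert(all(epi$d >= 0) && all(epi$p >= 0), "epi", "d and p must be >= 0")
  fm_assert(all(epi$p + epi$d <= epi$n), "epi", "p + d must not exceed n")
  invisible(epi)
}

#' Write a generated dataset to disk
#'
#' Images go to `<dir>/images/*.png`; a manifest CSV (`path,label,seed`) goes
#' to `<dir>/manifest.csv`.
#'
#' @param dataset list of `labeled_image`.
#' @param dir output directory (created if needed).
#' @return the manifest data.frame, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  img_dir <- file.path(dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(dataset), function(i) {
    img <- dataset[[i]]
    path <- file.path(img_dir, sprintf("%s_%04d.png", img$label, i))
    write_image(img$pixels, path)
    data.frame(path = path, label = img$label, seed = img$meta$seed)
  })
  manifest <- do.call(rbind, rows)
  if (is.null(manifest)) manifest <- data.frame(path = character(), label = character(),
                                                seed = integer())
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
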