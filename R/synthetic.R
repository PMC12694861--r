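# Seeded generator of grayscale fruit-quality image datasets: a bright disc
# ("fruit") on a dark background, with a class-dependent density of dark
# circular blemishes ("rot spots") plus Gaussian pixel noise. The three
# default classes model fresh / mild / rotten produce.

#' Specification of a synthetic fruit-quality dataset
#'
#' Defaults mirror the three-class, 150-image balanced study design
#' (50 images per class) at a desk-scale 16x16 resolution; 100x100 images
#' are supported through `image_size`. `spot_density` is the expected
#' fraction of the fruit disc covered by blemishes, and must increase
#' strictly with class index so the class signal is monotone.
#'
#' @param n_classes Number of classes (default 3: fresh / mild / rotten).
#' @param image_size Even side length in pixels.
#' @param n_per_class Images per class.
#' @param spot_density Per-class expected blemish coverage in `[0, 1]`,
#'   strictly increasing.
#' @param spot_radius Blemish radius in pixels.
#' @param background_level Background intensity in `[0, 1]`.
#' @param fruit_level Disc intensity in `[0, 1]`.
#' @param spot_level Blemish intensity in `[0, 1]`.
#' @param noise_sd Gaussian pixel-noise standard deviation.
#' @param seed Integer seed; generation is bit-reproducible.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_classes = 3L, image_size = 16L, n_per_class = 50L,
                           spot_density = c(0, 0.15, 0.4), spot_radius = 0.8,
                           background_level = 0.15, fruit_level = 0.85,
                           spot_level = 0.25, noise_sd = 0.05, seed = 1L) {
  if (image_size %% 2L != 0L) stop("image_size must be even")
  if (n_per_class < 1L) stop("n_per_class must be positive")
  if (length(spot_density) != n_classes) {
    stop("spot_density needs one value per class")
  }
  if (any(diff(spot_density) <= 0)) {
    stop("spot_density must be strictly increasing across classes")
  }
  if (any(spot_density < 0 | spot_density > 1)) stop("spot_density in [0,1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(n_classes = as.integer(n_classes),
                 image_size = as.integer(image_size),
                 n_per_class = as.integer(n_per_class),
                 spot_density = as.numeric(spot_density),
                 spot_radius = spot_radius,
                 background_level = background_level,
                 fruit_level = fruit_level, spot_level = spot_level,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

render_image <- function(spec) {
  s <- spec$image_size
  ctr <- (s + 1) / 2 + stats::runif(2L, -0.5, 0.5)
  r_disc <- 0.38 * s * stats::runif(1L, 0.98, 1.02)
  gx <- matrix(rep(seq_len(s), each = s), s, s)    # column index
  gy <- matrix(rep(seq_len(s), times = s), s, s)   # row index
  d2 <- (gy - ctr[1L])^2 + (gx - ctr[2L])^2
  img <- matrix(spec$background_level, s, s)
  img[d2 <= r_disc^2] <- spec$fruit_level
  img
}

add_spots <- function(img, spec, density) {
  if (density <= 0) return(img)
  s <- spec$image_size
  ctr <- (s + 1) / 2
  r_disc <- 0.38 * s
  mean_count <- density * (r_disc / spec$spot_radius)^2
  count <- stats::rpois(1L, mean_count)
  if (count == 0L) return(img)
  # spot centres uniform in the disc
  ang <- stats::runif(count, 0, 2 * pi)
  rad <- r_disc * sqrt(stats::runif(count))
  cy <- ctr + rad * sin(ang); cx <- ctr + rad * cos(ang)
  gx <- matrix(rep(seq_len(s), each = s), s, s)
  gy <- matrix(rep(seq_len(s), times = s), s, s)
  for (i in seq_len(count)) {
    hit <- (gy - cy[i])^2 + (gx - cx[i])^2 <= spec$spot_radius^2
    img[hit] <- spec$spot_level
  }
  img
}

#' Generate a synthetic fruit-quality dataset
#'
#' Produces `n_classes * n_per_class` images (balanced, labels 0-based,
#' class-blocked order) with pixel values clipped to `[0, 1]`. Identical
#' specs give bit-identical arrays.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `synthetic_dataset`: `images`
#'   (`n x size x size` array), `labels` (integer vector) and `spec`.
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_classes * spec$n_per_class
  images <- array(0, dim = c(n, spec$image_size, spec$image_size))
  labels <- integer(n)
  local_seed(spec$seed, {
    i <- 0L
    for (cls in seq_len(spec$n_classes) - 1L) {
      for (rep in seq_len(spec$n_per_class)) {
        i <- i + 1L
        img <- render_image(spec)
        img <- add_spots(img, spec, spec$spot_density[cls + 1L])
        if (spec$noise_sd > 0) {
          img <- img + matrix(stats::rnorm(length(img), 0, spec$noise_sd),
                              nrow(img), ncol(img))
        }
        images[i, , ] <- pmin(pmax(img, 0), 1)
        labels[i] <- cls
      }
    }
  })
  structure(list(images = images, labels = labels, spec = spec),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> ", length(x$labels), " images (",
      x$spec$image_size, "x", x$spec$image_size, "), ",
      x$spec$n_classes, " classes\n", sep = "")
  invisible(x)
}

#' Mean-intensity separability of a dataset
#'
#' A deliberately weak baseline: each image is reduced to its mean pixel
#' intensity, per-class intensity means are fitted on a train split, and
#' held-out images are assigned to the nearest class mean. Guards that the
#' generator emits a learnable task (blemishes darken the image
#' monotonically with class).
#'
#' @param dataset A `synthetic_dataset` (or list with `images`, `labels`).
#' @param train_frac Fraction used for fitting the class means.
#' @param seed Split seed.
#' @return Holdout accuracy in `[0, 1]`.
#' @export
separability_check <- function(dataset, train_frac = 0.7, seed = 1L) {
  labels <- as.integer(dataset$labels)
  if (length(unique(labels)) < 2L) stop("separability needs >= 2 classes")
  m <- apply(dataset$images, 1L, mean)
  n <- length(labels)
  idx <- local_seed(seed, sample.int(n))
  ntr <- max(2L, floor(train_frac * n))
  tr <- idx[seq_len(ntr)]; te <- idx[(ntr + 1L):n]
  centers <- tapply(m[tr], labels[tr], mean)
  cls <- as.integer(names(centers))
  pred <- cls[apply(abs(outer(m[te], centers, `-`)), 1L, which.min)]
  mean(pred == labels[te])
}

#' Save / load a dataset
#'
#' `save_dataset()` writes the images, labels and full spec echo to a
#' single RDS file; `load_dataset()` restores it with validation. The
#' round trip is exact.
#'
#' @param dataset A `synthetic_dataset`.
#' @param path File path to write/read.
#' @return `save_dataset()` the path invisibly; `load_dataset()` the
#'   dataset.
#' @export
save_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  saveRDS(dataset, path)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) {
  if (!file.exists(path)) stop("no such dataset file: ", path)
  x <- readRDS(path)
  if (!inherits(x, "synthetic_dataset") || is.null(x$images) || is.null(x$labels)) {
    stop("corrupt dataset file: ", path)
  }
  x
}

#' Export a dataset as PNG files plus a labels CSV
#'
#' Each image becomes an 8-bit grayscale PNG (`img_00001.png`, ...) and
#' `labels.csv` records filename and label. Quantisation to 8 bits means a
#' reloaded pixel differs from the original by at most `1/255 / 2` plus
#' rounding, i.e. `<= 1/255`.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
export_png <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(dataset$labels)
  files <- sprintf("img_%05d.png", seq_len(n))
  for (i in seq_len(n)) {
    png::writePNG(dataset$images[i, , ], file.path(dir, files[i]))
  }
  utils::write.csv(data.frame(file = files, label = dataset$labels),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a PNG directory back into image arrays
#'
#' @param dir Directory written by [export_png()].
#' @return A list with `images` and `labels`.
#' @export
import_png <- function(dir) {
  lab <- utils::read.csv(file.path(dir, "labels.csv"))
  imgs <- lapply(file.path(dir, lab$file), function(f) {
    m <- png::readPNG(f)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    m
  })
  n <- length(imgs)
  arr <- array(0, dim = c(n, nrow(imgs[[1L]]), ncol(imgs[[1L]])))
  for (i in seq_len(n)) arr[i, , ] <- imgs[[i]]
  list(images = arr, labels = as.integer(lab$label))
}

#' Augment a dataset for classical baselines
#'
#' Random affine augmentation in the style used for classical baseline
#' training on small sets: rotation up to 15 degrees, width/height shift up
#' to 0.1 of the image size, shear up to 0.1, zoom up to 0.1, and a
#' horizontal flip with probability 0.5, with nearest-pixel fill. The
#' quantum training path deliberately uses no augmentation (the extractor's
#' four measurement channels already enrich the representation), so this is
#' an opt-in tool for classical-model comparisons.
#'
#' @param dataset A `synthetic_dataset` (or list with `images`, `labels`).
#' @param times How many augmented copies per original image.
#' @param seed Integer seed.
#' @param rotation,shift,shear,zoom,hflip Augmentation ranges/switch.
#' @return A list with `images` (originals followed by augmented copies)
#'   and matching `labels`.
#' @export
augment_dataset <- function(dataset, times = 1L, seed = 1L,
                            rotation = 15, shift = 0.1, shear = 0.1,
                            zoom = 0.1, hflip = TRUE) {
  imgs <- dataset$images
  labels <- as.integer(dataset$labels)
  n <- dim(imgs)[1L]; s <- dim(imgs)[2L]
  aug <- local_seed(seed, {
    out <- array(0, dim = c(n * times, s, s))
    for (t in seq_len(times)) for (i in seq_len(n)) {
      out[(t - 1L) * n + i, , ] <- affine_augment(
        imgs[i, , ],
        ang = stats::runif(1, -rotation, rotation) * pi / 180,
        dy = stats::runif(1, -shift, shift) * s,
        dx = stats::runif(1, -shift, shift) * s,
        sh = stats::runif(1, -shear, shear),
        zm = 1 + stats::runif(1, -zoom, zoom),
        flip = hflip && stats::runif(1) < 0.5)
    }
    out
  })
  all_imgs <- array(0, dim = c(n * (1L + times), s, s))
  all_imgs[seq_len(n), , ] <- imgs
  all_imgs[(n + 1L):(n * (1L + times)), , ] <- aug
  list(images = all_imgs, labels = c(labels, rep(labels, times)))
}

# Inverse-mapped affine warp with nearest-neighbour sampling and
# nearest-edge fill.
affine_augment <- function(img, ang, dy, dx, sh, zm, flip) {
  s <- nrow(img)
  ctr <- (s + 1) / 2
  co <- cos(ang) / zm; si <- sin(ang) / zm
  out <- matrix(0, s, s)
  yy <- rep(seq_len(s), times = s) - ctr
  xx <- rep(seq_len(s), each = s) - ctr
  if (flip) xx <- -xx
  # inverse map: rotate/zoom, shear, then shift
  sy <- co * yy - si * xx + sh * xx - dy + ctr
  sx <- si * yy + co * xx - dx + ctr
  sy <- pmin(pmax(round(sy), 1L), s)
  sx <- pmin(pmax(round(sx), 1L), s)
  out[cbind(rep(seq_len(s), times = s), rep(seq_len(s), each = s))] <-
    img[cbind(sy, sx)]
  out
}
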