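#' Gaussian noise specification
#'
#' Zero-mean additive Gaussian pixel noise on the [0, 1] scale, applied
#' pixel-wise and per-channel independently. The draw is fully determined
#' by `seed`.
#'
#' @param sigma Standard deviation in pixel units; the sweep grid used by
#'   the robustness protocol is 0.01, 0.05, 0.10, 0.15, 0.20, with 0.10 the
#'   default training setting.
#' @param seed Seed for the noise field.
#' @param clip Clip the noisy image back to [0, 1] (disable for moment
#'   checks).
#' @param apply_to `"train"`: evaluation splits stay clean.
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(sigma = 0.10, seed = 1L, clip = TRUE,
                       apply_to = "train") {
  if (sigma < 0) stop("sigma must be nonnegative")
  structure(list(sigma = sigma, seed = as.integer(seed), clip = clip,
                 apply_to = apply_to), class = "noise_spec")
}

#' Inject Gaussian pixel noise
#'
#' Adds independent `N(0, sigma^2)` noise to every pixel of every channel.
#' Deterministic under the spec's seed; the ambient RNG state is preserved.
#'
#' @param image Array in [0, 1]; any shape (single image or batch).
#' @param ns A [noise_spec()].
#' @return Noisy array of the same shape.
#' @export
inject_gaussian_noise <- function(image, ns) {
  if (ns$sigma < 0) stop("sigma must be nonnegative")
  if (ns$sigma == 0) return(image)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(ns$seed)
  out <- image + array(rnorm(length(image), 0, ns$sigma),
                       dim(image) %||% length(image))
  if (isTRUE(ns$clip)) out <- pmin(pmax(out, 0), 1)
  out
}

#' Preprocessing specification
#'
#' Bilinear resize, center crop, and per-channel standardization with the
#' conventional ImageNet statistics.
#'
#' @param resize_to Resize side (default 550).
#' @param crop_to Center-crop side (default 448); must not exceed
#'   `resize_to`.
#' @param means,sds Per-channel normalization constants.
#' @return Object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(resize_to = 550L, crop_to = 448L,
                            means = c(0.485, 0.456, 0.406),
                            sds = c(0.229, 0.224, 0.225)) {
  if (crop_to > resize_to) stop("crop_to must not exceed resize_to")
  structure(list(resize_to = as.integer(resize_to),
                 crop_to = as.integer(crop_to), means = means, sds = sds),
            class = "preprocess_spec")
}

#' Preprocess one RGB image
#'
#' Bilinear resize to `resize_to` square, center crop to `crop_to`, then
#' per-channel standardization `(x - mean_c) / sd_c` on the [0, 1] scale.
#'
#' @param image H x W x 3 array in [0, 1].
#' @param ps A [preprocess_spec()].
#' @return `crop_to` x `crop_to` x 3 standardized array.
#' @export
preprocess_image <- function(image, ps = preprocess_spec()) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) stop("input must be an RGB image")
  r <- EBImage::resize(image, w = ps$resize_to, h = ps$resize_to)
  off <- (ps$resize_to - ps$crop_to) %/% 2L
  idx <- seq.int(off + 1L, off + ps$crop_to)
  cr <- r[idx, idx, , drop = FALSE]
  for (c in 1:3) cr[, , c] <- (cr[, , c] - ps$means[c]) / ps$sds[c]
  cr
}

# ---- procedural toy dataset ----------------------------------------------

# derived sub-seed, kept inside 32-bit integer range
sub_seed <- function(seed, a, b = 0L) {
  as.integer((as.double(seed) * 7919 + a * 1009 + b * 13) %% 2147483629)
}

# class recipe: shared food-like palette with a small class-specific shift
# (inter-class color overlap) and a class-specific texture scale within a
# family (the fine-grained discriminative signal). Consecutive classes
# share the texture family and differ only in its scale, so small class
# sets are genuinely fine-grained; texture contrast is kept low enough
# that heavy pixel noise measurably degrades a clean-trained classifier.
class_recipe <- function(k, contrast = 0.08) {
  fams <- c("stripes", "blobs", "granules")
  base <- c(0.55, 0.45, 0.35) +
    0.06 * c(sin(1.7 * k), cos(2.3 * k), sin(3.1 * k + 1))
  sc <- (k - 1L) %% 3L
  list(family = fams[(k - 1L) %/% 3L %% 3L + 1L],
       base = pmin(pmax(base, 0.15), 0.85),
       freq = 3 + 1.6 * sc,
       n_blob = 5L + 4L * sc,
       radius = 0.25 / (1 + 0.7 * sc),
       smooth = 1L + 2L * sc,
       chroma = contrast * c(1, -0.6, 0.3) * (1 + 0.15 * sin(k)))
}

render_toy_image <- function(recipe, size) {
  u <- matrix(seq(-1, 1, length.out = size), size, size)
  v <- t(u)
  s <- runif(1, 0.8, 1.25)
  th <- runif(1, 0, pi)
  bright <- runif(1, -0.08, 0.08)
  ur <- (u * cos(th) + v * sin(th)) / s
  vr <- (-u * sin(th) + v * cos(th)) / s
  tex <- switch(recipe$family,
    stripes = sin(2 * pi * recipe$freq * ur) *
      (0.7 + 0.3 * sin(2 * pi * 0.7 * recipe$freq * vr)),
    blobs = {
      t0 <- matrix(0, size, size)
      for (i in seq_len(recipe$n_blob)) {
        cu <- runif(1, -0.8, 0.8); cv <- runif(1, -0.8, 0.8)
        t0 <- t0 + exp(-((ur - cu)^2 + (vr - cv)^2) / recipe$radius^2)
      }
      2 * t0 / max(max(t0), 1e-9) - 1
    },
    granules = {
      w <- matrix(rnorm(size^2), size, size)
      k <- recipe$smooth
      if (k > 0) {
        for (rep in seq_len(k)) {
          w <- (w + rbind(w[-1, ], w[nrow(w), ]) +
                  rbind(w[1, ], w[-nrow(w), ]) +
                  cbind(w[, -1], w[, ncol(w)]) +
                  cbind(w[, 1], w[, -ncol(w)])) / 5
        }
      }
      w / max(abs(w))
    })
  img <- array(0, c(size, size, 3))
  for (c in 1:3) {
    img[, , c] <- recipe$base[c] + recipe$chroma[c] * tex + bright +
      0.02 * matrix(rnorm(size^2), size, size)
  }
  pmin(pmax(img, 0), 1)
}

#' Generate a toy labelled image dataset
#'
#' Writes a procedurally generated, fully seeded image classification
#' dataset in one-directory-per-class PNG layout with train/val/test
#' splits. Classes share overlapping colour palettes but differ in texture
#' family and scale, emulating the inter-class similarity / intra-class
#' variability of fine-grained recognition; per-image jitter of scale,
#' rotation and brightness supplies intra-class variation.
#'
#' @param n_classes At least 2.
#' @param per_class Images per class (at least 6, so every split is
#'   populated).
#' @param image_size Square image side; default 64.
#' @param seed Root seed; the dataset is bit-exactly regenerable from it.
#' @param dir Output directory.
#' @param split Train/val/test fractions; default 60/10/30.
#' @return A `dataset_manifest` list (also written as `manifest.json`).
#' @export
generate_toy_dataset <- function(n_classes, per_class, image_size = 64L,
                                 seed = 1L, dir = tempfile("toyfood"),
                                 split = c(0.6, 0.1, 0.3)) {
  if (n_classes < 2) stop("need at least 2 classes")
  n_tr <- max(1L, round(split[1] * per_class))
  n_va <- max(1L, round(split[2] * per_class))
  n_te <- per_class - n_tr - n_va
  if (per_class < 6 || n_te < 1) {
    stop("per_class too small for the split ratios")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  classes <- sprintf("class%02d", seq_len(n_classes))
  files <- NULL
  for (k in seq_len(n_classes)) {
    cdir <- file.path(dir, classes[k])
    dir.create(cdir, showWarnings = FALSE)
    recipe <- class_recipe(k)
    set.seed(sub_seed(seed, k))
    splits <- sample(rep(c("train", "val", "test"), c(n_tr, n_va, n_te)))
    for (j in seq_len(per_class)) {
      set.seed(sub_seed(seed, k, j))
      img <- render_toy_image(recipe, image_size)
      path <- file.path(cdir, sprintf("img%03d.png", j))
      png::writePNG(img, path)
      files <- rbind(files, data.frame(path = path, class = classes[k],
                                       class_idx = k, split = splits[j],
                                       stringsAsFactors = FALSE))
    }
  }
  manifest <- structure(list(classes = classes, files = files,
                             seed = as.integer(seed),
                             image_size = as.integer(image_size),
                             n_classes = as.integer(n_classes),
                             per_class = as.integer(per_class),
                             split = split, dir = dir),
                        class = "dataset_manifest")
  jsonlite::write_json(unclass(manifest),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  manifest
}

#' Load a toy dataset into memory
#'
#' @param manifest A `dataset_manifest`, or the path of a dataset directory
#'   containing `manifest.json`.
#' @return List with `images` (H x W x 3 x n array), `labels` (1..K),
#'   `split` (character vector) and `classes`.
#' @export
load_dataset <- function(manifest) {
  if (is.character(manifest)) {
    m <- jsonlite::read_json(file.path(manifest, "manifest.json"),
                             simplifyVector = TRUE)
    m$files <- as.data.frame(m$files, stringsAsFactors = FALSE)
    manifest <- structure(m, class = "dataset_manifest")
  }
  f <- manifest$files
  n <- nrow(f)
  sz <- manifest$image_size
  images <- array(0, c(sz, sz, 3, n))
  for (i in seq_len(n)) {
    img <- png::readPNG(f$path[i])
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
    images[, , , i] <- img[, , 1:3]
  }
  list(images = images, labels = as.integer(f$class_idx), split = f$split,
       classes = manifest$classes, manifest = manifest)
}

#' Build a noise-sweep set of training variants
#'
#' One training configuration per noise level, all sharing the identical
#' clean test split (the robustness protocol: noise at train time only,
#' clean evaluation).
#'
#' @param base A `dataset_manifest`.
#' @param sigmas Distinct noise standard deviations; default the standard
#'   sweep grid.
#' @return List of variants, each with `sigma`, a [noise_spec()], and the
#'   shared `manifest`.
#' @export
noise_sweep_manifest <- function(base,
                                 sigmas = c(0.01, 0.05, 0.10, 0.15, 0.20)) {
  if (!length(sigmas)) stop("sigmas must be non-empty")
  if (anyDuplicated(sigmas)) stop("duplicate sigma values")
  lapply(seq_along(sigmas), function(i) {
    list(sigma = sigmas[i],
         noise = noise_spec(sigma = sigmas[i],
                            seed = sub_seed(base$seed, 777L, i)),
         manifest = base)
  })
}
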