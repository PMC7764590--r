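#' Convert an RGB raster to grayscale luminance
#'
#' Uses the Rec. 601 weights `0.299 R + 0.587 G + 0.114 B`.
#'
#' @param rgb H x W x 3 array in \[0,1\].
#' @return H x W matrix in \[0,1\].
#' @export
to_grayscale <- function(rgb) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    stop("rgb must be an H x W x 3 array")
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

#' Cut a scan into multi-scale training crops
#'
#' Crops of `tile` x `tile` pixels with `overlap` pixels of overlap are cut
#' at full, half and quarter resolution (each scale skipped if the scan's
#' smaller side falls below `tile`), and one whole-scan resize to
#' `tile` x `tile` is always added.  Images are resampled bilinearly,
#' label maps by nearest neighbour.
#'
#' @param scan H x W grayscale matrix in \[0,1\].
#' @param labels H x W integer label matrix (codes 0-3; 0 = unlabeled,
#'   excluded from the training loss).
#' @param scan_id Provenance identifier stored in each record.
#' @param tile,overlap Crop geometry (defaults 224 / 100).
#' @return List of `CropRecord`s: each a list with `image`, `label`,
#'   `scan_id`, `scale` (1, 0.5, 0.25 or "global") and `origin`.
#' @export
build_crops <- function(scan, labels, scan_id = "scan", tile = 224L, overlap = 100L) {
  if (!all(dim(scan) == dim(labels))) stop("scan/label shape mismatch")
  crops <- list()
  img <- scan; lab <- labels
  for (scale in c(1, 0.5, 0.25)) {
    if (scale < 1) {
      oh <- as.integer(round(nrow(scan) * scale))
      ow <- as.integer(round(ncol(scan) * scale))
      img <- .cpp_resize_bilinear(scan, oh, ow)
      lab <- matrix(as.integer(.cpp_resize_nearest(labels, oh, ow)), oh, ow)
    }
    if (min(dim(img)) < tile) next
    grid <- make_tile_grid(nrow(img), ncol(img), tile, overlap)
    for (i in seq_len(nrow(grid$origins))) {
      r0 <- grid$origins[i, 1]; c0 <- grid$origins[i, 2]
      crops[[length(crops) + 1L]] <-
        list(image = img[(r0 + 1):(r0 + tile), (c0 + 1):(c0 + tile)],
             label = lab[(r0 + 1):(r0 + tile), (c0 + 1):(c0 + tile)],
             scan_id = scan_id, scale = scale, origin = c(r0, c0))
    }
  }
  crops[[length(crops) + 1L]] <-
    list(image = .cpp_resize_bilinear(scan, tile, tile),
         label = matrix(as.integer(.cpp_resize_nearest(labels, tile, tile)),
                        tile, tile),
         scan_id = scan_id, scale = "global", origin = c(0L, 0L))
  crops
}

#' Augmentation configuration
#'
#' Each augmented copy applies a random subset of four operations
#' (horizontal flip, vertical flip, additive white noise, Gaussian blur);
#' every operation is included independently with probability 0.5, and an
#' empty subset is re-drawn so every copy differs from its source.  Flips
#' are applied identically to image and label; noise and blur touch the
#' image only.
#'
#' @param copies_per_crop Augmented copies per crop (3 for the reference
#'   schedule: originals + 3 copies = 4x the data).
#' @param noise_sd Standard deviation of the additive white noise.
#' @param blur_sigma_range Range of the Gaussian-blur sigma, drawn
#'   uniformly per copy.
#' @param seed RNG seed.
#' @return An `AugmentationConfig` list.
#' @export
augmentation_config <- function(copies_per_crop = 3L, noise_sd = 0.02,
                                blur_sigma_range = c(0.5, 1.5), seed = 1L) {
  stopifnot(copies_per_crop >= 0, noise_sd > 0, all(blur_sigma_range > 0))
  structure(list(copies_per_crop = as.integer(copies_per_crop),
                 noise_sd = noise_sd, blur_sigma_range = blur_sigma_range,
                 seed = as.integer(seed)),
            class = "AugmentationConfig")
}

flip_h <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
flip_v <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]

augment_one <- function(crop, cfg) {
  repeat {
    ops <- runif(4) < 0.5
    if (any(ops)) break
  }
  img <- crop$image; lab <- crop$label
  if (ops[1]) { img <- flip_h(img); lab <- flip_h(lab) }
  if (ops[2]) { img <- flip_v(img); lab <- flip_v(lab) }
  if (ops[3]) img <- img + matrix(rnorm(length(img), 0, cfg$noise_sd),
                                  nrow(img), ncol(img))
  if (ops[4]) img <- .cpp_gauss_blur(img, runif(1, cfg$blur_sigma_range[1],
                                                cfg$blur_sigma_range[2]))
  crop$image <- pmin(pmax(img, 0), 1)
  crop$label <- lab
  crop$augmented <- TRUE
  crop
}

#' Augment training crops
#'
#' Returns the original crops followed by `copies_per_crop` randomly
#' augmented copies of each, so `|output| = (1 + copies_per_crop) |input|`.
#'
#' @param crops List of `CropRecord`s.
#' @param cfg An [augmentation_config()].
#' @return Augmented list of `CropRecord`s.
#' @export
augment_crops <- function(crops, cfg = augmentation_config()) {
  if (length(crops) == 0L) return(list())
  withr::with_seed(cfg$seed, {
    out <- vector("list", (1L + cfg$copies_per_crop) * length(crops))
    at <- 1L
    for (crop in crops) {
      out[[at]] <- crop; at <- at + 1L
      for (k in seq_len(cfg$copies_per_crop)) {
        out[[at]] <- augment_one(crop, cfg); at <- at + 1L
      }
    }
    out
  })
}

#' Split crops into train/dev/test by scan
#'
#' Distinct scan identifiers are shuffled with `seed` and assigned to the
#' three subsets, so every crop of a scan lands in the same subset and no
#' scan leaks across splits.
#'
#' @param records List of `CropRecord`s.
#' @param counts `c(n_train, n_dev, n_test)`; must sum to the number of
#'   distinct scans.
#' @param seed RNG seed for the shuffle.
#' @return A `DatasetSplit`: list with `train`, `dev`, `test` (crop lists)
#'   and `scan_assignment` (named character vector scan_id -> split).
#' @export
split_by_scan <- function(records, counts, seed = 1L) {
  scans <- unique(vapply(records, `[[`, character(1), "scan_id"))
  if (sum(counts) != length(scans))
    stop("counts (", sum(counts), ") inconsistent with ", length(scans), " scans")
  shuffled <- withr::with_seed(seed, sample(scans))
  assignment <- setNames(rep(c("train", "dev", "test"), times = counts), shuffled)
  by_split <- function(s) {
    keep <- vapply(records, function(r) assignment[[r$scan_id]] == s, logical(1))
    records[keep]
  }
  structure(list(train = by_split("train"), dev = by_split("dev"),
                 test = by_split("test"), scan_assignment = assignment),
            class = "DatasetSplit")
}
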