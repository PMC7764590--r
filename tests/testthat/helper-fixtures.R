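# shared fixture builders; everything is generated in code at test time

# deterministic random RGB raster in [0,1]
random_rgb <- function(h, w, seed = 1) {
  withr::with_seed(seed, array(runif(h * w * 3), dim = c(h, w, 3)))
}

# write a small annotation JSON and return its path
write_annotation_fixture <- function(polygons, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "ann.json")
  jsonlite::write_json(list(scan_id = "fix", coordinate_pixel_size_um = 1,
                            polygons = polygons),
                       path, auto_unbox = TRUE, digits = NA)
  path
}

# dense 2-D convolution oracle with the same mirror boundary as the
# package filters: pad by reflection, convolve directly
reflect_pad <- function(m, r) {
  idx <- function(n) {
    i <- seq(1 - r, n + r)
    while (any(i < 1 | i > n)) {
      i[i < 1] <- 1 - i[i < 1]
      i[i > n] <- 2 * n + 1 - i[i > n]
    }
    i
  }
  m[idx(nrow(m)), idx(ncol(m))]
}

dense_filter_oracle <- function(m, kernel) {
  r <- (nrow(kernel) - 1) / 2
  p <- reflect_pad(m, r)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m)))
    for (j in seq_len(ncol(m)))
      out[i, j] <- sum(p[i:(i + 2 * r), j:(j + 2 * r)] * kernel)
  out
}

gauss_kernel_2d <- function(sigma) {
  r <- ceiling(4 * sigma)
  g <- exp(-0.5 * (-r:r)^2 / sigma^2)
  k <- outer(g, g)
  k / sum(k)
}

# small three-band crop fixture for CNN tests
band_crop <- function(size = 224, seed = 1) {
  withr::with_seed(seed, {
    lab <- matrix(sample(1:3, 1), size, size)
    third <- floor(size / 3)
    lab[, (third + 1):(2 * third)] <- sample(1:3, 1)
    lab[, (2 * third + 1):size] <- sample(1:3, 1)
    img <- matrix(c(0.9, 0.6, 0.3)[lab], size, size) +
      matrix(rnorm(size * size, 0, 0.03), size, size)
    list(image = pmin(pmax(img, 0), 1), label = lab,
         scan_id = paste0("band", seed), scale = 1, origin = c(0L, 0L))
  })
}
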