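test_that("pyramid write/load round-trips and levels match direct downscaling", {
  dir <- withr::local_tempdir()
  # smooth image so cascaded factor-2 downscaling and one-shot downscaling
  # agree to resampling tolerance
  g <- outer(seq(0, 1, length.out = 128), seq(0, 1, length.out = 128),
             function(a, b) 0.5 + 0.4 * sin(2 * pi * a) * cos(2 * pi * b))
  rgb <- array(c(g, 0.8 * g, 0.5 + 0.3 * g), dim = c(128, 128, 3))
  pyr <- pyramid_from_array(rgb, pixel_size_um = 1, n_levels = 3, id = "p3")
  path <- file.path(dir, "p3.tif")
  write_pyramid(pyr, path)

  loaded <- load_pyramid(path)
  expect_length(loaded$levels, 3)
  ps <- vapply(loaded$levels, `[[`, numeric(1), "pixel_size_um")
  expect_equal(ps, c(1, 2, 4))
  dims <- t(vapply(loaded$levels, function(l) dim(l$raster)[1:2], integer(2)))
  expect_equal(dims[, 1], c(128L, 64L, 32L))
  # 8-bit TIFF quantization only
  expect_equal(loaded$levels[[1]]$raster, rgb, tolerance = 1 / 255)
  # coarser levels equal direct downscaling of the base raster
  for (k in 2:3) {
    direct <- scaffseg:::resize_rgb(rgb, 128 / 2^(k - 1), 128 / 2^(k - 1))
    expect_equal(loaded$levels[[k]]$raster, direct, tolerance = 0.02)
  }
})

test_that("load_pyramid fails informatively on missing files or metadata", {
  expect_error(load_pyramid("no/such/file.tif"), "file not found")
  dir <- withr::local_tempdir()
  path <- file.path(dir, "bare.png")
  png::writePNG(matrix(runif(16), 4, 4), path)
  expect_error(load_pyramid(path), "missing pixel size")
  expect_silent(load_pyramid(path, pixel_size_um = 0.5))
})

test_that("read_region output extent follows round(extent * base / target)", {
  # the working-bitmap arithmetic: a 44,054 px slide at 227 nm/px maps to
  # 1000 px at 10 um/px
  expect_equal(scaffseg:::region_out_dim(44054, 0.227, 10), 1000L)

  pyr <- pyramid_from_array(random_rgb(512, 512, seed = 2), 1, n_levels = 2)
  out <- read_region(pyr, 10)
  expect_equal(dim(out), c(51L, 51L, 3L))
})

test_that("read_region at a level's own pixel size is bit-exact; constants stay constant", {
  pyr <- pyramid_from_array(random_rgb(64, 96, seed = 3), 2, n_levels = 2)
  expect_identical(read_region(pyr, 2), pyr$levels[[1]]$raster)
  expect_identical(read_region(pyr, 4), pyr$levels[[2]]$raster)

  const <- array(rep(c(0.2, 0.5, 0.8), each = 64 * 64), dim = c(64, 64, 3))
  cpyr <- pyramid_from_array(const, 1, n_levels = 2)
  out <- read_region(cpyr, 3.7)
  expect_equal(max(abs(sweep(out, 3, c(0.2, 0.5, 0.8)))), 0, tolerance = 1e-12)

  expect_error(read_region(pyr, 1), "finer than the base")
  expect_error(read_region(pyr, 4, bbox = c(0, 0, 0, 10)), "empty bbox")
})

test_that("annotation colors map to classes; auxiliary and unknown handled", {
  tri <- function(x0, y0) list(color = "#FF00FF",
                               points = list(c(x0, y0), c(x0 + 5, y0), c(x0, y0 + 5)))
  polys <- list(
    list(color = "#FF00FF", points = list(c(0, 0), c(5, 0), c(0, 5))),
    list(color = "#000000", points = list(c(10, 0), c(15, 0), c(10, 5))),
    list(color = "#FF0000", points = list(c(20, 0), c(25, 0), c(20, 5))),
    list(color = "#00FF00", points = list(c(30, 0), c(35, 0), c(30, 5))))
  ann <- parse_annotations(write_annotation_fixture(polys))
  expect_equal(vapply(ann$items, `[[`, character(1), "class"),
               c("background", "intralobular", "extralobular", "auxiliary"))

  unknown <- list(list(color = "#123456", points = list(c(0, 0), c(5, 0), c(0, 5))))
  expect_warning(ann2 <- parse_annotations(write_annotation_fixture(unknown)),
                 "unknown annotation color")
  expect_equal(ann2$items[[1]]$class, "auxiliary")

  degenerate <- list(list(color = "#FF0000", points = list(c(0, 0), c(5, 0))))
  expect_error(parse_annotations(write_annotation_fixture(degenerate)),
               "fewer than 3 vertices")
})

test_that("annotation sets round-trip through the JSON schema", {
  withr::with_seed(4, {
    items <- lapply(1:5, function(i) {
      cls <- sample(c("background", "intralobular", "extralobular"), 1)
      col <- names(which(annotation_color_map() == cls))[1]
      list(polygon = cbind(x = runif(6, 0, 100), y = runif(6, 0, 100)),
           class = cls, color = col)
    })
  })
  ann <- structure(list(items = items, scan_id = "rt",
                        coordinate_pixel_size_um = 0.227),
                   class = "AnnotationSet")
  path <- file.path(withr::local_tempdir(), "rt.json")
  write_annotations(ann, path)
  back <- parse_annotations(path)
  expect_equal(back$scan_id, "rt")
  expect_equal(back$coordinate_pixel_size_um, 0.227)
  for (i in seq_along(items)) {
    expect_equal(back$items[[i]]$class, items[[i]]$class)
    expect_equal(unname(back$items[[i]]$polygon), unname(items[[i]]$polygon),
                 tolerance = 1e-12)
  }
})

test_that("scale_polygon rescales vertices between pixel frames", {
  sq <- cbind(c(0, 44, 44, 0), c(0, 0, 44, 44))
  expect_identical(scale_polygon(sq, 1), sq)
  scaled <- scale_polygon(sq, 0.227 / 10)
  expect_equal(scaled, sq * 0.0227)
  expect_equal(scaled[3, ], c(0.9988, 0.9988))
  expect_error(scale_polygon(sq, -1), "positive")
  expect_error(scale_polygon(sq, 0), "positive")
})

test_that("rasterization agrees with an independent point-in-polygon oracle", {
  skip_if_not_installed("pracma")
  withr::with_seed(7, {
    for (rep in 1:5) {
      n <- sample(3:8, 1)
      # star-shaped (simple) polygon: random vertices sorted by angle
      poly <- cbind(x = runif(n, 2, 60), y = runif(n, 2, 60))
      ctr <- colMeans(poly)
      poly <- poly[order(atan2(poly[, 2] - ctr[2], poly[, 1] - ctr[1])), , drop = FALSE]
      ann <- structure(list(items = list(list(polygon = poly, class = "intralobular",
                                              color = "#000000")),
                            scan_id = "o", coordinate_pixel_size_um = 1),
                       class = "AnnotationSet")
      mask <- rasterize_annotations(ann, c(64, 64))
      centers <- expand.grid(row = 1:64, col = 1:64)
      inside <- pracma::inpolygon(centers$col - 0.5, centers$row - 0.5,
                                  poly[, 1], poly[, 2])
      oracle <- matrix(2L * inside, 64, 64)
      expect_equal(as.vector(mask), as.vector(oracle))
    }
  })
})

test_that("rasterization honors class codes, auxiliary exclusion and overwrite order", {
  full <- cbind(c(-1, 65, 65, -1), c(-1, -1, 65, 65))
  ann <- structure(list(items = list(
    list(polygon = full, class = "background", color = "#FF00FF")),
    scan_id = "a", coordinate_pixel_size_um = 1), class = "AnnotationSet")
  expect_true(all(rasterize_annotations(ann, c(16, 16)) == 1L))

  empty <- structure(list(items = list(), scan_id = "a",
                          coordinate_pixel_size_um = 1), class = "AnnotationSet")
  expect_true(all(rasterize_annotations(empty, c(8, 8)) == 0L))

  aux <- structure(list(items = list(
    list(polygon = full, class = "auxiliary", color = "#00FF00")),
    scan_id = "a", coordinate_pixel_size_um = 1), class = "AnnotationSet")
  expect_true(all(rasterize_annotations(aux, c(8, 8)) == 0L))

  # later polygons overwrite earlier ones
  both <- structure(list(items = list(
    list(polygon = full, class = "background", color = "#FF00FF"),
    list(polygon = cbind(c(-1, 9, 9, -1), c(-1, -1, 9, 9)),
         class = "extralobular", color = "#FF0000")),
    scan_id = "a", coordinate_pixel_size_um = 1), class = "AnnotationSet")
  m <- rasterize_annotations(both, c(16, 16))
  expect_equal(m[4, 4], 3L)
  expect_equal(m[12, 12], 1L)

  expect_error(rasterize_annotations(empty, c(0, 4)), "zero-sized")
})

test_that("tile grids enumerate stride-spaced origins with a clamped final tile", {
  g <- make_tile_grid(448, 448, 224, 100)
  expect_equal(sort(unique(g$origins[, 1])), c(0L, 124L, 224L))
  expect_equal(nrow(g$origins), 9L)
  expect_false(g$padded)

  small <- make_tile_grid(100, 100, 224, 100)
  expect_equal(nrow(small$origins), 1L)
  expect_equal(unname(small$origins[1, ]), c(0L, 0L))
  expect_true(small$padded)

  expect_error(make_tile_grid(448, 448, 224, 224), "overlap")
})

test_that("tile grids match brute-force origin enumeration and cover every pixel", {
  brute_axis <- function(extent, tile, stride) {
    if (extent <= tile) return(0L)
    o <- c()
    at <- 0L
    while (TRUE) {
      o <- c(o, min(at, extent - tile))
      if (at + tile >= extent) break
      at <- at + stride
    }
    unique(o)
  }
  withr::with_seed(9, {
    for (rep in 1:25) {
      h <- sample(1:600, 1); w <- sample(1:600, 1)
      tile <- sample(1:300, 1); overlap <- sample(0:(tile - 1), 1)
      g <- make_tile_grid(h, w, tile, overlap)
      stride <- tile - overlap
      expect_equal(sort(unique(g$origins[, 1])), sort(brute_axis(h, tile, stride)))
      expect_equal(sort(unique(g$origins[, 2])), sort(brute_axis(w, tile, stride)))
      covered_r <- rep(FALSE, h)
      for (o in unique(g$origins[, 1])) covered_r[(o + 1):min(o + tile, h)] <- TRUE
      expect_true(all(covered_r))
      if (h >= tile) expect_true(all(g$origins[, 1] + tile <= h))
    }
  })
})

test_that("label masks survive the PNG round trip", {
  m <- matrix(sample(0:3, 64, TRUE), 8, 8)
  path <- file.path(withr::local_tempdir(), "mask.png")
  write_label_mask(m, path)
  expect_identical(read_label_mask(path), m)
})
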