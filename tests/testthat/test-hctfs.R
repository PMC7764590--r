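test_that("feature stack has 9 channels with the documented responses on constants", {
  v <- 0.37
  rgb <- array(v, dim = c(48, 48, 3))
  fs <- extract_features(rgb)
  expect_equal(dim(fs), c(48L, 48L, 9L))
  expect_equal(dimnames(fs)[[3]], feature_names())
  for (ch in 1:5) expect_equal(max(abs(fs[, , ch] - v)), 0, tolerance = 1e-12)
  # gradient-derived channels vanish on a constant image (reflect boundary
  # keeps them zero up to the border)
  for (ch in 6:9) expect_equal(max(abs(fs[, , ch])), 0, tolerance = 1e-12)

  expect_error(extract_features(array(2, dim = c(4, 4, 3))), "\\[0,1\\]")
  expect_error(extract_features(matrix(0.5, 4, 4)), "H x W x 3")
})

test_that("Gaussian channels match a dense direct-convolution oracle", {
  img <- random_rgb(32, 32, seed = 21)
  fs <- extract_features(img)
  red <- img[, , 1]
  for (sigma in c(2, 5)) {
    oracle <- dense_filter_oracle(red, gauss_kernel_2d(sigma))
    got <- if (sigma == 2) fs[, , 4] else fs[, , 5]
    expect_lt(max(abs(got - oracle)), 1e-4)
  }
})

test_that("Sobel magnitude and its smoothed/median responses match brute force", {
  img <- random_rgb(32, 32, seed = 22)
  red <- img[, , 1]
  kx <- rbind(c(-1, 0, 1), c(-2, 0, 2), c(-1, 0, 1))
  gx <- dense_filter_oracle(red, kx)
  gy <- dense_filter_oracle(red, t(kx))
  sob_oracle <- sqrt(gx^2 + gy^2)
  fs <- extract_features(img)
  expect_lt(max(abs(fs[, , 6] - sob_oracle)), 1e-10)
  for (sigma in c(2, 5)) {
    oracle <- dense_filter_oracle(sob_oracle, gauss_kernel_2d(sigma))
    got <- if (sigma == 2) fs[, , 7] else fs[, , 8]
    expect_lt(max(abs(got - oracle)), 1e-4)
  }
  # median over a disk of radius 5 (center included), brute force at
  # interior pixels
  pad <- reflect_pad(sob_oracle, 5)
  offs <- expand.grid(di = -5:5, dj = -5:5)
  offs <- offs[offs$di^2 + offs$dj^2 <= 25, ]
  for (i in c(10, 20)) for (j in c(10, 25)) {
    vals <- mapply(function(di, dj) pad[i + 5 + di, j + 5 + dj], offs$di, offs$dj)
    expect_equal(unname(fs[i, j, 9]), median(vals), tolerance = 1e-12)
  }
})

test_that("feature extraction is local: a single-pixel edit stays within filter support", {
  img <- random_rgb(64, 64, seed = 23)
  img2 <- img
  img2[32, 32, ] <- 1 - img2[32, 32, ]
  d <- abs(extract_features(img) - extract_features(img2))
  changed <- which(apply(d, c(1, 2), max) > 1e-12, arr.ind = TRUE)
  cheb <- pmax(abs(changed[, 1] - 32), abs(changed[, 2] - 32))
  # largest support: Gaussian sigma 5 truncated at 4 sigma (radius 20)
  # applied to the Sobel response (radius 1)
  expect_lte(max(cheb), 21)
})

test_that("fitted GNB moments equal directly computed per-class moments", {
  withr::with_seed(31, {
    x <- matrix(rnorm(60 * 9, mean = rep(c(0, 3), each = 30)), 60, 9)
    y <- rep(c(1L, 2L), each = 30)
  })
  model <- fit_gnb(x, y)
  mom <- gnb_moments(model)
  for (c in 1:2) {
    expect_equal(mom$mean[c, ], colMeans(x[y == c, ]), tolerance = 1e-12)
    expect_equal(mom$var[c, ],
                 colMeans(x[y == c, ]^2) - colMeans(x[y == c, ])^2,
                 tolerance = 1e-12)
  }
  expect_equal(unname(mom$priors[1:2]), c(0.5, 0.5))
  expect_error(fit_gnb(x[0, ], integer(0)), "empty")
  expect_error(fit_gnb(x, rep(4L, 60)), "unknown label")
})

test_that("incremental update equals pooled refit and empty update is identity", {
  withr::with_seed(32, {
    a <- matrix(runif(40 * 9), 40, 9); ya <- sample(1:3, 40, TRUE)
    b <- matrix(runif(25 * 9), 25, 9); yb <- sample(1:3, 25, TRUE)
  })
  pre <- fit_gnb(a, ya)
  expect_identical(update_gnb(pre, a[0, , drop = FALSE], integer(0)), pre)
  upd <- update_gnb(pre, b, yb)
  pooled <- fit_gnb(rbind(a, b), c(ya, yb))
  mu <- gnb_moments(upd); mp <- gnb_moments(pooled)
  expect_lt(max(abs(mu$mean - mp$mean)), 1e-9)
  expect_lt(max(abs(mu$var - mp$var)), 1e-9)
  expect_equal(mu$priors, mp$priors, tolerance = 1e-12)
  expect_error(update_gnb(pre, b[, 1:5], yb), "dimension mismatch")
  expect_error(update_gnb(pre, b, rep(4L, 25)), "unknown label")
})

test_that("predictions match a literal evaluation of the log-score formula", {
  withr::with_seed(33, {
    x <- matrix(rnorm(300 * 9), 300, 9)
    y <- sample(1:3, 300, TRUE)
    q <- matrix(rnorm(100 * 9), 100, 9)
  })
  model <- fit_gnb(x, y)
  mom <- gnb_moments(model)
  oracle_scores <- sapply(1:3, function(c) {
    sapply(seq_len(nrow(q)), function(i)
      log(mom$priors[c]) + sum(-0.5 * log(2 * pi * mom$var[c, ]) -
                                 (q[i, ] - mom$mean[c, ])^2 / (2 * mom$var[c, ])))
  })
  oracle_class <- apply(oracle_scores, 1, which.max)
  oracle_post <- t(apply(oracle_scores, 1, function(s) exp(s - max(s)) / sum(exp(s - max(s)))))
  pred <- predict_gnb(model, q)
  expect_equal(pred$classes, as.integer(oracle_class))
  expect_equal(unname(pred$posteriors), unname(oracle_post),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(rowSums(pred$posteriors), rep(1, 100), tolerance = 1e-6)
})

test_that("posterior ties resolve to the lowest class code", {
  # 1 informative feature, two classes at mu 0 and 2, equal variance and
  # priors: x = 1 is an exact tie
  x <- matrix(c(rep(0, 5), rep(2, 5)), ncol = 1)
  y <- rep(c(1L, 2L), each = 5)
  model <- fit_gnb(cbind(x, matrix(0.5, 10, 8)), y, var_floor = 1e-4)
  pred <- predict_gnb(model, matrix(c(1, rep(0.5, 8)), 1))
  expect_equal(pred$posteriors[1, 1], pred$posteriors[1, 2], tolerance = 1e-12)
  expect_equal(pred$classes, 1L)
})

test_that("single-class and uninformative models degrade as expected", {
  one <- fit_gnb(matrix(runif(10 * 9), 10, 9), rep(2L, 10))
  pred <- predict_gnb(one, matrix(runif(5 * 9), 5, 9))
  expect_true(all(pred$classes == 2L))

  # identical feature distributions: posteriors collapse to the priors
  x <- matrix(rep(seq(0, 1, length.out = 8), 9), 8, 9)
  both <- fit_gnb(rbind(x, x), rep(c(1L, 2L), each = 8), priors = c(0.7, 0.3, 0))
  pred2 <- predict_gnb(both, x)
  expect_equal(pred2$posteriors[, 1], rep(0.7, 8), tolerance = 1e-9)
})

test_that("well-separated Gaussian classes are recovered almost perfectly", {
  withr::with_seed(35, {
    n <- 2000
    y <- sample(1:3, n, TRUE)
    mu <- rbind(rep(0, 9), rep(6, 9), rep(12, 9))  # |delta mu| = 6 sigma
    x <- mu[y, ] + matrix(rnorm(n * 9), n, 9)
    model <- fit_gnb(x, y)
    y2 <- sample(1:3, n, TRUE)
    x2 <- mu[y2, ] + matrix(rnorm(n * 9), n, 9)
    acc <- mean(predict_gnb(model, x2)$classes == y2)
  })
  expect_gte(acc, 0.99)
})

test_that("GNB models survive JSON serialization", {
  withr::with_seed(36, {
    x <- matrix(runif(30 * 9), 30, 9); y <- sample(1:3, 30, TRUE)
  })
  model <- fit_gnb(x, y)
  path <- file.path(withr::local_tempdir(), "gnb.json")
  save_gnb(model, path)
  back <- load_gnb(path)
  q <- matrix(runif(10 * 9), 10, 9)
  expect_equal(predict_gnb(back, q)$classes, predict_gnb(model, q)$classes)
  expect_equal(gnb_moments(back)$mean, gnb_moments(model)$mean, tolerance = 1e-12)
})

test_that("tiled whole-slide segmentation equals whole-image prediction", {
  scan <- generate_scaffold_scan(scaffold_sim_config(extent = c(512, 512), seed = 41))
  ann <- generate_partial_annotations(scan, seed = 41)
  pyr <- pyramid_from_array(scan$rgb, scan$pixel_size_um, id = "tile-test")
  model <- pretrain_gnb(list(pyr), list(ann))

  seg_tiled <- segment_slide_hctfs(pyr, model, ann = NULL)
  whole <- predict_gnb(model, extract_features(scan$rgb))
  # the tile halo (32 px) exceeds every filter support, so the stitched
  # result matches the whole-image path exactly
  expect_identical(seg_tiled$classes, whole$classes)
  expect_equal(seg_tiled$posteriors, whole$posteriors, tolerance = 1e-12)
})
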