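#' Feature-bank configuration for stage-1 segmentation
#'
#' The nine hand-crafted texture features are computed on a working bitmap
#' of `working_pixel_size_um` micrometres per pixel: the raw R, G, B
#' intensities, Gaussian smoothings of the red channel (sigma 2 and 5 px),
#' the Sobel gradient magnitude of the red channel, Gaussian smoothings of
#' the Sobel response (sigma 2 and 5 px) and the median of the Sobel
#' response over a disk neighbourhood of 10 px diameter.
#'
#' @param gauss_sigmas Gaussian sigmas in pixels for the red channel.
#' @param sobel_gauss_sigmas Gaussian sigmas for the Sobel response.
#' @param median_diameter Diameter in pixels of the median disk.
#' @param working_pixel_size_um Working resolution of the stage-1 bitmap.
#' @param tile,halo Tile side and halo margin (px) for tiled whole-slide
#'   processing; the halo exceeds every filter support so stitching is
#'   seam free.
#' @return A `FeatureConfig` list.
#' @export
feature_config <- function(gauss_sigmas = c(2, 5),
                           sobel_gauss_sigmas = c(2, 5),
                           median_diameter = 10,
                           working_pixel_size_um = 10,
                           tile = 255L, halo = 32L) {
  stopifnot(all(gauss_sigmas > 0), all(sobel_gauss_sigmas > 0),
            median_diameter >= 1, working_pixel_size_um > 0)
  structure(list(gauss_sigmas = gauss_sigmas,
                 sobel_gauss_sigmas = sobel_gauss_sigmas,
                 median_diameter = median_diameter,
                 working_pixel_size_um = working_pixel_size_um,
                 tile = as.integer(tile), halo = as.integer(halo)),
            class = "FeatureConfig")
}

#' Names of the nine texture features, in channel order
#' @return Character vector of length 9.
#' @export
feature_names <- function() {
  c("R", "G", "B", "gauss2_R", "gauss5_R", "sobel_R",
    "gauss2_sobel", "gauss5_sobel", "median10_sobel")
}

#' Extract the 9-channel texture feature stack
#'
#' Only the red channel (strongly correlated with the others in H&E
#' material) feeds the filter bank.  The Sobel response is the gradient
#' magnitude `sqrt(gx^2 + gy^2)`; Gaussian kernels are truncated at 4
#' sigma with reflective boundary handling; the median uses a disk of
#' radius `median_diameter/2` including the center.
#'
#' @param rgb H x W x 3 array with values in \[0,1\].
#' @param cfg A [feature_config()].
#' @return H x W x 9 array (a `FeatureStack`); channels 1-5 lie in \[0,1\],
#'   channels 6-9 are non-negative.
#' @export
extract_features <- function(rgb, cfg = feature_config()) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    stop("rgb must be an H x W x 3 array")
  if (min(rgb) < 0 || max(rgb) > 1) stop("intensities must lie in [0,1]")
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  red <- rgb[, , 1]
  sob <- .cpp_sobel_mag(red)
  out <- array(0, dim = c(h, w, 9L))
  out[, , 1:3] <- rgb
  out[, , 4] <- .cpp_gauss_blur(red, cfg$gauss_sigmas[1])
  out[, , 5] <- .cpp_gauss_blur(red, cfg$gauss_sigmas[2])
  out[, , 6] <- sob
  out[, , 7] <- .cpp_gauss_blur(sob, cfg$sobel_gauss_sigmas[1])
  out[, , 8] <- .cpp_gauss_blur(sob, cfg$sobel_gauss_sigmas[2])
  out[, , 9] <- .cpp_median_disk(sob, as.integer(cfg$median_diameter / 2))
  dimnames(out) <- list(NULL, NULL, feature_names())
  out
}

# flatten an H x W x 9 stack to an (H*W) x 9 sample matrix (row-major in
# pixel index p = row + col*H, matching R's column-major layout)
stack_to_matrix <- function(stack) {
  d <- dim(stack)
  matrix(stack, nrow = d[1] * d[2], ncol = d[3],
         dimnames = list(NULL, dimnames(stack)[[3]]))
}

#' Fit a Gaussian naive Bayes pixel classifier
#'
#' Stores per-class, per-feature sufficient statistics (count, sum, sum of
#' squares) so the model can later be fine-tuned incrementally with
#' [update_gnb()].  Variances are sample moments floored at `var_floor`.
#'
#' @param features N x 9 numeric matrix.
#' @param labels Integer vector of class codes in `{1, 2, 3}`.
#' @param priors Optional length-3 prior vector (default: class
#'   frequencies among all data seen so far).
#' @param var_floor Variance floor for near-constant classes.
#' @return A `GnbModel`.
#' @export
fit_gnb <- function(features, labels, priors = NULL, var_floor = 1e-9) {
  features <- as.matrix(features)
  if (nrow(features) == 0L) stop("empty training set")
  model <- structure(list(n = setNames(numeric(3), 1:3),
                          s = matrix(0, 3, ncol(features)),
                          q = matrix(0, 3, ncol(features)),
                          priors = priors,
                          var_floor = var_floor,
                          n_features = ncol(features)),
                     class = "GnbModel")
  update_gnb(model, features, labels)
}

#' Incrementally train a Gaussian naive Bayes model
#'
#' Accumulates sufficient statistics; the resulting moments are identical
#' (to rounding) to refitting on the concatenation of all data ever seen.
#' Used for the paper-style per-slide fine-tuning on top of a pretrained
#' model.
#'
#' @param model A `GnbModel` from [fit_gnb()].
#' @param features M x 9 numeric matrix (M = 0 leaves the model unchanged).
#' @param labels Integer class codes in `{1, 2, 3}`.
#' @return The updated `GnbModel`.
#' @export
update_gnb <- function(model, features, labels) {
  stopifnot(inherits(model, "GnbModel"))
  features <- as.matrix(features)
  if (nrow(features) == 0L) return(model)
  if (ncol(features) != model$n_features)
    stop("feature dimension mismatch: expected ", model$n_features)
  labels <- as.integer(labels)
  if (length(labels) != nrow(features)) stop("labels/features length mismatch")
  if (any(!labels %in% 1:3)) stop("unknown label code (must be 1, 2 or 3)")
  for (c in 1:3) {
    idx <- labels == c
    if (!any(idx)) next
    x <- features[idx, , drop = FALSE]
    model$n[c] <- model$n[c] + nrow(x)
    model$s[c, ] <- model$s[c, ] + colSums(x)
    model$q[c, ] <- model$q[c, ] + colSums(x^2)
  }
  model
}

#' Per-class means, variances and priors of a GNB model
#'
#' @param model A `GnbModel`.
#' @return List with `mean` and `var` (3 x n_features matrices, rows =
#'   classes; `NA` for untrained classes), `priors`, and `classes` (codes
#'   with at least one sample).
#' @export
gnb_moments <- function(model) {
  mu <- model$s / model$n
  va <- model$q / model$n - mu^2
  va <- pmax(va, model$var_floor)
  trained <- which(model$n >= 1)
  if (is.null(model$priors)) {
    priors <- model$n / sum(model$n)
  } else {
    priors <- model$priors / sum(model$priors)
  }
  list(mean = mu, var = va, priors = priors, classes = trained)
}

#' Per-pixel Gaussian naive Bayes prediction
#'
#' For each pixel the class log-score is
#' `log pi_c + sum_i [ -0.5 log(2 pi sigma^2_ci) - (x_i - mu_ci)^2 / (2 sigma^2_ci) ]`;
#' posteriors are normalized exponentials and the predicted class is the
#' argmax, with ties resolved to the lowest class code.
#'
#' @param model A trained `GnbModel`.
#' @param features H x W x 9 array or N x 9 matrix.
#' @param pixel_size_um Pixel size recorded in the output.
#' @return For array input, a `SegmentationMap`: list with `classes`
#'   (H x W integer matrix), `posteriors` (H x W x 3) and `pixel_size_um`.
#'   For matrix input, a list with `classes` (length N) and `posteriors`
#'   (N x 3).
#' @export
predict_gnb <- function(model, features, pixel_size_um = NA_real_) {
  stopifnot(inherits(model, "GnbModel"))
  is_stack <- length(dim(features)) == 3L
  x <- if (is_stack) stack_to_matrix(features) else as.matrix(features)
  if (ncol(x) != model$n_features)
    stop("feature dimension mismatch: expected ", model$n_features)
  mom <- gnb_moments(model)
  if (length(mom$classes) == 0L) stop("model has no trained class")

  scores <- matrix(-Inf, nrow(x), 3)
  for (c in mom$classes) {
    mu <- mom$mean[c, ]; va <- mom$var[c, ]
    const <- log(mom$priors[c]) - 0.5 * sum(log(2 * pi * va))
    # -(x - mu)^2 / (2 va), summed over features, vectorized
    quad <- x^2 %*% (1 / (2 * va)) - x %*% (mu / va) + sum(mu^2 / (2 * va))
    scores[, c] <- const - quad
  }
  m <- pmax(scores[, 1], scores[, 2], scores[, 3])
  post <- exp(scores - m)
  post[!is.finite(post)] <- 0
  post <- post / rowSums(post)
  classes <- max.col(scores, ties.method = "first")

  if (is_stack) {
    d <- dim(features)
    list(classes = matrix(as.integer(classes), d[1], d[2]),
         posteriors = array(post, dim = c(d[1], d[2], 3L)),
         pixel_size_um = pixel_size_um)
  } else {
    list(classes = as.integer(classes), posteriors = post,
         pixel_size_um = pixel_size_um)
  }
}

# gather feature vectors at labeled pixels of a mask
labeled_features <- function(stack, mask) {
  x <- stack_to_matrix(stack)
  idx <- which(mask != 0L)
  list(features = x[idx, , drop = FALSE], labels = as.integer(mask[idx]))
}

#' Pretrain a GNB model from annotated slides
#'
#' Pools features from the annotated polygons of several slides (read at
#' the working resolution) into one pretraining corpus, mirroring the
#' pretraining-on-a-general-dataset step of the stage-1 workflow.
#'
#' @param pyramids List of `PyramidImage`s.
#' @param annotations List of `AnnotationSet`s (same order; vertex
#'   coordinates in each set's `coordinate_pixel_size_um` frame).
#' @param cfg A [feature_config()].
#' @return A pretrained `GnbModel`.
#' @export
pretrain_gnb <- function(pyramids, annotations, cfg = feature_config()) {
  stopifnot(length(pyramids) == length(annotations), length(pyramids) >= 1)
  model <- NULL
  for (i in seq_along(pyramids)) {
    rgb <- read_region(pyramids[[i]], cfg$working_pixel_size_um)
    ann <- annotations[[i]]
    f <- ann$coordinate_pixel_size_um / cfg$working_pixel_size_um
    if (is.na(f)) f <- pyramids[[i]]$base_pixel_size_um / cfg$working_pixel_size_um
    mask <- rasterize_annotations(scale_annotations(ann, f), dim(rgb)[1:2],
                                  cfg$working_pixel_size_um)
    lf <- labeled_features(extract_features(rgb, cfg), mask)
    if (nrow(lf$features) == 0L) next
    model <- if (is.null(model)) fit_gnb(lf$features, lf$labels)
             else update_gnb(model, lf$features, lf$labels)
  }
  if (is.null(model)) stop("no labeled pixels in any training slide")
  model
}

#' Stage-1 whole-slide segmentation (HCTFS)
#'
#' Reads the slide at the working resolution, optionally fine-tunes the
#' pretrained classifier on the slide's own partial annotations
#' (accumulating sufficient statistics), then predicts every pixel in
#' tiles with a halo margin and stitches the results.
#'
#' @param pyr A `PyramidImage`.
#' @param model A pretrained `GnbModel` (not modified in place; the
#'   fine-tuned copy is returned in the result).
#' @param ann Optional `AnnotationSet` for this slide.
#' @param cfg A [feature_config()].
#' @return A `SegmentationMap` (see [predict_gnb()]) with the additional
#'   element `model`, the per-slide fine-tuned classifier.
#' @export
segment_slide_hctfs <- function(pyr, model, ann = NULL, cfg = feature_config()) {
  rgb <- read_region(pyr, cfg$working_pixel_size_um)
  h <- dim(rgb)[1]; w <- dim(rgb)[2]

  if (!is.null(ann)) {
    f <- ann$coordinate_pixel_size_um / cfg$working_pixel_size_um
    if (is.na(f)) f <- pyr$base_pixel_size_um / cfg$working_pixel_size_um
    mask <- rasterize_annotations(scale_annotations(ann, f), c(h, w),
                                  cfg$working_pixel_size_um)
    lf <- labeled_features(extract_features(rgb, cfg), mask)
    if (nrow(lf$features) > 0L) model <- update_gnb(model, lf$features, lf$labels)
  }

  classes <- matrix(0L, h, w)
  post <- array(0, dim = c(h, w, 3L))
  grid <- make_tile_grid(h, w, min(cfg$tile, h, w), 0L)
  for (i in seq_len(nrow(grid$origins))) {
    r0 <- grid$origins[i, 1]; c0 <- grid$origins[i, 2]
    r1 <- min(r0 + grid$tile, h); c1 <- min(c0 + grid$tile, w)
    # expand by the halo so filters are valid over the tile core
    er0 <- max(0L, r0 - cfg$halo); ec0 <- max(0L, c0 - cfg$halo)
    er1 <- min(h, r1 + cfg$halo); ec1 <- min(w, c1 + cfg$halo)
    sub <- rgb[(er0 + 1):er1, (ec0 + 1):ec1, , drop = FALSE]
    pred <- predict_gnb(model, extract_features(sub, cfg),
                        cfg$working_pixel_size_um)
    rows <- (r0 - er0 + 1):(r1 - er0); cols <- (c0 - ec0 + 1):(c1 - ec0)
    classes[(r0 + 1):r1, (c0 + 1):c1] <- pred$classes[rows, cols]
    post[(r0 + 1):r1, (c0 + 1):c1, ] <- pred$posteriors[rows, cols, , drop = FALSE]
  }
  list(classes = classes, posteriors = post,
       pixel_size_um = cfg$working_pixel_size_um, model = model)
}

#' Serialize a GNB model to JSON
#' @param model A `GnbModel`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
save_gnb <- function(model, path) {
  jsonlite::write_json(list(n = unname(model$n), s = model$s, q = model$q,
                            priors = model$priors, var_floor = model$var_floor,
                            n_features = model$n_features,
                            feature_order = feature_names()),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a GNB model saved by [save_gnb()]
#' @param path JSON path.
#' @return A `GnbModel`.
#' @export
load_gnb <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  priors <- if (is.null(d$priors) || length(d$priors) == 0) NULL
            else as.numeric(d$priors)
  structure(list(n = setNames(as.numeric(d$n), 1:3),
                 s = matrix(as.numeric(d$s), 3), q = matrix(as.numeric(d$q), 3),
                 priors = priors, var_floor = d$var_floor,
                 n_features = d$n_features),
            class = "GnbModel")
}
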