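#' Configuration for the synthetic scaffold-scan simulator
#'
#' The simulator emulates an H&E-stained decellularized liver section at
#' the 10 um working resolution: lobules laid out as a Voronoi
#' tessellation inside a rounded tissue region, interlobular septa of
#' thick protein fibers along the Voronoi boundaries (saturated pink with
#' oriented striping), fine sinusoidal texture inside the lobules (pale
#' pink with scattered darker elliptical dots) and a near-white slide
#' background.  Mean luminance is ordered background > intralobular >
#' extralobular by construction, so both the color-based stage-1 features
#' and the grayscale stage-2 crops remain separable.
#'
#' @param extent `c(H, W)` in pixels (each >= 256).
#' @param n_lobules Number of Voronoi seeds.
#' @param septum_thickness Septum width in pixels (>= 2).
#' @param background_margin Margin (px) between image border and tissue.
#' @param pixel_size_um Physical pixel size of the base level.
#' @param dot_density Intralobular dots per pixel.
#' @param noise_sd Per-class additive Gaussian noise (background,
#'   intralobular, extralobular).
#' @param stripe_freq Spatial frequency (cycles/px) of the septum fiber
#'   striping.
#' @param central_vein Emit one auxiliary "central vein" disk annotation.
#' @param seed RNG seed.
#' @return A `ScaffoldSimConfig` list.
#' @export
scaffold_sim_config <- function(extent = c(768L, 768L), n_lobules = 24L,
                                septum_thickness = 10, background_margin = 40L,
                                pixel_size_um = 10, dot_density = 0.02,
                                noise_sd = c(0.015, 0.03, 0.03),
                                stripe_freq = 0.15, central_vein = FALSE,
                                seed = 1L) {
  stopifnot(all(extent >= 256), n_lobules >= 1, septum_thickness >= 2)
  structure(list(extent = as.integer(extent), n_lobules = as.integer(n_lobules),
                 septum_thickness = septum_thickness,
                 background_margin = as.integer(background_margin),
                 pixel_size_um = pixel_size_um, dot_density = dot_density,
                 noise_sd = noise_sd, stripe_freq = stripe_freq,
                 central_vein = central_vein, seed = as.integer(seed)),
            class = "ScaffoldSimConfig")
}

# class base colors (RGB in [0,1]); luminances 0.96 / 0.68 / 0.36
SIM_COLORS <- list(background   = c(0.96, 0.96, 0.97),
                   intralobular = c(0.80, 0.62, 0.70),
                   extralobular = c(0.55, 0.25, 0.42))

#' Generate a synthetic scaffold scan with exact ground truth
#'
#' @param cfg A [scaffold_sim_config()].
#' @return A `SyntheticScan`: list with `rgb` (H x W x 3 in \[0,1\]), `gt`
#'   (H x W integer mask, codes 1-3, no unlabeled pixels), `pixel_size_um`,
#'   `vein_center` (or `NULL`) and `config`.
#' @export
generate_scaffold_scan <- function(cfg = scaffold_sim_config()) {
  if (cfg$n_lobules < 1) stop("degenerate config: need at least one lobule")
  withr::with_seed(cfg$seed, {
    h <- cfg$extent[1]; w <- cfg$extent[2]
    rr <- matrix(seq_len(h) - 0.5, h, w)
    cc <- matrix(seq_len(w) - 0.5, h, w, byrow = TRUE)

    # rounded tissue region: radius modulated by low-frequency sinusoids
    cy <- h / 2; cx <- w / 2
    theta <- atan2(rr - cy, cc - cx)
    base_r <- min(h, w) / 2 - cfg$background_margin
    wob <- runif(3, -pi, pi)
    rad <- base_r * (1 + 0.08 * sin(2 * theta + wob[1]) +
                       0.05 * sin(3 * theta + wob[2]) +
                       0.03 * sin(5 * theta + wob[3]))
    dist_c <- sqrt((rr - cy)^2 + (cc - cx)^2)
    tissue <- dist_c <= rad

    # Voronoi seeds inside the tissue disk core
    n <- cfg$n_lobules
    ang <- runif(n, 0, 2 * pi)
    rs <- sqrt(runif(n)) * base_r * 0.95
    sy <- cy + rs * sin(ang); sx <- cx + rs * cos(ang)

    # distance to nearest and second-nearest seed
    d1 <- matrix(Inf, h, w); d2 <- matrix(Inf, h, w)
    for (i in seq_len(n)) {
      d <- sqrt((rr - sy[i])^2 + (cc - sx[i])^2)
      closer <- d < d1
      d2 <- ifelse(closer, d1, pmin(d2, d))
      d1 <- ifelse(closer, d, d1)
    }
    septum <- (d2 - d1) <= cfg$septum_thickness
    rim <- tissue & (dist_c >= rad - cfg$septum_thickness / 2)

    gt <- matrix(1L, h, w)                       # background
    gt[tissue] <- 2L                             # intralobular
    gt[tissue & (septum | rim)] <- 3L            # extralobular

    rgb <- array(0, dim = c(h, w, 3L))
    for (ch in 1:3) {
      plane <- matrix(SIM_COLORS$background[ch], h, w)
      plane[gt == 2L] <- SIM_COLORS$intralobular[ch]
      plane[gt == 3L] <- SIM_COLORS$extralobular[ch]
      rgb[, , ch] <- plane
    }

    # oriented fiber striping on the septa
    stripe_dir <- runif(1, 0, pi)
    stripes <- 0.10 * sin(2 * pi * cfg$stripe_freq *
                            (cc * cos(stripe_dir) + rr * sin(stripe_dir)))
    # scattered darker elliptical dots inside the lobules (sinusoidal voids)
    intra_idx <- which(gt == 2L)
    n_dots <- round(cfg$dot_density * length(intra_idx))
    dots <- matrix(0, h, w)
    if (n_dots > 0) {
      centers <- sample(intra_idx, n_dots, replace = TRUE)
      dc_r <- (centers - 1L) %% h + 1L
      dc_c <- (centers - 1L) %/% h + 1L
      ax <- runif(n_dots, 1, 3); bx <- runif(n_dots, 1, 3)
      rot <- runif(n_dots, 0, pi)
      for (i in seq_len(n_dots)) {
        r0 <- max(1L, dc_r[i] - 3L):min(h, dc_r[i] + 3L)
        c0 <- max(1L, dc_c[i] - 3L):min(w, dc_c[i] + 3L)
        dy <- outer(r0 - dc_r[i], rep(1, length(c0)))
        dx <- outer(rep(1, length(r0)), c0 - dc_c[i])
        u <- dx * cos(rot[i]) + dy * sin(rot[i])
        v <- -dx * sin(rot[i]) + dy * cos(rot[i])
        inside <- (u / ax[i])^2 + (v / bx[i])^2 <= 1
        dots[r0, c0][inside] <- 1
      }
    }

    noise_sd <- cfg$noise_sd[gt]
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[gt == 3L] <- plane[gt == 3L] * (1 + stripes[gt == 3L])
      plane[gt == 2L] <- plane[gt == 2L] * (1 - 0.35 * dots[gt == 2L])
      plane <- plane + rnorm(h * w, 0, noise_sd)
      rgb[, , ch] <- pmin(pmax(plane, 0), 1)
    }

    vein_center <- NULL
    if (cfg$central_vein) {
      # a small disk of intralobular texture near the first seed, marked
      # only by an auxiliary annotation (exercises the auxiliary path)
      vein_center <- c(sy[1], sx[1])
    }

    stopifnot(all(1:3 %in% gt))
    lum <- to_grayscale(rgb)
    stopifnot(mean(lum[gt == 1L]) > mean(lum[gt == 2L]),
              mean(lum[gt == 2L]) > mean(lum[gt == 3L]))

    structure(list(rgb = rgb, gt = gt, pixel_size_um = cfg$pixel_size_um,
                   vein_center = vein_center, config = cfg),
              class = "SyntheticScan")
  })
}

# convex polygon (jittered circle) around a center, (x, y) 0-based coords
convex_polygon <- function(cx, cy, radius, n_vertices = 7L) {
  ang <- sort(runif(n_vertices, 0, 2 * pi))
  rad <- radius * runif(n_vertices, 0.7, 1)
  cbind(x = cx + rad * cos(ang), y = cy + rad * sin(ang))
}

#' Generate sparse partial polygon annotations for a synthetic scan
#'
#' Places, for each class, small convex polygons strictly inside
#' single-class regions of the ground truth (mirroring an operator
#' outlining a few representative areas), with the total annotated area
#' capped at `max_cover_fraction` of the scan.  Polygon colors follow
#' [annotation_color_map()]; if the scan has a central vein, one
#' auxiliary (green) polygon is added.
#'
#' @param scan A `SyntheticScan`.
#' @param n_polygons_per_class Polygons per class.
#' @param max_cover_fraction Maximum annotated fraction of the scan.
#' @param seed RNG seed.
#' @param max_tries Placement attempts per polygon before giving up.
#' @return An `AnnotationSet` in the scan's pixel frame.
#' @export
generate_partial_annotations <- function(scan, n_polygons_per_class = 3L,
                                         max_cover_fraction = 0.05,
                                         seed = 1L, max_tries = 400L) {
  stopifnot(inherits(scan, "SyntheticScan"))
  gt <- scan$gt
  h <- nrow(gt); w <- ncol(gt)
  budget <- max_cover_fraction * h * w
  class_colors <- c(background = "#FF00FF", intralobular = "#000000",
                    extralobular = "#FF0000")
  withr::with_seed(seed, {
    items <- list()
    used <- 0
    for (cls in names(class_colors)) {
      code <- CLASS_NAMES[[cls]]
      pix <- which(gt == code)
      placed <- 0L
      tries <- 0L
      while (placed < n_polygons_per_class) {
        tries <- tries + 1L
        if (tries > max_tries)
          stop("cannot place a polygon for class ", cls,
               " after ", max_tries, " attempts")
        p <- sample(pix, 1L)
        pr <- (p - 1L) %% h + 1L
        pc <- (p - 1L) %/% h + 1L
        # try radii large to small; the polygon (plus a 1 px guard ring)
        # must sit in a single-class region
        ok <- FALSE
        for (radius in c(14, 10, 7, 5, 3)) {
          g <- radius + 2L
          if (pr - g < 1 || pr + g > h || pc - g < 1 || pc + g > w) next
          win <- gt[(pr - g):(pr + g), (pc - g):(pc + g)]
          dd <- sqrt(outer((-g:g)^2, rep(1, 2 * g + 1)) +
                       outer(rep(1, 2 * g + 1), (-g:g)^2))
          if (!all(win[dd <= radius + 1.5] == code)) next
          area <- pi * radius^2
          if (used + area > budget) next
          poly <- convex_polygon(pc - 1 + 0.5, pr - 1 + 0.5, radius)
          items[[length(items) + 1L]] <-
            list(polygon = poly, class = cls, color = class_colors[[cls]])
          used <- used + area
          placed <- placed + 1L
          ok <- TRUE
          break
        }
      }
    }
    if (!is.null(scan$vein_center)) {
      vc <- scan$vein_center
      items[[length(items) + 1L]] <-
        list(polygon = convex_polygon(vc[2], vc[1], 6), class = "auxiliary",
             color = "#00FF00")
    }
    structure(list(items = items, scan_id = "synthetic",
                   coordinate_pixel_size_um = scan$pixel_size_um),
              class = "AnnotationSet")
  })
}

#' Generate a synthetic study: scans, annotations, ground truth, manifest
#'
#' Writes `n_scans` simulated slides (2-level pyramidal TIFF with JSON
#' pixel-size sidecar), their partial annotations, their ground-truth
#' masks and a manifest JSON assigning scans to train/dev/test splits.
#'
#' @param out_dir Output directory (created if missing).
#' @param n_scans Number of scans (>= 3).
#' @param split `c(n_train, n_dev, n_test)`, summing to `n_scans`.
#' @param seed Master seed; scan `i` uses seed `seed * 1000 + i`.
#' @param extent Per-scan extent, passed to [scaffold_sim_config()].
#' @return The manifest list (invisibly): per scan `id`, `files` and
#'   `split`.
#' @export
generate_study <- function(out_dir, n_scans = 33L, split = c(25L, 4L, 4L),
                           seed = 1L, extent = c(768L, 768L)) {
  if (n_scans < 3L) stop("need at least 3 scans")
  if (sum(split) != n_scans) stop("split must sum to n_scans")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  assignment <- rep(c("train", "dev", "test"), times = split)
  scans <- list()
  for (i in seq_len(n_scans)) {
    id <- sprintf("scan%03d", i)
    cfg <- scaffold_sim_config(extent = extent, seed = seed * 1000L + i)
    scan <- generate_scaffold_scan(cfg)
    pyr <- pyramid_from_array(scan$rgb, scan$pixel_size_um, n_levels = 2L, id = id)
    tif <- file.path(out_dir, paste0(id, ".tif"))
    write_pyramid(pyr, tif)
    ann <- generate_partial_annotations(scan, seed = seed * 1000L + i)
    ann$scan_id <- id
    annpath <- file.path(out_dir, paste0(id, "_annotations.json"))
    write_annotations(ann, annpath)
    gtpath <- file.path(out_dir, paste0(id, "_gt.png"))
    write_label_mask(scan$gt, gtpath)
    scans[[i]] <- list(id = id, split = assignment[i],
                       files = list(image = basename(tif),
                                    annotations = basename(annpath),
                                    ground_truth = basename(gtpath)))
  }
  manifest <- list(seed = seed, n_scans = n_scans,
                   split = setNames(as.list(split), c("train", "dev", "test")),
                   scans = scans)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
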