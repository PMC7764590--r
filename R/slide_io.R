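#' Read a pyramidal slide image
#'
#' Reads a multi-page (pyramidal) or single-page TIFF, or a PNG, together
#' with its physical pixel size.  Pixel-size metadata is mandatory and comes
#' from a JSON sidecar (`<path>.json` or `<basename>.json`) containing at
#' least `{"pixel_size_um": <micrometres per pixel at level 0>}`.  Coarser
#' pyramid levels get their pixel size from their dimensions relative to
#' level 0.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param pixel_size_um Optional level-0 pixel size in micrometres,
#'   overriding the sidecar.  Required if no sidecar exists.
#' @return A `PyramidImage`: list with `levels` (each a list with `raster`,
#'   an H x W x 3 array in \[0,1\], and `pixel_size_um`), `base_pixel_size_um`
#'   and `id`.
#' @export
load_pyramid <- function(path, pixel_size_um = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(pixel_size_um)) {
    sidecars <- c(paste0(path, ".json"),
                  file.path(dirname(path),
                            paste0(tools::file_path_sans_ext(basename(path)), ".json")))
    sidecar <- sidecars[file.exists(sidecars)][1]
    if (is.na(sidecar))
      stop("missing pixel size: no 'pixel_size_um' given and no JSON sidecar for ", path)
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(meta$pixel_size_um))
      stop("missing pixel size: sidecar lacks 'pixel_size_um' for ", path)
    pixel_size_um <- as.numeric(meta$pixel_size_um)
  }
  stopifnot(is.numeric(pixel_size_um), pixel_size_um > 0)

  lower <- tolower(path)
  if (grepl("\\.tiff?$", lower)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  } else if (grepl("\\.png$", lower)) {
    pages <- list(png::readPNG(path))
  } else {
    stop("unreadable format: ", path, " (supported: TIFF, PNG)")
  }
  pages <- lapply(pages, as_rgb_array)
  base_w <- dim(pages[[1]])[2]
  levels <- lapply(seq_along(pages), function(k) {
    list(raster = pages[[k]],
         pixel_size_um = pixel_size_um * base_w / dim(pages[[k]])[2])
  })
  ps <- vapply(levels, function(l) l$pixel_size_um, numeric(1))
  if (is.unsorted(ps, strictly = length(ps) > 1))
    stop("pyramid levels must be ordered fine to coarse")
  structure(list(levels = levels,
                 base_pixel_size_um = pixel_size_um,
                 id = tools::file_path_sans_ext(basename(path))),
            class = "PyramidImage")
}

# coerce grayscale / RGBA rasters to H x W x 3
as_rgb_array <- function(x) {
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  if (dim(x)[3] != 3L) stop("raster must have 1, 3 or 4 channels")
  x
}

#' Build an in-memory pyramid from an RGB raster
#'
#' Convenience constructor used by the simulator and the tests: wraps a base
#' raster and optional factor-of-two coarser levels into a `PyramidImage`.
#'
#' @param rgb H x W x 3 array in \[0,1\].
#' @param pixel_size_um Level-0 pixel size in micrometres.
#' @param n_levels Number of pyramid levels (level k downsampled by 2^k).
#' @param id Scan identifier.
#' @return A `PyramidImage`.
#' @export
pyramid_from_array <- function(rgb, pixel_size_um, n_levels = 1L, id = "scan") {
  rgb <- as_rgb_array(rgb)
  levels <- vector("list", n_levels)
  levels[[1]] <- list(raster = rgb, pixel_size_um = pixel_size_um)
  for (k in seq_len(n_levels - 1L)) {
    prev <- levels[[k]]$raster
    oh <- max(1L, dim(prev)[1] %/% 2L)
    ow <- max(1L, dim(prev)[2] %/% 2L)
    levels[[k + 1L]] <- list(raster = resize_rgb(prev, oh, ow),
                             pixel_size_um = pixel_size_um * 2^k)
  }
  structure(list(levels = levels, base_pixel_size_um = pixel_size_um, id = id),
            class = "PyramidImage")
}

resize_rgb <- function(rgb, oh, ow) {
  out <- array(0, dim = c(oh, ow, 3L))
  for (ch in 1:3) out[, , ch] <- .cpp_resize_bilinear(rgb[, , ch], oh, ow)
  out
}

#' Write a pyramid to disk
#'
#' Writes all levels as a multi-page TIFF plus the JSON pixel-size sidecar
#' that [load_pyramid()] expects.
#'
#' @param pyr A `PyramidImage`.
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_pyramid <- function(pyr, path) {
  tiff::writeTIFF(lapply(pyr$levels, `[[`, "raster"), path)
  jsonlite::write_json(list(pixel_size_um = pyr$base_pixel_size_um,
                            scan_id = pyr$id),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# output extent of a resample from base pixel size to target
region_out_dim <- function(extent_px, base_um, target_um) {
  as.integer(round(extent_px * base_um / target_um))
}

#' Read a region of a pyramid at a target resolution
#'
#' Picks the finest pyramid level whose pixel size does not exceed the
#' target and resamples bilinearly to exactly the target pixel size.
#' Requesting a level's own pixel size over the full extent returns that
#' level bit-exactly.
#'
#' @param pyr A `PyramidImage`.
#' @param target_pixel_size_um Target resolution (>= base pixel size).
#' @param bbox Optional `c(row0, col0, height, width)` in level-0 pixels
#'   (0-based origin); `NULL` means the whole slide.
#' @return H x W x 3 array in \[0,1\] at the target pixel size.
#' @export
read_region <- function(pyr, target_pixel_size_um, bbox = NULL) {
  stopifnot(inherits(pyr, "PyramidImage"))
  base <- pyr$base_pixel_size_um
  if (target_pixel_size_um < base - 1e-9)
    stop("target pixel size ", target_pixel_size_um,
         " um is finer than the base resolution ", base, " um")
  dims0 <- dim(pyr$levels[[1]]$raster)
  if (is.null(bbox)) bbox <- c(0, 0, dims0[1], dims0[2])
  if (bbox[3] <= 0 || bbox[4] <= 0) stop("empty bbox")
  if (bbox[1] < 0 || bbox[2] < 0 ||
      bbox[1] + bbox[3] > dims0[1] || bbox[2] + bbox[4] > dims0[2])
    stop("bbox outside level-0 extent")

  ps <- vapply(pyr$levels, `[[`, numeric(1), "pixel_size_um")
  k <- max(which(ps <= target_pixel_size_um + 1e-9))
  lvl <- pyr$levels[[k]]
  f <- base / lvl$pixel_size_um  # level px per level-0 px
  r0 <- floor(bbox[1] * f); c0 <- floor(bbox[2] * f)
  r1 <- ceiling((bbox[1] + bbox[3]) * f); c1 <- ceiling((bbox[2] + bbox[4]) * f)
  dl <- dim(lvl$raster)
  r1 <- min(r1, dl[1]); c1 <- min(c1, dl[2])
  sub <- lvl$raster[(r0 + 1):r1, (c0 + 1):c1, , drop = FALSE]

  oh <- region_out_dim(bbox[3], base, target_pixel_size_um)
  ow <- region_out_dim(bbox[4], base, target_pixel_size_um)
  oh <- max(oh, 1L); ow <- max(ow, 1L)
  if (oh == dim(sub)[1] && ow == dim(sub)[2] &&
      abs(lvl$pixel_size_um - target_pixel_size_um) < 1e-9) {
    return(sub)
  }
  resize_rgb(sub, oh, ow)
}

#' Parse polygon annotations
#'
#' Reads the native annotation JSON schema: `{"scan_id",
#' "coordinate_pixel_size_um", "polygons": [{"color": "#FF00FF",
#' "points": [[x, y], ...]}]}`, with vertex coordinates in pixels of the
#' stated coordinate frame.  Colors map to classes via `color_map`;
#' unknown colors become auxiliary with a warning.
#'
#' @param path Annotation JSON file.
#' @param color_map Named vector, hex color -> class name
#'   (default [annotation_color_map()]).
#' @return An `AnnotationSet`: list with `items` (each a list with
#'   `polygon` (n x 2 matrix of (x, y)), `class`, `color`), `scan_id` and
#'   `coordinate_pixel_size_um`.
#' @export
parse_annotations <- function(path, color_map = annotation_color_map()) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$polygons)) stop("malformed annotation file: no 'polygons' field")
  items <- lapply(doc$polygons, function(p) {
    pts <- do.call(rbind, lapply(p$points, function(q) as.numeric(unlist(q))))
    if (is.null(pts) || nrow(pts) < 3L)
      stop("polygon with fewer than 3 vertices")
    if (!all(is.finite(pts))) stop("polygon with non-finite coordinates")
    color <- toupper(as.character(p$color))
    cls <- unname(color_map[color])
    if (is.na(cls)) {
      warning("unknown annotation color ", color, "; treating as auxiliary")
      cls <- "auxiliary"
    }
    list(polygon = pts, class = cls, color = color)
  })
  structure(list(items = items,
                 scan_id = if (is.null(doc$scan_id)) NA_character_ else doc$scan_id,
                 coordinate_pixel_size_um =
                   if (is.null(doc$coordinate_pixel_size_um)) NA_real_
                   else as.numeric(doc$coordinate_pixel_size_um)),
            class = "AnnotationSet")
}

#' Write polygon annotations
#'
#' Inverse of [parse_annotations()]; writes the native JSON schema.
#'
#' @param ann An `AnnotationSet`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  polys <- lapply(ann$items, function(it) {
    list(color = it$color,
         points = lapply(seq_len(nrow(it$polygon)),
                         function(i) as.numeric(it$polygon[i, ])))
  })
  jsonlite::write_json(list(scan_id = ann$scan_id,
                            coordinate_pixel_size_um = ann$coordinate_pixel_size_um,
                            polygons = polys),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rescale a polygon between pixel frames
#'
#' Multiplies every vertex by `factor` (target pixels per source pixel),
#' e.g. `source_pixel_size_um / target_pixel_size_um` to move annotations
#' from the scan's base resolution to a working bitmap.
#'
#' @param poly n x 2 matrix of (x, y) vertices.
#' @param factor Positive scale factor.
#' @return Scaled n x 2 vertex matrix.
#' @export
scale_polygon <- function(poly, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0)
    stop("scale factor must be a single positive number")
  poly * factor
}

#' Rescale every polygon of an annotation set
#'
#' @param ann An `AnnotationSet`.
#' @param factor Positive scale factor applied to all vertices.
#' @return The rescaled `AnnotationSet`.
#' @export
scale_annotations <- function(ann, factor) {
  ann$items <- lapply(ann$items, function(it) {
    it$polygon <- scale_polygon(it$polygon, factor)
    it
  })
  ann
}

#' Rasterize annotations to a label mask
#'
#' Fills each class polygon into an integer mask (0 = unlabeled,
#' 1 = background, 2 = intralobular, 3 = extralobular) by even-odd
#' point-in-polygon tests at pixel centers (0-based integer + 0.5).
#' Auxiliary polygons contribute no labels; later polygons overwrite
#' earlier ones on overlap.  Polygons must already be in the target pixel
#' frame.
#'
#' @param ann An `AnnotationSet`.
#' @param shape `c(H, W)` of the target raster.
#' @param pixel_size_um Pixel size of the target frame (stored as an
#'   attribute).
#' @return Integer H x W matrix with attribute `pixel_size_um`.
#' @export
rasterize_annotations <- function(ann, shape, pixel_size_um = NA_real_) {
  if (length(shape) != 2L || any(shape < 1)) stop("zero-sized shape")
  keep <- vapply(ann$items, function(it) it$class != "auxiliary", logical(1))
  items <- ann$items[keep]
  if (length(items) == 0L) {
    mask <- matrix(0L, shape[1], shape[2])
  } else {
    polys <- lapply(items, `[[`, "polygon")
    codes <- CLASS_NAMES[vapply(items, `[[`, character(1), "class")]
    mask <- .cpp_fill_polygons(as.integer(shape[1]), as.integer(shape[2]),
                               polys, as.integer(codes))
  }
  attr(mask, "pixel_size_um") <- pixel_size_um
  mask
}

#' Enumerate a tile grid
#'
#' Tile origins are multiples of `stride = tile - overlap`; the final
#' origin on each axis is clamped to `extent - tile` so the image edge is
#' covered exactly.  An image smaller than one tile yields the single
#' origin 0 with `padded = TRUE`.
#'
#' @param h,w Image extent in pixels.
#' @param tile Tile side in pixels.
#' @param overlap Overlap between adjacent tiles in pixels
#'   (`0 <= overlap < tile`).
#' @return A `TileGrid`: list with `tile`, `overlap`, `origins` (n x 2
#'   matrix of 0-based (row, col)) and `padded`.
#' @export
make_tile_grid <- function(h, w, tile, overlap = 0L) {
  stopifnot(h >= 1, w >= 1, tile >= 1)
  if (overlap >= tile || overlap < 0) stop("overlap must satisfy 0 <= overlap < tile")
  stride <- tile - overlap
  axis_origins <- function(extent) {
    if (extent <= tile) return(0L)
    last <- extent - tile
    o <- seq.int(0L, last, by = stride)
    if (o[length(o)] < last) o <- c(o, last)
    o
  }
  rows <- axis_origins(h)
  cols <- axis_origins(w)
  structure(list(tile = as.integer(tile), overlap = as.integer(overlap),
                 origins = as.matrix(expand.grid(row = rows, col = cols,
                                                 KEEP.OUT.ATTRS = FALSE)),
                 padded = (h < tile || w < tile)),
            class = "TileGrid")
}

#' Write a label mask as a PNG
#'
#' Codes 0-3 are stored in an 8-bit grayscale PNG (gray value = code/255);
#' [read_label_mask()] recovers the integer codes.
#'
#' @param mask Integer matrix with values in 0..3.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(all(mask %in% 0:3))
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' Read a label mask written by [write_label_mask()]
#'
#' @param path PNG path.
#' @return Integer matrix of codes.
#' @export
read_label_mask <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  matrix(as.integer(round(x * 255)), nrow(x), ncol(x))
}
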