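#' Gland image container
#'
#' An RGB raster of a tissue-microarray core or tile, stored as an 8-bit
#' `height x width x 3` array with 0-based pixel coordinates
#' `(x, y) = (column, row)` and pixel centers at integers.
#'
#' @param pixels numeric or integer array `h x w x 3` with values in 0..255,
#'   or an `h x w` matrix (greyscale, replicated to 3 channels).
#' @param id character image identifier.
#' @param pixel_size optional physical pixel size in micrometres.
#' @return A `gland_image` object.
#' @export
gland_image <- function(pixels, id = "image", pixel_size = NULL) {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3), dim = c(dim(pixels), 3))
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3)
  if (dim(pixels)[1] < 1 || dim(pixels)[2] < 1)
    stop_domain("image must be at least 1x1")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop_domain("channel values must lie in [0, 255]")
  structure(
    list(pixels = round(pixels), id = as.character(id), pixel_size = pixel_size),
    class = "gland_image"
  )
}

#' @export
print.gland_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<gland_image '%s' %dx%d px>\n", x$id, d[2], d[1]))
  invisible(x)
}

#' Read a PNG or TIFF image as a gland_image
#'
#' Greyscale images are replicated to three channels; the image id is the
#' file stem.
#'
#' @param path path to a PNG or TIFF file.
#' @return A [gland_image()].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_domain("image file not found: %s", path)
  img <- tryCatch(
    suppressWarnings(EBImage::readImage(path)),
    error = function(e) stop_domain("unsupported image format: %s (%s)",
                                    path, conditionMessage(e))
  )
  dat <- EBImage::imageData(img)  # (x, y[, channels]) in [0, 1]
  if (length(dim(dat)) == 2) {
    px <- t(dat) * 255
  } else {
    nc <- dim(dat)[3]
    if (nc < 3) {
      px <- t(dat[, , 1]) * 255
    } else {
      px <- array(0, dim = c(dim(dat)[2], dim(dat)[1], 3))
      for (c in 1:3) px[, , c] <- t(dat[, , c]) * 255
    }
  }
  gland_image(px, id = tools::file_path_sans_ext(basename(path)))
}

#' Write a gland_image to PNG or TIFF
#'
#' @param img a [gland_image()].
#' @param path output path; format from the extension (png/tif/tiff).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "gland_image"))
  d <- dim(img$pixels)
  dat <- array(0, dim = c(d[2], d[1], 3))
  for (c in 1:3) dat[, , c] <- t(img$pixels[, , c]) / 255
  EBImage::writeImage(EBImage::Image(dat, colormode = "Color"), path)
  invisible(path)
}

#' Construct a single segmented gland
#'
#' A gland is a closed, simple boundary polygon with its binary mask
#' (rasterized under the even-odd rule, pixel centers at integers), centroid,
#' and axial orientation in `[0, 180)` degrees.
#'
#' @param id integer gland id.
#' @param boundary `n x 2` matrix of (x, y) polygon vertices, `n >= 3`,
#'   non-self-intersecting.
#' @param mask optional precomputed logical mask (local bounding-box raster);
#'   rasterized from `boundary` when omitted.
#' @param offset (x0, y0) corner of the local mask in image coordinates.
#' @return A `gland` object.
#' @export
gland <- function(id, boundary, mask = NULL, offset = NULL) {
  boundary <- as.matrix(boundary)
  if (nrow(boundary) >= 2 &&
      all(abs(boundary[1, ] - boundary[nrow(boundary), ]) < 1e-12))
    boundary <- boundary[-nrow(boundary), , drop = FALSE]
  if (nrow(boundary) < 3) stop_domain("gland %s: boundary needs >= 3 vertices", id)
  if (is.null(mask)) {
    r <- rasterize_polygon(boundary)
    mask <- r$mask; offset <- r$offset
  }
  if (sum(mask) == 0) stop_domain("gland %s: empty mask", id)
  co <- mask_coords(mask, offset)
  centroid <- c(x = mean(co[, 1]), y = mean(co[, 2]))
  ori <- mask_orientation(co)
  structure(
    list(id = as.integer(id), boundary = boundary, mask = mask,
         offset = offset, centroid = centroid,
         orientation_deg = ori$angle, degenerate = ori$degenerate),
    class = "gland"
  )
}

#' Validate gland invariants
#'
#' Checks the shared contract every gland in the package must satisfy:
#' simple boundary polygon with at least 3 vertices, non-empty mask, and
#' orientation in `[0, 180)`.
#'
#' @param g a [gland()].
#' @return `TRUE` invisibly; otherwise an error.
#' @export
validate_gland <- function(g) {
  stopifnot(inherits(g, "gland"))
  if (nrow(g$boundary) < 3) stop_domain("gland %d: < 3 vertices", g$id)
  if (!is_simple_polygon(g$boundary))
    stop_domain("gland %d: boundary is self-intersecting", g$id)
  if (sum(g$mask) <= 0) stop_domain("gland %d: empty mask", g$id)
  if (g$orientation_deg < 0 || g$orientation_deg >= 180)
    stop_domain("gland %d: orientation outside [0, 180)", g$id)
  invisible(TRUE)
}

#' Construct an ordered collection of glands for one image
#'
#' @param image_id character id of the source image.
#' @param glands list of [gland()] objects with unique ids.
#' @param provenance one of "segmented", "imported", "synthetic".
#' @return A `gland_set` object.
#' @export
gland_set <- function(image_id, glands, provenance = "imported") {
  provenance <- match.arg(provenance, c("segmented", "imported", "synthetic"))
  ids <- vapply(glands, function(g) g$id, integer(1))
  if (anyDuplicated(ids)) stop_domain("duplicate gland ids in set '%s'", image_id)
  structure(list(image_id = as.character(image_id), glands = glands,
                 provenance = provenance),
            class = "gland_set")
}

#' @export
print.gland_set <- function(x, ...) {
  cat(sprintf("<gland_set '%s': %d glands (%s)>\n",
              x$image_id, length(x$glands), x$provenance))
  invisible(x)
}

#' @export
length.gland_set <- function(x) length(x$glands)

#' Import gland contours from a GeoJSON FeatureCollection
#'
#' Each Polygon feature (pixel coordinates, outer ring) becomes one gland
#' with a rasterized mask. Supports external segmentations of real images.
#'
#' @param path path to a GeoJSON file of Polygon features.
#' @param image_id image identifier; defaults to the file stem.
#' @return A [gland_set()] with provenance "imported".
#' @export
read_contours <- function(path, image_id = NULL) {
  if (!file.exists(path)) stop_domain("contour file not found: %s", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    stop_domain("expected a GeoJSON FeatureCollection")
  image_id <- image_id %||% tools::file_path_sans_ext(basename(path))
  glands <- vector("list", length(gj$features))
  for (i in seq_along(gj$features)) {
    f <- gj$features[[i]]
    if (!identical(f$geometry$type, "Polygon"))
      stop_domain("feature %d: only Polygon geometries are supported", i)
    ring <- f$geometry$coordinates[[1]]
    poly <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    if (nrow(poly) >= 2 && all(abs(poly[1, ] - poly[nrow(poly), ]) < 1e-12))
      poly <- poly[-nrow(poly), , drop = FALSE]
    if (!is_simple_polygon(poly))
      stop_domain("feature %d: polygon is self-intersecting", i)
    gid <- f$properties$id %||% i
    glands[[i]] <- gland(gid, poly)
  }
  gland_set(image_id, glands, provenance = "imported")
}

#' Write gland contours as GeoJSON
#'
#' @param gs a [gland_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contours <- function(gs, path) {
  stopifnot(inherits(gs, "gland_set"))
  feats <- lapply(gs$glands, function(g) {
    ring <- rbind(g$boundary, g$boundary[1, ])
    list(type = "Feature",
         properties = list(id = g$id,
                           orientation_deg = g$orientation_deg),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Read a clinical cohort table
#'
#' CSV with one row per patient/core. Required columns: `patient_id`,
#' `image_id`, `recurrence` (0/1), `survival_time` (months, >= 0),
#' `event` (0/1). Additional covariate columns are kept as given.
#'
#' @param path CSV path.
#' @return A `data.frame` with class `cohort_table`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_domain("cohort file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(df)
}

#' Validate a cohort table against its schema
#'
#' @param df a data.frame.
#' @return `df`, with class `cohort_table`.
#' @export
validate_cohort <- function(df) {
  req <- c("patient_id", "image_id", "recurrence", "survival_time", "event")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop_domain("cohort table missing required column(s): %s",
                paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$patient_id)) stop_domain("patient_id values must be unique")
  if (any(df$survival_time < 0)) stop_domain("survival_time must be >= 0")
  if (!all(df$recurrence %in% c(0, 1))) stop_domain("recurrence must be 0/1")
  if (!all(df$event %in% c(0, 1))) stop_domain("event must be 0/1")
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Write a 16-bit label mask TIFF (0 = background, k = gland k)
#'
#' @param gs a [gland_set()].
#' @param dim_hw c(height, width) of the target raster.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(gs, dim_hw, path) {
  lab <- paint_labels(gs$glands, dim_hw)
  EBImage::writeImage(EBImage::Image(t(lab) / 65535), path, bits.per.sample = 16L)
  invisible(path)
}
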