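#' Portal (MV imager) image container
#'
#' A 2-D pixel grid plus the acquisition geometry needed to interpret it:
#' gantry angle, pixel pitch and the central-pixel coordinates. Pixel
#' coordinates are 0-based with (0, 0) at the top-left; physical panel
#' coordinates are mm relative to the central pixel, u increasing with column
#' (+X at gantry 0) and v with row.
#'
#' @param pixels Numeric matrix, rows = v, columns = u. Higher values = more
#'   signal (attenuating objects appear as dips).
#' @param gantry_angle_deg Set gantry angle of the acquisition, degrees.
#' @param geom A [machine_geometry()].
#' @param central_px c(u, v) 0-based pixel coordinates of the beam axis;
#'   default the geometric centre of the matrix.
#' @param truth Optional list of simulator ground truth (see [render_mvi()]).
#' @return An object of class `portal_image`.
#' @export
portal_image <- function(pixels, gantry_angle_deg, geom = machine_geometry(),
                         central_px = NULL, truth = NULL) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (any(!is.finite(pixels))) stop("`pixels` must be finite", call. = FALSE)
  if (is.null(central_px)) {
    central_px <- c((ncol(pixels) - 1) / 2, (nrow(pixels) - 1) / 2)
  }
  stopifnot(length(central_px) == 2L)
  structure(
    list(pixels = pixels,
         gantry_angle_deg = normalize_gantry_angle(gantry_angle_deg),
         geom = geom,
         central_px = central_px,
         truth = truth),
    class = "portal_image"
  )
}

#' @export
print.portal_image <- function(x, ...) {
  cat(sprintf("<portal_image> %d x %d px, gantry %.1f deg, pitch %.3f mm\n",
              nrow(x$pixels), ncol(x$pixels), x$gantry_angle_deg,
              x$geom$pixel_pitch_mm))
  if (!is.null(x$truth)) cat("  carries simulator ground truth\n")
  invisible(x)
}

#' @export
dim.portal_image <- function(x) dim(x$pixels)

# mm coordinate of 0-based column / row indices
panel_u_mm <- function(image, col0) (col0 - image$central_px[1]) * image$geom$pixel_pitch_mm
panel_v_mm <- function(image, row0) (row0 - image$central_px[2]) * image$geom$pixel_pitch_mm

#' Write / read a portal image as TIFF or PNG with a YAML sidecar
#'
#' The pixel matrix is stored as a 16-bit grayscale image; acquisition
#' metadata (gantry angle, geometry, central pixel, pixel-value scaling and
#' any simulator ground truth) goes to `<path>.yaml`. `read_portal_image()`
#' restores the object; missing sidecar metadata must be supplied through
#' `geom`/`gantry_angle_deg` arguments or the read fails with an explicit
#' error. RGB input is rejected: portal images are single-channel.
#'
#' DICOM files are not supported; export QA images as 16-bit TIFF/PNG first.
#'
#' @param image A [portal_image()].
#' @param path Output file, extension `.tif`/`.tiff` or `.png`.
#' @return `write_portal_image()` returns `path` invisibly;
#'   `read_portal_image()` returns a [portal_image()].
#' @export
write_portal_image <- function(image, path) {
  stopifnot(inherits(image, "portal_image"))
  px <- image$pixels
  lo <- min(px); hi <- max(px)
  scale <- if (hi > lo) hi - lo else 1
  norm <- (px - lo) / scale
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(norm, path, bits.per.sample = 16L)
  } else if (ext == "png") {
    png::writePNG(norm, path)
  } else {
    stop("unsupported image format: .", ext, " (use .tif/.tiff/.png)",
         call. = FALSE)
  }
  meta <- list(
    gantry_angle_deg = image$gantry_angle_deg,
    central_px = as.numeric(image$central_px),
    value_offset = lo,
    value_scale = scale,
    geometry = list(sad_cm = image$geom$sad_cm, sid_cm = image$geom$sid_cm,
                    pixel_pitch_mm = image$geom$pixel_pitch_mm,
                    panel_extent_cm = as.numeric(image$geom$panel_extent_cm))
  )
  if (!is.null(image$truth)) meta$truth <- image$truth
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".yaml")

#' @rdname write_portal_image
#' @param gantry_angle_deg,geom Fallbacks used when the sidecar is missing.
#' @export
read_portal_image <- function(path, gantry_angle_deg = NULL, geom = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "dcm") {
    stop("DICOM input is not supported; export the image as 16-bit TIFF or ",
         "PNG with a YAML sidecar (see write_portal_image())", call. = FALSE)
  }
  px <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(px)) == 3L) {
    stop("multi-channel (RGB) image rejected: portal images must be ",
         "single-channel grayscale", call. = FALSE)
  }
  meta <- if (file.exists(sidecar_path(path))) {
    yaml::read_yaml(sidecar_path(path))
  } else {
    NULL
  }
  if (is.null(meta)) {
    if (is.null(geom)) {
      stop("no sidecar metadata found and no `geom` supplied: pixel pitch ",
           "and distances are required to interpret the image", call. = FALSE)
    }
    if (is.null(gantry_angle_deg)) {
      stop("no sidecar metadata found and no `gantry_angle_deg` supplied",
           call. = FALSE)
    }
    return(portal_image(px, gantry_angle_deg, geom))
  }
  g <- meta$geometry
  geom <- geom %||% machine_geometry(
    sad_cm = g$sad_cm, sid_cm = g$sid_cm, pixel_pitch_mm = g$pixel_pitch_mm,
    panel_extent_cm = as.numeric(unlist(g$panel_extent_cm))
  )
  px <- px * meta$value_scale + meta$value_offset
  portal_image(px,
               gantry_angle_deg = gantry_angle_deg %||% meta$gantry_angle_deg,
               geom = geom,
               central_px = as.numeric(unlist(meta$central_px)),
               truth = meta$truth)
}
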