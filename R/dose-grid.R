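#' 2-D dose map container
#'
#' A rectangular dose map on a uniform grid, with mm spacing and origin, as
#' produced by a 2-D detector array or a TPS planar export. `values[iy, ix]`
#' holds the dose at `x = origin[1] + (ix - 1) * spacing[1]`,
#' `y = origin[2] + (iy - 1) * spacing[2]`.
#'
#' @param values Numeric matrix of dose (Gy or %), finite and non-negative.
#' @param spacing_mm Grid spacing c(sx, sy) in mm (a scalar is recycled); > 0.
#' @param origin_mm Physical coordinates c(x, y) of `values[1, 1]`, mm.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(values, spacing_mm, origin_mm = c(0, 0)) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (any(!is.finite(values))) stop("dose values must be finite", call. = FALSE)
  if (any(values < 0)) stop("dose values must be non-negative", call. = FALSE)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 2L)
  stopifnot(length(spacing_mm) == 2L, length(origin_mm) == 2L)
  if (any(spacing_mm <= 0)) stop("`spacing_mm` must be positive", call. = FALSE)
  structure(
    list(values = values, spacing_mm = as.numeric(spacing_mm),
         origin_mm = as.numeric(origin_mm)),
    class = "dose_grid"
  )
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf(
    "<dose_grid> %d x %d points, spacing %.3g x %.3g mm, origin (%.3g, %.3g) mm\n",
    ncol(x$values), nrow(x$values), x$spacing_mm[1], x$spacing_mm[2],
    x$origin_mm[1], x$origin_mm[2]))
  cat(sprintf("  dose range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.dose_grid <- function(x) dim(x$values)

grid_x <- function(g) g$origin_mm[1] + (seq_len(ncol(g$values)) - 1) * g$spacing_mm[1]
grid_y <- function(g) g$origin_mm[2] + (seq_len(nrow(g$values)) - 1) * g$spacing_mm[2]

#' Tidy a dose grid to a long tibble
#' @param x A [dose_grid()].
#' @param ... Unused.
#' @return A tibble with columns `x_mm`, `y_mm`, `dose`.
#' @export
tidy.dose_grid <- function(x, ...) {
  tibble::tibble(
    x_mm = rep(grid_x(x), each = nrow(x$values)),
    y_mm = rep(grid_y(x), times = ncol(x$values)),
    dose = as.vector(x$values)
  )
}

#' Read and write delimited-text dose grids
#'
#' Plain-text planar dose format shared by the simulator and the gamma module:
#' a 3-line header
#' \preformatted{# nx <nx> ny <ny>
#' # spacing_mm <sx> <sy>
#' # origin_mm <ox> <oy>}
#' followed by `ny` rows of `nx` whitespace-separated doses (6 significant
#' figures on write, so write-read-write is textually stable).
#'
#' @param grid A [dose_grid()].
#' @param path File path.
#' @return `write_dose_grid()` returns `path` invisibly; `read_dose_grid()`
#'   returns a [dose_grid()].
#' @export
write_dose_grid <- function(grid, path) {
  stopifnot(inherits(grid, "dose_grid"))
  v <- grid$values
  hdr <- c(
    sprintf("# nx %d ny %d", ncol(v), nrow(v)),
    sprintf("# spacing_mm %.6g %.6g", grid$spacing_mm[1], grid$spacing_mm[2]),
    sprintf("# origin_mm %.6g %.6g", grid$origin_mm[1], grid$origin_mm[2])
  )
  rows <- apply(v, 1L, function(r) paste(sprintf("%.6g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_dose_grid
#' @export
read_dose_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 4L) stop("malformed dose grid file: fewer than 4 lines",
                               call. = FALSE)
  parse_hdr <- function(i, key, n) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) < 2L + n || parts[1] != "#" || parts[2] != key) {
      stop(sprintf("malformed dose grid header at line %d: expected '# %s ...'",
                   i, key), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(parts[3:(2 + n)]))
    if (any(is.na(vals))) {
      stop(sprintf("malformed dose grid header at line %d: non-numeric value", i),
           call. = FALSE)
    }
    vals
  }
  nxy <- parse_hdr(1L, "nx", 1L)
  ny <- {
    parts <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    if (length(parts) != 5L || parts[4] != "ny") {
      stop("malformed dose grid header at line 1: expected '# nx <n> ny <n>'",
           call. = FALSE)
    }
    as.numeric(parts[5])
  }
  nx <- nxy[1]
  spacing <- parse_hdr(2L, "spacing_mm", 2L)
  origin <- parse_hdr(3L, "origin_mm", 2L)
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != ny) {
    stop(sprintf("dose grid body has %d rows but header declares ny = %d (line 1)",
                 length(body), ny), call. = FALSE)
  }
  vals <- lapply(seq_along(body), function(i) {
    r <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "\\s+")[[1]]))
    if (length(r) != nx || any(is.na(r))) {
      stop(sprintf("dose grid row at line %d has %d values, expected nx = %d",
                   i + 3L, length(r), nx), call. = FALSE)
    }
    r
  })
  dose_grid(do.call(rbind, vals), spacing_mm = spacing, origin_mm = origin)
}
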