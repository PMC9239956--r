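#' Beam-axis line construction
#'
#' `displacement_to_axis_line()` back-projects a measured panel displacement
#' into the transverse (X-Z) isocentre plane: a point imaged `u` mm from the
#' central pixel lies on the ray whose perpendicular offset from the central
#' axis is `u / M` (`M = sid/sad`), directed along the beam. With `u = 1.5`
#' mm and `M = 1.5` at gantry 0 this is the vertical line at x = 1.0 mm.
#' `axis_line_through()` builds the line through a known point directly.
#'
#' @param u_mm Signed panel displacement from the central pixel, mm.
#' @param angle_deg Gantry angle, degrees.
#' @param geom A [machine_geometry()].
#' @return A one-row tibble with columns `angle_deg`, `px`, `pz` (a point on
#'   the line, mm), `dx`, `dz` (unit beam direction), `nx`, `nz` (unit
#'   normal) and `c` (signed line offset, `n . p`).
#' @export
displacement_to_axis_line <- function(u_mm, angle_deg,
                                      geom = machine_geometry()) {
  offset <- u_mm / magnification(geom)
  e_u <- panel_u_axis(angle_deg)
  axis_line_through(offset * e_u, angle_deg)
}

#' @rdname displacement_to_axis_line
#' @param point_mm c(x, z) point on the line in the isocentre plane, mm.
#' @export
axis_line_through <- function(point_mm, angle_deg) {
  d <- beam_direction(angle_deg)
  n <- c(-d[2], d[1])  # unit normal
  tibble::tibble(angle_deg = normalize_gantry_angle(angle_deg),
                 px = point_mm[1], pz = point_mm[2],
                 dx = d[1], dz = d[2], nx = n[1], nz = n[2],
                 c = n[1] * point_mm[1] + n[2] * point_mm[2])
}

# distance of point(s) p (n x 2 matrix) to each line: |N p - c| per line
line_distances <- function(lines, p) {
  abs(lines$nx * p[1] + lines$nz * p[2] - lines$c)
}

# Exact minimax centre for a small set of lines, by enumerating the LP
# vertices: pairwise line intersections (optimum with zero radius or a
# line-constraint pair active) and every triple of lines with the four
# distinct sign patterns of the active |.| constraints. Returns list(center,
# radius) minimizing max_i |n_i . p - c_i| over the subset.
minimax_enumerate <- function(lines) {
  m <- nrow(lines)
  N <- cbind(lines$nx, lines$nz)
  cc <- lines$c
  cands <- list()
  # pairwise intersections
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      A <- rbind(N[i, ], N[j, ])
      det <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
      if (abs(det) < 1e-12) next
      cands[[length(cands) + 1L]] <-
        c((cc[i] * A[2, 2] - cc[j] * A[1, 2]) / det,
          (cc[j] * A[1, 1] - cc[i] * A[2, 1]) / det)
    }
  }
  # triples with sign patterns (s1, s2, s3); overall sign flip is equivalent,
  # so fix s1 = +1
  if (m >= 3) {
    signs <- rbind(c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
    combos <- utils::combn(m, 3)
    for (ci in seq_len(ncol(combos))) {
      idx <- combos[, ci]
      for (si in seq_len(nrow(signs))) {
        s <- signs[si, ]
        A <- cbind(N[idx, , drop = FALSE], -s)
        det3 <- det(A)
        if (abs(det3) < 1e-12) next
        # a global sign flip maps (p, t) -> (p, -t): the centre is a valid
        # candidate whatever the sign of t
        sol <- solve(A, cc[idx])
        cands[[length(cands) + 1L]] <- sol[1:2]
      }
    }
  }
  if (!length(cands)) stop("degenerate line set", call. = FALSE)
  best_r <- Inf
  best_p <- NULL
  for (p in cands) {
    r <- max(line_distances(lines, p))
    if (r < best_r - 1e-15) {
      best_r <- r
      best_p <- p
    }
  }
  list(center = best_p, radius = best_r)
}

#' Fit the MV radiation isocentre from beam-axis lines
#'
#' The isocentre is taken as the Chebyshev point of the axis lines: the
#' centre minimizing the maximum point-to-line distance, i.e. the centre of
#' the smallest circle touched or crossed by every axis; the diameter is
#' twice that minimax distance. The fit is exact (an active-set solver over
#' the LP vertices of the minimax problem) and deterministic.
#'
#' At least 3 lines with non-degenerate angular coverage are required; a set
#' of mutually parallel lines has no transverse intersection and errors.
#'
#' @param lines Tibble of axis lines, as built by
#'   [displacement_to_axis_line()] (rows may be concatenated with
#'   `dplyr::bind_rows()`).
#' @param excluded_angles Angles that were dropped upstream, recorded in the
#'   result for reporting.
#' @return An object of class `isocentre_fit`: list with `center_mm` (x, z),
#'   `diameter_mm`, `residuals_mm` (per-line distance from the centre),
#'   `n_projections`, `excluded_angles`, `lines`.
#' @export
fit_isocentre <- function(lines, excluded_angles = numeric()) {
  stopifnot(is.data.frame(lines),
            all(c("nx", "nz", "c", "angle_deg") %in% names(lines)))
  if (nrow(lines) < 3) {
    stop("insufficient angular coverage: need at least 3 axis lines",
         call. = FALSE)
  }
  # all parallel (normals collinear)?
  cross <- abs(outer(lines$nx, lines$nz) - outer(lines$nz, lines$nx))
  if (max(cross) < 1e-9) {
    stop("insufficient angular coverage: all axis lines are parallel",
         call. = FALSE)
  }
  m <- nrow(lines)
  # active-set: solve exactly on a small subset, add the worst violator
  dir_ang <- atan2(lines$nz, lines$nx) %% pi
  ord <- order(dir_ang)
  active <- unique(c(ord[1], ord[ceiling(m / 3)], ord[ceiling(2 * m / 3)],
                     ord[m]))
  if (length(active) < 3) active <- unique(c(active, seq_len(min(3, m))))
  repeat {
    sol <- minimax_enumerate(lines[active, , drop = FALSE])
    d_all <- line_distances(lines, sol$center)
    worst <- which.max(d_all)
    if (d_all[worst] <= sol$radius + 1e-10 || worst %in% active) break
    active <- c(active, worst)
    if (length(active) > m) break
  }
  res <- line_distances(lines, sol$center)
  structure(
    list(center_mm = setNames(sol$center, c("x", "z")),
         diameter_mm = 2 * max(res),
         residuals_mm = res,
         n_projections = m,
         excluded_angles = excluded_angles,
         lines = lines),
    class = "isocentre_fit"
  )
}

#' @export
print.isocentre_fit <- function(x, ...) {
  cat("<isocentre_fit>\n")
  cat(sprintf("  centre (%.3f, %.3f) mm; diameter %.3f mm; %d projections\n",
              x$center_mm[1], x$center_mm[2], x$diameter_mm, x$n_projections))
  if (length(x$excluded_angles)) {
    cat("  excluded angles:", paste(x$excluded_angles, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy an isocentre fit: one row per projection
#' @param x An `isocentre_fit`.
#' @param ... Unused.
#' @return Tibble with `angle_deg`, the line parameters and `residual_mm`.
#' @export
tidy.isocentre_fit <- function(x, ...) {
  dplyr::bind_cols(x$lines, tibble::tibble(residual_mm = x$residuals_mm))
}

#' Summarize an isocentre fit in one row
#' @param x An `isocentre_fit`.
#' @param ... Unused.
#' @return One-row tibble: centre, diameter, residual spread, n, tolerance
#'   verdict at 1.00 mm.
#' @export
glance.isocentre_fit <- function(x, ...) {
  tibble::tibble(center_x_mm = unname(x$center_mm[1]),
                 center_z_mm = unname(x$center_mm[2]),
                 diameter_mm = x$diameter_mm,
                 max_residual_mm = max(x$residuals_mm),
                 rms_residual_mm = sqrt(mean(x$residuals_mm^2)),
                 n_projections = x$n_projections,
                 within_tolerance_1mm = x$diameter_mm <= 1.00)
}

#' Plot an isocentre fit: axis lines and the minimax circle
#' @param object An `isocentre_fit`.
#' @param ... Unused.
#' @param span_mm Half-extent of the plotted region, mm.
#' @return A ggplot object.
#' @export
autoplot.isocentre_fit <- function(object, ..., span_mm = NULL) {
  span_mm <- span_mm %||% max(1, 3 * object$diameter_mm)
  cx <- object$center_mm[1]; cz <- object$center_mm[2]
  segs <- purrr::pmap_dfr(object$lines, function(angle_deg, px, pz, dx, dz,
                                                 nx, nz, c, ...) {
    tibble::tibble(x = px - 2 * span_mm * dx, z = pz - 2 * span_mm * dz,
                   xend = px + 2 * span_mm * dx, zend = pz + 2 * span_mm * dz,
                   angle_deg = angle_deg)
  })
  th <- seq(0, 2 * pi, length.out = 181)
  circ <- tibble::tibble(x = cx + object$diameter_mm / 2 * cos(th),
                         z = cz + object$diameter_mm / 2 * sin(th))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, y = .data$z,
                                       xend = .data$xend, yend = .data$zend),
                          alpha = 0.4, linewidth = 0.3) +
    ggplot2::geom_path(data = circ, ggplot2::aes(x = .data$x, y = .data$z),
                       colour = "red") +
    ggplot2::annotate("point", x = cx, y = cz, colour = "red", size = 1) +
    ggplot2::coord_fixed(xlim = c(cx - span_mm, cx + span_mm),
                         ylim = c(cz - span_mm, cz + span_mm)) +
    ggplot2::labs(x = "x [mm]", y = "z [mm]",
                  title = sprintf("MV isocentre: diameter %.3f mm",
                                  object$diameter_mm)) +
    ggplot2::theme_minimal()
}

# Angles (deg) at which couch / phantom edges distort the ballbearing image:
# the arcs 50..130 and 230..310.
in_distortion_arc <- function(angle_deg) {
  a <- normalize_gantry_angle(angle_deg)
  (a >= 50 & a <= 130) | (a >= 230 & a <= 310)
}

#' Full isocentre analysis of a projection series
#'
#' Localizes the central ballbearing on every image ([locate_bb()]), drops
#' the excluded angles, back-projects each transverse displacement into a
#' beam-axis line and fits the isocentre. Because the gantry ring is rigid, a
#' beam-axis offset displaces the ballbearing image in the opposite sense
#' scaled by the magnification, so the *negated* measured displacement is
#' back-projected. Background subtraction is applied automatically for
#' angles inside the couch-distortion arcs (50-130 and 230-310 degrees), or
#' always/never on request. Images whose localization fails are reported and
#' skipped; the analysis continues while at least 3 usable lines remain.
#'
#' @param images List of [portal_image()]s carrying gantry angles (e.g. from
#'   [render_projection_series()] or [read_portal_image()]).
#' @param geom A [machine_geometry()]; default the geometry of the first
#'   image.
#' @param excluded_angles Gantry angles to drop, degrees.
#' @param background `"auto"` (distortion arcs only), `"always"` or
#'   `"never"`.
#' @param roi,roi_half_mm Passed to [locate_bb()].
#' @return An `isocentre_fit` whose `per_image` element tabulates each
#'   projection (angle, displacement, longitudinal v displacement, status).
#' @export
run_isocentre_analysis <- function(images, geom = NULL,
                                   excluded_angles = c(10, 20, 60, 300),
                                   background = c("auto", "always", "never"),
                                   roi = NULL, roi_half_mm = 12) {
  background <- match.arg(background)
  stopifnot(length(images) >= 1)
  geom <- geom %||% images[[1]]$geom
  rows <- purrr::map_dfr(images, function(im) {
    a <- im$gantry_angle_deg
    if (any(abs(normalize_gantry_angle(excluded_angles) - a) < 1e-6)) {
      return(tibble::tibble(angle_deg = a, u_mm = NA_real_, v_mm = NA_real_,
                            status = "excluded"))
    }
    bg <- switch(background, always = TRUE, never = FALSE,
                 auto = in_distortion_arc(a))
    loc <- tryCatch(locate_bb(im, roi = roi, roi_half_mm = roi_half_mm,
                              background = bg),
                    error = function(e) conditionMessage(e))
    if (is.character(loc)) {
      return(tibble::tibble(angle_deg = a, u_mm = NA_real_, v_mm = NA_real_,
                            status = paste("failed:", loc)))
    }
    tibble::tibble(angle_deg = a, u_mm = loc$u_mm, v_mm = loc$v_mm,
                   status = "used")
  })
  used <- rows[rows$status == "used", , drop = FALSE]
  failed <- rows$status[!rows$status %in% c("used", "excluded")]
  if (length(failed)) {
    message("localization failed for ", length(failed), " image(s); ",
            "continuing with ", nrow(used), " lines")
  }
  if (nrow(used) < 3) {
    stop("insufficient usable projections (", nrow(used), ") after ",
         "exclusions and failures", call. = FALSE)
  }
  lines <- purrr::pmap_dfr(used[, c("angle_deg", "u_mm")],
                           function(angle_deg, u_mm) {
    displacement_to_axis_line(-u_mm, angle_deg, geom)
  })
  fit <- fit_isocentre(lines, excluded_angles = excluded_angles)
  fit$per_image <- rows
  fit
}
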