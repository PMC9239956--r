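#' Gamma-comparison criteria
#'
#' Dose-difference / distance-to-agreement criteria for the gamma index,
#' with the normalization mode, the low-dose suppression threshold and the
#' evaluated-grid interpolation step.
#'
#' @param dose_diff_pct Dose-difference criterion, percent; > 0.
#' @param dta_mm Distance-to-agreement, mm; > 0.
#' @param normalization `"global"` (percent of the reference maximum) or
#'   `"local"` (percent of the reference dose at each point).
#' @param suppression_pct Reference doses below this percent of the reference
#'   maximum are excluded from the analysis; in [0, 100).
#' @param interpolation_step Evaluated-grid interpolation step as a fraction
#'   of `dta_mm`; default 0.1.
#' @return An object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_diff_pct = 2, dta_mm = 2,
                           normalization = c("local", "global"),
                           suppression_pct = 10, interpolation_step = 0.1) {
  normalization <- match.arg(normalization)
  if (dose_diff_pct <= 0 || dta_mm <= 0) {
    stop("`dose_diff_pct` and `dta_mm` must be positive", call. = FALSE)
  }
  if (suppression_pct < 0 || suppression_pct >= 100) {
    stop("`suppression_pct` must lie in [0, 100)", call. = FALSE)
  }
  if (interpolation_step <= 0 || interpolation_step > 1) {
    stop("`interpolation_step` must lie in (0, 1]", call. = FALSE)
  }
  structure(list(dose_diff_pct = dose_diff_pct, dta_mm = dta_mm,
                 normalization = normalization,
                 suppression_pct = suppression_pct,
                 interpolation_step = interpolation_step),
            class = "gamma_criteria")
}

#' @export
print.gamma_criteria <- function(x, ...) {
  cat(sprintf("<gamma_criteria> %.1f %% %s / %.1f mm, suppression < %.1f %%\n",
              x$dose_diff_pct, x$normalization, x$dta_mm, x$suppression_pct))
  invisible(x)
}

# bilinear interpolation of dose_grid g at arbitrary points (NA outside)
bilinear_at <- function(g, x, y) {
  sx <- g$spacing_mm[1]; sy <- g$spacing_mm[2]
  fx <- (x - g$origin_mm[1]) / sx
  fy <- (y - g$origin_mm[2]) / sy
  nx <- ncol(g$values); ny <- nrow(g$values)
  i0 <- floor(fx); j0 <- floor(fy)
  inside <- fx >= 0 & fx <= nx - 1 & fy >= 0 & fy <= ny - 1
  i0 <- pmin(pmax(i0, 0), nx - 2); j0 <- pmin(pmax(j0, 0), ny - 2)
  tx <- fx - i0; ty <- fy - j0
  v <- g$values
  idx <- function(jj, ii) v[cbind(jj + 1, ii + 1)]
  out <- (1 - tx) * (1 - ty) * idx(j0, i0) +
    tx * (1 - ty) * idx(j0, i0 + 1) +
    (1 - tx) * ty * idx(j0 + 1, i0) +
    tx * ty * idx(j0 + 1, i0 + 1)
  out[!inside] <- NA_real_
  out
}

#' Gamma-index map of two planar dose distributions
#'
#' For every reference point above the suppression threshold, the gamma
#' index is the minimum over evaluated positions within the search radius
#' (3 x DTA) of `sqrt((dDose/dD)^2 + (r/DTA)^2)`, with the evaluated
#' distribution bilinearly interpolated on a grid of step
#' `interpolation_step * DTA`. Dose differences are normalized by the
#' reference maximum (global) or the local reference dose (local). A point
#' passes when gamma <= 1.
#'
#' @param ref Reference [dose_grid()] (the measured or planned map whose
#'   points interrogate the other distribution).
#' @param eval Evaluated [dose_grid()]. Must overlap `ref` spatially.
#' @param criteria A [gamma_criteria()].
#' @return An object of class `gamma_result`: list with `gamma` (matrix
#'   aligned with `ref$values`, NA at suppressed points), `pass_rate`
#'   (percent of evaluated points with gamma <= 1), `n_evaluated`,
#'   `n_suppressed`, `criteria`, `ref`.
#' @export
gamma_map <- function(ref, eval, criteria = gamma_criteria()) {
  stopifnot(inherits(ref, "dose_grid"), inherits(eval, "dose_grid"),
            inherits(criteria, "gamma_criteria"))
  rx <- range(grid_x(ref)); ry <- range(grid_y(ref))
  ex <- range(grid_x(eval)); ey <- range(grid_y(eval))
  if (rx[1] > ex[2] || rx[2] < ex[1] || ry[1] > ey[2] || ry[2] < ey[1]) {
    stop("reference and evaluated grids do not overlap spatially",
         call. = FALSE)
  }
  if (max(ref$spacing_mm) > criteria$dta_mm) {
    warning("grid spacing coarser than the DTA criterion; gamma may be ",
            "overestimated", call. = FALSE)
  }
  dmax <- max(ref$values)
  if (dmax <= 0) stop("reference grid carries no dose", call. = FALSE)
  thr <- criteria$suppression_pct / 100 * dmax
  X <- rep(grid_x(ref), each = nrow(ref$values))
  Y <- rep(grid_y(ref), times = ncol(ref$values))
  Dr <- as.vector(ref$values)
  keep <- Dr >= thr & Dr > 0
  dD <- if (criteria$normalization == "global") {
    rep(criteria$dose_diff_pct / 100 * dmax, sum(keep))
  } else {
    criteria$dose_diff_pct / 100 * Dr[keep]
  }
  xs <- X[keep]; ys <- Y[keep]; ds <- Dr[keep]
  dta <- criteria$dta_mm
  h <- criteria$interpolation_step * dta
  rmax <- 3 * dta
  k <- seq(-floor(rmax / h), floor(rmax / h))
  offs <- expand.grid(dx = k * h, dy = k * h)
  offs <- offs[offs$dx^2 + offs$dy^2 <= rmax^2 + 1e-12, , drop = FALSE]
  offs <- offs[order(offs$dx^2 + offs$dy^2), , drop = FALSE]
  np <- length(xs)
  K <- 12L
  # per point, keep the K best coarse offsets (sorted gamma^2 and their
  # offsets): the refinement stage searches around each, so a minimum lying
  # in a competing basin of the coarse grid is still found
  G <- matrix(Inf, np, K)
  BX <- matrix(0, np, K); BY <- matrix(0, np, K)
  for (i in seq_len(nrow(offs))) {
    r2 <- (offs$dx[i]^2 + offs$dy[i]^2) / dta^2
    if (r2 >= max(G[, K])) next  # cannot enter any candidate list
    de <- bilinear_at(eval, xs + offs$dx[i], ys + offs$dy[i])
    cand <- ((de - ds) / dD)^2 + r2
    cand[is.na(cand)] <- Inf
    cx <- rep(offs$dx[i], np); cy <- rep(offs$dy[i], np)
    for (k in seq_len(K)) {  # sorted insert
      sw <- cand < G[, k]
      if (!any(sw)) break
      tmp <- G[sw, k]; G[sw, k] <- cand[sw]; cand[sw] <- tmp
      tmp <- BX[sw, k]; BX[sw, k] <- cx[sw]; cx[sw] <- tmp
      tmp <- BY[sw, k]; BY[sw, k] <- cy[sw]; cy[sw] <- tmp
    }
  }
  g2 <- G[, 1]
  # local refinement at a tenth of the interpolation step around every
  # candidate offset, resolving minima between the coarse samples
  fine <- h / 10
  fk <- seq(-h, h, by = fine)
  for (k in seq_len(K)) {
    if (all(!is.finite(G[, k]))) break
    for (fx in fk) {
      for (fy in fk) {
        if (fx == 0 && fy == 0) next
        ox <- BX[, k] + fx; oy <- BY[, k] + fy
        r2v <- (ox^2 + oy^2) / dta^2
        ok <- is.finite(G[, k]) & ox^2 + oy^2 <= rmax^2 + 1e-12 & r2v < g2
        if (!any(ok)) next
        de <- bilinear_at(eval, xs[ok] + ox[ok], ys[ok] + oy[ok])
        cand <- ((de - ds[ok]) / dD[ok])^2 + r2v[ok]
        better <- !is.na(cand) & cand < g2[ok]
        idx <- which(ok)[better]
        g2[idx] <- cand[better]
      }
    }
  }
  if (any(!is.finite(g2))) {
    stop("some reference points have no evaluated dose within the search ",
         "radius; grids barely overlap", call. = FALSE)
  }
  gam <- sqrt(g2)
  gmat <- matrix(NA_real_, nrow(ref$values), ncol(ref$values))
  gmat[keep] <- gam
  structure(
    list(gamma = gmat,
         pass_rate = 100 * mean(gam <= 1 + 1e-9),
         n_evaluated = length(gam),
         n_suppressed = sum(!keep),
         criteria = criteria,
         ref = ref),
    class = "gamma_result"
  )
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %.1f %% pass (gamma <= 1), %d points evaluated, %d suppressed\n",
              x$pass_rate, x$n_evaluated, x$n_suppressed))
  print(x$criteria)
  invisible(x)
}

#' Tidy a gamma result: one row per reference point
#' @param x A `gamma_result`.
#' @param ... Unused.
#' @return Tibble with `x_mm`, `y_mm`, `dose`, `gamma`, `suppressed`, `pass`.
#' @export
tidy.gamma_result <- function(x, ...) {
  out <- tidy.dose_grid(x$ref)
  out$gamma <- as.vector(x$gamma)
  out$suppressed <- is.na(out$gamma)
  out$pass <- !out$suppressed & out$gamma <= 1 + 1e-9
  out
}

#' Summarize a gamma result in one row
#' @param x A `gamma_result`.
#' @param ... Unused.
#' @return One-row tibble: pass rate, max/mean gamma, counts, criteria.
#' @export
glance.gamma_result <- function(x, ...) {
  g <- x$gamma[!is.na(x$gamma)]
  tibble::tibble(pass_rate = x$pass_rate,
                 max_gamma = max(g), mean_gamma = mean(g),
                 n_evaluated = x$n_evaluated, n_suppressed = x$n_suppressed,
                 dose_diff_pct = x$criteria$dose_diff_pct,
                 dta_mm = x$criteria$dta_mm,
                 normalization = x$criteria$normalization)
}

#' Plot a gamma map
#' @param object A `gamma_result`.
#' @param ... Unused.
#' @return A ggplot raster of the gamma map, failures highlighted.
#' @export
autoplot.gamma_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df[!df$suppressed, ],
                  ggplot2::aes(x = .data$x_mm, y = .data$y_mm,
                               fill = .data$gamma)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "red",
                                  midpoint = 1) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x [mm]", y = "y [mm]",
                  title = sprintf("Gamma %.1f%%/%.1f mm (%s): %.1f%% pass",
                                  object$criteria$dose_diff_pct,
                                  object$criteria$dta_mm,
                                  object$criteria$normalization,
                                  object$pass_rate)) +
    ggplot2::theme_minimal()
}

#' Pass-rate table over plans and criteria
#'
#' Runs [gamma_map()] for every (reference, evaluated) pair under every set
#' of criteria and tabulates the pass rates, one row per plan and one column
#' per criteria (named like `2%/2mm local`), the layout of an IMRT
#' commissioning report.
#'
#' @param plans Named list of `list(ref = dose_grid, eval = dose_grid)`
#'   pairs (e.g. from [make_dose_pair()]).
#' @param criteria_list List of [gamma_criteria()].
#' @param digits Decimals for the tabulated pass rates.
#' @return A tibble with a `plan` column and one pass-rate column per
#'   criteria.
#' @export
pass_rate_table <- function(plans, criteria_list = list(gamma_criteria(2, 2),
                                                        gamma_criteria(3, 3)),
                            digits = 1) {
  if (is.null(names(plans))) names(plans) <- paste0("plan_", seq_along(plans))
  cols <- purrr::map(criteria_list, function(cr) {
    unname(purrr::map_dbl(plans, function(p) {
      round(gamma_map(p$ref, p$eval, cr)$pass_rate, digits)
    }))
  })
  names(cols) <- purrr::map_chr(criteria_list, function(cr) {
    sprintf("%g%%/%gmm %s", cr$dose_diff_pct, cr$dta_mm, cr$normalization)
  })
  dplyr::bind_cols(tibble::tibble(plan = names(plans)),
                   tibble::as_tibble(cols))
}
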