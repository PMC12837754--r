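# Gap-length orifice area on a pair of leaflet free-edge polylines.

as_curve_matrix <- function(curve, arg = "curve") {
  if (is.data.frame(curve)) {
    stopifnot(all(c("x", "y", "z") %in% names(curve)))
    curve <- cbind(curve$x, curve$y, curve$z)
  }
  curve <- as.matrix(curve)
  if (ncol(curve) != 3 || nrow(curve) < 2 || !is.numeric(curve)) {
    abort(paste0(arg, " must be an n x 3 numeric matrix (n >= 2) or a data frame with x, y, z"))
  }
  storage.mode(curve) <- "double"
  curve
}

# Resample a polyline at m points equally spaced in normalized arc length.
resample_polyline <- function(curve, m) {
  d <- sqrt(rowSums(diff(curve)^2))
  t <- c(0, cumsum(d))
  if (t[length(t)] <= 0) return(curve[rep(1, m), , drop = FALSE])
  t <- t / t[length(t)]
  tt <- seq(0, 1, length.out = m)
  apply(curve, 2, function(col) stats::approx(t, col, xout = tt, ties = "ordered")$y)
}

#' Construct equally spaced cross-sectional planes
#'
#' Builds `n_planes` planes equally spaced along the commissure-to-commissure
#' direction. The coaptation line is estimated as the midcurve between the
#' two free edges (after arc-length resampling); each plane passes through a
#' midcurve point and is oriented perpendicular to the local midcurve
#' tangent (central differences).
#'
#' Plane centres sit at positions `(j - 1/2)/n_planes` along the commissural
#' span, so a single plane lies at mid-span and the plane spacing
#' `delta_x = span / n_planes` tiles the span exactly.
#'
#' @param anterior,posterior Free-edge curves: n x 3 matrices or data frames
#'   with `x`, `y`, `z` columns (mm).
#' @param n_planes Number of planes (default 40).
#' @param n_mid Resolution of the midcurve resampling.
#' @return Tibble with one row per plane: `position` (mm along the span),
#'   origin `ox, oy, oz`, unit normal `nx, ny, nz`; attributes `delta_x`
#'   and `span`.
#' @export
make_section_planes <- function(anterior, posterior, n_planes = 40, n_mid = 200) {
  stopifnot(n_planes >= 1)
  a <- as_curve_matrix(anterior, "anterior")
  p <- as_curve_matrix(posterior, "posterior")
  mid <- (resample_polyline(a, n_mid) + resample_polyline(p, n_mid)) / 2
  axis <- mid[n_mid, ] - mid[1, ]
  span <- sqrt(sum(axis^2))
  if (span < 1e-9) abort("Degenerate commissural span: midcurve endpoints coincide")
  axis <- axis / span
  tau <- as.numeric((mid - matrix(mid[1, ], n_mid, 3, byrow = TRUE)) %*% axis)
  pos <- (seq_len(n_planes) - 0.5) / n_planes * span
  # tangents by central differences on the resampled midcurve
  tang <- rbind(
    mid[2, ] - mid[1, ],
    mid[3:n_mid, ] - mid[1:(n_mid - 2), ],
    mid[n_mid, ] - mid[n_mid - 1, ]
  )
  tang <- tang / sqrt(rowSums(tang^2))
  idx <- vapply(pos, function(x) which.min(abs(tau - x)), integer(1))
  out <- tibble::tibble(
    position = pos,
    ox = mid[idx, 1], oy = mid[idx, 2], oz = mid[idx, 3],
    nx = tang[idx, 1], ny = tang[idx, 2], nz = tang[idx, 3]
  )
  attr(out, "delta_x") <- span / n_planes
  attr(out, "span") <- span
  out
}

# In-plane intersection points of a polyline with the plane n . (P - o) = 0,
# by segment crossing with linear interpolation; vertices on the plane and
# multiple crossings are all retained.
plane_polyline_intersections <- function(origin, normal, curve) {
  f <- as.numeric(curve %*% normal) - sum(origin * normal)
  n <- length(f)
  pts <- curve[abs(f) < 1e-12, , drop = FALSE]
  i <- which(f[-n] * f[-1] < 0)
  if (length(i) > 0) {
    t <- f[i] / (f[i] - f[i + 1])
    pts <- rbind(pts, curve[i, , drop = FALSE] + t * (curve[i + 1, , drop = FALSE] - curve[i, , drop = FALSE]))
  }
  pts
}

#' Local gap length within one cross-sectional plane
#'
#' Intersects both free-edge polylines with the plane and returns the
#' minimum distance between the two in-plane point sets. The gap is set to
#' zero when the edges touch (distance below `contact_tol`) or have crossed
#' (the nearest anterior point lies on the posterior side of the nearest
#' posterior point, judged against the mean anterior-to-posterior
#' direction), so the gap is never negative and never counts overlap.
#'
#' @param plane One row of [make_section_planes()] (data frame or named
#'   vector with `ox..oz`, `nx..nz`).
#' @param anterior,posterior Free-edge curves (see [make_section_planes()]).
#' @param contact_tol Distances below this count as contact (default 1e-12 mm).
#' @return Gap length in mm (0 if a plane misses a curve, with a warning).
#' @export
plane_gap <- function(plane, anterior, posterior, contact_tol = 1e-12) {
  plane <- as.list(as.data.frame(plane)[1, , drop = FALSE])
  origin <- c(plane$ox, plane$oy, plane$oz)
  normal <- c(plane$nx, plane$ny, plane$nz)
  a <- as_curve_matrix(anterior, "anterior")
  p <- as_curve_matrix(posterior, "posterior")
  pa <- plane_polyline_intersections(origin, normal, a)
  pp <- plane_polyline_intersections(origin, normal, p)
  if (nrow(pa) == 0 || nrow(pp) == 0) {
    warn("Plane misses one of the edge curves; gap contribution set to 0")
    return(0)
  }
  d2 <- outer(rowSums(pa^2), rowSums(pp^2), "+") - 2 * pa %*% t(pp)
  best <- arrayInd(which.min(d2), dim(d2))
  gap <- sqrt(max(0, d2[best]))
  side <- colMeans(a) - colMeans(p)
  crossed <- sum((pa[best[1], ] - pp[best[2], ]) * side) <= contact_tol
  if (crossed || gap < contact_tol) 0 else gap
}

#' Gap-length orifice area
#'
#' The orifice area between two leaflet free edges: the valve span is cut by
#' `n_planes` equally spaced cross-sectional planes perpendicular to the
#' local coaptation line, the local gap length is measured in each plane,
#' and the area is the discrete integral `sum(g_i) * delta_x` where
#' `delta_x` is the plane spacing.
#'
#' @inheritParams make_section_planes
#' @return An object of class `gap_profile`: list with `profile` (tibble
#'   `position`, `gap`), `delta_x`, `n_planes`, `area_mm2`.
#' @examples
#' ant <- cbind(seq(0, 20, length.out = 21), 1, 0)
#' post <- cbind(seq(0, 20, length.out = 21), -1, 0)
#' gap_length_area(ant, post, n_planes = 10)$area_mm2 # 2 mm gap x 20 mm span
#' @export
gap_length_area <- function(anterior, posterior, n_planes = 40, n_mid = 200) {
  planes <- make_section_planes(anterior, posterior, n_planes, n_mid)
  gaps <- vapply(
    seq_len(nrow(planes)),
    function(i) plane_gap(planes[i, ], anterior, posterior),
    numeric(1)
  )
  structure(
    list(
      profile = tibble::tibble(position = planes$position, gap = gaps),
      delta_x = attr(planes, "delta_x"),
      n_planes = n_planes,
      area_mm2 = sum(gaps) * attr(planes, "delta_x")
    ),
    class = "gap_profile"
  )
}

#' @export
print.gap_profile <- function(x, ...) {
  cat("<gap_profile> ", x$n_planes, " planes, area = ",
    format(x$area_mm2, digits = 5), " mm^2\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname gap_length_area
#' @param object A `gap_profile` object.
#' @param ... Ignored.
#' @export
autoplot.gap_profile <- function(object, ...) {
  ggplot2::ggplot(object$profile, ggplot2::aes(x = .data$position, y = .data$gap)) +
    ggplot2::geom_col(width = object$delta_x, fill = "steelblue", alpha = 0.8) +
    ggplot2::labs(
      x = "position along coaptation line (mm)", y = "gap length (mm)",
      title = sprintf("Gap profile, area = %.1f mm^2", object$area_mm2)
    )
}

#' Summarize a gap profile as JSON
#'
#' @param x A `gap_profile`.
#' @return JSON string `{n_planes, area_mm2}`.
#' @export
gap_profile_json <- function(x) {
  jsonlite::toJSON(list(n_planes = x$n_planes, area_mm2 = x$area_mm2),
    auto_unbox = TRUE, digits = NA
  )
}
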