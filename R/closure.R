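#' Constants of the kinematic coaptation rule
#'
#' The closure emulator compares the local chord demand `d(s)` with the
#' leaflet coverage `lambda(q) * (a(s) + p(s))`. The coaptation efficiency
#' \deqn{\lambda(q) = \lambda_0 \left(1 - c_h \frac{AH + PH}{h_{ref}}\right)
#'   \left(\frac{AP}{AP_{ref}}\right)^{\beta}}
#' decreases with annular saddle height (a taller saddle leaves the free
#' edges farther from the annular plane) and increases with the
#' anteroposterior diameter (a dilated annulus flattens the leaflets so
#' that more of their length is recruited into coaptation). `ap_ref` is the
#' midpoint of the physiological `AP_D` range; `h_ref` a reference combined
#' saddle height. All reference values are lengths in mm except the
#' dimensionless `lambda0`, `c_h` and `beta`.
#'
#' @param lambda0 Baseline coaptation efficiency (default 0.95).
#' @param c_h Saddle-height penalty coefficient (default 0.05).
#' @param h_ref Reference combined saddle height, mm (default 2.7).
#' @param ap_ref Reference anteroposterior diameter, mm (default 34.65).
#' @param beta Annular-dilation recruitment exponent (default 1.9).
#' @return Named list of the five constants.
#' @export
coaptation_constants <- function(lambda0 = 0.95, c_h = 0.05, h_ref = 2.7,
                                 ap_ref = 34.65, beta = 1.9) {
  list(lambda0 = lambda0, c_h = c_h, h_ref = h_ref, ap_ref = ap_ref, beta = beta)
}

coaptation_efficiency <- function(AP, AH, PH, constants) {
  constants$lambda0 * (1 - constants$c_h * (AH + PH) / constants$h_ref) *
    (AP / constants$ap_ref)^constants$beta
}

#' Emulate mid-systole valve closure
#'
#' Deterministic kinematic stand-in for a finite-element closure
#' simulation. At each station the residual gap is
#' `g(s) = max(0, d(s) - lambda(q) * (a(s) + p(s)))` and the leaflet free
#' edges are laid out symmetrically about the coaptation line:
#' the anterior edge at `y = +g/2`, the posterior edge at `y = -g/2`, both
#' at `z = 0`. The closed-form orifice area is the Riemann sum
#' `sum(g(s_i)) * IC / n_stations`.
#'
#' @param curves A `valve_curves` object from [build_valve_curves()].
#' @param q Physical parameters; defaults to those stored in `curves`.
#' @param constants See [coaptation_constants()].
#' @return An object of class `closed_valve`: list with `edges` (tibble
#'   `s, x, y_anterior, y_posterior, z, gap`), `oa_closed_form` (mm^2),
#'   `lambda`, `delta_x`, `params`, `constants`.
#' @examples
#' q <- sample_physical(1, seed = 1)
#' cl <- emulate_closure(build_valve_curves(q, 100))
#' cl$oa_closed_form
#' @export
emulate_closure <- function(curves, q = NULL, constants = coaptation_constants()) {
  stopifnot(inherits(curves, "valve_curves"))
  q <- tibble::as_tibble(as.data.frame(q %||% curves$params)[1, , drop = FALSE])
  lambda <- coaptation_efficiency(q$AP, q$AH, q$PH, constants)
  prof <- curves$profiles
  gap <- pmax(0, prof$chord - lambda * (prof$anterior + prof$posterior))
  edges <- tibble::tibble(
    s = prof$s, x = prof$x,
    y_anterior = gap / 2, y_posterior = -gap / 2, z = 0, gap = gap
  )
  structure(
    list(
      edges = edges,
      oa_closed_form = sum(gap) * curves$delta_x,
      lambda = lambda, delta_x = curves$delta_x,
      params = q, constants = constants
    ),
    class = "closed_valve"
  )
}

#' @export
print.closed_valve <- function(x, ...) {
  cat("<closed_valve> orifice area ", format(x$oa_closed_form, digits = 5),
    " mm^2 over ", nrow(x$edges), " stations (lambda = ",
    format(x$lambda, digits = 4), ")\n",
    sep = ""
  )
  invisible(x)
}

#' Extract a leaflet free-edge curve as an n x 3 matrix
#'
#' @param closed A `closed_valve` object.
#' @param side `"anterior"` or `"posterior"`.
#' @return Numeric matrix with columns x, y, z (mm).
#' @export
edge_curve <- function(closed, side = c("anterior", "posterior")) {
  side <- match.arg(side)
  e <- closed$edges
  y <- if (side == "anterior") e$y_anterior else e$y_posterior
  cbind(x = e$x, y = y, z = e$z)
}

#' @rdname emulate_closure
#' @param object A `closed_valve` object.
#' @param ... Ignored.
#' @export
autoplot.closed_valve <- function(object, ...) {
  ggplot2::ggplot(object$edges, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$y_posterior, ymax = .data$y_anterior),
      fill = "firebrick", alpha = 0.4
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$y_anterior)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$y_posterior)) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "intercommissural x (mm)", y = "anteroposterior y (mm)",
      title = sprintf("Residual orifice, area = %.1f mm^2", object$oa_closed_form)
    )
}

#' Emulated orifice area for one or many parameter vectors
#'
#' Vectorized composition of [build_valve_curves()] and [emulate_closure()]:
#' all rows share the station grid, so the gap profiles are evaluated with
#' dense matrix arithmetic. Deterministic: equal inputs give equal areas.
#'
#' @param params Data frame of physical parameters (one row per valve).
#' @param n_stations Station count for the closed-form Riemann sum.
#' @param constants See [coaptation_constants()].
#' @return Numeric vector of orifice areas (mm^2), one per row.
#' @export
emulate_orifice_area <- function(params, n_stations = 400,
                                 constants = coaptation_constants()) {
  params <- tibble::as_tibble(params)
  stopifnot(all(phys_param_names %in% names(params)))
  n <- nrow(params)
  if (n == 0) return(numeric(0))
  s <- (seq_len(n_stations) - 0.5) / n_stations
  sb <- sqrt(pmax(0, 1 - (2 * s - 1)^2))
  phi <- septal_bump(s)
  lsin <- log(sin(pi * s))
  out <- numeric(n)
  chunk <- 2000L
  for (i0 in seq(1L, n, by = chunk)) {
    idx <- i0:min(n, i0 + chunk - 1L)
    qq <- params[idx, ]
    m <- length(idx)
    # matrices are m x n_stations; length-m vectors recycle down rows
    SB <- matrix(sb, m, n_stations, byrow = TRUE)
    PHI <- matrix(phi, m, n_stations, byrow = TRUE)
    D <- (qq$AP * (1 - qq$D_shape)) * SB * (1 - (qq$SF_shape / qq$IC) * PHI)
    A <- qq$AL * exp((1 / qq$Ant_blunt) * matrix(lsin, m, n_stations, byrow = TRUE))
    U <- matrix(pmin(s, 1 - s), m, n_stations, byrow = TRUE)
    half <- (1 - qq$Com_cur) * qq$Com_loc
    TT <- pmin(pmax((U - (qq$Com_loc - half)) / (2 * half), 0), 1)
    W <- TT^2 * (3 - 2 * TT)
    P <- qq$CL + (qq$PL - qq$CL) * W
    lambda <- coaptation_efficiency(qq$AP, qq$AH, qq$PH, constants)
    G <- pmax(D - lambda * (A + P), 0) # matrix first: pmax keeps its dims
    out[idx] <- rowSums(G) * qq$IC / n_stations
  }
  out
}

#' Generate a synthetic geometry-to-orifice-area dataset
#'
#' Samples feasible physical parameter vectors uniformly (in normalized
#' space) and evaluates the closure emulator, producing the kind of
#' parameter/response table a batch of closure simulations would yield.
#' Deterministic for equal `(n, seed)`; an optional Gaussian noise term
#' (default off) is available for robustness experiments.
#'
#' @inheritParams sample_physical
#' @param n Number of rows.
#' @param seed Integer seed.
#' @param n_stations Stations for the emulator integral.
#' @param constants See [coaptation_constants()].
#' @param noise_sd Standard deviation (mm^2) of additive Gaussian noise.
#' @return Tibble with the twelve physical columns plus `orifice_area_mm2`;
#'   attributes `seed` and `n_rejected` record provenance.
#' @examples
#' d <- generate_dataset(10, seed = 1)
#' summary(d$orifice_area_mm2)
#' @export
generate_dataset <- function(n, seed, ranges = default_ranges(), n_stations = 400,
                             constants = coaptation_constants(), noise_sd = 0,
                             quiet = TRUE) {
  stopifnot(n >= 1)
  withr::with_seed(seed, {
    q <- sample_physical(n, ranges, quiet = quiet)
    y <- emulate_orifice_area(q, n_stations, constants)
    if (noise_sd > 0) y <- pmax(0, y + rnorm(n, 0, noise_sd))
    out <- dplyr::mutate(q, orifice_area_mm2 = y)
    attr(out, "seed") <- seed
    attr(out, "n_rejected") <- attr(q, "n_rejected")
    out
  })
}

#' Export a closed configuration as OBJ polylines
#'
#' Writes the anterior and posterior free-edge curves as two polylines in
#' Wavefront OBJ format for quick 3D visualization.
#'
#' @param closed A `closed_valve` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_closure_obj <- function(closed, path) {
  a <- edge_curve(closed, "anterior")
  p <- edge_curve(closed, "posterior")
  n <- nrow(a)
  v <- rbind(a, p)
  lines <- c(
    "# valvesens closed configuration: anterior and posterior free edges",
    sprintf("v %.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]),
    paste("l", paste(seq_len(n), collapse = " ")),
    paste("l", paste(n + seq_len(n), collapse = " "))
  )
  writeLines(lines, path)
  invisible(path)
}
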