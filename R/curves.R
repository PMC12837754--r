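# Profile building blocks. The commissural coordinate s runs from 0
# (anterolateral commissure) to 1 (posteromedial commissure); the annular
# plane is z = 0, the commissure-to-commissure axis is x and the
# anteroposterior axis is y.

# Septal flattening bump: a fixed Gaussian centred on the mid chord.
septal_bump <- function(s) exp(-(s - 0.5)^2 / (2 * 0.15^2))

# Smooth commissural ramp: 0 at both commissures, rising through a
# smoothstep whose transition midpoint sits at Com_loc (in the folded
# coordinate u = min(s, 1 - s)) and whose width shrinks as Com_cur grows.
commissure_ramp <- function(s, com_loc, com_cur) {
  u <- pmin(s, 1 - s)
  half <- (1 - com_cur) * com_loc
  t <- pmin(pmax((u - (com_loc - half)) / (2 * half), 0), 1)
  t^2 * (3 - 2 * t)
}

#' Evaluate the parametric valve profiles at arbitrary stations
#'
#' For a single physical parameter vector, evaluates the local
#' anteroposterior chord `d(s)`, the anterior leaflet length profile `a(s)`
#' and the posterior leaflet length profile `p(s)` along the commissural
#' coordinate `s` in `[0, 1]`:
#' \deqn{d(s) = AP\,\sqrt{1-(2s-1)^2}\,(1-D_{shape})\,(1-\frac{SF_{shape}}{IC}\phi(s))}
#' \deqn{a(s) = AL\,\sin(\pi s)^{1/Ant_{blunt}}}
#' \deqn{p(s) = CL + (PL - CL)\,w(s; Com_{loc}, Com_{cur})}
#' with \eqn{\phi} a fixed Gaussian septal-flattening bump centred at
#' `s = 0.5` and `w` a smooth ramp equal to 0 at the commissures and rising
#' to its plateau on the central belly.
#'
#' @param q A single physical parameter vector: one-row data frame or named
#'   list/vector with the columns of [unnormalize()].
#' @param s Numeric vector of stations in `[0, 1]`.
#' @return Tibble with columns `s`, `chord`, `anterior`, `posterior` (mm).
#' @export
valve_profiles <- function(q, s) {
  q <- as.list(as.data.frame(q)[1, , drop = FALSE])
  stopifnot(all(s >= 0), all(s <= 1))
  chord <- q$AP * sqrt(pmax(0, 1 - (2 * s - 1)^2)) *
    (1 - q$D_shape) * (1 - q$SF_shape / q$IC * septal_bump(s))
  anterior <- q$AL * sin(pi * s)^(1 / q$Ant_blunt)
  posterior <- q$CL + (q$PL - q$CL) * commissure_ramp(s, q$Com_loc, q$Com_cur)
  tibble::tibble(s = s, chord = chord, anterior = anterior, posterior = posterior)
}

#' Build the discretized parametric valve geometry
#'
#' Discretizes the valve profiles of [valve_profiles()] at `n_stations`
#' midpoint stations (`s_i = (i - 1/2)/n`) and lays out the annulus as two
#' three-dimensional rings: `x` spans the intercommissural diameter `IC`,
#' the half-chords sit at `y = +/- d(s)/2`, and the saddle height is
#' `AH sin(pi s)` on the anterior ring and `PH sin(pi s)` on the posterior
#' ring. Midpoint stations make the discrete chord integral
#' `sum(d * IC/n)` converge to the annular area (for an ellipse,
#' `pi * AP * IC / 4`).
#'
#' @inheritParams valve_profiles
#' @param n_stations Number of stations (default 400, independent of the 40
#'   cross-sectional planes of the orifice-area algorithm).
#' @return An object of class `valve_curves`: list with `profiles`
#'   (tibble `s, x, chord, anterior, posterior`), `annulus` (tibble
#'   `x, y, z, side`), `params`, `n_stations`, `delta_x`.
#' @examples
#' q <- sample_physical(1, seed = 1)
#' vc <- build_valve_curves(q, n_stations = 50)
#' head(vc$profiles)
#' @export
build_valve_curves <- function(q, n_stations = 400) {
  stopifnot(n_stations >= 3)
  q <- tibble::as_tibble(as.data.frame(q)[1, , drop = FALSE])
  stopifnot(all(phys_param_names %in% names(q)))
  if (q$AP <= 0 || q$IC <= 0 || q$AL <= 0 || q$AL >= q$AP || q$PL < 0 || q$CL < 0) {
    abort("Invalid physical parameters: need AP, IC > 0, 0 < AL < AP, PL >= 0, CL >= 0")
  }
  s <- (seq_len(n_stations) - 0.5) / n_stations
  prof <- valve_profiles(q, s)
  prof$x <- (s - 0.5) * q$IC
  prof <- prof[, c("s", "x", "chord", "anterior", "posterior")]
  annulus <- dplyr::bind_rows(
    tibble::tibble(x = prof$x, y = prof$chord / 2, z = q$AH * sin(pi * s), side = "anterior"),
    tibble::tibble(x = prof$x, y = -prof$chord / 2, z = q$PH * sin(pi * s), side = "posterior")
  )
  structure(
    list(
      profiles = prof, annulus = annulus, params = q,
      n_stations = n_stations, delta_x = q$IC / n_stations
    ),
    class = "valve_curves"
  )
}

#' @export
print.valve_curves <- function(x, ...) {
  cat("<valve_curves> ", x$n_stations, " stations; AP = ",
    format(x$params$AP, digits = 4), " mm, IC = ",
    format(x$params$IC, digits = 4), " mm\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname build_valve_curves
#' @param object A `valve_curves` object.
#' @param ... Ignored.
#' @export
autoplot.valve_curves <- function(object, ...) {
  long <- tidyr::pivot_longer(object$profiles, c("chord", "anterior", "posterior"),
    names_to = "profile", values_to = "length_mm"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$s, y = .data$length_mm, colour = .data$profile)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "commissural coordinate s", y = "length (mm)",
      title = "Parametric valve profiles"
    )
}
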