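# Histogram density estimates on a shared grid and the total-variation
# distance between them.

#' Common histogram breaks for several sample sets
#'
#' A fixed equal-width grid spanning the pooled range of all supplied
#' samples, so that densities estimated on it are directly comparable.
#'
#' @param ... Numeric vectors (or a single list of them).
#' @param n_bins Number of bins (default 100).
#' @return Numeric vector of `n_bins + 1` break points.
#' @export
common_breaks <- function(..., n_bins = 100) {
  xs <- list(...)
  if (length(xs) == 1 && is.list(xs[[1]]) && !is.numeric(xs[[1]])) xs <- xs[[1]]
  pooled <- range(unlist(xs), finite = TRUE)
  if (diff(pooled) <= 0) pooled <- pooled + c(-0.5, 0.5)
  seq(pooled[1], pooled[2], length.out = n_bins + 1)
}

#' Histogram density estimate on a fixed grid
#'
#' Normalized histogram: bin densities are counts divided by `n * bin
#' width`, so the density integrates to one over the grid. Samples outside
#' the grid are an error (build the grid with [common_breaks()] over the
#' pooled data).
#'
#' @param samples Numeric vector (at least 2 values).
#' @param breaks Bin break points; default 100 equal bins over the sample
#'   range.
#' @param n_bins Used when `breaks` is `NULL`.
#' @return Object of class `density_estimate`: tibble `mid, density` with
#'   attributes `breaks` and `bin_width`.
#' @export
estimate_density <- function(samples, breaks = NULL, n_bins = 100) {
  samples <- as.numeric(samples)
  if (length(samples) < 2) abort("Need at least 2 samples for a density estimate")
  if (is.null(breaks)) breaks <- common_breaks(samples, n_bins = n_bins)
  if (min(samples) < breaks[1] || max(samples) > breaks[length(breaks)]) {
    abort("Samples fall outside the supplied breaks")
  }
  h <- graphics::hist(samples, breaks = breaks, plot = FALSE, right = TRUE, include.lowest = TRUE)
  width <- diff(breaks)
  out <- tibble::tibble(mid = h$mids, density = h$counts / (length(samples) * width))
  attr(out, "breaks") <- breaks
  attr(out, "bin_width") <- width[1]
  class(out) <- c("density_estimate", class(out))
  out
}

#' Total-variation distance between two density estimates
#'
#' `TV(p, q) = 1/2 * sum(|p_i - q_i|) * bin width`, in `[0, 1]`. Both
#' estimates must share the same grid.
#'
#' @param p,q `density_estimate` objects on identical breaks.
#' @return Scalar in `[0, 1]`.
#' @examples
#' x <- rnorm(5000); y <- rnorm(5000, 2)
#' br <- common_breaks(x, y)
#' total_variation(estimate_density(x, br), estimate_density(y, br))
#' @export
total_variation <- function(p, q) {
  stopifnot(inherits(p, "density_estimate"), inherits(q, "density_estimate"))
  bp <- attr(p, "breaks")
  bq <- attr(q, "breaks")
  if (length(bp) != length(bq) || !isTRUE(all.equal(bp, bq, tolerance = 1e-12))) {
    abort("Density estimates are on different grids; rebuild with common_breaks()")
  }
  0.5 * sum(abs(p$density - q$density) * diff(bp))
}

#' Overlay several orifice-area densities
#'
#' @param densities Named list of `density_estimate` objects on one grid.
#' @return A ggplot object.
#' @export
plot_density_comparison <- function(densities) {
  stopifnot(length(densities) >= 1, !is.null(names(densities)))
  df <- purrr::imap_dfr(densities, function(d, nm) {
    tibble::tibble(mid = d$mid, density = d$density, case = nm)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$density, colour = .data$case)) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = expression("orifice area (mm"^2 * ")"), y = "density",
      title = "Orifice-area distributions"
    )
}

#' @export
autoplot.density_estimate <- function(object, ...) {
  plot_density_comparison(list(density = object))
}
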