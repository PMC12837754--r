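#' Convert normalized parameters to physical (mm-scale) parameters
#'
#' The normalized parameterization expresses most lengths as ratios; the
#' surrogate model and the sensitivity analysis work on the unnormalized
#' quantities. The mapping is
#' `AP = AP_D`, `IC = IC_D_R * AP`, `AL = AP / AL_R`,
#' `SF_shape = SF_Shape_R * IC`, `PL = PL_R * (AP - AL)`,
#' `CL = CL_R * (PL - PH)`, while `AH`, `PH`, `D_Shape`, `Ant_Blunt`,
#' `Com_Loc` and `Com_Cur` pass through unchanged.
#'
#' `AL_R` is treated as the ratio of `AP_D` to the anterior leaflet length
#' (so `AL = AP / AL_R`): with the published range of `AL_R` (3.2 to 7.2)
#' this is the only reading under which the anterior leaflet is shorter than
#' the annular diameter and `PL = PL_R * (AP - AL)` stays positive.
#'
#' A sample is infeasible when `PL <= PH`, because the commissure length
#' `CL = CL_R * (PL - PH)` would not be positive.
#'
#' @param params Data frame of normalized parameters (columns as in
#'   [default_ranges()]).
#' @param on_infeasible `"error"` (default) aborts if any row has
#'   `PL <= PH`; `"drop"` removes such rows and records their count in the
#'   `n_rejected` attribute.
#' @return A tibble with the twelve physical columns
#'   `AP, IC, AL, PL, CL, SF_shape, AH, PH, D_shape, Ant_blunt, Com_loc,
#'   Com_cur` (all lengths in mm).
#' @examples
#' unnormalize(sample_normalized(5, seed = 1), on_infeasible = "drop")
#' @export
unnormalize <- function(params, on_infeasible = c("error", "drop")) {
  on_infeasible <- match.arg(on_infeasible)
  missing <- setdiff(norm_param_names, names(params))
  if (length(missing) > 0) {
    abort(paste0("Missing normalized parameter columns: ", paste(missing, collapse = ", ")))
  }
  out <- dplyr::transmute(tibble::as_tibble(params),
    AP = .data$AP_D,
    IC = .data$IC_D_R * .data$AP_D,
    AL = .data$AP_D / .data$AL_R,
    PL = .data$PL_R * (.data$AP_D - .data$AP_D / .data$AL_R),
    CL = .data$CL_R * (.data$PL_R * (.data$AP_D - .data$AP_D / .data$AL_R) - .data$PH),
    SF_shape = .data$SF_Shape_R * .data$IC_D_R * .data$AP_D,
    AH = .data$AH,
    PH = .data$PH,
    D_shape = .data$D_Shape,
    Ant_blunt = .data$Ant_Blunt,
    Com_loc = .data$Com_Loc,
    Com_cur = .data$Com_Cur
  )
  infeasible <- out$PL <= out$PH
  if (any(infeasible)) {
    if (on_infeasible == "error") {
      abort(paste0(
        sum(infeasible), " sample(s) infeasible: PL <= PH makes the ",
        "commissure length CL non-positive. Use on_infeasible = \"drop\" ",
        "or resample."
      ))
    }
    out <- out[!infeasible, ]
  }
  attr(out, "n_rejected") <- sum(infeasible)
  out
}

#' Sample feasible physical parameter vectors
#'
#' Draws normalized parameters uniformly within `ranges`, unnormalizes them,
#' and rejects infeasible draws (`PL <= PH`) until exactly `n` feasible rows
#' are obtained. The number of rejected draws is reported via a message and
#' stored in the `n_rejected` attribute.
#'
#' @inheritParams sample_normalized
#' @param quiet Suppress the rejection-count message.
#' @return Tibble of `n` physical parameter rows.
#' @export
sample_physical <- function(n, ranges = default_ranges(), seed = NULL, quiet = FALSE) {
  stopifnot(n >= 0)
  draw <- function() {
    got <- list()
    total <- 0L
    rejected <- 0L
    while (total < n) {
      m <- max(16L, ceiling((n - total) * 1.25))
      batch <- unnormalize(sample_normalized(m, ranges), on_infeasible = "drop")
      rejected <- rejected + attr(batch, "n_rejected")
      got[[length(got) + 1L]] <- batch
      total <- total + nrow(batch)
    }
    out <- dplyr::bind_rows(got)[seq_len(n), ]
    if (!quiet && rejected > 0) {
      inform(paste0("sample_physical: rejected ", rejected, " infeasible draw(s)"))
    }
    attr(out, "n_rejected") <- rejected
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Empirical means of the induced physical parameter distribution
#'
#' The unnormalization map is nonlinear, so the mean of each physical
#' parameter under uniform sampling of the normalized parameters is not the
#' midpoint of a range. This helper estimates those means by Monte Carlo;
#' they are the values at which non-influential parameters are held fixed in
#' the reduced-parameter analysis.
#'
#' @inheritParams sample_physical
#' @param n Number of Monte Carlo draws (default `1e5`).
#' @return Named numeric vector of twelve physical means.
#' @export
physical_means <- function(ranges = default_ranges(), n = 1e5, seed = 1) {
  q <- sample_physical(n, ranges, seed = seed, quiet = TRUE)
  colMeans(as.matrix(q))
}
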