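# First-order Sobol indices by the dimension-fixing Monte Carlo scheme:
# S_i = V_i / Var(y) with V_i = Var_{X_i}( E[Y | X_i] ).

#' First-order Sobol indices by the fixing scheme
#'
#' For each input dimension `d`: draw `n_outer` fixed values (the `d`-th
#' column of one joint draw), and for each fixed value draw `n_inner` fresh
#' joint samples, overwrite their `d`-th column with the fixed value,
#' evaluate the model and take the inner mean. `V_d` is the variance of the
#' `n_outer` inner means; the denominator `Var(y)` is pooled over all
#' `n_outer * n_inner * D` model evaluations. When the joint sampler
#' couples the dimensions (as the valve unnormalization does), overwriting
#' one physical coordinate deliberately breaks that coupling: the index
#' measures the effect of varying that coordinate alone.
#'
#' Raw index estimates can be slightly negative from Monte Carlo noise;
#' they are kept raw here and clipped at zero only in ranked summaries.
#'
#' @param model Function: data frame of joint samples -> numeric vector.
#' @param sampler Function: `n` -> data frame of `n` joint samples (one
#'   column per input dimension).
#' @param n_outer,n_inner Outer (fixed values) and inner (conditional
#'   expectation) sample counts, both at least 2.
#' @param seed Integer seed controlling every draw.
#' @param names Optional parameter names; default: sampler column names.
#' @return Object of class `sobol_result`: list with `indices` (tibble
#'   `parameter, Vi, Si`), `var_y`, `n_outer`, `n_inner`, `seed`.
#' @examples
#' add <- function(df) df[[1]] + 2 * df[[2]]
#' unif2 <- function(n) data.frame(x1 = runif(n), x2 = runif(n))
#' tidy(first_order_indices(add, unif2, 100, 100, seed = 1))
#' @export
first_order_indices <- function(model, sampler, n_outer, n_inner, seed = 1,
                                names = NULL) {
  stopifnot(n_outer >= 2, n_inner >= 2)
  withr::with_seed(seed, {
    X_out <- as.data.frame(sampler(n_outer))
    D <- ncol(X_out)
    names <- names %||% colnames(X_out)
    Vi <- numeric(D)
    tot_n <- 0
    tot_sum <- 0
    tot_sumsq <- 0
    for (d in seq_len(D)) {
      Z <- as.data.frame(sampler(n_outer * n_inner))
      Z[[d]] <- rep(X_out[[d]], each = n_inner)
      y <- model(Z)
      stopifnot(length(y) == n_outer * n_inner)
      inner_means <- colMeans(matrix(y, nrow = n_inner))
      Vi[d] <- var(inner_means)
      tot_n <- tot_n + length(y)
      tot_sum <- tot_sum + sum(y)
      tot_sumsq <- tot_sumsq + sum(y^2)
    }
    var_y <- (tot_sumsq - tot_sum^2 / tot_n) / (tot_n - 1)
    if (var_y <= 0) {
      warn("Degenerate model output (zero variance); all Sobol indices set to 0")
      Si <- rep(0, D)
      var_y <- 0
    } else {
      Si <- Vi / var_y
    }
    structure(
      list(
        indices = tibble::tibble(parameter = names, Vi = Vi, Si = Si),
        var_y = var_y, n_outer = n_outer, n_inner = n_inner, seed = seed
      ),
      class = "sobol_result"
    )
  })
}

#' @export
print.sobol_result <- function(x, ...) {
  cat("<sobol_result> ", nrow(x$indices), " parameters, ",
    x$n_outer, " x ", x$n_inner, " samples per dimension\n",
    sep = ""
  )
  print(dplyr::arrange(x$indices, dplyr::desc(.data$Si)))
  invisible(x)
}

#' @export
tidy.sobol_result <- function(x, ...) x$indices

#' @export
glance.sobol_result <- function(x, ...) {
  tibble::tibble(
    var_y = x$var_y, n_outer = x$n_outer, n_inner = x$n_inner,
    seed = x$seed, sum_Si = sum(x$indices$Si)
  )
}

#' Rank parameters by first-order index
#'
#' @param r A `sobol_result`.
#' @param k How many names to return (at most the number of parameters).
#' @return Character vector of the top-`k` parameter names, indices
#'   descending; negative estimates are clipped at 0 for ranking and ties
#'   are broken alphabetically.
#' @export
rank_parameters <- function(r, k = 4) {
  stopifnot(inherits(r, "sobol_result"))
  idx <- r$indices
  if (k > nrow(idx)) abort("k exceeds the number of parameters")
  ord <- order(-pmax(idx$Si, 0), idx$parameter)
  idx$parameter[ord][seq_len(k)]
}

#' @rdname first_order_indices
#' @param object A `sobol_result`.
#' @param top_k Number of bars highlighted.
#' @param ... Ignored.
#' @export
autoplot.sobol_result <- function(object, top_k = 4, ...) {
  top <- rank_parameters(object, top_k)
  df <- dplyr::mutate(object$indices,
    parameter = stats::reorder(.data$parameter, -pmax(.data$Si, 0)),
    influential = .data$parameter %in% top
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$parameter, y = pmax(.data$Si, 0),
    fill = .data$influential
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey60")) +
    ggplot2::labs(
      x = NULL, y = "first-order Sobol index",
      title = "Parameter influence on orifice area"
    ) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
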