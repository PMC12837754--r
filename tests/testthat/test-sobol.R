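unif_sampler <- function(d, lo = 0, hi = 1) {
  function(n) {
    as.data.frame(setNames(
      lapply(seq_len(d), function(i) runif(n, lo, hi)),
      paste0("x", seq_len(d))
    ))
  }
}

test_that("an additive model recovers the analytic variance split", {
  # Y = X1 + 2 X2 + 0 X3, Xi ~ U(0,1): variances 1/12, 4/12, 0 -> S = 0.2, 0.8, 0
  model <- function(df) df$x1 + 2 * df$x2 + 0 * df$x3
  r <- first_order_indices(model, unif_sampler(3), 1000, 1000, seed = 101)
  expect_equal(r$indices$Si, c(0.2, 0.8, 0), tolerance = 0.02)
  expect_equal(r$var_y, 5 / 12, tolerance = 0.02)
  expect_lte(sum(r$indices$Si), 1 + 0.05)
})

test_that("a constant model yields zero indices with a warning", {
  model <- function(df) rep(2.5, nrow(df))
  expect_warning(
    r <- first_order_indices(model, unif_sampler(2), 10, 10, seed = 1),
    "zero variance"
  )
  expect_equal(r$indices$Si, c(0, 0))
})

test_that("the estimator matches an independent brute-force double loop", {
  model <- function(df) df$x1 + 2 * df$x2^2 + df$x1 * df$x3
  n_outer <- 20
  n_inner <- 30
  pool <- withr::with_seed(77, matrix(runif(3 * (n_outer + 3 * n_outer * n_inner)),
    ncol = 3, dimnames = list(NULL, c("x1", "x2", "x3"))
  ))
  r <- first_order_indices(model, pool_sampler(pool), n_outer, n_inner, seed = 1)

  # brute force: explicit nested loops over the same pre-drawn rows
  take <- local({
    used <- 0L
    function(n) {
      rows <- pool[used + seq_len(n), , drop = FALSE]
      used <<- used + n
      rows
    }
  })
  X_out <- take(n_outer)
  all_y <- c()
  V <- numeric(3)
  for (d in 1:3) {
    cond_means <- numeric(n_outer)
    for (k in 1:n_outer) {
      block <- take(n_inner)
      block[, d] <- X_out[k, d]
      yk <- numeric(n_inner)
      for (j in 1:n_inner) {
        row <- block[j, ]
        yk[j] <- row["x1"] + 2 * row["x2"]^2 + row["x1"] * row["x3"]
      }
      cond_means[k] <- sum(yk) / n_inner
      all_y <- c(all_y, yk)
    }
    V[d] <- sum((cond_means - mean(cond_means))^2) / (n_outer - 1)
  }
  var_y <- sum((all_y - mean(all_y))^2) / (length(all_y) - 1)
  expect_equal(r$indices$Vi, V, tolerance = 1e-12)
  expect_equal(r$var_y, var_y, tolerance = 1e-12)
  expect_equal(r$indices$Si, V / var_y, tolerance = 1e-12)
})

test_that("estimates tighten when the sampling budget is quadrupled", {
  model <- function(df) df$x1 + 2 * df$x2 + 0 * df$x3
  truth <- c(0.2, 0.8, 0)
  err <- function(n, seed) {
    r <- first_order_indices(model, unif_sampler(3), n, n, seed = seed)
    max(abs(r$indices$Si - truth))
  }
  seeds <- 1:8
  small <- mean(vapply(seeds, function(s) err(50, s), numeric(1)))
  large <- mean(vapply(seeds, function(s) err(200, s), numeric(1)))
  expect_lt(large, small)
})

test_that("ranking sorts by index with alphabetical tie-break", {
  r <- structure(
    list(
      indices = tibble::tibble(
        parameter = c("b", "a", "c", "d"),
        Vi = c(0.5, 0.3, 0.1, 0.1), Si = c(0.5, 0.3, 0.1, 0.1)
      ),
      var_y = 1, n_outer = 2, n_inner = 2, seed = 1
    ),
    class = "sobol_result"
  )
  expect_equal(rank_parameters(r, 2), c("b", "a"))
  expect_equal(rank_parameters(r, 4), c("b", "a", "c", "d"))
  expect_error(rank_parameters(r, 5), "exceeds")
  # negative estimates are clipped for ranking
  r$indices$Si <- c(-0.01, -0.2, 0.3, 0.1)
  expect_equal(rank_parameters(r, 4), c("c", "d", "a", "b"))
  expect_s3_class(ggplot2::autoplot(r, top_k = 2), "ggplot")
})

test_that("the emulator's own indices are dominated by IC, AL, PL and CL", {
  sampler <- function(n) sample_physical(n, quiet = TRUE)
  model <- function(df) emulate_orifice_area(df, n_stations = 60)
  r <- first_order_indices(model, sampler, 150, 150, seed = 2026)
  expect_setequal(rank_parameters(r, 4), c("IC", "AL", "PL", "CL"))
})
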