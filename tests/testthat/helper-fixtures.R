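# Shared fixtures, built in code at test time.

# A fixed feasible physical parameter vector (mid-range-ish values).
fixture_params <- function(...) {
  args <- list(
    AP = 34, IC = 38, AL = 7, PL = 14, CL = 6, SF_shape = 0.5,
    AH = 0.5, PH = 1.5, D_shape = 0.02, Ant_blunt = 1.2,
    Com_loc = 0.4, Com_cur = 0.4
  )
  mods <- list(...)
  args[names(mods)] <- mods
  do.call(tibble::tibble, args) # length-1 defaults recycle against vector mods
}

# Straight free edges along x, constant separation in y.
straight_edges <- function(length_mm = 20, gap_mm = 2, n_pts = 21) {
  x <- seq(0, length_mm, length.out = n_pts)
  list(
    anterior = cbind(x = x, y = rep(gap_mm / 2, n_pts), z = 0),
    posterior = cbind(x = x, y = rep(-gap_mm / 2, n_pts), z = 0)
  )
}

rotation_matrix <- function(ax, ay, az) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  Ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  Rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# A sampler backed by a pre-generated pool of rows, so that two estimators
# consuming draws at different granularities see identical values.
pool_sampler <- function(pool) {
  used <- 0L
  function(n) {
    rows <- pool[used + seq_len(n), , drop = FALSE]
    used <<- used + n
    as.data.frame(rows)
  }
}

# The experiment bundle shared by the acceptance tests (computed once).
.acceptance_cache <- new.env(parent = emptyenv())
acceptance_bundle <- function() {
  if (is.null(.acceptance_cache$bundle)) {
    cfg <- experiment_config(
      sobol_n_outer = 500, sobol_n_inner = 500,
      n_density = 10000, seed = 20260919
    )
    .acceptance_cache$bundle <- run_experiment(cfg, progress = FALSE)
  }
  .acceptance_cache$bundle
}
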