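# End-to-end experiment: dataset generation, repeated train/test surrogate
# comparison, Sobol ranking, reduced-parameter densities and their
# total-variation distances.

#' Experiment configuration
#'
#' Defaults follow the study protocol: 440 emulated closure simulations,
#' five random 350/90 train/test splits, 5-fold cross-validation for the
#' initial GP length scale, Sobol indices from 1000 x 1000 fixing-scheme
#' samples per dimension, the top 4 parameters retained, and 100-bin
#' densities.
#'
#' @param n_samples,n_train,n_test Dataset size and split sizes
#'   (`n_train + n_test` must equal `n_samples`).
#' @param n_splits Number of random train/test splits.
#' @param sigma2 Fixed GP noise variance (standardized targets).
#' @param cv_multipliers Candidate initial length-scale multipliers.
#' @param n_stations Emulator station count.
#' @param n_planes Cross-sectional planes of the gap-length algorithm
#'   (recorded for provenance; the pipeline response uses the closed form).
#' @param sobol_n_outer,sobol_n_inner Sobol sample counts per dimension.
#' @param top_k Number of influential parameters retained.
#' @param n_bins Histogram bins for the density comparison.
#' @param n_density Monte Carlo sample size per density.
#' @param n_means Sample size for [physical_means()].
#' @param seed Master seed; spawns independent child seeds per stage.
#' @param ranges Parameter ranges tibble.
#' @param constants Emulator constants, see [coaptation_constants()].
#' @param noise_sd Emulator observation noise (default 0).
#' @return Object of class `experiment_config` (a named list).
#' @export
experiment_config <- function(n_samples = 440, n_train = 350, n_test = 90,
                              n_splits = 5, sigma2 = 1e-4,
                              cv_multipliers = 10^seq(-1, 1, by = 0.5),
                              n_stations = 400, n_planes = 40,
                              sobol_n_outer = 1000, sobol_n_inner = 1000,
                              top_k = 4, n_bins = 100, n_density = 10000,
                              n_means = 1e5, seed = 1,
                              ranges = default_ranges(),
                              constants = coaptation_constants(),
                              noise_sd = 0) {
  cfg <- list(
    n_samples = n_samples, n_train = n_train, n_test = n_test,
    n_splits = n_splits, sigma2 = sigma2, cv_multipliers = cv_multipliers,
    n_stations = n_stations, n_planes = n_planes,
    sobol_n_outer = sobol_n_outer, sobol_n_inner = sobol_n_inner,
    top_k = top_k, n_bins = n_bins, n_density = n_density,
    n_means = n_means, seed = seed, ranges = ranges,
    constants = constants, noise_sd = noise_sd
  )
  stopifnot(
    n_train + n_test == n_samples,
    all(unlist(cfg[c(
      "n_samples", "n_train", "n_test", "n_splits", "n_stations",
      "n_planes", "sobol_n_outer", "sobol_n_inner", "top_k", "n_bins",
      "n_density", "n_means"
    )]) > 0)
  )
  validate_ranges(ranges)
  structure(cfg, class = "experiment_config")
}

#' Fix non-influential parameters at their means
#'
#' Replaces every physical parameter column not listed in `keep` by its
#' mean under the generating distribution (see [physical_means()]).
#'
#' @param params Tibble of physical parameters.
#' @param keep Character vector of parameter names left varying.
#' @param means Named vector of physical means covering all columns.
#' @return Tibble of the same shape with non-kept columns constant.
#' @export
fix_noninfluential <- function(params, keep, means) {
  params <- tibble::as_tibble(params)
  unknown <- setdiff(keep, names(params))
  if (length(unknown) > 0) {
    abort(paste0("Unknown parameter name(s): ", paste(unknown, collapse = ", ")))
  }
  for (nm in setdiff(phys_param_names, keep)) {
    if (is.na(means[nm])) abort(paste0("No mean supplied for ", nm))
    params[[nm]] <- rep(as.numeric(means[nm]), nrow(params))
  }
  params
}

#' Run the full geometry-to-orifice-area experiment
#'
#' Executes, with per-stage child seeds spawned from the master seed:
#' dataset generation with the closure emulator; `n_splits` random
#' train/test splits each fitting a cross-validation-initialized GP and an
#' OLS baseline and scoring R^2 and MAPE on the test set; a rebuild of the
#' GP on all samples with the length scales of the best-scoring split; the
#' fixing-scheme Sobol analysis of the full surrogate; ranking of the
#' `top_k` influential parameters; density estimation of the orifice area
#' for (a) the emulator, (b) the GP with all parameters varying and (c) the
#' GP with only the influential parameters varying; and the three pairwise
#' total-variation distances.
#'
#' @param cfg An [experiment_config()].
#' @param progress Emit stage messages.
#' @return Object of class `valve_experiment`: list with `data`, `fits`,
#'   `fit_summary`, `gp_lengthscales`, `sobol`, `top_k`, `densities`,
#'   `tv`, `provenance`.
#' @export
run_experiment <- function(cfg = experiment_config(), progress = TRUE) {
  stopifnot(inherits(cfg, "experiment_config"))
  say <- function(...) if (progress) inform(paste0("[valvesens] ", ...))
  seeds <- withr::with_seed(cfg$seed, sample.int(2^31 - 1, 6))

  say("stage 1/6: generating ", cfg$n_samples, " emulated closure samples")
  data <- generate_dataset(cfg$n_samples, seeds[1],
    ranges = cfg$ranges,
    n_stations = cfg$n_stations, constants = cfg$constants,
    noise_sd = cfg$noise_sd
  )

  say("stage 2/6: ", cfg$n_splits, " train/test splits (GP vs linear)")
  split_test_idx <- withr::with_seed(
    seeds[2],
    purrr::map(seq_len(cfg$n_splits), ~ sample.int(cfg$n_samples, cfg$n_test))
  )
  gps <- vector("list", cfg$n_splits)
  fits <- purrr::map_dfr(seq_len(cfg$n_splits), function(i) {
    test <- data[split_test_idx[[i]], ]
    train <- data[-split_test_idx[[i]], ]
    cv <- cv_init_lengthscale(train,
      multipliers = cfg$cv_multipliers,
      seed = (seeds[3] %% 2^30) + i, sigma2 = cfg$sigma2
    )
    gp <- fit_gp(train, sigma2 = cfg$sigma2, init_lengthscales = cv$init)
    gps[[i]] <<- gp
    lr <- fit_linear(train)
    dplyr::bind_rows(
      evaluate_fit(gp, test, "gp", i),
      evaluate_fit(lr, test, "linear", i)
    )
  })
  fit_summary <- dplyr::summarise(dplyr::group_by(fits, .data$model),
    mean_r2 = mean(.data$r2), mean_mape = mean(.data$mape), .groups = "drop"
  )

  say("stage 3/6: rebuilding the surrogate on all samples")
  gp_r2 <- dplyr::filter(fits, .data$model == "gp")$r2
  best <- which.max(gp_r2)
  gp_full <- fit_gp(data,
    sigma2 = cfg$sigma2,
    init_lengthscales = as.numeric(gps[[best]]$lengthscales), optimize = FALSE
  )

  say(
    "stage 4/6: Sobol indices (", cfg$sobol_n_outer, " x ", cfg$sobol_n_inner,
    " per dimension)"
  )
  sampler <- function(n) sample_physical(n, cfg$ranges, quiet = TRUE)
  sobol <- first_order_indices(
    model = function(df) predict(gp_full, df),
    sampler = sampler,
    n_outer = cfg$sobol_n_outer, n_inner = cfg$sobol_n_inner,
    seed = seeds[4]
  )
  top_k <- rank_parameters(sobol, cfg$top_k)

  say("stage 5/6: orifice-area densities (emulator, GP-12, GP-", cfg$top_k, ")")
  means <- physical_means(cfg$ranges, n = cfg$n_means, seed = seeds[5])
  dens <- withr::with_seed(seeds[6], {
    q <- sample_physical(cfg$n_density, cfg$ranges, quiet = TRUE)
    y_sim <- emulate_orifice_area(q, cfg$n_stations, cfg$constants)
    y_gp12 <- predict(gp_full, q)
    y_gp4 <- predict(gp_full, fix_noninfluential(q, top_k, means))
    br <- common_breaks(y_sim, y_gp12, y_gp4, n_bins = cfg$n_bins)
    list(
      sim = estimate_density(y_sim, br),
      gp_all = estimate_density(y_gp12, br),
      gp_top = estimate_density(y_gp4, br)
    )
  })

  say("stage 6/6: total-variation distances")
  tv <- tibble::tibble(
    pair = c("sim_gp12", "sim_gp4", "gp4_gp12"),
    tv = c(
      total_variation(dens$sim, dens$gp_all),
      total_variation(dens$sim, dens$gp_top),
      total_variation(dens$gp_top, dens$gp_all)
    )
  )

  structure(
    list(
      config = cfg, data = data, fits = fits, fit_summary = fit_summary,
      gp_lengthscales = gp_full$lengthscales, sobol = sobol, top_k = top_k,
      densities = dens, tv = tv,
      provenance = list(
        config_hash = rlang::hash(unclass(cfg)),
        master_seed = cfg$seed, stage_seeds = as.integer(seeds),
        package_version = as.character(utils::packageVersion("valvesens"))
      )
    ),
    class = "valve_experiment"
  )
}

#' @export
print.valve_experiment <- function(x, ...) {
  cat("<valve_experiment> n =", x$config$n_samples, "samples,",
      x$config$n_splits, "splits\n")
  print(x$fit_summary)
  cat("influential parameters:", paste(x$top_k, collapse = ", "), "\n")
  print(x$tv)
  invisible(x)
}

#' @export
tidy.valve_experiment <- function(x, ...) x$fits

#' @export
glance.valve_experiment <- function(x, ...) {
  fs <- x$fit_summary
  gp <- fs[fs$model == "gp", ]
  lr <- fs[fs$model == "linear", ]
  tibble::tibble(
    n_samples = x$config$n_samples,
    gp_mean_r2 = gp$mean_r2, gp_mean_mape = gp$mean_mape,
    linear_mean_r2 = lr$mean_r2, linear_mean_mape = lr$mean_mape,
    top_parameters = paste(x$top_k, collapse = ","),
    tv_sim_gp12 = x$tv$tv[x$tv$pair == "sim_gp12"],
    tv_sim_gp4 = x$tv$tv[x$tv$pair == "sim_gp4"],
    tv_gp4_gp12 = x$tv$tv[x$tv$pair == "gp4_gp12"]
  )
}

#' Canonical JSON report of an experiment
#'
#' Deterministic serialization (no timestamps): identical experiments give
#' byte-identical JSON.
#'
#' @param bundle A `valve_experiment`.
#' @return JSON string.
#' @export
report_json <- function(bundle) {
  stopifnot(inherits(bundle, "valve_experiment"))
  obj <- list(
    provenance = bundle$provenance,
    config = list(
      n_samples = bundle$config$n_samples, n_train = bundle$config$n_train,
      n_test = bundle$config$n_test, n_splits = bundle$config$n_splits,
      sigma2 = bundle$config$sigma2,
      sobol_n_outer = bundle$config$sobol_n_outer,
      sobol_n_inner = bundle$config$sobol_n_inner,
      top_k = bundle$config$top_k, seed = bundle$config$seed
    ),
    fit_reports = bundle$fits,
    mean_metrics = bundle$fit_summary,
    gp_lengthscales = as.list(bundle$gp_lengthscales),
    sobol = bundle$sobol$indices,
    sobol_var_y = bundle$sobol$var_y,
    top_parameters = bundle$top_k,
    total_variation = bundle$tv
  )
  as.character(jsonlite::toJSON(obj, dataframe = "columns", auto_unbox = TRUE, digits = NA, pretty = TRUE))
}

#' Write the experiment report to disk
#'
#' Emits `report.json`, `fit_reports.csv`, `sobol_indices.csv`,
#' `total_variation.csv`, `dataset.csv` and (optionally) PNG figures for
#' the Sobol bar chart and the density overlay.
#'
#' @param bundle A `valve_experiment`.
#' @param dir Output directory (created if needed).
#' @param figures Also write PNG figures (default `FALSE`).
#' @return `dir`, invisibly.
#' @export
write_report <- function(bundle, dir, figures = FALSE) {
  stopifnot(inherits(bundle, "valve_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(report_json(bundle), file.path(dir, "report.json"))
  readr::write_csv(bundle$fits, file.path(dir, "fit_reports.csv"))
  readr::write_csv(bundle$sobol$indices, file.path(dir, "sobol_indices.csv"))
  readr::write_csv(bundle$tv, file.path(dir, "total_variation.csv"))
  write_dataset_csv(bundle$data, file.path(dir, "dataset.csv"))
  if (figures) {
    tryCatch(
      {
        ggplot2::ggsave(file.path(dir, "sobol_indices.png"),
          autoplot(bundle$sobol, top_k = bundle$config$top_k),
          width = 7, height = 4, dpi = 150
        )
        ggplot2::ggsave(file.path(dir, "densities.png"),
          plot_density_comparison(bundle$densities),
          width = 7, height = 4, dpi = 150
        )
      },
      error = function(e) warn(paste0("Figure export failed: ", conditionMessage(e)))
    )
  }
  invisible(dir)
}
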