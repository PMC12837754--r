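# CSV interfaces. Parameter tables carry one header row naming the twelve
# columns exactly; datasets add the response column orifice_area_mm2.

param_cols <- function(type = c("normalized", "physical")) {
  switch(match.arg(type), normalized = norm_param_names, physical = phys_param_names)
}

#' Read and write parameter tables as CSV
#'
#' @param params Tibble of parameters.
#' @param path File path.
#' @param type `"normalized"` (range-table column names) or `"physical"`.
#' @return `read_params_csv`: tibble with the twelve columns in canonical
#'   order; `write_params_csv`: `path`, invisibly.
#' @export
write_params_csv <- function(params, path, type = c("normalized", "physical")) {
  cols <- param_cols(type)
  missing <- setdiff(cols, names(params))
  if (length(missing) > 0) abort(paste0("Missing columns: ", paste(missing, collapse = ", ")))
  readr::write_csv(tibble::as_tibble(params)[cols], path)
  invisible(path)
}

#' @rdname write_params_csv
#' @export
read_params_csv <- function(path, type = c("normalized", "physical")) {
  cols <- param_cols(type)
  out <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(cols, names(out))
  if (length(missing) > 0) abort(paste0("Missing columns in ", path, ": ", paste(missing, collapse = ", ")))
  out[cols]
}

#' Read and write geometry-to-orifice-area datasets as CSV
#'
#' A dataset is a physical parameter table plus the `orifice_area_mm2`
#' response column.
#'
#' @param data Dataset tibble (see [generate_dataset()]).
#' @param path File path.
#' @return `read_dataset_csv`: the dataset tibble; `write_dataset_csv`:
#'   `path`, invisibly.
#' @export
write_dataset_csv <- function(data, path) {
  cols <- c(phys_param_names, "orifice_area_mm2")
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) abort(paste0("Missing columns: ", paste(missing, collapse = ", ")))
  readr::write_csv(tibble::as_tibble(data)[cols], path)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  cols <- c(phys_param_names, "orifice_area_mm2")
  missing <- setdiff(cols, names(out))
  if (length(missing) > 0) abort(paste0("Missing columns in ", path, ": ", paste(missing, collapse = ", ")))
  out[cols]
}

#' Read a free-edge curve from CSV (columns x, y, z)
#'
#' @param path File path.
#' @return n x 3 numeric matrix.
#' @export
read_curve_csv <- function(path) {
  as_curve_matrix(readr::read_csv(path, show_col_types = FALSE), path)
}

#' Serialize a fitted GP to JSON (and back)
#'
#' Stores the length scales, noise variance, standardization constants and
#' training data; `gp_from_json` rebuilds the kernel factorization.
#'
#' @param gp A `gp_fit`.
#' @param path File path.
#' @return `gp_to_json`: `path`, invisibly; `gp_from_json`: a `gp_fit`.
#' @export
gp_to_json <- function(gp, path) {
  stopifnot(inherits(gp, "gp_fit"), !isTRUE(gp$constant))
  obj <- list(
    lengthscales = as.numeric(gp$lengthscales),
    sigma2 = gp$sigma2, y_mu = gp$y_mu, y_sd = gp$y_sd,
    predictors = gp$predictors, response = gp$response,
    X_train = apply(gp$X_train, 2, as.numeric, simplify = FALSE),
    y_train = as.numeric(gp$y_train)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname gp_to_json
#' @export
gp_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  data <- tibble::as_tibble(as.data.frame(obj$X_train))
  names(data) <- obj$predictors
  data[[obj$response]] <- obj$y_train
  fit_gp(data,
    response = obj$response, predictors = obj$predictors,
    sigma2 = obj$sigma2, init_lengthscales = obj$lengthscales, optimize = FALSE
  )
}
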