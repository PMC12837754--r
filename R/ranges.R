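#' Default physiological ranges of the twelve geometric parameters
#'
#' The mitral valve is parameterized by twelve geometric quantities: the
#' anteroposterior annular diameter (`AP_D`, mm, measured between the A2 and
#' P2 scallops), the intercommissural diameter ratio (`IC_D_R`), the anterior
#' and posterior leaflet length ratios (`AL_R`, `PL_R`), the commissure
#' length ratio (`CL_R`), the anterior leaflet free-edge bluntness
#' (`Ant_Blunt`), the anterior and posterior annular saddle heights (`AH`,
#' `PH`, mm), the anterior annulus D-shape factor (`D_Shape`), the septal
#' flattening ratio (`SF_Shape_R`), and the commissure location and
#' curvature (`Com_Loc`, `Com_Cur`). Each parameter is sampled uniformly
#' within a physiological range.
#'
#' @return A tibble with columns `name`, `lo`, `hi` (one row per parameter,
#'   twelve rows, in canonical order).
#' @examples
#' default_ranges()
#' @export
default_ranges <- function() {
  tibble::tribble(
    ~name,        ~lo,   ~hi,
    "AP_D",       24.1,  45.2,
    "IC_D_R",     0.97,  1.29,
    "AL_R",       3.2,   7.2,
    "PL_R",       0.16,  1,
    "CL_R",       0.5,   0.75,
    "Ant_Blunt",  0.5,   2.05,
    "AH",         0.3,   0.7,
    "PH",         1,     2,
    "D_Shape",    0,     0.038,
    "SF_Shape_R", 0.01,  0.019,
    "Com_Loc",    0.26,  0.6,
    "Com_Cur",    0.2,   0.6
  )
}

#' Read parameter ranges from a YAML or JSON configuration file
#'
#' The file must contain a mapping from parameter name to a two-element
#' `[lo, hi]` list covering exactly the twelve parameter names of
#' [default_ranges()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A ranges tibble as returned by [default_ranges()].
#' @export
read_ranges_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    abort("Unsupported config extension: ", ext)
  )
  if (!is.null(raw$ranges)) raw <- raw$ranges
  missing <- setdiff(norm_param_names, names(raw))
  if (length(missing) > 0) {
    abort(paste0("Config is missing ranges for: ", paste(missing, collapse = ", ")))
  }
  out <- tibble::tibble(
    name = norm_param_names,
    lo = purrr::map_dbl(norm_param_names, ~ as.numeric(raw[[.x]][[1]])),
    hi = purrr::map_dbl(norm_param_names, ~ as.numeric(raw[[.x]][[2]]))
  )
  validate_ranges(out)
  out
}

validate_ranges <- function(ranges) {
  stopifnot(is.data.frame(ranges), all(c("name", "lo", "hi") %in% names(ranges)))
  if (!setequal(ranges$name, norm_param_names)) {
    abort(paste0(
      "Ranges must cover exactly the 12 parameters: ",
      paste(norm_param_names, collapse = ", ")
    ))
  }
  bad <- ranges$lo > ranges$hi
  if (any(bad)) {
    abort(paste0(
      "Invalid range (lo > hi) for: ",
      paste(ranges$name[bad], collapse = ", ")
    ))
  }
  invisible(ranges)
}

#' Sample normalized geometric parameters uniformly within their ranges
#'
#' Each of the twelve parameters is drawn independently and uniformly on its
#' range. With a fixed `seed` the returned table is bitwise reproducible.
#'
#' @param n Number of samples (may be 0).
#' @param ranges Ranges tibble, see [default_ranges()].
#' @param seed Optional integer seed. When `NULL` the current RNG stream is
#'   used (and advanced), which is what the sensitivity-analysis internals
#'   rely on.
#' @return A tibble with `n` rows and the twelve normalized parameter columns.
#' @examples
#' sample_normalized(3, seed = 1)
#' @export
sample_normalized <- function(n, ranges = default_ranges(), seed = NULL) {
  validate_ranges(ranges)
  stopifnot(length(n) == 1, n >= 0)
  draw <- function() {
    cols <- purrr::map(norm_param_names, function(nm) {
      r <- ranges[ranges$name == nm, ]
      if (n == 0) numeric(0) else runif(n, r$lo, r$hi)
    })
    tibble::as_tibble(setNames(cols, norm_param_names))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
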