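#' Serialise parameter sets
#'
#' Parameter objects round-trip losslessly through a flat named list
#' (`params_to_list()` / `as_scenario_params()`) and through JSON or YAML
#' files (`write_params()` / `read_params()`; the format follows the file
#' extension).
#'
#' @param params A [scenario_params] object.
#' @return `params_to_list()`: a plain named list with a `scenario` entry;
#'   `as_scenario_params()`: a validated parameter object;
#'   `read_params()`/`write_params()`: the parameter object (invisibly for
#'   the writer).
#' @export
#' @examples
#' p <- default_params("sharing")
#' identical(as_scenario_params(params_to_list(p)), p)
params_to_list <- function(params) {
  stopifnot(inherits(params, "niche_params"))
  out <- unclass(params)
  out[!purrr::map_lgl(out, is.null)]
}

#' @rdname params_to_list
#' @param x A named list with a `scenario` entry and constructor fields
#'   (unknown keys are rejected).
#' @export
as_scenario_params <- function(x) {
  if (inherits(x, "niche_params")) return(x)
  stopifnot(is.list(x), !is.null(x$scenario))
  ctor <- switch(as.character(x$scenario),
    additional = additional_resources,
    multiple = multiple_habitats,
    sharing = interstage_sharing,
    stop(sprintf("unknown scenario '%s'", x$scenario), call. = FALSE)
  )
  args <- x[setdiff(names(x), "scenario")]
  unknown <- setdiff(names(args), names(formals(ctor)))
  if (length(unknown)) {
    stop(sprintf("unknown parameter field(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  do.call(ctor, args)
}

#' @rdname params_to_list
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @export
write_params <- function(params, path) {
  lst <- params_to_list(params)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(lst, path)
  } else {
    stop("unsupported config format: use .json or .yaml", call. = FALSE)
  }
  invisible(params)
}

#' @rdname params_to_list
#' @export
read_params <- function(path) {
  lst <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    stop("unsupported config format: use .json or .yaml", call. = FALSE)
  }
  as_scenario_params(lst)
}

#' Random parameter fixtures around the reference defaults
#'
#' Draws reproducible random parameter sets by jittering every rate of the
#' scenario's [default_params()] by an independent uniform factor in
#' `1 + c(-jitter, jitter)`. Conversion efficiencies are capped at 1;
#' structural fields (resource/habitat counts, subsidy flags) are kept at
#' their defaults.
#'
#' @param n Number of fixtures.
#' @param scenario One of `"additional"`, `"multiple"`, `"sharing"`.
#' @param seed Integer seed; the global RNG state is left untouched.
#' @param jitter Half-width of the relative jitter (default 0.5, i.e. each
#'   rate varies within +/-50% of its default).
#' @return List of [scenario_params] objects.
#' @export
#' @examples
#' generate_fixture_params(2, "sharing", seed = 1)
generate_fixture_params <- function(n, scenario, seed, jitter = 0.5) {
  stopifnot(n >= 1, jitter >= 0, jitter < 1)
  base <- params_to_list(default_params(scenario))
  numeric_fields <- setdiff(
    names(base)[purrr::map_lgl(base, is.numeric)],
    c("n_J", "n_A", "I_J", "I_A", "l_J", "l_A")
  )
  make_one <- function() {
    lst <- base
    for (f in numeric_fields) {
      fac <- stats::runif(length(lst[[f]]), 1 - jitter, 1 + jitter)
      lst[[f]] <- lst[[f]] * fac
      if (grepl("^b_", f)) lst[[f]] <- pmin(lst[[f]], 1)
    }
    as_scenario_params(lst)
  }
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  replicate(n, make_one(), simplify = FALSE)
}
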