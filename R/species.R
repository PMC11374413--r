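#' Load the shipped species parameter sets
#'
#' Returns the fitted thermal reaction-norm parameter set for one of the
#' shipped species: `"bagrada"` (invasive, subtropical), `"harlequin"`
#' (naturalized, Mediterranean-adapted), or `"generic"` (a synthetic
#' warm-adapted ectotherm with exponential maturation, used for qualitative
#' model analyses).
#'
#' @param name species label.
#' @return a [species_traits()] object.
#' @export
#' @examples
#' tn_species("harlequin")
tn_species <- function(name = c("bagrada", "harlequin", "generic")) {
  name <- match.arg(name)
  load_species(system.file("extdata", paste0(name, ".json"),
                           package = "thermalniche", mustWork = TRUE))
}

# Parse one fixture block; returns list(value=..) or list(errors=..) with
# errors prefixed by the block name.
parse_block <- function(x, block, builder) {
  b <- x[[block]]
  if (is.null(b)) return(list(errors = sprintf("missing block `%s`", block)))
  get <- function(field, optional = FALSE) {
    v <- unlist(b[[field]])
    if (is.null(v) || length(v) == 0 || (length(v) == 1 && is.na(v))) {
      if (optional) return(NULL)
      abort(sprintf("%s.%s: required field is missing", block, field))
    }
    if (!is.numeric(v)) abort(sprintf("%s.%s: not numeric", block, field))
    as.numeric(v)
  }
  tryCatch(list(value = builder(get)),
           error = function(e) list(errors = paste0(block, ": ", conditionMessage(e))))
}

#' Validate a species fixture file
#'
#' Parses a JSON species file, checks every field and type invariant, and
#' returns either the valid [species_traits()] object or a character vector
#' listing each violated field. Field names mirror the conventional
#' reaction-norm symbols (`b_topt`, `t_opt_b`, `s`; `m_tr`, `a_m`, `a_l`,
#' `t_l_half`, `a_h`, `t_h_half`; `d_jtr`, `a_dj`; `d_atr`, `a_da`).
#' Partial records are refused.
#'
#' @param path path to a JSON species file.
#' @return a `species_traits` object, or a character vector of error messages
#'   (class `"fixture_errors"`) when validation fails.
#' @export
validate_fixture <- function(path) {
  if (!file.exists(path))
    return(structure(paste0("no such fixture: ", path), class = "fixture_errors"))
  x <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) NULL)
  if (is.null(x))
    return(structure(paste0("not parseable as JSON: ", path), class = "fixture_errors"))
  blocks <- list(
    birth = function(get)
      gaussian_params(get("b_topt"), get("t_opt_b"), get("s")),
    maturation = function(get)
      schoolfield_params(get("m_tr"), get("a_m"), t_ref = get("t_r"),
                         a_low = get("a_l", TRUE), t_half_low = get("t_l_half", TRUE),
                         a_high = get("a_h", TRUE), t_half_high = get("t_h_half", TRUE)),
    juvenile_mortality = function(get)
      arrhenius_params(get("d_jtr"), get("a_dj"), t_ref = get("t_r")),
    adult_mortality = function(get)
      arrhenius_params(get("d_atr"), get("a_da"), t_ref = get("t_r"))
  )
  parsed <- lapply(names(blocks), function(nm) parse_block(x, nm, blocks[[nm]]))
  errs <- unlist(lapply(parsed, `[[`, "errors"))
  if (is.null(x$name) || !nzchar(x$name %||% ""))
    errs <- c(errs, "name: required field is missing")
  if (length(errs)) return(structure(errs, class = "fixture_errors"))
  species_traits(x$name, parsed[[1]]$value, parsed[[2]]$value,
                 parsed[[3]]$value, parsed[[4]]$value)
}

#' Read a species parameter fixture
#'
#' Strict variant of [validate_fixture()]: throws a configuration error
#' listing every violated field instead of returning them.
#'
#' @param path path to a JSON species file.
#' @return a [species_traits()] object.
#' @export
load_species <- function(path) {
  res <- validate_fixture(path)
  if (inherits(res, "fixture_errors"))
    abort(paste0("invalid species fixture:\n", paste0("  - ", res, collapse = "\n")),
          class = "thermalniche_config_error")
  res
}

#' @export
print.fixture_errors <- function(x, ...) {
  cat("fixture validation failed:\n")
  cat(paste0("  - ", unclass(x), collapse = "\n"), "\n")
  invisible(x)
}
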