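#' Normalize a concept name for matching
#'
#' Matching of concept names throughout the package is case-insensitive with
#' internal whitespace collapsed; no synonym expansion is performed (concept
#' names are taken as given, there is no UMLS dependency).
#'
#' @param x character vector of concept names.
#' @return character vector of normalized names.
#' @examples
#' normalize_name("  Congestive   Heart Failure ")
#' @export
normalize_name <- function(x) {
  tolower(gsub("\\s+", " ", trimws(as.character(x))))
}

# Classed conditions so callers (and the command-line wrapper) can map
# failure modes to exit codes without string matching.
stop_empty_input <- function(message, ...) {
  abort(message, class = "semsumm_empty_input_error", ...)
}

stop_format <- function(message, ...) {
  abort(message, class = "semsumm_format_error", ...)
}

stop_usage <- function(message, ...) {
  abort(message, class = "semsumm_usage_error", ...)
}

# Split comma-joined semantic-type codes into a list column entry.
split_semtypes <- function(x) {
  lapply(strsplit(as.character(x), ",", fixed = TRUE), function(s) {
    s <- trimws(s)
    s[nzchar(s)]
  })
}

join_semtypes <- function(x) {
  vapply(x, paste, character(1), collapse = ",")
}

assert_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) == 0 || anyNA(x) ||
      any(x < min) || any(x != floor(x))) {
    abort(sprintf("`%s` must contain integers >= %d", name, min),
          class = "semsumm_argument_error")
  }
  invisible(x)
}
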