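#' @keywords internal
"_PACKAGE"

#' @useDynLib itbregnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Internal: stop with a consistent validation-error class so callers/tests can
# distinguish bad input from bugs.
validation_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("itb_validation_error", "error")))
}

parse_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("itb_parse_error", "error")))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}
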