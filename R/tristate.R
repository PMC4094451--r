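#' Tri-state values
#'
#' State variables of molecule components take one of three values:
#' `"on"`, `"off"` or `"dont_care"`. Stored complexes inside reaction rules
#' are patterns and may legitimately carry `"dont_care"`; concrete search
#' patterns default unconstrained variables to `"dont_care"`.
#'
#' @return `tri_states()` returns the character vector of the three legal
#'   values, in the order `on`, `off`, `dont_care`.
#' @export
#' @examples
#' tri_states()
tri_states <- function() c("on", "off", "dont_care")

is_tri_state <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) && x %in% tri_states()
}

#' Tri-state overlap matching
#'
#' Two tri-state values match when either is `"dont_care"` or both are
#' equal. This is the matching relation used by state search: a query
#' `"dont_care"` matches stored `"on"` and `"off"`, and a stored
#' `"dont_care"` (a rule pattern) likewise matches any query value.
#'
#' @param a,b tri-state values (`"on"`, `"off"` or `"dont_care"`).
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' tri_match("dont_care", "off")
#' tri_match("on", "off")
tri_match <- function(a, b) {
  stopifnot(is_tri_state(a), is_tri_state(b))
  a == "dont_care" || b == "dont_care" || a == b
}
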