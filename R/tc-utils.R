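#' Transporter Classification (TC) number utilities
#'
#' TC numbers have 3-5 dot-separated components:
#' `class.subclass.family[.subfamily[.serial]]`, e.g. `2.A.1.1.1`.  The first
#' component is an integer (the TC class), the second a letter, the rest
#' integers.  The *family* is the first four components and the superfamily
#' ("TCS") the first three.
#'
#' @name tc-utils
NULL

.TC_REGEX <- "^[0-9]+\\.[A-Za-z](\\.[0-9]+){1,3}$"

#' Validate TC number grammar
#' @param tc character vector.
#' @return logical vector.
#' @export
is_valid_tc <- function(tc) {
  grepl(.TC_REGEX, trimws(tc))
}

#' Truncate a TC number to its leading components
#'
#' `tc_prefix(tc, 3)` gives the superfamily (TCS) number, `tc_prefix(tc, 4)`
#' the family.  Numbers already at or below the requested depth are returned
#' unchanged, so the roll-up is idempotent.
#'
#' @param tc character vector of TC numbers.
#' @param n_components number of leading components to keep.
#' @return character vector.
#' @export
tc_prefix <- function(tc, n_components = 3L) {
  vapply(strsplit(trimws(tc), ".", fixed = TRUE), function(p) {
    paste(p[seq_len(min(length(p), n_components))], collapse = ".")
  }, character(1))
}

#' TC class (first component) of a TC number
#' @param tc character vector of TC numbers.
#' @return character vector of class digits.
#' @export
tc_class <- function(tc) {
  sub("\\..*$", "", trimws(tc))
}
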