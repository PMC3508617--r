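#' Enzyme Commission number utilities
#'
#' Helpers shared by every module that touches EC numbers: normalization,
#' validation, partial/complete tests, prefix matching and the leading-digit
#' enzyme-class lookup.
#'
#' An EC number is four dot-separated components, `class.subclass.subsubclass.
#' serial`; trailing components may be the placeholder `-`, in which case the
#' number is *partial* (e.g. `3.2.2.-`).  Typographic dashes (en/em) are
#' canonicalized to the ASCII hyphen so `3.2.2.-` and `3.2.2.–` compare
#' equal.
#'
#' @name ec-utils
NULL

# canonical EC grammar after normalization: digits, then three components each
# digits-or-dash
.EC_REGEX <- "^[0-9]+(\\.([0-9]+|-)){3}$"

#' Normalize an EC number string
#'
#' Trims whitespace and canonicalizes en-dash/em-dash/minus characters to the
#' ASCII hyphen used as the partial-component placeholder.
#'
#' @param ec character vector of raw EC strings.
#' @return character vector of normalized EC strings.
#' @export
#' @examples
#' normalize_ec(c(" 1.1.1.1", "3.2.2.–"))
normalize_ec <- function(ec) {
  ec <- trimws(ec)
  # en dash, em dash, minus sign, figure dash -> hyphen
  gsub("[‐‒–—−]", "-", ec)
}

#' Validate EC number grammar
#'
#' @param ec character vector (normalized or not).
#' @return logical vector, `TRUE` where the string is a well-formed complete
#'   or partial EC number.
#' @export
is_valid_ec <- function(ec) {
  grepl(.EC_REGEX, normalize_ec(ec))
}

#' Is an EC number partial?
#'
#' A partial EC number carries at least one `-` placeholder component.
#'
#' @param ec character vector.
#' @return logical vector.
#' @export
is_partial_ec <- function(ec) {
  grepl("-", normalize_ec(ec), fixed = TRUE)
}

#' Does a complete EC number refine a partial one?
#'
#' `ec_refines("3.2.2.27", "3.2.2.-")` is `TRUE`: every non-placeholder
#' component of the partial number matches the complete one.  A complete
#' number does not refine a different complete number, and the relation is
#' reflexive on equal strings.
#'
#' @param complete candidate refining EC string (scalar).
#' @param partial EC string possibly containing `-` placeholders (scalar).
#' @return logical scalar.
#' @export
ec_refines <- function(complete, partial) {
  complete <- normalize_ec(complete)
  partial <- normalize_ec(partial)
  if (identical(complete, partial)) return(TRUE)
  pc <- strsplit(partial, ".", fixed = TRUE)[[1L]]
  cc <- strsplit(complete, ".", fixed = TRUE)[[1L]]
  if (length(pc) != 4L || length(cc) != 4L) return(FALSE)
  all(pc == "-" | pc == cc)
}

#' Enzyme class from the leading EC digit
#'
#' @param ec character vector of EC strings.
#' @return character vector: one of `oxidoreductase`, `transferase`,
#'   `hydrolase`, `lyase`, `isomerase`, `ligase`, or `NA` for any other
#'   leading digit.
#' @export
ec_class <- function(ec) {
  lead <- sub("\\..*$", "", normalize_ec(ec))
  classes <- c("oxidoreductase", "transferase", "hydrolase",
               "lyase", "isomerase", "ligase")
  out <- rep(NA_character_, length(ec))
  idx <- suppressWarnings(as.integer(lead))
  ok <- !is.na(idx) & idx >= 1L & idx <= 6L
  out[ok] <- classes[idx[ok]]
  out
}

#' Split a comma-delimited EC field into a normalized character vector
#'
#' Empty fields give `character(0)`.  Used by every TSV reader that stores EC
#' sets in a single column.
#'
#' @param field scalar character (may be `NA` or empty).
#' @param validate error on malformed EC strings when `TRUE`.
#' @return character vector of normalized EC strings.
#' @export
split_ec_field <- function(field, validate = TRUE) {
  if (is.na(field) || !nzchar(trimws(field))) return(character(0))
  ecs <- normalize_ec(strsplit(field, ",", fixed = TRUE)[[1L]])
  ecs <- ecs[nzchar(ecs)]
  if (validate && any(!is_valid_ec(ecs))) {
    stop("malformed EC number(s): ",
         paste(ecs[!is_valid_ec(ecs)], collapse = ", "))
  }
  ecs
}

# equality of two EC sets after normalization (order-free)
ec_sets_equal <- function(a, b) {
  setequal(normalize_ec(a), normalize_ec(b))
}
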