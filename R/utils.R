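`%||%` <- function(x, y) if (is.null(x)) y else x

#' Extract a document-relative, 0-based character slice
#'
#' All offsets in the BioC data model are 0-based character counts from the
#' start of the document text.
#'
#' @param text character scalar.
#' @param offset 0-based start.
#' @param length number of characters.
#' @return the covered substring.
#' @keywords internal
#' @noRd
substr0 <- function(text, offset, length) {
  substr(text, offset + 1L, offset + length)
}

#' Read an infon value
#'
#' @param x any BioC element carrying an `infons` list.
#' @param key infon key.
#' @param default value returned when the key is absent.
#' @return character scalar or `default`.
#' @export
infon <- function(x, key, default = NULL) {
  v <- x$infons[[key]]
  if (is.null(v)) default else v
}

#' Set an infon value
#'
#' @param x any BioC element carrying an `infons` list.
#' @param key infon key.
#' @param value coerced to character.
#' @return the modified element.
#' @export
set_infon <- function(x, key, value) {
  x$infons[[key]] <- as.character(value)
  x
}

# deterministic number formatting for infons (scores etc.)
format_score <- function(x) sprintf("%.6f", x)

as_integer_strict <- function(x, what) {
  v <- suppressWarnings(as.integer(x))
  if (any(is.na(v)) || any(v != as.numeric(x))) {
    stop(sprintf("%s must be a non-negative integer, got '%s'", what, x), call. = FALSE)
  }
  v
}
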