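#' Round half away from zero
#'
#' Label-style rounding used for displayed percentages: halves always round
#' up in magnitude (base [round()] rounds halves to even).
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 2.5)) # 1 2 3, not 0 2 2
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

## internal: stop with a data-validation message listing offending rows
validation_error <- function(msg, rows = NULL) {
  if (!is.null(rows) && length(rows) > 0) {
    msg <- paste0(msg, " (row", if (length(rows) > 1) "s", " ",
                  paste(rows, collapse = ", "), ")")
  }
  abort(msg, class = "nutriclaim_validation_error")
}

## internal: TRUE where x is present (non-NA)
has_value <- function(x) !is.na(x)

## internal: named empty-string-safe paste for messages
comma <- function(x) paste(x, collapse = ", ")
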