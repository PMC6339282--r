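#' Round half away from zero
#'
#' Report-style rounding: exact halves move away from zero, matching the
#' convention of the published tables (base `round()` rounds half to even).
#' Internal statistics are never rounded; this is applied only when
#' formatting percentages and test statistics for output.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_apobec3 <- function(..., class = "apobec3pop_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

#' @noRd
is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == as.integer(x)
}

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' Classify a single-nucleotide substitution
#'
#' @param ref,alt single-character nucleotide strings.
#' @return `"transition"` (purine-purine or pyrimidine-pyrimidine) or
#'   `"transversion"`.
#' @export
substitution_class <- function(ref, alt) {
  stopifnot(nchar(ref) == 1L, nchar(alt) == 1L, ref != alt)
  same_family <- (ref %in% PURINES) == (alt %in% PURINES)
  if (same_family) "transition" else "transversion"
}
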