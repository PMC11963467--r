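#' Round half away from zero to the nearest integer
#'
#' Commercial ("half-up") rounding, as opposed to the IEEE banker's rounding
#' of [base::round()]. All printed coverage percentages use this rule.
#'
#' @param x numeric vector
#' @return integer vector
#' @examples
#' round_half_up(c(0.5, 1.5, 2.4))
#' @export
round_half_up <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Integer percentage with half-up rounding
#'
#' @param n numerator count
#' @param d denominator count; a zero denominator yields 0
#' @return integer percent in 0..100
#' @export
pct_of <- function(n, d) {
  if (d == 0) return(0L)
  round_half_up(100 * n / d)
}

# internal: non-empty scalar string after trimming
chr1 <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single string", what))
  }
  x <- trimws(x)
  if (!nzchar(x)) abort(sprintf("`%s` must be non-empty", what))
  x
}

# internal: stable unit separator for composite keys
SEP <- "\u001f"

# internal: sort a list of records by a character key
sort_by_key <- function(x, key_fn) {
  if (length(x) == 0L) return(x)
  x[order(vapply(x, key_fn, character(1)), method = "radix")]
}
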