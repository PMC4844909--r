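#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going up (0.5 -> 1), the
#' convention used throughout the package when printing counts as
#' percentages and ratings as means.  Base [round()] uses banker's
#' rounding and would print 59/151 as 39.0 rather than 39.1.
#'
#' @param x Numeric vector (non-negative values expected).
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(100 * 59 / 151, 1)  # 39.1
#' round_half_up(8 / 3, 2)           # 2.67
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # the tiny offset absorbs binary representation error in values such as
  # 266.49999999999997 that are exactly x.5 in decimal
  floor(x * p + 0.5 + 1e-9) / p
}

stop_pddi <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == trunc(x)
}

is_probability <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

#' Path to a file shipped with the package
#'
#' @param file File name under `extdata/` (empty to list the directory).
#' @return Absolute path to the installed file.
#' @export
pddikit_extdata <- function(file = "") {
  path <- system.file("extdata", file, package = "pddikit")
  if (identical(path, "")) {
    stop_pddi("no packaged file '%s'", file)
  }
  path
}

# Largest-remainder apportionment of `total` into parts proportional to
# `weights`; deterministic (ties broken by position).  Used for length-
# stratified scenario allocation and for scaling the default scenario
# sizes to corpora that are not 208 sections.
apportion <- function(total, weights) {
  if (total == 0L) {
    return(rep(0L, length(weights)))
  }
  quota <- total * weights / sum(weights)
  base <- floor(quota)
  short <- total - sum(base)
  if (short > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}
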