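#' Round half away from zero
#'
#' Report-style rounding: ties go away from zero (so 0.845 -> 0.85 at two
#' decimals), unlike [round()] which rounds half to even. Used for all
#' table-facing output; internal computation is always full precision.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(c(0.25, 0.35), 1)  # 0.3, 0.4
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # small guard against representation error just below a .5 boundary
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# sample SD with the n-1 denominator; NA when fewer than 2 values
sample_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x)
}

# moment-based skewness, m3 / m2^(3/2) (biased / population form)
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(NA_real_)
  mean((x - m)^3) / m2^1.5
}

stop_midsat <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "midsat_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
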