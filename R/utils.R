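#' Truncated percentage
#'
#' Computes `100 * count / total` truncated (not rounded) to `digits` decimal
#' places. Truncation is the display convention used throughout the package:
#' 309/326 -> 94.7, 37/70 -> 52.8, 30/70 -> 42.8.
#'
#' @param count Numerator count.
#' @param total Denominator count (> 0).
#' @param digits Decimal places to keep (default 1).
#' @return Numeric percentage, truncated.
#' @examples
#' trunc_pct(309, 326)      # 94.7
#' trunc_pct(20, 70, 2)     # 28.57
#' @export
trunc_pct <- function(count, total, digits = 1) {
  if (any(total <= 0)) stop("total must be positive")
  # tiny epsilon guards against 52.799999... artefacts of binary floats
  trunc(100 * count / total * 10^digits + 1e-9) / 10^digits
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (the convention of most clinical
#' calculators), unlike [round()]'s round-half-even. Applied only at
#' serialization / display time.
#'
#' @param x Numeric vector (non-negative in this package's use).
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  scaled <- x * 10^digits
  # relative epsilon so decimal literals sitting just under a .5 boundary
  # in binary (e.g. 2.675 * 100 = 267.4999...) still round up
  floor(scaled + 0.5 + abs(scaled) * 1e-12 + 1e-12) / 10^digits
}

#' Format a truncated percentage string
#' @param count,total,digits As in [trunc_pct()].
#' @return Character like "52.8%".
#' @export
format_pct <- function(count, total, digits = 1) {
  sprintf(paste0("%.", digits, "f%%"), trunc_pct(count, total, digits))
}

# split a ";"-separated field into a character vector, dropping empties
split_semi <- function(x) {
  if (length(x) != 1 || is.na(x) || !nzchar(x)) return(character(0))
  v <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  v[nzchar(v)]
}

join_semi <- function(x) paste(x, collapse = ";")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items.
#' Labels may be any atomic type; only the induced partitions matter.
#'
#' @param x,y Label vectors of equal length.
#' @return ARI in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) == 0) return(1)
  tab <- table(x, y)
  comb2 <- function(n) n * (n - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n_pairs <- comb2(length(x))
  expected <- sum_i * sum_j / n_pairs
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
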