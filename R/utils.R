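# Internal helpers shared across modules.

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Coefficient of determination
#'
#' R-squared in the conventional regression sense, `1 - SSE/SST`, with the
#' total sum of squares taken about the mean of `obs`. Returns `NA` when
#' `obs` has zero variance (the statistic is undefined there).
#'
#' @param obs numeric vector of observed values.
#' @param pred numeric vector of predictions, same length as `obs`.
#' @return A single number `<= 1`, or `NA` for degenerate `obs`.
#' @export
r_squared <- function(obs, pred) {
  stopifnot(length(obs) == length(pred))
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((obs - pred)^2) / sst
}

assert_scalar_num <- function(x, name, lo = -Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  bound_ok <- if (allow_zero) x >= lo else x > lo
  if (!bound_ok) {
    stop(sprintf("`%s` must be %s %s", name,
                 if (allow_zero) ">=" else ">", lo), call. = FALSE)
  }
  invisible(x)
}

# Row-major flattening of an LDP grid (row 0 nearest the light source first).
flatten_ldp <- function(ldp) as.vector(t(ldp))

unflatten_ldp <- function(v, rows = 18L, cols = 40L) {
  matrix(v, nrow = rows, ncol = cols, byrow = TRUE)
}
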