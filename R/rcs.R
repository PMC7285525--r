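#' Restricted cubic spline basis
#'
#' Natural (restricted) cubic spline columns in the truncated-power
#' parameterisation: piecewise cubic between the knots and constrained to
#' be linear beyond the boundary knots. With k knots the basis has k-1
#' columns (the linear term plus k-2 nonlinear ones); the default three
#' knots sit at the 5th, 50th and 95th percentiles, giving a linear and
#' one nonlinear column.
#'
#' @param x numeric vector.
#' @param knots explicit knot locations, or `NULL` to place them at
#'   `percentiles` of `x`.
#' @param percentiles knot percentiles used when `knots` is `NULL`.
#' @return matrix with columns `x`, `x'`, `x''`, ... and attribute
#'   `knots`; duplicate knots are an error suggesting fewer knots.
#' @export
rcs_basis <- function(x, knots = NULL, percentiles = c(5, 50, 95)) {
  if (is.null(knots)) {
    knots <- unname(stats::quantile(x, percentiles / 100, na.rm = TRUE,
                                    type = 7))
  }
  knots <- sort(knots)
  if (anyDuplicated(knots)) {
    stop("duplicate knots (too few distinct values); use fewer knots")
  }
  k <- length(knots)
  stopifnot(k >= 3L)
  tk <- knots[k]
  tk1 <- knots[k - 1L]
  norm <- (tk - knots[1L])^2
  pos3 <- function(u) pmax(u, 0)^3
  cols <- vapply(seq_len(k - 2L), function(j) {
    tj <- knots[j]
    (pos3(x - tj) -
       pos3(x - tk1) * (tk - tj) / (tk - tk1) +
       pos3(x - tk) * (tk1 - tj) / (tk - tk1)) / norm
  }, numeric(length(x)))
  out <- cbind(x, cols)
  colnames(out) <- c("x", paste0("x", strrep("'", seq_len(k - 2L))))
  attr(out, "knots") <- knots
  out
}
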