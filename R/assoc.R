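#' Partial Spearman correlation
#'
#' Spearman-flavoured partial correlation: all variables are rank
#' transformed, x and y are each projected onto the control variables by
#' least squares, and the partial correlation is the Pearson correlation of
#' the residuals. The P-value uses the t statistic
#' \eqn{t = \rho \sqrt{(n - k - 2)/(1 - \rho^2)}} on n - k - 2 degrees of
#' freedom (k = number of controls). The zero-order Spearman correlation
#' (no controls) is reported alongside. Used to relate a taxon's relative
#' abundance to the assembly SES while controlling for the other taxa.
#'
#' @param x,y numeric vectors of equal length.
#' @param controls optional numeric matrix/data.frame of control variables
#'   (columns), same number of rows; constant controls are dropped with a
#'   warning; with no controls the result reduces to the zero-order
#'   Spearman correlation.
#' @param x_name,y_name labels carried into the result.
#' @return A list of class `partial_corr`: `x_name`, `y_name`, `controls`,
#'   `rho`, `p_value`, `n`, `zero_order_rho`.
#' @export
partial_spearman <- function(x, y, controls = NULL, x_name = "x",
                             y_name = "y") {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("x and y must not be constant")
  if (!is.null(controls)) {
    controls <- as.matrix(controls)
    if (nrow(controls) != n) stop("controls must have the same length")
    const <- apply(controls, 2, function(v) stats::sd(v) == 0)
    if (any(const)) {
      warning(sum(const), " constant control(s) dropped")
      controls <- controls[, !const, drop = FALSE]
    }
    if (ncol(controls) == 0L) controls <- NULL
  }
  k <- if (is.null(controls)) 0L else ncol(controls)
  if (n <= k + 2L) stop("need n > number of controls + 2")

  rx <- rank(x); ry <- rank(y)
  zero_order <- stats::cor(rx, ry)
  if (k == 0L) {
    rho <- zero_order
  } else {
    rz <- apply(controls, 2, rank)
    if (qr(cbind(1, rz))$rank < k + 1L) stop("singular control matrix")
    ex <- stats::lm.fit(cbind(1, rz), rx)$residuals
    ey <- stats::lm.fit(cbind(1, rz), ry)$residuals
    rho <- stats::cor(ex, ey)
  }
  df <- n - k - 2L
  tstat <- rho * sqrt(df / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = df)
  structure(list(x_name = x_name, y_name = y_name,
                 controls = if (k) colnames(controls) %||% paste0("c", 1:k)
                            else character(0),
                 rho = rho, p_value = p, n = n,
                 zero_order_rho = zero_order),
            class = "partial_corr")
}

#' @export
print.partial_corr <- function(x, ...) {
  cat(sprintf(
    "partial Spearman %s ~ %s | %d control(s): rho=%.3f (P=%.3g), zero-order=%.3f\n",
    x$x_name, x$y_name, length(x$controls), x$rho, x$p_value,
    x$zero_order_rho))
  invisible(x)
}
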